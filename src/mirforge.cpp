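#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <set>
using namespace Rcpp;

// Internal scan kernels. Coordinates are 0-based half-open throughout; the R
// wrappers own validation and any 1-based presentation.

static const int KANCHOR = 6; // floor(min read length 18 / 3)

static inline char comp_base(char c) {
  switch (c) {
  case 'A': return 'T';
  case 'C': return 'G';
  case 'G': return 'C';
  case 'T': return 'A';
  default:  return 'N';
  }
}

static std::string revcomp(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (size_t i = 0; i < r.size(); ++i) r[i] = comp_base(r[i]);
  return r;
}

static inline int base2(char c) {
  switch (c) {
  case 'A': return 0;
  case 'C': return 1;
  case 'G': return 2;
  case 'T': return 3;
  default:  return -1; // N: never indexed, never matches
  }
}

// Hamming distance with early abort; N on either side counts as mismatch.
static inline int hamming_capped(const std::string& a, const std::string& b,
                                 size_t bo, int cap) {
  int mm = 0;
  for (size_t i = 0; i < a.size(); ++i) {
    char x = a[i], y = b[bo + i];
    if (x != y || x == 'N') {
      if (++mm > cap) return mm;
    }
  }
  return mm;
}

// [[Rcpp::export]]
DataFrame cpp_map_reads(CharacterVector reads, CharacterVector ref_seqs,
                        int max_mm) {
  int nref = ref_seqs.size();
  std::vector<std::string> refs(nref);
  for (int i = 0; i < nref; ++i) refs[i] = as<std::string>(ref_seqs[i]);

  // k-mer index over all references: key -> (ref, pos) pairs
  std::unordered_map<uint32_t, std::vector<std::pair<int, int> > > index;
  for (int r = 0; r < nref; ++r) {
    const std::string& s = refs[r];
    if ((int)s.size() < KANCHOR) continue;
    uint32_t key = 0; int valid = 0;
    for (size_t p = 0; p < s.size(); ++p) {
      int b = base2(s[p]);
      if (b < 0) { valid = 0; key = 0; continue; }
      key = ((key << 2) | (uint32_t)b) & ((1u << (2 * KANCHOR)) - 1u);
      if (++valid >= KANCHOR)
        index[key].push_back(std::make_pair(r, (int)p - KANCHOR + 1));
    }
  }

  std::vector<int> out_read, out_ref, out_start, out_mm;
  std::vector<char> out_strand;

  int nreads = reads.size();
  for (int q = 0; q < nreads; ++q) {
    std::string fwd = as<std::string>(reads[q]);
    int L = (int)fwd.size();
    if (L < KANCHOR) continue;
    std::string rev = revcomp(fwd);
    for (int strand = 0; strand < 2; ++strand) {
      const std::string& rd = strand == 0 ? fwd : rev;
      // pigeonhole: with <= max_mm mismatches, at least one of (max_mm + 1)
      // equal thirds is an exact match, so anchor each segment start
      int nseg = max_mm + 1;
      int seg = L / nseg;
      if (seg < KANCHOR) seg = KANCHOR; // fall back: may scan extra anchors
      std::set<std::pair<int, int> > seen;
      for (int a = 0; a + KANCHOR <= L; a += seg) {
        uint32_t key = 0; bool ok = true;
        for (int i = 0; i < KANCHOR; ++i) {
          int b = base2(rd[a + i]);
          if (b < 0) { ok = false; break; }
          key = (key << 2) | (uint32_t)b;
        }
        if (!ok) continue;
        std::unordered_map<uint32_t,
          std::vector<std::pair<int, int> > >::const_iterator it =
          index.find(key);
        if (it == index.end()) continue;
        for (size_t h = 0; h < it->second.size(); ++h) {
          int r = it->second[h].first;
          int start = it->second[h].second - a;
          if (start < 0 || start + L > (int)refs[r].size()) continue;
          std::pair<int, int> cand(r, start);
          if (!seen.insert(cand).second) continue;
          int mm = hamming_capped(rd, refs[r], (size_t)start, max_mm);
          if (mm <= max_mm) {
            out_read.push_back(q + 1);
            out_ref.push_back(r + 1);
            out_start.push_back(start);
            out_mm.push_back(mm);
            out_strand.push_back(strand == 0 ? '+' : '-');
          }
        }
      }
    }
  }

  int n = (int)out_read.size();
  CharacterVector strand_col(n);
  for (int i = 0; i < n; ++i)
    strand_col[i] = std::string(1, out_strand[i]);
  return DataFrame::create(
    _["read"] = wrap(out_read), _["ref"] = wrap(out_ref),
    _["strand"] = strand_col, _["start"] = wrap(out_start),
    _["mismatches"] = wrap(out_mm), _["stringsAsFactors"] = false);
}

// DUST-style low-complexity score: sum over distinct 3-mers of c(c-1)/2,
// divided by (#triplets - 1). High for repeats/homopolymers, ~0 for random.
// [[Rcpp::export]]
NumericVector cpp_dust_score(CharacterVector seqs) {
  int n = seqs.size();
  NumericVector out(n);
  for (int q = 0; q < n; ++q) {
    std::string s = as<std::string>(seqs[q]);
    int L = (int)s.size();
    int ntrip = L - 2;
    if (ntrip < 2) { out[q] = 0.0; continue; }
    std::unordered_map<uint32_t, int> counts;
    for (int i = 0; i < ntrip; ++i) {
      int b0 = base2(s[i]), b1 = base2(s[i + 1]), b2 = base2(s[i + 2]);
      uint32_t key = (b0 < 0 || b1 < 0 || b2 < 0)
        ? 64u + (uint32_t)i  // triplets with N are unique, score-neutral
        : (uint32_t)(b0 * 16 + b1 * 4 + b2);
      counts[key]++;
    }
    double sc = 0.0;
    for (std::unordered_map<uint32_t, int>::const_iterator it = counts.begin();
         it != counts.end(); ++it) {
      double c = (double)it->second;
      sc += c * (c - 1.0) / 2.0;
    }
    out[q] = sc / (double)(ntrip - 1);
  }
  return out;
}

// Seed-weighted antisense complementarity scan of one miRNA over every
// gapless window of a transcript. Position i of the miRNA (1-based from the
// 5' end) faces transcript base site_start + L - i. Penalties: mismatch
// mm_pen, G:U wobble gu_pen, doubled at miRNA positions seed_from..seed_to.
// Returns window starts (0-based) with score <= score_max.
// [[Rcpp::export]]
DataFrame cpp_scan_target_sites(std::string mirna, std::string transcript,
                                double mm_pen, double gu_pen,
                                int seed_from, int seed_to,
                                double score_max) {
  int L = (int)mirna.size();
  int n = (int)transcript.size();
  std::vector<int> starts;
  std::vector<double> scores;
  for (int s = 0; s + L <= n; ++s) {
    double sc = 0.0;
    for (int i = 1; i <= L; ++i) {
      char m = mirna[i - 1];
      char t = transcript[s + L - i];
      double pen = 0.0;
      if (m == 'N' || t == 'N') pen = mm_pen;
      else if (comp_base(m) == t) pen = 0.0;
      else if ((m == 'G' && t == 'T') || (m == 'T' && t == 'G')) pen = gu_pen;
      else pen = mm_pen;
      if (i >= seed_from && i <= seed_to) pen *= 2.0;
      sc += pen;
      if (sc > score_max) break;
    }
    if (sc <= score_max) { starts.push_back(s); scores.push_back(sc); }
  }
  return DataFrame::create(_["start"] = wrap(starts),
                           _["score"] = wrap(scores));
}
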