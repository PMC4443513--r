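---
title: "Discovering plant miRNAs without conservation: the mirforge pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering plant miRNAs without conservation: the mirforge pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Most plant miRNA catalogues are built by homology to miRNAs already known in
other species, which systematically misses young, fast-evolving or
lineage-specific families. In species with huge, polyploid genomes and no
finished genome sequence (hexaploid wheat being the canonical case), discovery
has to work directly from deep-sequenced small-RNA libraries mapped to an
expressed-sequence (EST) reference. mirforge implements such a
conservation-independent pipeline end to end: read preprocessing, precursor
window extraction and folding, machine-learned validation of the mature miRNA
position within its hairpin, expression-profile filtering, conserved-family
annotation, differential expression between libraries, target prediction and
GO-Slim enrichment — plus a seeded synthetic-data generator so that every
stage can be exercised and scored against known ground truth on a desk.

# The discovery model, stage by stage

## Preprocessing and mapping

Reads are adapter-trimmed (longest exact adapter-prefix suffix match, at
least 6 nt), length-filtered to the canonical small-RNA window of 18-30 nt
inclusive, and quality-filtered at mean Phred >= 20 when qualities are
present (the gate is configurable and skipped for FASTA input). Low
complexity reads are removed by a self-contained DUST-style statistic —
the sum of c(c-1)/2 over 3-mer counts scaled by the triplet count, dropped
above 2.0 — plus a homopolymer rule (one base > 80% of the read). This
replaces database-driven repeat masking so the pipeline has no external
database dependency; it removes the same reads a repeat masker would flag as
simple repeats, though genuinely transposon-derived reads that are not
low-complexity will survive it.

Surviving reads are collapsed to unique sequences with per-library counts,
and every unique sequence is mapped to both strands of every reference
transcript, gapless and full-length, with at most 2 mismatches (`N` never
matches). All hits are kept: miRNA families are repetitive and best-hit
selection would silently drop paralogous loci. The mapper anchors 6-mers by
the pigeonhole principle (with <= 2 mismatches one read third is exact) and
is verified against an exhaustive scan in the test suite.

## Precursor windows, folding, and the stem-loop trim

For each mapped locus the window from 20 nt upstream of the read start to
160 nt downstream of its end (clipped at the transcript bounds) is extracted
on **both** strands — exactly two candidates per locus, a structural
invariant the suite asserts. Windows are folded with `RNAfold` (ViennaRNA)
at its default 37 degrees C parameters; the engine version is recorded in the
run summary.

A 200-nt window almost always folds with extra structure in the flanks
beyond the true hairpin, so the window fold is first *trimmed* to the single
stem-loop branch that covers the seed read: starting at a terminal loop, the
enclosing helix is extended basally until a multiloop junction or the
exterior loop is reached. The trimmed precursor is refolded to obtain its
own MFE. Hard gates then require exactly one terminal loop, paired fraction
>= 0.4 and MFE < 0; gated survivors are scored by a random forest over
standard hairpin descriptors (length, GC, MFE, AMFE = MFE per 100 nt,
MFEI = AMFE / GC%, paired fraction, longest helix, loop size, longest
bulge), trained on constructed hairpins versus folded dinucleotide shuffles.
This classifier is a deliberately permissive pre-filter (threshold 0.5): its
job is broad recall ahead of the position classifier, mirroring the role
that external hairpin predictors play in comparable pipelines.

## The duplex-position score

The pipeline's central filter asks not "is this a hairpin?" but "is the
mature miRNA in the right place inside it?". For a candidate mature interval
the package derives the miRNA:miRNA* duplex from the pairing table and
describes it with the four classical quantities: A, the number of bulges in
the duplex; B, the longest run of successive unpaired bases in a bulge; C,
the total unpaired bases in the duplex; and D, the terminal loop size. The
full 34-feature schema adds the mature's length, composition, 5'-end
identity, arm, distance to the loop and to the hairpin ends, loop overlap,
the pairing state of mature positions 1-9, a stacking proxy and
precursor-level energies. The schema is versioned inside every trained
model so it can be replaced without silently mixing feature orders.

A seeded, class-balanced random forest is trained on true positions versus
position-perturbed negatives (the true interval shifted by 5-30 nt or placed
on the opposite arm, three negatives per positive). Because the raw
vote fraction of a forest is not a calibrated probability, the model applies
Platt scaling fitted on out-of-bag votes; the reported score is 100 x the
calibrated probability. Candidates are accepted when the score strictly
exceeds 90 **and** the mature sequence reaches 100 reads in at least one
library. The boundary convention is: score gate strict (> 90), abundance
gate inclusive (>= 100). A rule-based structural checker in the style of
classic plant-miRNA filters (caps on unpaired mature bases, bulge runs and
duplex asymmetry) is computed side by side for every candidate but never
filters by default; it is strictly more exclusionary than the learned gate
on fixture sets, which the acceptance suite verifies — notably, duplexes
with bulge runs up to 5 nt remain acceptable to the learned score.

Training sets for both classifiers are generated by embedding constructed
hairpins in random transcript context, folding the embedding window and
trimming the stem-loop — the same transformation the discovery funnel
applies — because a model trained on pristine constructs is mis-calibrated
on trimmed windows (we observed true positions losing ~10 score points,
enough to fall under the fixed 90 gate).

## Expression-profile rules

Every read mapping inside an accepted precursor (same strand) is assigned to
mature / star / loop / other buckets by >= 80% overlap, with a 2-nt shift
tolerance for mature and star (Dicer imprecision of 1-2 nt is the field
norm). The relaxed expression rules then require processing precision —
(mature + star) / total >= 0.75 — and either observed star reads or mature
expression of >= 100 reads in at least two libraries in lieu of star
evidence. The exact relaxation used in comparable published pipelines is not
printed anywhere; these two parameters are our documented defaults and are
configurable. Candidates whose mature reads exceed 50% (strictly) of all
precursor reads are classed *typical*; end-shift variants within 2 nt are
reported as isomiRs, flagged when they out-express the canonical mature.

## Conservation, differential expression, targets, enrichment

*Conservation*: unique sequences with >= 100 reads in some library are
searched against a mature-miRNA reference set by word-seeded (7-mer exact),
ungapped alignment scored +1/match, -2/mismatch, and kept at identity
>= 80% with query and subject coverage both >= 90%. We drop the e-value
gate such searches often carry: with no gaps and double coverage the
identity/coverage restrictions dominate, and e-values depend on database
size. Family labels take the best hit, normalised to the miRNNN stem (ties
report all families).

*Differential expression*: counts are rpm-normalised; sequences below 100
reads in all libraries are removed first. Between two libraries the pooled
two-proportion z statistic
z = (p1 - p2) / sqrt(p0 (1 - p0)(1/N1 + 1/N2)) is computed on raw counts
with library sizes as denominators, two-sided normal p-values are BH-adjusted
per comparison, and a call requires q < 0.05 **and** rpm fold change outside
(0.5, 2.0). Fold changes add a 0.5-rpm pseudo-count on both sides to handle
zeros (our choice; configurable). Crossing the calls of a tolerant and a
sensitive genotype yields eight groups per stress; groups 5-6 (same
direction in both genotypes) read as stress *response*, all others as
*tolerance* candidates.

*Targets*: antisense complementarity over every gapless transcript window,
penalised 1 per mismatch, 0.5 per G:U wobble, doubled at miRNA positions
2-12; sites scoring <= 3 must also reach a duplex free-energy ratio (site
MFE over perfect-complement MFE, from `RNAduplex`) >= 0.7. Transcripts
described as unknown/uncharacterized/hypothetical proteins are excluded.
*Enrichment*: hypergeometric upper-tail tests per GO-Slim term against a
global (all annotated clusters) or condition-restricted background, binned
+++ (p < 1e-5), ++ (p < 1e-3), + (p < 0.05).

# The synthetic-data generator

`sim_config()` / `generate_dataset()` emulate a multi-library wheat-style
small-RNA experiment with known truth. True hairpins are built by
construction — 5' arm containing the mature, loop, reverse-complemented arm
with planted bulges (A bulges of runs <= B) — and redrawn until the folding
engine confirms a clean single-loop hairpin, then embedded mid-EST. Reads
are drawn per library: mature and star reads are excised exactly with
probability `dicer_precision` (default 0.9) and 1-2-nt end-jittered
otherwise; a 10% background of random hairpin positions and a configurable
noise fraction (default 0.5 of planted reads; 95% from non-hairpin EST
regions, 5% fully random) exercise the mapping and complexity filters.
Decoy hairpins (default 200) fold like real precursors but carry diffuse
low-tier reads (50-90 per library, half at a mild preferred position), so
they reach the folding and scoring stages and must be rejected by the
abundance and expression gates. Planted fold changes (4x up and 4x down on
disjoint quarters of the true set per comparison) are applied to expected
counts; up- and down-effects are planted together deliberately, because rpm
normalisation is compositional — planting only up-effects in a small
library inflates the library size itself and visibly compresses every
apparent rpm ratio.

The default conditions (20 true miRNAs, 200 decoys, 4 libraries of roughly
50k reads each, mature expectations 200-1200 log-uniform, star fraction
0.15) give a ~200k-read dataset that the full pipeline processes in about
two minutes.

What the generator does *not* emulate: sequencing error inside reads,
colorspace artefacts, adapter chemistry beyond suffix ligation, multi-locus
gene families sharing one mature sequence, RNA editing, and hairpins whose
true structure disagrees with the MFE fold. Green recovery numbers on this
synthetic regime therefore demonstrate that the machinery is correct and
calibrated, not that real wheat libraries would yield the same rates.

# Numerical choices and degenerate inputs

- Coordinates are 0-based half-open internally; reports are 1-based
  inclusive. The internal alphabet is DNA (U mapped to T on input); RNA
  appears only at presentation boundaries (Vienna files, probes).
- `N` never pairs, never matches, and counts as a mismatch everywhere.
- Degenerate z-tests (pooled proportion 0 or 1) return z = 0, p = 1,
  flagged.
- MFEI is recorded as missing for GC = 0 windows; all-dot structures have
  zero terminal loops and fail the hairpin gates.
- Identical window sequences from overlapping reads are folded once and
  deduplicated; how duplicate windows should be merged is not specified
  anywhere, so we deduplicate on (window sequence, read offset).
- Ties in family assignment report every tied family, joined with commas.
- The measured dicing precision is scored against the declared mature locus
  and the *modal* star product; scoring the star against the inferred
  interval instead would punish 1-2-nt star-interval uncertainty that the
  trimmed fold cannot resolve. On synthetic data the measurement still runs
  ~0.03 below the planted precision because background hairpin reads
  contaminate the mature/star buckets; we report the honest value.

# Problem sizes used by the shipped tests

The test suite and the acceptance script run entirely on generated data:
oracle-equivalence suites use a 5-kb reference with 30 reads, 1,000 random
hairpins, 10,000 z-test draws, and a 200-entry mature database; the
end-to-end benchmark uses the default study conditions above. These sizes
were chosen so the whole suite documents the method at interactive speed
while keeping every statistical check comfortably powered.

# Known limitations

- The hairpin and position classifiers are trained on synthetic hairpins;
  for production use on real libraries they should be retrained on curated
  miRBase precursors of the relevant clade (the three `training_scope`
  labels — all / plants / monocots — exist for exactly that).
- The target-site scheme is the standard plant convention, not a reverse
  engineering of any specific scorer; its two gates (score <= 3, ratio
  >= 0.7) are the fixed contract and everything else is configurable.
- GO-Slim tables are treated as flat annotations; no DAG propagation.
- Gapless alignment throughout; a 1-nt bulge mode for target sites exists
  behind the gap penalty but is off by default.
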