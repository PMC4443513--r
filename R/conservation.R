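#' Conserved-family homology search
#'
#' Word-seeded, ungapped alignment of abundant small RNAs against a
#' mature-miRNA reference set (miRBase-style FASTA; RNA accepted). Only
#' queries reaching `abundance_min` reads in at least one library are
#' searched. Candidate alignments are seeded by shared exact `word_size`-mers
#' and extended without gaps over the full overlap; hits are kept iff
#' identity, query coverage and subject coverage all reach their thresholds.
#' Scores are `matches x 1 + mismatches x (-2)`; `N` never matches.
#'
#' @param queries character vector of query sequences, or a count matrix
#'   from [collapse_reads()] whose rownames are the queries (then the
#'   abundance gate uses its counts).
#' @param mature_db data frame with `id`, `sequence` and optionally `family`
#'   columns (e.g. from [read_sequences()] on a miRBase-style FASTA).
#' @param word_size exact seed length.
#' @param identity_min,qcov_min,scov_min percent thresholds.
#' @param abundance_min read-count gate (ignored when `queries` is a plain
#'   character vector).
#' @return data frame of hits: `query_seq`, `db_id`, `db_family`,
#'   `align_start_q`, `align_start_db` (0-based), `align_len`, `matches`,
#'   `mismatches`, `score`, `identity_pct`, `query_cov_pct`,
#'   `subject_cov_pct`. One best-scoring alignment per (query, db entry).
#' @export
search_conserved <- function(queries, mature_db, word_size = 7L,
                             identity_min = 80, qcov_min = 90,
                             scov_min = 90, abundance_min = 100) {
  if (is.matrix(queries)) {
    keep <- apply(queries, 1L, max) >= abundance_min
    queries <- rownames(queries)[keep]
  }
  queries <- dna(queries)
  if (nrow(mature_db) == 0L) .stopf("empty mature miRNA database")
  db_seq <- dna(mature_db$sequence)
  db_fam <- if (!is.null(mature_db$family)) mature_db$family
  else normalize_family(mature_db$id)
  out <- vector("list", length(queries))
  qraw <- lapply(queries, function(q) utf8ToInt(q))
  sraw <- lapply(db_seq, function(s) utf8ToInt(s))
  nN <- utf8ToInt("N")
  for (qi in seq_along(queries)) {
    q <- queries[qi]; qv <- qraw[[qi]]; lq <- length(qv)
    if (lq < word_size) next
    qwords <- substring(q, 1:(lq - word_size + 1L),
                        word_size:lq)
    rows <- list()
    for (si in seq_along(db_seq)) {
      sv <- sraw[[si]]; ls <- length(sv)
      if (ls < word_size) next
      swords <- substring(db_seq[si], 1:(ls - word_size + 1L), word_size:ls)
      # alignment offsets (db start - query start) sharing an exact word
      hitw <- which(outer(qwords, swords, "=="), arr.ind = TRUE)
      if (!nrow(hitw)) next
      offs <- unique(hitw[, 2L] - hitw[, 1L])
      best <- NULL
      for (d in offs) {
        # ungapped full-overlap alignment at offset d
        qs <- max(1L, 1L - d); qe <- min(lq, ls - d)
        if (qe < qs) next
        al <- qe - qs + 1L
        a <- qv[qs:qe]; b <- sv[(qs + d):(qe + d)]
        m <- sum(a == b & a != nN)
        mm <- al - m
        sc <- m - 2L * mm
        rec <- c(qs, d, al, m, mm, sc)
        if (is.null(best) || sc > best[6L]) best <- rec
      }
      if (is.null(best)) next
      idp <- 100 * best[4L] / best[3L]
      qcov <- 100 * best[3L] / lq
      scov <- 100 * best[3L] / ls
      if (idp >= identity_min && qcov >= qcov_min && scov >= scov_min) {
        rows[[length(rows) + 1L]] <- data.frame(
          query_seq = q, db_id = mature_db$id[si], db_family = db_fam[si],
          align_start_q = best[1L] - 1L,
          align_start_db = best[1L] - 1L + best[2L],
          align_len = best[3L], matches = best[4L], mismatches = best[5L],
          score = best[6L], identity_pct = idp, query_cov_pct = qcov,
          subject_cov_pct = scov, stringsAsFactors = FALSE)
      }
    }
    if (length(rows)) out[[qi]] <- do.call(rbind, rows)
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(query_seq = character(), db_id = character(),
                      db_family = character(), align_start_q = integer(),
                      align_start_db = integer(), align_len = integer(),
                      matches = integer(), mismatches = integer(),
                      score = integer(), identity_pct = numeric(),
                      query_cov_pct = numeric(), subject_cov_pct = numeric(),
                      stringsAsFactors = FALSE)
  }
  rownames(res) <- NULL
  res
}

#' Canonical family stem of a mature miRNA identifier
#'
#' Strips the species prefix and trailing paralog/arm suffixes, reducing
#' e.g. `ath-miR166a-5p` to `miR166`.
#'
#' @param ids character vector of miRBase-style identifiers.
#' @return character vector of family stems (the input where no stem is
#'   recognisable).
#' @export
normalize_family <- function(ids) {
  m <- regmatches(ids, regexpr("[mM][iI][rR][0-9]+", ids))
  out <- ids
  has <- regexpr("[mM][iI][rR][0-9]+", ids) > 0
  out[has] <- sub("^[mM][iI][rR]", "miR", m)
  out
}

#' Family assignment from homology hits
#'
#' Labels each query with the family of its best-scoring hit; score ties
#' across distinct families report all tied families.
#'
#' @param hits data frame from [search_conserved()].
#' @return data frame `query_seq`, `family` (comma-joined on ties),
#'   `score`.
#' @export
assign_family <- function(hits) {
  if (!nrow(hits)) {
    return(data.frame(query_seq = character(), family = character(),
                      score = integer(), stringsAsFactors = FALSE))
  }
  res <- lapply(split(hits, hits$query_seq), function(h) {
    top <- h[h$score == max(h$score), , drop = FALSE]
    fams <- sort(unique(normalize_family(top$db_family)))
    data.frame(query_seq = h$query_seq[1L],
               family = paste(fams, collapse = ","),
               score = max(h$score), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
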