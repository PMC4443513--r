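#' Complementarity score of a miRNA against a target site
#'
#' Antisense, gapless alignment of the miRNA (5'-3') to a transcript window
#' of the same length. Penalties: mismatch 1.0, G:U wobble 0.5; penalties
#' are doubled at miRNA positions 2-12 (the seed-extended region). The
#' score is the penalty sum; a perfect reverse complement scores 0.
#'
#' @param mirna mature miRNA sequence (5'-3').
#' @param transcript_window transcript site, same length, transcript
#'   orientation.
#' @param mm_pen,gu_pen,seed_range,seed_mult scheme parameters (the doubled
#'   seed multiplier is fixed at 2 in the scan; exposed here for the
#'   single-site evaluator).
#' @return list with `score` and `alignment` (`|` match, `o` wobble,
#'   `x` mismatch, left to right along the miRNA 5'-3').
#' @export
score_target_site <- function(mirna, transcript_window, mm_pen = 1.0,
                              gu_pen = 0.5, seed_range = c(2L, 12L),
                              seed_mult = 2.0) {
  mirna <- dna(mirna)
  transcript_window <- dna(transcript_window)
  L <- nchar(mirna)
  if (nchar(transcript_window) != L)
    .stopf("window length %d != miRNA length %d",
           nchar(transcript_window), L)
  m <- strsplit(mirna, "")[[1L]]
  t <- strsplit(transcript_window, "")[[1L]]
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "?")
  score <- 0
  aln <- character(L)
  for (i in seq_len(L)) {
    tb <- t[L - i + 1L]  # miRNA position i faces the site 3'->5'
    pen <- if (m[i] == "N" || tb == "N") mm_pen
    else if (comp[[m[i]]] == tb) 0
    else if ((m[i] == "G" && tb == "T") || (m[i] == "T" && tb == "G")) gu_pen
    else mm_pen
    if (i >= seed_range[1L] && i <= seed_range[2L]) pen <- pen * seed_mult
    score <- score + pen
    aln[i] <- if (pen == 0) "|" else if (pen %in% (gu_pen * c(1, seed_mult)))
      "o" else "x"
  }
  list(score = score, alignment = paste(aln, collapse = ""))
}

#' Duplex free-energy ratio of a miRNA:site pair
#'
#' Ratio of the duplex MFE of the miRNA bound to the site over the MFE of
#' the miRNA bound to its perfect complement, both from the folding engine's
#' duplex mode, clamped to \[0, 1\]. A perfect complement scores 1.
#'
#' @param mirna miRNA sequence.
#' @param site target site (transcript orientation), or vector of sites.
#' @return numeric vector of ratios.
#' @export
energy_ratio <- function(mirna, site) {
  perfect <- duplex_mfe(mirna, revcomp(mirna))
  if (perfect == 0) .stopf("perfect-complement duplex has zero MFE")
  mfes <- duplex_mfe(rep(mirna, length(site)), site)
  pmin(1, pmax(0, mfes / perfect))
}

#' Predict miRNA targets on a transcript reference
#'
#' Scans every gapless window of each annotated transcript with the
#' complementarity scheme, keeps sites with score at most `score_max`, then
#' gates on the duplex free-energy ratio (`>= ratio_min`). Transcripts whose
#' description matches the unknown-protein exclusion patterns are skipped;
#' hits are unique per (miRNA, transcript, site).
#'
#' @param mirnas named character vector of mature miRNA sequences (names are
#'   miRNA ids).
#' @param reference data frame with `id`, `sequence`.
#' @param annotation a `"mirforge_annotation"` (or NULL to scan all
#'   transcripts without descriptions).
#' @param score_max maximum penalty score.
#' @param ratio_min minimum free-energy ratio.
#' @param exclude_patterns case-insensitive description patterns to skip.
#' @return data frame of `TargetHit` rows: `mirna_id`, `transcript_id`,
#'   `annotation_id`, `site_start`, `site_end` (0-based half-open),
#'   `score`, `energy_ratio`, `alignment`.
#' @export
predict_targets <- function(mirnas, reference, annotation = NULL,
                            score_max = 3.0, ratio_min = 0.7,
                            exclude_patterns = c("unknown",
                                                 "uncharacterized",
                                                 "hypothetical")) {
  refs <- reference
  ann_map <- NULL
  if (!is.null(annotation)) {
    tr <- annotation$transcripts
    bad <- grepl(paste(exclude_patterns, collapse = "|"), tr$description,
                 ignore.case = TRUE)
    keep_ids <- tr$transcript_id[!bad]
    refs <- refs[refs$id %in% keep_ids, , drop = FALSE]
    ann_map <- setNames(tr$cluster_id, tr$transcript_id)
  }
  if (length(mirnas) == 0L || nrow(refs) == 0L) {
    return(data.frame(mirna_id = character(), transcript_id = character(),
                      annotation_id = character(), site_start = integer(),
                      site_end = integer(), score = numeric(),
                      energy_ratio = numeric(), alignment = character(),
                      stringsAsFactors = FALSE))
  }
  if (is.null(names(mirnas)))
    names(mirnas) <- paste0("mir", seq_along(mirnas))
  rows <- list()
  for (k in seq_along(mirnas)) {
    mseq <- dna(mirnas[[k]])
    L <- nchar(mseq)
    for (r in seq_len(nrow(refs))) {
      hits <- cpp_scan_target_sites(mseq, dna(refs$sequence[r]),
                                    1.0, 0.5, 2L, 12L, score_max)
      if (!nrow(hits)) next
      rows[[length(rows) + 1L]] <- data.frame(
        mirna_id = names(mirnas)[k], transcript_id = refs$id[r],
        site_start = hits$start, site_end = hits$start + L,
        score = hits$score, site_seq = substr(refs$sequence[r],
                                              hits$start + 1L,
                                              hits$start + L),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(predict_targets(character(), refs, NULL))
  }
  out <- do.call(rbind, rows)
  out <- out[!duplicated(out[c("mirna_id", "transcript_id",
                               "site_start")]), , drop = FALSE]
  # energy-ratio gate, batched per miRNA
  out$energy_ratio <- NA_real_
  for (id in unique(out$mirna_id)) {
    sel <- out$mirna_id == id
    out$energy_ratio[sel] <- energy_ratio(dna(mirnas[[id]]),
                                          out$site_seq[sel])
  }
  out <- out[out$energy_ratio >= ratio_min, , drop = FALSE]
  out$alignment <- vapply(seq_len(nrow(out)), function(i) {
    score_target_site(mirnas[[out$mirna_id[i]]], out$site_seq[i])$alignment
  }, character(1))
  out$annotation_id <- if (!is.null(ann_map))
    unname(ann_map[out$transcript_id]) else NA_character_
  rownames(out) <- NULL
  out[, c("mirna_id", "transcript_id", "annotation_id", "site_start",
          "site_end", "score", "energy_ratio", "alignment")]
}

#' Hypergeometric GO-Slim enrichment
#'
#' For every GO term annotated to at least one background cluster, tests
#' over-representation among the target clusters with the upper-tail
#' hypergeometric probability \eqn{P(X \ge k)} for k annotated targets out
#' of n, against K annotated clusters in a background of N. Terms with
#' p < 0.05 are enriched; significance bins: `high` (p < 1e-5), `medium`
#' (p < 1e-3), `low` (p < 0.05), `none` otherwise, rendered as `+++`, `++`,
#' `+` and blank.
#'
#' @param target_set character vector of annotation (cluster) ids in the
#'   foreground.
#' @param background character vector of annotation ids (must contain the
#'   target set).
#' @param go_table data frame from [read_go_table()] (`cluster_id`,
#'   `go_terms`, `category`).
#' @return data frame of `EnrichmentRow`s: `go_term`, `category`, `k`, `K`,
#'   `n`, `N`, `p`, `enriched`, `bin`, `glyph`.
#' @export
hypergeom_enrichment <- function(target_set, background, go_table) {
  target_set <- unique(target_set)
  background <- unique(background)
  missing <- setdiff(target_set, background)
  if (length(missing))
    .stopf("target annotation id absent from background: %s", missing[1L])
  go <- go_table[go_table$cluster_id %in% background, , drop = FALSE]
  if (!nrow(go)) {
    return(data.frame(go_term = character(), category = character(),
                      k = integer(), K = integer(), n = integer(),
                      N = integer(), p = numeric(), enriched = logical(),
                      bin = character(), glyph = character(),
                      stringsAsFactors = FALSE))
  }
  long <- do.call(rbind, lapply(seq_len(nrow(go)), function(i) {
    terms <- strsplit(go$go_terms[i], ",")[[1L]]
    terms <- trimws(terms[nzchar(trimws(terms))])
    if (!length(terms)) return(NULL)
    data.frame(cluster_id = go$cluster_id[i], go_term = terms,
               category = go$category[i], stringsAsFactors = FALSE)
  }))
  long <- unique(long)
  N <- length(background)
  n <- length(target_set)
  res <- lapply(split(long, long$go_term), function(g) {
    K <- length(unique(g$cluster_id))
    k <- length(intersect(g$cluster_id, target_set))
    p <- phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
    data.frame(go_term = g$go_term[1L], category = g$category[1L],
               k = k, K = K, n = n, N = N, p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$enriched <- out$p < 0.05
  out$bin <- ifelse(out$p < 1e-5, "high",
                    ifelse(out$p < 1e-3, "medium",
                           ifelse(out$p < 0.05, "low", "none")))
  out$glyph <- c(high = "+++", medium = "++", low = "+", none = "")[out$bin]
  out <- out[order(out$p), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Enrichment background construction
#'
#' Global mode uses every annotated cluster of the reference; condition
#' mode restricts the background to the clusters of targets identified in
#' the two compared libraries (always a subset of the global background).
#'
#' @param mode `"global"` or `"condition"`.
#' @param annotation a `"mirforge_annotation"`.
#' @param condition_targets character vector of cluster ids (condition
#'   mode).
#' @return character vector of cluster ids.
#' @export
build_background <- function(mode = c("global", "condition"), annotation,
                             condition_targets = NULL) {
  mode <- match.arg(mode)
  global <- unique(annotation$transcripts$cluster_id)
  if (mode == "global") return(global)
  if (is.null(condition_targets))
    .stopf("condition mode requires condition_targets")
  intersect(unique(condition_targets), global)
}
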