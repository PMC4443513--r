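#' Positional read profile of a precursor candidate
#'
#' Assigns every read mapping inside a candidate precursor window to one of
#' four buckets — mature, star, loop, other — by positional overlap of at
#' least `min_overlap` of the read with the interval (mature and star
#' intervals are evaluated with a +/- `shift_tol` nt shift tolerance for
#' Dicer imprecision). Bucket assignment is a partition: each read lands in
#' exactly one bucket, tested in the order mature, star, loop, other.
#'
#' @param reads data frame with `offset` (0-based read start within the
#'   window), `length`, `library_id`, `count` and optionally `sequence`.
#' @param mature_start,mature_end 0-based half-open mature interval in the
#'   window.
#' @param star_start,star_end star interval (NA when unknown).
#' @param loop_start,loop_end terminal loop interval (NA when unknown).
#' @param min_overlap minimum read fraction overlapping the interval.
#' @param shift_tol shift tolerance in nt for mature/star.
#' @return object of class `"mirforge_profile"`: the `reads` with a `bucket`
#'   column, per-bucket per-library totals, and exact-dicing counts.
#' @export
build_profile <- function(reads, mature_start, mature_end,
                          star_start = NA, star_end = NA,
                          loop_start = NA, loop_end = NA,
                          min_overlap = 0.8, shift_tol = 2L) {
  ov_frac <- function(s, e, is_, ie_) {
    if (is.na(is_)) return(rep(0, length(s)))
    pmax(0L, pmin(e, ie_) - pmax(s, is_)) / (e - s)
  }
  s <- reads$offset
  e <- reads$offset + reads$length
  # shift tolerance: expand the target interval by shift_tol on both sides
  f_mat <- ov_frac(s, e, mature_start - shift_tol, mature_end + shift_tol)
  f_star <- ov_frac(s, e, ifelse(is.na(star_start), NA, star_start - shift_tol),
                    star_end + shift_tol)
  f_loop <- ov_frac(s, e, loop_start, loop_end)
  bucket <- rep("other", nrow(reads))
  bucket[f_loop >= min_overlap] <- "loop"
  bucket[f_star >= min_overlap] <- "star"
  bucket[f_mat >= min_overlap] <- "mature"
  reads$bucket <- bucket
  libs <- unique(reads$library_id)
  agg <- sapply(libs, function(l) {
    sapply(c("mature", "star", "loop", "other"), function(b) {
      sum(reads$count[reads$library_id == l & reads$bucket == b])
    })
  })
  if (is.null(dim(agg))) agg <- matrix(agg, ncol = length(libs),
                                       dimnames = list(c("mature", "star",
                                                         "loop", "other"),
                                                       libs))
  # exact mature product = the declared mature locus; exact star product =
  # the modal (start, length) of the star bucket, which is robust to 1-2 nt
  # uncertainty in the inferred star interval
  exact <- reads$offset == mature_start &
    reads$length == mature_end - mature_start
  star_rows <- which(bucket == "star")
  if (length(star_rows)) {
    key <- paste(reads$offset[star_rows], reads$length[star_rows])
    cnt <- tapply(reads$count[star_rows], key, sum)
    modal <- names(cnt)[which.max(cnt)]
    exact[star_rows] <- key == modal
  }
  structure(list(reads = reads, buckets = agg,
                 mature = c(mature_start, mature_end),
                 star = c(star_start, star_end),
                 exact_dicing = sum(reads$count[exact & bucket %in%
                                                  c("mature", "star")]),
                 total = sum(reads$count)),
            class = "mirforge_profile")
}

#' Measured dicing precision of a profile
#'
#' Fraction of mature/star-bucket reads that fall exactly on the mature or
#' star locus (start and length both exact).
#' @param profile a `"mirforge_profile"`.
#' @return numeric in \[0, 1\] (NA when no mature/star reads).
#' @export
dicer_precision <- function(profile) {
  ms <- sum(profile$buckets[c("mature", "star"), ])
  if (ms == 0) return(NA_real_)
  profile$exact_dicing / ms
}

#' Expression-based filtering of a candidate profile
#'
#' Relaxed plant-annotation expression rules: the candidate passes iff its
#' processing precision — (mature + star reads) / total — reaches
#' `precision_min`, and either star reads are observed or the mature is
#' expressed at `min_expr` reads in at least two libraries (the relaxation
#' accepted in lieu of star evidence). Failure reasons are reported.
#'
#' @param profile a `"mirforge_profile"` from [build_profile()].
#' @param precision_min minimum processing precision.
#' @param min_expr per-library mature count counting as "expressed".
#' @param require_star_or_multilib apply the star-or-multi-library clause.
#' @return list with `pass` (logical), `precision`, `reasons` (character).
#' @export
meyers_filter <- function(profile, precision_min = 0.75, min_expr = 100,
                          require_star_or_multilib = TRUE) {
  reasons <- character(0)
  if (profile$total == 0) {
    return(list(pass = FALSE, precision = NA_real_,
                reasons = "no expression"))
  }
  prec <- sum(profile$buckets[c("mature", "star"), ]) / profile$total
  if (prec < precision_min)
    reasons <- c(reasons, sprintf("precision %.2f < %.2f", prec,
                                  precision_min))
  if (require_star_or_multilib) {
    star_total <- sum(profile$buckets["star", ])
    nlib_expr <- sum(profile$buckets["mature", ] >= min_expr)
    if (star_total == 0 && nlib_expr < 2L)
      reasons <- c(reasons, "no star reads and mature expressed in < 2 libraries")
  }
  list(pass = length(reasons) == 0L, precision = prec, reasons = reasons)
}

#' Typical / atypical expression classification
#'
#' A candidate is *typical* when its mature reads make up strictly more than
#' half of all reads mapping to the precursor.
#'
#' @param profile a `"mirforge_profile"`.
#' @return `"typical"` or `"atypical"`.
#' @export
classify_typical <- function(profile) {
  if (profile$total == 0) return("atypical")
  if (sum(profile$buckets["mature", ]) / profile$total > 0.5)
    "typical" else "atypical"
}

#' IsomiR variants of a mature miRNA in a profile
#'
#' Lists mature-bucket reads whose ends differ from the canonical mature by
#' at most `tol` nt, ranked by total count; a variant out-expressing the
#' canonical sequence is flagged dominant.
#'
#' @param profile a `"mirforge_profile"` (its `reads` need a `sequence`
#'   column).
#' @param mature_seq canonical mature sequence.
#' @param tol maximum end shift in nt.
#' @return data frame `sequence`, `offset`, `length`, `count`, `dominant`,
#'   ordered by decreasing count (canonical row excluded).
#' @export
associate_isomirs <- function(profile, mature_seq, tol = 2L) {
  rd <- profile$reads
  rd <- rd[rd$bucket == "mature", , drop = FALSE]
  if (!nrow(rd) || is.null(rd$sequence)) {
    return(data.frame(sequence = character(), offset = integer(),
                      length = integer(), count = integer(),
                      dominant = logical()))
  }
  ms <- profile$mature[1L]; me <- profile$mature[2L]
  ok <- abs(rd$offset - ms) <= tol & abs((rd$offset + rd$length) - me) <= tol
  rd <- rd[ok, , drop = FALSE]
  agg <- stats::aggregate(count ~ sequence + offset + length, rd, sum)
  canon <- agg$sequence == mature_seq
  canon_count <- if (any(canon)) max(agg$count[canon]) else 0L
  iso <- agg[!canon, , drop = FALSE]
  iso <- iso[order(-iso$count), , drop = FALSE]
  iso$dominant <- iso$count > canon_count
  rownames(iso) <- NULL
  iso[, c("sequence", "offset", "length", "count", "dominant")]
}
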