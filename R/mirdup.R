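#' Duplex characteristics of a mature position in a hairpin
#'
#' Describes the miRNA:miRNA* duplex by the four quantities used to
#' characterise candidate secondary structures: `A`, the number of bulges in
#' the duplex; `B`, the maximum number of successive unpaired bases in any
#' single bulge; `C`, the total number of unpaired bases within the duplex;
#' and `D`, the nucleotide count of the terminal loop subtended by the
#' mature's hairpin. The duplex region is the mature arm plus its pairing
#' partners up to the loop-proximal end; bulges are maximal runs of unpaired
#' positions strictly inside the duplex on either strand.
#'
#' @param dotbracket structure of the precursor.
#' @param mature_start,mature_end 0-based half-open mature interval.
#' @return list with fields `A`, `B`, `C`, `D`.
#' @export
duplex_characteristics <- function(dotbracket, mature_start, mature_end) {
  pt <- pairing_table(dotbracket)
  n <- length(pt)
  mi <- (mature_start + 1L):mature_end        # 1-based mature positions
  if (mature_start < 0L || mature_end > n || mature_end <= mature_start)
    .stopf("mature interval [%d,%d) outside structure of length %d",
           mature_start, mature_end, n)
  paired <- mi[pt[mi] > 0L]
  if (!length(paired)) .stopf("no duplex: mature has no paired bases")
  # unpaired runs strictly inside the mature-side span
  span_m <- paired[1L]:paired[length(paired)]
  # star-side span: partner range of the paired mature bases
  partners <- pt[paired]
  span_s <- min(partners):max(partners)
  if (length(intersect(span_m, span_s)))
    .stopf("no duplex: mature lies in the terminal loop")
  runs_in <- function(span) {
    un <- pt[span] == 0L
    if (!any(un)) return(integer(0))
    r <- rle(un)
    r$lengths[r$values]
  }
  bulges <- c(runs_in(span_m), runs_in(span_s))
  # terminal loop: the innermost region between the loop-proximal mature
  # pair and its partner
  on5 <- span_m[1L] < span_s[1L]
  prox <- if (on5) paired[length(paired)] else paired[1L]
  lo <- min(prox, pt[prox]); hi <- max(prox, pt[prox])
  inner <- if (hi - lo > 1L) (lo + 1L):(hi - 1L) else integer(0)
  loops <- .terminal_loops(pt)
  loops <- loops[loops$start >= lo + 1L & loops$end <= hi - 1L, , drop = FALSE]
  D <- if (nrow(loops)) max(loops$end - loops$start + 1L)
  else sum(pt[inner] == 0L)
  list(A = length(bulges), B = if (length(bulges)) max(bulges) else 0L,
       C = sum(bulges), D = as.integer(D))
}

#' Infer the star interval of a mature miRNA
#'
#' The star spans the pairing partners of the mature's paired bases, with
#' the star 3' end extended by the universal 2-nt Dicer overhang; unpaired
#' mature termini shift the span by their offsets. When fewer than half of
#' the mature bases are paired, the interval is flagged low-confidence.
#'
#' @param dotbracket structure of the precursor.
#' @param mature_start,mature_end 0-based half-open mature interval.
#' @param overhang 3' overhang in nt (Dicer convention, 2).
#' @return list with `start`, `end` (0-based half-open, clipped to the
#'   precursor) and `low_confidence`.
#' @export
infer_star <- function(dotbracket, mature_start, mature_end, overhang = 2L) {
  pt <- pairing_table(dotbracket)
  n <- length(pt)
  mi <- (mature_start + 1L):mature_end
  paired <- mi[pt[mi] > 0L]
  if (!length(paired)) {
    return(list(start = NA_integer_, end = NA_integer_,
                low_confidence = TRUE))
  }
  low <- length(paired) < 0.5 * length(mi)
  i1 <- paired[1L]; i2 <- paired[length(paired)]
  o1 <- i1 - (mature_start + 1L)       # unpaired overhead at mature 5' end
  o2 <- mature_end - i2                # at mature 3' end
  p1 <- pt[i1] + o1                    # partner of mature 5' side, adjusted
  p2 <- pt[i2] - o2
  lo <- min(p1, p2); hi <- max(p1, p2)
  hi <- hi + overhang                  # star 3' end carries the overhang
  list(start = max(0L, as.integer(lo - 1L)),
       end = min(n, as.integer(hi)),
       low_confidence = low)
}

# ordered feature schema of the duplex-position classifier
.mirdup_schema_version <- "1"
.mirdup_feature_names <- c(
  "duplex_pairs", "bulge_count", "bulge_max_run", "unpaired_total",
  "loop_size", "mature_len", "dist_to_loop", "loop_overlap", "arm5",
  "mature_gc", "nt5_A", "nt5_C", "nt5_G", "nt5_T", "stacked_pairs",
  paste0("pos_paired_", 1:9), "count_A", "count_C", "count_G", "count_T",
  "dist_hairpin_5p", "dist_hairpin_3p", "mature_unpaired_frac",
  "premirna_len", "premirna_mfe", "premirna_amfe")

#' Feature vector of a (precursor, mature position) pair
#'
#' The fixed, versioned schema covers every feature family relevant to
#' duplex position scoring in plants: duplex geometry (pair count, bulge
#' count A, maximal bulge run B, total unpaired C, terminal loop size D),
#' the mature's placement (arm, distance to the loop, loop overlap,
#' distances to the hairpin ends), its composition (length, GC, base counts,
#' 5'-end identity), the pairing state of mature positions 1-9, a stacking
#' proxy, and precursor-level energy descriptors.
#'
#' @param sequence,dotbracket,mfe the folded precursor.
#' @param mature_start,mature_end 0-based half-open mature interval.
#' @return named numeric vector following the schema (34 features).
#' @export
extract_features <- function(sequence, dotbracket, mfe, mature_start,
                             mature_end) {
  sequence <- dna(sequence)
  pt <- pairing_table(dotbracket)
  n <- length(pt)
  mi <- (mature_start + 1L):mature_end
  mlen <- length(mi)
  bases <- strsplit(substr(sequence, mature_start + 1L, mature_end), "")[[1L]]
  paired <- mi[pt[mi] > 0L]
  dup <- tryCatch(duplex_characteristics(dotbracket, mature_start,
                                         mature_end),
                  error = function(e) list(A = NA, B = NA, C = NA, D = NA))
  # terminal loop nearest the mature (for distance/overlap features)
  loops <- .terminal_loops(pt)
  if (nrow(loops)) {
    # nucleotides strictly between the mature and the loop
    dists <- pmax(0L, pmax(loops$start - mature_end - 1L,
                           mature_start + 1L - loops$end - 1L))
    k <- which.min(dists)
    lstart <- loops$start[k]; lend <- loops$end[k]
    dist_to_loop <- dists[k]
    loop_overlap <- max(0L, min(mature_end, lend) -
                          max(mature_start + 1L, lstart) + 1L)
    lsize <- lend - lstart + 1L
  } else {
    dist_to_loop <- n; loop_overlap <- 0L; lsize <- 0L
  }
  arm5 <- as.numeric(length(paired) > 0 && mean(pt[paired] > paired) > 0.5)
  stacked <- 0L
  for (i in mi[-length(mi)]) {
    if (pt[i] > 0L && pt[i + 1L] == pt[i] - 1L) stacked <- stacked + 1L
  }
  nt5 <- bases[1L]
  v <- c(
    duplex_pairs = length(paired),
    bulge_count = ifelse(is.na(dup$A), mlen, dup$A),
    bulge_max_run = ifelse(is.na(dup$B), mlen, dup$B),
    unpaired_total = ifelse(is.na(dup$C), mlen, dup$C),
    loop_size = ifelse(is.na(dup$D), lsize, dup$D),
    mature_len = mlen,
    dist_to_loop = dist_to_loop,
    loop_overlap = loop_overlap,
    arm5 = arm5,
    mature_gc = mean(bases %in% c("G", "C")),
    nt5_A = as.numeric(nt5 == "A"), nt5_C = as.numeric(nt5 == "C"),
    nt5_G = as.numeric(nt5 == "G"), nt5_T = as.numeric(nt5 == "T"),
    stacked_pairs = stacked,
    setNames(as.numeric(pt[mi[pmin(1:9, mlen)]] > 0L),
             paste0("pos_paired_", 1:9)),
    count_A = sum(bases == "A"), count_C = sum(bases == "C"),
    count_G = sum(bases == "G"), count_T = sum(bases == "T"),
    dist_hairpin_5p = mature_start,
    dist_hairpin_3p = n - mature_end,
    mature_unpaired_frac = 1 - length(paired) / mlen,
    premirna_len = n,
    premirna_mfe = mfe,
    premirna_amfe = mfe / n * 100)
  v[.mirdup_feature_names]
}

#' Train the duplex-position classifier
#'
#' Trains a seeded random forest to recognise the true mature position
#' within a folded precursor, against position-perturbed negatives (shifted
#' or opposite-arm placements on the same hairpins). The trained model
#' carries its feature schema version and a `training_scope` label
#' (`"all"`, `"plants"` or `"monocots"`) describing the provenance of the
#' supplied training set.
#'
#' @param examples data frame with columns `sequence`, `dotbracket`, `mfe`,
#'   `mature_start`, `mature_end`, `label` (1 = true position, 0 =
#'   negative).
#' @param scope dataset scope label.
#' @param seed integer seed.
#' @param ntree forest size.
#' @return object of class `"mirforge_mirdup_model"`.
#' @export
train_mirdup <- function(examples, scope = c("all", "plants", "monocots"),
                         seed = 7L, ntree = 600L) {
  scope <- match.arg(scope)
  if (!all(examples$label %in% c(0, 1)))
    .stopf("labels must be 0/1")
  npos <- sum(examples$label == 1); nneg <- sum(examples$label == 0)
  if (npos < 20L || nneg < 20L)
    .stopf("need at least 20 positives and 20 negatives (got %d / %d)",
           npos, nneg)
  key <- sprintf("%s:%d:%d", examples$sequence, examples$mature_start,
                 examples$mature_end)
  if (any(key[examples$label == 1] %in% key[examples$label == 0]))
    .stopf("degenerate labels: a negative equals a positive position")
  x <- t(vapply(seq_len(nrow(examples)), function(i) {
    extract_features(examples$sequence[i], examples$dotbracket[i],
                     examples$mfe[i], examples$mature_start[i],
                     examples$mature_end[i])
  }, numeric(length(.mirdup_feature_names))))
  x <- as.data.frame(x)
  y <- factor(ifelse(examples$label == 1, "true", "decoy"),
              levels = c("decoy", "true"))
  set.seed(seed)
  rf <- randomForest::randomForest(x, y, ntree = ntree,
                                   sampsize = rep(min(table(y)), 2L))
  # calibrate raw vote fractions into probabilities on out-of-bag votes
  # (Platt scaling), so the 0-100 score is a calibrated confidence
  oob <- rf$votes[, "true"]
  cal <- suppressWarnings(stats::glm((y == "true") ~ oob,
                                     family = stats::binomial))
  calib <- unname(stats::coef(cal))
  if (any(!is.finite(calib))) calib <- c(0, 1)
  structure(list(forest = rf, calibration = calib,
                 schema_version = .mirdup_schema_version,
                 features = .mirdup_feature_names,
                 training_scope = scope, seed = seed),
            class = "mirforge_mirdup_model")
}

#' Score mature positions with a trained duplex-position model
#'
#' @param model a `"mirforge_mirdup_model"`.
#' @param features matrix or data frame of feature vectors (rows follow the
#'   model schema), or a single named vector from [extract_features()].
#' @return numeric scores in \[0, 100\]: 100 x the classifier probability of
#'   the true-position class.
#' @export
score_position <- function(model, features) {
  if (!inherits(model, "mirforge_mirdup_model"))
    .stopf("score_position() needs a trained duplex-position model")
  if (is.null(dim(features))) features <- t(as.matrix(features))
  features <- as.data.frame(features)
  if (!identical(names(features), model$features))
    .stopf("feature schema mismatch (model schema version %s)",
           model$schema_version)
  v <- unname(predict(model$forest, features, type = "prob")[, "true"])
  if (!is.null(model$calibration)) {
    v <- stats::plogis(model$calibration[1L] + model$calibration[2L] * v)
  }
  100 * v
}

#' Negative position sampling for duplex-position training
#'
#' For each true (precursor, mature) pair, draws `n_neg` perturbed
#' placements: shifts of the true position by 5-30 nt in either direction
#' and opposite-arm placements, all within the precursor.
#'
#' @param examples data frame with `sequence`, `dotbracket`, `mfe`,
#'   `mature_start`, `mature_end` of true positions.
#' @param n_neg negatives per positive.
#' @param shift_range inclusive range of absolute shifts.
#' @param seed integer seed.
#' @return the input rows labelled 1, followed by negative rows labelled 0.
#' @export
sample_negative_positions <- function(examples, n_neg = 3L,
                                      shift_range = c(5L, 30L), seed = 7L) {
  set.seed(seed)
  pos <- examples
  pos$label <- 1
  negs <- list()
  for (i in seq_len(nrow(examples))) {
    n <- nchar(examples$sequence[i])
    mlen <- examples$mature_end[i] - examples$mature_start[i]
    drawn <- 0L; tries <- 0L
    while (drawn < n_neg && tries < 50L) {
      tries <- tries + 1L
      sh <- sample(shift_range[1L]:shift_range[2L], 1L) *
        sample(c(-1L, 1L), 1L)
      ns <- examples$mature_start[i] + sh
      if (ns < 0L || ns + mlen > n) next
      row <- examples[i, , drop = FALSE]
      row$mature_start <- ns
      row$mature_end <- ns + mlen
      row$label <- 0
      negs[[length(negs) + 1L]] <- row
      drawn <- drawn + 1L
    }
  }
  rbind(pos, do.call(rbind, negs))
}

#' Gate scored candidates on score and abundance
#'
#' Keeps a candidate iff its duplex-position score strictly exceeds
#' `score_min` (default 90) and its raw read count reaches `abundance_min`
#' (default 100) in at least one library.
#'
#' @param candidates data frame with a `score` column and a `mature_seq`
#'   column naming rows of `matrix`.
#' @param matrix count matrix from [collapse_reads()].
#' @param score_min strict lower bound on the score.
#' @param abundance_min per-library count threshold (kept when equal).
#' @return the accepted subset of `candidates`.
#' @export
accept_candidates <- function(candidates, matrix, score_min = 90,
                              abundance_min = 100) {
  if (!nrow(candidates)) return(candidates)
  maxc <- apply(matrix, 1L, max)
  cnt <- maxc[candidates$mature_seq]
  cnt[is.na(cnt)] <- 0
  keep <- candidates$score > score_min & cnt >= abundance_min
  candidates[keep, , drop = FALSE]
}

#' Rule-based structural check of a mature position
#'
#' A rule filter in the spirit of classic plant-miRNA structural checkers,
#' used side-by-side with the learned duplex-position score for comparison —
#' never as a hard filter by default. A position passes iff the number of
#' unpaired mature bases, the longest bulge run in the duplex, and the
#' duplex asymmetry all stay within the configured caps, and the mature does
#' not overlap the terminal loop.
#'
#' @param dotbracket,mature_start,mature_end the candidate position.
#' @param max_unpaired cap on unpaired mature bases.
#' @param max_bulge cap on the longest run of successive unpaired bases.
#' @param max_asym cap on |unpaired mature-side - unpaired star-side|.
#' @return logical verdict.
#' @export
mircheck_rules <- function(dotbracket, mature_start, mature_end,
                           max_unpaired = 4L, max_bulge = 2L,
                           max_asym = 3L) {
  pt <- pairing_table(dotbracket)
  mi <- (mature_start + 1L):mature_end
  unpaired_m <- sum(pt[mi] == 0L)
  if (unpaired_m > max_unpaired) return(FALSE)
  dup <- tryCatch(duplex_characteristics(dotbracket, mature_start,
                                         mature_end),
                  error = function(e) NULL)
  if (is.null(dup)) return(FALSE)
  if (dup$B > max_bulge) return(FALSE)
  # asymmetry between the two duplex strands
  paired <- mi[pt[mi] > 0L]
  span_m <- paired[1L]:paired[length(paired)]
  span_s <- min(pt[paired]):max(pt[paired])
  un_m <- sum(pt[span_m] == 0L); un_s <- sum(pt[span_s] == 0L)
  if (abs(un_m - un_s) > max_asym) return(FALSE)
  # no overlap with the terminal loop
  loops <- .terminal_loops(pt)
  if (nrow(loops)) {
    ov <- any(loops$start <= mature_end & loops$end >= mature_start + 1L)
    if (ov) return(FALSE)
  }
  TRUE
}
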