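#' Extract candidate precursor windows around a mapped locus
#'
#' For every mapped small-RNA locus, two candidate sequences are emitted: the
#' reference window spanning 20 nt upstream of the read start to 160 nt
#' downstream of its end (clipped at the reference bounds), and the reverse
#' complement of the same window — i.e. both strands of the locus, exactly
#' two candidates per hit.
#'
#' @param hits data frame from [map_reads()] (or a subset).
#' @param reference data frame with `id`, `sequence`.
#' @param upstream,downstream window extension in nt before the read start /
#'   after the read end.
#' @return data frame with one row per candidate: `ref_id`, `strand` (window
#'   strand), `window_start`, `window_end` (0-based half-open, + strand
#'   coordinates), `sequence`, `seed_read`, `read_offset` (0-based start of
#'   the seed read within the window sequence), `read_len`.
#' @export
extract_windows <- function(hits, reference, upstream = 20L,
                            downstream = 160L) {
  refseq <- setNames(dna(reference$sequence), reference$id)
  reflen <- setNames(nchar(refseq), reference$id)
  ws <- pmax(0L, hits$start - upstream)
  we <- pmin(reflen[hits$ref_id], hits$end + downstream)
  plus_seq <- substr(refseq[hits$ref_id], ws + 1L, we)
  minus_seq <- revcomp(plus_seq)
  rl <- hits$end - hits$start
  # read position within the window on each strand
  off_plus <- hits$start - ws
  off_minus <- we - hits$end
  mk <- function(strand, seqs, off, seed) {
    data.frame(ref_id = hits$ref_id, strand = strand,
               window_start = as.integer(ws), window_end = as.integer(we),
               sequence = unname(seqs), seed_read = seed,
               read_offset = as.integer(off), read_len = as.integer(rl),
               stringsAsFactors = FALSE)
  }
  # the seed read as it appears on each window strand
  seed_plus <- ifelse(hits$strand == "+", hits$sequence,
                      revcomp(hits$sequence))
  seed_minus <- revcomp(seed_plus)
  out <- rbind(mk("+", plus_seq, off_plus, seed_plus),
               mk("-", minus_seq, off_minus, seed_minus))
  out$id <- sprintf("%s:%d-%d(%s)", out$ref_id, out$window_start,
                    out$window_end, out$strand)
  rownames(out) <- NULL
  out
}

# uniform feature frame for hairpin classification
.hairpin_feature_frame <- function(sequences, structures, mfes) {
  do.call(rbind, lapply(seq_along(sequences), function(i) {
    hairpin_features(sequences[i], structures[i], mfes[i])
  }))
}

#' Train the hairpin plausibility classifier
#'
#' A seeded random-forest over [hairpin_features()] that separates genuine
#' pre-miRNA hairpins from folded background sequence. It replaces external
#' hairpin predictors as a broad-recall pre-filter ahead of the duplex
#' position classifier, so its default decision threshold is permissive.
#'
#' @param positives,negatives data frames with `sequence`, `structure`,
#'   `mfe` columns (e.g. from [fold()]).
#' @param seed integer seed; training is reproducible for a fixed seed.
#' @param ntree forest size.
#' @return object of class `"mirforge_hairpin_model"`.
#' @export
train_hairpin_model <- function(positives, negatives, seed = 42L,
                                ntree = 300L) {
  if (nrow(positives) == 0L || nrow(negatives) == 0L)
    .stopf("both positive and negative hairpins are required")
  if (nrow(positives) < 20L || nrow(negatives) < 20L)
    .stopf("need at least 20 examples per class (got %d / %d)",
           nrow(positives), nrow(negatives))
  r <- nrow(positives) / nrow(negatives)
  if (r > 10 || r < 0.1)
    .warnf("class imbalance exceeds 10:1 (%d vs %d)",
           nrow(positives), nrow(negatives))
  x <- rbind(
    .hairpin_feature_frame(positives$sequence, positives$structure,
                           positives$mfe),
    .hairpin_feature_frame(negatives$sequence, negatives$structure,
                           negatives$mfe))
  x$mfei[is.na(x$mfei)] <- 0
  y <- factor(rep(c("hairpin", "background"),
                  c(nrow(positives), nrow(negatives))),
              levels = c("background", "hairpin"))
  set.seed(seed)
  rf <- randomForest::randomForest(x, y, ntree = ntree)
  structure(list(forest = rf, features = names(x), seed = seed),
            class = "mirforge_hairpin_model")
}

#' Score a candidate window as a pre-miRNA hairpin
#'
#' Hard structural gates are applied first — exactly one terminal loop,
#' paired fraction at least `min_paired`, negative MFE — then the trained
#' model assigns a hairpin probability. Gated-out candidates score 0.
#'
#' @param model a `"mirforge_hairpin_model"` from [train_hairpin_model()].
#' @param sequences,structures,mfes candidate windows (parallel vectors).
#' @param min_paired hard gate on paired fraction.
#' @return data frame with `prob` (0 for gated-out candidates) and `gated`
#'   (TRUE when a hard gate rejected the candidate).
#' @export
classify_premirna <- function(model, sequences, structures, mfes,
                              min_paired = 0.4) {
  if (!inherits(model, "mirforge_hairpin_model"))
    .stopf("classify_premirna() needs a trained hairpin model")
  feats <- .hairpin_feature_frame(sequences, structures, mfes)
  feats$mfei[is.na(feats$mfei)] <- 0
  gated <- feats$n_terminal_loops != 1L | feats$paired_fraction < min_paired |
    feats$mfe >= 0
  prob <- rep(0, length(sequences))
  if (any(!gated)) {
    p <- predict(model$forest, feats[!gated, , drop = FALSE], type = "prob")
    prob[!gated] <- p[, "hairpin"]
  }
  data.frame(prob = prob, gated = gated)
}

#' Dinucleotide-preserving sequence shuffle
#'
#' Generates background sequences with the dinucleotide composition of the
#' input (random Eulerian-walk shuffle with a plain-shuffle fallback for
#' degenerate inputs); used to build negatives for the hairpin classifier.
#'
#' @param sequence nucleotide string.
#' @return shuffled string.
#' @export
dinucleotide_shuffle <- function(sequence) {
  b <- strsplit(dna(sequence), "")[[1L]]
  n <- length(b)
  if (n < 4L) return(paste(sample(b), collapse = ""))
  # adjacency lists of the dinucleotide multigraph
  adj <- split(b[-1L], b[-n])
  adj <- lapply(adj, sample)
  cur <- b[1L]
  out <- character(n)
  out[1L] <- cur
  ptr <- setNames(rep(1L, length(adj)), names(adj))
  for (i in 2:n) {
    nxt_list <- adj[[cur]]
    p <- ptr[[cur]]
    if (is.null(nxt_list) || p > length(nxt_list)) {
      # walk stuck before consuming all edges: fall back to plain shuffle
      return(paste(sample(b), collapse = ""))
    }
    nxt <- nxt_list[p]
    ptr[[cur]] <- p + 1L
    out[i] <- nxt
    cur <- nxt
  }
  paste(out, collapse = "")
}
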