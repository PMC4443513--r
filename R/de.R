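#' Reads-per-million normalization
#'
#' @param count raw count(s).
#' @param library_size total mapped reads in the library.
#' @return `count / library_size * 1e6`.
#' @export
rpm_normalize <- function(count, library_size) {
  if (any(library_size <= 0)) .stopf("library size must be positive")
  count / library_size * 1e6
}

#' Abundance prefilter of a count matrix
#'
#' Removes sequences whose read count is below `min_count` in all
#' libraries; a sequence reaching the threshold in any one library
#' survives.
#'
#' @param matrix count matrix from [collapse_reads()].
#' @param min_count threshold (kept when the maximum equals it).
#' @return the filtered matrix with its `library_sizes` attribute intact
#'   (sizes stay those of the unfiltered libraries).
#' @export
prefilter_min_count <- function(matrix, min_count = 100L) {
  keep <- apply(matrix, 1L, max) >= min_count
  out <- matrix[keep, , drop = FALSE]
  attr(out, "library_sizes") <- attr(matrix, "library_sizes")
  out
}

#' Pooled two-proportion z statistic for tag counts
#'
#' The corrected z-score for comparing a tag's frequency between two
#' libraries: with \eqn{p_1 = x_1/N_1}, \eqn{p_2 = x_2/N_2} and the pooled
#' \eqn{p_0 = (x_1 + x_2)/(N_1 + N_2)},
#' \deqn{z = (p_1 - p_2) / \sqrt{p_0 (1 - p_0) (1/N_1 + 1/N_2)}}
#' with a two-sided normal p-value. Degenerate pools (\eqn{p_0 \in \{0,1\}})
#' return z = 0, p = 1 and are flagged.
#'
#' @param x1,x2 tag counts (vectorised).
#' @param N1,N2 library sizes.
#' @return data frame with `z`, `p`, `degenerate`.
#' @export
kal_z <- function(x1, N1, x2, N2) {
  if (any(N1 <= 0) || any(N2 <= 0)) .stopf("library sizes must be positive")
  if (any(x1 < 0) || any(x2 < 0) || any(x1 > N1) || any(x2 > N2))
    .stopf("counts must satisfy 0 <= x <= N")
  p1 <- x1 / N1
  p2 <- x2 / N2
  p0 <- (x1 + x2) / (N1 + N2)
  degen <- p0 <= 0 | p0 >= 1
  se <- sqrt(p0 * (1 - p0) * (1 / N1 + 1 / N2))
  z <- ifelse(degen, 0, (p1 - p2) / se)
  p <- ifelse(degen, 1, 2 * pnorm(-abs(z)))
  data.frame(z = z, p = p, degenerate = degen)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param pvalues numeric vector in \[0, 1\].
#' @return adjusted q-values (monotone, each at most 1).
#' @export
bh_fdr <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues < 0) || any(pvalues > 1))
    .stopf("p-values must lie in [0, 1]")
  p.adjust(pvalues, method = "BH")
}

#' Differential-expression calls between two libraries
#'
#' For each sequence of a (prefiltered) count matrix, computes rpm in the
#' treated and control libraries, the fold change on rpm with a pseudo-count
#' added to both sides, the pooled two-proportion z statistic on the raw
#' counts, BH-adjusted q-values (per comparison), and a regulation call:
#' `up` iff q < `fdr` and fold change >= `fc_high`, `down` iff q < `fdr`
#' and fold change <= `fc_low`, otherwise `ns`.
#'
#' @param matrix count matrix with a `library_sizes` attribute.
#' @param treated,control library (column) names.
#' @param label comparison label (defaults to `"treated/control"`).
#' @param fc_low,fc_high fold-change gates (retained outside
#'   (`fc_low`, `fc_high`)).
#' @param fdr FDR level.
#' @param pseudo_rpm pseudo-count (rpm units) added to both sides of the
#'   ratio.
#' @return data frame of class `"mirforge_de"`: `sequence`,
#'   `comparison_id`, `count_treated`, `count_control`, `rpm_treated`,
#'   `rpm_control`, `fold_change`, `z`, `p`, `q`, `call`.
#' @export
call_regulation <- function(matrix, treated, control, label = NULL,
                            fc_low = 0.5, fc_high = 2.0, fdr = 0.05,
                            pseudo_rpm = 0.5) {
  if (!all(c(treated, control) %in% colnames(matrix)))
    .stopf("unknown library id: %s",
           paste(setdiff(c(treated, control), colnames(matrix)),
                 collapse = ", "))
  sizes <- attr(matrix, "library_sizes")
  if (is.null(sizes)) sizes <- colSums(matrix)
  if (is.null(label)) label <- paste0(treated, "/", control)
  x1 <- matrix[, treated]
  x2 <- matrix[, control]
  r1 <- rpm_normalize(x1, sizes[[treated]])
  r2 <- rpm_normalize(x2, sizes[[control]])
  fc <- (r1 + pseudo_rpm) / (r2 + pseudo_rpm)
  zt <- kal_z(x1, sizes[[treated]], x2, sizes[[control]])
  q <- bh_fdr(zt$p)
  call <- rep("ns", nrow(matrix))
  call[q < fdr & fc >= fc_high] <- "up"
  call[q < fdr & fc <= fc_low] <- "down"
  res <- data.frame(sequence = rownames(matrix), comparison_id = label,
                    count_treated = unname(x1), count_control = unname(x2),
                    rpm_treated = unname(r1), rpm_control = unname(r2),
                    fold_change = unname(fc), z = zt$z, p = zt$p, q = q,
                    call = call, stringsAsFactors = FALSE)
  rownames(res) <- NULL
  class(res) <- c("mirforge_de", "data.frame")
  res
}

#' Volcano table of a DE result
#'
#' @param de a result of [call_regulation()].
#' @return data frame `sequence`, `log10_fc`, `neg_log10_q`, `call`.
#' @export
volcano_table <- function(de) {
  data.frame(sequence = de$sequence, log10_fc = log10(de$fold_change),
             neg_log10_q = -log10(pmax(de$q, .Machine$double.xmin)),
             call = de$call, stringsAsFactors = FALSE)
}

#' Expression-pattern group classification across two genotypes
#'
#' Crosses the regulation calls of the same sequences in a tolerant and a
#' sensitive genotype into eight groups. Groups 5 and 6 (up in both / down
#' in both) show the same pattern in both genotypes and are associated with
#' the stress *response*; all other groups differ between genotypes and are
#' associated with *tolerance*. Sequences not significant in either
#' comparison are unclassified (`NA`).
#'
#' @param calls_tolerant,calls_sensitive `"mirforge_de"` results over the
#'   same sequences (one per genotype).
#' @param stress stress label attached to the group code (e.g. `"Co"`,
#'   `"Al"`, `"Dev"`).
#' @return data frame `sequence`, `group_index` (1-8 or NA), `group`
#'   (e.g. `"Co5"`), `semantics` (`"response"` / `"tolerance"` / NA).
#' @export
classify_groups <- function(calls_tolerant, calls_sensitive, stress = "Co") {
  stopifnot(identical(calls_tolerant$sequence, calls_sensitive$sequence))
  a <- calls_tolerant$call     # tolerant genotype
  b <- calls_sensitive$call    # sensitive genotype
  idx <- rep(NA_integer_, length(a))
  idx[a == "up" & b == "ns"] <- 1L
  idx[a == "down" & b == "ns"] <- 2L
  idx[a == "ns" & b == "up"] <- 3L
  idx[a == "ns" & b == "down"] <- 4L
  idx[a == "up" & b == "up"] <- 5L
  idx[a == "down" & b == "down"] <- 6L
  idx[a == "up" & b == "down"] <- 7L
  idx[a == "down" & b == "up"] <- 8L
  sem <- ifelse(is.na(idx), NA_character_,
                ifelse(idx %in% c(5L, 6L), "response", "tolerance"))
  data.frame(sequence = calls_tolerant$sequence, group_index = idx,
             group = ifelse(is.na(idx), NA_character_,
                            paste0(stress, idx)),
             semantics = sem, stringsAsFactors = FALSE)
}
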