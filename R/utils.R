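#' Sequence alphabet helpers
#'
#' All sequences are held internally in the DNA alphabet (`A`, `C`, `G`, `T`,
#' `N`); RNA input is converted on read (`U` to `T`) and RNA is produced only
#' at presentation boundaries such as probes or folding-engine input.
#'
#' @param x character vector of sequences.
#' @return character vector of the same length.
#' @name alphabet
NULL

#' @rdname alphabet
#' @export
dna <- function(x) {
  x <- chartr("u", "t", toupper(x))
  chartr("U", "T", x)
}

#' @rdname alphabet
#' @export
rna <- function(x) chartr("T", "U", toupper(x))

#' @rdname alphabet
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# validate sequences against the internal alphabet
.check_alphabet <- function(x, what = "sequence") {
  bad <- grepl("[^ACGTN]", x)
  if (any(bad)) {
    stop(sprintf("%s contains characters outside {A,C,G,T,N}: '%s'",
                 what, x[which(bad)[1L]]), call. = FALSE)
  }
  invisible(x)
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# deterministic child seeds below 2^31, derived from one root seed
.child_seed <- function(seed, k) {
  (as.integer(seed) %% 1000000L) * 1000L + as.integer(k) %% 1000L
}
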