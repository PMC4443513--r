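#' Trim 3' sequencing adapters
#'
#' Removes from each read the longest suffix that exactly matches a prefix of
#' the adapter, requiring at least `min_overlap` matching bases. Reads where
#' no such overlap exists are kept intact and flagged, so the caller can
#' decide whether untrimmed reads enter the pipeline.
#'
#' @param reads character vector of read sequences (or a data frame from
#'   [read_sequences()], whose `sequence`/`quality` columns are updated).
#' @param adapter adapter sequence (DNA or RNA; converted internally).
#' @param min_overlap minimum adapter prefix length to trigger trimming.
#' @return data frame with `sequence` (trimmed), `trimmed` (logical) and,
#'   when present on input, `quality` clipped to the same length.
#' @export
trim_adapter <- function(reads, adapter, min_overlap = 6L) {
  if (is.data.frame(reads)) {
    res <- trim_adapter(reads$sequence, adapter, min_overlap)
    reads$sequence <- res$sequence
    reads$trimmed <- res$trimmed
    if (!is.null(reads$quality))
      reads$quality <- substr(reads$quality, 1L, nchar(res$sequence))
    return(reads)
  }
  adapter <- dna(adapter)
  if (!nzchar(adapter)) .stopf("adapter must be non-empty")
  seqs <- dna(reads)
  n <- nchar(seqs)
  maxov <- pmin(n, nchar(adapter))
  cut <- rep(NA_integer_, length(seqs))
  # longest adapter prefix occurring as a read suffix, scanning long -> short
  for (ov in seq(nchar(adapter), min(min_overlap, nchar(adapter)))) {
    todo <- is.na(cut) & maxov >= ov
    if (!any(todo)) next
    hit <- substr(seqs[todo], n[todo] - ov + 1L, n[todo]) ==
      substr(adapter, 1L, ov)
    cut[todo][hit] <- ov
  }
  # adapters can also sit internally: full adapter prefix found mid-read
  inner <- regexpr(substr(adapter, 1L, max(min_overlap, 10L)), seqs,
                   fixed = TRUE)
  use_inner <- is.na(cut) & inner > 0L
  cut[use_inner] <- n[use_inner] - inner[use_inner] + 1L
  trimmed <- !is.na(cut)
  out <- seqs
  out[trimmed] <- substr(seqs[trimmed], 1L, n[trimmed] - cut[trimmed])
  data.frame(sequence = out, trimmed = trimmed, stringsAsFactors = FALSE)
}

#' Length and quality filtering of reads
#'
#' Keeps reads whose length lies in `[min_len, max_len]` (both inclusive,
#' default the 18-30 nt small-RNA window) and, when per-base qualities are
#' present, whose mean Phred score meets `min_mean_quality`.
#'
#' @param reads data frame with `sequence` and optional `quality`
#'   (Phred+33), or a character vector.
#' @param min_len,max_len inclusive length bounds.
#' @param min_mean_quality mean Phred threshold; applied only when qualities
#'   exist.
#' @return filtered object of the same type.
#' @export
filter_reads <- function(reads, min_len = 18L, max_len = 30L,
                         min_mean_quality = 20) {
  seqs <- if (is.data.frame(reads)) reads$sequence else reads
  len <- nchar(seqs)
  keep <- len >= min_len & len <= max_len
  if (is.data.frame(reads) && !is.null(reads$quality)) {
    q <- reads$quality
    meanq <- vapply(which(keep), function(i) {
      mean(as.integer(charToRaw(q[i]))) - 33
    }, numeric(1))
    keep[keep][meanq < min_mean_quality] <- FALSE
  }
  if (is.data.frame(reads)) reads[keep, , drop = FALSE] else seqs[keep]
}

#' Low-complexity read filter
#'
#' A self-contained replacement for database-driven repeat masking: a
#' DUST-style statistic over 3-mer over-representation (sum of
#' \eqn{c(c-1)/2} over triplet counts, scaled by the triplet count minus
#' one) plus a homopolymer rule (any single base making up more than
#' `max_mono` of the read). Reads exceeding either rule are dropped.
#'
#' @param sequences character vector.
#' @param dust_threshold DUST score above which a read is dropped.
#' @param max_mono maximum tolerated single-base fraction.
#' @return logical vector, `TRUE` = keep.
#' @export
low_complexity_filter <- function(sequences, dust_threshold = 2.0,
                                  max_mono = 0.8) {
  sequences <- dna(sequences)
  dust <- cpp_dust_score(sequences)
  n <- nchar(sequences)
  mono <- vapply(c("A", "C", "G", "T"), function(b) {
    nchar(sequences) - nchar(gsub(b, "", sequences, fixed = TRUE))
  }, numeric(length(sequences)))
  if (length(sequences) == 1L) mono <- matrix(mono, nrow = 1L)
  monofrac <- apply(mono, 1L, max) / n
  dust <= dust_threshold & monofrac <= max_mono
}

#' @rdname low_complexity_filter
#' @export
dust_score <- function(sequences) cpp_dust_score(dna(sequences))

#' Collapse reads to a unique-sequence expression matrix
#'
#' @param reads data frame with columns `sequence` and `library_id`.
#' @param libraries optional character vector fixing library order (defaults
#'   to order of appearance).
#' @return integer matrix unique sequences x libraries with a
#'   `library_sizes` attribute (column sums); total counts equal the number
#'   of input reads per library.
#' @export
collapse_reads <- function(reads, libraries = NULL) {
  if (is.null(libraries)) libraries <- unique(reads$library_id)
  seqs <- unique(reads$sequence)
  m <- matrix(0L, nrow = length(seqs), ncol = length(libraries),
              dimnames = list(seqs, libraries))
  tab <- table(factor(reads$sequence, levels = seqs),
               factor(reads$library_id, levels = libraries))
  m[] <- as.integer(tab)
  attr(m, "library_sizes") <- colSums(m)
  m
}

#' Map unique sequences to a reference with mismatches
#'
#' Reports every gapless full-length occurrence of each sequence on either
#' strand of every reference record with Hamming distance at most
#' `max_mismatches` (`N` never matches). All hits are kept: multi-mapping
#' sequences are not resolved to a best hit, since miRNA families are
#' repetitive. The scan is k-mer anchored (pigeonhole over read thirds), and
#' equals a brute-force scan over all offsets.
#'
#' @param sequences character vector (typically rownames of the collapsed
#'   matrix).
#' @param reference data frame with `id` and `sequence` columns
#'   (from [read_sequences()]).
#' @param max_mismatches maximum Hamming distance (default 2).
#' @return data frame with columns `sequence`, `ref_id`, `strand`, `start`,
#'   `end` (0-based half-open on the reference + strand), `mismatches`.
#' @export
map_reads <- function(sequences, reference, max_mismatches = 2L) {
  sequences <- dna(sequences)
  .check_alphabet(sequences, "read")
  refs <- dna(reference$sequence)
  hits <- cpp_map_reads(sequences, refs, as.integer(max_mismatches))
  len <- nchar(sequences)[hits$read]
  out <- data.frame(sequence = sequences[hits$read],
                    ref_id = reference$id[hits$ref],
                    strand = hits$strand,
                    start = hits$start,
                    end = hits$start + len,
                    mismatches = hits$mismatches,
                    stringsAsFactors = FALSE)
  out[order(out$ref_id, out$start, out$strand, out$sequence), , drop = FALSE]
}
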