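#' Read sequences from FASTA or FASTQ
#'
#' Parses a FASTA or FASTQ (Sanger Phred+33) file into a data frame of
#' records. Sequences are uppercased and `U` is mapped to `T` so that reads,
#' transcript references and miRBase-style RNA inputs share one comparison
#' alphabet.
#'
#' @param path file path.
#' @param format `"fasta"` or `"fastq"`; default guessed from the extension.
#' @param library_id optional library label attached to every record
#'   (small-RNA reads are organised per sequencing library).
#' @return A data frame with columns `id`, `sequence`, and for FASTQ
#'   `quality` (Phred+33 string) plus `library_id` when supplied.
#' @export
read_sequences <- function(path, format = c("auto", "fasta", "fastq"),
                           library_id = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(fq|fastq)(\\.gz)?$", path, ignore.case = TRUE))
      "fastq" else "fasta"
  }
  if (!file.exists(path)) .stopf("file not found: %s", path)
  res <- tryCatch({
    if (format == "fastq") {
      ss <- Biostrings::readDNAStringSet(path, format = "fastq",
                                         with.qualities = TRUE)
      qual <- as.character(S4Vectors::mcols(ss)$qualities)
      data.frame(id = names(ss), sequence = dna(as.character(ss)),
                 quality = qual, stringsAsFactors = FALSE)
    } else {
      # read as BStringSet first so RNA input (U) is accepted, then map U->T
      ss <- Biostrings::readBStringSet(path, format = "fasta")
      data.frame(id = sub("\\s.*$", "", names(ss)),
                 sequence = dna(as.character(ss)), stringsAsFactors = FALSE)
    }
  }, error = function(e) {
    .stopf("malformed %s file '%s': %s", format, path, conditionMessage(e))
  })
  if (nrow(res) == 0L) .warnf("no records in %s", path)
  if (format == "fastq" && nrow(res) > 0L) {
    bad <- nchar(res$quality) != nchar(res$sequence)
    if (any(bad)) {
      .stopf("FASTQ record %d ('%s'): quality length %d != sequence length %d",
             which(bad)[1L], res$id[which(bad)[1L]],
             nchar(res$quality)[which(bad)[1L]],
             nchar(res$sequence)[which(bad)[1L]])
    }
  }
  .check_alphabet(res$sequence, path)
  if (!is.null(library_id)) res$library_id <- library_id
  rownames(res) <- NULL
  res
}

#' Load a sequence-by-library count matrix from TSV
#'
#' The first column must be `sequence`; every remaining column is an integer
#' count column for one library. Library sizes are the column sums.
#'
#' @param path TSV file path.
#' @return An integer matrix with sequences as rownames and a
#'   `library_sizes` attribute.
#' @export
load_count_matrix <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"sequence" %in% names(tab)) .stopf("'%s': no 'sequence' column", path)
  seqs <- dna(tab$sequence)
  if (anyDuplicated(seqs)) {
    .stopf("duplicate sequence rows in '%s' (e.g. '%s')", path,
           seqs[duplicated(seqs)][1L])
  }
  num <- as.matrix(tab[setdiff(names(tab), "sequence")])
  if (!is.numeric(num) || any(is.na(num)) || any(num < 0) ||
      any(num != round(num))) {
    .stopf("'%s': counts must be non-negative integers", path)
  }
  m <- matrix(as.integer(num), nrow = nrow(num), dimnames =
                list(seqs, colnames(num)))
  attr(m, "library_sizes") <- colSums(m)
  m
}

#' Write a sequence-by-library count matrix to TSV
#' @param matrix integer count matrix with sequence rownames.
#' @param path output path.
#' @export
write_count_matrix <- function(matrix, path) {
  tab <- data.frame(sequence = rownames(matrix), matrix,
                    check.names = FALSE, stringsAsFactors = FALSE)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read transcript annotation and GO-Slim tables
#'
#' `read_annotation` expects a TSV with columns `transcript_id`,
#' `cluster_id` (protein cluster / UniRef-style id) and `description`;
#' `read_go_table` a TSV with columns `cluster_id` and `go_terms`
#' (comma-separated GO-Slim ids, optionally with a `category` column).
#'
#' @param path TSV path.
#' @param go_path GO table TSV path (optional).
#' @return `read_annotation`: a list with `transcripts` (data frame) and
#'   `go` (data frame or NULL), of class `"mirforge_annotation"`. Clusters
#'   carrying GO terms but absent from the transcript mapping are flagged in
#'   the `orphan` column of `go`.
#' @export
read_annotation <- function(path, go_path = NULL) {
  tr <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("transcript_id", "cluster_id", "description")
  if (!all(need %in% names(tr)))
    .stopf("'%s': need columns %s", path, paste(need, collapse = ", "))
  go <- if (!is.null(go_path)) read_go_table(go_path) else NULL
  if (!is.null(go)) go$orphan <- !(go$cluster_id %in% tr$cluster_id)
  structure(list(transcripts = tr, go = go),
            class = "mirforge_annotation")
}

#' @rdname read_annotation
#' @export
read_go_table <- function(go_path) {
  go <- read.delim(go_path, stringsAsFactors = FALSE)
  if (!all(c("cluster_id", "go_terms") %in% names(go)))
    .stopf("'%s': need columns cluster_id, go_terms", go_path)
  if (is.null(go$category)) go$category <- "BP"
  go
}

#' Write candidate report
#'
#' One TSV row per (mature, pre-miRNA) association: identifiers, sequences,
#' coordinates (1-based inclusive in reports), dot-bracket, MFE, duplex
#' position score, per-library counts and expression class; plus one
#' Vienna-format file (sequence line + dot-bracket line) per pre-miRNA.
#'
#' @param candidates data frame of scored candidates as produced by the
#'   discovery stages (columns `mature_id`, `mature_seq`, `premirna_id`,
#'   `ref_id`, `strand`, `window_start`, `window_end`, `premirna_seq`,
#'   `dotbracket`, `mfe`, `mature_start`, `mature_end`, `score`,
#'   `expression_class`, plus `count.<lib>` columns).
#' @param path output TSV path.
#' @param vienna_dir directory for per-precursor Vienna files (created);
#'   `NULL` to skip.
#' @return `path`, invisibly.
#' @export
write_candidate_report <- function(candidates, path, vienna_dir = NULL) {
  out <- candidates
  if (nrow(out)) {
    # reports are 1-based inclusive
    out$window_start <- out$window_start + 1L
    out$mature_start <- out$mature_start + 1L
  }
  ok <- tryCatch({
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    TRUE
  }, error = function(e) .stopf("cannot write '%s': %s", path,
                                conditionMessage(e)))
  if (!is.null(vienna_dir) && nrow(candidates)) {
    dir.create(vienna_dir, showWarnings = FALSE, recursive = TRUE)
    keep <- !duplicated(candidates$premirna_id)
    for (i in which(keep)) {
      write_vienna(candidates$premirna_seq[i], candidates$dotbracket[i],
                   candidates$mfe[i],
                   file.path(vienna_dir,
                             paste0(candidates$premirna_id[i], ".vienna")),
                   id = candidates$premirna_id[i])
    }
  }
  invisible(path)
}

#' Read a candidate report written by [write_candidate_report()]
#' @param path TSV path.
#' @return data frame with internal 0-based half-open coordinates restored.
#' @export
read_candidate_report <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  if (nrow(tab)) {
    tab$window_start <- tab$window_start - 1L
    tab$mature_start <- tab$mature_start - 1L
  }
  tab
}

#' Vienna dot-bracket files
#'
#' @param sequence,structure sequence and dot-bracket strings.
#' @param mfe minimum free energy (kcal/mol).
#' @param path file path.
#' @param id header id.
#' @name vienna
#' @export
write_vienna <- function(sequence, structure, mfe, path, id = "candidate") {
  writeLines(c(paste0(">", id), rna(sequence),
               sprintf("%s (%.2f)", structure, mfe)), path)
  invisible(path)
}

#' @rdname vienna
#' @export
read_vienna <- function(path) {
  ln <- readLines(path)
  structure_line <- ln[3L]
  m <- regmatches(structure_line,
                  regexec("^([.()]+)\\s+\\((\\s*-?[0-9.]+)\\)", structure_line))[[1L]]
  list(id = sub("^>", "", ln[1L]), sequence = dna(ln[2L]),
       structure = m[2L], mfe = as.numeric(m[3L]))
}
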