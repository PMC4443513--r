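#' Fold sequences with the ViennaRNA engine
#'
#' Computes the minimum-free-energy secondary structure of each sequence by
#' calling `RNAfold` (ViennaRNA) in one batch. Folding parameters are pinned
#' (37 degrees C, default dangles); the engine version is recorded so runs
#' are reproducible for a fixed installation.
#'
#' @param sequences character vector (DNA or RNA; T is read as U by the
#'   engine).
#' @return data frame with columns `sequence`, `structure` (dot-bracket) and
#'   `mfe` (kcal/mol); attribute `engine` holds the RNAfold version string.
#' @export
fold <- function(sequences) {
  if (length(sequences) == 0L) {
    return(data.frame(sequence = character(), structure = character(),
                      mfe = numeric(), stringsAsFactors = FALSE))
  }
  if (any(nchar(sequences) < 4L))
    .stopf("fold(): sequences must be at least 4 nt")
  exe <- Sys.which("RNAfold")
  if (exe == "") .stopf("RNAfold not found on PATH (install ViennaRNA)")
  inp <- as.vector(rbind(paste0(">s", seq_along(sequences)),
                         rna(sequences)))
  out <- suppressWarnings(
    system2(exe, "--noPS", input = inp, stdout = TRUE, stderr = FALSE))
  st <- attr(out, "status")
  if (!is.null(st) && st != 0L)
    .stopf("RNAfold failed (status %d) on a batch of %d sequences",
           st, length(sequences))
  heads <- grep("^>", out)
  if (length(heads) != length(sequences))
    .stopf("RNAfold returned %d records for %d sequences",
           length(heads), length(sequences))
  struct_lines <- out[heads + 2L]
  m <- regmatches(struct_lines,
                  regexec("^([.()]+)\\s+\\(\\s*(-?[0-9.]+)\\)", struct_lines))
  bad <- vapply(m, length, integer(1)) != 3L
  if (any(bad))
    .stopf("unparseable RNAfold output for candidate %d: '%s'",
           which(bad)[1L], struct_lines[which(bad)[1L]])
  res <- data.frame(sequence = dna(sequences),
                    structure = vapply(m, `[`, "", 2L),
                    mfe = as.numeric(vapply(m, `[`, "", 3L)),
                    stringsAsFactors = FALSE)
  attr(res, "engine") <- fold_engine_version()
  res
}

#' @rdname fold
#' @export
fold_engine_version <- function() {
  exe <- Sys.which("RNAfold")
  if (exe == "") return(NA_character_)
  v <- tryCatch(system2(exe, "--version", stdout = TRUE, stderr = FALSE)[1L],
                error = function(e) NA_character_)
  v
}

#' Duplex minimum free energy of miRNA:target pairs
#'
#' Calls `RNAduplex` (ViennaRNA) on each (miRNA, site) pair in one batch and
#' returns the duplex MFE in kcal/mol. Positive energies (no stable duplex)
#' are returned as reported.
#'
#' @param mirnas,sites equal-length character vectors; each pair is folded
#'   as an intermolecular duplex.
#' @return numeric vector of duplex MFEs.
#' @export
duplex_mfe <- function(mirnas, sites) {
  stopifnot(length(mirnas) == length(sites))
  if (length(mirnas) == 0L) return(numeric())
  exe <- Sys.which("RNAduplex")
  if (exe == "") .stopf("RNAduplex not found on PATH (install ViennaRNA)")
  inp <- as.vector(rbind(rna(mirnas), rna(sites)))
  out <- suppressWarnings(system2(exe, character(), input = inp,
                                  stdout = TRUE, stderr = FALSE))
  vals <- regmatches(out, regexec("\\(\\s*(-?[0-9.]+)\\)\\s*$", out))
  en <- vapply(vals, function(v) if (length(v) == 2L)
    as.numeric(v[2L]) else NA_real_, numeric(1))
  en <- en[!is.na(en)]
  if (length(en) != length(mirnas))
    .stopf("RNAduplex returned %d energies for %d pairs",
           length(en), length(mirnas))
  en
}
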