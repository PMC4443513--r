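#' Pairing table of a dot-bracket structure
#'
#' @param dotbracket dot-bracket string.
#' @return integer vector: `pt[i]` is the 1-based partner of position `i`,
#'   or 0 when unpaired.
#' @export
pairing_table <- function(dotbracket) {
  ch <- strsplit(dotbracket, "")[[1L]]
  pt <- integer(length(ch))
  stack <- integer(0)
  for (i in seq_along(ch)) {
    if (ch[i] == "(") {
      stack <- c(stack, i)
    } else if (ch[i] == ")") {
      if (!length(stack)) .stopf("unbalanced structure at position %d", i)
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      pt[i] <- j
      pt[j] <- i
    } else if (ch[i] != ".") {
      .stopf("invalid structure character '%s' at position %d", ch[i], i)
    }
  }
  if (length(stack)) .stopf("unbalanced structure: %d unclosed '('",
                            length(stack))
  pt
}

# terminal loops: maximal runs of '.' directly enclosed by a pair with no
# pairs inside; returns data.frame(open, close, start, end) 1-based inclusive
.terminal_loops <- function(pt) {
  n <- length(pt)
  res <- NULL
  for (i in seq_len(n)) {
    j <- pt[i]
    if (j > i) {
      inner <- if (j - i > 1L) (i + 1L):(j - 1L) else integer(0)
      if (length(inner) && all(pt[inner] == 0L)) {
        res <- rbind(res, c(i, j, i + 1L, j - 1L))
      }
    }
  }
  if (is.null(res)) {
    return(data.frame(open = integer(), close = integer(),
                      start = integer(), end = integer()))
  }
  data.frame(open = res[, 1], close = res[, 2], start = res[, 3],
             end = res[, 4])
}

#' Hairpin-level structural features
#'
#' Standard pre-miRNA descriptors of a folded window: length, GC fraction,
#' MFE, AMFE (MFE per 100 nt), MFEI (AMFE over GC percentage), paired
#' fraction, longest helix, number and size of terminal loops, and longest
#' internal bulge.
#'
#' @param sequence nucleotide string.
#' @param dotbracket matching dot-bracket string.
#' @param mfe minimum free energy, kcal/mol.
#' @return one-row data frame of features; `mfei` is `NA` when GC = 0.
#' @export
hairpin_features <- function(sequence, dotbracket, mfe) {
  sequence <- dna(sequence)
  n <- nchar(sequence)
  if (n != nchar(dotbracket))
    .stopf("sequence (%d nt) and structure (%d) lengths differ",
           n, nchar(dotbracket))
  pt <- pairing_table(dotbracket)
  bases <- strsplit(sequence, "")[[1L]]
  gc <- mean(bases %in% c("G", "C"))
  amfe <- mfe / n * 100
  mfei <- if (gc > 0) amfe / (gc * 100) else NA_real_
  paired <- pt > 0L
  # longest helix: run of consecutive '(' whose partners are also consecutive
  ch <- strsplit(dotbracket, "")[[1L]]
  longest_stem <- 0L
  run <- 0L
  for (i in seq_len(n)) {
    if (ch[i] == "(" && i > 1L && ch[i - 1L] == "(" &&
        pt[i] == pt[i - 1L] - 1L) {
      run <- run + 1L
    } else if (ch[i] == "(") {
      run <- 1L
    } else {
      run <- 0L
    }
    longest_stem <- max(longest_stem, run)
  }
  loops <- .terminal_loops(pt)
  loop_sizes <- loops$end - loops$start + 1L
  # bulges: maximal unpaired runs between the outermost pair that are not a
  # terminal loop
  runs <- rle(pt == 0L)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  is_loop_run <- function(s, e) {
    any(loops$start == s & loops$end == e)
  }
  bulge_len <- 0L
  first_p <- if (any(paired)) which(paired)[1L] else NA_integer_
  last_p <- if (any(paired)) max(which(paired)) else NA_integer_
  if (!is.na(first_p)) {
    for (k in seq_along(runs$lengths)) {
      if (!runs$values[k]) next
      s <- starts[k]; e <- ends[k]
      if (s > first_p && e < last_p && !is_loop_run(s, e))
        bulge_len <- max(bulge_len, e - s + 1L)
    }
  }
  data.frame(length = n, gc_fraction = gc, mfe = mfe, amfe = amfe,
             mfei = mfei, paired_fraction = mean(paired),
             longest_stem = longest_stem, n_terminal_loops = nrow(loops),
             terminal_loop_size = if (nrow(loops)) max(loop_sizes) else 0L,
             longest_bulge = bulge_len)
}

#' Trim a folded window to the stem-loop covering an interval
#'
#' Extracted precursor windows are longer than the true hairpin, so the fold
#' of the full window usually carries extra structure in the flanks. This
#' locates, in the folded window, the single stem-loop branch (one terminal
#' loop, extended basally until another branch or the exterior loop is
#' reached) that covers the seed read, and returns its span.
#'
#' @param dotbracket dot-bracket of the folded window.
#' @param read_start,read_end 0-based half-open interval of the seed read in
#'   the window.
#' @param min_cover minimum fraction of the read that the stem-loop must
#'   cover.
#' @return `NULL` if no stem-loop covers the read, else a list with `start`,
#'   `end` (0-based half-open span of the stem-loop in the window).
#' @export
stemloop_span <- function(dotbracket, read_start, read_end,
                          min_cover = 0.9) {
  pt <- pairing_table(dotbracket)
  loops <- .terminal_loops(pt)
  if (!nrow(loops)) return(NULL)
  best <- NULL
  for (k in seq_len(nrow(loops))) {
    a <- loops$open[k]; b <- loops$close[k]
    # extend basally while the enclosing pair closes this branch only
    repeat {
      i <- a - 1L
      while (i >= 1L && pt[i] == 0L) i <- i - 1L
      if (i < 1L) break
      j <- pt[i]
      if (j <= b) break              # branch closes: sibling helix
      inner <- if (j - b > 1L) (b + 1L):(j - 1L) else integer(0)
      if (length(inner) && any(pt[inner] != 0L)) break  # multiloop junction
      a <- i; b <- j
    }
    span <- c(a - 1L, b)             # back to 0-based half-open
    ov <- max(0L, min(span[2L], read_end) - max(span[1L], read_start))
    cover <- ov / (read_end - read_start)
    if (cover >= min_cover &&
        (is.null(best) || (span[2L] - span[1L]) > (best$end - best$start))) {
      best <- list(start = span[1L], end = span[2L], cover = cover)
    }
  }
  best
}
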