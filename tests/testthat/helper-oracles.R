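# Independent brute-force oracles used to cross-check the implementation.
# These deliberately use different algorithms from the package internals.

# exhaustive gapless scan of one read over every offset and both strands;
# mismatch counts accumulated per-position over vectorised offsets
oracle_map <- function(sequences, reference, max_mm = 2L) {
  out <- list()
  for (r in seq_len(nrow(reference))) {
    ref <- strsplit(reference$sequence[r], "")[[1L]]
    nref <- length(ref)
    for (q in seq_along(sequences)) {
      for (strand in c("+", "-")) {
        rd <- if (strand == "+") sequences[q] else revcomp(sequences[q])
        rv <- strsplit(rd, "")[[1L]]
        L <- length(rv)
        if (L > nref) next
        offs <- seq_len(nref - L + 1L)
        mm <- integer(length(offs))
        for (i in seq_len(L)) {
          b <- ref[offs + i - 1L]
          mm <- mm + as.integer(b != rv[i] | rv[i] == "N" | b == "N")
        }
        hit <- which(mm <= max_mm)
        if (length(hit)) {
          out[[length(out) + 1L]] <- data.frame(
            sequence = sequences[q], ref_id = reference$id[r],
            strand = strand, start = hit - 1L, end = hit - 1L + L,
            mismatches = mm[hit], stringsAsFactors = FALSE)
        }
      }
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res)) return(res)
  res[order(res$ref_id, res$start, res$strand, res$sequence), , drop = FALSE]
}

# pairing partners via depth matching (no stack): the partner of '(' at i is
# the first ')' after i whose running depth drops back to depth(i) - 1
oracle_pairing <- function(db) {
  ch <- strsplit(db, "")[[1L]]
  n <- length(ch)
  step <- ifelse(ch == "(", 1L, ifelse(ch == ")", -1L, 0L))
  lv <- cumsum(step)
  pt <- integer(n)
  for (i in which(ch == "(")) {
    j <- i + 1L
    while (j <= n && !(ch[j] == ")" && lv[j] == lv[i] - 1L)) j <- j + 1L
    pt[i] <- j
    pt[j] <- i
  }
  pt
}

# duplex characteristics recomputed with explicit per-position scans
oracle_duplex <- function(db, ms, me) {
  pt <- oracle_pairing(db)
  mi <- (ms + 1L):me
  paired <- mi[pt[mi] > 0L]
  if (!length(paired)) stop("no duplex")
  runs <- function(positions) {
    lens <- integer(0)
    cur <- 0L
    for (p in positions) {
      if (pt[p] == 0L) cur <- cur + 1L
      else { if (cur > 0L) lens <- c(lens, cur); cur <- 0L }
    }
    if (cur > 0L) lens <- c(lens, cur)
    lens
  }
  span_m <- seq(min(paired), max(paired))
  partners <- pt[paired]
  span_s <- seq(min(partners), max(partners))
  if (length(intersect(span_m, span_s))) stop("no duplex")
  bl <- c(runs(span_m), runs(span_s))
  # terminal loop: walk inward from the loop-proximal pair collecting dots
  on5 <- min(span_m) < min(span_s)
  prox <- if (on5) max(paired) else min(paired)
  lo <- min(prox, pt[prox]); hi <- max(prox, pt[prox])
  # terminal loop: a maximal dot run whose flanks pair with each other
  best <- 0L
  p <- lo + 1L
  while (p < hi) {
    if (pt[p] == 0L) {
      e <- p
      while (e + 1L < hi && pt[e + 1L] == 0L) e <- e + 1L
      if (pt[p - 1L] == e + 1L) best <- max(best, e - p + 1L)
      p <- e + 1L
    } else p <- p + 1L
  }
  list(A = length(bl), B = if (length(bl)) max(bl) else 0L, C = sum(bl),
       D = best)
}

# textbook pooled two-proportion z-test, scalar arithmetic
oracle_kal <- function(x1, N1, x2, N2) {
  phat <- (x1 + x2) / (N1 + N2)
  z <- ((x1 / N1) - (x2 / N2)) /
    sqrt(phat * (1 - phat) * (1 / N1 + 1 / N2))
  c(z = z, p = 2 * pnorm(-abs(z)))
}

# BH step-up computed from the definition (min over larger ranks)
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  sorted <- p[o]
  for (i in seq_len(m)) {
    q[i] <- min(sorted[i:m] * m / (i:m))
  }
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# exact hypergeometric upper tail by enumeration of all C(N, n) draws
oracle_hyper_enum <- function(N, K, n, k) {
  draws <- utils::combn(N, n)
  special <- seq_len(K)
  hits <- colSums(matrix(draws %in% special, nrow = n))
  mean(hits >= k)
}

# exhaustive ungapped alignment of a query against every db entry/offset;
# like the search definition, an alignment needs a word_size run of exact
# matches (the seed), checked here on the per-position match vector
oracle_conserve <- function(queries, db, identity_min = 80, qcov_min = 90,
                            scov_min = 90, word_size = 7L) {
  rows <- list()
  for (q in queries) {
    qv <- strsplit(q, "")[[1L]]
    for (s in seq_len(nrow(db))) {
      sv <- strsplit(dna(db$sequence[s]), "")[[1L]]
      best <- NULL
      for (d in seq(-(length(qv) - 1L), length(sv) - 1L)) {
        qs <- max(1L, 1L - d); qe <- min(length(qv), length(sv) - d)
        if (qe < qs) next
        a <- qv[qs:qe]; b <- sv[(qs + d):(qe + d)]
        eq <- a == b & a != "N"
        r <- rle(eq)
        if (!any(r$values & r$lengths >= word_size)) next
        m <- sum(eq)
        sc <- m - 2L * ((qe - qs + 1L) - m)
        if (is.null(best) || sc > best["score"]) {
          best <- c(score = sc, len = qe - qs + 1L, matches = m)
        }
      }
      if (is.null(best)) next
      idp <- 100 * best["matches"] / best["len"]
      qc <- 100 * best["len"] / length(qv)
      sc2 <- 100 * best["len"] / length(sv)
      if (idp >= identity_min && qc >= qcov_min && sc2 >= scov_min) {
        rows[[length(rows) + 1L]] <- data.frame(
          query_seq = q, db_id = db$id[s], score = unname(best["score"]),
          stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, rows)
  if (is.null(res)) data.frame(query_seq = character(), db_id = character(),
                               score = integer()) else res
}

random_dna <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}
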