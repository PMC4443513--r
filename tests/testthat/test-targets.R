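test_that("complementarity scoring follows the seed-weighted scheme", {
  set.seed(60)
  m <- random_dna(21)
  site <- revcomp(m)
  perfect <- score_target_site(m, site)
  expect_equal(perfect$score, 0)
  expect_equal(perfect$alignment, strrep("|", 21))

  # G:U wobble at miRNA position 15 (outside the seed) costs 0.5
  place_vs <- function(mir_pos, target_base) {
    s <- site
    p <- 21 - mir_pos + 1
    substr(s, p, p) <- target_base
    s
  }
  m2 <- m
  substr(m2, 15, 15) <- "G"
  s2 <- revcomp(m2)
  substr(s2, 21 - 15 + 1, 21 - 15 + 1) <- "T"   # G faces U
  expect_equal(score_target_site(m2, s2)$score, 0.5)

  # mismatch in the seed (position 5) is doubled
  m3 <- m
  substr(m3, 5, 5) <- "A"
  s3 <- revcomp(m3)
  substr(s3, 21 - 5 + 1, 21 - 5 + 1) <- "A"     # A faces A: plain mismatch
  sc3 <- score_target_site(m3, s3)
  expect_equal(sc3$score, 2.0)

  # permutation stability: the score is the sum of per-position penalties
  per_pos <- function(mirna, window) {
    mv <- strsplit(mirna, "")[[1]]
    tv <- strsplit(window, "")[[1]]
    L <- length(mv)
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    total <- 0
    for (i in seq_len(L)) {
      tb <- tv[L - i + 1]
      pen <- if (comp[[mv[i]]] == tb) 0
      else if ((mv[i] == "G" && tb == "T") || (mv[i] == "T" && tb == "G"))
        0.5 else 1
      if (i >= 2 && i <= 12) pen <- 2 * pen
      total <- total + pen
    }
    total
  }
  for (k in 1:25) {
    mm <- random_dna(21)
    w <- random_dna(21)
    expect_equal(score_target_site(mm, w)$score, per_pos(mm, w))
  }
})

test_that("energy ratio is 1 for perfect complements and gates weak sites", {
  set.seed(61)
  m <- random_dna(21, gc = 0.55)
  expect_equal(energy_ratio(m, revcomp(m)), 1)
  # ratio non-increasing as mismatches accumulate
  sites <- revcomp(m)
  ratios <- numeric(4)
  ratios[1] <- energy_ratio(m, sites)
  s <- sites
  for (k in 2:4) {
    p <- 3 + 5 * k
    substr(s, p, p) <- setdiff(c("A", "C", "G", "T"), substr(s, p, p))[1]
    ratios[k] <- energy_ratio(m, s)
  }
  expect_true(all(diff(ratios) <= 1e-9))
})

test_that("target prediction scans transcripts and applies both gates", {
  set.seed(62)
  m <- random_dna(21, gc = 0.55)
  hit_t <- paste0(random_dna(60), revcomp(m), random_dna(60))
  miss_t <- random_dna(150)
  unknown_t <- paste0(random_dna(30), revcomp(m), random_dna(30))
  ref <- data.frame(id = c("T1", "T2", "T3"),
                    sequence = c(hit_t, miss_t, unknown_t),
                    stringsAsFactors = FALSE)
  at <- tempfile(fileext = ".tsv")
  writeLines(c("transcript_id\tcluster_id\tdescription",
               "T1\tCL1\tauxin response factor",
               "T2\tCL2\tkinase",
               "T3\tCL3\tunknown protein"), at)
  ann <- read_annotation(at)
  hits <- predict_targets(c(mir1 = m), ref, ann)
  expect_equal(hits$transcript_id, "T1")   # unknown-protein EST excluded
  expect_equal(hits$site_start, 60L)
  expect_equal(hits$score, 0)
  expect_equal(hits$annotation_id, "CL1")
  expect_true(all(hits$score <= 3 & hits$energy_ratio >= 0.7))
  # no sub-threshold window anywhere -> empty
  none <- predict_targets(c(mir1 = random_dna(21)),
                          ref[2, , drop = FALSE], NULL)
  expect_equal(nrow(none), 0L)
})

test_that("hypergeometric enrichment equals exact enumeration", {
  # worked example: N=20, K=5, n=5, k=3
  p_closed <- phyper(2, 5, 15, 5, lower.tail = FALSE)
  expect_equal(p_closed, 1126 / 15504, tolerance = 1e-12)
  expect_equal(oracle_hyper_enum(20, 5, 5, 3), 1126 / 15504,
               tolerance = 1e-12)

  go <- data.frame(cluster_id = sprintf("CL%02d", 1:20),
                   go_terms = c(rep("GO:A", 5), rep("GO:B", 15)),
                   category = "BP", stringsAsFactors = FALSE)
  bg <- sprintf("CL%02d", 1:20)
  tgt <- c("CL01", "CL02", "CL03", "CL06", "CL07")  # k=3 of GO:A
  res <- hypergeom_enrichment(tgt, bg, go)
  a <- res[res$go_term == "GO:A", ]
  expect_equal(a$k, 3L)
  expect_equal(a$p, 1126 / 15504, tolerance = 1e-12)
  expect_false(a$enriched)  # 0.0726 > 0.05

  # randomized agreement with enumeration at N <= 25
  set.seed(63)
  for (i in 1:10) {
    N <- sample(10:22, 1)
    K <- sample(2:(N - 2), 1)
    n <- sample(2:(N - 2), 1)
    bg2 <- sprintf("X%02d", 1:N)
    go2 <- data.frame(cluster_id = bg2,
                      go_terms = c(rep("GO:T", K), rep("GO:other", N - K)),
                      category = "MF", stringsAsFactors = FALSE)
    tgt2 <- sample(bg2, n)
    k <- sum(tgt2 %in% bg2[1:K])
    res2 <- hypergeom_enrichment(tgt2, bg2, go2)
    expect_equal(res2$p[res2$go_term == "GO:T"],
                 oracle_hyper_enum(N, K, n, k), tolerance = 1e-10)
  }
  expect_error(hypergeom_enrichment("CL99", bg, go), "absent")
})

test_that("significance bins follow the printed thresholds", {
  # a singleton background: the only term has p = 1, bin none
  go <- data.frame(cluster_id = "CL1", go_terms = "GO:A", category = "BP",
                   stringsAsFactors = FALSE)
  res <- hypergeom_enrichment("CL1", "CL1", go)
  expect_equal(res$p, 1)
  expect_equal(res$bin, "none")
  expect_equal(res$glyph, "")
  go3 <- data.frame(cluster_id = sprintf("C%03d", 1:200),
                    go_terms = c(rep("GO:hot", 12), rep("GO:cold", 188)),
                    category = "BP", stringsAsFactors = FALSE)
  res3 <- hypergeom_enrichment(sprintf("C%03d", 1:12),
                               sprintf("C%03d", 1:200), go3)
  hot <- res3[res3$go_term == "GO:hot", ]
  expect_equal(hot$bin, "high")      # all 12 of 12 drawn: p ~ 1e-27
  expect_equal(hot$glyph, "+++")
  # bins are the thresholded p-value on every returned row
  for (r in seq_len(nrow(res3))) {
    want <- if (res3$p[r] < 1e-5) "high" else if (res3$p[r] < 1e-3)
      "medium" else if (res3$p[r] < 0.05) "low" else "none"
    expect_equal(res3$bin[r], want)
  }
})

test_that("backgrounds are global or condition-restricted subsets", {
  at <- tempfile(fileext = ".tsv")
  writeLines(c("transcript_id\tcluster_id\tdescription",
               paste(sprintf("T%02d", 1:50), sprintf("CL%02d", 1:50),
                     "protein", sep = "\t")), at)
  ann <- read_annotation(at)
  bg <- build_background("global", ann)
  expect_length(bg, 50)
  cond <- build_background("condition", ann,
                           condition_targets = sprintf("CL%02d", 5:16))
  expect_length(cond, 12)
  expect_true(all(cond %in% bg))
  expect_error(build_background("condition", ann), "condition_targets")
})
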