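test_that("rpm and the abundance prefilter follow their definitions", {
  expect_equal(rpm_normalize(250, 5e6), 50)
  expect_equal(rpm_normalize(0, 5e6), 0)
  expect_equal(rpm_normalize(5e6, 5e6), 1e6)
  expect_error(rpm_normalize(1, 0), "positive")

  m <- matrix(c(99L, 99L, 100L, 0L, 0L, 0L), nrow = 3, byrow = TRUE,
              dimnames = list(c("a", "b", "c"), c("L1", "L2")))
  attr(m, "library_sizes") <- c(L1 = 1000, L2 = 1000)
  f <- prefilter_min_count(m)
  expect_equal(rownames(f), "b")   # (99,99) out, (100,0) kept, (0,0) out
  expect_equal(attr(f, "library_sizes"), c(L1 = 1000, L2 = 1000))
})

test_that("kal_z matches the worked example and its symmetries", {
  r <- kal_z(100, 1e6, 300, 1e6)
  expect_equal(round(r$z, 2), -10.00)
  # antisymmetry
  r2 <- kal_z(300, 1e6, 100, 1e6)
  expect_equal(r2$z, -r$z)
  expect_equal(r2$p, r$p)
  # equal proportions
  r3 <- kal_z(50, 1000, 50, 1000)
  expect_equal(r3$z, 0)
  expect_equal(r3$p, 1)
  # degenerate pool
  r4 <- kal_z(0, 1000, 0, 2000)
  expect_true(r4$degenerate)
  expect_equal(r4$p, 1)
  expect_error(kal_z(-1, 10, 1, 10), "counts")
})

test_that("kal_z equals the textbook pooled two-proportion test", {
  set.seed(50)
  n <- 10000
  N1 <- sample(1e4:1e6, n, replace = TRUE)
  N2 <- sample(1e4:1e6, n, replace = TRUE)
  x1 <- rbinom(n, 2000, 0.5)
  x2 <- rbinom(n, 2000, 0.5)
  got <- kal_z(x1, N1, x2, N2)
  for (i in sample(n, 200)) {
    want <- oracle_kal(x1[i], N1[i], x2[i], N2[i])
    expect_equal(got$z[i], unname(want["z"]), tolerance = 1e-9)
    expect_lt(abs(got$p[i] - unname(want["p"])), 1e-9)
  }
  # full-vector agreement
  want_z <- ((x1 / N1) - (x2 / N2)) /
    sqrt(((x1 + x2) / (N1 + N2)) * (1 - (x1 + x2) / (N1 + N2)) *
           (1 / N1 + 1 / N2))
  expect_equal(got$z, want_z, tolerance = 1e-9)
})

test_that("BH adjustment matches an independent step-up", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.007), 0.007)
  expect_equal(bh_fdr(rep(0.2, 5)), rep(0.2, 5))
  expect_error(bh_fdr(c(0.5, 1.2)), "0, 1")
  set.seed(51)
  for (i in 1:20) {
    p <- runif(sample(3:50, 1))^sample(1:3, 1)
    q <- bh_fdr(p)
    expect_equal(q, oracle_bh(p), tolerance = 1e-12)
    # q is monotone in p-rank
    o <- order(p)
    expect_true(all(diff(q[o]) >= -1e-12))
    expect_true(all(q >= p))
  }
})

test_that("regulation calls require both the FDR and fold-change gates", {
  set.seed(52)
  seqs <- vapply(rep(21, 6), random_dna, character(1))
  m <- matrix(c(3000L, 1000L,   # FC 3, tiny p -> up
                1500L, 1000L,   # FC 1.5 -> ns despite tiny p
                300L, 1200L,    # FC 0.25 -> down
                1000L, 1000L,   # null
                990L, 1010L,    # null
                260L, 130L),    # FC 2 boundary
              nrow = 6, byrow = TRUE, dimnames = list(seqs, c("T", "C")))
  attr(m, "library_sizes") <- c(T = 1e6, C = 1e6)
  de <- call_regulation(m, "T", "C", pseudo_rpm = 0)
  expect_equal(de$call[1], "up")
  expect_equal(de$call[2], "ns")
  expect_equal(de$call[3], "down")
  expect_equal(de$call[4], "ns")
  expect_true(all(de$q >= de$p))
  # DEResult invariants
  expect_true(all(de$fold_change[de$call == "up"] >= 2))
  expect_true(all(de$fold_change[de$call == "down"] <= 0.5))
  expect_true(all(de$q[de$call != "ns"] < 0.05))
  expect_error(call_regulation(m, "T", "X"), "unknown library")
  v <- volcano_table(de)
  expect_equal(v$log10_fc, log10(de$fold_change))
})

test_that("planted fold changes are recovered with controlled error", {
  set.seed(53)
  n_each <- 60
  fc <- rep(c(0.25, 1, 4), each = n_each)
  base <- 600
  x_c <- rpois(length(fc), base)
  x_t <- rpois(length(fc), base * fc)
  extra_c <- 3e5 - sum(x_c); extra_t <- 3e5 - sum(x_t)
  m <- rbind(cbind(x_t, x_c),
             matrix(c(extra_t, extra_c), nrow = 1))
  rownames(m) <- c(sprintf("s%03d", seq_along(fc)), "rest")
  colnames(m) <- c("T", "C")
  attr(m, "library_sizes") <- colSums(m)
  de <- call_regulation(m, "T", "C")
  de <- de[seq_along(fc), ]
  sens_up <- mean(de$call[fc == 4] == "up")
  sens_dn <- mean(de$call[fc == 0.25] == "down")
  expect_gte(sens_up, 0.9)
  expect_gte(sens_dn, 0.9)
  false_calls <- mean(de$call[fc == 1] != "ns")
  expect_lte(false_calls, 0.1)
})

test_that("null libraries keep the type-I rate near nominal", {
  set.seed(54)
  n <- 1000
  xc <- rpois(n, 300); xt <- rpois(n, 300)
  m <- cbind(T = xt, C = xc)
  rownames(m) <- sprintf("n%04d", 1:n)
  attr(m, "library_sizes") <- c(T = 5e5, C = 5e5)
  de <- call_regulation(m, "T", "C")
  frac_sig <- mean(de$q < 0.05)
  expect_lte(frac_sig, 0.05 + 2 * sqrt(0.05 * 0.95 / n))
})

test_that("expression-pattern groups cross two genotypes into 8 classes", {
  mk <- function(calls) {
    structure(data.frame(sequence = sprintf("s%d", seq_along(calls)),
                         call = calls, stringsAsFactors = FALSE),
              class = c("mirforge_de", "data.frame"))
  }
  tol <- mk(c("up", "down", "ns", "ns", "up", "down", "up", "down", "ns"))
  sen <- mk(c("ns", "ns", "up", "down", "up", "down", "down", "up", "ns"))
  g <- classify_groups(tol, sen, stress = "Co")
  expect_equal(g$group_index, c(1L, 2L, 3L, 4L, 5L, 6L, 7L, 8L, NA))
  expect_equal(g$group[5], "Co5")
  expect_equal(g$semantics[5:6], c("response", "response"))
  expect_true(all(g$semantics[c(1:4, 7:8)] == "tolerance"))
  expect_true(is.na(g$semantics[9]))
})
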