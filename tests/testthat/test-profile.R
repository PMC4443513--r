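make_reads <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    data.frame(sequence = r$seq %||% "N", offset = r$off, length = r$len,
               library_id = r$lib %||% "L1", count = r$n,
               stringsAsFactors = FALSE)
  }))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("bucket assignment partitions reads with shift tolerance", {
  # mature [10,31), star [40,61), loop [31,40)
  reads <- make_reads(
    list(off = 10, len = 21, n = 100),            # exact mature
    list(off = 12, len = 21, n = 5),              # +2 shift -> mature
    list(off = 20, len = 21, n = 3),              # ~50% overlap -> other
    list(off = 40, len = 21, n = 8),              # exact star
    list(off = 32, len = 7, n = 2),               # inside loop
    list(off = 0, len = 8, n = 1))                # elsewhere
  prof <- build_profile(reads, 10, 31, 40, 61, 31, 40)
  expect_s3_class(prof, "mirforge_profile")
  b <- prof$reads$bucket
  expect_equal(b, c("mature", "mature", "other", "star", "loop", "other"))
  # partition: totals reconcile
  expect_equal(sum(prof$buckets), prof$total)
  expect_equal(sum(prof$buckets["mature", ]), 105)
  expect_equal(sum(prof$buckets["star", ]), 8)
})

test_that("dicing precision is the exact fraction of mature/star reads", {
  reads <- make_reads(
    list(off = 10, len = 21, n = 90),
    list(off = 11, len = 21, n = 10),   # jittered mature
    list(off = 40, len = 21, n = 9),
    list(off = 41, len = 20, n = 1))    # jittered star
  prof <- build_profile(reads, 10, 31, 40, 61)
  expect_equal(dicer_precision(prof), (90 + 9) / 110)
})

test_that("expression rules require precision and star or multi-library", {
  # precision 0.85 with star evidence -> pass
  reads <- make_reads(list(off = 10, len = 21, n = 80),
                      list(off = 40, len = 21, n = 5),
                      list(off = 32, len = 7, n = 15))
  prof <- build_profile(reads, 10, 31, 40, 61, 31, 40)
  res <- meyers_filter(prof)
  expect_true(res$pass)
  expect_equal(res$precision, 0.85)

  # precision 0.4, no star, single library -> fail with both reasons
  reads2 <- make_reads(list(off = 10, len = 21, n = 40),
                       list(off = 0, len = 8, n = 60))
  prof2 <- build_profile(reads2, 10, 31, 40, 61)
  res2 <- meyers_filter(prof2)
  expect_false(res2$pass)
  expect_equal(res2$precision, 0.4)
  expect_length(res2$reasons, 2)

  # no expression at all
  prof3 <- build_profile(make_reads(list(off = 10, len = 21, n = 0)),
                         10, 31)
  expect_equal(meyers_filter(prof3)$reasons, "no expression")

  # the multi-library relaxation substitutes for star evidence
  reads4 <- rbind(make_reads(list(off = 10, len = 21, n = 150, lib = "L1")),
                  make_reads(list(off = 10, len = 21, n = 120, lib = "L2")))
  prof4 <- build_profile(reads4, 10, 31, 40, 61)
  expect_true(meyers_filter(prof4)$pass)
})

test_that("typical classification is strict at 50%", {
  p <- function(mat, oth) {
    build_profile(make_reads(list(off = 10, len = 21, n = mat),
                             list(off = 0, len = 8, n = oth)), 10, 31)
  }
  expect_equal(classify_typical(p(60, 40)), "typical")
  expect_equal(classify_typical(p(50, 50)), "atypical")
  expect_equal(classify_typical(p(100, 0)), "typical")
  empty <- build_profile(make_reads(list(off = 0, len = 8, n = 0)), 10, 31)
  expect_equal(classify_typical(empty), "atypical")
})

test_that("typical classification is monotone in the mature count", {
  oth <- 50
  cls <- vapply(c(10, 50, 51, 200), function(mat) {
    classify_typical(build_profile(
      make_reads(list(off = 10, len = 21, n = mat),
                 list(off = 0, len = 8, n = oth)), 10, 31))
  }, character(1))
  expect_equal(cls, c("atypical", "atypical", "typical", "typical"))
})

test_that("isomiRs are end-shift variants ranked by count", {
  canon <- random_dna(21)
  v1 <- random_dna(21)
  reads <- make_reads(list(seq = canon, off = 10, len = 21, n = 50),
                      list(seq = v1, off = 11, len = 21, n = 80),
                      list(seq = random_dna(21), off = 20, len = 21, n = 9))
  prof <- build_profile(reads, 10, 31)
  iso <- associate_isomirs(prof, canon)
  expect_equal(nrow(iso), 1L)          # out-of-tolerance variant excluded
  expect_equal(iso$sequence, v1)
  expect_true(iso$dominant)            # out-expresses the canonical mature
  # canonical-only profile has no isomiRs
  only <- build_profile(make_reads(list(seq = canon, off = 10, len = 21,
                                        n = 50)), 10, 31)
  expect_equal(nrow(associate_isomirs(only, canon)), 0L)
})
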