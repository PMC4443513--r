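test_that("duplex characteristics match worked structures", {
  d <- duplex_characteristics("((((((((....))))))))", 0, 8)
  expect_equal(d, list(A = 0L, B = 0L, C = 0L, D = 4L))
  d2 <- duplex_characteristics("(((.(((....))).)))", 0, 7)
  expect_equal(d2, list(A = 2L, B = 1L, C = 2L, D = 4L))
  # mature inside the loop has no duplex
  expect_error(duplex_characteristics("((((((((....))))))))", 8, 12),
               "no duplex")
})

test_that("duplex characteristics equal the brute-force parser on random hairpins", {
  bank <- random_hairpin_bank(250, seed = 406L)
  checked <- 0L
  for (i in seq_len(nrow(bank))) {
    got <- tryCatch(duplex_characteristics(bank$structure[i],
                                           bank$mature_start[i],
                                           bank$mature_end[i]),
                    error = function(e) "err")
    want <- tryCatch(oracle_duplex(bank$structure[i], bank$mature_start[i],
                                   bank$mature_end[i]),
                     error = function(e) "err")
    if (identical(want, "err")) {
      expect_identical(got, "err")
    } else {
      expect_equal(got, want, info = paste("hairpin", i))
      checked <- checked + 1L
    }
  }
  expect_gt(checked, 200L)
})

test_that("star inference follows the 2-nt overhang convention", {
  stem <- strrep("(", 20)
  db <- paste0(stem, "....", strrep(")", 20))
  st <- infer_star(db, 0, 8)
  expect_equal(st$start, 36L)
  expect_equal(st$end, 44L)
  expect_false(st$low_confidence)
  # involution on a perfect stem recovers the mature up to the overhang
  back <- infer_star(db, st$start, st$end)
  ov <- min(back$end, 8) - max(back$start, 0)
  expect_gte(ov, 8 - 2)
  # unpaired mature is flagged
  un <- infer_star(strrep(".", 40), 0, 8)
  expect_true(un$low_confidence)
})

test_that("feature extraction is deterministic and counts what it names", {
  stem <- strrep("(", 20)
  db <- paste0(stem, "....", strrep(")", 20))
  seq <- paste0(random_dna(20, gc = 0.6), "AACA", random_dna(20))
  v <- extract_features(seq, db, -30, 0, 8)
  expect_equal(length(v), 34L)
  expect_equal(unname(v["bulge_count"]), 0)
  expect_equal(unname(v["unpaired_total"]), 0)
  expect_equal(unname(v["loop_size"]), 4)
  expect_equal(unname(v["mature_len"]), 8)
  expect_equal(unname(v["dist_to_loop"]), 12)  # stem 20 - mature 8
  expect_equal(unname(v["arm5"]), 1)
  expect_identical(v, extract_features(seq, db, -30, 0, 8))
  # loop overlap feature counts overlapping nucleotides
  v2 <- extract_features(seq, db, -30, 13, 23)  # mature [13,23): 3 nt in loop
  expect_equal(unname(v2["loop_overlap"]), 3)
})

test_that("duplex-position training is seeded, validated and accurate", {
  model <- cached_mirdup_model()
  expect_s3_class(model, "mirforge_mirdup_model")
  expect_equal(model$training_scope, "plants")

  # determinism on a probe set
  tp <- cached_position_examples()
  hold <- cached_mirdup_holdout()
  train <- tp[!(paste(tp$sequence, tp$mature_start) %in%
                  paste(hold$sequence, hold$mature_start)), , drop = FALSE]
  m2 <- train_mirdup(train, scope = "plants", seed = 404L)
  s1 <- mirdup_scores_for(model, hold[1:10, ])
  expect_identical(s1, mirdup_scores_for(m2, hold[1:10, ]))
  # scores bounded in [0, 100]
  all_sc <- mirdup_scores_for(model, hold)
  expect_true(all(all_sc >= 0 & all_sc <= 100))

  # held-out accuracy and score separation
  acc <- mean((all_sc > 50) == (hold$label == 1))
  expect_gte(acc, 0.85)
  expect_gt(median(all_sc[hold$label == 1]),
            median(all_sc[hold$label == 0]))

  # degenerate labels: negatives equal to positives are rejected
  bad <- tp[tp$label == 1, ][1:25, ]
  bad2 <- bad
  bad2$label <- 0
  expect_error(train_mirdup(rbind(bad, bad2)), "degenerate")
  # schema mismatch
  expect_error(score_position(model, c(a = 1, b = 2)), "schema")
})

test_that("candidate acceptance applies the strict score and abundance gates", {
  m <- matrix(c(120L, 3L, 10000L, 0L, 99L, 99L, 100L, 0L), nrow = 4,
              byrow = TRUE,
              dimnames = list(c("S1", "S2", "S3", "S4"), c("L1", "L2")))
  cand <- data.frame(mature_seq = c("S1", "S2", "S3", "S4", "S4"),
                     score = c(91, 89, 99, 95, 90),
                     stringsAsFactors = FALSE)
  acc <- accept_candidates(cand, m)
  expect_equal(acc$mature_seq, c("S1", "S4"))
  expect_equal(acc$score, c(91, 95))       # 89 fails score, 99 fails counts,
                                           # 90 is not > 90
})

test_that("rule-based check is a comparator, stricter on bulged duplexes", {
  stem <- strrep("(", 20)
  db <- paste0(stem, "....", strrep(")", 20))
  expect_true(mircheck_rules(db, 0, 8))
  # a 5-nt bulge run fails the rule caps but remains scoreable
  hp <- make_hairpin(random_dna(21), bulges_A = 1, max_run_B = 5,
                     loop_D = 5, seed = 31)
  fd <- fold(hp$sequence)
  d <- duplex_characteristics(fd$structure, hp$mature_start, hp$mature_end)
  if (d$B >= 5) {
    expect_false(mircheck_rules(fd$structure, hp$mature_start,
                                hp$mature_end))
  }
  sc <- score_position(cached_mirdup_model(),
                       extract_features(fd$sequence, fd$structure, fd$mfe,
                                        hp$mature_start, hp$mature_end))
  expect_true(is.finite(sc) && sc >= 0 && sc <= 100)
  # mature with many unpaired bases fails
  loose <- "((((....((((....))))....))))"
  expect_false(mircheck_rules(loose, 0, 12, max_unpaired = 4))
})
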