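test_that("window extraction emits two strand candidates per hit", {
  set.seed(20)
  ref <- data.frame(id = "r1", sequence = random_dna(400),
                    stringsAsFactors = FALSE)
  hits <- data.frame(sequence = substr(ref$sequence, 101, 121),
                     ref_id = "r1", strand = "+", start = 100L, end = 121L,
                     mismatches = 0L, stringsAsFactors = FALSE)
  w <- extract_windows(hits, ref)
  expect_equal(nrow(w), 2L)
  expect_setequal(w$strand, c("-", "+"))
  expect_equal(unique(w$window_start), 80L)
  expect_equal(unique(w$window_end), 281L)
  expect_equal(unique(nchar(w$sequence)), 201L)  # 20 + 21 + 160
  # minus-strand candidate is the reverse complement of the plus window
  expect_equal(w$sequence[w$strand == "-"],
               revcomp(w$sequence[w$strand == "+"]))
  # the seed read sits at read_offset on each strand
  for (k in 1:2) {
    expect_equal(substr(w$sequence[k], w$read_offset[k] + 1,
                        w$read_offset[k] + w$read_len[k]), w$seed_read[k])
  }

  # clipping at the reference start
  hits2 <- hits
  hits2$start <- 10L; hits2$end <- 31L
  hits2$sequence <- substr(ref$sequence, 11, 31)
  w2 <- extract_windows(hits2, ref)
  expect_equal(unique(w2$window_start), 0L)
  expect_equal(unique(nchar(w2$sequence)), 191L)

  # N hits in, exactly 2N candidates out
  set.seed(21)
  starts <- sample(50:200, 7)
  hits3 <- data.frame(sequence = substr(rep(ref$sequence, 7), starts + 1,
                                        starts + 21),
                      ref_id = "r1", strand = "+", start = starts,
                      end = starts + 21L, mismatches = 0L,
                      stringsAsFactors = FALSE)
  expect_equal(nrow(extract_windows(hits3, ref)), 14L)
})

test_that("folding returns MFE structures with expected properties", {
  # constructed 20-bp inverted repeat with a 4-nt spacer pairs extensively
  set.seed(22)
  stem <- random_dna(20, gc = 0.6)
  hp <- paste0(stem, "AACA", revcomp(stem))
  fd <- fold(hp)
  expect_lt(fd$mfe, 0)
  expect_gte(sum(strsplit(fd$structure, "")[[1]] == "("), 15)
  # homopolymer cannot pair
  fa <- fold(strrep("A", 60))
  expect_equal(fa$mfe, 0)
  expect_equal(fa$structure, strrep(".", 60))
  # determinism across calls
  expect_identical(fold(hp), fold(hp))
})

test_that("hairpin classifier trains reproducibly and separates classes", {
  model <- cached_hairpin_model()
  th <- cached_training_hairpins()
  # determinism: retraining with the same seed scores identically
  m2 <- train_hairpin_model(th$positives, th$negatives, seed = 402L)
  probe <- th$positives[1:10, ]
  p1 <- classify_premirna(model, probe$sequence, probe$structure, probe$mfe)
  p2 <- classify_premirna(m2, probe$sequence, probe$structure, probe$mfe)
  expect_identical(p1$prob, p2$prob)

  # held-out separation: fresh hairpins vs their shuffles
  bank <- random_hairpin_bank(30, seed = 405L)
  shuf <- vapply(bank$sequence, dinucleotide_shuffle, character(1),
                 USE.NAMES = FALSE)
  fs <- fold(shuf)
  pos <- classify_premirna(model, bank$sequence, bank$structure, bank$mfe)
  neg <- classify_premirna(model, fs$sequence, fs$structure, fs$mfe)
  lab <- c(rep(1, nrow(bank)), rep(0, nrow(fs)))
  pred <- c(pos$prob, neg$prob) >= 0.5
  expect_gt(mean(pred == lab), 0.8)

  # hard gates reject regardless of the forest
  two_loops <- paste0(strrep("GC", 4), "AAAA", strrep("CG", 4),
                      strrep("GC", 4), "AAAA", strrep("CG", 4))
  fd <- fold(two_loops)
  ft <- hairpin_features(fd$sequence, fd$structure, fd$mfe)
  if (ft$n_terminal_loops > 1) {
    res <- classify_premirna(model, fd$sequence, fd$structure, fd$mfe)
    expect_true(res$gated)
    expect_equal(res$prob, 0)
  }
  res0 <- classify_premirna(model, strrep("A", 60), strrep(".", 60), 0)
  expect_true(res0$gated)  # mfe = 0 window rejected
})

test_that("hairpin training validates its inputs", {
  th <- cached_training_hairpins()
  expect_error(train_hairpin_model(th$positives, th$negatives[0, ]),
               "positive and negative")
  expect_error(train_hairpin_model(th$positives[1:5, ], th$negatives),
               "at least 20")
})
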