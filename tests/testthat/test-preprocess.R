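adapter <- "TGGAATTCTCGGGTGCCAAGG"

test_that("adapter trimming removes the longest matching suffix", {
  insert <- "ACGTACGTACGTACGTACGTA"
  res <- trim_adapter(paste0(insert, adapter), adapter)
  expect_equal(res$sequence, insert)
  expect_true(res$trimmed)
  # partial adapter at the read end
  res2 <- trim_adapter(paste0(insert, substr(adapter, 1, 8)), adapter)
  expect_equal(res2$sequence, insert)
  # no adapter: kept intact, flagged untrimmed
  res3 <- trim_adapter(insert, adapter)
  expect_equal(res3$sequence, insert)
  expect_false(res3$trimmed)
  # read shorter than min_overlap
  res4 <- trim_adapter("ACG", adapter, min_overlap = 6)
  expect_equal(res4$sequence, "ACG")
  expect_false(res4$trimmed)
  expect_error(trim_adapter("ACGT", ""), "non-empty")
})

test_that("length filter keeps the 18-30 nt window inclusively", {
  reads <- vapply(c(17, 18, 25, 30, 31), random_dna, character(1))
  kept <- filter_reads(reads)
  expect_equal(nchar(kept), c(18, 25, 30))
})

test_that("quality gate applies only when qualities are present", {
  df <- data.frame(sequence = c(random_dna(20), random_dna(20)),
                   quality = c(strrep("I", 20), strrep("#", 20)),
                   stringsAsFactors = FALSE)
  kept <- filter_reads(df, min_mean_quality = 20)
  expect_equal(nrow(kept), 1L)
  expect_equal(kept$quality, strrep("I", 20))
  noq <- data.frame(sequence = df$sequence, stringsAsFactors = FALSE)
  expect_equal(nrow(filter_reads(noq, min_mean_quality = 20)), 2L)
})

test_that("low-complexity filter drops homopolymers and repeats", {
  expect_false(low_complexity_filter("AAAAAAAAAAAAAAAAAAAA"))
  expect_false(low_complexity_filter("ACACACACACACACACACAC"))
  set.seed(0)
  rnd <- random_dna(21)
  expect_true(low_complexity_filter(rnd))
  # oracle: triplet over-representation score computed by hand
  trip <- substring("ACACACACACACACACACAC", 1:18, 3:20)
  counts <- table(trip)
  expect_equal(dust_score("ACACACACACACACACACAC"),
               sum(counts * (counts - 1) / 2) / (18 - 1))
})

test_that("collapsing conserves per-library read totals", {
  set.seed(2)
  seqs <- vapply(rep(21, 5), random_dna, character(1))
  reads <- data.frame(
    sequence = c(rep(seqs[1], 5), rep(seqs[2], 2), seqs[3]),
    library_id = c(rep("L1", 5), rep("L2", 2), "L1"),
    stringsAsFactors = FALSE)
  m <- collapse_reads(reads, libraries = c("L1", "L2", "L3"))
  expect_equal(unname(m[seqs[1], ]), c(5L, 0L, 0L))
  expect_equal(unname(m[seqs[2], ]), c(0L, 2L, 0L))
  expect_equal(sum(m), nrow(reads))
  expect_equal(unname(attr(m, "library_sizes")), unname(colSums(m)))
  expect_equal(unname(m[, "L3"]), rep(0L, 3))  # empty library -> zero column
})

test_that("mapper reports exact, mismatched and reverse-complement hits", {
  set.seed(3)
  ref <- data.frame(id = "r1", sequence = random_dna(400),
                    stringsAsFactors = FALSE)
  rd <- substr(ref$sequence, 101, 121)
  h <- map_reads(rd, ref)
  expect_true(any(h$strand == "+" & h$start == 100 & h$end == 121 &
                    h$mismatches == 0))
  # two substitutions -> hit with mm = 2; three -> none at that locus
  rd2 <- rd
  substr(rd2, 3, 3) <- setdiff(c("A", "C", "G", "T"), substr(rd, 3, 3))[1]
  substr(rd2, 10, 10) <- setdiff(c("A", "C", "G", "T"),
                                 substr(rd, 10, 10))[1]
  h2 <- map_reads(rd2, ref)
  expect_true(any(h2$start == 100 & h2$mismatches == 2))
  rd3 <- rd2
  substr(rd3, 15, 15) <- setdiff(c("A", "C", "G", "T"),
                                 substr(rd, 15, 15))[1]
  h3 <- map_reads(rd3, ref, max_mismatches = 2)
  expect_false(any(h3$start == 100 & h3$strand == "+"))
  # reverse complement maps on the minus strand at the same + coordinates
  rc <- revcomp(substr(ref$sequence, 51, 71))
  h4 <- map_reads(rc, ref)
  expect_true(any(h4$strand == "-" & h4$start == 50 & h4$end == 71))
})

test_that("mapper equals the exhaustive scan and is strand-symmetric", {
  set.seed(4)
  ref <- data.frame(id = c("rA", "rB"),
                    sequence = c(random_dna(1500), random_dna(900)),
                    stringsAsFactors = FALSE)
  reads <- character(40)
  for (i in 1:40) {
    src <- sample(2, 1)
    L <- sample(18:24, 1)
    s <- sample(nchar(ref$sequence[src]) - L, 1)
    rd <- substr(ref$sequence[src], s, s + L - 1)
    nmut <- sample(0:3, 1)
    for (m in seq_len(nmut)) {
      p <- sample(L, 1)
      substr(rd, p, p) <- sample(c("A", "C", "G", "T"), 1)
    }
    if (sample(c(TRUE, FALSE), 1)) rd <- revcomp(rd)
    reads[i] <- rd
  }
  got <- map_reads(reads, ref, 2)
  want <- oracle_map(reads, ref, 2)
  rownames(got) <- rownames(want) <- NULL
  expect_equal(got[order(got$sequence, got$ref_id, got$start, got$strand), ],
               want[order(want$sequence, want$ref_id, want$start,
                          want$strand), ],
               ignore_attr = TRUE)
  # symmetry: reverse-complementing reads and reference flips strands
  ref_rc <- data.frame(id = ref$id, sequence = revcomp(ref$sequence),
                       stringsAsFactors = FALSE)
  got_rc <- map_reads(reads, ref_rc, 2)
  expect_equal(nrow(got_rc), nrow(got))
  expect_equal(sort(got_rc$mismatches), sort(got$mismatches))
})
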