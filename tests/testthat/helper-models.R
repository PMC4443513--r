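# trained models and training draws are expensive (folding + forests);
# build them once per test run and share across test files
.model_cache <- new.env(parent = emptyenv())

cached_training_hairpins <- function() {
  if (is.null(.model_cache$th)) {
    .model_cache$th <- training_hairpins(n = 150L, seed = 401L)
  }
  .model_cache$th
}

cached_hairpin_model <- function() {
  if (is.null(.model_cache$hp)) {
    th <- cached_training_hairpins()
    .model_cache$hp <- train_hairpin_model(th$positives, th$negatives,
                                           seed = 402L)
  }
  .model_cache$hp
}

cached_position_examples <- function() {
  if (is.null(.model_cache$tp)) {
    .model_cache$tp <- training_positions(cached_training_hairpins(),
                                          seed = 403L)
  }
  .model_cache$tp
}

cached_mirdup_model <- function() {
  if (is.null(.model_cache$md)) {
    tp <- cached_position_examples()
    # hold out ~30% of hairpins for evaluation tests
    n_hp <- nrow(cached_training_hairpins()$positives)
    hold <- seq_len(n_hp) %% 3L == 0L
    hold_seq <- cached_training_hairpins()$positives$sequence[hold]
    train <- tp[!(tp$sequence %in% hold_seq), , drop = FALSE]
    .model_cache$md <- train_mirdup(train, scope = "plants", seed = 404L)
    .model_cache$md_holdout <- tp[tp$sequence %in% hold_seq, , drop = FALSE]
  }
  .model_cache$md
}

cached_mirdup_holdout <- function() {
  cached_mirdup_model()
  .model_cache$md_holdout
}

mirdup_scores_for <- function(model, examples) {
  vapply(seq_len(nrow(examples)), function(i) {
    fv <- extract_features(examples$sequence[i], examples$dotbracket[i],
                           examples$mfe[i], examples$mature_start[i],
                           examples$mature_end[i])
    score_position(model, fv)
  }, numeric(1))
}

# a small bank of folded random hairpins with known mature positions
random_hairpin_bank <- function(n, seed = 99L) {
  set.seed(seed)
  drafts <- lapply(seq_len(n), function(i) {
    make_hairpin(random_dna(sample(19:24, 1L)),
                 bulges_A = sample(0:2, 1L),
                 max_run_B = sample(1:3, 1L),
                 loop_D = sample(3:9, 1L))
  })
  fd <- fold(vapply(drafts, `[[`, "", "sequence"))
  data.frame(sequence = fd$sequence, structure = fd$structure, mfe = fd$mfe,
             mature_start = vapply(drafts, `[[`, integer(1), "mature_start"),
             mature_end = vapply(drafts, `[[`, integer(1), "mature_end"),
             stringsAsFactors = FALSE)
}

write_fasta_tmp <- function(ids, seqs) {
  f <- tempfile(fileext = ".fasta")
  writeLines(as.vector(rbind(paste0(">", ids), seqs)), f)
  f
}

write_fastq_tmp <- function(ids, seqs, quals = NULL) {
  if (is.null(quals)) {
    quals <- vapply(nchar(seqs), function(n)
      paste(rep("I", n), collapse = ""), character(1))
  }
  f <- tempfile(fileext = ".fastq")
  writeLines(as.vector(rbind(paste0("@", ids), seqs, "+", quals)), f)
  f
}
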