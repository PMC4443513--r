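#' Build training sets for the two classifiers
#'
#' `training_hairpins()` draws fold-checked synthetic hairpins (positives)
#' and folded dinucleotide shuffles of the same sequences (negatives) for
#' the hairpin plausibility model. `training_positions()` turns the same
#' hairpin draws into labelled (precursor, mature position) examples with
#' shifted negatives for the duplex-position model.
#'
#' @param n number of positive examples.
#' @param seed integer seed.
#' @param bulge_A_range,bulge_B_range,loop_D_range hairpin geometry ranges
#'   sampled per draw.
#' @return `training_hairpins()`: list with `positives`, `negatives` (data
#'   frames with `sequence`, `structure`, `mfe`) and `positions` (the true
#'   mature intervals). `training_positions()`: a labelled example frame for
#'   [train_mirdup()].
#' @name training_sets
#' @export
training_hairpins <- function(n = 120L, seed = 7L,
                              bulge_A_range = c(0L, 2L),
                              bulge_B_range = c(1L, 3L),
                              loop_D_range = c(3L, 9L)) {
  set.seed(seed)
  draws <- list()
  while (length(draws) < n) {
    batch <- lapply(seq_len(n - length(draws)), function(i) {
      hp <- make_hairpin(.random_seq(sample(19:24, 1L), gc = 0.5),
                         bulges_A = sample(bulge_A_range[1L]:
                                             bulge_A_range[2L], 1L),
                         max_run_B = sample(bulge_B_range[1L]:
                                              bulge_B_range[2L], 1L),
                         loop_D = sample(loop_D_range[1L]:
                                           loop_D_range[2L], 1L))
      # embed in transcript context so training sees the same trimmed
      # stem-loops the discovery funnel produces from extracted windows
      left <- sample(5:15, 1L)
      hp$window <- paste0(.random_seq(left), hp$sequence,
                          .random_seq(sample(80:120, 1L)))
      hp$mature_start <- hp$mature_start + left
      hp$mature_end <- hp$mature_end + left
      hp
    })
    fd <- fold(vapply(batch, `[[`, "", "window"))
    spans <- lapply(seq_along(batch), function(k) {
      stemloop_span(fd$structure[k], batch[[k]]$mature_start,
                    batch[[k]]$mature_end, min_cover = 1)
    })
    keep <- !vapply(spans, is.null, logical(1))
    if (!any(keep)) next
    pre_seq <- vapply(which(keep), function(k) {
      substr(fd$sequence[k], spans[[k]]$start + 1L, spans[[k]]$end)
    }, character(1))
    fdp <- fold(pre_seq)
    ki <- which(keep)
    for (j in seq_along(ki)) {
      k <- ki[j]
      m0 <- batch[[k]]$mature_start - spans[[k]]$start
      m1 <- batch[[k]]$mature_end - spans[[k]]$start
      ft <- hairpin_features(fdp$sequence[j], fdp$structure[j], fdp$mfe[j])
      ok <- ft$n_terminal_loops == 1L && ft$mfe < 0 && m0 >= 0L &&
        m1 <= nchar(fdp$sequence[j]) &&
        !is.null(tryCatch(duplex_characteristics(
          fdp$structure[j], m0, m1), error = function(e) NULL))
      if (ok) {
        draws[[length(draws) + 1L]] <- list(
          sequence = fdp$sequence[j], structure = fdp$structure[j],
          mfe = fdp$mfe[j], mature_start = m0, mature_end = m1)
      }
      if (length(draws) >= n) break
    }
  }
  pos <- data.frame(
    sequence = vapply(draws, `[[`, "", "sequence"),
    structure = vapply(draws, `[[`, "", "structure"),
    mfe = vapply(draws, `[[`, numeric(1), "mfe"),
    stringsAsFactors = FALSE)
  shuf <- vapply(pos$sequence, dinucleotide_shuffle, character(1),
                 USE.NAMES = FALSE)
  fn <- fold(shuf)
  neg <- data.frame(sequence = fn$sequence, structure = fn$structure,
                    mfe = fn$mfe, stringsAsFactors = FALSE)
  positions <- data.frame(
    mature_start = vapply(draws, `[[`, integer(1), "mature_start"),
    mature_end = vapply(draws, `[[`, integer(1), "mature_end"))
  list(positives = pos, negatives = neg, positions = positions)
}

#' @rdname training_sets
#' @param hairpins result of `training_hairpins()` (drawn when NULL).
#' @param n_neg negatives per positive position.
#' @export
training_positions <- function(hairpins = NULL, n = 120L, seed = 7L,
                               n_neg = 3L) {
  if (is.null(hairpins)) hairpins <- training_hairpins(n = n, seed = seed)
  ex <- data.frame(sequence = hairpins$positives$sequence,
                   dotbracket = hairpins$positives$structure,
                   mfe = hairpins$positives$mfe,
                   mature_start = hairpins$positions$mature_start,
                   mature_end = hairpins$positions$mature_end,
                   stringsAsFactors = FALSE)
  sample_negative_positions(ex, n_neg = n_neg, seed = seed)
}

#' Default pipeline parameters
#' @return named list of every tunable threshold with its default.
#' @export
pipeline_defaults <- function() {
  list(min_len = 18L, max_len = 30L, max_mismatches = 2L,
       min_mean_quality = 20, dust_threshold = 2.0, adapter_min_overlap = 6L,
       upstream = 20L, downstream = 160L,
       min_seed_count = 10L, hairpin_threshold = 0.5, min_paired = 0.4,
       score_min = 90, abundance_min = 100,
       precision_min = 0.75, meyers_min_expr = 100,
       word_size = 7L, identity_min = 80, qcov_min = 90, scov_min = 90,
       fc_low = 0.5, fc_high = 2.0, fdr = 0.05, pseudo_rpm = 0.5,
       target_score_max = 3.0, target_ratio_min = 0.7)
}

#' Discover miRNA candidates from a collapsed matrix and a reference
#'
#' The core discovery funnel: sequences reaching `min_seed_count` reads in
#' some library seed candidate loci; windows of 20 nt upstream to 160 nt
#' downstream are extracted on both strands of every mapped locus, folded,
#' trimmed to the stem-loop covering the seed read, gated structurally,
#' scored by the hairpin model and then by the duplex-position model; the
#' score and abundance gates and the expression-profile rules produce the
#' accepted candidate set.
#'
#' @param matrix collapsed count matrix.
#' @param reference reference data frame (`id`, `sequence`).
#' @param hairpin_model,mirdup_model trained models.
#' @param params list from [pipeline_defaults()] (partial overrides
#'   allowed).
#' @return list with `candidates` (every scored candidate), `accepted`
#'   (score, abundance and expression-filtered rows, one per
#'   mature/precursor association), `hits`, and `funnel` (stage counts).
#' @export
discover_candidates <- function(matrix, reference, hairpin_model,
                                mirdup_model, params = list()) {
  p <- utils::modifyList(pipeline_defaults(), params)
  maxc <- apply(matrix, 1L, max)
  seeds <- rownames(matrix)[maxc >= p$min_seed_count]
  hits <- map_reads(rownames(matrix), reference, p$max_mismatches)
  seed_hits <- hits[hits$sequence %in% seeds, , drop = FALSE]
  windows <- extract_windows(seed_hits, reference, p$upstream, p$downstream)
  funnel <- list(sequences = nrow(matrix), mapped_sequences =
                   length(unique(hits$sequence)),
                 seed_loci = nrow(seed_hits), windows = nrow(windows))

  if (!nrow(windows)) {
    return(list(candidates = NULL, accepted = NULL, hits = hits,
                funnel = funnel))
  }
  # fold unique window sequences once
  key <- paste(windows$sequence, windows$read_offset)
  uk <- !duplicated(key)
  fd <- fold(windows$sequence[uk])
  fmap <- match(key, key[uk])
  struct <- fd$structure[fmap]
  wmfe <- fd$mfe[fmap]

  # trim each window to the stem-loop covering its seed read
  cand <- vector("list", nrow(windows))
  for (i in seq_len(nrow(windows))) {
    sp <- stemloop_span(struct[i], windows$read_offset[i],
                        windows$read_offset[i] + windows$read_len[i])
    if (is.null(sp)) next
    cand[[i]] <- c(i, sp$start, sp$end)
  }
  cand <- do.call(rbind, cand)
  funnel$stemloop <- if (is.null(cand)) 0L else nrow(cand)
  if (is.null(cand)) {
    return(list(candidates = NULL, accepted = NULL, hits = hits,
                funnel = funnel))
  }
  wi <- cand[, 1L]
  pre_seq <- substr(windows$sequence[wi], cand[, 2L] + 1L, cand[, 3L])
  # refold the trimmed precursor for its own structure and MFE
  ukp <- !duplicated(pre_seq)
  fdp <- fold(pre_seq[ukp])
  pmap <- match(pre_seq, pre_seq[ukp])
  pre_struct <- fdp$structure[pmap]
  pre_mfe <- fdp$mfe[pmap]

  hp <- classify_premirna(hairpin_model, pre_seq, pre_struct, pre_mfe,
                          min_paired = p$min_paired)
  pass_hp <- !hp$gated & hp$prob >= p$hairpin_threshold
  funnel$hairpin_pass <- sum(pass_hp)

  idx <- which(pass_hp)
  rows <- vector("list", length(idx))
  for (j in seq_along(idx)) {
    i <- idx[j]; w <- wi[i]
    m0 <- windows$read_offset[w] - cand[i, 2L]
    m1 <- m0 + windows$read_len[w]
    if (m0 < 0L || m1 > nchar(pre_seq[i])) next
    fv <- tryCatch(extract_features(pre_seq[i], pre_struct[i], pre_mfe[i],
                                    m0, m1), error = function(e) NULL)
    if (is.null(fv)) next
    sc <- score_position(mirdup_model, fv)
    mc <- tryCatch(mircheck_rules(pre_struct[i], m0, m1),
                   error = function(e) FALSE)
    # precursor span on the reference + strand
    if (windows$strand[w] == "+") {
      ps <- windows$window_start[w] + cand[i, 2L]
      pe <- windows$window_start[w] + cand[i, 3L]
      mrs <- ps + m0
    } else {
      ps <- windows$window_end[w] - cand[i, 3L]
      pe <- windows$window_end[w] - cand[i, 2L]
      mrs <- pe - m1
    }
    rows[[j]] <- data.frame(
      mature_seq = windows$seed_read[w], ref_id = windows$ref_id[w],
      strand = windows$strand[w], window_start = ps, window_end = pe,
      premirna_seq = pre_seq[i], dotbracket = pre_struct[i],
      mfe = pre_mfe[i], mature_start = m0, mature_end = m1,
      mature_ref_start = mrs, mature_ref_end = mrs + (m1 - m0),
      hairpin_prob = hp$prob[i], score = sc, mircheck = mc,
      stringsAsFactors = FALSE)
  }
  candidates <- do.call(rbind, rows)
  if (is.null(candidates) || !nrow(candidates)) {
    return(list(candidates = candidates, accepted = NULL, hits = hits,
                funnel = funnel))
  }
  candidates <- candidates[!duplicated(candidates[c("mature_seq", "ref_id",
                                                    "strand",
                                                    "window_start")]), ,
                           drop = FALSE]
  candidates$premirna_id <- sprintf("pre_%s_%d_%s", candidates$ref_id,
                                    candidates$window_start,
                                    candidates$strand)
  funnel$scored <- nrow(candidates)

  acc <- accept_candidates(candidates, matrix, p$score_min, p$abundance_min)
  funnel$score_abundance_pass <- nrow(acc)

  # expression-profile filtering on the accepted precursors
  if (nrow(acc)) {
    keep <- logical(nrow(acc))
    acc$precision <- NA_real_
    acc$dicer_precision <- NA_real_
    acc$expression_class <- NA_character_
    acc$n_isomirs <- NA_integer_
    libs <- colnames(matrix)
    cnt <- matrix
    for (k in seq_len(nrow(acc))) {
      prof <- profile_for_candidate(acc[k, ], hits, cnt)
      mf <- meyers_filter(prof, precision_min = p$precision_min,
                          min_expr = p$meyers_min_expr)
      keep[k] <- mf$pass
      acc$precision[k] <- mf$precision
      acc$dicer_precision[k] <- dicer_precision(prof)
      acc$expression_class[k] <- classify_typical(prof)
      acc$n_isomirs[k] <- nrow(associate_isomirs(prof,
                                                 acc$mature_seq[k]))
    }
    accepted <- acc[keep, , drop = FALSE]
  } else {
    accepted <- acc
  }
  funnel$expression_pass <- nrow(accepted)
  funnel$accepted_mirnas <- length(unique(accepted$mature_seq))
  # per-library counts of the accepted matures
  if (nrow(accepted)) {
    for (l in colnames(matrix)) {
      accepted[[paste0("count.", l)]] <- unname(matrix[accepted$mature_seq,
                                                       l])
    }
  }
  list(candidates = candidates, accepted = accepted, hits = hits,
       funnel = funnel)
}

#' Positional read profile of one discovered candidate
#'
#' Collects every mapped read lying inside the candidate precursor on its
#' strand, converts it to precursor coordinates, and builds the bucketed
#' profile (mature / star / loop / other).
#'
#' @param cand one row of a candidate table from [discover_candidates()].
#' @param hits full mapping table.
#' @param matrix count matrix (per-library counts of each sequence).
#' @return a `"mirforge_profile"`.
#' @export
profile_for_candidate <- function(cand, hits, matrix) {
  h <- hits[hits$ref_id == cand$ref_id & hits$strand == cand$strand &
              hits$start >= cand$window_start - 2L &
              hits$end <= cand$window_end + 2L, , drop = FALSE]
  if (cand$strand == "+") {
    off <- h$start - cand$window_start
  } else {
    off <- cand$window_end - h$end
  }
  libs <- colnames(matrix)
  reads <- do.call(rbind, lapply(seq_len(nrow(h)), function(i) {
    cc <- matrix[h$sequence[i], ]
    nz <- which(cc > 0)
    if (!length(nz)) return(NULL)
    data.frame(sequence = h$sequence[i], offset = off[i],
               length = h$end[i] - h$start[i], library_id = libs[nz],
               count = unname(cc[nz]), stringsAsFactors = FALSE)
  }))
  if (is.null(reads)) {
    reads <- data.frame(sequence = character(), offset = integer(),
                        length = integer(), library_id = character(),
                        count = integer(), stringsAsFactors = FALSE)
  }
  star <- infer_star(cand$dotbracket, cand$mature_start, cand$mature_end)
  pt <- pairing_table(cand$dotbracket)
  loops <- .terminal_loops(pt)
  ls <- if (nrow(loops)) loops$start[1L] - 1L else NA
  le <- if (nrow(loops)) loops$end[1L] else NA
  build_profile(reads, cand$mature_start, cand$mature_end,
                star$start, star$end, ls, le)
}

#' Pipeline configuration
#'
#' Declares the input files, the library design and the comparisons for
#' [run_all()]. `libraries` mirrors a sequencing design table: one row per
#' library with its id and FASTQ path; `comparisons` declares
#' (treated, control, label) pairs.
#'
#' @param reference_path transcript/EST FASTA.
#' @param libraries data frame with `id`, `path` (and optional metadata
#'   columns such as genotype or condition).
#' @param comparisons data frame with `treated`, `control`, `label`.
#' @param annotation_path,go_path,mature_db_path optional TSV/FASTA inputs
#'   for the annotation-dependent stages.
#' @param adapter adapter to trim (`NULL` to skip trimming).
#' @param out_dir artifact directory.
#' @param seed root seed for classifier training.
#' @param params threshold overrides over [pipeline_defaults()].
#' @return list of class `"mirforge_config"`.
#' @export
pipeline_config <- function(reference_path, libraries, comparisons = NULL,
                            annotation_path = NULL, go_path = NULL,
                            mature_db_path = NULL, adapter = NULL,
                            out_dir = tempfile("mirforge_run_"),
                            seed = 1L, params = list()) {
  for (f in c(reference_path, libraries$path, annotation_path, go_path,
              mature_db_path)) {
    if (!is.null(f) && !file.exists(f)) .stopf("input not found: %s", f)
  }
  structure(list(reference_path = reference_path, libraries = libraries,
                 comparisons = comparisons, annotation_path = annotation_path,
                 go_path = go_path, mature_db_path = mature_db_path,
                 adapter = adapter, out_dir = out_dir, seed = seed,
                 params = utils::modifyList(pipeline_defaults(), params)),
            class = "mirforge_config")
}

#' Run the full discovery pipeline
#'
#' Executes preprocess, map, discover, score, expression-filter,
#' conservation, differential expression, target prediction and GO
#' enrichment in order, writes per-stage artifacts under the configured
#' output directory, and returns a run summary whose funnel counts
#' reconcile with the stage outputs.
#'
#' @param config a `"mirforge_config"`.
#' @param models optional list with pre-trained `hairpin` and `mirdup`
#'   models (trained from the config seed when absent).
#' @return list of class `"mirforge_run"`: `summary` (funnel counts, seeds,
#'   engine version), `matrix`, `accepted`, `conserved`, `de`, `targets`,
#'   `enrichment`.
#' @export
run_all <- function(config, models = NULL) {
  stopifnot(inherits(config, "mirforge_config"))
  p <- config$params
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  reference <- read_sequences(config$reference_path, "fasta")

  # preprocess each library: trim, filter, low-complexity, collapse
  all_reads <- list()
  raw_total <- 0L
  for (i in seq_len(nrow(config$libraries))) {
    lib <- config$libraries$id[i]
    rd <- read_sequences(config$libraries$path[i], library_id = lib)
    raw_total <- raw_total + nrow(rd)
    if (!is.null(config$adapter)) {
      rd <- trim_adapter(rd, config$adapter, p$adapter_min_overlap)
      rd <- rd[rd$trimmed, , drop = FALSE]  # adapter-less reads are chimeric
    }
    rd <- filter_reads(rd, p$min_len, p$max_len, p$min_mean_quality)
    all_reads[[lib]] <- rd
  }
  reads <- do.call(rbind, lapply(all_reads, function(r)
    r[c("sequence", "library_id")]))
  mat <- collapse_reads(reads, libraries = config$libraries$id)
  keep <- low_complexity_filter(rownames(mat), p$dust_threshold)
  mat <- mat[keep, , drop = FALSE]
  attr(mat, "library_sizes") <- colSums(mat)
  write_count_matrix(mat, file.path(config$out_dir, "counts.tsv"))

  # models
  if (is.null(models)) {
    th <- training_hairpins(n = 200L, seed = .child_seed(config$seed, 1L))
    hairpin_model <- train_hairpin_model(th$positives, th$negatives,
                                         seed = .child_seed(config$seed, 2L))
    tp <- training_positions(th, seed = .child_seed(config$seed, 3L))
    mirdup_model <- train_mirdup(tp, scope = "plants",
                                 seed = .child_seed(config$seed, 4L))
  } else {
    hairpin_model <- models$hairpin
    mirdup_model <- models$mirdup
  }

  disc <- discover_candidates(mat, reference, hairpin_model, mirdup_model,
                              p)
  accepted <- disc$accepted
  if (!is.null(accepted) && nrow(accepted)) {
    accepted$mature_id <- sprintf("mir-c%04d",
                                  as.integer(factor(accepted$mature_seq)))
    write_candidate_report(
      accepted[c("mature_id", "mature_seq", "premirna_id", "ref_id",
                 "strand", "window_start", "window_end", "premirna_seq",
                 "dotbracket", "mfe", "mature_start", "mature_end", "score",
                 "expression_class",
                 grep("^count\\.", names(accepted), value = TRUE))],
      file.path(config$out_dir, "candidates.tsv"),
      vienna_dir = file.path(config$out_dir, "vienna"))
  }

  # conservation
  conserved <- NULL
  if (!is.null(config$mature_db_path)) {
    db <- read_sequences(config$mature_db_path, "fasta")
    ch <- search_conserved(mat, db, p$word_size, p$identity_min,
                           p$qcov_min, p$scov_min, p$abundance_min)
    conserved <- assign_family(ch)
    write.table(ch, file.path(config$out_dir, "conserved_hits.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }

  # differential expression
  de <- NULL
  filt <- prefilter_min_count(mat, p$abundance_min)
  if (!is.null(config$comparisons) && nrow(config$comparisons)) {
    de <- lapply(seq_len(nrow(config$comparisons)), function(r) {
      cmp <- config$comparisons[r, ]
      call_regulation(filt, cmp$treated, cmp$control,
                      label = if (!is.null(cmp$label)) cmp$label else NULL,
                      fc_low = p$fc_low, fc_high = p$fc_high, fdr = p$fdr,
                      pseudo_rpm = p$pseudo_rpm)
    })
    names(de) <- vapply(de, function(d) d$comparison_id[1L], character(1))
    de_all <- do.call(rbind, de)
    write.table(de_all, file.path(config$out_dir, "de.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(volcano_table(de_all),
                file.path(config$out_dir, "volcano.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }

  # targets and enrichment
  targets <- NULL; enrichment <- NULL
  if (!is.null(config$annotation_path) && !is.null(accepted) &&
      nrow(accepted)) {
    ann <- read_annotation(config$annotation_path, config$go_path)
    mirnas <- setNames(unique(accepted$mature_seq),
                       accepted$mature_id[!duplicated(accepted$mature_seq)])
    targets <- predict_targets(mirnas, reference, ann,
                               p$target_score_max, p$target_ratio_min)
    write.table(targets, file.path(config$out_dir, "targets.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(ann$go) && nrow(targets)) {
      bg <- build_background("global", ann)
      enrichment <- hypergeom_enrichment(
        unique(targets$annotation_id[!is.na(targets$annotation_id)]),
        bg, ann$go)
      write.table(enrichment, file.path(config$out_dir, "enrichment.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }

  summary <- list(
    raw_reads = raw_total,
    filtered_reads = nrow(reads),
    distinct_sequences = disc$funnel$sequences,
    mapped_sequences = disc$funnel$mapped_sequences,
    seed_loci = disc$funnel$seed_loci,
    windows = disc$funnel$windows,
    stemloop = disc$funnel$stemloop,
    hairpin_pass = disc$funnel$hairpin_pass,
    scored = disc$funnel$scored,
    score_abundance_pass = disc$funnel$score_abundance_pass,
    expression_pass = disc$funnel$expression_pass,
    accepted_mirnas = disc$funnel$accepted_mirnas,
    conserved_queries = if (!is.null(conserved)) nrow(conserved) else NA,
    de_counts = if (!is.null(de)) lapply(de, function(d)
      table(d$call)[c("up", "down")]) else NULL,
    seed = config$seed,
    fold_engine = fold_engine_version())
  jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE,
                       null = "null", na = "null")
  structure(list(summary = summary, matrix = mat, accepted = accepted,
                 candidates = disc$candidates, hits = disc$hits,
                 conserved = conserved, de = de, targets = targets,
                 enrichment = enrichment, config = config),
            class = "mirforge_run")
}

#' @export
print.mirforge_run <- function(x, ...) {
  s <- x$summary
  cat("mirforge run\n")
  cat(sprintf("  raw reads          %s\n", s$raw_reads))
  cat(sprintf("  filtered reads     %s\n", s$filtered_reads))
  cat(sprintf("  distinct sequences %s\n", s$distinct_sequences))
  cat(sprintf("  seed loci          %s\n", s$seed_loci))
  cat(sprintf("  windows (2x loci)  %s\n", s$windows))
  cat(sprintf("  hairpin-passing    %s\n", s$hairpin_pass))
  cat(sprintf("  score+abundance    %s\n", s$score_abundance_pass))
  cat(sprintf("  expression-passing %s\n", s$expression_pass))
  cat(sprintf("  accepted miRNAs    %s\n", s$accepted_mirnas))
  invisible(x)
}

#' End-to-end parameter-recovery benchmark on synthetic data
#'
#' Generates a synthetic dataset with known ground truth, runs the full
#' pipeline on the written files, and scores recovery: the fraction of
#' planted miRNAs recovered among accepted candidates, the false-discovery
#' fraction among accepted matures (a discovery is true when its mature
#' interval overlaps a planted mature or star locus within 2 nt), the
#' fraction of planted fold changes whose direction is recalled by the DE
#' stage, and the measured dicing precision.
#'
#' @param seed root seed (drives both the generator and the pipeline).
#' @param config a `"mirforge_sim_config"` (default: the standard benchmark
#'   conditions at this seed).
#' @param out_dir working directory (a temporary directory by default,
#'   removed afterwards).
#' @param keep_run return the full run object as well.
#' @return list with `recovery`, `fdr`, `de_direction`, `dicer_precision`,
#'   `n_true`, `n_accepted`, `funnel`, and (optionally) `run`.
#' @export
run_recovery_benchmark <- function(seed = 1L, config = NULL,
                                   out_dir = NULL, keep_run = FALSE) {
  if (is.null(config)) config <- sim_config(seed = seed)
  cleanup <- is.null(out_dir)
  if (is.null(out_dir)) out_dir <- tempfile("mirforge_bench_")
  sim <- generate_dataset(config, file.path(out_dir, "data"))
  pc <- pipeline_config(
    reference_path = sim$paths$reference,
    libraries = data.frame(id = config$libraries,
                           path = unlist(sim$paths[config$libraries]),
                           stringsAsFactors = FALSE),
    comparisons = unique(config$planted_fc[c("treated", "control")]),
    annotation_path = sim$paths$annotation, go_path = sim$paths$go,
    mature_db_path = sim$paths$mature_db,
    adapter = config$adapter,
    out_dir = file.path(out_dir, "run"), seed = seed)
  run <- run_all(pc)

  man <- sim$manifest
  acc <- run$accepted
  # truth intervals per planted miRNA (mature and star loci, +/- 2 nt)
  truth <- list()
  for (i in seq_len(nrow(man))) {
    m_len <- nchar(man$mature_seq[i])
    iv <- data.frame(mirna = man$mirna[i], est = man$est_id[i],
                     start = man$mature_start[i],
                     end = man$mature_start[i] + m_len)
    if (!is.na(man$star_seq[i])) {
      hpseq <- NULL # star located via hairpin span
      iv <- rbind(iv, data.frame(
        mirna = man$mirna[i], est = man$est_id[i],
        start = man$hairpin_start[i],
        end = man$hairpin_start[i] + man$hairpin_len[i]))
    }
    truth[[i]] <- iv
  }
  truth <- do.call(rbind, truth)

  recovered <- logical(nrow(man))
  true_disc <- logical(0)
  if (!is.null(acc) && nrow(acc)) {
    uniq <- acc[!duplicated(acc$mature_seq), , drop = FALSE]
    true_disc <- logical(nrow(uniq))
    for (k in seq_len(nrow(uniq))) {
      # a true discovery lies within a planted hairpin locus
      hit <- truth$est == uniq$ref_id[k] &
        uniq$mature_ref_start[k] >= truth$start - 2L &
        uniq$mature_ref_end[k] <= truth$end + 2L
      true_disc[k] <- any(hit)
      # recovery requires overlap with the planted mature/star sequence
      rec <- man$mirna[man$mature_seq == uniq$mature_seq[k] |
                         (!is.na(man$star_seq) &
                            man$star_seq == uniq$mature_seq[k])]
      recovered[man$mirna %in% rec] <- TRUE
      # also count shift-variants on the mature locus
      mhit <- man$est_id == uniq$ref_id[k] &
        abs(man$mature_start - uniq$mature_ref_start[k]) <= 2L
      recovered[mhit & abs(man$mature_start + nchar(man$mature_seq) -
                             uniq$mature_ref_end[k]) <= 2L] <- TRUE
    }
  }

  # DE direction recall for planted fold changes
  de_dir <- NA_real_
  if (!is.null(sim$fc_truth) && !is.null(run$de)) {
    ft <- sim$fc_truth
    ok <- logical(0)
    for (r in seq_len(nrow(ft))) {
      cmp <- paste0(ft$treated[r], "/", ft$control[r])
      if (!cmp %in% names(run$de)) next
      d <- run$de[[cmp]]
      seqm <- man$mature_seq[man$mirna == ft$mirna[r]]
      row <- d[d$sequence == seqm, , drop = FALSE]
      if (!nrow(row)) { ok <- c(ok, FALSE); next }
      want <- if (ft$fc[r] > 1) "up" else "down"
      ok <- c(ok, row$call[1L] == want)
    }
    de_dir <- if (length(ok)) mean(ok) else NA_real_
    n_de_cases <- length(ok)
  } else n_de_cases <- 0L

  dp <- if (!is.null(acc) && nrow(acc))
    stats::weighted.mean(acc$dicer_precision,
                         apply(acc[grep("^count\\.", names(acc))], 1L, max),
                         na.rm = TRUE) else NA_real_

  res <- list(recovery = mean(recovered),
              fdr = if (length(true_disc)) 1 - mean(true_disc) else NA_real_,
              de_direction = de_dir,
              dicer_precision = dp,
              n_true = nrow(man),
              n_recovered = sum(recovered),
              n_accepted = length(true_disc),
              n_de_cases = n_de_cases,
              total_reads = run$summary$raw_reads,
              funnel = run$summary)
  if (keep_run) res$run <- run
  if (cleanup) unlink(out_dir, recursive = TRUE)
  res
}
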