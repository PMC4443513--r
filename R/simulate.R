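#' Synthetic-dataset configuration
#'
#' Defines the study conditions emulated by the generator: a multi-library
#' small-RNA experiment over an EST reference, with true miRNA hairpins
#' showing Dicer-like positional read concentration, decoy hairpins with
#' diffuse reads, abundance tiers, planted fold changes between libraries,
#' and uniform background noise.
#'
#' @param seed root seed; every stochastic choice derives from it.
#' @param n_ests,est_length number of reference ESTs and their length range.
#' @param n_true_mirnas planted true miRNAs.
#' @param n_decoy_hairpins decoy hairpins with diffuse (non-Dicer) reads.
#' @param mature_len_range mature length range, nt.
#' @param dicer_precision probability that a mature/star read is excised
#'   exactly; imprecise reads jitter both ends by up to 2 nt.
#' @param libraries character vector of library ids.
#' @param base_count_range per-library expected mature read count range for
#'   a true miRNA (log-uniform; medium-to-high abundance tiers).
#' @param star_fraction,other_fraction expected star and background reads on
#'   a true hairpin, as fractions of the mature expectation.
#' @param planted_fc data frame with columns `treated`, `control`, `fc`,
#'   `fraction` — each comparison plants fold change `fc` on `fraction` of
#'   the true miRNAs (the affected set is sampled per comparison).
#' @param decoy_count_range per-library expected decoy read count range.
#' @param noise_read_fraction background reads as a fraction of planted
#'   reads (sampled from non-hairpin EST regions, plus 5 percent fully
#'   random sequence).
#' @param bulge_A_range,bulge_B_range,loop_D_range hairpin duplex geometry
#'   ranges (number of bulges, maximal bulge run, terminal loop size).
#' @param adapter 3' adapter ligated to simulated reads (`NULL` for none).
#' @param read_total_len total read length when an adapter is ligated.
#' @param n_conserved number of true matures copied into the synthetic
#'   mature-miRNA reference (with family labels) for the conservation stage.
#' @param n_target_sites target sites embedded per true miRNA (antisense
#'   matches in coding ESTs) for the target-prediction stage.
#' @return a list of class `"mirforge_sim_config"`.
#' @export
sim_config <- function(seed = 1L,
                       n_ests = 300L,
                       est_length = c(300L, 600L),
                       n_true_mirnas = 20L,
                       n_decoy_hairpins = 200L,
                       mature_len_range = c(20L, 22L),
                       dicer_precision = 0.9,
                       libraries = c("L1", "L2", "L3", "L4"),
                       base_count_range = c(200L, 1200L),
                       star_fraction = 0.15,
                       other_fraction = 0.10,
                       planted_fc = data.frame(
                         treated = c("L2", "L2", "L4", "L4"),
                         control = c("L1", "L1", "L3", "L3"),
                         fc = c(4, 0.25, 4, 0.25),
                         fraction = c(0.25, 0.25, 0.25, 0.25),
                         stringsAsFactors = FALSE),
                       decoy_count_range = c(50L, 90L),
                       noise_read_fraction = 0.5,
                       bulge_A_range = c(0L, 2L),
                       bulge_B_range = c(1L, 2L),
                       loop_D_range = c(4L, 8L),
                       adapter = "TGGAATTCTCGGGTGCCAAGG",
                       read_total_len = 36L,
                       n_conserved = 8L,
                       n_target_sites = 2L) {
  cfg <- as.list(environment())
  stopifnot(cfg$dicer_precision >= 0, cfg$dicer_precision <= 1,
            cfg$noise_read_fraction >= 0, cfg$star_fraction >= 0)
  class(cfg) <- "mirforge_sim_config"
  cfg
}

.random_seq <- function(n, gc = 0.45) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

#' Construct a hairpin precursor around a mature sequence
#'
#' Builds `5' flank + mature + flank + loop + reverse complement of the 5'
#' arm`, then plants exactly `bulges_A` unpaired insertions (runs of at most
#' `max_run_B` nt) at interior positions of the 3' arm. By construction the
#' sequence folds into a single-loop hairpin for the large majority of
#' draws; callers that require a clean fold verify with the folding engine
#' and redraw.
#'
#' @param mature mature sequence (19-24 nt).
#' @param bulges_A number of planted bulges.
#' @param max_run_B maximal bulge run length, nt.
#' @param loop_D terminal loop size, nt (>= 3).
#' @param seed integer seed.
#' @param flank flank length on each side of the mature within the 5' arm.
#' @return list: `sequence`, `mature_start`, `mature_end` (0-based
#'   half-open in the precursor).
#' @export
make_hairpin <- function(mature, bulges_A = 0L, max_run_B = 1L, loop_D = 4L,
                         seed = NULL, flank = 10L) {
  if (!is.null(seed)) set.seed(seed)
  mature <- dna(mature)
  mlen <- nchar(mature)
  if (mlen < 19L || mlen > 24L) .stopf("mature must be 19-24 nt (got %d)",
                                       mlen)
  if (loop_D < 3L) .stopf("terminal loop must be at least 3 nt")
  if (bulges_A * max_run_B >= mlen / 2)
    .stopf("infeasible bulge profile: A x B = %d >= mature length / 2",
           bulges_A * max_run_B)
  f5 <- .random_seq(flank)
  f3 <- .random_seq(flank)
  arm5 <- paste0(f5, mature, f3)
  arm3 <- revcomp(arm5)
  # loop biased away from self-pairing
  loop <- paste(sample(c("A", "C"), loop_D, replace = TRUE,
                       prob = c(0.6, 0.4)), collapse = "")
  if (bulges_A > 0L) {
    # insert unpaired runs at interior 3'-arm positions (star-side bulges)
    pos <- sort(sample(seq(4L, nchar(arm3) - 4L), bulges_A))
    for (i in rev(seq_along(pos))) {
      run <- sample(seq_len(max_run_B), 1L)
      ins <- paste(sample(c("A", "C"), run, replace = TRUE), collapse = "")
      arm3 <- paste0(substr(arm3, 1L, pos[i]), ins,
                     substr(arm3, pos[i] + 1L, nchar(arm3)))
    }
  }
  seq <- paste0(arm5, loop, arm3)
  list(sequence = seq, mature_start = flank,
       mature_end = flank + mlen)
}

# jitter both read ends by at most `tol` nt (at least one end moves)
.jitter_interval <- function(start, end, tol = 2L, ref_len = Inf) {
  repeat {
    ds <- sample(-tol:tol, 1L)
    de <- sample(-tol:tol, 1L)
    if (ds != 0L || de != 0L) break
  }
  s <- max(0L, start + ds)
  e <- min(ref_len, end + de)
  if (e - s < 15L) return(c(start, end))
  c(s, e)
}

#' Generate a synthetic multi-library small-RNA dataset
#'
#' Embeds true miRNA hairpins and decoy hairpins into random ESTs, draws
#' per-library reads (mature/star with Dicer-like precision, diffuse decoy
#' reads, uniform noise), applies planted fold changes, ligates adapters,
#' and writes everything in standard formats alongside a ground-truth
#' manifest.
#'
#' @param config a `"mirforge_sim_config"`.
#' @param out_dir output directory (created). `NULL` returns objects
#'   without writing files.
#' @return list with `reference` (data frame), `reads` (per-library data
#'   frames), `annotation`, `go`, `mature_db`, `manifest` (data frame of
#'   planted truth) and `paths` (written files, when `out_dir` given).
#' @export
generate_dataset <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "mirforge_sim_config"))
  set.seed(config$seed)
  nlib <- length(config$libraries)

  # --- reference ESTs -----------------------------------------------------
  est_len <- sample(config$est_length[1L]:config$est_length[2L],
                    config$n_ests, replace = TRUE)
  ests <- vapply(est_len, .random_seq, character(1))
  est_ids <- sprintf("EST%05d", seq_len(config$n_ests))

  n_hp <- config$n_true_mirnas + config$n_decoy_hairpins
  if (n_hp > config$n_ests)
    .stopf("need at least as many ESTs as hairpins (%d < %d)",
           config$n_ests, n_hp)
  host <- sample(config$n_ests, n_hp)

  # --- hairpins (fold-checked construction) -------------------------------
  hp <- vector("list", n_hp)
  pending <- seq_len(n_hp)
  tries <- 0L
  while (length(pending) && tries < 12L) {
    tries <- tries + 1L
    drafts <- lapply(pending, function(i) {
      mlen <- sample(config$mature_len_range[1L]:config$mature_len_range[2L],
                     1L)
      make_hairpin(.random_seq(mlen, gc = 0.5),
                   bulges_A = sample(config$bulge_A_range[1L]:
                                       config$bulge_A_range[2L], 1L),
                   max_run_B = sample(config$bulge_B_range[1L]:
                                        config$bulge_B_range[2L], 1L),
                   loop_D = sample(config$loop_D_range[1L]:
                                     config$loop_D_range[2L], 1L))
    })
    fd <- fold(vapply(drafts, `[[`, "", "sequence"))
    ok <- vapply(seq_along(drafts), function(k) {
      ft <- hairpin_features(fd$sequence[k], fd$structure[k], fd$mfe[k])
      span <- stemloop_span(fd$structure[k],
                            drafts[[k]]$mature_start,
                            drafts[[k]]$mature_end, min_cover = 1)
      ft$n_terminal_loops == 1L && ft$mfe < 0 && !is.null(span) &&
        !is.null(tryCatch(duplex_characteristics(
          fd$structure[k], drafts[[k]]$mature_start,
          drafts[[k]]$mature_end), error = function(e) NULL))
    }, logical(1))
    for (k in which(ok)) hp[[pending[k]]] <- drafts[[k]]
    pending <- pending[!ok]
  }
  if (length(pending))
    .stopf("hairpin construction failed to fold for %d candidates",
           length(pending))

  # embed hairpins mid-EST
  hp_start <- integer(n_hp)
  for (i in seq_len(n_hp)) {
    e <- host[i]
    L <- nchar(hp[[i]]$sequence)
    pos <- sample(seq(40L, est_len[e] - L - 40L), 1L)
    ests[e] <- paste0(substr(ests[e], 1L, pos),
                      hp[[i]]$sequence,
                      substr(ests[e], pos + 1L, est_len[e]))
    est_len[e] <- nchar(ests[e])
    hp_start[i] <- pos   # 0-based start of hairpin in EST
  }

  is_true <- seq_len(n_hp) <= config$n_true_mirnas
  mature_seq <- vapply(seq_len(n_hp), function(i) {
    substr(hp[[i]]$sequence, hp[[i]]$mature_start + 1L, hp[[i]]$mature_end)
  }, character(1))

  # star intervals from the constructed fold (for read placement)
  fd_all <- fold(vapply(hp, `[[`, "", "sequence"))
  star_iv <- lapply(seq_len(n_hp), function(i) {
    infer_star(fd_all$structure[i], hp[[i]]$mature_start,
               hp[[i]]$mature_end)
  })

  # --- planted abundances and fold changes --------------------------------
  lam <- exp(runif(config$n_true_mirnas, log(config$base_count_range[1L]),
                   log(config$base_count_range[2L])))
  fc_mat <- matrix(1, config$n_true_mirnas, nlib,
                   dimnames = list(NULL, config$libraries))
  fc_truth <- NULL
  if (!is.null(config$planted_fc) && nrow(config$planted_fc)) {
    used <- list()
    for (r in seq_len(nrow(config$planted_fc))) {
      pf <- config$planted_fc[r, ]
      # affected sets are disjoint within a comparison
      pool <- setdiff(seq_len(config$n_true_mirnas),
                      used[[pf$treated]])
      aff <- sample(pool, min(length(pool),
                              round(pf$fraction * config$n_true_mirnas)))
      used[[pf$treated]] <- c(used[[pf$treated]], aff)
      fc_mat[aff, pf$treated] <- fc_mat[aff, pf$treated] * pf$fc
      fc_truth <- rbind(fc_truth, data.frame(
        mirna = sprintf("mir%03d", aff), treated = pf$treated,
        control = pf$control, fc = pf$fc, stringsAsFactors = FALSE))
    }
  }

  # --- reads --------------------------------------------------------------
  draw_reads <- function(est_idx, s, e, n_exact, n_jitter, lib) {
    if (n_exact + n_jitter == 0L) return(NULL)
    L <- est_len[est_idx]
    iv <- matrix(rep(c(s, e), n_exact + n_jitter), ncol = 2, byrow = TRUE)
    if (n_jitter > 0L) {
      for (j in seq_len(n_jitter)) {
        iv[n_exact + j, ] <- .jitter_interval(s, e, 2L, L)
      }
    }
    data.frame(sequence = substr(rep(ests[est_idx], nrow(iv)),
                                 iv[, 1L] + 1L, iv[, 2L]),
               library_id = lib, stringsAsFactors = FALSE)
  }

  reads <- list()
  for (li in seq_len(nlib)) {
    lib <- config$libraries[li]
    parts <- list()
    for (i in seq_len(n_hp)) {
      e <- host[i]
      ms <- hp_start[i] + hp[[i]]$mature_start
      me <- hp_start[i] + hp[[i]]$mature_end
      if (is_true[i]) {
        lam_i <- lam[i] * fc_mat[i, lib]
        n_mat <- rpois(1L, lam_i)
        n_star <- rpois(1L, lam_i * config$star_fraction)
        n_oth <- rpois(1L, lam_i * config$other_fraction)
        ex_m <- rbinom(1L, n_mat, config$dicer_precision)
        parts[[length(parts) + 1L]] <-
          draw_reads(e, ms, me, ex_m, n_mat - ex_m, lib)
        if (!is.na(star_iv[[i]]$start) && n_star > 0L) {
          ss <- hp_start[i] + star_iv[[i]]$start
          se <- hp_start[i] + star_iv[[i]]$end
          ex_s <- rbinom(1L, n_star, config$dicer_precision)
          parts[[length(parts) + 1L]] <-
            draw_reads(e, ss, se, ex_s, n_star - ex_s, lib)
        }
        if (n_oth > 0L) {
          hl <- nchar(hp[[i]]$sequence)
          rl <- sample(18:24, n_oth, replace = TRUE)
          off <- vapply(rl, function(l) sample(0:(hl - l), 1L), integer(1))
          parts[[length(parts) + 1L]] <- data.frame(
            sequence = substr(rep(ests[e], n_oth),
                              hp_start[i] + off + 1L,
                              hp_start[i] + off + rl),
            library_id = lib, stringsAsFactors = FALSE)
        }
      } else {
        # decoy: diffuse reads, half at a mild preferred position
        n_dec <- rpois(1L, runif(1L, config$decoy_count_range[1L],
                                 config$decoy_count_range[2L]))
        if (n_dec == 0L) next
        n_pref <- rbinom(1L, n_dec, 0.5)
        parts[[length(parts) + 1L]] <-
          draw_reads(e, ms, me, n_pref, 0L, lib)
        hl <- nchar(hp[[i]]$sequence)
        if (n_dec - n_pref > 0L) {
          rl <- sample(18:24, n_dec - n_pref, replace = TRUE)
          off <- vapply(rl, function(l) sample(0:(hl - l), 1L), integer(1))
          parts[[length(parts) + 1L]] <- data.frame(
            sequence = substr(rep(ests[e], length(rl)),
                              hp_start[i] + off + 1L,
                              hp_start[i] + off + rl),
            library_id = lib, stringsAsFactors = FALSE)
        }
      }
    }
    planted <- do.call(rbind, parts)
    n_noise <- round(config$noise_read_fraction * nrow(planted))
    if (n_noise > 0L) {
      n_rand <- round(0.05 * n_noise)
      n_est <- n_noise - n_rand
      ei <- sample(config$n_ests, n_est, replace = TRUE)
      rl <- sample(18:28, n_est, replace = TRUE)
      off <- vapply(seq_len(n_est), function(k) {
        sample(0:(est_len[ei[k]] - rl[k]), 1L)
      }, integer(1))
      noise <- data.frame(
        sequence = substr(ests[ei], off + 1L, off + rl),
        library_id = lib, stringsAsFactors = FALSE)
      rand <- if (n_rand > 0L) data.frame(
        sequence = vapply(sample(18:28, n_rand, replace = TRUE),
                          .random_seq, character(1)),
        library_id = lib, stringsAsFactors = FALSE) else NULL
      planted <- rbind(planted, noise, rand)
    }
    reads[[lib]] <- planted[sample(nrow(planted)), , drop = FALSE]
  }

  # --- annotation, GO, conserved db, target sites -------------------------
  clusters <- sprintf("CL%05d", seq_len(config$n_ests))
  descs <- sample(c("auxin response factor", "protein kinase",
                    "transcription factor", "transport protein",
                    "stress response protein", "metabolic enzyme",
                    "unknown protein", "hypothetical protein"),
                  config$n_ests, replace = TRUE,
                  prob = c(rep(0.13, 6), 0.11, 0.11))
  go_pool <- sprintf("GO:%07d", seq(8150, by = 7, length.out = 15L))
  go_terms <- vapply(seq_len(config$n_ests), function(i) {
    paste(sample(go_pool, sample(1:3, 1L)), collapse = ",")
  }, character(1))

  # embed antisense target sites for the first miRNAs in non-host ESTs
  target_truth <- NULL
  if (config$n_target_sites > 0L) {
    free <- setdiff(seq_len(config$n_ests), host)
    for (i in seq_len(min(10L, config$n_true_mirnas))) {
      site <- revcomp(mature_seq[i])
      picks <- sample(free, config$n_target_sites)
      for (e in picks) {
        pos <- sample(seq(20L, est_len[e] - nchar(site) - 20L), 1L)
        ests[e] <- paste0(substr(ests[e], 1L, pos), site,
                          substr(ests[e], pos + nchar(site) + 1L,
                                 est_len[e]))
        if (grepl("unknown|hypothetical", descs[e])) descs[e] <-
            "transcription factor"
        target_truth <- rbind(target_truth, data.frame(
          mirna = sprintf("mir%03d", i), transcript_id = est_ids[e],
          site_start = pos, stringsAsFactors = FALSE))
      }
    }
  }

  mature_db <- NULL
  if (config$n_conserved > 0L) {
    idx <- seq_len(min(config$n_conserved, config$n_true_mirnas))
    fam <- sprintf("miR%d", 160 + idx)
    mature_db <- data.frame(
      id = sprintf("syn-%s%s", fam, letters[1 + (idx %% 2)]),
      family = fam, sequence = mature_seq[idx], stringsAsFactors = FALSE)
    # a few unrelated entries
    extra <- data.frame(
      id = sprintf("syn-miR%d", 900 + 1:10),
      family = sprintf("miR%d", 900 + 1:10),
      sequence = vapply(rep(21L, 10L), .random_seq, character(1)),
      stringsAsFactors = FALSE)
    mature_db <- rbind(mature_db, extra)
  }

  manifest <- data.frame(
    mirna = sprintf("mir%03d", seq_len(config$n_true_mirnas)),
    mature_seq = mature_seq[is_true],
    star_seq = vapply(which(is_true), function(i) {
      if (is.na(star_iv[[i]]$start)) return(NA_character_)
      substr(hp[[i]]$sequence, star_iv[[i]]$start + 1L, star_iv[[i]]$end)
    }, character(1)),
    est_id = est_ids[host[is_true]],
    mature_start = hp_start[is_true] +
      vapply(hp[is_true], `[[`, integer(1), "mature_start"),
    hairpin_start = hp_start[is_true],
    hairpin_len = vapply(hp[is_true], function(h) nchar(h$sequence),
                         integer(1)),
    base_count = lam,
    stringsAsFactors = FALSE)
  for (lib in config$libraries) {
    manifest[[paste0("expected_", lib)]] <- lam * fc_mat[, lib]
  }

  reference <- data.frame(id = est_ids, sequence = ests,
                          stringsAsFactors = FALSE)
  annotation <- structure(list(
    transcripts = data.frame(transcript_id = est_ids, cluster_id = clusters,
                             description = descs, stringsAsFactors = FALSE),
    go = data.frame(cluster_id = clusters, go_terms = go_terms,
                    category = "BP", orphan = FALSE,
                    stringsAsFactors = FALSE)),
    class = "mirforge_annotation")

  res <- list(reference = reference, reads = reads,
              annotation = annotation, mature_db = mature_db,
              manifest = manifest, fc_truth = fc_truth,
              target_truth = target_truth, config = config)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    p <- list()
    p$reference <- file.path(out_dir, "reference.fasta")
    writeLines(as.vector(rbind(paste0(">", est_ids), ests)), p$reference)
    for (lib in config$libraries) {
      rd <- reads[[lib]]
      seqs <- rd$sequence
      if (!is.null(config$adapter)) {
        seqs <- substr(paste0(seqs, config$adapter), 1L,
                       config$read_total_len)
      }
      qual <- vapply(nchar(seqs), function(n)
        paste(rep("I", n), collapse = ""), character(1))
      fq <- file.path(out_dir, paste0(lib, ".fastq"))
      writeLines(as.vector(rbind(
        sprintf("@%s_r%06d", lib, seq_along(seqs)), seqs, "+", qual)), fq)
      p[[lib]] <- fq
    }
    p$annotation <- file.path(out_dir, "annotation.tsv")
    write.table(annotation$transcripts, p$annotation, sep = "\t",
                quote = FALSE, row.names = FALSE)
    p$go <- file.path(out_dir, "go.tsv")
    write.table(annotation$go[c("cluster_id", "go_terms", "category")],
                p$go, sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(mature_db)) {
      p$mature_db <- file.path(out_dir, "mature_db.fasta")
      writeLines(as.vector(rbind(
        paste0(">", mature_db$id), rna(mature_db$sequence))), p$mature_db)
    }
    p$manifest <- file.path(out_dir, "manifest.json")
    jsonlite::write_json(list(manifest = manifest, fc_truth = fc_truth,
                              seed = config$seed),
                         p$manifest, digits = NA, auto_unbox = TRUE)
    res$paths <- p
  }
  res
}
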