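#' Per-class kinetic parameters for a simulated annotation
#'
#' Assigns each gene kinetic rates drawn from class-typical ranges:
#' intron-containing mRNAs get first-order splicing with slow mature decay
#' (RP genes splicing faster on average than non-RP genes); the unstable
#' non-coding classes (CUT, XUT) get multi-step (Erlang) processing with
#' fast final decay, SUTs a slower decay, reproducing the delayed,
#' non-first-order early kinetics of those classes; snoRNAs process
#' quickly; intronless mRNAs ("other") mature nearly instantly and decay
#' slowly. Rates are log-uniform within the class range.
#'
#' @param models Annotation tibble.
#' @param seed Integer seed.
#' @return Parameter tibble for [simulate_labeled_abundances()].
#' @export
simulate_kinetic_params <- function(models, seed = 1L) {
  ranges <- list(
    #                 k_syn        k_splice      k_decay      n_steps
    `RP-intronic`     = list(c(5, 30), c(0.4, 2.0), c(0.05, 0.2), 1L),
    `non-RP-intronic` = list(c(2, 15), c(0.1, 1.0), c(0.05, 0.2), 1L),
    CUT               = list(c(1, 5),  c(0.2, 0.6), c(0.5, 2.0),  4L),
    SUT               = list(c(1, 5),  c(0.2, 0.6), c(0.1, 0.4),  3L),
    XUT               = list(c(1, 5),  c(0.2, 0.6), c(0.4, 1.5),  4L),
    snoRNA            = list(c(2, 10), c(1.0, 3.0), c(0.02, 0.1), 2L),
    other             = list(c(2, 20), c(3.0, 6.0), c(0.05, 0.3), 1L)
  )
  runif_log <- function(n, lo, hi) exp(runif(n, log(lo), log(hi)))
  with_seed(derive_seed(seed, 808L), {
    rows <- lapply(seq_len(nrow(models)), function(i) {
      rg <- ranges[[models$class[i]]]
      kinetic_params(
        k_syn = runif_log(1, rg[[1]][1], rg[[1]][2]),
        k_splice = runif_log(1, rg[[2]][1], rg[[2]][2]),
        k_decay = runif_log(1, rg[[3]][1], rg[[3]][2]),
        n_maturation_steps = rg[[4]],
        gene_id = models$gene_id[i]
      )
    })
    bind_rows(rows)
  })
}

#' Intronic share of FPKM over the intron-containing genes
#'
#' The per-nucleotide intron read density over the per-nucleotide total
#' density, summed over intron-containing genes — the "intronic FPKM
#' percentage" statistic that feeds [background_bound()] (the FPKM depth and
#' scale factors cancel in the ratio).
#'
#' @param counts Region-count tibble ([count_regions()]); if it carries a
#'   `time` column one fraction per time point is returned.
#' @param models Annotation tibble.
#' @return Tibble with optional `time` and `intronic_fraction`.
#' @export
intronic_fpkm_fraction <- function(counts, models) {
  idx <- match(counts$gene_id, models$gene_id)
  intronic <- models$intron_len[idx] > 0
  counts <- counts[intronic, , drop = FALSE]
  idx <- idx[intronic]
  d_i <- counts$intron / pmax(models$intron_len[idx], 1)
  d_e <- (counts$exon1 + counts$exon2 + counts$junction +
            counts$boundary_5ss + counts$boundary_3ss) /
    (models$exon1_len[idx] + models$exon2_len[idx])
  keys <- intersect("time", names(counts))
  df <- tibble(d_i = d_i, d_e = d_e)
  for (k in keys) df[[k]] <- counts[[k]]
  df |>
    group_by(across(all_of(keys))) |>
    summarise(intronic_fraction = sum(.data$d_i) / (sum(.data$d_i) + sum(.data$d_e)),
              .groups = "drop")
}

#' Default pipeline configuration
#'
#' The single source of truth for an all-synthetic end-to-end run: the
#' labeling design (1.5, 2.5 and 5 min plus steady state, >= 2 replicates),
#' the selection thresholds (whole-gene FPKM > 10, 95% credible interval
#' width < 0.3, adjusted p < 0.05), the fragment model and the Gibbs
#' settings. Any element can be overridden via `...` or a YAML file passed
#' to [run_pipeline()].
#'
#' @param ... Named overrides of the defaults.
#' @return A named list (class `tu_config`).
#' @export
default_run_config <- function(...) {
  cfg <- list(
    seed = 1L,
    n_genes = 40L,
    class_mix = c(`RP-intronic` = 0.25, `non-RP-intronic` = 0.25,
                  CUT = 0.2, SUT = 0.2, other = 0.1),
    times = c(1.5, 2.5, 5),
    n_replicates = 2L,
    n_fragments = 20000L,
    read_len = 50L, frag_len_mean = 80, frag_len_sd = 10,
    background_fraction = 0.05,
    min_fpkm = 10, ci_max_width = 0.3, p_thresh = 0.05,
    estimator = "posterior", n_iter = 2000L, burn_in = 500L,
    min_anchor = 5L
  )
  overrides <- list(...)
  cfg[names(overrides)] <- overrides
  structure(cfg, class = c("tu_config", "list"))
}

stage_log <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

write_stage_tsv <- function(df, path, stage, cfg_hash) {
  header <- sprintf("# tukinetics stage=%s config=%s", stage, cfg_hash)
  writeLines(header, path)
  readr::write_tsv(df, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

read_stage_tsv <- function(path) {
  readr::read_tsv(path, comment = "#", show_col_types = FALSE)
}

#' Run the full synthetic 4tU-seq analysis pipeline
#'
#' Orchestrates simulate -> count -> quantify -> kinetics -> features ->
#' statistics as one reproducible run: simulates an annotated gene set with
#' class-typical kinetics, draws reads for every labeling time point,
#' replicate and the steady state, estimates splicing ratios (posterior
#' means averaged across replicates, steady state pooled), applies the
#' credible-interval filter, computes splicing-speed AUCs and decay-rate
#' proxies, bounds the background contamination from the simulated
#' background sample, extracts intron features, and runs the feature
#' statistics. Every stage writes a TSV (with a header line naming the
#' stage and the config hash) into `out_dir`, plus a `manifest.tsv` of file
#' checksums; identical configs produce byte-identical outputs.
#'
#' @param config A [default_run_config()] list, a YAML file path, or `NULL`
#'   for the defaults.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the main result tables and the manifest.
#' @export
run_pipeline <- function(config = NULL, out_dir = tempfile("tukinetics_run_")) {
  cfg <- if (is.null(config)) {
    default_run_config()
  } else if (is.character(config)) {
    do.call(default_run_config, yaml::read_yaml(config))
  } else {
    do.call(default_run_config, unclass(config))
  }
  if (is.list(cfg$class_mix)) cfg$class_mix <- unlist(cfg$class_mix)
  if (is.unsorted(cfg$times, strictly = TRUE) || any(cfg$times <= 0)) {
    abort("Config `times` must be strictly increasing and positive.")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg_hash <- rlang::hash(cfg)

  # --- simulate ---------------------------------------------------------
  models <- simulate_annotation(cfg$n_genes, cfg$class_mix, seed = cfg$seed)
  params <- simulate_kinetic_params(models, seed = cfg$seed)
  truth <- simulate_labeled_abundances(params, cfg$times)
  stage_log("simulate", "%d genes (%d intron-containing), %d time points + steady state",
            nrow(models), sum(models$intron_len > 0), length(cfg$times))
  write_annotation(models, file.path(out_dir, "annotation.gtf"))
  write_stage_tsv(models, file.path(out_dir, "annotation.tsv"), "simulate", cfg_hash)
  write_stage_tsv(truth, file.path(out_dir, "truth_abundances.tsv"), "simulate", cfg_hash)

  reads_by_rep <- lapply(seq_len(cfg$n_replicates), function(r) {
    simulate_reads(truth, models, n_fragments = cfg$n_fragments,
                   read_len = cfg$read_len, frag_len_mean = cfg$frag_len_mean,
                   frag_len_sd = cfg$frag_len_sd,
                   background_fraction = cfg$background_fraction,
                   min_anchor = cfg$min_anchor,
                   seed = derive_seed(cfg$seed, 9000L + r))
  })
  # a pure background sample (the 0-min mock purification)
  bg_truth <- filter(truth, is.infinite(.data$time))
  bg_reads <- simulate_reads(bg_truth, models, n_fragments = cfg$n_fragments,
                             read_len = cfg$read_len,
                             frag_len_mean = cfg$frag_len_mean,
                             frag_len_sd = cfg$frag_len_sd,
                             seed = derive_seed(cfg$seed, 9999L))
  write_read_table(reads_by_rep[[1]], file.path(out_dir, "reads_rep1.tsv"))
  stage_log("reads", "%d fragments x %d replicates (+%d background)",
            nrow(reads_by_rep[[1]]), cfg$n_replicates, nrow(bg_reads))

  # --- count ------------------------------------------------------------
  counts_by_rep <- lapply(reads_by_rep, count_regions, models = models,
                          min_anchor = cfg$min_anchor)
  write_stage_tsv(counts_by_rep[[1]], file.path(out_dir, "counts_rep1.tsv"),
                  "count", cfg_hash)

  # --- background bound -------------------------------------------------
  bg_counts <- count_regions(bg_reads, models, min_anchor = cfg$min_anchor)
  alpha0 <- intronic_fpkm_fraction(bg_counts, models)$intronic_fraction
  a1_tab <- intronic_fpkm_fraction(counts_by_rep[[1]], models)
  alpha1 <- a1_tab$intronic_fraction[a1_tab$time == min(cfg$times)]
  background <- background_bound(alpha0, alpha1)
  write_stage_tsv(background, file.path(out_dir, "background_bound.tsv"),
                  "background", cfg_hash)
  stage_log("background", "alpha0 = %.3f, alpha1 = %.3f, bound = %.1f%%",
            alpha0, alpha1, 100 * background$fraction_bound)

  # --- quantify splicing ------------------------------------------------
  est_by_rep <- lapply(seq_along(reads_by_rep), function(r) {
    nascent <- filter(reads_by_rep[[r]], is.finite(.data$time))
    est <- quantify_splicing(nascent, models, estimator = cfg$estimator,
                             min_fpkm = cfg$min_fpkm,
                             min_anchor = cfg$min_anchor,
                             n_iter = cfg$n_iter, burn_in = cfg$burn_in,
                             seed = derive_seed(cfg$seed, 7000L + r))
    est$replicate <- r
    est
  })
  est_all <- bind_rows(est_by_rep)
  n_before <- dplyr::n_distinct(est_all$gene_id)
  retained <- ci_filter(est_all, max_width = cfg$ci_max_width)
  n_after <- dplyr::n_distinct(retained$gene_id)
  stage_log("quantify", "%d genes estimated -> %d retained at CI width < %g",
            n_before, n_after, cfg$ci_max_width)
  if (n_after == 0) {
    warn("No genes survive the credible-interval filter; downstream tables are empty.")
  }
  write_stage_tsv(est_all, file.path(out_dir, "splicing_estimates.tsv"),
                  "quantify", cfg_hash)

  # steady state: pooled reads across replicates
  ss_reads <- bind_rows(lapply(reads_by_rep, filter, is.infinite(.data$time)))
  attr(ss_reads, "frag_len_mean") <- cfg$frag_len_mean
  keep_genes <- unique(retained$gene_id)
  speeds <- tibble(gene_id = character(), `r_1.5` = numeric(),
                   `r_2.5` = numeric(), `r_5.0` = numeric(),
                   r_ss = numeric(), auc = numeric())
  if (length(keep_genes) > 0) {
    ss_est <- posterior_ratio(
      filter(ss_reads, .data$gene_id %in% keep_genes),
      models, n_iter = cfg$n_iter, burn_in = cfg$burn_in,
      seed = derive_seed(cfg$seed, 7500L)
    )
    combined <- combine_replicates(retained)
    combined <- bind_rows(combined,
                          select(ss_est, "gene_id", "time", "ratio") |>
                            mutate(n_replicates = cfg$n_replicates))
    speeds <- splicing_speed(combined)
    write_stage_tsv(combined, file.path(out_dir, "splicing_combined.tsv"),
                    "quantify", cfg_hash)
  }
  write_stage_tsv(speeds, file.path(out_dir, "splicing_speed.tsv"),
                  "speed", cfg_hash)
  stage_log("speed", "%d genes with AUC splicing speeds", nrow(speeds))

  # --- decay of the non-coding classes ---------------------------------
  fp <- lapply(reads_by_rep, fpkm_table, models = models)
  fp_mean <- bind_rows(fp) |>
    group_by(.data$gene_id, .data$time) |>
    summarise(fpkm = mean(.data$fpkm), .groups = "drop")
  fp_wide <- fp_mean |>
    mutate(tp = dplyr::case_when(
      .data$time == 1.5 ~ "fpkm_1.5", .data$time == 2.5 ~ "fpkm_2.5",
      .data$time == 5 ~ "fpkm_5.0", is.infinite(.data$time) ~ "fpkm_ss",
      TRUE ~ NA_character_)) |>
    filter(!is.na(.data$tp)) |>
    select("gene_id", "tp", "fpkm") |>
    tidyr::pivot_wider(names_from = "tp", values_from = "fpkm") |>
    left_join(select(models, "gene_id", "class", "tx_len"), by = "gene_id")
  nc <- filter(fp_wide, .data$class %in% c("CUT", "SUT", "XUT"))
  decay <- mutate(nc, decay_proxy = decay_rate_proxy(
    .data$`fpkm_1.5`, .data$`fpkm_2.5`, .data$`fpkm_5.0`, .data$fpkm_ss))
  write_stage_tsv(decay, file.path(out_dir, "decay_proxy.tsv"), "decay", cfg_hash)
  stage_log("decay", "%d non-coding transcripts with decay proxies",
            sum(!is.na(decay$decay_proxy)))

  # --- features + statistics -------------------------------------------
  stats_out <- list()
  intronic <- models[models$intron_len > 0 & models$gene_id %in% speeds$gene_id, ]
  if (nrow(intronic) >= 9) {
    introns <- simulate_intron_sequences(
      nrow(intronic), au_bias = 0.6,
      length = pmax(intronic$intron_len, 60L),
      seed = derive_seed(cfg$seed, 1212L))
    seqs <- vapply(seq_len(nrow(intronic)), function(i) {
      m <- intronic[i, ]
      paste0(random_exon_seq(m$exon1_len, derive_seed(cfg$seed, 5000L + i)),
             introns$seq[i],
             random_exon_seq(m$exon2_len, derive_seed(cfg$seed, 6000L + i)))
    }, character(1))
    names(seqs) <- intronic$gene_id
    models_adj <- mutate(intronic,
                         intron_len = introns$length,
                         tx_len = .data$exon1_len + introns$length + .data$exon2_len)
    feats <- extract_intron_features(
      models_adj, seqs,
      tibble(gene_id = intronic$gene_id, bp_pos = introns$bp_pos))
    feats <- left_join(feats, select(speeds, "gene_id", "auc"), by = "gene_id")
    write_stage_tsv(feats, file.path(out_dir, "intron_features.tsv"),
                    "features", cfg_hash)
    split3 <- thirds_split(feats, gene_id, auc)
    stats_out$wilcoxon_dg <- wilcoxon_thirds(split3, dg_per_nt_intron)
    stats_out$correlations <- feature_speed_correlations(
      select(feats, -"gene_id", -"class", -"window_truncated", -"bp_pos"), auc)
    write_stage_tsv(stats_out$correlations,
                    file.path(out_dir, "feature_correlations.tsv"),
                    "stats", cfg_hash)
    stage_log("features", "%d genes x %d features", nrow(feats), ncol(feats) - 2L)
  } else {
    stage_log("features", "too few retained intron-containing genes; stage skipped")
  }

  manifest_files <- sort(list.files(out_dir, pattern = "\\.(tsv|gtf)$"))
  manifest <- tibble(
    file = manifest_files,
    md5 = unname(tools::md5sum(file.path(out_dir, manifest_files))),
    config = cfg_hash
  )
  readr::write_tsv(manifest, file.path(out_dir, "manifest.tsv"))
  stage_log("done", "%d output files in %s", nrow(manifest) + 1L, out_dir)
  invisible(list(models = models, truth = truth, estimates = est_all,
                 retained = retained, speeds = speeds, decay = decay,
                 background = background, stats = stats_out,
                 manifest = manifest, out_dir = out_dir, config = cfg))
}

random_exon_seq <- function(len, seed) {
  with_seed(seed, paste(sample(c("A", "C", "G", "U"), len, replace = TRUE),
                        collapse = ""))
}
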