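#' Run the full seed-PLS analysis pipeline
#'
#' Orchestrates every stage behind one configuration document: load (or
#' simulate) the study table, gray-matter volumes and hippocampus mask;
#' TIV-scale and split the hippocampus into the four long-axis seed
#' regions; extract seed values; run the seed PLS with permutation test
#' and bootstrap; extract BSR clusters; run the volumetric and
#' brain-score group statistics; and write all results (JSON numerics,
#' TSV tables, NIfTI BSR maps, and a log of versions, seeds and
#' parameters) to an output directory.
#'
#' @param config path to a YAML or JSON configuration file, or an
#'   equivalent named list. Recognised fields: `subject_table`, `mask`
#'   (input paths; volume paths come from the table's `path` column) or
#'   `simulate` (arguments to [synthetic_config()]); `n_perm` (default
#'   2000), `n_boot` (1000), `bsr_threshold` (3.8), `min_cluster_size`
#'   (50), `connectivity` (26), `n_lv_report` (3), `seed`, `output_dir`,
#'   and optionally `analysis_mask` (a brain mask for the image block;
#'   default: every voxel of the grid).
#' @param output_dir overrides `config$output_dir`.
#' @return The output directory path, invisibly; side effect: the result
#'   files.
#' @export
run_pipeline <- function(config, output_dir = NULL) {
  if (is.character(config)) {
    config <- if (grepl("\\.json$", config, ignore.case = TRUE))
      jsonlite::read_json(config, simplifyVector = TRUE)
    else yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  out <- output_dir %||% config$output_dir
  if (is.null(out)) stop("no output directory given", call. = FALSE)
  n_perm <- config$n_perm %||% 2000
  n_boot <- config$n_boot %||% 1000
  thr <- config$bsr_threshold %||% 3.8
  min_size <- config$min_cluster_size %||% 50
  conn <- config$connectivity %||% 26
  n_lv_report <- config$n_lv_report %||% 3
  rng_seed <- config$seed %||% 1L

  if (!is.null(config$simulate)) {
    args <- config$simulate
    if (isTRUE(args)) args <- list()
    if (is.null(args$rng_seed)) args$rng_seed <- rng_seed
    ds <- generate_dataset(do.call(synthetic_config, args))
    table <- ds$table; volumes <- ds$volumes; mask <- ds$mask
  } else {
    missing_inputs <- character(0)
    for (f in c("subject_table", "mask"))
      if (is.null(config[[f]]) || !file.exists(config[[f]]))
        missing_inputs <- c(missing_inputs, f)
    if (length(missing_inputs))
      stop("missing input(s) before computation:\n",
           paste0("  - ", missing_inputs, collapse = "\n"), call. = FALSE)
    table <- read_study_table(config$subject_table)
    if (is.null(table$path))
      stop("subject table must carry a 'path' column naming each scan's volume",
           call. = FALSE)
    absent <- table$path[!file.exists(table$path)]
    if (length(absent))
      stop("missing volume file(s):\n", paste0("  - ", absent, collapse = "\n"),
           call. = FALSE)
    mask <- read_volume(config$mask, binary = TRUE)
    volumes <- lapply(table$path, read_volume)
    names(volumes) <- scan_id(table$subject_id, table$timepoint)
  }

  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  set.seed(rng_seed)

  submasks <- split_hippocampus(mask, long_axis_spec())
  for (nm in names(submasks))
    write_volume(submasks[[nm]], file.path(out, paste0("mask_", nm, ".nii.gz")))
  seeds <- extract_seed_values(volumes, table, submasks)
  utils::write.table(seeds, file.path(out, "seed_values.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  amask <- if (!is.null(config$analysis_mask))
    read_volume(config$analysis_mask, binary = TRUE)
  else whole_grid_mask(mask)
  flat <- flatten(volumes, amask, table)
  fit <- seed_pls(flat, seeds, n_perm = n_perm, n_boot = n_boot,
                  bsr_threshold = thr)

  n_rep <- min(n_lv_report, fit$n_lv)
  cluster_tabs <- list()
  if (!is.null(fit$bsr)) {
    for (k in seq_len(n_rep)) {
      bm <- bsr_map(fit, k)
      write_volume(bm, file.path(out, sprintf("bsr_LV%d.nii.gz", k)))
      cl <- extract_clusters(bm, threshold = thr, connectivity = conn,
                             min_size = min_size)
      cluster_tabs[[paste0("LV", k)]] <- cl
      utils::write.table(cl, file.path(out, sprintf("clusters_LV%d.tsv", k)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }

  # group statistics: seed volumetry and brain scores
  stats_rows <- list()
  merged <- merge(seeds, unique(table[, c("subject_id", "age", "gender",
                                          "education")]), by = "subject_id")
  for (oc in seed_names()) {
    an <- mixed_anova(merged, oc)
    stats_rows[[oc]] <- data.frame(
      outcome = oc,
      time_F = an$time$statistic, time_p = an$time$p,
      interaction_F = an$interaction$statistic, interaction_p = an$interaction$p)
  }
  bs <- fit$brain_scores
  bs <- merge(bs, unique(table[, c("subject_id", "age", "gender",
                                   "education")]), by = "subject_id")
  for (k in seq_len(n_rep)) {
    an <- mixed_anova(bs, paste0("LV", k))
    stats_rows[[paste0("LV", k)]] <- data.frame(
      outcome = paste0("brain_score_LV", k),
      time_F = an$time$statistic, time_p = an$time$p,
      interaction_F = an$interaction$statistic, interaction_p = an$interaction$p)
  }
  anova_tab <- do.call(rbind, stats_rows)
  anova_tab$fdr_interaction_p <- bh_fdr(anova_tab$interaction_p)
  utils::write.table(anova_tab, file.path(out, "mixed_anova.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  res <- list(
    singular_values = fit$singular_values,
    covariance_fraction = fit$covariance_fraction,
    covariance_pct = 100 * fit$covariance_fraction,
    perm_p = fit$perm_p,   # NULL (absent) when n_perm = 0
    seed_corr = fit$seed_corr,
    brain_scores = fit$brain_scores,
    n_perm = n_perm, n_boot = n_boot, bsr_threshold = thr,
    clusters = cluster_tabs)
  jsonlite::write_json(res, file.path(out, "pls_results.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns",
                       null = "null")

  writeLines(c(
    sprintf("seedpls version: %s",
            as.character(utils::packageVersion("seedpls"))),
    sprintf("R version: %s", R.version.string),
    sprintf("timestamp: %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
    sprintf("rng_seed: %d", rng_seed),
    sprintf("n_perm: %d | n_boot: %d | bsr_threshold: %g | min_cluster_size: %d | connectivity: %d",
            n_perm, n_boot, thr, min_size, conn),
    sprintf("scans: %d | voxels in analysis mask: %d", nrow(flat$values),
            ncol(flat$values))),
    file.path(out, "pipeline_log.txt"))
  invisible(out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Analysis mask covering the whole grid of a reference volume.
whole_grid_mask <- function(ref) {
  volume_grid(array(1, dim = dim(ref$data)), ref$affine)
}
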