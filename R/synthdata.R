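#' Design-cell labels
#'
#' The 2x3 design has six cells, ordered group-major: control.TP1,
#' control.TP2, control.TP3, training.TP1, training.TP2, training.TP3.
#' This is the canonical row-block order of the stacked correlation matrix.
#'
#' @param groups,timepoints factor levels in design order.
#' @return Character vector of cell labels.
#' @export
cell_labels <- function(groups = c("control", "training"),
                        timepoints = c("TP1", "TP2", "TP3")) {
  as.vector(t(outer(groups, timepoints, paste, sep = ".")))
}

seed_names <- function() c("l_ahc", "l_phc", "r_ahc", "r_phc")

#' Define a planted latent covariance pattern
#'
#' A pattern couples the four hippocampal seed regions to a set of support
#' voxels through a per-subject latent score: within each design cell, each
#' scan draws z ~ N(0, latent_sd^2) and receives
#' z * loading(seed, cell) * gain(cell) at every voxel of each seed ROI and
#' z * weight(voxel) * gain(cell) at every support voxel. Support voxels
#' must be disjoint from the seed ROIs so that the planted seed-voxel
#' covariance is genuine rather than tautological.
#'
#' @param seed_loadings either a length-4 numeric (one loading per seed, in
#'   [seed_names()] order, recycled across cells) or a 4 x 6 matrix of
#'   per-cell loadings (rows = seeds, columns = [cell_labels()]).
#' @param support_voxels integer matrix (n x 3) of 1-based voxel indices.
#' @param support_weights signed numeric weights, one per support voxel
#'   (scalar recycled).
#' @param cell_gains numeric multiplier per cell: scalar, length-6 vector in
#'   [cell_labels()] order, or 2 x 3 matrix (groups x timepoints).
#' @param latent_sd positive scale of the per-scan latent score.
#' @return An object of class `planted_pattern`.
#' @export
planted_pattern <- function(seed_loadings = rep(1, 4), support_voxels,
                            support_weights = 1, cell_gains = 1,
                            latent_sd = 1) {
  cells <- cell_labels()
  if (is.matrix(seed_loadings)) {
    stopifnot(nrow(seed_loadings) == 4L, ncol(seed_loadings) == 6L)
    L <- seed_loadings
  } else {
    stopifnot(length(seed_loadings) == 4L)
    L <- matrix(seed_loadings, 4, 6)
  }
  dimnames(L) <- list(seed_names(), cells)
  support_voxels <- rbind(support_voxels)
  storage.mode(support_voxels) <- "integer"
  stopifnot(ncol(support_voxels) == 3L, nrow(support_voxels) >= 1L)
  w <- rep_len(as.numeric(support_weights), nrow(support_voxels))
  if (is.matrix(cell_gains)) cell_gains <- as.vector(t(cell_gains))
  g <- rep_len(as.numeric(cell_gains), 6L)
  names(g) <- cells
  if (all(g == 0)) stop("at least one cell gain must be nonzero", call. = FALSE)
  if (!is.finite(latent_sd) || latent_sd <= 0)
    stop("`latent_sd` must be positive", call. = FALSE)
  structure(list(loadings = L, support_voxels = support_voxels,
                 support_weights = w, cell_gains = g, latent_sd = latent_sd),
            class = "planted_pattern")
}

# 1-based voxel index matrix -> linear indices into an array of shape `shp`
voxel_linear_index <- function(ijk, shp) {
  ijk <- rbind(ijk)
  as.integer(ijk[, 1] + (ijk[, 2] - 1) * shp[1] +
               (ijk[, 3] - 1) * shp[1] * shp[2])
}

#' Synthetic hippocampus mask
#'
#' Two rectangular hemispheric blocks spanning y in [-42, -2] mm
#' continuously, so the long-axis split retains anterior and posterior
#' bands and excludes the gap slices around y = -20.
#'
#' @param grid_shape integer length-3 voxel counts.
#' @param affine 4x4 voxel-to-mm affine.
#' @return Binary `volume_grid` mask.
#' @export
synthetic_hippocampus_mask <- function(grid_shape, affine) {
  vol <- volume_grid(array(0, dim = grid_shape), affine)
  mm <- grid_mm_coords(vol)
  x <- mm[, 1]; y <- mm[, 2]; z <- mm[, 3]
  inside <- (abs(x) >= 11 & abs(x) <= 21) & (y >= -42 & y <= -2) &
    (z >= -15 & z <= -3)
  vol$data[] <- as.double(inside)
  vol
}

#' Noise level for a target seed-voxel correlation
#'
#' For a support voxel carrying latent amplitude a = weight * gain *
#' latent_sd and i.i.d. Gaussian noise of standard deviation s, the
#' population seed-voxel correlation (with a noiseless seed) is
#' a / sqrt(a^2 + s^2); inverting gives s = a * sqrt(1/rho^2 - 1).
#'
#' @param rho target per-voxel correlation in (0, 1).
#' @param amplitude latent amplitude at the voxel.
#' @return Noise standard deviation.
#' @export
noise_sd_for_correlation <- function(rho, amplitude = 1) {
  stopifnot(rho > 0, rho < 1)
  amplitude * sqrt(1 / rho^2 - 1)
}

#' Configuration of a synthetic longitudinal VBM dataset
#'
#' Defines the study conditions emulated by [generate_dataset()]: two
#' groups of `n_per_group` subjects scanned at three time points on a
#' common grid, four hippocampal seed ROIs, planted latent seed-voxel
#' covariance patterns that may differ by design cell, per-subject TIV
#' variation, and i.i.d. Gaussian voxel noise.
#'
#' Defaults follow the emulated study: 30 subjects per group, a 24 x 28 x
#' 24 grid of 2 mm voxels spanning both hemispheres and the hippocampal
#' y-range, TIV ~ N(1.55e6, 1.25e5^2) mm^3, and a noise level giving a
#' per-voxel seed-voxel correlation of about 0.5 for the default unit
#' pattern.
#'
#' @param n_per_group subjects per group (>= 3).
#' @param grid_shape,voxel_size_mm,origin_mm grid geometry; the affine is
#'   diag(voxel_size) with translation `origin_mm`.
#' @param seed_rois named list of four disjoint voxel-index matrices
#'   (l_ahc, l_phc, r_ahc, r_phc); by default derived by splitting
#'   [synthetic_hippocampus_mask()] with [long_axis_spec()].
#' @param patterns list of [planted_pattern()]s; default one pattern with
#'   unit loadings supported on a supra-hippocampal block.
#' @param tiv_mean,tiv_sd TIV distribution in mm^3.
#' @param noise_sd i.i.d. Gaussian voxel noise SD (>= 0).
#' @param baseline constant background gray-matter level plus a fixed smooth
#'   spatial modulation.
#' @param rng_seed integer; identical seeds reproduce the dataset
#'   bit-for-bit.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_per_group = 30, grid_shape = c(24, 28, 24),
                             voxel_size_mm = c(2, 2, 2),
                             origin_mm = c(-23, -49, -23),
                             seed_rois = NULL, patterns = NULL,
                             tiv_mean = 1.55e6, tiv_sd = 1.25e5,
                             noise_sd = noise_sd_for_correlation(0.5),
                             baseline = 0.45, rng_seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3L, all(grid_shape > 0))
  affine <- diag(c(voxel_size_mm, 1))
  affine[1:3, 4] <- origin_mm
  if (n_per_group < 3) stop("`n_per_group` must be >= 3", call. = FALSE)
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  if (tiv_sd < 0 || tiv_mean <= 0)
    stop("`tiv_mean` must be > 0 and `tiv_sd` >= 0", call. = FALSE)
  mask <- synthetic_hippocampus_mask(grid_shape, affine)
  if (is.null(seed_rois)) {
    sub <- split_hippocampus(mask, long_axis_spec())
    seed_rois <- lapply(sub, function(m) which(m$data != 0, arr.ind = TRUE))
  }
  stopifnot(identical(sort(names(seed_rois)), sort(seed_names())))
  seed_rois <- seed_rois[seed_names()]
  if (is.null(patterns)) {
    vol <- volume_grid(array(0, grid_shape), affine)
    mm <- grid_mm_coords(vol)
    blk <- which(abs(mm[, 1]) <= 11 & mm[, 2] >= -31 & mm[, 2] <= -13 &
                   mm[, 3] >= 5 & mm[, 3] <= 13)
    patterns <- list(planted_pattern(
      support_voxels = arrayInd(blk, grid_shape)))
  }
  cfg <- structure(list(n_per_group = as.integer(n_per_group),
                        grid_shape = grid_shape, affine = affine,
                        seed_rois = seed_rois, patterns = patterns,
                        mask = mask, tiv_mean = tiv_mean, tiv_sd = tiv_sd,
                        noise_sd = noise_sd, baseline = baseline,
                        rng_seed = as.integer(rng_seed)),
                   class = "synthetic_config")
  validate_synthetic_config(cfg)
  cfg
}

validate_synthetic_config <- function(cfg) {
  shp <- cfg$grid_shape
  lin <- lapply(cfg$seed_rois, function(ijk) {
    ijk <- rbind(ijk)
    if (nrow(ijk) == 0) stop("empty seed ROI", call. = FALSE)
    if (any(ijk < 1) || any(t(ijk) > shp))
      stop("seed ROI voxel index outside the grid", call. = FALSE)
    voxel_linear_index(ijk, shp)
  })
  all_roi <- unlist(lin)
  if (anyDuplicated(all_roi)) {
    dup <- unique(all_roi[duplicated(all_roi)])
    idx <- arrayInd(dup[seq_len(min(5, length(dup)))], shp)
    stop("seed ROIs overlap at voxel(s): ",
         paste(apply(idx, 1, paste, collapse = ","), collapse = "; "),
         call. = FALSE)
  }
  for (p in cfg$patterns) {
    sv <- voxel_linear_index(p$support_voxels, shp)
    if (any(p$support_voxels < 1) || any(t(p$support_voxels) > shp))
      stop("pattern support voxel outside the grid", call. = FALSE)
    hit <- intersect(sv, all_roi)
    if (length(hit)) {
      idx <- arrayInd(hit[seq_len(min(5, length(hit)))], shp)
      stop("pattern support overlaps a seed ROI at voxel(s): ",
           paste(apply(idx, 1, paste, collapse = ","), collapse = "; "),
           call. = FALSE)
    }
  }
  invisible(cfg)
}

#' Zero one seed's loading in one design cell
#'
#' Returns a modified configuration in which the named seed no longer
#' participates in the named pattern within one group-by-timepoint cell,
#' leaving every other cell untouched. This reproduces, with known ground
#' truth, a seed whose coupling to a covariance pattern is absent at one
#' time point only.
#'
#' @param config a [synthetic_config()].
#' @param pattern index of the pattern to modify.
#' @param seed seed name (`l_ahc`, `l_phc`, `r_ahc`, `r_phc`) or index.
#' @param cell cell label such as `"training.TP2"` (see [cell_labels()]),
#'   or a length-2 character vector (group, timepoint).
#' @return A new `synthetic_config`.
#' @export
decouple_cell <- function(config, pattern = 1L, seed, cell) {
  stopifnot(inherits(config, "synthetic_config"))
  if (pattern < 1 || pattern > length(config$patterns))
    stop("invalid pattern index", call. = FALSE)
  if (length(cell) == 2) cell <- paste(cell, collapse = ".")
  cells <- cell_labels()
  if (!cell %in% cells)
    stop("unknown cell '", cell, "'; valid cells: ",
         paste(cells, collapse = ", "), call. = FALSE)
  if (is.character(seed) && !seed %in% seed_names())
    stop("unknown seed '", seed, "'; valid seeds: ",
         paste(seed_names(), collapse = ", "), call. = FALSE)
  config$patterns[[pattern]]$loadings[seed, cell] <- 0
  config
}

#' Generate a synthetic longitudinal VBM dataset
#'
#' Draws per-subject TIV and demographic covariates once per subject, then
#' for every scan builds a TIV-proportional image (fixed smooth baseline +
#' planted latent patterns + i.i.d. Gaussian noise) and multiplies it by
#' the subject's TIV, so that [scale_by_tiv()] recovers the planted
#' structure exactly. With the same configuration and `rng_seed` the output
#' is bit-for-bit reproducible.
#'
#' @param config a [synthetic_config()].
#' @return List of class `synth_dataset` with elements `table` (a
#'   [study_table()]), `volumes` (named list of `volume_grid`s keyed by
#'   `subject_timepoint`), `mask` (the hippocampus mask) and `truth` (the
#'   list of planted patterns).
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  validate_synthetic_config(config)
  set.seed(config$rng_seed)
  shp <- config$grid_shape
  nvox <- prod(shp)
  groups <- c("control", "training")
  tps <- c("TP1", "TP2", "TP3")
  n <- config$n_per_group
  subj <- c(sprintf("ctl%03d", seq_len(n)), sprintf("trn%03d", seq_len(n)))
  grp <- rep(groups, each = n)
  tiv <- pmax(config$tiv_mean + config$tiv_sd * stats::rnorm(2 * n),
              config$tiv_mean / 3)
  age <- round(23.2 + 1.4 * stats::rnorm(2 * n), 1)
  gender <- sample(c("M", "F"), 2 * n, replace = TRUE)
  education <- round(16.6 + 1.2 * stats::rnorm(2 * n), 1)

  base_vol <- volume_grid(array(config$baseline, shp), config$affine)
  mm <- grid_mm_coords(base_vol)
  baseline_field <- config$baseline +
    0.1 * exp(-((mm[, 1])^2 + (mm[, 2] + 20)^2 + (mm[, 3])^2) / 2000)

  roi_lin <- lapply(config$seed_rois, voxel_linear_index, shp = shp)
  pat_info <- lapply(config$patterns, function(p)
    list(p = p, sup = voxel_linear_index(p$support_voxels, shp)))

  rows <- list(); volumes <- list()
  for (s in seq_along(subj)) {
    for (tp in tps) {
      cell <- paste(grp[s], tp, sep = ".")
      img <- baseline_field
      for (pi in pat_info) {
        z <- stats::rnorm(1, sd = pi$p$latent_sd)
        gain <- pi$p$cell_gains[[cell]]
        if (gain != 0) {
          for (k in seq_along(roi_lin)) {
            l <- pi$p$loadings[k, cell]
            if (l != 0) img[roi_lin[[k]]] <- img[roi_lin[[k]]] + z * l * gain
          }
          img[pi$sup] <- img[pi$sup] + z * pi$p$support_weights * gain
        }
      }
      if (config$noise_sd > 0)
        img <- img + stats::rnorm(nvox, sd = config$noise_sd)
      id <- scan_id(subj[s], tp)
      volumes[[id]] <- volume_grid(array(img * tiv[s], shp), config$affine)
      rows[[id]] <- data.frame(subject_id = subj[s], group = grp[s],
                               timepoint = tp, tiv_mm3 = tiv[s],
                               age = age[s], gender = gender[s],
                               education = education[s],
                               stringsAsFactors = FALSE)
    }
  }
  table <- study_table(do.call(rbind, rows))
  rownames(table) <- NULL
  structure(list(table = table, volumes = volumes, mask = config$mask,
                 truth = config$patterns, config = config),
            class = "synth_dataset")
}

#' Write a synthetic dataset to disk
#'
#' Writes one NIfTI per scan, the hippocampus mask, a TSV study table with
#' a `path` column, and a JSON ground-truth sidecar describing the planted
#' patterns.
#'
#' @param ds a `synth_dataset` from [generate_dataset()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "synth_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tab <- ds$table
  ids <- scan_id(tab$subject_id, tab$timepoint)
  tab$path <- file.path(dir, paste0(ids, ".nii.gz"))
  for (i in seq_along(ids)) write_volume(ds$volumes[[ids[i]]], tab$path[i])
  write_volume(ds$mask, file.path(dir, "hippocampus_mask.nii.gz"))
  write_study_table(tab, file.path(dir, "subjects.tsv"))
  truth <- lapply(ds$truth, function(p) list(
    loadings = as.data.frame(p$loadings),
    support_voxels = unname(apply(p$support_voxels, 1, paste, collapse = ",")),
    support_weights = p$support_weights,
    cell_gains = as.list(p$cell_gains), latent_sd = p$latent_sd))
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
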