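#' Anterior/posterior long-axis specification
#'
#' The hippocampus is split along the MNI y-axis: anterior (head) spans
#' y in [-18, -2] mm and posterior (body + tail) spans y in [-42, -24] mm,
#' both intervals closed. The gap between them (a 2 mm coronal slice
#' trimmed from each adjacent end, leaving >= 4 mm) guards against
#' cross-contamination from misregistration and partial-volume effects at
#' the uncal apex.
#'
#' @param anterior_y_range,posterior_y_range closed mm intervals
#'   (length-2 numeric, any order).
#' @return An object of class `long_axis_spec`.
#' @export
long_axis_spec <- function(anterior_y_range = c(-18, -2),
                           posterior_y_range = c(-42, -24)) {
  a <- sort(as.numeric(anterior_y_range))
  p <- sort(as.numeric(posterior_y_range))
  gap <- max(a[1], p[1]) - min(a[2], p[2])
  if (!(p[2] < a[1] || a[2] < p[1]) || abs(gap) < 4)
    stop("anterior and posterior y ranges must be disjoint with a gap of at least 4 mm",
         call. = FALSE)
  structure(list(anterior_y_range = a, posterior_y_range = p),
            class = "long_axis_spec")
}

#' Scale a volume by total intracranial volume
#'
#' Divides every voxel by the subject's TIV so that values represent
#' proportional regional gray-matter volume, removing head-size effects.
#'
#' @param vol a [volume_grid()].
#' @param tiv total intracranial volume in mm^3 (> 0).
#' @return A `volume_grid` with every voxel divided by `tiv`; affine
#'   unchanged.
#' @export
scale_by_tiv <- function(vol, tiv) {
  stopifnot(inherits(vol, "volume_grid"))
  if (!is.finite(tiv) || tiv <= 0)
    stop("`tiv` must be a positive finite number", call. = FALSE)
  volume_grid(vol$data / tiv, vol$affine)
}

#' Split a hippocampus mask into left/right anterior/posterior subregions
#'
#' A mask voxel with mm coordinate (x, y, z) is anterior iff y lies in the
#' anterior range, posterior iff y lies in the posterior range, and excluded
#' otherwise (the uncal-apex gap). Hemisphere is the sign of x; voxels at
#' x = 0 exactly are excluded from both.
#'
#' @param mask binary `volume_grid` (values in {0, 1}).
#' @param spec a [long_axis_spec()].
#' @return Named list of four binary `volume_grid` masks:
#'   `l_ahc`, `l_phc`, `r_ahc`, `r_phc` (pairwise disjoint subsets of
#'   `mask`).
#' @export
split_hippocampus <- function(mask, spec = long_axis_spec()) {
  stopifnot(inherits(mask, "volume_grid"), inherits(spec, "long_axis_spec"))
  if (!all(mask$data %in% c(0, 1)))
    stop("`mask` must be binary (0/1)", call. = FALSE)
  mm <- grid_mm_coords(mask)
  x <- mm[, 1]; y <- mm[, 2]
  inmask <- as.vector(mask$data) != 0
  ant <- y >= spec$anterior_y_range[1] & y <= spec$anterior_y_range[2]
  post <- y >= spec$posterior_y_range[1] & y <= spec$posterior_y_range[2]
  sel <- list(l_ahc = inmask & ant & x < 0,
              l_phc = inmask & post & x < 0,
              r_ahc = inmask & ant & x > 0,
              r_phc = inmask & post & x > 0)
  out <- lapply(names(sel), function(nm) {
    v <- sel[[nm]]
    if (!any(v))
      stop(sprintf("subregion '%s' is empty: seed undefined", nm),
           call. = FALSE)
    volume_grid(array(as.double(v), dim = dim(mask$data)), mask$affine)
  })
  names(out) <- names(sel)
  out
}

#' Mean voxel value within an ROI
#'
#' The in-mask voxel values are summed and divided by the number of mask
#' voxels.
#'
#' @param vol a `volume_grid` (typically TIV-scaled).
#' @param mask binary `volume_grid` on the same grid.
#' @return Arithmetic mean of the in-mask voxel values.
#' @export
roi_mean <- function(vol, mask) {
  stopifnot(inherits(vol, "volume_grid"), inherits(mask, "volume_grid"))
  if (!same_grid(vol, mask))
    stop("volume and mask are not on the same grid", call. = FALSE)
  sel <- mask$data != 0
  if (!any(sel)) stop("empty ROI mask", call. = FALSE)
  mean(vol$data[sel])
}

#' Seed-region values for every scan
#'
#' TIV-scales each scan and extracts the mean voxel value of each
#' hippocampal subregion; these four per-scan values are the PLS seeds.
#'
#' @param volumes named list of `volume_grid`s keyed by `subject_id_timepoint`.
#' @param table validated [study_table()].
#' @param submasks named list of four subregion masks from
#'   [split_hippocampus()].
#' @return Data frame with columns subject_id, group, timepoint, and one
#'   column per subregion (l_ahc, l_phc, r_ahc, r_phc), one row per scan in
#'   table order.
#' @export
extract_seed_values <- function(volumes, table, submasks) {
  ids <- scan_id(table$subject_id, table$timepoint)
  miss <- setdiff(ids, names(volumes))
  if (length(miss))
    stop("missing volume(s) for scan(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  vals <- t(vapply(seq_along(ids), function(i) {
    v <- scale_by_tiv(volumes[[ids[i]]], table$tiv_mm3[i])
    vapply(submasks, function(m) roi_mean(v, m), numeric(1))
  }, numeric(length(submasks))))
  colnames(vals) <- names(submasks)
  cbind(table[, c("subject_id", "group", "timepoint")], as.data.frame(vals))
}
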