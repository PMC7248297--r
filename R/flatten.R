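#' Flatten scans to a (scans x in-mask voxels) matrix
#'
#' Vectorises every scan over the analysis mask into one matrix, keeping
#' voxel bookkeeping (array indices and mm coordinates per column) and the
#' design labels per row. Rows are ordered by (group, timepoint,
#' subject_id) — both groups, each with its three conditions, entered in
#' one block — which is the canonical scan order of the PLS analysis.
#'
#' @param volumes named list of `volume_grid`s keyed by
#'   `subject_id_timepoint`.
#' @param mask binary `volume_grid` defining the analysis voxels.
#' @param table validated [study_table()].
#' @param scale_tiv divide each scan by its subject's TIV (default `TRUE`,
#'   the convention for all downstream analysis).
#' @return An object of class `masked_dataset`: list with `values`
#'   (n_scans x n_voxels matrix), `voxel_index` (n_voxels x 3, 1-based),
#'   `mm_coord` (n_voxels x 3), `labels` (data frame subject_id, group,
#'   timepoint) and `mask`.
#' @export
flatten <- function(volumes, mask, table, scale_tiv = TRUE) {
  stopifnot(inherits(mask, "volume_grid"))
  table <- table[order(table$group, table$timepoint, table$subject_id), ,
                 drop = FALSE]
  ids <- scan_id(table$subject_id, table$timepoint)
  miss <- setdiff(ids, names(volumes))
  if (length(miss))
    stop("missing volume(s) for scan(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  sel <- which(mask$data != 0)
  if (!length(sel)) stop("analysis mask is empty", call. = FALSE)
  vals <- matrix(NA_real_, nrow = length(ids), ncol = length(sel))
  for (i in seq_along(ids)) {
    v <- volumes[[ids[i]]]
    if (!same_grid(v, mask))
      stop(sprintf("scan '%s' does not share grid shape/affine with the mask",
                   ids[i]), call. = FALSE)
    x <- as.vector(v$data)[sel]
    if (scale_tiv) x <- x / table$tiv_mm3[i]
    vals[i, ] <- x
  }
  rownames(vals) <- ids
  ijk <- arrayInd(sel, dim(mask$data))
  structure(list(values = vals, voxel_index = ijk,
                 mm_coord = voxel_to_mm(mask$affine, ijk),
                 labels = data.frame(subject_id = table$subject_id,
                                     group = table$group,
                                     timepoint = table$timepoint,
                                     stringsAsFactors = FALSE),
                 mask = mask),
            class = "masked_dataset")
}

#' @export
print.masked_dataset <- function(x, ...) {
  cat(sprintf("<masked_dataset> %d scans x %d voxels (%d subjects, %d cells)\n",
              nrow(x$values), ncol(x$values),
              length(unique(x$labels$subject_id)),
              length(unique(paste(x$labels$group, x$labels$timepoint)))))
  invisible(x)
}

#' Restore a flattened per-voxel statistic to a 3D map
#'
#' @param dataset a [flatten()] result.
#' @param values one number per in-mask voxel.
#' @param fill value outside the mask.
#' @return A `volume_grid` on the mask's grid.
#' @export
unflatten <- function(dataset, values, fill = 0) {
  stopifnot(inherits(dataset, "masked_dataset"),
            length(values) == nrow(dataset$voxel_index))
  arr <- array(fill, dim = dim(dataset$mask$data))
  arr[dataset$voxel_index] <- values
  volume_grid(arr, dataset$mask$affine)
}
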