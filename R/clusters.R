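# Neighbor offsets for 6-, 18- and 26-connectivity in 3D.
connectivity_offsets <- function(connectivity) {
  g <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  d <- rowSums(abs(g))
  keep <- switch(as.character(connectivity),
                 "6" = d == 1, "18" = d >= 1 & d <= 2, "26" = d >= 1,
                 stop("connectivity must be 6, 18 or 26", call. = FALSE))
  g[keep, , drop = FALSE]
}

# Label connected components of a logical 3D array by breadth-first search.
# Returns an integer array (0 = background). Hand-rolled: no installed
# package labels 3D components at selectable connectivity.
label_components <- function(sel, connectivity = 26) {
  shp <- dim(sel)
  off <- connectivity_offsets(connectivity)
  lab <- array(0L, dim = shp)
  idx <- which(sel)
  cur <- 0L
  for (start in idx) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue)) {
      v <- queue[length(queue)]
      queue <- queue[-length(queue)]
      ai <- arrayInd(v, shp)
      nb <- sweep(off, 2, as.integer(ai), "+")
      ok <- nb[, 1] >= 1 & nb[, 1] <= shp[1] & nb[, 2] >= 1 &
        nb[, 2] <= shp[2] & nb[, 3] >= 1 & nb[, 3] <= shp[3]
      nb <- nb[ok, , drop = FALSE]
      lin <- nb[, 1] + (nb[, 2] - 1L) * shp[1] + (nb[, 3] - 1L) * shp[1] * shp[2]
      lin <- lin[sel[lin] & lab[lin] == 0L]
      if (length(lin)) {
        lab[lin] <- cur
        queue <- c(queue, lin)
      }
    }
  }
  lab
}

#' Extract suprathreshold clusters from a BSR map
#'
#' Positive clusters are connected components of {BSR > threshold} and
#' negative clusters of {BSR < -threshold}, at the chosen voxel
#' connectivity. Each cluster is reported with its sign, voxel count, peak
#' (maximum |BSR|) millimeter coordinate and peak BSR, the columns of a
#' standard PLS cluster table. Peaks tie-break by lexicographic voxel
#' index; records are sorted by peak y descending (most anterior first).
#'
#' @param bsr_map a `volume_grid` of BSR values (e.g. from [bsr_map()]).
#' @param mask optional binary `volume_grid` restricting the search.
#' @param threshold positive reliability threshold on |BSR| (default 3.8).
#' @param connectivity 6, 18 or 26 (default 26, the SPM convention).
#' @param min_size minimum cluster extent in voxels (default 50).
#' @param lookup optional function mapping a length-3 mm coordinate to an
#'   anatomical label string.
#' @return Data frame with columns label, sign, n_voxels, x_mm, y_mm,
#'   z_mm, peak_bsr; zero rows when nothing survives.
#' @export
extract_clusters <- function(bsr_map, mask = NULL, threshold = 3.8,
                             connectivity = 26, min_size = 50,
                             lookup = NULL) {
  stopifnot(inherits(bsr_map, "volume_grid"), threshold > 0)
  vals <- bsr_map$data
  keep <- array(TRUE, dim = dim(vals))
  if (!is.null(mask)) {
    if (!same_grid(bsr_map, mask))
      stop("mask and BSR map are not on the same grid", call. = FALSE)
    keep <- mask$data != 0
  }
  recs <- list()
  for (sgn in c("positive", "negative")) {
    sel <- if (sgn == "positive") vals > threshold else vals < -threshold
    sel <- sel & keep
    sel[is.na(sel)] <- FALSE
    if (!any(sel)) next
    lab <- label_components(sel, connectivity)
    for (cl in seq_len(max(lab))) {
      vox <- which(lab == cl)
      if (length(vox) < min_size) next
      a <- abs(vals[vox])
      peak <- vox[which(a == max(a))]
      peak <- sort(peak)[1]             # lexicographic tie-break
      mmc <- voxel_to_mm(bsr_map$affine, arrayInd(peak, dim(vals)))
      recs[[length(recs) + 1L]] <- data.frame(
        label = if (is.null(lookup)) NA_character_
                else as.character(lookup(drop(mmc))),
        sign = sgn, n_voxels = length(vox),
        x_mm = mmc[1], y_mm = mmc[2], z_mm = mmc[3],
        peak_bsr = vals[peak], stringsAsFactors = FALSE)
    }
  }
  if (!length(recs))
    return(data.frame(label = character(), sign = character(),
                      n_voxels = integer(), x_mm = numeric(),
                      y_mm = numeric(), z_mm = numeric(),
                      peak_bsr = numeric(), stringsAsFactors = FALSE))
  out <- do.call(rbind, recs)
  out <- out[order(-out$y_mm, out$x_mm, out$z_mm), , drop = FALSE]
  rownames(out) <- NULL
  out
}
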