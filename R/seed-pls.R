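#' Fit a seed partial least squares model of structural covariance
#'
#' The full seed-PLS analysis in one call: stacks the cell-wise seed-voxel
#' Pearson correlations across the six group x timepoint design cells,
#' decomposes the stack by SVD into latent variables (LVs), computes every
#' scan's brain scores, assesses LV significance by permutation of the
#' seed-to-image assignment, and assesses voxel reliability by a
#' stratified subject bootstrap with Procrustes alignment, yielding
#' bootstrap salience ratio (BSR) maps and 95% bootstrap confidence
#' intervals for the per-cell seed-to-brain-score correlations.
#'
#' @param dataset a [flatten()] result: TIV-scaled scans over the analysis
#'   mask with design labels.
#' @param seeds seed-region values from [extract_seed_values()] (or a
#'   matrix aligned to the dataset's rows).
#' @param n_perm permutations for LV significance (default 2000; 0 skips
#'   the test and reports p-values as absent).
#' @param n_boot bootstrap draws for BSR and CIs (default 1000; values < 2
#'   skip the bootstrap).
#' @param n_lv number of LVs to bootstrap and report maps for (default:
#'   all).
#' @param bsr_threshold reliability threshold on |BSR| (default 3.8,
#'   corresponding to a two-tailed normal tail probability of about
#'   0.0001).
#' @param seed integer RNG seed covering both resampling stages.
#' @return An object of class `seed_pls`. Key components:
#'   `singular_values`, `covariance_fraction`, `design_weights` (design
#'   rows x K), `saliences` (voxels x K unit-norm), `brain_scores` (data
#'   frame with labels and one column per LV), `perm_p` (or `NULL` when
#'   `n_perm = 0`), `bsr` / `bsr_se` / `bsr_flags`, `seed_corr` (per cell,
#'   seed and LV with bootstrap CI), `stack` (the [correlation_stack()]).
#' @seealso [summary.seed_pls()], [bsr_map()], [extract_clusters()]
#' @examples
#' cfg <- synthetic_config(n_per_group = 5, grid_shape = c(12, 14, 12),
#'                         voxel_size_mm = c(4, 4, 4),
#'                         origin_mm = c(-22, -49, -17), rng_seed = 7)
#' ds <- generate_dataset(cfg)
#' sub <- split_hippocampus(ds$mask)
#' seeds <- extract_seed_values(ds$volumes, ds$table, sub)
#' flat <- flatten(ds$volumes, ds$mask, ds$table)
#' fit <- seed_pls(flat, seeds, n_perm = 20, n_boot = 10, seed = 1)
#' fit
#' @export
seed_pls <- function(dataset, seeds, n_perm = 2000, n_boot = 1000,
                     n_lv = NULL, bsr_threshold = 3.8, seed = NULL) {
  stopifnot(inherits(dataset, "masked_dataset"))
  if (!is.null(seed)) set.seed(seed)
  stack <- correlation_stack(dataset, seeds)
  dec <- pls_svd(stack)
  K <- if (is.null(n_lv)) length(dec$singular_values)
       else min(n_lv, length(dec$singular_values))
  scores <- brain_scores(dataset, dec$saliences[, seq_len(K), drop = FALSE])
  perm_p <- if (n_perm > 0)
    permutation_test(dataset, seeds, n_perm = n_perm) else NULL
  boot <- if (n_boot >= 2)
    pls_bootstrap(dataset, seeds, n_boot = n_boot, n_lv = K) else NULL
  out <- list(
    singular_values = dec$singular_values,
    covariance_fraction = dec$covariance_fraction,
    design_weights = dec$design_weights,
    saliences = dec$saliences,
    n_lv = K,
    brain_scores = cbind(dataset$labels, as.data.frame(scores)),
    perm_p = perm_p,
    bsr = boot$bsr, bsr_se = boot$bsr_se, bsr_flags = boot$bsr_flags,
    seed_corr = boot$seed_corr,
    stack = stack,
    mask = dataset$mask, voxel_index = dataset$voxel_index,
    mm_coord = dataset$mm_coord,
    n_perm = n_perm, n_boot = n_boot, bsr_threshold = bsr_threshold,
    call = match.call())
  class(out) <- "seed_pls"
  out
}

#' BSR map of one latent variable as a volume
#'
#' @param object a fitted [seed_pls()] model (with bootstrap).
#' @param lv which latent variable.
#' @return A `volume_grid` holding the voxel-wise bootstrap salience
#'   ratio; voxels outside the analysis mask are 0.
#' @export
bsr_map <- function(object, lv = 1) {
  stopifnot(inherits(object, "seed_pls"))
  if (is.null(object$bsr)) stop("model was fitted without a bootstrap",
                                call. = FALSE)
  vals <- object$bsr[, lv]
  arr <- array(0, dim = dim(object$mask$data))
  arr[object$voxel_index] <- vals
  volume_grid(arr, object$mask$affine)
}

#' @export
print.seed_pls <- function(x, ...) {
  cat("Seed PLS structural covariance model\n")
  cat(sprintf("  %d scans x %d voxels; %d design rows; %d LVs retained\n",
              nrow(x$brain_scores), nrow(x$saliences), nrow(x$design_weights),
              x$n_lv))
  k <- seq_len(min(x$n_lv, 5))
  tab <- data.frame(LV = k, singular_value = signif(x$singular_values[k], 5),
                    covariance_pct = round(100 * x$covariance_fraction[k], 2))
  if (!is.null(x$perm_p)) tab$perm_p <- signif(x$perm_p[k], 3)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Summarise a seed PLS fit
#'
#' Reports per-LV singular values, covariance fractions (percent of the
#' cross-correlation variance), permutation p-values, and — when a
#' bootstrap was run — the number of reliable voxels at the BSR threshold
#' and the per-cell seed correlations whose 95% CI excludes zero.
#'
#' @param object a `seed_pls` fit.
#' @param ... unused.
#' @return An object of class `summary.seed_pls`.
#' @export
summary.seed_pls <- function(object, ...) {
  k <- seq_len(object$n_lv)
  lv_tab <- data.frame(LV = k,
                       singular_value = object$singular_values[k],
                       covariance_pct = 100 * object$covariance_fraction[k])
  lv_tab$perm_p <- if (!is.null(object$perm_p)) object$perm_p[k] else NA_real_
  if (!is.null(object$bsr)) {
    thr <- object$bsr_threshold
    lv_tab$n_reliable_pos <- colSums(object$bsr > thr)
    lv_tab$n_reliable_neg <- colSums(object$bsr < -thr)
  }
  sig_corr <- if (!is.null(object$seed_corr)) {
    sc <- object$seed_corr
    sc[!is.na(sc$lower) & (sc$lower > 0 | sc$upper < 0), , drop = FALSE]
  }
  structure(list(lv = lv_tab, significant_seed_corr = sig_corr,
                 n_perm = object$n_perm, n_boot = object$n_boot,
                 bsr_threshold = object$bsr_threshold),
            class = "summary.seed_pls")
}

#' @export
print.summary.seed_pls <- function(x, ...) {
  cat(sprintf("Seed PLS summary (%d permutations, %d bootstrap draws, |BSR| threshold %.2f)\n\n",
              x$n_perm, x$n_boot, x$bsr_threshold))
  tab <- x$lv
  tab$singular_value <- signif(tab$singular_value, 5)
  tab$covariance_pct <- round(tab$covariance_pct, 2)
  tab$perm_p <- signif(tab$perm_p, 3)
  print(utils::head(tab, 10), row.names = FALSE)
  if (!is.null(x$significant_seed_corr) && nrow(x$significant_seed_corr)) {
    cat("\nSeed correlations with 95% bootstrap CI excluding 0 (first LVs):\n")
    sc <- x$significant_seed_corr
    sc <- sc[sc$lv <= 3, , drop = FALSE]
    sc$r <- round(sc$r, 3); sc$lower <- round(sc$lower, 3)
    sc$upper <- round(sc$upper, 3)
    print(sc, row.names = FALSE)
  }
  invisible(x)
}

#' @export
coef.seed_pls <- function(object, type = c("design", "salience"), ...) {
  type <- match.arg(type)
  if (type == "design") object$design_weights
  else object$saliences
}

#' Brain scores for new scans
#'
#' Projects new (TIV-scaled, same-mask) scans onto the fitted voxel
#' saliences.
#'
#' @param object a `seed_pls` fit.
#' @param newdata a [flatten()] result on the same mask; default: refitted
#'   scores of the training data.
#' @param ... unused.
#' @return Data frame of labels plus one score column per retained LV.
#' @export
predict.seed_pls <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$brain_scores)
  stopifnot(inherits(newdata, "masked_dataset"))
  sc <- brain_scores(newdata, object$saliences[, seq_len(object$n_lv),
                                               drop = FALSE])
  cbind(newdata$labels, as.data.frame(sc))
}

#' Plot a seed PLS fit
#'
#' Three displays: `"scree"` — covariance fraction per LV with permutation
#' p-values; `"seed_corr"` — per-cell seed-to-brain-score correlations with
#' 95% bootstrap CIs for one LV (the bar chart idiom of seed-PLS papers);
#' `"scores"` — group mean brain-score trajectories over time points.
#'
#' @param x a `seed_pls` fit.
#' @param type which display.
#' @param lv latent variable for `"seed_corr"` and `"scores"`.
#' @param ... passed to the underlying base-graphics calls.
#' @return `x`, invisibly.
#' @export
plot.seed_pls <- function(x, type = c("scree", "seed_corr", "scores"),
                          lv = 1, ...) {
  type <- match.arg(type)
  if (type == "scree") {
    k <- seq_len(x$n_lv)
    bp <- graphics::barplot(100 * x$covariance_fraction[k],
                            names.arg = paste0("LV", k),
                            ylab = "% cross-correlation variance", ...)
    if (!is.null(x$perm_p))
      graphics::text(bp, 100 * x$covariance_fraction[k],
                     labels = sprintf("p=%.3g", x$perm_p[k]), pos = 3,
                     cex = 0.7, xpd = NA)
  } else if (type == "seed_corr") {
    if (is.null(x$seed_corr)) stop("no bootstrap results to plot", call. = FALSE)
    sc <- x$seed_corr[x$seed_corr$lv == lv, , drop = FALSE]
    bp <- graphics::barplot(sc$r, names.arg = paste(sc$cell, sc$seed),
                            las = 2, cex.names = 0.6,
                            ylim = range(c(sc$lower, sc$upper, 0), na.rm = TRUE),
                            ylab = sprintf("seed correlation (LV%d)", lv), ...)
    graphics::arrows(bp, sc$lower, bp, sc$upper, angle = 90, code = 3,
                     length = 0.02)
    graphics::abline(h = 0, lty = 2)
  } else {
    bs <- x$brain_scores
    col_lv <- paste0("LV", lv)
    agg <- stats::aggregate(bs[[col_lv]],
                            by = list(group = bs$group, timepoint = bs$timepoint),
                            FUN = mean)
    tps <- sort(unique(agg$timepoint))
    graphics::matplot(
      seq_along(tps),
      sapply(split(agg, agg$group), function(d) d$x[order(d$timepoint)]),
      type = "b", pch = 16, lty = 1, xaxt = "n", xlab = "time point",
      ylab = sprintf("mean brain score (LV%d)", lv), ...)
    graphics::axis(1, at = seq_along(tps), labels = as.character(tps))
    graphics::legend("topleft", legend = unique(as.character(agg$group)),
                     col = seq_along(unique(agg$group)), lty = 1, pch = 16,
                     bty = "n")
  }
  invisible(x)
}
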