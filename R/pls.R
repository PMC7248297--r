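# ---- internal helpers -------------------------------------------------------

# Center columns and scale to unit Euclidean norm, so that crossprod() of two
# such matrices is the Pearson correlation. Zero-variance columns become zero.
unitize_cols <- function(M) {
  M <- sweep(M, 2, colMeans(M), "-")
  nrm <- sqrt(colSums(M^2))
  bad <- nrm < .Machine$double.eps * nrow(M) * 10
  nrm[bad] <- 1
  M <- sweep(M, 2, nrm, "/")
  M[, bad] <- 0
  attr(M, "zero_variance") <- bad
  M
}

# Row indices per design cell, in canonical cell order.
cell_indices <- function(labels) {
  cell <- factor(paste(labels$group, labels$timepoint, sep = "."),
                 levels = cell_labels(levels(factor(labels$group)),
                                      levels(factor(labels$timepoint))))
  split(seq_along(cell), cell)
}

# Stack of cell-wise seed-voxel correlations from raw matrices.
# S: scans x seeds, X: scans x voxels, idx: list of row indices per cell.
stack_correlations <- function(S, X, idx, warn = FALSE) {
  blocks <- lapply(idx, function(i) {
    Zs <- unitize_cols(S[i, , drop = FALSE])
    Zx <- unitize_cols(X[i, , drop = FALSE])
    if (warn && (any(attr(Zs, "zero_variance")) ||
                 any(attr(Zx, "zero_variance"))))
      warning("zero-variance seed or voxel within a cell; correlation set to 0",
              call. = FALSE)
    crossprod(Zs, Zx)
  })
  do.call(rbind, blocks)
}

# Align a seed-value table to the row order of a masked_dataset.
align_seeds <- function(dataset, seeds) {
  sn <- seed_names()
  if (is.matrix(seeds)) {
    stopifnot(nrow(seeds) == nrow(dataset$values))
    return(seeds)
  }
  stopifnot(all(sn %in% names(seeds)))
  key_d <- scan_id(dataset$labels$subject_id, dataset$labels$timepoint)
  key_s <- scan_id(seeds$subject_id, seeds$timepoint)
  m <- match(key_d, key_s)
  if (anyNA(m))
    stop("seed values missing for scan(s): ",
         paste(key_d[is.na(m)], collapse = ", "), call. = FALSE)
  as.matrix(seeds[m, sn, drop = FALSE])
}

# Singular values only, via the small Gram matrix (rows << voxels).
singular_values_fast <- function(R) {
  ev <- eigen(tcrossprod(R), symmetric = TRUE, only.values = TRUE)$values
  sqrt(pmax(ev, 0))
}

# ---- exported operations ----------------------------------------------------

#' Stacked cell-wise seed-voxel correlation matrix
#'
#' For every design cell (group x timepoint, in [cell_labels()] order) and
#' every seed region, computes the Pearson correlation across the cell's
#' subjects between the seed value and each in-mask voxel, and stacks the
#' results into one (n_cells * n_seeds) x n_voxels matrix — the matrix the
#' PLS decomposes. A seed or voxel with zero variance within a cell yields
#' correlation 0 with a warning.
#'
#' @param dataset a [flatten()] result (TIV-scaled values).
#' @param seeds seed-value data frame from [extract_seed_values()] (matched
#'   to scans by subject and timepoint), or a matrix aligned to dataset
#'   rows.
#' @return An object of class `correlation_stack`: list with `R` (the
#'   stacked matrix, entries in [-1, 1]) and `row_labels` (data frame with
#'   cell, group, timepoint, seed per row).
#' @export
correlation_stack <- function(dataset, seeds) {
  stopifnot(inherits(dataset, "masked_dataset"))
  S <- align_seeds(dataset, seeds)
  idx <- cell_indices(dataset$labels)
  small <- vapply(idx, length, integer(1)) < 3
  if (any(small))
    stop("cell(s) with fewer than 3 subjects: ",
         paste(names(idx)[small], collapse = ", "), call. = FALSE)
  R <- stack_correlations(S, dataset$values, idx, warn = TRUE)
  lab <- do.call(rbind, lapply(names(idx), function(cl) {
    gt <- strsplit(cl, ".", fixed = TRUE)[[1]]
    data.frame(cell = cl, group = gt[1], timepoint = gt[2],
               seed = seed_names(), stringsAsFactors = FALSE)
  }))
  rownames(R) <- paste(lab$cell, lab$seed, sep = ":")
  structure(list(R = R, row_labels = lab), class = "correlation_stack")
}

#' Singular value decomposition of a correlation stack
#'
#' Decomposes R = sum_k u_k s_k v_k' into latent variables: unit-norm voxel
#' saliences v_k, unit-norm design/seed weights u_k, and non-increasing
#' singular values s_k. The covariance fraction of LV k is
#' s_k^2 / sum_j s_j^2, its share of the stack's squared Frobenius norm.
#' Sign convention: each v_k is flipped so that its largest-magnitude entry
#' is positive, with u_k flipped jointly.
#'
#' @param x a [correlation_stack()] (or a bare matrix).
#' @return List with `singular_values`, `design_weights` (rows of R x K),
#'   `saliences` (voxels x K), `covariance_fraction`.
#' @export
pls_svd <- function(x) {
  R <- if (inherits(x, "correlation_stack")) x$R else as.matrix(x)
  if (!all(is.finite(R))) stop("correlation stack must be finite", call. = FALSE)
  if (all(R == 0)) stop("no covariance structure: stack is all zero", call. = FALSE)
  K <- min(dim(R))
  sv <- svd(R, nu = K, nv = K)
  u <- sv$u; v <- sv$v; d <- sv$d[seq_len(K)]
  for (k in seq_len(K)) {
    j <- which.max(abs(v[, k]))
    if (v[j, k] < 0) { v[, k] <- -v[, k]; u[, k] <- -u[, k] }
  }
  rownames(u) <- rownames(R)
  list(singular_values = d, design_weights = u, saliences = v,
       covariance_fraction = d^2 / sum(d^2))
}

#' Brain scores: projection of scans onto voxel saliences
#'
#' A scan's brain score for LV k is the dot product of its (TIV-scaled)
#' in-mask voxel values with the LV's voxel saliences, measuring how
#' strongly that scan expresses the covariance pattern.
#'
#' @param dataset a [flatten()] result.
#' @param saliences voxels x K salience matrix (or a single salience
#'   vector).
#' @return n_scans x K matrix of scores.
#' @export
brain_scores <- function(dataset, saliences) {
  stopifnot(inherits(dataset, "masked_dataset"))
  V <- cbind(saliences)
  if (nrow(V) != ncol(dataset$values))
    stop("salience length does not match the number of in-mask voxels",
         call. = FALSE)
  sc <- dataset$values %*% V
  rownames(sc) <- rownames(dataset$values)
  colnames(sc) <- paste0("LV", seq_len(ncol(V)))
  sc
}

#' Permutation test of the latent variables
#'
#' Under the null of no seed-voxel association, the assignment of
#' seed-value rows to image rows is permuted uniformly at random across all
#' scans (images keep their cell labels, so cell sizes are preserved), the
#' correlation stack and its singular values are recomputed, and each
#' observed singular value is compared rank-for-rank with its permuted
#' counterparts: p_k = (1 + #(s'_k >= s_k)) / (1 + n_perm).
#'
#' @param dataset a [flatten()] result.
#' @param seeds seed values (see [correlation_stack()]).
#' @param n_perm number of permutations (paper default 2000); 0 returns
#'   `NULL` (p-values absent, not zero).
#' @param seed optional RNG seed.
#' @return Numeric vector of p-values per LV, or `NULL` if `n_perm == 0`.
#' @export
permutation_test <- function(dataset, seeds, n_perm = 2000, seed = NULL) {
  if (n_perm == 0) return(NULL)
  stopifnot(n_perm >= 1)
  if (!is.null(seed)) set.seed(seed)
  S <- align_seeds(dataset, seeds)
  idx <- cell_indices(dataset$labels)
  obs <- singular_values_fast(stack_correlations(S, dataset$values, idx))
  K <- length(obs)
  # voxel blocks are fixed under this permutation scheme: precompute them
  Zx <- lapply(idx, function(i) unitize_cols(dataset$values[i, , drop = FALSE]))
  count <- numeric(K)
  n <- nrow(S)
  for (b in seq_len(n_perm)) {
    Sp <- S[sample.int(n), , drop = FALSE]
    Rp <- do.call(rbind, lapply(seq_along(idx), function(ci)
      crossprod(unitize_cols(Sp[idx[[ci]], , drop = FALSE]), Zx[[ci]])))
    sp <- singular_values_fast(Rp)
    count <- count + (sp[seq_len(K)] >= obs)
  }
  (1 + count) / (1 + n_perm)
}

#' Orthogonal Procrustes alignment of bootstrap saliences
#'
#' Returns the orthogonal matrix Q (rotations and reflections) minimizing
#' ||V_boot Q - V_ref||_F, computed from the SVD of V_boot' V_ref. This
#' resolves the sign and order indeterminacy of the SVD across resamples.
#' If the overlap matrix is rank-deficient the alignment falls back to
#' per-column sign matching (diagonal Q of +/-1), recorded in the
#' `"method"` attribute.
#'
#' @param V_boot,V_ref matrices with the same shape and (near-)orthonormal
#'   columns.
#' @return Orthogonal matrix Q with attribute `method` equal to
#'   `"procrustes"` or `"sign"`.
#' @export
procrustes_align <- function(V_boot, V_ref) {
  stopifnot(identical(dim(V_boot), dim(V_ref)))
  M <- crossprod(V_boot, V_ref)
  sv <- svd(M)
  if (min(sv$d) < 1e-8 * max(sv$d, 1e-300)) {
    s <- sign(diag(M)); s[s == 0] <- 1
    Q <- diag(s, nrow = ncol(V_boot))
    attr(Q, "method") <- "sign"
    return(Q)
  }
  Q <- sv$u %*% t(sv$v)
  attr(Q, "method") <- "procrustes"
  Q
}

#' Stratified subject bootstrap: BSR maps and seed-correlation CIs
#'
#' Subjects are resampled with replacement within each group (a subject's
#' scans move together across time points, preserving the longitudinal
#' dependence and the group x timepoint cell sizes). For each draw the
#' correlation stack and its SVD are recomputed and the bootstrap saliences
#' are aligned to the original by orthogonal Procrustes rotation. The
#' bootstrap salience ratio at a voxel is the original unscaled salience
#' (s_k v_k) divided by the standard deviation of the aligned bootstrap
#' saliences — a pseudo-z reliability index. Per (cell, seed, LV), the
#' correlation between resampled seed values and resampled brain scores is
#' recomputed per draw and summarised by percentile 2.5/97.5 bounds.
#'
#' @param dataset a [flatten()] result.
#' @param seeds seed values (see [correlation_stack()]).
#' @param n_boot number of bootstrap draws (paper default 1000; >= 2).
#' @param n_lv number of LVs to align and report (default: all).
#' @param seed optional RNG seed.
#' @return List with `bsr` (voxels x K), `bsr_se`, `bsr_flags` (TRUE where
#'   the bootstrap SE was numerically zero and the BSR is a signed infinite
#'   sentinel),
#'   `seed_corr` (data frame: cell, group, timepoint, seed, lv, r, lower,
#'   upper), and `n_boot`.
#' @export
pls_bootstrap <- function(dataset, seeds, n_boot = 1000, n_lv = NULL,
                          seed = NULL) {
  stopifnot(n_boot >= 2)
  if (!is.null(seed)) set.seed(seed)
  S <- align_seeds(dataset, seeds)
  X <- dataset$values
  idx <- cell_indices(dataset$labels)
  fit <- pls_svd(stack_correlations(S, X, idx))
  K <- if (is.null(n_lv)) length(fit$singular_values)
       else min(n_lv, length(fit$singular_values))
  Vref <- fit$saliences[, seq_len(K), drop = FALSE]
  sref <- fit$singular_values[seq_len(K)]

  lab <- dataset$labels
  groups <- levels(lab$group)
  # per group: ordered subject list and their scan rows per timepoint
  sub_rows <- lapply(groups, function(g) {
    subs <- unique(lab$subject_id[lab$group == g])
    lapply(subs, function(s) which(lab$subject_id == s))  # 3 rows, cell order
  })
  names(sub_rows) <- groups

  obs_scores <- X %*% Vref
  seed_corr_obs <- seed_corr_table(S, obs_scores, idx)

  acc <- array(NA_real_, dim = c(ncol(X), K, n_boot))
  corr_draws <- array(NA_real_, dim = c(nrow(seed_corr_obs), n_boot))
  for (b in seq_len(n_boot)) {
    rows <- integer(0)
    for (g in groups) {
      take <- sample.int(length(sub_rows[[g]]), replace = TRUE)
      rows <- c(rows, unlist(sub_rows[[g]][take]))
    }
    # reorder into canonical (group, timepoint) cell order
    lab_b <- lab[rows, , drop = FALSE]
    ord <- order(lab_b$group, lab_b$timepoint)
    rows <- rows[ord]
    idx_b <- cell_indices(lab[rows, , drop = FALSE])
    Sb <- S[rows, , drop = FALSE]
    Xb <- X[rows, , drop = FALSE]
    Rb <- stack_correlations(Sb, Xb, idx_b)
    svb <- svd(Rb, nu = K, nv = K)
    Vb <- svb$v
    Q <- procrustes_align(Vb, Vref)
    acc[, , b] <- Vb %*% (diag(svb$d[seq_len(K)], K) %*% Q)
    corr_draws[, b] <- seed_corr_table(Sb, Xb %*% (Vb %*% Q), idx_b)$r
  }
  se <- apply(acc, c(1, 2), stats::sd)
  num <- sweep(Vref, 2, sref, "*")
  # an SE below ~1e-10 of the per-LV salience scale is numerically zero
  # (degenerate bootstrap), not a licence for a huge BSR
  flags <- sweep(se, 2, 1e-10 * pmax(apply(abs(num), 2, max), 1e-300),
                 "<")
  bsr <- num / se
  bsr[flags] <- sign(num[flags]) * Inf
  if (any(flags))
    warning(sprintf("%d voxel x LV cells had zero bootstrap SE; BSR set to signed Inf sentinel",
                    sum(flags)), call. = FALSE)
  ci <- t(apply(corr_draws, 1, stats::quantile, probs = c(0.025, 0.975),
                na.rm = TRUE, names = FALSE))
  seed_corr <- cbind(seed_corr_obs, lower = ci[, 1], upper = ci[, 2])
  colnames(bsr) <- colnames(se) <- paste0("LV", seq_len(K))
  list(bsr = bsr, bsr_se = se, bsr_flags = flags, seed_corr = seed_corr,
       n_boot = n_boot)
}

# Observed per-(cell, seed, LV) correlation between seed values and scores.
seed_corr_table <- function(S, scores, idx) {
  K <- ncol(scores)
  out <- do.call(rbind, lapply(names(idx), function(cl) {
    i <- idx[[cl]]
    gt <- strsplit(cl, ".", fixed = TRUE)[[1]]
    do.call(rbind, lapply(seq_len(ncol(S)), function(s) {
      r <- vapply(seq_len(K), function(k) {
        ss <- S[i, s]; sc <- scores[i, k]
        if (stats::sd(ss) == 0 || stats::sd(sc) == 0) return(NA_real_)
        stats::cor(ss, sc)
      }, numeric(1))
      data.frame(cell = cl, group = gt[1], timepoint = gt[2],
                 seed = seed_names()[s], lv = seq_len(K), r = r,
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(out) <- NULL
  out
}
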