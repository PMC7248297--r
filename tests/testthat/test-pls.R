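test_that("correlation stack reproduces hand-computed Pearson correlations", {
  vals <- rbind(c(1, 1, 9), c(2, 2, 5), c(4, 3, 1))
  S <- cbind(l_ahc = c(1, 2, 3), l_phc = c(3, 1, 2),
             r_ahc = c(1, 1, 1), r_phc = c(1, 2, 3))
  dset <- manual_dataset(vals, group = rep("control", 3),
                         timepoint = rep("TP1", 3))
  expect_warning(cs <- correlation_stack(dset, S), "zero-variance")
  # seed (1,2,3) vs voxel (1,2,4): r = 3 / sqrt(2 * 14/3) = 0.9819805...
  expect_equal(unname(cs$R["control.TP1:l_ahc", 1]), 3 / sqrt(2 * 14 / 3),
               tolerance = 1e-12)
  expect_equal(unname(cs$R["control.TP1:l_ahc", 1]), 0.9819805,
               tolerance = 1e-6)
  # seed identical to a voxel column
  expect_equal(unname(cs$R["control.TP1:l_ahc", 2]), 1, tolerance = 1e-12)
  # constant seed row: correlation 0 by convention
  expect_true(all(cs$R["control.TP1:r_ahc", ] == 0))
  expect_true(all(cs$R >= -1 - 1e-12 & cs$R <= 1 + 1e-12))
})

test_that("cells with fewer than three subjects are rejected", {
  vals <- matrix(rnorm(10), 2, 5)
  dset <- manual_dataset(vals, group = rep("control", 2),
                         timepoint = rep("TP1", 2))
  expect_error(correlation_stack(dset, matrix(rnorm(8), 2, 4)),
               "fewer than 3")
})

test_that("SVD decomposition satisfies its algebraic identities", {
  # orthogonal rows of norms 4 and 3
  R <- rbind(c(4, 0, 0, 0), c(0, 3, 0, 0))
  dec <- pls_svd(R)
  expect_equal(dec$singular_values, c(4, 3))
  expect_equal(dec$covariance_fraction, c(0.64, 0.36))
  # rank-1 matrix
  r1 <- outer(c(1, 2), c(3, 1, 2))
  expect_equal(pls_svd(r1)$covariance_fraction[1], 1)
  # random stacks: Frobenius conservation, orthonormality, sign convention
  set.seed(21)
  for (rep in 1:5) {
    R <- matrix(rnorm(6 * 50), 6, 50)
    dec <- pls_svd(R)
    expect_equal(sum(dec$singular_values^2), sum(R^2), tolerance = 1e-10)
    expect_equal(sum(dec$covariance_fraction), 1, tolerance = 1e-12)
    expect_equal(crossprod(dec$saliences), diag(6), tolerance = 1e-10,
                 ignore_attr = TRUE)
    expect_equal(crossprod(dec$design_weights), diag(6), tolerance = 1e-10,
                 ignore_attr = TRUE)
    for (k in 1:6) {
      v <- dec$saliences[, k]
      expect_gt(v[which.max(abs(v))], 0)
    }
    # reconstruction
    rec <- dec$design_weights %*% diag(dec$singular_values) %*%
      t(dec$saliences)
    expect_equal(rec, R, tolerance = 1e-10, ignore_attr = TRUE)
  }
  expect_error(pls_svd(matrix(0, 3, 4)), "no covariance")
})

test_that("brain scores are dot products and voxel-order equivariant", {
  set.seed(4)
  vals <- matrix(rnorm(3 * 6), 3, 6)
  dset <- manual_dataset(vals, rep("control", 3), rep("TP1", 3))
  onehot <- c(0, 0, 0, 1, 0, 0)
  expect_equal(drop(brain_scores(dset, onehot)), vals[, 4],
               ignore_attr = TRUE)
  v <- rnorm(6)
  x <- vals[1, ]
  orth <- v - sum(v * x) / sum(x * x) * x    # salience orthogonal to scan 1
  expect_equal(drop(brain_scores(dset, orth))[1], 0, tolerance = 1e-10)
  sal <- c(0.5, 0.5, -0.5, 0.2, 0, 1)
  expect_equal(drop(brain_scores(dset, sal)),
               apply(vals, 1, function(x) sum(x * sal)), ignore_attr = TRUE)
  # permuting voxels consistently leaves scores unchanged
  p <- sample(6)
  dset_p <- manual_dataset(vals[, p], rep("control", 3), rep("TP1", 3))
  expect_equal(brain_scores(dset_p, sal[p]), brain_scores(dset, sal))
})

test_that("permutation p has the add-one floor and is absent for n_perm = 0", {
  an <- small_analysis(small_config(n_per_group = 5, noise_sd = 0.1,
                                    rng_seed = 8))
  p <- permutation_test(an$flat, an$seeds, n_perm = 99, seed = 1)
  expect_equal(p[1], 1 / 100)
  expect_null(permutation_test(an$flat, an$seeds, n_perm = 0))
  # deterministic under a fixed seed
  p2 <- permutation_test(an$flat, an$seeds, n_perm = 25, seed = 5)
  p3 <- permutation_test(an$flat, an$seeds, n_perm = 25, seed = 5)
  expect_identical(p2, p3)
})

test_that("Monte-Carlo permutation p matches the exhaustive null on 4 scans", {
  set.seed(31)
  vals <- matrix(rnorm(4 * 5), 4, 5)
  S <- matrix(rnorm(16), 4, 4)
  dset <- manual_dataset(vals, rep("control", 4), rep("TP1", 4))
  obs <- pls_svd(correlation_stack(dset, S)$R)$singular_values[1]
  # exhaustive oracle over all 4! = 24 seed-row relabelings
  P <- all_perms(4)
  s1 <- apply(P, 1, function(pr) {
    Zs <- scale(S[pr, ]); Zs <- Zs / sqrt(3); Zs[is.na(Zs)] <- 0
    Zx <- scale(vals); Zx <- Zx / sqrt(3)
    svd(crossprod(Zs, Zx))$d[1]
  })
  p_exact <- mean(s1 >= obs - 1e-12)
  p_mc <- permutation_test(dset, S, n_perm = 4000, seed = 9)[1]
  se <- sqrt(p_exact * (1 - p_exact) / 4000)
  expect_lt(abs(p_mc - p_exact), 3 * se + 2 / 4000)
})

test_that("Procrustes alignment resolves sign flips, swaps and reflections", {
  set.seed(12)
  V <- qr.Q(qr(matrix(rnorm(10 * 3), 10, 3)))
  Q <- procrustes_align(V, V)
  expect_equal(Q, diag(3), tolerance = 1e-10, ignore_attr = TRUE)
  Q2 <- procrustes_align(-V, V)
  expect_equal(Q2, -diag(3), tolerance = 1e-10, ignore_attr = TRUE)
  # swapped columns: Q is exactly the inverse permutation matrix
  perm <- c(2, 1, 3)
  Q3 <- procrustes_align(V[, perm], V)
  Pm <- diag(3)[perm, ]
  expect_equal(Q3, Pm, tolerance = 1e-10, ignore_attr = TRUE)
  # ... and no other 3x3 signed permutation matrix is closer
  err <- function(Q) sum((V[, perm] %*% Q - V)^2)
  base <- err(Q3)
  for (pr in asplit(all_perms(3), 1))
    for (s1 in c(-1, 1)) for (s2 in c(-1, 1)) for (s3 in c(-1, 1)) {
      cand <- diag(c(s1, s2, s3)) %*% diag(3)[pr, ]
      expect_gte(err(cand), base - 1e-10)
    }
  # rank-deficient overlap falls back to sign matching
  Vd <- V; Vd[, 3] <- 0
  Qd <- procrustes_align(Vd, V * 0)
  expect_equal(attr(Qd, "method"), "sign")
})

test_that("bootstrap BSR matches a brute-force recomputation with frozen draws", {
  set.seed(55)
  n <- 4
  vals <- matrix(rnorm(2 * n * 6), 2 * n, 6)
  S <- matrix(rnorm(2 * n * 4), 2 * n, 4)
  grp <- rep(c("a", "b"), each = n)
  dset <- manual_dataset(vals, grp, rep("TP1", 2 * n))
  n_boot <- 3
  res <- pls_bootstrap(dset, S, n_boot = n_boot, seed = 77)

  # oracle: regenerate the same resample indices, recompute naively
  fit <- pls_svd(correlation_stack(dset, S)$R)
  K <- length(fit$singular_values)
  pearson_stack <- function(Sm, Xm, idx) {
    do.call(rbind, lapply(idx, function(i) {
      t(sapply(seq_len(ncol(Sm)), function(s)
        sapply(seq_len(ncol(Xm)), function(v) {
          if (sd(Sm[i, s]) == 0 || sd(Xm[i, v]) == 0) 0
          else cor(Sm[i, s], Xm[i, v])
        })))
    }))
  }
  idx <- list(a = 1:n, b = n + 1:n)
  set.seed(77)
  draws <- array(NA_real_, dim = c(6, K, n_boot))
  for (b in seq_len(n_boot)) {
    rows <- c(sample.int(n, replace = TRUE),
              n + sample.int(n, replace = TRUE))
    Rb <- pearson_stack(S[rows, ], vals[rows, ], list(1:n, n + 1:n))
    svb <- svd(Rb, nu = K, nv = K)
    M <- t(svb$v) %*% fit$saliences
    sv <- svd(M)
    Q <- sv$u %*% t(sv$v)
    draws[, , b] <- svb$v %*% diag(svb$d[1:K], K) %*% Q
  }
  se <- apply(draws, c(1, 2), sd)
  bsr_oracle <- (fit$saliences %*% diag(fit$singular_values, K)) / se
  expect_equal(unname(res$bsr), unname(bsr_oracle), tolerance = 1e-8)
})

test_that("zero bootstrap SE yields a flagged signed sentinel, not a drop", {
  cfg <- small_config(n_per_group = 4, noise_sd = 0, rng_seed = 13)
  an <- small_analysis(cfg)
  expect_warning(
    res <- pls_bootstrap(an$flat, an$seeds, n_boot = 5, n_lv = 2, seed = 3),
    "zero bootstrap SE")
  pat <- an$ds$truth[[1]]
  sup <- pat$support_voxels[1, ]
  col <- which(an$flat$voxel_index[, 1] == sup[1] &
                 an$flat$voxel_index[, 2] == sup[2] &
                 an$flat$voxel_index[, 3] == sup[3])
  expect_true(res$bsr_flags[col, 1])
  expect_true(is.infinite(res$bsr[col, 1]))
  expect_equal(unname(sign(res$bsr[col, 1])), 1)
})

test_that("the full fit recovers a planted pattern and orders two by strength", {
  cfg <- small_config(n_per_group = 12, noise_sd = 0.6, rng_seed = 17)
  an <- small_analysis(cfg)
  fit <- seed_pls(an$flat, an$seeds, n_perm = 99, n_boot = 30, seed = 2)
  expect_lte(fit$perm_p[1], 0.05)
  # cosine between LV1 saliences and the planted direction (all coupled voxels)
  truth <- numeric(ncol(an$flat$values))
  shp <- cfg$grid_shape
  lin_all <- seedpls:::voxel_linear_index(an$flat$voxel_index, shp)
  coupled <- c(unlist(lapply(cfg$seed_rois, seedpls:::voxel_linear_index,
                             shp = shp)),
               seedpls:::voxel_linear_index(cfg$patterns[[1]]$support_voxels,
                                            shp))
  truth[match(coupled, lin_all)] <- 1
  truth <- truth / sqrt(sum(truth^2))
  expect_gt(abs(sum(fit$saliences[, 1] * truth)), 0.9)

  # two orthogonally planted patterns with distinct strengths come out ordered
  vol_idx <- function(cond) {
    mm <- seedpls:::grid_mm_coords(cfg$mask)
    arrayInd(which(cond(mm)), cfg$grid_shape)
  }
  sup1 <- vol_idx(function(mm) abs(mm[, 1]) <= 10 & mm[, 2] >= -29 &
                    mm[, 2] <= -13 & mm[, 3] >= 5 & mm[, 3] <= 13)
  sup2 <- vol_idx(function(mm) abs(mm[, 1]) <= 10 & mm[, 2] >= -49 &
                    mm[, 2] <= -37 & mm[, 3] >= 5 & mm[, 3] <= 13)
  p1 <- planted_pattern(seed_loadings = c(1, 1, 1, 1), support_voxels = sup1,
                        latent_sd = 1.5)
  p2 <- planted_pattern(seed_loadings = c(1, -1, 1, -1), support_voxels = sup2,
                        latent_sd = 1.0)
  cfg2 <- small_config(n_per_group = 15, noise_sd = 0.2, rng_seed = 19,
                       patterns = list(p1, p2))
  an2 <- small_analysis(cfg2)
  fit2 <- seed_pls(an2$flat, an2$seeds, n_perm = 0, n_boot = 0)
  w1 <- fit2$design_weights[, 1]; w2 <- fit2$design_weights[, 2]
  same <- rep(c(1, 1, 1, 1), 6) / sqrt(24)
  diffv <- rep(c(1, -1, 1, -1), 6) / sqrt(24)
  # strongest LV carries the common pattern, the second the differential one
  expect_gt(abs(sum(w1 * same)), 0.9)
  expect_gt(abs(sum(w2 * diffv)), 0.7)
  expect_gt(abs(sum(w2 * diffv)), abs(sum(w2 * same)))
  # covariance fractions ordered by planted strength, both above the noise floor
  expect_gt(fit2$covariance_fraction[1], fit2$covariance_fraction[2])
  expect_gt(fit2$covariance_fraction[2], fit2$covariance_fraction[3])
})
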