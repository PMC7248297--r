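# Shared fixtures, built in code.

# Test-scale geometry: 12 x 14 x 12 voxels at 4 mm covers the hippocampal
# y-bands while keeping full pipeline runs fast.
small_config <- function(n_per_group = 6, rng_seed = 1, ...) {
  synthetic_config(n_per_group = n_per_group, grid_shape = c(12, 14, 12),
                   voxel_size_mm = c(4, 4, 4), origin_mm = c(-22, -49, -17),
                   rng_seed = rng_seed, ...)
}

whole_mask <- function(vol) {
  volume_grid(array(1, dim = dim(vol$data)), vol$affine)
}

# Generate, split, extract seeds and flatten in one go.
small_analysis <- function(cfg) {
  ds <- generate_dataset(cfg)
  sub <- split_hippocampus(ds$mask)
  list(ds = ds,
       seeds = extract_seed_values(ds$volumes, ds$table, sub),
       flat = flatten(ds$volumes, whole_mask(ds$mask), ds$table))
}

# Hand-built masked_dataset for matrix-level unit tests.
manual_dataset <- function(values, group, timepoint, subject_id = NULL) {
  n <- nrow(values)
  if (is.null(subject_id)) subject_id <- sprintf("s%02d", seq_len(n))
  affine <- diag(4)
  nv <- ncol(values)
  mask <- volume_grid(array(1, dim = c(nv, 1, 1)), affine)
  ijk <- cbind(seq_len(nv), 1L, 1L)
  structure(list(values = values, voxel_index = ijk,
                 mm_coord = voxel_to_mm(affine, ijk),
                 labels = data.frame(subject_id = subject_id,
                                     group = factor(group),
                                     timepoint = factor(timepoint),
                                     stringsAsFactors = FALSE),
                 mask = mask),
            class = "masked_dataset")
}

# All permutations of 1..n (tiny n only), for exhaustive null enumeration.
all_perms <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- all_perms(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

# Independent connected-components oracle: reachability by repeated
# boolean matrix multiplication over the voxel adjacency graph.
components_oracle <- function(coords, connectivity) {
  n <- nrow(coords)
  if (n == 0) return(integer(0))
  d <- as.matrix(dist(coords, method = "maximum"))
  dman <- as.matrix(dist(coords, method = "manhattan"))
  adj <- switch(as.character(connectivity),
                "6" = dman == 1,
                "18" = d == 1 & dman <= 2,
                "26" = d == 1)
  reach <- adj | diag(n) > 0
  repeat {
    nxt <- (reach %*% reach) > 0
    if (identical(nxt, reach)) break
    reach <- nxt
  }
  comp <- integer(n); cur <- 0L
  for (i in seq_len(n)) {
    if (comp[i] == 0L) { cur <- cur + 1L; comp[reach[i, ]] <- cur }
  }
  comp
}
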