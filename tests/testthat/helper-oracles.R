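# Independent brute-force oracles used to validate the vectorized paths.

# per-voxel loop classification: explicit if/else over the band rules
oracle_classify <- function(ct, region, scheme = threshold_scheme()) {
  dm <- dim(ct$voxels)
  lab <- array(0L, dm)
  for (k in seq_len(dm[3])) for (j in seq_len(dm[2])) for (i in seq_len(dm[1])) {
    if (!region[i, j, k]) next
    h <- ct$voxels[i, j, k]
    lab[i, j, k] <-
      if (h < scheme$hu_min || h > scheme$hu_max) 4L
      else if (h < scheme$air_soft) 1L
      else if (h < scheme$soft_bone) 2L
      else 3L
  }
  lab
}

# exact Wilcoxon signed-rank two-sided p by enumerating all 2^n sign
# assignments (requires no zeros and no tied |d|)
oracle_wilcoxon_exact <- function(d) {
  stopifnot(all(d != 0), !anyDuplicated(abs(d)))
  n <- length(d)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  Wall <- as.vector(signs %*% r)
  p_le <- mean(Wall <= W)
  p_ge <- mean(Wall >= W)
  # same two-sided convention as the exact signed-rank test: double the
  # smaller tail, capped at 1
  if (W > n * (n + 1) / 4) min(1, 2 * p_ge) else min(1, 2 * p_le)
}

# brute-force rasterization of a half-open box [lo, hi) by voxel centres
oracle_box_mask <- function(lo, hi, grid) {
  dm <- dim(grid$voxels)
  m <- array(FALSE, dm)
  for (k in seq_len(dm[3])) for (j in seq_len(dm[2])) for (i in seq_len(dm[1])) {
    ctr <- grid$origin + (c(i, j, k) - 1) * grid$spacing
    m[i, j, k] <- all(ctr >= lo) && all(ctr < hi)
  }
  m
}

# small random CT + mask on a given grid
random_ct <- function(dm, seed, hu_range = c(-2500, 2500), spacing = 0.5) {
  set.seed(seed)
  ct <- ct_volume(array(runif(prod(dm), hu_range[1], hu_range[2]), dm),
                  spacing = rep(spacing, 3))
  mask <- voi_mask(array(runif(prod(dm)) < 0.7, dm), reference = ct)
  list(ct = ct, mask = mask)
}

# standard small phantom used across tests (32^3 keeps suites fast)
small_phantom <- function(fill = 0.5, seed = 1L, grid_dim = 32)
  generate_phantom(phantom_spec(fill = fill, grid_dim = grid_dim, seed = seed))

# the 8 corners of a box; MX points take two opposite corners so the
# midsagittal laterality check is satisfiable
eight_corner_landmarks <- function(lo, hi) {
  landmark_set(rbind(
    S = c(hi[1], lo[2], lo[3]),
    N = c(lo[1], hi[2], lo[3]),
    Ba = c(hi[1], hi[2], lo[3]),
    ANS = c(lo[1], lo[2], hi[3]),
    PNS = c(hi[1], lo[2], hi[3]),
    A = c(lo[1], hi[2], hi[3]),
    MX_left = c(lo[1], lo[2], lo[3]),
    MX_right = c(hi[1], hi[2], hi[3])))
}
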