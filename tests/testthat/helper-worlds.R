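# Shared fixtures: compact synthetic worlds built in code.

# small centered grid whose affine puts (0,0,0) mid-grid
centered_affine <- function(dim3, voxel = 3) {
  make_affine(voxel, -voxel * (dim3 - 1) / 2)
}

# group-level acceptance world: full sample size on a reduced grid
zmap_world_spec <- function(seed, ...) {
  dims <- c(12, 14, 12)
  cohort_spec(grid_shape = dims, affine = centered_affine(dims),
              seed_centers_mm = list(c(-6, -6, 6), c(6, -6, 6)),
              target_center_mm = c(0, 8, -4), region_radius_mm = 7,
              rng_seed = seed, ...)
}

# brute-force censoring oracle: stamp a window around every spike frame
oracle_censor_mask <- function(fd, ssc, cfg) {
  n <- length(fd)
  mask <- logical(n)
  for (t in seq_len(n)) {
    if (fd[t] >= cfg$fd_threshold_mm || ssc[t] > cfg$intensity_threshold) {
      for (w in (t - cfg$mask_before):(t + cfg$mask_after))
        if (w >= 1 && w <= n) mask[w] <- TRUE
    }
  }
  mask
}

# brute-force lattice oracle: voxel offsets within radius of a voxel center
oracle_sphere_count <- function(radius_mm, voxel_mm) {
  lim <- ceiling(radius_mm / voxel_mm)
  g <- expand.grid(dx = -lim:lim, dy = -lim:lim, dz = -lim:lim)
  sum(voxel_mm^2 * (g$dx^2 + g$dy^2 + g$dz^2) <= radius_mm^2)
}

# empty censoring result for design-matrix construction without spikes
no_censoring <- function(n) build_temporal_mask(rep(0, n), rep(0, n))

run_to_series <- function(run, censoring = NULL) {
  if (is.null(censoring))
    censoring <- build_temporal_mask(compute_fd(run$motion),
                                     compute_scaled_signal_change(run))
  X <- build_design_matrix(run$task, run$motion, run$tissue, censoring,
                           run$tr_s, dim(run$data)[4])
  bandpass_filter(fit_glm_residuals(run, X, censoring$censored_mask))
}
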