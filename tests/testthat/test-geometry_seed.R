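test_that("sphere masks match the lattice-point oracle", {
  # radius 5 mm, 3 mm grid, center on a voxel center -> 19 voxels
  aff3 <- centered_affine(c(11, 11, 11))
  expect_equal(sum(make_sphere_mask(c(0, 0, 0), 5, c(11, 11, 11), aff3)), 19)
  expect_equal(oracle_sphere_count(5, 3), 19)

  # radius below half the voxel size -> single voxel
  expect_equal(sum(make_sphere_mask(c(0, 0, 0), 1, c(11, 11, 11), aff3)), 1)

  # radius 10 mm on a 2 mm grid vs brute-force enumeration
  aff2 <- centered_affine(c(21, 21, 21), voxel = 2)
  expect_equal(sum(make_sphere_mask(c(0, 0, 0), 10, c(21, 21, 21), aff2)),
               oracle_sphere_count(10, 2))

  expect_error(make_sphere_mask(c(100, 0, 0), 5, c(11, 11, 11), aff3),
               "outside")
})

test_that("voxel/world mappings are mutual inverses", {
  aff <- make_affine(3, c(-36, -60, -24))
  ijk <- rbind(c(1, 1, 1), c(10, 20, 5), c(24, 42, 24))
  expect_equal(unname(world_to_voxel(voxel_to_world(ijk, aff), aff)),
               unname(ijk))
  expect_equal(as.numeric(voxel_to_world(c(1, 1, 1), aff)), c(-36, -60, -24))
})

test_that("default geometry holds the anatomical coordinates interior", {
  spec <- cohort_spec()
  v <- world_to_voxel(rbind(c(-11, -52, 37), c(12, -52, 35), c(-2, 50, -6)),
                      spec$affine)
  expect_true(all(v > 1 & v < rep(spec$grid_shape, each = 3)))
  # masks match a direct voxel-center distance count and stay disjoint
  # (centers are off the voxel lattice, so counts differ from the
  # lattice-centered case)
  count_oracle <- function(center, radius) {
    ijk <- as.matrix(expand.grid(seq_len(spec$grid_shape[1]),
                                 seq_len(spec$grid_shape[2]),
                                 seq_len(spec$grid_shape[3])))
    xyz <- cbind(ijk, 1) %*% t(spec$affine[1:3, ])
    sum(colSums((t(xyz) - center)^2) <= radius^2)
  }
  sm <- Reduce(`|`, lapply(spec$seed_centers_mm, make_sphere_mask,
                           radius_mm = 5, dim3 = spec$grid_shape,
                           affine = spec$affine))
  tm <- make_sphere_mask(spec$target_center_mm, 10, spec$grid_shape,
                         spec$affine)
  expect_equal(sum(sm), count_oracle(c(-11, -52, 37), 5) +
                 count_oracle(c(12, -52, 35), 5))
  expect_equal(sum(tm), count_oracle(c(-2, 50, -6), 10))
  expect_gt(sum(tm), 100)
  expect_equal(sum(sm & tm), 0)
})

test_that("ROI mask is the source-map/sphere intersection", {
  dims <- c(15, 15, 15)
  aff <- centered_affine(dims)
  src <- array(TRUE, dims)
  roi <- build_roi_mask(src, aff, c(0, 0, 0), 10)
  expect_equal(roi$n_voxels, oracle_sphere_count(10, 3))

  src2 <- array(FALSE, dims); src2[1:8, , ] <- TRUE     # overlap only partial
  roi2 <- build_roi_mask(src2, aff, c(0, 0, 0), 10)
  expect_true(roi2$n_voxels < roi$n_voxels && roi2$n_voxels > 0)
  expect_true(all(which(roi2$mask) %in% which(src2)))

  src3 <- array(FALSE, dims); src3[15, 15, 15] <- TRUE
  expect_error(build_roi_mask(src3, aff, c(-12, -12, -12), 3), "overlap")
})

test_that("seed series is the unweighted mean over the sphere union", {
  dims <- c(9, 9, 9); aff <- centered_affine(dims)
  nt <- 60
  sp <- seed_spec(centers_mm = list(c(-6, 0, 0), c(6, 0, 0)), radius_mm = 1)
  mk_series <- function(M, cens = rep(FALSE, nt)) {
    structure(list(data = M, dim3 = dims, affine = aff, tr_s = 2.5,
                   censored_mask = cens, run_starts = 1L),
              class = "residual_series")
  }
  M <- matrix(0, prod(dims), nt)
  vox <- which(make_sphere_mask(c(-6, 0, 0), 1, dims, aff) |
                 make_sphere_mask(c(6, 0, 0), 1, dims, aff))
  expect_length(vox, 2)
  a <- sin(seq_len(nt)); b <- cos(seq_len(nt))
  M[vox[1], ] <- a; M[vox[2], ] <- b
  s <- extract_seed_series(mk_series(M), sp)
  expect_equal(as.numeric(s), (a + b) / 2, ignore_attr = TRUE)

  # censored frames excluded from the output index set
  cens <- rep(FALSE, nt); cens[5:8] <- TRUE
  s2 <- extract_seed_series(mk_series(M, cens), sp)
  expect_length(s2, nt - 4)
  expect_equal(attr(s2, "frames"), setdiff(1:nt, 5:8))
})

test_that("z maps apply correlation, clipping, and the Fisher transform", {
  set.seed(4)
  dims <- c(5, 5, 4); nv <- prod(dims); nt <- 600
  aff <- centered_affine(dims)
  seed_series <- rnorm(nt)
  M <- matrix(rnorm(nv * nt), nv, nt)
  M[1, ] <- seed_series                        # r -> 1
  M[2, ] <- 3 * seed_series + 5                # scale/shift invariance
  M[3, ] <- 0                                  # zero variance
  ser <- structure(list(data = M, dim3 = dims, affine = aff, tr_s = 2.5,
                        censored_mask = rep(FALSE, nt), run_starts = 1L),
                   class = "residual_series")
  s <- seed_series; attr(s, "frames") <- 1:nt
  zm <- seed_zmap(ser, s, subject = "s1")
  expect_equal(zm$data[1], atanh(1 - 1e-7))
  expect_equal(zm$data[2], atanh(1 - 1e-7))
  expect_equal(zm$data[3], 0)
  expect_true(3 %in% zm$zero_variance)
  expect_lt(max(abs(zm$data[-(1:3)])), 0.2)    # null bound at 600 frames

  # r = 0.5 -> z = atanh(0.5) = 0.5493
  y <- numeric(nt); y[1:2] <- c(1, -1)
  x <- numeric(nt); x[1:3] <- c(1, 0, -1)
  r_manual <- cor(x, y)
  M2 <- M; M2[4, ] <- y
  ser$data <- M2
  s2 <- x; attr(s2, "frames") <- 1:nt
  zm2 <- seed_zmap(ser, s2)
  expect_equal(zm2$data[4], atanh(r_manual))
  expect_equal(atanh(0.5), 0.5493, tolerance = 1e-4)

  ser_cens <- ser
  ser_cens$censored_mask <- rep(c(FALSE, TRUE), c(10, nt - 10))
  short <- seed_series[1:10]; attr(short, "frames") <- 1:10
  expect_error(seed_zmap(ser_cens, short), "30 retained")
  expect_error(seed_zmap(ser, s2[1:50]), "length")
})

test_that("scaling a voxel series leaves its z unchanged", {
  set.seed(12)
  dims <- c(4, 4, 2); nv <- prod(dims); nt <- 200
  M <- matrix(rnorm(nv * nt), nv, nt)
  ser <- structure(list(data = M, dim3 = dims, affine = centered_affine(dims),
                        tr_s = 2.5, censored_mask = rep(FALSE, nt),
                        run_starts = 1L), class = "residual_series")
  s <- rnorm(nt); attr(s, "frames") <- 1:nt
  z1 <- seed_zmap(ser, s)$data
  ser$data[7, ] <- 42 * ser$data[7, ]
  z2 <- seed_zmap(ser, s)$data
  expect_equal(z2[7], z1[7])
})
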