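#' Seed specification for posterior-cingulate connectivity
#'
#' Defaults are the two bilateral posterior cingulate coordinates
#' (left -11, -52, 37; right 12, -52, 35) with 5 mm sphere radius; the seed
#' time series is the unweighted mean over the union of both spheres.
#'
#' @param centers_mm list of world coordinates (each length 3)
#' @param radius_mm sphere radius in mm
#' @return object of class `seed_spec`
#' @export
seed_spec <- function(centers_mm = list(c(-11, -52, 37), c(12, -52, 35)),
                      radius_mm = 5) {
  stopifnot(length(centers_mm) >= 1, radius_mm > 0)
  structure(list(centers_mm = centers_mm, radius_mm = radius_mm),
            class = "seed_spec")
}

# union-of-spheres voxel mask for a seed spec
seed_union_mask <- function(seed, dim3, affine) {
  masks <- lapply(seed$centers_mm, make_sphere_mask,
                  radius_mm = seed$radius_mm, dim3 = dim3, affine = affine)
  Reduce(`|`, masks)
}

#' Extract the mean seed time series
#'
#' Averages the residual series over the union of the seed spheres,
#' returning values at retained (non-censored) volumes only; the retained
#' volume indices are attached as attribute `frames`.
#'
#' @param series a `residual_series`
#' @param seed a [seed_spec()]
#' @return numeric vector over retained frames, with attribute `frames`
#' @export
extract_seed_series <- function(series, seed = seed_spec()) {
  mask <- seed_union_mask(seed, series$dim3, series$affine)
  vox <- which(mask)
  if (!length(vox)) stop("seed union mask is empty")
  retained <- which(!series$censored_mask)
  s <- colMeans(series$data[vox, retained, drop = FALSE])
  attr(s, "frames") <- retained
  s
}

#' Voxel-wise Fisher-z seed-connectivity map
#'
#' Correlates every voxel's residual series with the seed series over the
#' retained volumes, clips |r| at 1 - 1e-7, and applies the Fisher z
#' transform (atanh). Zero-variance voxels get z = 0 and are flagged rather
#' than erroring (synthetic backgrounds may be constant).
#'
#' @param series a `residual_series`
#' @param seed_series output of [extract_seed_series()]
#' @param subject,session identifiers carried on the map
#' @param seed the seed specification used (stored for provenance)
#' @return object of class `zmap`: list with `data` (3D array of z values),
#'   `subject`, `session`, `n_frames`, `zero_variance` (voxel indices)
#' @export
seed_zmap <- function(series, seed_series, subject = NA, session = NA,
                      seed = NULL) {
  frames <- attr(seed_series, "frames")
  if (is.null(frames)) frames <- which(!series$censored_mask)
  if (length(frames) < 30)
    stop("fewer than 30 retained frames; connectivity map unreliable")
  if (length(seed_series) != length(frames))
    stop("seed series length does not match the retained frame count")
  Y <- series$data[, frames, drop = FALSE]
  s <- as.numeric(seed_series)
  sc <- s - mean(s)
  Yc <- Y - rowMeans(Y)
  denom_v <- sqrt(rowSums(Yc^2))
  denom_s <- sqrt(sum(sc^2))
  zero_var <- which(denom_v == 0 | !is.finite(denom_v))
  denom_v[zero_var] <- 1
  r <- as.numeric(Yc %*% sc) / (denom_v * denom_s)
  r[zero_var] <- 0
  r <- pmin(pmax(r, -(1 - 1e-7)), 1 - 1e-7)
  z <- atanh(r)
  z[zero_var] <- 0
  structure(list(data = array(z, dim = series$dim3),
                 affine = series$affine,
                 subject = subject, session = session,
                 seed = seed, n_frames = length(frames),
                 zero_variance = zero_var),
            class = "zmap")
}

#' Stack subject z-maps into a subjects x voxels matrix
#'
#' @param zmaps list of `zmap` objects sharing one grid
#' @return numeric matrix with attributes `dim3` and `affine`
#' @export
zmap_stack <- function(zmaps) {
  stopifnot(length(zmaps) >= 1)
  d0 <- dim(zmaps[[1]]$data)
  Y <- t(vapply(zmaps, function(z) {
    if (!identical(dim(z$data), d0)) stop("z-map grid mismatch")
    as.numeric(z$data)
  }, numeric(prod(d0))))
  rownames(Y) <- vapply(zmaps, function(z) as.character(z$subject), character(1))
  attr(Y, "dim3") <- d0
  attr(Y, "affine") <- zmaps[[1]]$affine
  Y
}
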