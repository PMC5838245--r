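#' Build a simple scaled-translation voxel-to-world affine
#'
#' Returns a 4x4 matrix mapping 1-based voxel indices (i, j, k) to world
#' (MNI-like) mm coordinates, with isotropic or anisotropic voxel sizes and
#' a world-space origin placed at the first voxel center.
#'
#' @param voxel_size_mm voxel edge length(s) in mm (length 1 or 3)
#' @param origin_mm world coordinate of voxel (1, 1, 1), length 3
#' @return 4x4 numeric affine matrix
#' @export
make_affine <- function(voxel_size_mm = 3, origin_mm = c(-36, -60, -24)) {
  vs <- rep(voxel_size_mm, length.out = 3)
  aff <- diag(4)
  diag(aff)[1:3] <- vs
  # subtract one voxel so that voxel index 1 maps onto the origin
  aff[1:3, 4] <- origin_mm - vs
  aff
}

#' Map voxel indices to world coordinates
#'
#' @param ijk n x 3 matrix (or length-3 vector) of 1-based voxel indices
#' @param affine 4x4 voxel-to-world matrix
#' @return n x 3 matrix of world mm coordinates
#' @export
voxel_to_world <- function(ijk, affine) {
  ijk <- rbind(ijk)
  h <- cbind(ijk, 1)
  xyz <- h %*% t(affine[1:3, , drop = FALSE])
  colnames(xyz) <- c("x", "y", "z")
  xyz
}

#' Map world coordinates to (fractional) voxel indices
#'
#' @param xyz n x 3 matrix (or length-3 vector) of world mm coordinates
#' @param affine 4x4 voxel-to-world matrix
#' @return n x 3 matrix of 1-based, possibly fractional, voxel indices
#' @export
world_to_voxel <- function(xyz, affine) {
  xyz <- rbind(xyz)
  h <- cbind(xyz, 1)
  ijk <- h %*% t(solve(affine)[1:3, , drop = FALSE])
  colnames(ijk) <- c("i", "j", "k")
  ijk
}

# world coordinates of every voxel center, as a V x 3 matrix in array order
grid_world_coords <- function(dim3, affine) {
  ijk <- as.matrix(expand.grid(i = seq_len(dim3[1]),
                               j = seq_len(dim3[2]),
                               k = seq_len(dim3[3])))
  voxel_to_world(ijk, affine)
}

#' Spherical region-of-interest mask on a voxel grid
#'
#' A voxel belongs to the sphere when the Euclidean distance from its world
#' space center to `center_mm` is at most `radius_mm` (voxel-center
#' membership, no partial volumes).
#'
#' @param center_mm world coordinate of the sphere center, length 3
#' @param radius_mm sphere radius in mm (> 0)
#' @param dim3 grid dimensions, length 3
#' @param affine 4x4 voxel-to-world matrix
#' @return logical 3D array of dimension `dim3`
#' @export
make_sphere_mask <- function(center_mm, radius_mm, dim3, affine) {
  stopifnot(length(center_mm) == 3, radius_mm > 0, length(dim3) == 3)
  frac <- world_to_voxel(center_mm, affine)
  if (any(frac < 0.5) || any(frac > dim3 + 0.5)) {
    stop("sphere center [", paste(center_mm, collapse = ", "),
         "] maps outside the voxel grid")
  }
  xyz <- grid_world_coords(dim3, affine)
  d2 <- (xyz[, 1] - center_mm[1])^2 + (xyz[, 2] - center_mm[2])^2 +
    (xyz[, 3] - center_mm[3])^2
  mask <- array(d2 <= radius_mm^2, dim = dim3)
  if (!any(mask)) stop("sphere mask is empty (radius too small for grid)")
  mask
}

#' Intersect a binary map with a spherical mask
#'
#' Builds a region-of-interest mask as the overlap of a supplied binary map
#' (e.g. a meta-analytic network map) and a sphere centered on a peak
#' coordinate, mirroring the standard peak-plus-map ROI construction.
#'
#' @param source_map logical/0-1 3D array on the analysis grid
#' @param affine 4x4 voxel-to-world matrix of the grid
#' @param center_mm sphere center in world mm (default the anterior
#'   default-mode peak c(-2, 50, -6))
#' @param radius_mm sphere radius in mm (default 10)
#' @return list with `mask` (logical 3D array) and `n_voxels`
#' @export
build_roi_mask <- function(source_map, affine, center_mm = c(-2, 50, -6),
                           radius_mm = 10) {
  dim3 <- dim(source_map)
  stopifnot(length(dim3) == 3)
  sphere <- make_sphere_mask(center_mm, radius_mm, dim3, affine)
  mask <- sphere & (array(as.logical(source_map), dim = dim3))
  if (!any(mask)) stop("ROI mask is empty: source map and sphere do not overlap")
  list(mask = mask, n_voxels = sum(mask))
}
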