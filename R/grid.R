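#' Define a 3D voxel grid
#'
#' A grid couples integer voxel indices (0-based, column-major) to world
#' coordinates in millimetres through an affine transform. The default
#' affine is diagonal scaling by the voxel size with the grid centred on the
#' world origin, which is all the synthetic cohorts need; any invertible
#' 4x4 affine (e.g. from a NIfTI header) is accepted.
#'
#' @param dims Integer vector of length 3: voxels along x, y, z.
#' @param voxel_mm Voxel edge length in mm (isotropic) or length-3 vector.
#' @param affine Optional 4x4 voxel-to-mm transform; overrides `voxel_mm`
#'   placement.
#' @return An object of class `brain_grid` with fields `dims`, `affine`,
#'   `n_voxels`.
#' @export
brain_grid <- function(dims, voxel_mm = 4, affine = NULL) {
  dims <- as.integer(dims)
  stopifnot(length(dims) == 3, all(dims >= 1))
  if (is.null(affine)) {
    voxel_mm <- rep_len(as.numeric(voxel_mm), 3)
    affine <- diag(c(voxel_mm, 1))
    affine[1:3, 4] <- -voxel_mm * (dims - 1) / 2
  }
  affine <- unname(as.matrix(affine))
  stopifnot(all(dim(affine) == c(4, 4)))
  if (abs(det(affine)) < .Machine$double.eps)
    abort("grid affine must be invertible")
  structure(
    list(dims = dims, affine = affine, n_voxels = prod(dims)),
    class = "brain_grid"
  )
}

#' @export
print.brain_grid <- function(x, ...) {
  cat("<brain_grid> ", paste(x$dims, collapse = " x "),
      " voxels (", x$n_voxels, ")\n", sep = "")
  invisible(x)
}

#' Convert voxel indices to world mm coordinates
#'
#' @param grid A [brain_grid()].
#' @param ijk Matrix (n x 3) of 0-based voxel indices.
#' @return n x 3 matrix of mm coordinates.
#' @export
voxel_to_mm <- function(grid, ijk) {
  ijk <- matrix(as.numeric(ijk), ncol = 3)
  t(grid$affine %*% rbind(t(ijk), 1))[, 1:3, drop = FALSE]
}

#' Convert world mm coordinates to (fractional) voxel indices
#'
#' @inheritParams voxel_to_mm
#' @param mm Matrix (n x 3) of mm coordinates.
#' @return n x 3 matrix of 0-based voxel indices (not rounded).
#' @export
mm_to_voxel <- function(grid, mm) {
  mm <- matrix(as.numeric(mm), ncol = 3)
  t(solve(grid$affine) %*% rbind(t(mm), 1))[, 1:3, drop = FALSE]
}

# mm coordinates of every voxel centre, V x 3, column-major voxel order
grid_coords <- function(grid) {
  d <- grid$dims
  ijk <- cbind(
    rep.int(seq_len(d[1]) - 1L, d[2] * d[3]),
    rep.int(rep(seq_len(d[2]) - 1L, each = d[1]), d[3]),
    rep(seq_len(d[3]) - 1L, each = d[1] * d[2])
  )
  voxel_to_mm(grid, ijk)
}

#' Spherical voxel mask around a world-space centre
#'
#' Membership is by voxel-centre Euclidean distance: a voxel belongs to the
#' sphere when its centre lies within `radius_mm` of `center_mm`.
#'
#' @param grid A [brain_grid()].
#' @param center_mm Length-3 mm coordinate of the sphere centre.
#' @param radius_mm Sphere radius in mm (default 4, the seed radius).
#' @return Logical vector over all grid voxels (column-major).
#' @export
sphere_mask <- function(grid, center_mm, radius_mm = 4) {
  xyz <- grid_coords(grid)
  d2 <- (xyz[, 1] - center_mm[1])^2 + (xyz[, 2] - center_mm[2])^2 +
    (xyz[, 3] - center_mm[3])^2
  d2 <= radius_mm^2
}

# Isotropic Gaussian blob (peak value 1) around a mm centre; the planted
# covariance patterns are smooth, mirroring real salience maps.
gaussian_pattern <- function(grid, center_mm, sd_mm) {
  xyz <- grid_coords(grid)
  d2 <- (xyz[, 1] - center_mm[1])^2 + (xyz[, 2] - center_mm[2])^2 +
    (xyz[, 3] - center_mm[3])^2
  exp(-d2 / (2 * sd_mm^2))
}
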