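#' Volume geometry
#'
#' Describes the spatial layout of a 3D/4D image: grid dimensions, voxel size
#' in mm and the 4x4 affine mapping 0-based voxel coordinates to world mm
#' (see the package help for the coordinate convention).
#'
#' @param dims integer triple (nx, ny, nz), all >= 1.
#' @param voxel_size mm triple, all > 0.
#' @param affine optional 4x4 voxel-to-world matrix; defaults to a diagonal
#'   scaling by `voxel_size` with the origin at voxel (0, 0, 0).
#' @return An object of class `vol_geometry`.
#' @export
volume_geometry <- function(dims, voxel_size, affine = NULL) {
  dims <- as.integer(dims)
  voxel_size <- as.numeric(voxel_size)
  stopifnot(length(dims) == 3L, length(voxel_size) == 3L)
  if (any(dims < 1L)) stop("all dims must be >= 1")
  if (any(voxel_size <= 0)) stop("all voxel sizes must be > 0")
  if (is.null(affine)) {
    affine <- diag(c(voxel_size, 1))
  }
  affine <- as.matrix(affine)
  stopifnot(all(dim(affine) == c(4L, 4L)))
  if (abs(det(affine)) < .Machine$double.eps * 1e3) {
    stop("affine must be invertible")
  }
  structure(list(dims = dims, voxel_size = voxel_size, affine = affine),
            class = "vol_geometry")
}

#' @export
print.vol_geometry <- function(x, ...) {
  cat(sprintf("<vol_geometry> %d x %d x %d voxels, %.4g x %.4g x %.4g mm\n",
              x$dims[1], x$dims[2], x$dims[3],
              x$voxel_size[1], x$voxel_size[2], x$voxel_size[3]))
  invisible(x)
}

geometry_equal <- function(a, b, tol = 1e-6) {
  all(a$dims == b$dims) &&
    all(abs(a$voxel_size - b$voxel_size) < tol) &&
    all(abs(a$affine - b$affine) < tol)
}

#' Convert continuous 0-based voxel coordinates to world mm
#'
#' @param geometry a [volume_geometry()].
#' @param vox n x 3 matrix (or length-3 vector) of 0-based voxel coordinates.
#' @return n x 3 matrix of world coordinates in mm.
#' @export
voxel_to_world <- function(geometry, vox) {
  vox <- rbind3(vox)
  h <- cbind(vox, 1) %*% t(geometry$affine)
  h[, 1:3, drop = FALSE]
}

#' Convert world mm coordinates to continuous 0-based voxel coordinates
#'
#' @inheritParams voxel_to_world
#' @param world n x 3 matrix (or length-3 vector) of world mm coordinates.
#' @export
world_to_voxel <- function(geometry, world) {
  world <- rbind3(world)
  h <- cbind(world, 1) %*% t(solve(geometry$affine))
  h[, 1:3, drop = FALSE]
}

rbind3 <- function(x) {
  if (is.null(dim(x))) matrix(x, ncol = 3) else as.matrix(x)
}

# nearest array index (1-based) for a continuous 0-based voxel coordinate;
# returns NA for coordinates outside the grid
voxel_index <- function(geometry, vox) {
  idx <- floor(vox + 0.5) + 1
  bad <- idx < 1 | idx > matrix(geometry$dims, nrow(idx), 3, byrow = TRUE)
  idx[rowSums(bad) > 0, ] <- NA_real_
  idx
}
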