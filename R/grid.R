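#' Regular 3-D simulation grid
#'
#' Defines the voxel lattice shared by field maps, tissue volumes and masks.
#' World coordinates are in metres, with the origin at the centre of the coil
#' assembly; `origin` gives the world position of the geometric centre of the
#' grid box. The z axis runs along the scanner bore and the patient faces the
#' negative y axis. Voxel membership throughout the package is decided by the
#' voxel-centre position.
#'
#' @param dims Integer vector of length 3: voxels along x, y, z (each >= 2).
#' @param spacing Numeric vector of length 3: voxel edge lengths in metres.
#'   The default matches the 0.39 cm x 0.45 cm x 0.35 cm field-map resolution.
#' @param origin World coordinates (m) of the grid-box centre.
#' @return An object of class `grid3d`.
#' @examples
#' g <- grid3d(c(16, 16, 16), spacing = c(0.01, 0.01, 0.01))
#' dim(voxel_coords(g))
#' @export
grid3d <- function(dims, spacing = c(0.0039, 0.0045, 0.0035),
                   origin = c(0, 0, 0)) {
  dims <- as.integer(dims)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(dims) != 3L || any(!is.finite(dims)) || any(dims < 2L))
    stop("grid3d: 'dims' must be three integers >= 2")
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("grid3d: 'spacing' must be three positive lengths (m)")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("grid3d: 'origin' must be three finite coordinates (m)")
  structure(list(dims = dims, spacing = spacing, origin = origin),
            class = "grid3d")
}

#' @export
print.grid3d <- function(x, ...) {
  cat(sprintf("<grid3d> %d x %d x %d voxels, spacing %.4g x %.4g x %.4g m\n",
              x$dims[1], x$dims[2], x$dims[3],
              x$spacing[1], x$spacing[2], x$spacing[3]))
  invisible(x)
}

#' @rdname grid3d
#' @param grid A `grid3d`.
#' @return `voxel_volume()`: the volume of one voxel in m^3.
#' @export
voxel_volume <- function(grid) prod(grid$spacing)

#' Voxel-centre coordinates along one axis
#'
#' @param grid A `grid3d`.
#' @param axis 1, 2 or 3 (x, y, z).
#' @return Numeric vector of world coordinates (m) of voxel centres.
#' @export
axis_coords <- function(grid, axis) {
  n <- grid$dims[axis]
  grid$origin[axis] + (seq_len(n) - (n + 1) / 2) * grid$spacing[axis]
}

#' World coordinates of every voxel centre
#'
#' @param grid A `grid3d`.
#' @return An (nx*ny*nz) x 3 matrix in the array's natural (x fastest) order.
#' @export
voxel_coords <- function(grid) {
  x <- axis_coords(grid, 1); y <- axis_coords(grid, 2); z <- axis_coords(grid, 3)
  cbind(rep(x, times = length(y) * length(z)),
        rep(rep(y, each = length(x)), times = length(z)),
        rep(z, each = length(x) * length(y)))
}

#' Map a world point to the enclosing voxel index
#'
#' Points outside the grid box return `NA`. Uses nearest-voxel-centre binning,
#' consistent with voxel-centre membership.
#'
#' @param grid A `grid3d`.
#' @param p Numeric length-3 world point (m), or an n x 3 matrix of points.
#' @return Integer (i, j, k) triplet (1-based), or an n x 3 matrix.
#' @export
world_to_index <- function(grid, p) {
  if (is.null(dim(p))) p <- matrix(p, nrow = 1)
  idx <- sapply(1:3, function(a) {
    i <- round((p[, a] - grid$origin[a]) / grid$spacing[a] + (grid$dims[a] + 1) / 2)
    i[i < 1 | i > grid$dims[a]] <- NA_real_
    i
  })
  idx <- matrix(as.integer(idx), ncol = 3)
  if (nrow(idx) == 1L) idx[1, ] else idx
}

#' @rdname world_to_index
#' @param ijk Integer triplet or n x 3 matrix of 1-based voxel indices.
#' @return `index_to_world()`: world coordinates of the voxel centre(s).
#' @export
index_to_world <- function(grid, ijk) {
  if (is.null(dim(ijk))) ijk <- matrix(ijk, nrow = 1)
  w <- sapply(1:3, function(a)
    grid$origin[a] + (ijk[, a] - (grid$dims[a] + 1) / 2) * grid$spacing[a])
  w <- matrix(w, ncol = 3)
  if (nrow(w) == 1L) w[1, ] else w
}
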