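#' Rigid-body transforms of patient geometry
#'
#' A transform rotates about the grid origin (x, then y, then z axis, i.e.
#' R = Rz %*% Ry %*% Rx) and then translates. Used for the position-robustness
#' experiment, where the optimized shim weights of the original pose are
#' applied to a displaced patient.
#'
#' @param angles Rotation angles about x, y, z (radians).
#' @param translation Offsets along x, y, z (m).
#' @return An object of class `rigid_transform` with the 3 x 3 rotation matrix
#'   `R` and translation `t`.
#' @export
rigid_transform <- function(angles = c(0, 0, 0), translation = c(0, 0, 0)) {
  if (any(!is.finite(c(angles, translation))))
    stop("rigid_transform: angles and offsets must be finite")
  cx <- cos(angles[1]); sx <- sin(angles[1])
  cy <- cos(angles[2]); sy <- sin(angles[2])
  cz <- cos(angles[3]); sz <- sin(angles[3])
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
  structure(list(R = Rz %*% Ry %*% Rx, t = as.numeric(translation),
                 angles = as.numeric(angles)),
            class = "rigid_transform")
}

#' Compose two rigid transforms
#'
#' `compose_transforms(a, b)` applies `b` first, then `a`.
#' @param a,b `rigid_transform` objects.
#' @export
compose_transforms <- function(a, b) {
  out <- rigid_transform()
  out$R <- a$R %*% b$R
  out$t <- as.numeric(a$R %*% b$t + a$t)
  out$angles <- NULL
  out
}

#' Apply a rigid transform to patient geometry
#'
#' Lead polylines are transformed exactly (an isometry: arc length and
#' inter-vertex distances are preserved). For a synthetic ellipsoidal head
#' phantom the head mask is regenerated from the transformed ellipsoid; an
#' error is raised if the transformed head no longer fits in the grid.
#'
#' @param x A [lead_model()] or a [tissue_model()] created by
#'   [generate_head_phantom()].
#' @param transform A [rigid_transform()].
#' @param ... Unused.
#' @return The transformed object.
#' @export
apply_rigid_transform <- function(x, transform, ...) UseMethod("apply_rigid_transform")

#' @export
apply_rigid_transform.lead_model <- function(x, transform, ...) {
  x$vertices <- t(transform$R %*% t(x$vertices)) +
    matrix(transform$t, nrow(x$vertices), 3, byrow = TRUE)
  x
}

#' @export
apply_rigid_transform.tissue_model <- function(x, transform, ...) {
  if (is.null(x$head_centre))
    stop("apply_rigid_transform: tissue model lacks ellipsoid parameters")
  grid <- x$grid
  centre <- as.numeric(transform$R %*% x$head_centre + transform$t)
  # axis-aligned bounding half-extent of the rotated ellipsoid
  half <- sqrt(colSums((transform$R * matrix(x$head_radii, 3, 3))^2))
  if (any(abs(centre - grid$origin) + half > grid$dims * grid$spacing / 2 + 1e-12))
    stop("apply_rigid_transform: transformed head exits grid")
  p <- voxel_coords(grid)
  q <- (p - matrix(centre, nrow(p), 3, byrow = TRUE)) %*% transform$R  # R^T rows
  inside <- (q[, 1] / x$head_radii[1])^2 + (q[, 2] / x$head_radii[2])^2 +
    (q[, 3] / x$head_radii[3])^2 <= 1
  out <- tissue_model(grid, array(inside, grid$dims),
                      sigma = max(x$sigma), rho = max(x$rho),
                      C_t = max(x$C), k_t = max(x$k),
                      V_b = max(x$V_b), Q_m = max(x$Q_m),
                      rho_b = x$rho_b, C_b = x$C_b, T_b = x$T_b)
  out$head_centre <- centre
  out$head_radii <- x$head_radii
  out$head_rotation <- transform$R
  out
}

#' Draw a random rigid-body shift within stated bounds
#'
#' Per-axis rotation uniform in [-max_angle, +max_angle] and per-axis
#' translation uniform in [-max_shift, +max_shift], the displacement model of
#' the robustness experiment (default 10 degrees and 4 cm).
#'
#' @param seed Integer seed; the draw is deterministic given the seed.
#' @param max_angle_deg Per-axis rotation bound (degrees).
#' @param max_shift Per-axis translation bound (m).
#' @return A [rigid_transform()].
#' @export
random_rigid_transform <- function(seed, max_angle_deg = 10, max_shift = 0.04) {
  with_local_seed(seed, {
    ang <- stats::runif(3, -max_angle_deg, max_angle_deg) * pi / 180
    tr <- stats::runif(3, -max_shift, max_shift)
    rigid_transform(ang, tr)
  })
}

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# random-number stream.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
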