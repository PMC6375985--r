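#' Parallel-transmit coil array geometry
#'
#' N rectangular loop elements wrapped on a cylinder, element centres spaced
#' 2*pi/N radians apart in azimuth. Defaults follow the study geometry: a
#' 25 cm diameter, 15 cm tall pTx former with per-element arc length 19.6 cm
#' for N = 4 and 9.8 cm for N = 8, driven at 128 MHz (3 T). Each element is
#' discretized into straight current segments for quasi-static field
#' evaluation.
#'
#' @param n_channels Number of elements; 1, 2, 4, 8 or 16 are supported.
#' @param radius Cylinder radius (m).
#' @param height Element (cylinder) height (m).
#' @param arc_length Per-element azimuthal arc length (m); default 19.6 cm for
#'   N = 4, 9.8 cm for N = 8, and 80% of the available pitch otherwise.
#' @param segments_per_loop Number of straight segments discretizing each loop.
#' @param frequency Drive frequency (Hz).
#' @return An object of class `coil_array` with per-element segment midpoints
#'   and direction vectors (unit drive current).
#' @export
coil_array <- function(n_channels, radius = 0.125, height = 0.15,
                       arc_length = NULL, segments_per_loop = 48L,
                       frequency = 128e6) {
  if (!n_channels %in% c(1L, 2L, 4L, 8L, 16L))
    stop("coil_array: n_channels must be one of 1, 2, 4, 8, 16")
  if (is.null(arc_length)) {
    arc_length <- switch(as.character(n_channels),
                         "4" = 0.196, "8" = 0.098,
                         0.8 * 2 * pi * radius / n_channels)
  }
  if (arc_length * n_channels > 2 * pi * radius + 1e-12)
    stop("coil_array: element arc lengths overlap around the cylinder")
  azimuths <- 2 * pi * (seq_len(n_channels) - 1L) / n_channels
  elements <- lapply(azimuths, function(phi0)
    loop_segments(radius, height, arc_length, phi0, segments_per_loop))
  structure(list(n_channels = as.integer(n_channels), radius = radius,
                 height = height, arc_length = arc_length,
                 azimuths = azimuths, frequency = frequency,
                 elements = elements),
            class = "coil_array")
}

#' @export
print.coil_array <- function(x, ...) {
  cat(sprintf("<coil_array> %d elements on r = %.3f m cylinder, arc %.1f cm, %.0f MHz\n",
              x$n_channels, x$radius, 100 * x$arc_length, x$frequency / 1e6))
  invisible(x)
}

#' Birdcage reference coil as a fixed-quadrature array
#'
#' The conventional transmit/receive birdcage (28 cm diameter, 35 cm height,
#' 16 rungs) is emulated as a 16-element array driven with fixed quadrature
#' weights; it serves as the reference excitation and is never optimized.
#'
#' @param radius,height Former radius and height (m).
#' @param ... Passed to [coil_array()].
#' @return A `coil_array` with 16 channels.
#' @export
birdcage_array <- function(radius = 0.14, height = 0.35, ...) {
  coil_array(16L, radius = radius, height = height, ...)
}

# Discretize one rectangular loop wrapped on the cylinder into straight
# segments. Returns midpoints (m) and segment vectors dl (m) for unit current
# flowing around the loop.
loop_segments <- function(radius, height, arc_length, phi0, n_seg) {
  half_ang <- arc_length / (2 * radius)
  n_arc <- max(4L, round(n_seg * 0.35))
  n_vert <- max(2L, round((n_seg - 2 * n_arc) / 2))
  phi <- seq(phi0 - half_ang, phi0 + half_ang, length.out = n_arc + 1L)
  arc_pts <- function(z) cbind(radius * cos(phi), radius * sin(phi), z)
  vert_pts <- function(ph, z0, z1)
    cbind(radius * cos(ph), radius * sin(ph), seq(z0, z1, length.out = n_vert + 1L))
  # traverse: bottom arc (+phi), up at +phi side, top arc (-phi), down at -phi side
  pts <- rbind(arc_pts(-height / 2),
               vert_pts(phi0 + half_ang, -height / 2, height / 2)[-1, ],
               arc_pts(height / 2)[(n_arc + 1L):1, ][-1, ],
               vert_pts(phi0 - half_ang, height / 2, -height / 2)[-1, ])
  dimnames(pts) <- NULL
  dl <- diff(rbind(pts, pts[1, , drop = FALSE]))
  mid <- (pts + rbind(pts[-1, , drop = FALSE], pts[1, , drop = FALSE])) / 2
  list(mid = mid, dl = dl)
}
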