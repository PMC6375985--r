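#' Per-channel RF shim weights
#'
#' Static amplitude and phase applied to the common RF waveform of each
#' transmit channel. The complex drive of channel n is A_n * exp(i * phi_n).
#'
#' @param amplitudes Non-negative finite drive scales, one per channel.
#' @param phases Phases in radians, one per channel.
#' @return An object of class `shim_weights`.
#' @export
shim_weights <- function(amplitudes, phases) {
  amplitudes <- as.numeric(amplitudes)
  phases <- as.numeric(phases)
  if (length(amplitudes) != length(phases) || length(amplitudes) < 1L)
    stop("shim_weights: 'amplitudes' and 'phases' must have equal positive length")
  if (any(!is.finite(amplitudes)) || any(amplitudes < 0) || any(!is.finite(phases)))
    stop("shim_weights: amplitudes must be finite and >= 0, phases finite")
  structure(list(amplitudes = amplitudes, phases = phases,
                 n_channels = length(amplitudes)),
            class = "shim_weights")
}

#' @export
print.shim_weights <- function(x, ...) {
  cat(sprintf("<shim_weights> %d channels\n  A:   %s\n  phi: %s\n",
              x$n_channels,
              paste(sprintf("%.3f", x$amplitudes), collapse = " "),
              paste(sprintf("%+.2f", x$phases), collapse = " ")))
  invisible(x)
}

#' Complex drive vector of a weight set
#' @param weights A [shim_weights()].
#' @return Complex vector A_n * exp(i * phi_n).
#' @export
as_complex_drive <- function(weights) {
  weights$amplitudes * exp(1i * weights$phases)
}

#' Quadrature-mode weights
#'
#' Equal amplitudes with phases phi_n = 2*pi*n/N (n = 0..N-1), the circularly
#' polarized excitation that emulates a birdcage drive; the reference mode of
#' the safety precheck.
#'
#' @param n_channels Number of channels (>= 1).
#' @return A [shim_weights()].
#' @examples
#' quadrature_weights(4)$phases   # 0, pi/2, pi, 3*pi/2
#' @export
quadrature_weights <- function(n_channels) {
  if (n_channels < 1L) stop("quadrature_weights: n_channels must be >= 1")
  n <- seq_len(n_channels) - 1L
  shim_weights(rep(1, n_channels), 2 * pi * n / n_channels)
}

#' Combine per-channel maps under shim weights
#'
#' Linear superposition of the per-channel basis maps:
#' E_tot(r) = sum_n A_n exp(i phi_n) e_n(r) and likewise for B1+.
#'
#' @param weights A [shim_weights()] with as many channels as `maps`.
#' @param maps A `coil_maps` from [compute_coil_maps()].
#' @return An object of class `combined_field` with complex `E` (n_voxel x 3)
#'   and `B1` (n_voxel), the grid, and provenance.
#' @export
combine_fields <- function(weights, maps) {
  stopifnot(inherits(weights, "shim_weights"), inherits(maps, "coil_maps"))
  if (weights$n_channels != maps$n_channels)
    stop(sprintf("combine_fields: %d weights for %d channels",
                 weights$n_channels, maps$n_channels))
  w <- as_complex_drive(weights)
  B1 <- as.vector(maps$B1 %*% w)
  E <- maps$E[[1]] * w[1]
  if (length(w) > 1L)
    for (n in 2:length(w)) E <- E + maps$E[[n]] * w[n]
  structure(list(grid = maps$grid, E = E, B1 = B1, weights = weights),
            class = "combined_field")
}

#' Normalize weights to a target VOI-mean transmit field
#'
#' Rescales all amplitudes by a single common factor so that the mean |B1+|
#' over the VOI equals `target_mean_b1` (default 1 microtesla, the
#' cross-configuration comparison condition). Phases are untouched, so the
#' field pattern is preserved exactly.
#'
#' @param weights A [shim_weights()].
#' @param maps A `coil_maps`.
#' @param voi A [region_mask()] (role VOI).
#' @param target_mean_b1 Target mean |B1+| (tesla).
#' @return Normalized [shim_weights()].
#' @export
normalize_weights <- function(weights, maps, voi, target_mean_b1 = 1e-6) {
  stopifnot(inherits(voi, "region_mask"))
  idx <- which(voi$mask)
  w <- as_complex_drive(weights)
  mu <- mean(abs(maps$B1[idx, , drop = FALSE] %*% w))
  if (mu <= 0) stop("normalize_weights: zero B1+ over the VOI")
  shim_weights(weights$amplitudes * (target_mean_b1 / mu), weights$phases)
}
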