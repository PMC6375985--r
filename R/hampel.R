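#' Hampel outlier filter
#'
#' Sliding-window median/MAD despiking, used to remove the non-physical
#' spikes that full-wave solvers produce at dielectric interfaces. For each
#' position the window median m and the scaled median absolute deviation
#' s = 1.4826 * median(|x - m|) are computed over the centred window; the
#' value is replaced by m iff |x - m| > k * s. When s = 0 (locally constant
#' data) any value different from the median is replaced. Windows are
#' truncated at the sequence edges.
#'
#' @param x Numeric vector (non-empty, finite).
#' @param window Odd window length >= 3 (default 5).
#' @param k Threshold in scaled-MAD units (default 3).
#' @return Filtered vector, same length.
#' @examples
#' hampel_filter(c(1, 1, 1, 100, 1, 1, 1))  # spike replaced by 1
#' @export
hampel_filter <- function(x, window = 5L, k = 3) {
  if (length(x) == 0L) stop("hampel_filter: empty input")
  if (any(!is.finite(x))) stop("hampel_filter: input must be finite")
  window <- as.integer(window)
  if (window < 3L || window %% 2L == 0L)
    stop("hampel_filter: 'window' must be an odd integer >= 3")
  if (k < 0) stop("hampel_filter: 'k' must be >= 0")
  n <- length(x)
  h <- window %/% 2L
  out <- x
  for (i in seq_len(n)) {
    w <- x[max(1L, i - h):min(n, i + h)]
    m <- stats::median(w)
    s <- 1.4826 * stats::median(abs(w - m))
    dev <- abs(x[i] - m)
    if ((s == 0 && dev > 0) || (s > 0 && dev > k * s)) out[i] <- m
  }
  out
}

#' Despike a 3-D volume axis-by-axis
#'
#' Applies [hampel_filter()] along every grid line of the x axis, then y,
#' then z. For complex volumes the filter acts on the magnitude and the
#' phasor is rescaled, preserving phase.
#'
#' @param vol 3-D numeric or complex array.
#' @param window,k Passed to [hampel_filter()].
#' @return Filtered array, same shape and type.
#' @export
hampel_filter_volume <- function(vol, window = 5L, k = 3) {
  if (is.complex(vol)) {
    mag <- abs(vol)
    fm <- hampel_filter_volume(mag, window, k)
    scale <- ifelse(mag > 0, fm / mag, 0)
    return(vol * scale)
  }
  d <- dim(vol)
  stopifnot(length(d) == 3L)
  for (axis in 1:3) {
    vol <- apply(vol, setdiff(1:3, axis), hampel_filter, window = window, k = k)
    # apply() puts the looped axis first; restore x,y,z order
    perm <- order(c(axis, setdiff(1:3, axis)))
    vol <- aperm(vol, perm)
  }
  array(vol, dim = d)
}
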