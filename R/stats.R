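#' Wilcoxon signed-rank test for paired samples
#'
#' Zero differences are discarded; |differences| are ranked with midranks for
#' ties; W is the sum of ranks of the positive differences. The two-sided p
#' value is exact (full enumeration of all 2^n sign assignments, honouring
#' ties) for n <= 15 non-zero pairs, and uses the normal approximation with
#' tie correction and continuity correction above.
#'
#' @param x,y Paired numeric vectors, or `x` a vector of differences when `y`
#'   is `NULL`.
#' @param exact_max Largest n for which full enumeration is used.
#' @return List with `W`, `p_value`, `n` (non-zero pairs) and `method`.
#' @examples
#' wilcoxon_signed_rank(1:9, rep(0, 9))  # W = 45, p = 2/512
#' @export
wilcoxon_signed_rank <- function(x, y = NULL, exact_max = 15L) {
  d <- if (is.null(y)) x else x - y
  d <- d[d != 0]
  n <- length(d)
  if (n < 1L) stop("wilcoxon_signed_rank: all differences are zero")
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  if (n <= exact_max) {
    # enumerate all sign assignments; ties make the null distribution
    # data-dependent, so enumerate with the observed ranks
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    Wall <- as.vector(signs %*% r)
    centre <- n * (n + 1) / 4
    p <- mean(abs(Wall - centre) >= abs(W - centre) - 1e-9)
    method <- "exact enumeration"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (W - mu - sign(W - mu) * 0.5) / sqrt(sig2)
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal approximation"
  }
  list(W = W, p_value = min(1, p), n = n, method = method)
}

#' Box-plot summary with 1.5 IQR outliers
#'
#' Quartiles by linear interpolation (type 7); outliers are points outside
#' [Q1 - 1.5 IQR, Q3 + 1.5 IQR].
#'
#' @param values Non-empty numeric vector.
#' @return List with `median`, `q1`, `q3`, `iqr`, `outliers`.
#' @export
box_summary <- function(values) {
  if (length(values) == 0L) stop("box_summary: empty input")
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  iqr <- q[3] - q[1]
  out <- values[values < q[1] - 1.5 * iqr | values > q[3] + 1.5 * iqr]
  list(median = q[2], q1 = q[1], q3 = q[3], iqr = iqr, outliers = out)
}

#' Percent reduction relative to a reference
#'
#' 100 * (1 - value / reference).
#'
#' @param reference Positive reference value.
#' @param value Value to compare.
#' @return Reduction in percent (negative when `value > reference`).
#' @examples
#' percent_reduction(1.6, 0.10)  # 93.75, i.e. 94% at integer rounding
#' @export
percent_reduction <- function(reference, value) {
  if (reference <= 0) stop("percent_reduction: reference must be positive")
  100 * (1 - value / reference)
}

#' Average shim weights across a patient group
#'
#' Per channel: the amplitude is the arithmetic mean of the amplitudes; the
#' phase is the circular mean (argument of the mean unit phasor), which is
#' well defined at the 0/2pi seam. `mode = "arithmetic"` averages the wrapped
#' phase values directly, for comparison.
#'
#' @param weights_list List of [shim_weights()] with equal channel counts
#'   (>= 2 members).
#' @param mode "circular" (default) or "arithmetic" phase averaging.
#' @return A [shim_weights()].
#' @export
average_group_weights <- function(weights_list, mode = c("circular", "arithmetic")) {
  mode <- match.arg(mode)
  if (length(weights_list) < 2L)
    stop("average_group_weights: need at least 2 weight sets")
  ns <- vapply(weights_list, function(w) w$n_channels, integer(1))
  if (length(unique(ns)) != 1L)
    stop("average_group_weights: channel counts differ")
  N <- ns[1]
  A <- rowMeans(matrix(vapply(weights_list, function(w) w$amplitudes,
                              numeric(N)), nrow = N))
  if (mode == "circular") {
    Z <- rowMeans(matrix(vapply(weights_list, function(w) exp(1i * w$phases),
                                complex(N)), nrow = N))
    if (any(Mod(Z) < 1e-6)) stop("phase average undefined")
    phi <- Arg(Z)
  } else {
    phi <- rowMeans(matrix(vapply(weights_list, function(w) w$phases,
                                  numeric(N)), nrow = N))
  }
  shim_weights(A, phi)
}
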