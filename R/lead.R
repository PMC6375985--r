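#' DBS lead geometric model
#'
#' A lead is an ordered 3-D polyline from the proximal end (excess length
#' coiled at the skull) to the distal tip inside the brain. Geometry constants
#' follow a standard quadripolar DBS lead: outer diameter 1.27 mm, solid
#' central core 260 um, contact wall thickness 150 um, and a distal exposed
#' span carrying the four cylindrical electrode contacts.
#'
#' @param vertices n x 3 numeric matrix of world coordinates (m), ordered
#'   proximal to distal, n >= 2.
#' @param diameter Lead outer diameter (m).
#' @param core_diameter Central core diameter (m).
#' @param wall_thickness Contact wall thickness (m).
#' @param tip_span Arc length (m) of the distal un-insulated segment carrying
#'   the contacts (default 7.5 mm: four 1.5 mm contacts, 0.5 mm gaps).
#' @param length_bounds Permitted total arc-length range (m); `NULL` disables
#'   the check.
#' @param check_clearance If TRUE, verify that non-adjacent segments are
#'   separated by more than one lead diameter.
#' @return An object of class `lead_model`.
#' @export
lead_model <- function(vertices, diameter = 1.27e-3, core_diameter = 260e-6,
                       wall_thickness = 150e-6, tip_span = 7.5e-3,
                       length_bounds = NULL, check_clearance = FALSE) {
  vertices <- unname(as.matrix(vertices))
  if (ncol(vertices) != 3L || nrow(vertices) < 2L || any(!is.finite(vertices)))
    stop("lead_model: 'vertices' must be a finite n x 3 matrix with n >= 2")
  obj <- structure(list(vertices = vertices, diameter = diameter,
                        core_diameter = core_diameter,
                        wall_thickness = wall_thickness, tip_span = tip_span),
                   class = "lead_model")
  L <- lead_length(obj)
  if (!is.null(length_bounds) && (L < length_bounds[1] || L > length_bounds[2]))
    stop(sprintf("lead_model: arc length %.3f m outside bounds [%.3f, %.3f] m",
                 L, length_bounds[1], length_bounds[2]))
  if (check_clearance) {
    d <- lead_min_clearance(obj)
    if (d <= diameter)
      stop(sprintf("lead_model: non-adjacent segment clearance %.2f mm <= lead diameter",
                   d * 1e3))
  }
  obj
}

#' @export
print.lead_model <- function(x, ...) {
  cat(sprintf("<lead_model> %d vertices, length %.1f cm, tip at (%.1f, %.1f, %.1f) cm\n",
              nrow(x$vertices), 100 * lead_length(x),
              100 * x$vertices[nrow(x$vertices), 1],
              100 * x$vertices[nrow(x$vertices), 2],
              100 * x$vertices[nrow(x$vertices), 3]))
  invisible(x)
}

#' Total arc length of a lead (m)
#' @param lead A [lead_model()].
#' @export
lead_length <- function(lead) {
  d <- diff(lead$vertices)
  sum(sqrt(rowSums(d^2)))
}

#' Distal tip position (m)
#' @param lead A [lead_model()].
#' @export
lead_tip <- function(lead) lead$vertices[nrow(lead$vertices), ]

#' Midpoint of the exposed-contact span
#'
#' World point at arc length (total - tip_span / 2) from the proximal end,
#' the centre of the four-contact electrode segment.
#' @param lead A [lead_model()].
#' @export
lead_tip_midpoint <- function(lead) {
  point_at_arclength(lead, lead_length(lead) - lead$tip_span / 2)
}

#' Unit tangent at the distal tip
#' @param lead A [lead_model()].
#' @export
lead_tip_tangent <- function(lead) {
  n <- nrow(lead$vertices)
  t <- lead$vertices[n, ] - lead$vertices[n - 1, ]
  t / sqrt(sum(t^2))
}

point_at_arclength <- function(lead, s) {
  v <- lead$vertices
  seg <- sqrt(rowSums(diff(v)^2))
  cum <- c(0, cumsum(seg))
  s <- min(max(s, 0), cum[length(cum)])
  i <- findInterval(s, cum, rightmost.closed = TRUE)
  i <- min(i, length(seg))
  f <- if (seg[i] > 0) (s - cum[i]) / seg[i] else 0
  v[i, ] + f * (v[i + 1, ] - v[i, ])
}

#' Resample a lead polyline at uniform arc-length steps
#'
#' @param lead A [lead_model()].
#' @param ds Target step (m).
#' @return Matrix of points including both endpoints.
#' @export
lead_resample <- function(lead, ds) {
  L <- lead_length(lead)
  s <- seq(0, L, length.out = max(2L, ceiling(L / ds) + 1L))
  t(vapply(s, function(si) point_at_arclength(lead, si), numeric(3)))
}

#' Minimum distance between non-adjacent lead segments
#'
#' Brute-force pairwise segment-segment distance over all segment pairs that
#' are not contiguous along the lead. Because a finely sampled smooth curve
#' has index-neighbouring segments at arbitrarily small distances, adjacency
#' is defined by along-lead separation: two segments are compared only when
#' the arc length between them exceeds `min_arc_gap`. Used to enforce the
#' "clearance greater than the lead diameter" constraint on trajectories.
#'
#' @param lead A [lead_model()].
#' @param min_arc_gap Arc-length separation (m) below which two segments are
#'   considered contiguous and skipped (default 5 mm, a few lead diameters).
#' @return Minimum clearance (m); `Inf` when no eligible pair exists.
#' @export
lead_min_clearance <- function(lead, min_arc_gap = 5e-3) {
  v <- lead$vertices
  ns <- nrow(v) - 1L
  if (ns < 3L) return(Inf)
  seg <- sqrt(rowSums(diff(v)^2))
  cum <- c(0, cumsum(seg))            # arc length at each vertex
  dmin <- Inf
  for (i in seq_len(ns - 2L)) {
    j <- (i + 2L):ns
    j <- j[cum[j] - cum[i + 1L] > min_arc_gap]
    if (length(j) == 0L) next
    d <- segment_segment_distance(v[i, ], v[i + 1, ],
                                  v[j, , drop = FALSE], v[j + 1, , drop = FALSE])
    dmin <- min(dmin, d)
  }
  dmin
}

# Distance from segment (p1,p2) to segments (q1[k,],q2[k,]), vectorized over
# k (closest-point parameterization with clamped re-projection).
segment_segment_distance <- function(p1, p2, q1, q2) {
  d1 <- p2 - p1                       # length-3
  d2 <- q2 - q1                       # k x 3
  r <- sweep(q1, 2, p1, "-") * -1     # p1 - q1, k x 3
  a <- sum(d1 * d1)
  e <- rowSums(d2 * d2)
  f <- rowSums(d2 * r)
  c_ <- as.vector(r %*% d1)
  b <- as.vector(d2 %*% d1)
  denom <- a * e - b^2
  s <- ifelse(denom > 1e-30, pmin(pmax((b * f - c_ * e) / denom, 0), 1), 0)
  t <- ifelse(e > 1e-30, (b * s + f) / e, 0)
  tc <- pmin(pmax(t, 0), 1)
  # re-clamp s for the clamped t
  s <- pmin(pmax(ifelse(rep(a > 1e-30, length(tc)), (b * tc - c_) / a, 0), 0), 1)
  cp <- outer(s, d1) + matrix(p1, nrow(q1), 3, byrow = TRUE)
  cq <- q1 + d2 * tc
  sqrt(rowSums((cp - cq)^2))
}

#' Read / write lead trajectories as CSV
#'
#' One row per vertex, columns `x`, `y`, `z` in metres, header required.
#'
#' @param path File path.
#' @param lead A [lead_model()] (for writing).
#' @param ... Passed to [lead_model()] when reading.
#' @return `read_lead_csv()` returns a `lead_model`.
#' @export
read_lead_csv <- function(path, ...) {
  d <- utils::read.csv(path)
  if (!all(c("x", "y", "z") %in% names(d)))
    stop("read_lead_csv: CSV must have columns x, y, z (metres)")
  lead_model(as.matrix(d[, c("x", "y", "z")]), ...)
}

#' @rdname read_lead_csv
#' @export
write_lead_csv <- function(lead, path) {
  d <- as.data.frame(lead$vertices)
  names(d) <- c("x", "y", "z")
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}
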