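#' Generate a seeded synthetic DBS lead trajectory
#'
#' Emulates the geometry seen in implanted patients: the surgeon bundles the
#' excess lead length into a looped figure-eight pattern near the skull
#' vertex, and the distal segment penetrates to a lateralized deep-brain
#' target. The bundle is a four-turn figure-eight (Gerono lemniscate) lying in
#' a plane tangent to the skull, stacked slightly along the inward normal so
#' that crossing strands keep a clearance larger than the lead diameter
#' (1.27 mm). Total arc length is drawn in the 40-50 cm range. The
#' construction is fully deterministic given the seed.
#'
#' @param lateralization "left" or "right": hemisphere of the deep target.
#'   With the patient facing -y and z superior, the patient's left is +x.
#' @param seed Integer seed.
#' @param grid Optional [grid3d()]; only used to sanity-check that the
#'   trajectory stays inside the grid box.
#' @param n_turns Number of figure-eight turns (default 4).
#' @param length_range Total arc-length range to draw from (m).
#' @param points_per_turn Polyline resolution of the bundle.
#' @param max_attempts Clearance-repair attempts (pitch is widened on each)
#'   before giving up.
#' @return A [lead_model()].
#' @examples
#' lead <- generate_lead_trajectory("left", seed = 1)
#' lead_length(lead)   # between 0.40 and 0.50 m
#' @export
generate_lead_trajectory <- function(lateralization = c("left", "right"),
                                     seed, grid = NULL, n_turns = 4L,
                                     length_range = c(0.42, 0.48),
                                     points_per_turn = 48L,
                                     max_attempts = 10L) {
  lateralization <- match.arg(lateralization)
  if (missing(seed)) stop("generate_lead_trajectory: 'seed' is required")
  side <- if (lateralization == "left") 1 else -1

  draw <- with_local_seed(seed, list(
    L_target = stats::runif(1, length_range[1], length_range[2]),
    target = c(side * 0.012, -0.002, 0.002) + stats::runif(3, -2e-3, 2e-3),
    entry = c(side * 0.030, -0.010, 0.066) + stats::runif(3, -4e-3, 4e-3),
    bundle_swing = stats::runif(1, -0.6, 0.6),
    tilt = stats::runif(1, -0.2, 0.2)
  ))

  pitch <- 4e-3
  for (attempt in seq_len(max_attempts)) {
    verts <- build_lead_polyline(draw, n_turns, pitch, points_per_turn)
    lead <- lead_model(verts)
    if (lead_min_clearance(lead) > lead$diameter) {
      if (!is.null(grid)) {
        half <- grid$dims * grid$spacing / 2
        if (any(abs(t(verts) - grid$origin) > half))
          stop("generate_lead_trajectory: trajectory exits the grid box")
      }
      L <- lead_length(lead)
      if (L < 0.40 || L > 0.50)
        stop(sprintf("generate_lead_trajectory: length %.3f m outside 0.40-0.50 m", L))
      return(lead)
    }
    pitch <- pitch * 1.3
  }
  stop(sprintf(paste0("generate_lead_trajectory: could not achieve %.2f mm segment",
                      " clearance after %d pitch-widening attempts (seed %d)"),
               1.27, max_attempts, seed))
}

# Assemble bundle + exit connector + penetration polyline for one draw.
#
# The lemniscate's long axis (u2) points from the bundle centre toward the
# entry point, the bundle sits on the side of the entry away from the deep
# target, and the strand stack descends along the inward normal. The
# trajectory ends its final turn at the lobe extreme nearest the entry, runs
# radially past the bundle radius (w0), climbs out of the strand slab (w1)
# and reaches the entry point before penetrating to the target, so the
# connector never threads through the stacked crossings.
build_lead_polyline <- function(draw, n_turns, pitch, points_per_turn) {
  entry <- draw$entry
  target <- draw$target
  n_out <- entry / sqrt(sum(entry^2))
  ip <- function(w) { w <- w - sum(w * n_out) * n_out; w / sqrt(sum(w^2)) }
  t_ip <- ip(target - entry)               # in-plane direction toward target
  sw <- draw$bundle_swing                  # jitter around the away direction
  v0 <- cross3(n_out, t_ip)
  away <- -cos(sw) * t_ip + sin(sw) * v0
  centre <- entry + 0.020 * away - 0.010 * n_out
  u2 <- ip(entry - centre)                 # long axis, toward the entry
  # tilt the bundle plane slightly about the long axis
  v_flat <- cross3(n_out, u2)
  n_b <- cos(draw$tilt) * n_out + sin(draw$tilt) * v_flat
  v2 <- cross3(n_b, u2)

  penetr_len <- sqrt(sum((entry - target)^2))
  t_end <- (n_turns - 1L) * 2 * pi + pi / 2   # final lobe extreme on +u2 side
  r <- 0.014
  for (pass in 1:2) {
    tt <- seq(0, t_end, length.out = n_turns * points_per_turn + 1L)
    depth <- pitch * tt / (2 * pi)
    bundle <- matrix(centre, length(tt), 3, byrow = TRUE) +
      outer(r * sin(tt), u2) +
      outer(r * sin(tt) * cos(tt), v2) -
      outer(depth, n_b)
    d_end <- depth[length(depth)]
    h_e <- sum((entry - centre) * n_b)
    w0 <- centre + 1.8 * r * u2 - d_end * n_b
    w1 <- centre + 1.8 * r * u2 + h_e * n_b
    conn_len <- sqrt(sum((w0 - bundle[nrow(bundle), ])^2)) +
      sqrt(sum((w1 - w0)^2)) + sqrt(sum((entry - w1)^2))
    loop_len <- sum(sqrt(rowSums(diff(bundle)^2)))
    need <- draw$L_target - penetr_len - conn_len
    r <- r * need / loop_len
  }
  penetr <- t(sapply(seq(0, 1, length.out = 12L)[-1],
                     function(f) entry + f * (target - entry)))
  rbind(bundle, w0, w1, entry, penetr)
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}
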