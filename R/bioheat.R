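#' Stable explicit time step for the bioheat solver
#'
#' Forward-Euler stability bound for the 7-point diffusion stencil with a
#' safety factor of 0.5: dt = 0.5 * min over tissue of
#' (rho C / (2 k)) / (1/dx^2 + 1/dy^2 + 1/dz^2). In the diffusion-free limit
#' (k -> 0) the bound is unbounded and the configured cap is returned.
#'
#' @param tissue A [tissue_model()].
#' @param grid A [grid3d()] (defaults to the tissue's grid).
#' @param cap Upper bound on the returned step (s).
#' @return Time step in seconds.
#' @export
stable_timestep <- function(tissue, grid = tissue$grid, cap = 30) {
  if (any(grid$spacing <= 0)) stop("stable_timestep: degenerate spacing")
  active <- tissue$head_mask | tissue$insulation_mask
  rhoC <- tissue$rho[active] * tissue$C[active]
  k <- tissue$k[active]
  if (any(rhoC <= 0)) stop("stable_timestep: rho * C must be positive in tissue")
  inv_h2 <- sum(1 / grid$spacing^2)
  pos <- k > 0
  if (!any(pos)) return(cap)
  dt <- 0.5 * min(rhoC[pos] / (2 * k[pos])) / inv_h2
  min(dt, cap)
}

#' Finite-difference Pennes bioheat simulation
#'
#' Explicit forward-Euler integration of
#' rho C dT/dt = div(k grad T) + V_b rho C_b (T_b - T) + rho SAR + rho Q_m
#' on the voxel grid (7-point Laplacian in flux form with face-averaged
#' conductivity). Only head and insulation voxels are integrated; insulation
#' voxels use insulation properties with no perfusion or metabolic heat.
#' Surface voxels exchange heat with the ambient through a Robin condition
#' q = h (T_ambient - T) on each exposed face. The initial temperature is
#' uniform at body temperature.
#'
#' @param tissue A [tissue_model()].
#' @param sar A [raw_sar()] field (W/kg), or `NULL` for no RF source.
#' @param duration Simulated time (s).
#' @param dt Time step (s); defaults to [stable_timestep()]. Must not exceed
#'   the stability bound.
#' @param bc List: `ambient` (deg C, default 20), `h` (surface exchange
#'   coefficient, W/(m^2 K), default 10; use 0 for an insulated surface).
#' @param T0 Initial temperature (deg C, default body temperature 37).
#' @param n_snapshots Number of stored full-volume snapshots (>= 2).
#' @param tip Optional world point whose voxel temperature is recorded every
#'   step (the lead-tip probe).
#' @return An object of class `thermal_field`: snapshot list `T` (3-D arrays,
#'   deg C), `times`, the per-step `tip_series` (if `tip` given), `dt`, and
#'   the grid.
#' @export
pennes_simulate <- function(tissue, sar = NULL, duration, dt = NULL,
                            bc = list(ambient = 20, h = 10), T0 = 37,
                            n_snapshots = 9L, tip = NULL) {
  grid <- tissue$grid
  if (duration <= 0) stop("pennes_simulate: duration must be positive")
  dt_max <- stable_timestep(tissue, grid, cap = Inf)
  if (is.null(dt)) dt <- min(if (is.finite(dt_max)) dt_max else duration / 10,
                             duration / 4)
  if (dt > dt_max * (1 + 1e-9))
    stop(sprintf("pennes_simulate: dt = %.3g s exceeds stability bound %.3g s",
                 dt, dt_max))
  if (is.null(bc$ambient)) bc$ambient <- 20
  if (is.null(bc$h)) bc$h <- 10

  dims <- grid$dims
  active <- tissue$head_mask | tissue$insulation_mask
  rhoC <- tissue$rho * tissue$C
  src <- tissue$rho * tissue$Q_m               # W/m^3
  if (!is.null(sar)) src <- src + tissue$rho * sar$sar
  perf <- tissue$V_b * tissue$rho * tissue$C_b  # W/(m^3 K)

  n_steps <- max(1L, ceiling(duration / dt))
  dt <- duration / n_steps
  snap_at <- unique(round(seq(0, n_steps, length.out = max(2L, n_snapshots))))

  Tarr <- array(T0, dims)
  Tarr[!active] <- bc$ambient
  snaps <- list(array(T0, dims))
  times <- 0
  tip_idx <- NULL
  tip_series <- NULL
  if (!is.null(tip)) {
    ijk <- world_to_index(grid, tip)
    if (any(is.na(ijk))) stop("pennes_simulate: tip outside grid")
    tip_idx <- ijk
    tip_series <- numeric(n_steps + 1L)
    tip_series[1] <- T0
  }

  shift <- function(a, axis, by) {
    # shift array contents by `by` along axis, zero-filled
    out <- array(0, dim(a))
    n <- dim(a)[axis]
    idx_src <- list(1:dims[1], 1:dims[2], 1:dims[3])
    idx_dst <- idx_src
    if (by == 1L) { idx_dst[[axis]] <- 2:n; idx_src[[axis]] <- 1:(n - 1) }
    else { idx_dst[[axis]] <- 1:(n - 1); idx_src[[axis]] <- 2:n }
    out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
      a[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
    out
  }

  kk <- tissue$k
  act_n <- lapply(1:3, function(ax) list(p = shift(active, ax, 1L),
                                         m = shift(active, ax, -1L)))
  k_n <- lapply(1:3, function(ax) list(p = shift(kk, ax, 1L),
                                       m = shift(kk, ax, -1L)))
  face_k <- lapply(1:3, function(ax) list(
    p = ifelse(act_n[[ax]]$p, (kk + k_n[[ax]]$p) / 2, 0),
    m = ifelse(act_n[[ax]]$m, (kk + k_n[[ax]]$m) / 2, 0)))
  # number of exposed faces per active voxel, weighted by 1/h for Robin flux
  exposed <- array(0, dims)
  for (ax in 1:3) {
    exposed <- exposed +
      (!act_n[[ax]]$p) / grid$spacing[ax] + (!act_n[[ax]]$m) / grid$spacing[ax]
  }
  robin <- bc$h * exposed  # W/(m^3 K) when multiplied by (T_amb - T)

  for (step in seq_len(n_steps)) {
    lap <- array(0, dims)
    for (ax in 1:3) {
      Tp <- shift(Tarr, ax, 1L)
      Tm <- shift(Tarr, ax, -1L)
      lap <- lap + (face_k[[ax]]$p * (Tp - Tarr) +
                    face_k[[ax]]$m * (Tm - Tarr)) / grid$spacing[ax]^2
    }
    rhs <- lap + perf * (tissue$T_b - Tarr) + src + robin * (bc$ambient - Tarr)
    Tnew <- Tarr + dt * rhs / rhoC
    Tnew[!active] <- bc$ambient
    Tarr <- Tnew
    if (any(abs(Tarr[active]) > 200)) {
      bad <- which(abs(Tarr) > 200 & active, arr.ind = TRUE)[1, ]
      stop(sprintf("pennes_simulate: instability at voxel (%d, %d, %d)",
                   bad[1], bad[2], bad[3]))
    }
    if (!is.null(tip_idx)) tip_series[step + 1L] <- Tarr[tip_idx[1], tip_idx[2], tip_idx[3]]
    if (step %in% snap_at) {
      snaps[[length(snaps) + 1L]] <- Tarr
      times <- c(times, step * dt)
    }
  }
  structure(list(grid = grid, T = snaps, times = times, dt = dt,
                 duration = duration, tip_series = tip_series,
                 T0 = T0, bc = bc, active = active),
            class = "thermal_field")
}

#' @export
print.thermal_field <- function(x, ...) {
  last <- x$T[[length(x$T)]]
  cat(sprintf("<thermal_field> %d snapshots over %.0f s, dt %.3g s, max T %.2f degC\n",
              length(x$T), x$duration, x$dt, max(last[x$active])))
  invisible(x)
}

#' Peak temperature rise at the lead tip
#'
#' Maximum over stored times of T(tip voxel) - T(initial). Uses the per-step
#' tip probe series when the simulation recorded one, otherwise the stored
#' snapshots.
#'
#' @param thermal A `thermal_field` from [pennes_simulate()].
#' @param lead A [lead_model()]; the probe point is the exposed-tip midpoint.
#' @return Peak temperature increase (deg C).
#' @export
peak_tip_delta_t <- function(thermal, lead) {
  tipm <- lead_tip_midpoint(lead)
  ijk <- world_to_index(thermal$grid, tipm)
  if (any(is.na(ijk))) stop("peak_tip_delta_t: tip outside grid")
  if (!is.null(thermal$tip_series))
    return(max(thermal$tip_series) - thermal$T0)
  tip_t <- vapply(thermal$T, function(a) a[ijk[1], ijk[2], ijk[3]], numeric(1))
  max(tip_t) - thermal$T0
}
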