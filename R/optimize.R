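#' Optimization configuration
#'
#' Settings for the lambda-swept, safety-limited shim optimization. The cost
#' weighting lambda trades tip-power suppression (E-field term) against
#' transmit homogeneity (B1+ term); the sweep covers lambda = 0 (homogeneity
#' only) up to the value beyond which solutions no longer change
#' (approximately 6), on a 13-point grid by default. Solutions whose 1 g SAR
#' in the ROM exceeds `sar_limit` (0.4 W/kg) are discarded; among the
#' survivors the B1+ inhomogeneity threshold starts at 10% and is relaxed in
#' 5-point steps until a solution qualifies.
#'
#' @param lambda_grid Non-negative lambda values, ordered; must include 0 for
#'   a sweep.
#' @param sar_limit ROM 1 g SAR safety limit (W/kg).
#' @param cov_start,cov_step Initial COV acceptance threshold and relaxation
#'   step (fractions).
#' @param target_mean_b1 Normalization target for the VOI-mean |B1+| (tesla).
#' @param maxit Nelder-Mead iteration cap per start.
#' @param reltol Nelder-Mead relative convergence tolerance.
#' @param restarts Number of seeded perturbed restarts (besides the
#'   quadrature start and any warm start).
#' @param seed Integer seed for restart perturbations.
#' @param ratio_floor Relative floor on |E_quad|^2: ROM voxels whose
#'   quadrature E-field power is below `ratio_floor * max` are excluded from
#'   the ratio mean (guards the division at quadrature nulls).
#' @return An object of class `optimization_config`.
#' @export
optimization_config <- function(lambda_grid = seq(0, 6, length.out = 13),
                                sar_limit = 0.4, cov_start = 0.10,
                                cov_step = 0.05, target_mean_b1 = 1e-6,
                                maxit = 800, reltol = 1e-8, restarts = 3,
                                seed = 1, ratio_floor = 1e-12) {
  if (any(lambda_grid < 0)) stop("optimization_config: lambda values must be >= 0")
  if (sar_limit <= 0) stop("optimization_config: sar_limit must be positive")
  if (cov_start <= 0 || cov_start > 1 || cov_step <= 0)
    stop("optimization_config: COV thresholds must lie in (0, 1]")
  structure(list(lambda_grid = lambda_grid, sar_limit = sar_limit,
                 cov_start = cov_start, cov_step = cov_step,
                 target_mean_b1 = target_mean_b1, maxit = maxit,
                 reltol = reltol, restarts = restarts, seed = seed,
                 ratio_floor = ratio_floor),
            class = "optimization_config")
}

# Precomputed restriction of the maps to the voxels the cost touches.
# Everything the inner loop needs is dense small matrices.
shim_problem <- function(maps, voi, rom, cfg = optimization_config()) {
  stopifnot(inherits(maps, "coil_maps"))
  N <- maps$n_channels
  voi_idx <- which(voi$mask)
  rom_idx <- which(rom$mask)
  if (length(rom_idx) == 0L) stop("shim_problem: empty ROM")
  B1v <- maps$B1[voi_idx, , drop = FALSE]
  Er <- matrix(0 + 0i, length(rom_idx) * 3L, N)
  for (n in seq_len(N)) Er[, n] <- as.vector(maps$E[[n]][rom_idx, ])

  wq <- quadrature_weights(N)
  dq <- as_complex_drive(wq)
  muq <- mean(abs(B1v %*% dq))
  if (muq <= 0) stop("shim_problem: zero quadrature B1+ in the VOI")
  sq <- cfg$target_mean_b1 / muq
  eq <- matrix(Er %*% dq, ncol = 3L) * sq
  eq2 <- rowSums(Mod(eq)^2)
  floor_ <- cfg$ratio_floor * max(eq2)
  keep <- eq2 > floor_
  if (!any(keep)) stop("shim_problem: quadrature E-field vanishes over the ROM")
  list(N = N, B1v = B1v, Er = Er, n_rom = length(rom_idx),
       eq2 = eq2[keep], keep = keep, target = cfg$target_mean_b1)
}

# Cost terms for a complex drive vector, on a precomputed problem.
# Normalization to the target VOI-mean B1+ is applied inside, so the cost is
# invariant under global amplitude rescaling and global phase shifts.
problem_cost_terms <- function(problem, drive, lambda) {
  b <- abs(problem$B1v %*% drive)
  mu <- mean(b)
  if (mu <= 0) return(list(cost = Inf, cov = Inf, rom = Inf))
  covt <- sqrt(mean((b - mu)^2)) / mu
  sc <- problem$target / mu
  et <- matrix(problem$Er %*% drive, ncol = 3L)
  e2 <- (rowSums(Mod(et)^2) * sc^2)[problem$keep]
  romt <- mean(e2 / problem$eq2)
  list(cost = covt + lambda * romt, cov = covt, rom = romt)
}

#' Shim cost function
#'
#' The two-term objective: s_VOI(|B1+|) / mu_VOI(|B1+|)
#' + lambda * mu_ROM(|E_tot|^2 / |E_quad|^2), evaluated after normalizing the
#' weights to the target VOI-mean |B1+|. The ROM mean is over the pointwise
#' power ratio against the normalized quadrature field, with near-null
#' quadrature voxels excluded.
#'
#' @param weights A [shim_weights()].
#' @param maps A `coil_maps`.
#' @param voi,rom [region_mask()]s.
#' @param lambda Non-negative trade-off weight.
#' @param cfg An [optimization_config()].
#' @return List with `cost`, `cov_term`, `rom_term`.
#' @export
shim_cost <- function(weights, maps, voi, rom, lambda,
                      cfg = optimization_config()) {
  if (lambda < 0) stop("shim_cost: lambda must be >= 0")
  problem <- shim_problem(maps, voi, rom, cfg)
  ct <- problem_cost_terms(problem, as_complex_drive(weights), lambda)
  list(cost = ct$cost, cov_term = ct$cov, rom_term = ct$rom)
}

#' Quadrature-mode safety precheck
#'
#' Evaluates the normalized quadrature excitation's 1 g SAR in the ROM. If it
#' is already below the safety limit the implant couples negligibly and the
#' optimization is skipped (this also keeps near-zero quadrature E-fields out
#' of the cost's denominator).
#'
#' @param maps A `coil_maps`.
#' @param tissue A [tissue_model()].
#' @param lead A [lead_model()].
#' @param limit Safety limit (W/kg).
#' @param voi Optional VOI mask (defaults to [build_voi_mask()] on the grid).
#' @param rom Optional precomputed ROM mask.
#' @param cfg An [optimization_config()].
#' @return List with `decision` ("safe-skip" or "optimize"), the quadrature
#'   `rom_sar_1g`, and the normalized quadrature `weights`.
#' @export
quadrature_precheck <- function(maps, tissue, lead, limit = 0.4, voi = NULL,
                                rom = NULL, cfg = optimization_config()) {
  if (is.null(voi)) voi <- build_voi_mask(maps$grid)
  if (is.null(rom)) rom <- build_rom_mask(maps$grid, lead, tissue)
  wq <- normalize_weights(quadrature_weights(maps$n_channels), maps, voi,
                          cfg$target_mean_b1)
  fq <- combine_fields(wq, maps)
  s <- local_1g_sar(raw_sar(fq, tissue), tissue, lead, rom = rom)
  list(decision = if (s < limit) "safe-skip" else "optimize",
       rom_sar_1g = s, weights = wq)
}

#' Optimize shim weights at a fixed lambda
#'
#' Nelder-Mead over 2N-1 real parameters: N unconstrained amplitude
#' parameters mapped through |.| and N-1 phases with the first channel's
#' phase pinned to zero (removing the global-phase degeneracy). The search is
#' initialized at quadrature, with seeded perturbed restarts (and optional
#' warm starts); the best solution over all starts is returned, so the
#' result's cost never exceeds the quadrature start's.
#'
#' @param maps A `coil_maps` (N >= 2 channels).
#' @param voi,rom [region_mask()]s.
#' @param lambda Non-negative cost weighting.
#' @param cfg An [optimization_config()].
#' @param tissue,lead Needed to report ROM/whole-head SAR on the result;
#'   optional if `metrics = FALSE`.
#' @param problem Precomputed internal problem (for sweeps).
#' @param extra_starts List of additional parameter vectors to start from.
#' @param metrics If TRUE (default) evaluate full-grid SAR metrics.
#' @return An `optimization_result`: normalized `weights`, `lambda`,
#'   `cov_term`, `rom_term`, `cost`, `rom_sar_1g`, `whole_head_sar`,
#'   `fevals`, `converged`, and the raw parameter vector `par`.
#' @export
optimize_weights <- function(maps, voi, rom, lambda, cfg = optimization_config(),
                             tissue = NULL, lead = NULL, problem = NULL,
                             extra_starts = NULL, metrics = TRUE) {
  N <- maps$n_channels
  if (N < 2L) stop("optimize_weights: at least 2 channels are required")
  if (is.null(problem)) problem <- shim_problem(maps, voi, rom, cfg)

  par_to_drive <- function(par) {
    abs(par[1:N]) * exp(1i * c(0, par[(N + 1):(2 * N - 1)]))
  }
  fn <- function(par) {
    ct <- problem_cost_terms(problem, par_to_drive(par), lambda)
    if (!is.finite(ct$cost))
      stop(sprintf("optimize_weights: non-finite cost at parameters [%s]",
                   paste(signif(par, 4), collapse = ", ")))
    ct$cost
  }

  quad <- quadrature_weights(N)
  start0 <- c(quad$amplitudes, quad$phases[-1])
  starts <- c(list(start0), extra_starts)
  if (cfg$restarts > 0) {
    perturb <- with_local_seed(cfg$seed + round(1000 * lambda) %% 100000L,
      lapply(seq_len(cfg$restarts), function(i)
        start0 + c(stats::rnorm(N, 0, 0.35), stats::rnorm(N - 1, 0, 0.8))))
    starts <- c(starts, perturb)
  }

  best <- NULL
  fevals <- 0L
  for (st in starts) {
    opt <- stats::optim(st, fn, method = "Nelder-Mead",
                        control = list(maxit = cfg$maxit, reltol = cfg$reltol))
    fevals <- fevals + opt$counts[1]
    if (is.null(best) || opt$value < best$value) best <- opt
  }

  drive <- par_to_drive(best$par)
  amps <- abs(best$par[1:N])
  phases <- c(0, best$par[(N + 1):(2 * N - 1)])
  # normalize to the target VOI-mean B1+
  mu <- mean(abs(problem$B1v %*% drive))
  weights <- shim_weights(amps * (problem$target / mu), phases)
  ct <- problem_cost_terms(problem, drive, lambda)

  res <- structure(list(weights = weights, lambda = lambda,
                        cov_term = ct$cov, rom_term = ct$rom, cost = ct$cost,
                        rom_sar_1g = NA_real_, whole_head_sar = NA_real_,
                        fevals = fevals, converged = best$convergence == 0,
                        par = best$par),
                   class = "optimization_result")
  if (metrics) {
    if (is.null(tissue) || is.null(lead))
      stop("optimize_weights: 'tissue' and 'lead' are required for metrics")
    res <- add_result_metrics(res, maps, voi, rom, tissue, lead)
  }
  res
}

add_result_metrics <- function(res, maps, voi, rom, tissue, lead) {
  f <- combine_fields(res$weights, maps)
  s <- raw_sar(f, tissue)
  res$rom_sar_1g <- local_1g_sar(s, tissue, lead, rom = rom)
  res$whole_head_sar <- whole_head_sar(s, tissue)
  res
}

#' @export
print.optimization_result <- function(x, ...) {
  cat(sprintf(paste0("<optimization_result> lambda %.2f: cost %.4f ",
                     "(COV %.1f%%, ROM term %.3g), 1g SAR %.3g W/kg\n"),
              x$lambda, x$cost, 100 * x$cov_term, x$rom_term, x$rom_sar_1g))
  invisible(x)
}

#' Sweep the cost weighting lambda
#'
#' Runs [optimize_weights()] for each lambda in the grid (ordered), warm-
#' starting each optimization with the previous lambda's solution in addition
#' to the quadrature start and restarts, then makes a backward refinement
#' pass (each lambda re-optimized from its upper neighbour's solution when
#' that start evaluates better), so neighbouring solutions inform each other
#' in both directions. Per-lambda failures are recorded and the sweep
#' continues; it fails only if every lambda fails.
#'
#' @param maps A `coil_maps`.
#' @param voi,rom [region_mask()]s.
#' @param tissue,lead For result metrics.
#' @param cfg An [optimization_config()].
#' @return List of `optimization_result` (class `lambda_sweep`), ordered by
#'   lambda; failed entries carry the error message in `$error`.
#' @export
lambda_sweep <- function(maps, voi, rom, tissue, lead,
                         cfg = optimization_config()) {
  grid_l <- sort(cfg$lambda_grid)
  if (length(grid_l) == 0L) stop("lambda_sweep: empty lambda grid")
  problem <- shim_problem(maps, voi, rom, cfg)
  results <- vector("list", length(grid_l))
  prev_par <- NULL
  for (i in seq_along(grid_l)) {
    res <- tryCatch(
      optimize_weights(maps, voi, rom, grid_l[i], cfg, tissue, lead,
                       problem = problem,
                       extra_starts = if (is.null(prev_par)) NULL else list(prev_par)),
      error = function(e) structure(list(lambda = grid_l[i],
                                         error = conditionMessage(e)),
                                    class = "optimization_result"))
    if (is.null(res$error)) prev_par <- res$par
    results[[i]] <- res
  }
  # backward pass: let low-lambda solutions profit from high-lambda basins
  N <- maps$n_channels
  par_drive <- function(par) abs(par[1:N]) * exp(1i * c(0, par[(N + 1):(2 * N - 1)]))
  for (i in rev(seq_len(length(grid_l) - 1L))) {
    cur <- results[[i]]
    nxt <- results[[i + 1L]]
    if (!is.null(cur$error) || !is.null(nxt$error)) next
    warm <- problem_cost_terms(problem, par_drive(nxt$par), grid_l[i])
    if (warm$cost < cur$cost) {
      res <- tryCatch(
        optimize_weights(maps, voi, rom, grid_l[i], cfg, tissue, lead,
                         problem = problem,
                         extra_starts = list(nxt$par, cur$par)),
        error = function(e) NULL)
      if (!is.null(res) && res$cost < cur$cost) results[[i]] <- res
    }
  }
  if (all(vapply(results, function(r) !is.null(r$error), TRUE)))
    stop("lambda_sweep: every lambda failed")
  structure(results, class = c("lambda_sweep", "list"))
}

#' Select the final solution from a lambda sweep
#'
#' Two-stage rule: discard solutions whose ROM 1 g SAR exceeds the safety
#' limit; among the survivors, accept those with COV at or below the current
#' inhomogeneity threshold (starting at 10%) and return the one with minimum
#' ROM 1 g SAR. If none qualifies, relax the threshold by 5 percentage points
#' and repeat, up to 100%.
#'
#' @param results A `lambda_sweep` (or list of `optimization_result`).
#' @param cfg An [optimization_config()].
#' @return The selected `optimization_result`.
#' @export
select_solution <- function(results, cfg = optimization_config()) {
  ok <- Filter(function(r) is.null(r$error) && is.finite(r$rom_sar_1g), results)
  if (length(ok) == 0L) stop("select_solution: no usable results")
  safe <- Filter(function(r) r$rom_sar_1g <= cfg$sar_limit, ok)
  if (length(safe) == 0L) stop("no safe solution")
  thr <- cfg$cov_start
  repeat {
    fit <- Filter(function(r) r$cov_term <= thr, safe)
    if (length(fit) > 0L) {
      sars <- vapply(fit, function(r) r$rom_sar_1g, numeric(1))
      out <- fit[[which.min(sars)]]
      out$cov_threshold <- thr
      return(out)
    }
    if (thr >= 1) stop("no safe solution")
    thr <- min(1, thr + cfg$cov_step)
  }
}
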