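test_that("the cost reduces to COV at lambda 0 and is affine in lambda", {
  tp <- tiny_problem()
  w <- shim_weights(c(1, 0.8, 1.2, 0.9), c(0, 0.4, 1.2, 2.5))
  f <- combine_fields(normalize_weights(w, tp$maps, tp$voi), tp$maps)
  c0 <- shim_cost(w, tp$maps, tp$voi, tp$rom, lambda = 0)
  expect_equal(c0$cost, cov_b1(f, tp$voi), tolerance = 1e-12)
  c1 <- shim_cost(w, tp$maps, tp$voi, tp$rom, lambda = 1)
  c2 <- shim_cost(w, tp$maps, tp$voi, tp$rom, lambda = 2)
  expect_equal(c2$cost - c1$cost, c1$rom_term, tolerance = 1e-12)
  # quadrature weights give a unit pointwise ratio: cost = COV_quad + lambda
  wq <- quadrature_weights(4)
  cq <- shim_cost(wq, tp$maps, tp$voi, tp$rom, lambda = 3)
  expect_equal(cq$rom_term, 1, tolerance = 1e-12)
  expect_equal(cq$cost, cq$cov_term + 3, tolerance = 1e-12)
})

test_that("the cost is invariant under global phase and amplitude scaling", {
  tp <- tiny_problem()
  w <- shim_weights(c(1, 0.5, 1.5, 0.7), c(0, 1, 2, 3))
  base <- shim_cost(w, tp$maps, tp$voi, tp$rom, lambda = 2)
  wp <- shim_weights(w$amplitudes, w$phases + 0.913)
  ws <- shim_weights(7.3 * w$amplitudes, w$phases)
  expect_equal(shim_cost(wp, tp$maps, tp$voi, tp$rom, 2)$cost, base$cost,
               tolerance = 1e-12)
  expect_equal(shim_cost(ws, tp$maps, tp$voi, tp$rom, 2)$cost, base$cost,
               tolerance = 1e-12)
})

test_that("the quadrature precheck compares 1 g SAR to the limit", {
  tp <- tiny_problem()
  pre <- quadrature_precheck(tp$maps, tp$tissue, tp$lead, limit = 0.4,
                             voi = tp$voi, rom = tp$rom)
  expect_equal(pre$decision, "optimize")   # default gain couples strongly
  # with no coupling the tip region sees only background: safe
  tp0 <- tiny_problem(gain = 0)
  pre0 <- quadrature_precheck(tp0$maps, tp0$tissue, tp0$lead, limit = 0.4,
                              voi = tp0$voi, rom = tp0$rom)
  expect_equal(pre0$decision, "safe-skip")
  # an infinite limit always skips
  pinf <- quadrature_precheck(tp$maps, tp$tissue, tp$lead, limit = Inf,
                              voi = tp$voi, rom = tp$rom)
  expect_equal(pinf$decision, "safe-skip")
})

test_that("optimization never exceeds the quadrature start and is deterministic", {
  tp <- tiny_problem()
  cfg <- optimization_config(maxit = 300, restarts = 1, seed = 5)
  problem <- ptxshim:::shim_problem(tp$maps, tp$voi, tp$rom, cfg)
  lam <- 2
  quad_cost <- ptxshim:::problem_cost_terms(problem,
                                            as_complex_drive(quadrature_weights(4)),
                                            lam)$cost
  r1 <- optimize_weights(tp$maps, tp$voi, tp$rom, lam, cfg,
                         tissue = tp$tissue, lead = tp$lead)
  expect_lte(r1$cost, quad_cost)
  r2 <- optimize_weights(tp$maps, tp$voi, tp$rom, lam, cfg,
                         tissue = tp$tissue, lead = tp$lead)
  expect_identical(r1$par, r2$par)
  expect_identical(r1$cost, r2$cost)
  expect_error(optimize_weights(tiny_problem(n_channels = 1L)$maps,
                                tp$voi, tp$rom, 1, cfg), "2 channels")
})

test_that("proportional E maps admit an exact null the optimizer finds", {
  # channel 2's E map is twice channel 1's, so w2 = -w1 / 2 nulls the total
  # E-field analytically while the B1 maps (and the in-cost normalization)
  # stay finite. (Strictly identical maps would be degenerate here: the
  # two-channel quadrature reference is itself antiphase, so |E_quad|^2
  # vanishes identically -- the situation the safety precheck exists to
  # exclude from optimization.)
  tp <- tiny_problem(n_channels = 2L)
  dup <- tp$maps
  dup$E[[2]] <- 2 * dup$E[[1]]
  cfg <- optimization_config(maxit = 2000, restarts = 3, seed = 2,
                             reltol = 1e-12)
  res <- optimize_weights(dup, tp$voi, tp$rom, lambda = 50, cfg,
                          metrics = FALSE)
  expect_lt(res$rom_term, 1e-4)
  drive <- as_complex_drive(res$weights)
  expect_equal(Mod(drive[1] + 2 * drive[2]) / Mod(drive[1]), 0,
               tolerance = 0.05)
})

test_that("a 2-channel toy matches an exhaustive grid search", {
  # 2 channels, 2-voxel VOI, 1-voxel ROM: free parameters reduce to the
  # relative amplitude and relative phase of channel 2
  g <- grid3d(c(2, 2, 2), rep(0.01, 3))
  nv <- 8L
  set.seed(31)
  B1 <- matrix(complex(real = rnorm(nv * 2), imaginary = rnorm(nv * 2)), nv, 2)
  E <- list(matrix(complex(real = rnorm(nv * 3), imaginary = rnorm(nv * 3)), nv, 3),
            matrix(complex(real = rnorm(nv * 3), imaginary = rnorm(nv * 3)), nv, 3))
  maps <- structure(list(grid = g, n_channels = 2L, B1 = B1, E = E,
                         kappa = complex(2), frequency = 128e6,
                         cfg = synthetic_config()), class = "coil_maps")
  vm <- array(FALSE, c(2, 2, 2)); vm[1:2, 1, 1] <- TRUE
  rm_ <- array(FALSE, c(2, 2, 2)); rm_[1, 2, 2] <- TRUE
  voi <- region_mask(g, vm, "VOI"); rom <- region_mask(g, rm_, "ROM")
  lam <- 1.5
  grid_cost <- function(a2, p2)
    shim_cost(shim_weights(c(1, a2), c(0, p2)), maps, voi, rom, lam)$cost
  amps <- seq(0, 2, by = 0.01)
  phs <- seq(0, 2 * pi - 0.01, by = 0.01)
  best <- Inf
  problem <- ptxshim:::shim_problem(maps, voi, rom, optimization_config())
  for (a2 in amps) {
    drv <- rbind(rep(1 + 0i, length(phs)), a2 * exp(1i * phs))
    b <- abs(problem$B1v %*% drv)                # 2 x nph
    mu <- colMeans(b)
    covt <- sqrt(colMeans(sweep(b, 2, mu)^2)) / mu
    sc <- problem$target / mu
    et <- problem$Er %*% drv                     # (3) x nph
    e2 <- colSums(Mod(et)^2) * sc^2
    cost <- covt + lam * e2 / problem$eq2
    best <- min(best, min(cost))
  }
  cfg <- optimization_config(maxit = 3000, restarts = 5, seed = 3,
                             reltol = 1e-12)
  res <- optimize_weights(maps, voi, rom, lam, cfg, metrics = FALSE)
  expect_lte(res$cost, best + 1e-4)
  expect_equal(res$cost, best, tolerance = 0.02)
})

test_that("lambda sweep is ordered, complete, and monotone at the ends", {
  tp <- tiny_problem()
  cfg <- optimization_config(maxit = 400, restarts = 1, seed = 4)
  sw <- lambda_sweep(tp$maps, tp$voi, tp$rom, tp$tissue, tp$lead, cfg)
  expect_length(sw, 13L)
  expect_equal(sw[[1]]$lambda, 0)
  covs <- vapply(sw, function(r) r$cov_term, numeric(1))
  sars <- vapply(sw, function(r) r$rom_sar_1g, numeric(1))
  # the lambda = 0 result optimizes homogeneity alone
  expect_true(all(covs[1] <= covs + 1e-6))
  # the largest lambda suppresses tip SAR at least as well as lambda = 0
  expect_lte(sars[13], sars[1])
})

test_that("solution selection applies the SAR limit then relaxes the COV threshold", {
  mk <- function(sar, cov, lam = 1)
    structure(list(lambda = lam, cov_term = cov, rom_term = 0.1, cost = cov,
                   rom_sar_1g = sar, whole_head_sar = 0.2,
                   weights = quadrature_weights(2)),
              class = "optimization_result")
  cfg <- optimization_config()
  # a single safe, homogeneous solution is selected at the first threshold
  s1 <- select_solution(list(mk(0.2, 0.08)), cfg)
  expect_equal(s1$rom_sar_1g, 0.2)
  expect_equal(s1$cov_threshold, 0.10)
  # none below 10%: threshold relaxes to 15% and the min-SAR survivor wins
  s2 <- select_solution(list(mk(0.2, 0.12), mk(0.3, 0.14)), cfg)
  expect_equal(s2$rom_sar_1g, 0.2)
  expect_equal(s2$cov_threshold, 0.15)
  # nothing under the SAR limit
  expect_error(select_solution(list(mk(0.9, 0.05)), cfg), "no safe solution")
})
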