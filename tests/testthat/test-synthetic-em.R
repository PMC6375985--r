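test_that("coil arrays are laid out 2*pi/N apart with the stated arc lengths", {
  a4 <- coil_array(4L)
  expect_equal(a4$azimuths, c(0, pi / 2, pi, 3 * pi / 2))
  expect_equal(a4$arc_length, 0.196)
  a8 <- coil_array(8L)
  expect_equal(a8$arc_length, 0.098)
  expect_equal(diff(a8$azimuths)[1], pi / 4)
  a1 <- coil_array(1L)
  expect_equal(a1$azimuths, 0)
  expect_error(coil_array(3L), "n_channels")
  expect_error(coil_array(4L, arc_length = 0.25), "overlap")
  # each element is a closed loop: segment vectors sum to zero
  dl_sum <- colSums(a4$elements[[1]]$dl)
  expect_equal(dl_sum, c(0, 0, 0), tolerance = 1e-12)
})

test_that("head phantom carries homogeneous brain-mimicking properties", {
  g <- tiny_grid(12L, 0.008)
  ph <- generate_head_phantom(g, radii = c(0.03, 0.035, 0.03))
  expect_true(all(ph$sigma[ph$head_mask] == 0.69))
  expect_true(all(ph$sigma[!ph$head_mask] == 0))
  expect_equal(ph$eps_r, 67)
  # mass equals rho * voxel volume * voxel count (direct summation oracle)
  expect_equal(head_mass(ph), 1000 * voxel_volume(g) * sum(ph$head_mask))
  expect_error(generate_head_phantom(g, radii = c(0, 0, 0)), "positive|radii")
  expect_error(generate_head_phantom(g, radii = c(1, 1, 1)), "fit")
})

test_that("synthetic lead trajectories satisfy their geometric contract", {
  for (s in c(3L, 8L, 21L)) {
    lead <- generate_lead_trajectory("left", seed = s)
    L <- lead_length(lead)
    expect_gte(L, 0.40); expect_lte(L, 0.50)
    expect_gt(lead_min_clearance(lead), 1.27e-3)
  }
  l1 <- generate_lead_trajectory("right", seed = 5L)
  l2 <- generate_lead_trajectory("right", seed = 5L)
  expect_identical(l1$vertices, l2$vertices)
  # lateralization controls the tip hemisphere (patient-left is +x)
  expect_lt(lead_tip(generate_lead_trajectory("right", seed = 2L))[1], 0)
  expect_gt(lead_tip(generate_lead_trajectory("left", seed = 2L))[1], 0)
})

test_that("field maps are strictly linear in the channel drives", {
  tp <- tiny_problem()
  w1 <- shim_weights(c(1, 0.5, 2, 0.2), c(0, 1, 2, 3))
  w2 <- shim_weights(c(0.3, 1, 0.1, 1.5), c(2, 0.5, 1, 0))
  f1 <- combine_fields(w1, tp$maps)
  f2 <- combine_fields(w2, tp$maps)
  wsum <- as_complex_drive(w1) + as_complex_drive(w2)
  fsum <- combine_fields(shim_weights(Mod(wsum), Arg(wsum)), tp$maps)
  expect_equal(fsum$E, f1$E + f2$E, tolerance = 1e-12)
  expect_equal(fsum$B1, f1$B1 + f2$B1, tolerance = 1e-12)
  # doubling drive doubles both fields exactly
  fd <- combine_fields(shim_weights(2 * w1$amplitudes, w1$phases), tp$maps)
  expect_equal(fd$E, 2 * f1$E, tolerance = 1e-14)
  expect_equal(fd$B1, 2 * f1$B1, tolerance = 1e-14)
})

test_that("zero coupling gain reduces to the background-only maps", {
  tp <- tiny_problem()
  cfg0 <- synthetic_config(coupling_gain = 0)
  m0 <- compute_coil_maps(tp$coils, tp$tissue, tp$lead, tp$grid, cfg0)
  mbg <- compute_coil_maps(tp$coils, tp$tissue, NULL, tp$grid, cfg0)
  for (n in 1:4) expect_equal(m0$E[[n]], mbg$E[[n]], tolerance = 1e-14)
})

test_that("coupling matches an independent fine-step quadrature oracle", {
  tp <- tiny_problem()
  cfg_fine <- tp$cfg
  cfg_fine$lead_step <- tp$cfg$lead_step / 10
  for (n in c(1L, 3L)) {
    lp <- lead_resample(tp$lead, cfg_fine$lead_step)
    seg <- diff(lp); ds <- sqrt(rowSums(seg^2)); tang <- seg / ds
    mids <- (lp[-1, ] + lp[-nrow(lp), ]) / 2
    L <- sum(ds); s_mid <- cumsum(ds) - ds / 2
    omega <- 2 * pi * tp$maps$frequency
    ba <- ptxshim:::biot_savart_BA(tp$coils$elements[[n]], mids)
    Et <- -1i * omega * tp$cfg$e_scale * rowSums(ba$A * tang)
    w <- exp(-(L - s_mid) / tp$cfg$attenuation_length) *
      exp(-2i * pi * (L - s_mid) / tp$cfg$coupling_wavelength)
    kap <- sum(Et * w * ds)
    # midpoint-rule refinement converges at ~4e-5 relative per decade of step
    expect_lt(Mod(tp$maps$kappa[n] - kap) / Mod(kap), 1e-3)
  }
})

test_that("identical generator config and seed give bit-identical maps", {
  tp1 <- tiny_problem(seed_cfg = 7L)
  tp2 <- tiny_problem(seed_cfg = 7L)
  expect_identical(tp1$maps$B1, tp2$maps$B1)
  expect_identical(tp1$maps$E, tp2$maps$E)
})

test_that("tip hot spot dominates the background SAR distribution", {
  tp <- tiny_problem()
  wq <- normalize_weights(quadrature_weights(4L), tp$maps, tp$voi)
  s <- raw_sar(combine_fields(wq, tp$maps), tp$tissue)
  ijk <- world_to_index(tp$grid, lead_tip_midpoint(tp$lead))
  tip_sar <- s$sar[ijk[1], ijk[2], ijk[3]]
  bg <- quantile(s$sar[tp$tissue$head_mask], 0.95)
  expect_gt(tip_sar, bg)
})

test_that("background coupling reuse equals direct map computation", {
  tp <- tiny_problem()
  mbg <- compute_coil_maps(tp$coils, tp$tissue, NULL, tp$grid, tp$cfg)
  m2 <- add_lead_coupling(mbg, tp$coils, tp$lead)
  expect_equal(m2$kappa, tp$maps$kappa, tolerance = 1e-12)
  for (n in 1:4) expect_equal(m2$E[[n]], tp$maps$E[[n]], tolerance = 1e-12)
  expect_error(add_lead_coupling(m2, tp$coils, tp$lead), "already")
})

test_that("rigid transforms are isometries and compose correctly", {
  lead <- generate_lead_trajectory("left", seed = 4L)
  tid <- rigid_transform()
  expect_equal(apply_rigid_transform(lead, tid)$vertices, lead$vertices)
  tr <- rigid_transform(c(0.2, -0.1, 0.3), c(0.01, 0.02, -0.01))
  lt <- apply_rigid_transform(lead, tr)
  expect_equal(lead_length(lt), lead_length(lead), tolerance = 1e-9)
  dd <- function(v) sqrt(rowSums(diff(v)^2))
  expect_equal(dd(lt$vertices), dd(lead$vertices), tolerance = 1e-9)
  # composition equals single composed-matrix application
  t1 <- rigid_transform(c(0.1, 0.2, -0.1), c(0.01, 0, 0.005))
  t2 <- rigid_transform(c(-0.05, 0.15, 0.2), c(-0.003, 0.01, 0))
  lc <- apply_rigid_transform(apply_rigid_transform(lead, t2), t1)
  tc <- compose_transforms(t1, t2)
  lm <- apply_rigid_transform(lead, tc)
  expect_equal(lc$vertices, lm$vertices, tolerance = 1e-12)
})

test_that("transformed phantoms stay ellipsoids and respect grid bounds", {
  g <- grid3d(c(24, 24, 24), rep(0.01, 3))
  ph <- generate_head_phantom(g, radii = c(0.06, 0.07, 0.065))
  pht <- apply_rigid_transform(ph, rigid_transform(c(0.1, 0, 0), c(0.01, 0, 0)))
  expect_gt(sum(pht$head_mask), 0.9 * sum(ph$head_mask))
  expect_error(apply_rigid_transform(ph, rigid_transform(translation = c(0.1, 0, 0))),
               "exits grid")
})

test_that("random rigid shifts sample inside the stated bounds", {
  for (s in 1:200) {
    tr <- random_rigid_transform(s)
    expect_true(all(abs(tr$angles) <= 10 * pi / 180))
    expect_true(all(abs(tr$t) <= 0.04))
  }
  expect_identical(random_rigid_transform(3)$t, random_rigid_transform(3)$t)
})
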