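test_that("grid3d validates inputs and exposes voxel geometry", {
  g <- grid3d(c(4, 5, 6), c(0.01, 0.02, 0.03), origin = c(0.1, 0, -0.1))
  expect_equal(voxel_volume(g), 0.01 * 0.02 * 0.03)
  expect_equal(length(axis_coords(g, 2)), 5L)
  expect_equal(mean(axis_coords(g, 1)), 0.1)
  p <- voxel_coords(g)
  expect_equal(nrow(p), 4 * 5 * 6)
  ijk <- world_to_index(g, index_to_world(g, c(2, 3, 4)))
  expect_identical(ijk, c(2L, 3L, 4L))
  expect_true(all(is.na(world_to_index(g, c(10, 10, 10)))))
  expect_error(grid3d(c(1, 4, 4)), "dims")
  expect_error(grid3d(c(4, 4, 4), c(0, 1, 1)), "spacing")
})

test_that("VOI mask matches its analytic membership rule", {
  g <- grid3d(c(40, 40, 30), c(0.005, 0.005, 0.005))
  voi <- build_voi_mask(g)
  # the stated column centre is inside
  ci <- world_to_index(g, c(-0.005, 0.01, 0.03))
  expect_true(voi$mask[ci[1], ci[2], ci[3]])
  # a point offset 6.2 cm in x (beyond the 6 cm semi-axis) is outside
  co <- world_to_index(g, c(0.057, 0.01, 0.03))
  expect_false(voi$mask[co[1], co[2], co[3]])
  expect_error(build_voi_mask(g, centre = c(10, 10, 10)), "empty VOI")
  expect_error(build_voi_mask(g, rx = -1), "positive")
})

test_that("VOI mask agrees with a brute-force point-in-region oracle", {
  g <- grid3d(c(12, 12, 12), c(0.008, 0.009, 0.007))
  set.seed(42)
  for (rep in 1:20) {
    centre <- runif(3, -0.02, 0.02)
    rx <- runif(1, 0.01, 0.04); ry <- runif(1, 0.01, 0.04)
    len <- runif(1, 0.01, 0.06)
    got <- tryCatch(sum(build_voi_mask(g, centre, rx, ry, len)$mask),
                    error = function(e) 0L)
    expect_equal(got, oracle_voi_count(g, centre, rx, ry, len))
  }
})

test_that("ROM cube encloses at least 1 g and is tight to one shell", {
  g <- tiny_grid(12L, 0.004)        # 64 mg per voxel at rho = 1000
  tissue <- generate_head_phantom(g, radii = c(0.022, 0.022, 0.022))
  lead <- tiny_lead(from = c(0, 0, 0.02))
  rom <- build_rom_mask(g, lead, tissue)
  dv <- voxel_volume(g)
  mass <- region_mass(rom, tissue)
  expect_gte(mass, 1e-3)
  # the mask is the cube intersected with tissue; check the tip voxel is in
  ijk <- world_to_index(g, lead_tip_midpoint(lead))
  expect_true(rom$mask[ijk[1], ijk[2], ijk[3]])
  # removing the outermost shell (shrinking the cube by one voxel per side)
  # must fall below 1 g: rebuild with the inner cube radius
  idx <- which(rom$mask, arr.ind = TRUE)
  r <- max(abs(sweep(idx, 2, ijk)))
  expect_gte(r, 1L)
  inner <- array(FALSE, g$dims)
  rng <- lapply(1:3, function(a) max(1, ijk[a] - r + 1):min(g$dims[a], ijk[a] + r - 1))
  inner[rng[[1]], rng[[2]], rng[[3]]] <- TRUE
  inner_mass <- sum(tissue$rho[inner & tissue$head_mask]) * dv
  expect_lt(inner_mass, 1e-3)
})

test_that("ROM construction enforces its preconditions", {
  g <- tiny_grid(10L, 0.01)
  tissue <- generate_head_phantom(g, radii = rep(0.035, 3))
  outside <- lead_model(rbind(c(0, 0, 0.049), c(0.002, 0, 0.049)))
  expect_error(build_rom_mask(g, outside, tissue), "outside head")
  # a head lighter than 1 g
  feather <- generate_head_phantom(g, radii = rep(0.035, 3), rho = 1e-4)
  expect_error(build_rom_mask(g, tiny_lead(), feather), "less than")
})

test_that("Hampel filter implements the median/MAD replacement rule", {
  expect_equal(hampel_filter(c(2, 2, 2, 2, 2)), c(2, 2, 2, 2, 2))
  expect_equal(hampel_filter(c(1, 1, 1, 100, 1, 1, 1)), rep(1, 7))
  expect_equal(hampel_filter(1:5, k = 3), as.numeric(1:5))
  expect_error(hampel_filter(numeric(0)), "empty")
  expect_error(hampel_filter(1:5, window = 4), "odd")
  set.seed(7)
  for (rep in 1:10) {
    x <- rnorm(25)
    x[sample(25, 2)] <- x[sample(25, 2)] + 40
    w <- sample(c(3, 5, 7), 1)
    expect_equal(hampel_filter(x, w, 3), oracle_hampel(x, w, 3))
  }
})

test_that("Hampel filter is idempotent on its own output for isolated spikes", {
  # the solver-despiking use case: smooth field values with sparse spikes
  x <- sin(seq(0, 3 * pi, length.out = 60))
  x[c(12, 37)] <- x[c(12, 37)] + c(40, -25)
  y <- hampel_filter(x, 5, 3)
  expect_equal(hampel_filter(y, 5, 3), y)
  expect_lt(max(abs(y - sin(seq(0, 3 * pi, length.out = 60)))), 0.2)
})

test_that("volume Hampel despikes along all three axes and preserves phase", {
  a <- array(1, c(6, 6, 6))
  a[3, 3, 3] <- 50
  f <- hampel_filter_volume(a)
  expect_equal(f[3, 3, 3], 1)
  expect_equal(f, array(1, c(6, 6, 6)))
  z <- array(complex(modulus = 1, argument = 0.3), c(6, 6, 6))
  z[2, 2, 2] <- complex(modulus = 80, argument = 0.3)
  fz <- hampel_filter_volume(z)
  expect_equal(Arg(fz[2, 2, 2]), 0.3, tolerance = 1e-12)
  expect_equal(Mod(fz[2, 2, 2]), 1, tolerance = 1e-12)
})

test_that("lead model computes arc length, tip geometry and clearance", {
  v <- rbind(c(0, 0, 0), c(0.1, 0, 0), c(0.1, 0.1, 0))
  lead <- lead_model(v, tip_span = 0.05)
  expect_equal(lead_length(lead), 0.2)
  expect_equal(lead_tip(lead), c(0.1, 0.1, 0))
  expect_equal(lead_tip_midpoint(lead), c(0.1, 0.075, 0))
  expect_equal(lead_tip_tangent(lead), c(0, 1, 0))
  expect_error(lead_model(matrix(0, 1, 3)), "n >= 2")
  expect_error(lead_model(v, length_bounds = c(0.3, 0.5)), "outside bounds")
  # a hairpin passing 0.5 mm from the first segment violates clearance
  hp <- rbind(c(0, 0, 0), c(0.1, 0, 0), c(0.1, 0.02, 0), c(0, 0.0005, 0.0005))
  expect_lt(lead_min_clearance(lead_model(hp), min_arc_gap = 1e-3), 1.27e-3)
})
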