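# Shared fixtures (built in code) and independent brute-force oracles.

tiny_grid <- function(n = 10L, sp = 0.01) grid3d(rep(n, 3), rep(sp, 3))

# A slanted lead descending into the head; the lateral offset keeps its
# tangential E-field projection away from the array's symmetry null on the
# cylinder axis. Far smaller than a clinical lead but tip-span capable.
tiny_lead <- function(tip = c(0.004, -0.004, -0.002),
                      from = c(0.014, 0.009, 0.043)) {
  s <- seq(0, 1, length.out = 10L)
  lead_model(outer(1 - s, from) + outer(s, tip))
}

# Small self-consistent problem: head phantom, VOI, lead, 4-channel maps.
tiny_problem <- function(n_channels = 4L, gain = 5300, n = 10L, sp = 0.01,
                         seed_cfg = NULL) {
  grid <- tiny_grid(n, sp)
  half <- n * sp / 2
  tissue <- generate_head_phantom(grid, radii = rep(0.72 * half, 3))
  lead <- tiny_lead(from = c(0, 0, 0.9 * half))
  tissue <- add_lead_insulation(tissue, lead)
  voi <- build_voi_mask(grid, centre = c(0, 0, 0), rx = 0.6 * half,
                        ry = 0.6 * half, length = 0.8 * half)
  coils <- coil_array(n_channels, segments_per_loop = 16L)
  cfg <- synthetic_config(coupling_gain = gain, seed = seed_cfg)
  maps <- compute_coil_maps(coils, tissue, lead, grid, cfg)
  rom <- build_rom_mask(grid, lead, tissue)
  list(grid = grid, tissue = tissue, lead = lead, voi = voi, rom = rom,
       coils = coils, maps = maps, cfg = cfg)
}

# Independent window-by-window evaluation of the Hampel rule.
oracle_hampel <- function(x, window = 5L, k = 3) {
  h <- window %/% 2L
  vapply(seq_along(x), function(i) {
    w <- x[seq(max(1L, i - h), min(length(x), i + h))]
    m <- median(w)
    s <- 1.4826 * median(abs(w - m))
    if ((s == 0 && x[i] != m) || (s > 0 && abs(x[i] - m) > k * s)) m else x[i]
  }, numeric(1))
}

# Mass-weighted region average by explicit voxel loop.
oracle_mass_avg <- function(sar_arr, mask, rho_arr) {
  num <- 0; den <- 0
  idx <- which(mask, arr.ind = TRUE)
  for (r in seq_len(nrow(idx))) {
    i <- idx[r, 1]; j <- idx[r, 2]; k <- idx[r, 3]
    num <- num + sar_arr[i, j, k] * rho_arr[i, j, k]
    den <- den + rho_arr[i, j, k]
  }
  num / den
}

# Exact signed-rank two-sided p by direct enumeration (independent of the
# package's vectorized version: loops over assignments explicitly).
oracle_wilcoxon_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  centre <- n * (n + 1) / 4
  count <- 0L
  for (m in 0:(2^n - 1)) {
    bits <- as.integer(intToBits(m))[1:n]
    Wm <- sum(r[bits == 1L])
    if (abs(Wm - centre) >= abs(W - centre) - 1e-9) count <- count + 1L
  }
  count / 2^n
}

# Brute-force membership re-test of the elliptical-column VOI.
oracle_voi_count <- function(grid, centre, rx, ry, len) {
  cnt <- 0L
  for (i in seq_len(grid$dims[1])) for (j in seq_len(grid$dims[2]))
    for (k in seq_len(grid$dims[3])) {
      p <- index_to_world(grid, c(i, j, k))
      if (((p[1] - centre[1]) / rx)^2 + ((p[2] - centre[2]) / ry)^2 <= 1 &&
          abs(p[3] - centre[3]) <= len / 2) cnt <- cnt + 1L
    }
  cnt
}

# The default study configuration, with the bioheat runs disabled where a
# test only needs SAR/COV. Cohort-level objects are cached per session so
# the cohort-pattern tests share one run.
cached_cohort <- local({
  env <- new.env()
  function() {
    if (is.null(env$cohort)) env$cohort <- run_cohort(study_config())
    env$cohort
  }
})
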