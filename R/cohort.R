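#' Study configuration for the synthetic cohort
#'
#' Bundles every setting of the desk-scale study reproduction: grid, phantom,
#' coil configurations, surrogate coupling, optimization, thermal exposure
#' and cohort composition. Defaults mirror the study design: nine patients
#' (five left-, four right-lateralized implants), a birdcage reference plus
#' 4- and 8-channel pTx, and a 13-point lambda sweep. The RF exposure for the
#' temperature estimate is the steady optimized SAR field applied for
#' `thermal$duration` seconds (default 360 s).
#'
#' @param grid_dims,grid_spacing Study grid (voxels, metres).
#' @param ptx_channels pTx channel counts to optimize.
#' @param n_left,n_right Cohort composition by implant lateralization.
#' @param base_seed Seed from which per-patient seeds are derived.
#' @param synthetic A [synthetic_config()].
#' @param optimization An [optimization_config()].
#' @param thermal List: `duration` (s), `bc` (see [pennes_simulate()]).
#' @param e_scale_by_config Named per-configuration overrides of the
#'   surrogate's background E-field scale. Each coil assembly is tuned and
#'   matched separately, so the degree of conservative-field cancellation is
#'   configuration-specific; the defaults are calibrated once so each
#'   configuration's normalized quadrature whole-head SAR sits at the
#'   0.1-0.3 W/kg order expected for a head transmit coil.
#' @return Nested configuration list of class `study_config`.
#' @export
study_config <- function(grid_dims = c(32L, 32L, 32L),
                         grid_spacing = c(0.008, 0.008, 0.008),
                         ptx_channels = c(4L, 8L),
                         n_left = 5L, n_right = 4L, base_seed = 1000L,
                         synthetic = synthetic_config(),
                         optimization = optimization_config(),
                         thermal = list(duration = 360,
                                        bc = list(ambient = 20, h = 10)),
                         e_scale_by_config = c(birdcage = 0.0038,
                                               ptx4 = 0.134, ptx8 = 0.040)) {
  structure(list(grid_dims = grid_dims, grid_spacing = grid_spacing,
                 ptx_channels = as.integer(ptx_channels),
                 n_left = as.integer(n_left), n_right = as.integer(n_right),
                 base_seed = as.integer(base_seed), synthetic = synthetic,
                 optimization = optimization, thermal = thermal,
                 e_scale_by_config = e_scale_by_config),
            class = "study_config")
}

#' Precompute cohort-shared assets
#'
#' The head phantom, VOI and per-configuration background field maps depend
#' only on the study configuration, not on the patient, so a cohort computes
#' them once. Configuration names are `"birdcage"` (16-element fixed
#' quadrature reference) and `"ptx<N>"`.
#'
#' @param cfg A [study_config()].
#' @return List with `grid`, `phantom`, `voi`, `coils` and background `maps`
#'   per configuration.
#' @export
make_study_assets <- function(cfg = study_config()) {
  grid <- grid3d(cfg$grid_dims, cfg$grid_spacing)
  phantom <- generate_head_phantom(grid)
  voi <- build_voi_mask(grid)
  coils <- c(list(birdcage = birdcage_array()),
             stats::setNames(lapply(cfg$ptx_channels, coil_array),
                             paste0("ptx", cfg$ptx_channels)))
  maps <- lapply(names(coils), function(nm) {
    syn <- cfg$synthetic
    if (!is.null(cfg$e_scale_by_config) && nm %in% names(cfg$e_scale_by_config))
      syn$e_scale <- unname(cfg$e_scale_by_config[nm])
    compute_coil_maps(coils[[nm]], phantom, lead = NULL, grid, syn)
  })
  names(maps) <- names(coils)
  list(grid = grid, phantom = phantom, voi = voi, coils = coils, maps = maps)
}

#' Build one synthetic patient
#'
#' A seeded lead trajectory, the phantom with the lead's insulation
#' voxelized in, the tip ROM, and per-configuration field maps with this
#' lead's coupling attached.
#'
#' @param assets From [make_study_assets()].
#' @param lateralization "left" or "right".
#' @param seed Integer seed for the trajectory.
#' @param cfg A [study_config()].
#' @return List with `lead`, `tissue`, `rom`, `maps` (per configuration),
#'   `lateralization`, `seed`.
#' @export
synthetic_patient <- function(assets, lateralization, seed, cfg = study_config()) {
  lead <- generate_lead_trajectory(lateralization, seed = seed, grid = assets$grid)
  tissue <- add_lead_insulation(assets$phantom, lead)
  rom <- build_rom_mask(assets$grid, lead, tissue)
  maps <- lapply(names(assets$maps), function(nm)
    add_lead_coupling(assets$maps[[nm]], assets$coils[[nm]], lead))
  names(maps) <- names(assets$maps)
  list(lead = lead, tissue = tissue, rom = rom, maps = maps,
       lateralization = lateralization, seed = seed)
}

#' Evaluate the four study metrics for a weight set
#'
#' ROM 1 g SAR, COV of |B1+| over the VOI, whole-head SAR, and the peak
#' lead-tip temperature rise under the configured exposure.
#'
#' @param weights A [shim_weights()] (already scaled as intended).
#' @param maps The patient's `coil_maps` for one configuration.
#' @param patient From [synthetic_patient()].
#' @param assets From [make_study_assets()].
#' @param cfg A [study_config()].
#' @param thermal If FALSE, skip the bioheat run (`delta_t = NA`).
#' @return List of the four metrics.
#' @export
evaluate_weights <- function(weights, maps, patient, assets,
                             cfg = study_config(), thermal = TRUE) {
  f <- combine_fields(weights, maps)
  s <- raw_sar(f, patient$tissue)
  out <- list(
    rom_sar_1g = local_1g_sar(s, patient$tissue, patient$lead, rom = patient$rom),
    cov = cov_b1(f, assets$voi),
    sar_wh = whole_head_sar(s, patient$tissue),
    delta_t = NA_real_)
  if (thermal) {
    th <- pennes_simulate(patient$tissue, s, duration = cfg$thermal$duration,
                          bc = cfg$thermal$bc,
                          tip = lead_tip_midpoint(patient$lead))
    out$delta_t <- peak_tip_delta_t(th, patient$lead)
  }
  out
}

#' Run the full per-patient workflow
#'
#' Records the quadrature birdcage reference metrics, then for each pTx
#' configuration runs the safety precheck and, when optimization is needed,
#' the lambda sweep and two-stage solution selection. All four metrics are
#' recorded per configuration; a failed configuration is recorded with its
#' reason.
#'
#' @param patient From [synthetic_patient()].
#' @param assets From [make_study_assets()].
#' @param cfg A [study_config()].
#' @param thermal Pass FALSE to skip temperature estimates.
#' @return List: `records` (data frame, one row per configuration) and
#'   `solutions` (selected weights and sweep per pTx configuration).
#' @export
run_patient <- function(patient, assets, cfg = study_config(), thermal = TRUE) {
  ocfg <- cfg$optimization
  rows <- list()
  solutions <- list()

  wq_bc <- normalize_weights(quadrature_weights(16L), patient$maps$birdcage,
                             assets$voi, ocfg$target_mean_b1)
  m <- evaluate_weights(wq_bc, patient$maps$birdcage, patient, assets, cfg, thermal)
  rows[["birdcage"]] <- data.frame(config = "birdcage", decision = "quadrature",
                                   lambda = NA_real_, rom_sar_1g = m$rom_sar_1g,
                                   cov = m$cov, sar_wh = m$sar_wh,
                                   delta_t = m$delta_t)
  solutions$birdcage <- list(weights = wq_bc)

  for (nch in cfg$ptx_channels) {
    nm <- paste0("ptx", nch)
    maps <- patient$maps[[nm]]
    res <- tryCatch({
      pre <- quadrature_precheck(maps, patient$tissue, patient$lead,
                                 limit = ocfg$sar_limit, voi = assets$voi,
                                 rom = patient$rom, cfg = ocfg)
      if (pre$decision == "safe-skip") {
        mm <- evaluate_weights(pre$weights, maps, patient, assets, cfg, thermal)
        list(row = data.frame(config = nm, decision = "safe-skip",
                              lambda = NA_real_, rom_sar_1g = mm$rom_sar_1g,
                              cov = mm$cov, sar_wh = mm$sar_wh,
                              delta_t = mm$delta_t),
             sol = list(weights = pre$weights, precheck = pre))
      } else {
        sweep <- lambda_sweep(maps, assets$voi, patient$rom, patient$tissue,
                              patient$lead, ocfg)
        sel <- select_solution(sweep, ocfg)
        mm <- evaluate_weights(sel$weights, maps, patient, assets, cfg, thermal)
        list(row = data.frame(config = nm, decision = "optimized",
                              lambda = sel$lambda, rom_sar_1g = mm$rom_sar_1g,
                              cov = mm$cov, sar_wh = mm$sar_wh,
                              delta_t = mm$delta_t),
             sol = list(weights = sel$weights, selected = sel, sweep = sweep,
                        precheck = pre))
      }
    }, error = function(e)
      list(row = data.frame(config = nm, decision = paste("failed:",
                                                          conditionMessage(e)),
                            lambda = NA_real_, rom_sar_1g = NA_real_,
                            cov = NA_real_, sar_wh = NA_real_,
                            delta_t = NA_real_),
           sol = NULL))
    rows[[nm]] <- res$row
    solutions[[nm]] <- res$sol
  }
  records <- do.call(rbind, rows)
  records$lateralization <- patient$lateralization
  records$seed <- patient$seed
  rownames(records) <- NULL
  list(records = records, solutions = solutions)
}

#' Run the synthetic cohort study
#'
#' Builds the shared assets, generates the seeded patients (per-patient seed
#' = base seed + patient index) and runs [run_patient()] for each. Fully
#' deterministic for a given configuration.
#'
#' @param cfg A [study_config()].
#' @param thermal Pass FALSE to skip temperature estimates.
#' @param assets Optional precomputed [make_study_assets()].
#' @param progress Print one line per patient.
#' @return Object of class `cohort_result`: `records` (long data frame),
#'   `patients`, `solutions`, `assets`, `cfg`.
#' @export
run_cohort <- function(cfg = study_config(), thermal = TRUE, assets = NULL,
                       progress = FALSE) {
  if (is.null(assets)) assets <- make_study_assets(cfg)
  lats <- c(rep("left", cfg$n_left), rep("right", cfg$n_right))
  patients <- list()
  solutions <- list()
  records <- list()
  for (i in seq_along(lats)) {
    pat <- synthetic_patient(assets, lats[i], seed = cfg$base_seed + i, cfg)
    pr <- run_patient(pat, assets, cfg, thermal)
    pr$records$patient <- i
    records[[i]] <- pr$records
    patients[[i]] <- pat
    solutions[[i]] <- pr$solutions
    if (progress)
      cat(sprintf("patient %d (%s): %s\n", i, lats[i],
                  paste(sprintf("%s %.3g W/kg", pr$records$config,
                                pr$records$rom_sar_1g), collapse = ", ")))
  }
  structure(list(records = do.call(rbind, records), patients = patients,
                 solutions = solutions, assets = assets, cfg = cfg),
            class = "cohort_result")
}

#' @export
print.cohort_result <- function(x, ...) {
  cat(sprintf("<cohort_result> %d patients\n", length(x$patients)))
  agg <- stats::aggregate(cbind(rom_sar_1g, cov, sar_wh) ~ config, x$records,
                          stats::median)
  print(agg)
  invisible(x)
}

#' Group-averaged ("generic") weights experiment
#'
#' For each pTx configuration and lateralization group, averages the
#' patient-specific optimized weights ([average_group_weights()]) and applies
#' the averaged weights to every patient in the group, re-normalized to the
#' comparison B1+ target. Probes whether one-size-fits-all shims stay safe.
#'
#' @param cohort A [run_cohort()] result.
#' @param thermal Include temperature estimates.
#' @return Data frame of per-patient metrics under averaged weights.
#' @export
averaged_weights_experiment <- function(cohort, thermal = FALSE) {
  cfg <- cohort$cfg
  assets <- cohort$assets
  rows <- list()
  for (nch in cfg$ptx_channels) {
    nm <- paste0("ptx", nch)
    for (side in c("left", "right")) {
      idx <- which(vapply(cohort$patients, function(p)
        p$lateralization == side, TRUE))
      ws <- lapply(idx, function(i) cohort$solutions[[i]][[nm]]$weights)
      keep <- !vapply(ws, is.null, TRUE)
      if (sum(keep) < 2L) next
      wavg <- average_group_weights(ws[keep])
      for (i in idx) {
        pat <- cohort$patients[[i]]
        w <- normalize_weights(wavg, pat$maps[[nm]], assets$voi,
                               cfg$optimization$target_mean_b1)
        m <- evaluate_weights(w, pat$maps[[nm]], pat, assets, cfg, thermal)
        rows[[length(rows) + 1L]] <-
          data.frame(config = nm, lateralization = side, patient = i,
                     rom_sar_1g = m$rom_sar_1g, cov = m$cov,
                     sar_wh = m$sar_wh, delta_t = m$delta_t)
      }
    }
  }
  do.call(rbind, rows)
}

#' Rigid-shift robustness experiment
#'
#' For each patient, draws a seeded rigid-body displacement (rotations
#' uniform in +/-10 degrees per axis, translations uniform in +/-4 cm per
#' axis), regenerates the patient geometry and coupling in the displaced
#' pose, and applies the weights optimized for the ORIGINAL pose. If the
#' displaced head exits the grid the transform is redrawn (bounded retries).
#'
#' @param cohort A [run_cohort()] result.
#' @param max_angle_deg,max_shift Displacement bounds.
#' @param thermal Include temperature estimates.
#' @param max_retries Redraw attempts per patient.
#' @return Data frame of per-patient, per-configuration metrics after shift.
#' @export
shift_experiment <- function(cohort, max_angle_deg = 10, max_shift = 0.04,
                             thermal = FALSE, max_retries = 20L) {
  cfg <- cohort$cfg
  assets <- cohort$assets
  rows <- list()
  for (i in seq_along(cohort$patients)) {
    pat <- cohort$patients[[i]]
    shifted <- NULL
    tf <- NULL
    for (k in seq_len(max_retries)) {
      tf <- random_rigid_transform(pat$seed * 131L + k, max_angle_deg, max_shift)
      shifted <- tryCatch(shift_patient(pat, tf, assets), error = function(e) NULL)
      if (!is.null(shifted)) break
    }
    if (is.null(shifted))
      stop(sprintf("shift_experiment: no admissible transform for patient %d", i))
    for (nm in names(cohort$solutions[[i]])) {
      sol <- cohort$solutions[[i]][[nm]]
      if (is.null(sol)) next
      m <- evaluate_weights(sol$weights, shifted$maps[[nm]], shifted, assets,
                            cfg, thermal)
      rows[[length(rows) + 1L]] <-
        data.frame(config = nm, patient = i,
                   lateralization = pat$lateralization,
                   rom_sar_1g = m$rom_sar_1g, cov = m$cov, sar_wh = m$sar_wh,
                   delta_t = m$delta_t)
    }
  }
  do.call(rbind, rows)
}

# Rebuild a patient in a displaced pose, reusing the cohort's background maps.
shift_patient <- function(patient, transform, assets) {
  lead <- apply_rigid_transform(patient$lead, transform)
  phantom <- apply_rigid_transform(assets$phantom, transform)
  tissue <- add_lead_insulation(phantom, lead)
  rom <- build_rom_mask(assets$grid, lead, tissue)
  maps <- lapply(names(assets$maps), function(nm)
    add_lead_coupling(assets$maps[[nm]], assets$coils[[nm]], lead))
  names(maps) <- names(assets$maps)
  list(lead = lead, tissue = tissue, rom = rom, maps = maps,
       lateralization = patient$lateralization, seed = patient$seed)
}
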