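#' Read and write volumes as NIfTI
#'
#' Masks, property volumes, SAR maps and temperature snapshots are exchanged
#' as scalar NIfTI volumes whose affine encodes the grid spacing and origin
#' (voxel centres, metres; NIfTI stores millimetres).
#'
#' @param vol 3-D numeric or logical array on `grid`.
#' @param grid A [grid3d()].
#' @param path Output path (`.nii` / `.nii.gz`).
#' @return `write_volume_nifti()` returns `path` invisibly;
#'   `read_volume_nifti()` returns a list with `vol` and `grid`.
#' @export
write_volume_nifti <- function(vol, grid, path) {
  stopifnot(inherits(grid, "grid3d"))
  vol <- array(as.numeric(vol), grid$dims)
  sp_mm <- grid$spacing * 1000
  first_mm <- 1000 * vapply(1:3, function(a) axis_coords(grid, a)[1], numeric(1))
  aff <- diag(c(sp_mm, 1))
  aff[1:3, 4] <- first_mm
  img <- RNifti::asNifti(vol)
  img <- RNifti::`sform<-`(img, structure(aff, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume_nifti
#' @export
read_volume_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  vol <- array(as.numeric(img), dim(img))
  aff <- RNifti::xform(img)
  sp <- abs(diag(aff)[1:3]) / 1000
  dims <- dim(vol)[1:3]
  first <- aff[1:3, 4] / 1000
  origin <- first + (dims - 1) / 2 * sp
  list(vol = vol, grid = grid3d(dims, sp, origin))
}

#' Serialize shim weights as JSON
#'
#' `{"amplitudes": [...], "phases_rad": [...]}`.
#'
#' @param weights A [shim_weights()].
#' @param path File path.
#' @return `read_weights_json()` returns a `shim_weights`.
#' @export
write_weights_json <- function(weights, path) {
  jsonlite::write_json(list(amplitudes = weights$amplitudes,
                            phases_rad = weights$phases),
                       path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_weights_json
#' @export
read_weights_json <- function(path) {
  d <- jsonlite::read_json(path, simplifyVector = TRUE)
  shim_weights(d$amplitudes, d$phases_rad)
}

#' Serialize per-channel field maps
#'
#' A `coil_maps` object is written as a directory: per channel `n`, 4-D NIfTI
#' volumes `coil<n>_E_real` / `coil<n>_E_imag` (nx x ny x nz x 3, V/m) and
#' `coil<n>_B1_real` / `coil<n>_B1_imag` (nx x ny x nz, tesla), plus a
#' `maps.json` sidecar holding the grid, frequency, coupling values and the
#' generator configuration.
#'
#' @param maps A `coil_maps`.
#' @param dir Output directory (created if needed).
#' @return `read_coil_maps()` returns a `coil_maps`.
#' @export
write_coil_maps <- function(maps, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  grid <- maps$grid
  d4 <- c(grid$dims, 3L)
  for (n in seq_len(maps$n_channels)) {
    E <- array(maps$E[[n]], d4)
    b <- array(maps$B1[, n], grid$dims)
    RNifti::writeNifti(RNifti::asNifti(array(Re(E), d4)),
                       file.path(dir, sprintf("coil%d_E_real.nii.gz", n)))
    RNifti::writeNifti(RNifti::asNifti(array(Im(E), d4)),
                       file.path(dir, sprintf("coil%d_E_imag.nii.gz", n)))
    RNifti::writeNifti(RNifti::asNifti(Re(b)),
                       file.path(dir, sprintf("coil%d_B1_real.nii.gz", n)))
    RNifti::writeNifti(RNifti::asNifti(Im(b)),
                       file.path(dir, sprintf("coil%d_B1_imag.nii.gz", n)))
  }
  meta <- list(n_channels = maps$n_channels, dims = grid$dims,
               spacing = grid$spacing, origin = grid$origin,
               frequency = maps$frequency,
               kappa_real = Re(maps$kappa), kappa_imag = Im(maps$kappa),
               tip_point = maps$tip_point, tip_tangent = maps$tip_tangent,
               config = unclass(maps$cfg), coil = maps$coil)
  jsonlite::write_json(meta, file.path(dir, "maps.json"),
                       digits = NA, auto_unbox = TRUE, null = "null")
  invisible(dir)
}

#' @rdname write_coil_maps
#' @export
read_coil_maps <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "maps.json"), simplifyVector = TRUE)
  grid <- grid3d(meta$dims, meta$spacing, meta$origin)
  nvox <- prod(grid$dims)
  N <- meta$n_channels
  E <- vector("list", N)
  B1 <- matrix(0 + 0i, nvox, N)
  rd <- function(f) {
    img <- RNifti::readNifti(file.path(dir, f))
    array(as.numeric(img), dim(img))
  }
  for (n in seq_len(N)) {
    Er <- rd(sprintf("coil%d_E_real.nii.gz", n))
    Ei <- rd(sprintf("coil%d_E_imag.nii.gz", n))
    E[[n]] <- matrix(complex(real = Er, imaginary = Ei), nvox, 3)
    br <- rd(sprintf("coil%d_B1_real.nii.gz", n))
    bi <- rd(sprintf("coil%d_B1_imag.nii.gz", n))
    B1[, n] <- complex(real = br, imaginary = bi)
  }
  cfg <- do.call(synthetic_config, meta$config[
    intersect(names(meta$config), names(formals(synthetic_config)))])
  structure(list(grid = grid, n_channels = N, B1 = B1, E = E,
                 kappa = complex(real = meta$kappa_real,
                                 imaginary = meta$kappa_imag),
                 tip_point = meta$tip_point, tip_tangent = meta$tip_tangent,
                 frequency = meta$frequency, cfg = cfg, coil = meta$coil),
            class = "coil_maps")
}

#' Write an optimization result (with sweep table) as JSON
#'
#' @param selected The selected `optimization_result`.
#' @param sweep Optional `lambda_sweep` to include as a table.
#' @param path Output path.
#' @export
write_result_json <- function(selected, sweep = NULL, path) {
  row <- function(r) {
    if (!is.null(r$error)) return(list(lambda = r$lambda, error = r$error))
    list(lambda = r$lambda, cost = r$cost, cov_term = r$cov_term,
         rom_term = r$rom_term, rom_sar_1g = r$rom_sar_1g,
         whole_head_sar = r$whole_head_sar, fevals = r$fevals,
         converged = r$converged,
         amplitudes = r$weights$amplitudes, phases_rad = r$weights$phases)
  }
  out <- list(selected = row(selected))
  if (!is.null(selected$cov_threshold))
    out$selected$cov_threshold <- selected$cov_threshold
  if (!is.null(sweep)) out$sweep <- lapply(sweep, row)
  jsonlite::write_json(out, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Load a run configuration from YAML or JSON
#'
#' Recognized top-level blocks mirror [study_config()]: `grid`, `synthetic`,
#' `optimization`, `thermal`, `cohort`. Unknown keys are rejected. Lengths in
#' the `grid` block may be given in centimetres via `spacing_cm`.
#'
#' @param path YAML or JSON file.
#' @return A [study_config()].
#' @export
read_study_config <- function(path) {
  raw <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
         else yaml::read_yaml(path)
  known <- c("grid", "synthetic", "optimization", "thermal", "cohort")
  bad <- setdiff(names(raw), known)
  if (length(bad) > 0)
    stop(sprintf("read_study_config: unknown block(s): %s",
                 paste(bad, collapse = ", ")))
  args <- list()
  if (!is.null(raw$grid)) {
    if (!is.null(raw$grid$dims)) args$grid_dims <- raw$grid$dims
    if (!is.null(raw$grid$spacing)) args$grid_spacing <- raw$grid$spacing
    if (!is.null(raw$grid$spacing_cm)) args$grid_spacing <- raw$grid$spacing_cm / 100
  }
  if (!is.null(raw$synthetic))
    args$synthetic <- do.call(synthetic_config, raw$synthetic)
  if (!is.null(raw$optimization))
    args$optimization <- do.call(optimization_config, raw$optimization)
  if (!is.null(raw$thermal)) args$thermal <- raw$thermal
  if (!is.null(raw$cohort)) {
    for (k in c("n_left", "n_right", "base_seed", "ptx_channels"))
      if (!is.null(raw$cohort[[k]])) args[[k]] <- raw$cohort[[k]]
  }
  do.call(study_config, args)
}
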