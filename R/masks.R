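#' Build the imaging volume-of-interest (VOI) mask
#'
#' The VOI is an elliptical column: voxel centres satisfying
#' ((x-cx)/r_x)^2 + ((y-cy)/r_y)^2 <= 1 and |z - cz| <= L/2. Defaults place it
#' at the approximate brain location of a head centred in the coil: centre
#' (-0.5, 1, 3) cm, semi-axes r_x = 6 cm, r_y = 7.5 cm, length L = 4.5 cm.
#'
#' @param grid A [grid3d()].
#' @param centre Column centre (m).
#' @param rx,ry Semi-axes along x and y (m).
#' @param length Column extent along z (m).
#' @return A [region_mask()] with role "VOI".
#' @export
build_voi_mask <- function(grid, centre = c(-0.005, 0.01, 0.03),
                           rx = 0.06, ry = 0.075, length = 0.045) {
  stopifnot(inherits(grid, "grid3d"))
  if (rx <= 0 || ry <= 0 || length <= 0)
    stop("build_voi_mask: radii and length must be positive")
  p <- voxel_coords(grid)
  inside <- ((p[, 1] - centre[1]) / rx)^2 + ((p[, 2] - centre[2]) / ry)^2 <= 1 &
    abs(p[, 3] - centre[3]) <= length / 2
  if (!any(inside)) stop("empty VOI")
  region_mask(grid, array(inside, dim = grid$dims), "VOI")
}

#' Build the 1 g region-of-minimization (ROM) mask at the lead tip
#'
#' Returns the tissue voxels inside an axis-aligned cube centred on the voxel
#' containing the midpoint of the exposed-contact span, grown in whole-voxel
#' shells (cube sizes 1, 3, 5, ... voxels) until the enclosed tissue mass
#' reaches at least 1 g. Insulation voxels fall inside the cube but carry no
#' tissue mass and are excluded from the mask.
#'
#' @param grid A [grid3d()].
#' @param lead A [lead_model()]; its exposed tip must lie inside the head.
#' @param tissue A [tissue_model()] on the same grid.
#' @param target_mass Mass to enclose (kg), default 1 g.
#' @return A [region_mask()] with role "ROM".
#' @export
build_rom_mask <- function(grid, lead, tissue, target_mass = 1e-3) {
  stopifnot(inherits(grid, "grid3d"), inherits(lead, "lead_model"),
            inherits(tissue, "tissue_model"))
  centre <- lead_tip_midpoint(lead)
  ijk <- world_to_index(grid, centre)
  if (any(is.na(ijk))) stop("build_rom_mask: lead tip outside grid")
  if (!tissue$head_mask[ijk[1], ijk[2], ijk[3]])
    stop("build_rom_mask: lead tip outside head mask")
  if (head_mass(tissue) < target_mass)
    stop("build_rom_mask: whole head holds less than the target mass")
  tissue_vox <- tissue$head_mask & !tissue$insulation_mask
  dv <- voxel_volume(grid)
  r <- 0L
  repeat {
    rng <- lapply(1:3, function(a)
      max(1L, ijk[a] - r):min(grid$dims[a], ijk[a] + r))
    cube <- array(FALSE, grid$dims)
    cube[rng[[1]], rng[[2]], rng[[3]]] <- TRUE
    sel <- cube & tissue_vox
    mass <- sum(tissue$rho[sel]) * dv
    if (mass >= target_mass) break
    if (all(vapply(1:3, function(a)
      rng[[a]][1] == 1L && rng[[a]][length(rng[[a]])] == grid$dims[a], TRUE)))
      stop("build_rom_mask: cube reached grid bounds before enclosing target mass")
    r <- r + 1L
  }
  region_mask(grid, sel, "ROM")
}

#' Tissue mass enclosed by a region (kg)
#'
#' @param region A [region_mask()].
#' @param tissue A [tissue_model()] on the same grid.
#' @export
region_mass <- function(region, tissue) {
  sel <- region$mask & tissue$head_mask & !tissue$insulation_mask
  sum(tissue$rho[sel]) * voxel_volume(region$grid)
}
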