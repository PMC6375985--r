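#' Tissue model: electromagnetic and thermal property volumes
#'
#' Per-voxel properties of the simulated head plus the blood constants used by
#' the Pennes perfusion term. The head is homogeneous by default, with the
#' dielectric properties of average brain tissue at 128 MHz (3 T): conductivity
#' 0.69 S/m, relative permittivity 67. Voxels flagged by `insulation_mask`
#' (the implant's insulated jacket) override the tissue values with insulation
#' properties: sigma = 0, C = 1500 J/(kg K), k = 0.026 W/(m K), no perfusion,
#' no metabolic heat.
#'
#' @param grid A [grid3d()].
#' @param head_mask Logical array (`grid$dims`): TRUE inside the head.
#' @param insulation_mask Logical array, same shape; defaults to all-FALSE.
#' @param sigma Tissue conductivity, S/m.
#' @param eps_r Tissue relative permittivity (carried for completeness).
#' @param rho Tissue density, kg/m^3 (also used for insulation voxel mass).
#' @param C_t Tissue specific heat, J/(kg K).
#' @param k_t Tissue thermal conductivity, W/(m K).
#' @param V_b Blood perfusion rate, kg_blood / (s kg_tissue).
#' @param Q_m Metabolic heat, W/kg.
#' @param rho_b,C_b,T_b Blood density (kg/m^3), specific heat (J/(kg K)) and
#'   temperature (deg C).
#' @param ins_C,ins_k Insulation specific heat and thermal conductivity.
#' @return An object of class `tissue_model` holding property volumes
#'   (`sigma`, `rho`, `C`, `k`, `V_b`, `Q_m` as 3-D arrays), the two masks and
#'   the blood constants. Outside the head all properties are zero.
#' @export
tissue_model <- function(grid, head_mask, insulation_mask = NULL,
                         sigma = 0.69, eps_r = 67, rho = 1000,
                         C_t = 3650, k_t = 0.6, V_b = 0.0085, Q_m = 0,
                         rho_b = 1050, C_b = 3617, T_b = 37,
                         ins_C = 1500, ins_k = 0.026) {
  stopifnot(inherits(grid, "grid3d"))
  head_mask <- array(as.logical(head_mask), dim = grid$dims)
  if (is.null(insulation_mask)) insulation_mask <- array(FALSE, dim = grid$dims)
  insulation_mask <- array(as.logical(insulation_mask), dim = grid$dims)
  vals <- c(sigma = sigma, rho = rho, C_t = C_t, k_t = k_t, V_b = V_b,
            Q_m = Q_m, rho_b = rho_b, C_b = C_b, ins_C = ins_C, ins_k = ins_k)
  if (any(!is.finite(vals)) || any(vals < 0))
    stop("tissue_model: physical properties must be finite and >= 0")

  fill <- function(inside, ins) {
    a <- array(0, dim = grid$dims)
    a[head_mask] <- inside
    a[insulation_mask] <- ins
    a
  }
  obj <- list(
    grid = grid,
    head_mask = head_mask,
    insulation_mask = insulation_mask,
    sigma = fill(sigma, 0),           # insulation is effectively non-conductive
    eps_r = eps_r,
    rho = fill(rho, rho),
    C = fill(C_t, ins_C),
    k = fill(k_t, ins_k),
    V_b = fill(V_b, 0),
    Q_m = fill(Q_m, 0),
    rho_b = rho_b, C_b = C_b, T_b = T_b
  )
  class(obj) <- "tissue_model"
  obj
}

#' @export
print.tissue_model <- function(x, ...) {
  cat(sprintf("<tissue_model> %d head voxels (%.1f g), %d insulation voxels\n",
              sum(x$head_mask), 1000 * head_mass(x), sum(x$insulation_mask)))
  invisible(x)
}

#' Total tissue mass of the head (kg)
#'
#' Insulation voxels carry no tissue mass.
#' @param tissue A [tissue_model()].
#' @export
head_mass <- function(tissue) {
  m <- tissue$head_mask & !tissue$insulation_mask
  sum(tissue$rho[m]) * voxel_volume(tissue$grid)
}

#' Region mask on a grid
#'
#' A boolean voxel field tagged by its role: `"VOI"` (the imaging volume over
#' which B1+ homogeneity is scored), `"ROM"` (the 1 g region of minimization at
#' the exposed lead tip) or `"HEAD"`.
#'
#' @param grid A [grid3d()].
#' @param mask Logical array of shape `grid$dims` with at least one TRUE voxel.
#' @param role One of "VOI", "ROM", "HEAD".
#' @return An object of class `region_mask`.
#' @export
region_mask <- function(grid, mask, role = c("VOI", "ROM", "HEAD")) {
  role <- match.arg(role)
  stopifnot(inherits(grid, "grid3d"))
  mask <- array(as.logical(mask), dim = grid$dims)
  if (!any(mask)) stop(sprintf("region_mask: empty %s", role))
  structure(list(grid = grid, mask = mask, role = role), class = "region_mask")
}

#' @export
print.region_mask <- function(x, ...) {
  cat(sprintf("<region_mask> %s: %d voxels (%.2f cm^3)\n", x$role,
              sum(x$mask), 1e6 * sum(x$mask) * voxel_volume(x$grid)))
  invisible(x)
}
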