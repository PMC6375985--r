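#' Raw (per-voxel) SAR of a combined field
#'
#' SAR(r) = sigma(r) |E(r)|^2 / (2 rho(r)) inside the head, 0 elsewhere;
#' |E| is the phasor magnitude of the complex vector field.
#'
#' @param field A `combined_field` from [combine_fields()].
#' @param tissue A [tissue_model()] on the same grid.
#' @return An object of class `sar_field`: the raw SAR volume (W/kg, 3-D
#'   array) plus its grid.
#' @export
raw_sar <- function(field, tissue) {
  stopifnot(inherits(field, "combined_field"), inherits(tissue, "tissue_model"))
  grid <- tissue$grid
  head <- as.vector(tissue$head_mask)
  rho <- as.vector(tissue$rho)
  if (any(head & rho <= 0))
    stop("raw_sar: zero density inside the head")
  e2 <- rowSums(Mod(field$E)^2)
  sar <- numeric(length(head))
  sar[head] <- as.vector(tissue$sigma)[head] * e2[head] / (2 * rho[head])
  structure(list(grid = grid, sar = array(sar, grid$dims)),
            class = "sar_field")
}

#' @export
print.sar_field <- function(x, ...) {
  cat(sprintf("<sar_field> max %.3g W/kg, mean(nonzero) %.3g W/kg\n",
              max(x$sar), mean(x$sar[x$sar > 0])))
  invisible(x)
}

#' Mass-weighted volume-averaged SAR over a region
#'
#' sum(SAR * rho * dV) / sum(rho * dV) over in-region tissue voxels, the
#' discrete form of the region-averaged SAR integral. With a homogeneous
#' density this reduces to the arithmetic mean.
#'
#' @param sar A [raw_sar()] field.
#' @param region A [region_mask()].
#' @param tissue A [tissue_model()] on the same grid.
#' @return Averaged SAR, W/kg.
#' @export
volume_avg_sar <- function(sar, region, tissue) {
  stopifnot(inherits(sar, "sar_field"), inherits(region, "region_mask"))
  sel <- region$mask & tissue$head_mask & !tissue$insulation_mask
  m <- sum(tissue$rho[sel])
  if (m <= 0) stop("volume_avg_sar: zero tissue mass in region")
  sum(sar$sar[sel] * tissue$rho[sel]) / m
}

#' Local 1 g SAR at the exposed lead tip
#'
#' Volume-averaged SAR over the 1 g region of minimization (ROM): the
#' whole-voxel cube at the exposed-tip midpoint grown to enclose at least
#' 1 g of tissue (see [build_rom_mask()]).
#'
#' @param sar A [raw_sar()] field.
#' @param tissue A [tissue_model()].
#' @param lead A [lead_model()].
#' @param rom Optional precomputed ROM [region_mask()]; built from the lead
#'   when omitted.
#' @return 1 g averaged SAR, W/kg.
#' @export
local_1g_sar <- function(sar, tissue, lead, rom = NULL) {
  if (is.null(rom)) rom <- build_rom_mask(sar$grid, lead, tissue)
  volume_avg_sar(sar, rom, tissue)
}

#' Whole-head averaged SAR
#'
#' @param sar A [raw_sar()] field.
#' @param tissue A [tissue_model()].
#' @return Mass-averaged SAR over the head mask, W/kg.
#' @export
whole_head_sar <- function(sar, tissue) {
  head <- region_mask(tissue$grid, tissue$head_mask, "HEAD")
  volume_avg_sar(sar, head, tissue)
}

#' Coefficient of variation of |B1+| over the VOI
#'
#' COV = s(|B1+|) / mu(|B1+|) over VOI voxels, with s the population
#' standard deviation (the VOI is the entire population of interest).
#' Dimensionless; multiply by 100 to report percent.
#'
#' @param field A `combined_field`.
#' @param voi A [region_mask()].
#' @return COV (dimensionless).
#' @examples
#' # two-voxel VOI with |B1+| = {1, 3}: population COV = 0.5
#' @export
cov_b1 <- function(field, voi) {
  stopifnot(inherits(field, "combined_field"), inherits(voi, "region_mask"))
  b <- abs(field$B1[which(voi$mask)])
  mu <- mean(b)
  if (mu <= 0) stop("cov_b1: zero mean |B1+| over the VOI")
  sqrt(mean((b - mu)^2)) / mu
}
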