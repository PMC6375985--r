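#' Generate a homogeneous ellipsoidal head phantom
#'
#' Desk-scale stand-in for the segmented patient head: an ellipsoid of
#' homogeneous brain-mimicking tissue (sigma = 0.69 S/m, eps_r = 67 at
#' 128 MHz) centred in the coil. The z axis is superior-inferior (along the
#' bore); the patient faces -y.
#'
#' @param grid A [grid3d()].
#' @param centre Ellipsoid centre (m).
#' @param radii Semi-axes (m); defaults approximate an adult head.
#' @param ... Tissue property overrides passed to [tissue_model()].
#' @return A [tissue_model()] with the ellipsoidal head mask.
#' @export
generate_head_phantom <- function(grid, centre = c(0, 0, 0),
                                  radii = c(0.075, 0.09, 0.085), ...) {
  stopifnot(inherits(grid, "grid3d"))
  if (any(radii <= 0)) stop("generate_head_phantom: radii must be positive")
  half_span <- grid$dims * grid$spacing / 2
  if (any(abs(centre - grid$origin) + radii > half_span + 1e-12))
    stop("generate_head_phantom: ellipsoid does not fit within the grid")
  p <- voxel_coords(grid)
  inside <- ((p[, 1] - centre[1]) / radii[1])^2 +
    ((p[, 2] - centre[2]) / radii[2])^2 +
    ((p[, 3] - centre[3]) / radii[3])^2 <= 1
  if (!any(inside)) stop("generate_head_phantom: empty head mask")
  tm <- tissue_model(grid, array(inside, grid$dims), ...)
  tm$head_centre <- centre
  tm$head_radii <- radii
  tm
}

#' Voxelize a lead's insulated jacket into the tissue model
#'
#' Marks the voxels traversed by the insulated portion of the lead (everything
#' proximal of the exposed-contact span) as insulation, overriding their
#' electromagnetic and thermal properties. Because the jacket (1.27 mm) is
#' much thinner than a voxel, flagging the voxel that also contains the
#' exposed contacts would wrongly de-conduct the hot-spot region; the jacket
#' is therefore truncated one voxel diagonal before the exposed span. Voxels
#' outside the head are left untouched.
#'
#' @param tissue A [tissue_model()].
#' @param lead A [lead_model()] on the same grid.
#' @return A new `tissue_model` with the insulation mask set.
#' @export
add_lead_insulation <- function(tissue, lead) {
  grid <- tissue$grid
  L <- lead_length(lead)
  pts <- lead_resample(lead, min(grid$spacing) / 3)
  s <- c(0, cumsum(sqrt(rowSums(diff(pts)^2))))
  margin <- sqrt(sum(grid$spacing^2))
  ins_pts <- pts[s < L - lead$tip_span - margin, , drop = FALSE]
  ins <- array(FALSE, grid$dims)
  if (nrow(ins_pts) > 0) {
    idx <- world_to_index(grid, ins_pts)
    idx <- idx[stats::complete.cases(idx), , drop = FALSE]
    ins[idx] <- TRUE
  }
  ins <- ins & tissue$head_mask
  out <- tissue_model(grid, tissue$head_mask, insulation_mask = ins,
                      sigma = max(tissue$sigma), rho = max(tissue$rho),
                      C_t = max(tissue$C), k_t = max(tissue$k),
                      V_b = max(tissue$V_b), Q_m = max(tissue$Q_m),
                      rho_b = tissue$rho_b, C_b = tissue$C_b, T_b = tissue$T_b)
  out$head_centre <- tissue$head_centre
  out$head_radii <- tissue$head_radii
  out
}
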