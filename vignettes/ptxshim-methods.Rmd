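---
title: "Optimized pTx RF shimming for DBS implant heating: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Optimized pTx RF shimming for DBS implant heating: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ptxshim)
```

## The problem

A deep-brain-stimulation (DBS) lead is a long insulated conductor whose
exposed distal contacts sit in deep grey matter. During MRI the lead couples
to the transmitted RF electric field (the antenna effect) and concentrates
power at the exposed tip, where the specific absorption rate (SAR) — and
hence tissue temperature — can rise far beyond safe levels. With a
parallel-transmit (pTx) coil, each of the N elements is driven by the same
waveform scaled by a static amplitude $A_n$ and phase $\varphi_n$ ("RF
shimming"). Because the fields superpose linearly,

$$\mathbf{E}_{tot}(\mathbf{r}) = \sum_n A_n e^{i\varphi_n}\,\mathbf{e}_n(\mathbf{r}),
\qquad
B_{1,tot}^{+}(\mathbf{r}) = \sum_n A_n e^{i\varphi_n}\, b_{1,n}^{+}(\mathbf{r}),$$

the weights can be chosen to null the E-field at the lead tip while keeping
the transmit field $B_1^+$ usable for imaging.

## The cost function and the selection procedure

Weights are found by Nelder-Mead minimization of a two-term cost

$$\min_{A_n,\varphi_n}\;
\frac{s_{VOI}(|B_{1,tot}^{+}|)}{\mu_{VOI}(|B_{1,tot}^{+}|)}
\;+\;\lambda\,\mu_{ROM}\!\left(\frac{|\mathbf{E}_{tot}|^2}{|\mathbf{E}_{quad}|^2}\right)$$

where the first term is the coefficient of variation (COV) of $|B_1^+|$ over
the imaging volume of interest (VOI: an elliptical column, centre
$(-0.5, 1, 3)$ cm, semi-axes 6 and 7.5 cm, length 4.5 cm), and the second is
the mean, over the 1 g region of minimization (ROM) at the exposed tip, of
the pointwise E-field power ratio against the quadrature reference
($A_n = 1$, $\varphi_n = 2\pi n/N$). Implementation specifics:

* **Normalization inside the cost.** Weights are rescaled at every
  evaluation so that $\mu_{VOI}(|B_1^+|) = 1\,\mu$T. Without this, shrinking
  all amplitudes shrinks the E-field term without physical meaning; with it,
  the cost is exactly invariant under global amplitude scaling and global
  phase shifts (both are tested).
* **Parameterization.** $2N-1$ real parameters: all $N$ amplitudes through
  $|\cdot|$, and $N-1$ phases with $\varphi_0 \equiv 0$ to remove the
  global-phase degeneracy. The search starts at quadrature, with three
  seeded perturbed restarts per $\lambda$; the sweep also warm-starts each
  $\lambda$ from its neighbours (a forward pass followed by a backward
  refinement pass), which in practice makes the $\lambda = 0$ solution the
  best-COV solution of the whole sweep.
* **Denominator guard.** $|\mathbf{E}_{quad}|^2$ can approach zero at
  quadrature nulls; ROM voxels whose quadrature power is below
  $10^{-12}\times$ the ROM maximum are excluded from the ratio mean. The
  safety precheck (below) keeps the grossly degenerate cases out of the
  optimization entirely. A fully degenerate example worth knowing about:
  channels with *identical* E maps make $\mathbf{E}_{quad} \equiv 0$
  (quadrature phases sum to zero), so the ratio is 0/0 everywhere — the
  tests exercise the analytic-null case with proportional maps instead.

**Precheck.** Before optimizing, the normalized quadrature mode's 1 g SAR in
the ROM is compared with the 0.4 W/kg safety limit; if it is already below
the limit the implant couples negligibly and quadrature is used as-is.

**$\lambda$ selection.** One optimization per $\lambda$ on a 13-point grid
over $[0, 6]$ ($\lambda = 0$ is homogeneity-only; by roughly 6 the solutions
stop changing). Solutions with ROM 1 g SAR above 0.4 W/kg are discarded;
among the survivors, those with COV at or below 10% are eligible and the one
with minimum 1 g SAR is selected; if none qualifies the COV threshold is
relaxed in 5-point steps.

## Metrics

* Raw SAR: $\sigma |\mathbf{E}|^2 / (2\rho)$ per voxel, zero outside the head.
* Region averages are mass weighted ($\Sigma\, SAR\,\rho\,dV / \Sigma\,\rho\,dV$);
  with the homogeneous phantom this equals the arithmetic mean.
* 1 g SAR: the average over a whole-voxel cube centred on the exposed-tip
  midpoint, grown shell by shell until it encloses at least 1 g of tissue
  (insulation voxels carry no mass). No fractional-voxel or surface
  interpolation is attempted — the simple rule is exactly reproducible by a
  brute-force oracle, which is how it is tested.
* COV of $B_1^+$ uses the *population* standard deviation over VOI voxels
  (the VOI is the whole population of interest); reported as percent.

## The bioheat solver

Temperature is integrated with an explicit finite-difference scheme for the
Pennes equation

$$\rho_t C_t \frac{\partial T}{\partial t} =
k_t \nabla^2 T + V_b \rho_t C_b (T_b - T) + \rho_t\,SAR + Q_m$$

with brain-tissue constants $C_t = 3650$ J/(kg K), $k_t = 0.6$ W/(m K),
$V_b = 0.0085$ kg/(s kg), $C_b = 3617$ J/(kg K), $T_b = 37$ °C, $Q_m = 0$,
and insulation overrides ($C = 1500$ J/(kg K), $k = 0.026$ W/(m K), no
perfusion). Two unit choices deserve note: the printed perfusion term is
reconciled as $V_b\,\rho_t\,C_b\,(T_b - T)$ so that it carries W/m³, and
thermal conductivities quoted in J/(m K) are read as W/(m K). The Laplacian
is a 7-point flux-form stencil with face-averaged conductivity (symmetric,
hence exactly energy conserving when insulated); head-surface voxels
exchange heat with 20 °C ambient air through a Robin condition with a
configurable coefficient (default 10 W/(m² K) — the exposure law is not
standardized, only the ambient temperature is). The time step defaults to
half the explicit stability bound. Closed-form checks: the adiabatic rate
$SAR/C_t$, the perfusion equilibrium $SAR/(V_b C_b)$, the fixed point at
$T = T_b$, energy conservation, the discrete maximum principle, and
first-order convergence in dt at the tip probe.

The RF exposure behind the reported temperature rise is the steady selected
SAR field applied for 360 s. This stands in for a high-power spin-echo
acquisition; the true sequence duty cycle is not modelled, so temperature
values are comparable across configurations but are not predictions for any
particular protocol.

## The synthetic electromagnetic surrogate

No solver output or patient data ships with the package; a quasi-static
surrogate generates everything, preserving the single property the method
depends on — strict linearity of all fields in the complex channel drives.

* **Coils.** Rectangular loop elements wrapped on a 25 cm diameter, 15 cm
  tall cylinder, centres $2\pi/N$ apart, arc lengths 19.6 cm (N = 4) and
  9.8 cm (N = 8), discretized into straight segments. The birdcage reference
  (28 cm diameter, 35 cm, 16 rungs) is emulated as a 16-element array locked
  to quadrature weights — a reference excitation, never optimized.
* **Background fields.** Biot-Savart gives $\mathbf{B}$ (and
  $b_1^+ = (B_x + iB_y)/2$); the background E-field is $-i\omega\mathbf{A}$
  from the loop's vector potential, scaled by a per-configuration factor
  `e_scale` standing for the partial cancellation of the conservative field
  in a tuned, matched coil. Because quasi-static loop arrays have strongly
  element-size-dependent E/B1 efficiency while real tuned coils do not, the
  scale is calibrated per configuration (birdcage 0.0038, 4-channel 0.134,
  8-channel 0.040) so that each configuration's normalized quadrature
  whole-head SAR lands at the physically expected 0.15-0.25 W/kg.
* **Implant coupling.** A transfer-function model: per channel,
  $\kappa_n = \int \mathbf{E}_n(s)\cdot\hat{t}(s)\,
  e^{-(L-s)/\ell_a}\, e^{-2\pi i (L-s)/\lambda_c}\, ds$ along the lead
  ($\ell_a = 10$ cm attenuation, $\lambda_c = 27$ cm propagation wavelength
  in tissue at 128 MHz). The propagation phase matters: a figure-eight
  bundle traverses successive lobes with alternating handedness, and a
  purely real kernel lets their tangential-E contributions cancel pairwise,
  leaving coupling dominated by numerical residue. The deposited tip field
  is $\kappa_n \cdot g \cdot e^{-d/\delta}$ along the tip tangent
  ($\delta = 3$ mm), with $d$ measured from the centre of the voxel
  containing the exposed-tip midpoint so that sub-voxel placement luck does
  not modulate the hot spot on coarse grids. The gain $g = 5300$ m$^{-1}$ is
  calibrated once so that every synthetic patient's quadrature mode exceeds
  the 0.4 W/kg precheck limit (cohort minima ~0.7 W/kg, medians ~5 W/kg for
  pTx and ~15 W/kg for the birdcage) — i.e. so the optimizer always has
  something to suppress, as in the patient study the workflow reproduces.
* **Trajectories.** Seeded synthetic leads: a four-turn figure-eight
  (Gerono lemniscate) bundled near the skull vertex in a tangent plane,
  stacked 4 mm per turn along the inward normal so crossing strands keep
  more than one lead diameter (1.27 mm) of clearance, an exit connector
  routed around the bundle, and a straight penetration to a lateralized deep
  target. Total length is drawn in 42-48 cm (within the 40-50 cm clinical
  range); a brute-force pairwise segment-distance check backs the clearance
  guarantee, with bounded pitch-widening repair. Identical seeds give
  bit-identical trajectories.

**What the surrogate does not emulate.** Wavelength effects and dielectric
loading inside the head, tissue heterogeneity, coil tuning/matching circuit
detail, and the true transfer function of a specific lead. Consequently the
cohort's absolute SAR and temperature levels are surrogate-calibrated, not
patient-accurate: passing the cohort tests demonstrates that the
optimization machinery finds and exploits the linear null structure and that
the qualitative contrasts (pTx vs birdcage, 8 vs 4 channels, patient-specific
vs averaged weights, robustness to pose shifts) behave as in the real study —
it does not validate absolute dosimetry for real patients.

## Study reproduction defaults

`study_config()` fixes the desk-scale study: a 32³ grid at 8 mm isotropic
voxels (the phantom head, an ellipsoid of 7.5 x 9 x 8.5 cm semi-axes, and all
three coil configurations fit comfortably), nine synthetic patients — five
left- and four right-lateralized, per-patient seed = base seed + index — and
the 13-point $\lambda$ sweep. One full patient (three configurations,
thermal runs included) takes on the order of ten seconds on a single core;
the full cohort with both robustness experiments runs in a few minutes. At
8 mm resolution one voxel holds ~0.5 g, so the 1 g cube is 3³ voxels
(~13 g): coarse, but the whole-voxel growth rule and its mass-closure
property are resolution independent and are additionally tested at finer
spacings.

Statistical conventions: type-7 (linear interpolation) quartiles; outliers
outside 1.5 IQR; Wilcoxon signed-rank with midranks, zeros dropped, exact
two-sided p by full sign-assignment enumeration for n ≤ 15 (the nine-patient
comparisons are exact) and a tie-corrected normal approximation above.
Group-averaged ("generic") weights use the circular mean for phases —
the argument of the mean unit phasor — because arithmetic averaging is ill
defined at the 0/2π seam; an arithmetic mode exists behind a flag for
comparison.

## Numerical edge cases and known limitations

* The Hampel despiking filter (window 5, threshold 3 scaled-MAD, truncated
  windows at edges, replace-on-any-deviation when the window MAD is zero) is
  provided for conditioning imported solver data; the surrogate's own fields
  are smooth and are not filtered by default. Note the zero-MAD rule makes
  the filter non-idempotent on pathological plateau-generating inputs; on
  its intended regime (isolated spikes over smooth data) a second pass is a
  no-op.
* `build_rom_mask` grows whole-voxel shells and therefore overshoots 1 g by
  up to one shell; removing the outermost shell always drops below 1 g
  (tested as the mass-closure property).
* Nelder-Mead is local. Restarts plus the bidirectional sweep warm starts
  make the default study deterministic and reliably near-optimal on the toy
  problems with known optima, but global optimality is not guaranteed —
  which mirrors the method being reproduced.
* The insulated lead jacket is voxelized one voxel-diagonal short of the
  exposed span: flagging the tip-containing voxel as non-conducting
  insulation would erase the hot spot that the 1.27 mm-thin real jacket
  does not cover.
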