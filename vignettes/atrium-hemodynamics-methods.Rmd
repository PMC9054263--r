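---
title: "Methods: right-atrium hemodynamic post-processing on sampled flow fields"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: right-atrium hemodynamic post-processing on sampled flow fields}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(atriumflow)
```

# Scope and data model

The right atrium (RA) receives systemic venous return from the inferior and
superior venae cavae (IVC, SVC) plus a small coronary-sinus contribution.
Clinically relevant interventions — veno-venous ECMO, dialysis catheters —
re-balance the IVC/SVC split, and the hemodynamic consequences are usually
studied by large-eddy simulation (LES) on patient-derived geometries. This
package implements the *post-processing* side of such a study: given
time-resolved velocity fields, it computes blood rheology, subgrid
turbulence quantities, turbulent kinetic energy (TKE), helicity, vorticity
and wall-shear metrics, aggregates them over named regions and inlet-split
scenarios, and runs the accompanying morphometry statistics and
verification utilities. It deliberately contains no flow solver.

Fields live on a voxel lattice: a `uniform_grid` (node-centred, uniform
spacing, SI units), a `fluid_mask` labelling nodes fluid / wall / exterior,
and a `flow_field` holding one `n_nodes x 3` velocity matrix per time
sample. Wall nodes carry exactly zero velocity (no-slip convention); wall
*faces* — voxel faces separating a fluid from a wall node — carry the
axis-aligned outward normals and areas used for surface metrics. A
body-fitted polyhedral mesh, as a solver would use, is out of scope by
design: the voxel lattice admits exact analytic oracles (tube, channel,
vortex and Beltrami fields) and clean second-order stencils, at the price
of staircase walls (see *Wall shear stress* below). Surface and volume
averages over voxelised geometry therefore approximate, rather than
reproduce, averages over a body-fitted surface; the convergence tests
quantify that gap on analytic fixtures.

# Blood rheology

Blood is shear-thinning; the package uses the Quemada model

$$\mu(\dot\gamma) = \mu_p\left(1 - \tfrac12 k(\dot\gamma)\,Hct\right)^{-2},
\qquad
k = \frac{k_0 + k_\infty\sqrt{\dot\gamma/\dot\gamma_c}}
         {1 + \sqrt{\dot\gamma/\dot\gamma_c}},$$

with plasma viscosity $\mu_p$ (default $1.2\times10^{-3}$ Pa s),
haematocrit $Hct$ (default 0.35, an ECMO-typical value) and the classical
exponential-polynomial fits of $k_0$, $k_\infty$, $\dot\gamma_c$ to
Cokelet's human-blood data as haematocrit-dependent defaults. All four are
overridable. At $Hct = 0.35$ and $\dot\gamma = 100\,\mathrm{s^{-1}}$ the
defaults give $\mu = 3.43$ mPa s, inside the physiological 3–4 mPa s band
and close to the ~3.0 mPa s volume averages reported for atrial flow at
this haematocrit. Numerical choices:

* **Shear-rate floor** $10^{-3}\,\mathrm{s^{-1}}$: $k(\dot\gamma)$ is
  evaluated at $\max(\dot\gamma, \text{floor})$, regularising the
  $\dot\gamma = 0$ evaluation. With the default fits the floored model is
  regular at every haematocrit; a parameter set that still drives
  $1 - k\,Hct/2 \le 0$ raises an explicit singularity error rather than
  returning a negative or infinite viscosity.
* **Hard validity bound** $Hct < 2/k_\infty$, checked at construction: the
  infinite-shear branch must stay finite for the model to make sense at
  any shear.
* The shear rate feeding `viscosity_field()` is the strain-rate modulus
  $S = \sqrt{2S_{ij}S_{ij}}$, which reduces to $\dot\gamma$ for simple
  shear.

# Subgrid (WALE) operator

Applied diagnostically to a given snapshot — no momentum solve — the
wall-adapting local eddy-viscosity model reads

$$\mu_t = \rho\,\Delta^2 S_W,\qquad
\Delta = \min(\kappa d,\; C_W V^{1/3}),$$

with $\kappa = 0.41$, $C_W = 0.544$, $d$ the wall distance, $V$ the cell
volume, and

$$S_W = \frac{(S^d\!:\!S^d)^{3/2}}{(S\!:\!S)^{5/2} + (S^d\!:\!S^d)^{5/4}},$$

where $S$ is the strain-rate tensor and $S^d$ the traceless symmetric part
of the squared velocity-gradient tensor (the standard WALE operator — the
only published one consistent with $C_W = 0.544$). $S_W$ vanishes
identically for uniform flow and pure shear (the wall-adapting property)
and equals $(2/3)^{1/4}\Omega$ for solid-body rotation, which the tests
assert against the closed form. The denominator carries an additive guard
of $10^{-30}$ (SI) so that $S_W = 0$ when both contractions vanish,
removing the $0/0$ at uniform flow.

Wall distance is the Euclidean distance to the nearest wall-face centroid,
computed by (chunked) brute force — exact for voxel geometry. A mask with
no walls yields $d = \infty$, so $\Delta$ falls back to its
$C_W V^{1/3}$ branch, which is what periodic benchmark boxes need.

The subgrid TKE estimate is implemented as

$$k_{SGS} = C_t\,\frac{\mu_t}{\rho}\,S, \qquad C_t = 3.5 .$$

The product $C_t\,\mu_t\,\rho\,S$ sometimes seen in print is dimensionally
inconsistent with J/kg; $C_t (\mu_t/\rho) S$ has units m²/s² and matches
the eddy-viscosity-based subgrid energy estimates this coefficient comes
from. This reading is a deliberate, documented choice.

# Velocity gradients and derived metrics

Gradients use second-order central differences where both axis neighbours
are fluid and second-order one-sided (three-point) stencils into the fluid
at wall- or exterior-adjacent nodes, degrading to two-point stencils only
where fewer than three consecutive fluid nodes exist; a fluid node with no
neighbour along any axis is an error. All derived quantities — vorticity
$\omega = \nabla\times u$, helicity density $h = u\cdot\omega$, strain
modulus — inherit second-order convergence, verified on Lamb–Oseen (peak
vorticity, circulation), ABC/Beltrami (volume-mean helicity
$A^2+B^2+C^2$, parity sign flip under mirror reflection) and swirling-pipe
(plane-averaged helicity $\Omega_0 U_0/3$) fixtures with log–log slopes
$\ge 1.8$ over three refinements.

**Time averaging and resolved TKE.** Scenario reporting uses a sliding
window of 50 samples (the conventional choice for this application;
configurable). `sliding_window_mean()` keeps only "valid" centred windows
($n - w + 1$ outputs). Resolved TKE is
$k_r = \tfrac12(\overline{u'^2} + \overline{v'^2} + \overline{w'^2})$
with fluctuations taken against the sliding-window mean centred on each
sample (windows clamped at the horizon ends) and variances averaged over
all samples; how window means and variances interact is recorded here
because conventions differ. For independent snapshots this estimator
carries a known $(1 - 1/w)$ bias — about 2% at $w = 50$ — well inside the
5% tolerance of the recovery tests. Total TKE adds $k_{SGS}$ pointwise and
is reported both as a volume average (J/kg) and as the region-integrated
energy $\rho\int k\,dV$ in mJ, the two forms linked by the region volume;
thresholded "turbulent volume" extraction (`tke_exceedance_volume`,
default 0.08 J/kg) sums voxel volumes above threshold.

**Plane sections.** `extract_plane()` clips every fluid voxel against the
plane exactly (polygon of the cube–plane intersection), so area weights
sum to the voxelised cross-section; on-plane corners are tie-broken to the
positive side. Velocities and helicity are interpolated trilinearly at
polygon centroids.

**Wall shear stress.** Per wall face, the velocity-gradient tensor at the
adjacent fluid node and at the next node along the face axis is linearly
extrapolated to the face centroid (a second-order one-sided evaluation;
faces with fewer than three fluid nodes along the normal are an error),
and the viscous traction $\mu (G + G^T)\hat n$ is projected onto the wall
tangent plane. The normal $\hat n$ is *not* the raw axis-aligned face
normal: on a staircase approximation of a curved wall the axis normals
systematically bias the face-averaged shear magnitude low (by $\pi/4$ in
the limit), so $\hat n$ is estimated by area-weighted averaging of
wall-face normals within 2.5 grid spacings — a standard remedy in
voxel-based hemodynamics. On flat axis-aligned walls this reduces to the
exact normal. With it, the face-averaged TAWSS of a voxelised Poiseuille
tube lands within 3% of $2\mu U_{max}/R$ at 64 nodes per diameter (0.6%
measured). Convergence of the wall-shear error is demonstrated on a
plane-channel fixture with a quartic profile and walls aligned exactly on
voxel faces: the tube's staircase introduces irregular face-placement
noise that would contaminate a slope fit, while the channel isolates the
stencil truncation error.

# Scenario engine

A `flow_scenario` splits a constant total inflow (default 6 L/min): the
coronary sinus takes a fixed fraction (default 2%), and the caval
remainder is divided IVC : SVC as $f : (1-f)$. The IVC/SVC percentages are
interpreted as fractions of the *caval* (non-coronary-sinus) flow, so the
printed pairs sum to 100; within each tree, flow is allocated
proportionally to inlet cross-sectional area (branch-level
proportionality). The default sweep runs the nine splits 30/70 … 70/30 in
5-point steps, with per-scenario seeds recorded in the output table.
Trends of any metric across the sweep use ordinary least squares with a
$t$-based two-sided P on $n-2$ degrees of freedom; numerically exact fits
are resolved explicitly (constant metric → slope 0, $P = 1$; exact nonzero
slope → $P = 0$) instead of dividing by a zero residual variance.

Inlet waveforms: the pulsatility index is defined as
$(\max - \min)/\text{mean}$ (the standard Doppler convention; the
generator normalises its base shape on the sample grid so the requested PI
is met exactly). A PI above 2 implies transient flow reversal, as venous
waveforms can genuinely show.

# Morphometry statistics

Descriptive statistics of the packaged four-subject vein table use the
population SD (divide by $n$) — the convention under which the table's
printed summary rows are reproducible — with the sample convention
available by flag. Variability is compared per vessel via the coefficient
of variation (population SD / mean) of minimum vs maximum diameters over
the 8 veins with paired min/max columns (the RA axis lengths have no such
pair and are excluded), and the paired CVs are tested with a Wilcoxon
signed-rank test: zero differences dropped, average ranks for ties,
continuity-corrected normal approximation as the headline P (0.0209 on the
packaged table) with the exact $2^n$ enumeration also reported (0.0156).
Exhaustive comparison of the two methods shows worst-case absolute
disagreement of 0.020 at $n = 8$, shrinking to 0.011 at $n = 15$; typical
mid-range values agree much more closely. One caveat on printed-table
reproduction: the subject cells are printed at 2 decimal places, so a
summary recomputed from them carries up to half a unit of propagated
rounding on top of the summary cell's own print rounding; the acceptance
test therefore uses a one-ulp (0.01 cm) tolerance, and 35 of 36 cells
agree at the printed precision outright.

The synthetic morphometry generator draws lognormal diameters (positive
by construction, population CV exactly the target) with one latent factor
per subject and vessel shared between the minimum and maximum, which keeps
min ≤ max except in a negligible tail that is clamped. Sample CVs converge
to the targets as subjects grow; 500 subjects recover (0.33, 0.17) within
5%.

# Verification utilities

`gci()` implements the three-grid Richardson-extrapolation procedure with
safety factor 1.25 (the three-grid convention; neither the factor nor the
formula edition is standardised in print, so both are recorded in the
output): apparent order from the grid-to-grid differences (fixed-point
solve for mixed refinement ratios), extrapolated value, and fine/coarse
GCIs in percent. Identical solutions report exact convergence with GCI 0;
sign-alternating differences are flagged oscillatory. Meshes reported by
cell count are placed on the refinement axis via
$h = (V/N)^{1/3}$. `power_spectrum()` is a Welch-averaged one-sided
periodogram (rectangular or Hann), Parseval-exact in single-segment
rectangular mode, with an optional log–log slope fit over a chosen band
against the $-5/3$ inertial-range reference; `power_law_signal()`
synthesises seeded random-phase probe signals with prescribed spectral
slope for validating the fit.

# What the synthetic data does and does not show

The generators emulate *properties* — known vorticity, helicity, wall
shear, ensemble TKE, prescribed pulsatility and between-subject
variability — not the atrium. Passing tests demonstrate that every
operator computes its quantity correctly and converges; they say nothing
about patient geometry, junction morphology, caval helicity magnitudes or
any solver-dependent result, all of which require an actual LES on a
reconstructed model. The two-vortex chamber is a qualitative stand-in for
the central-atrium vortex and its counter-rotating auricular companion,
used to exercise the region/sweep/trend pathway end to end (its
fluctuation stage scales TKE linearly with the SVC fraction so the trend
test has a constructed truth); its numbers are demonstrations, not
predictions.

# Problem sizes and determinism

Test and acceptance runs use deliberately modest sizes — 64 nodes per
diameter for wall-shear oracles, $48^3$ for Beltrami fields, $20^3 \times
200$ snapshots for TKE recovery, 500 synthetic subjects, 8192-sample probe
series — chosen so the full suite exercises every operator at tolerances
the convergence analysis supports. All stochastic stages take explicit
seeds; the pipeline fans per-stage seeds out of one global seed by a
stable hash of the stage name, and identical configurations produce
byte-identical output tables.

# Known limitations

* Staircase walls: surface averages on curved walls carry a resolution-
  dependent geometric bias even with smoothed normals; body-fitted
  accuracy is out of scope.
* The WALE operator is diagnostic; it does not feed back into any
  momentum balance, so $\mu_t$ on a given snapshot is an estimate of what
  an LES would model, not a solver state.
* The resolved/subgrid TKE split depends on the averaging-window
  convention documented above.
* Exact Wilcoxon enumeration is limited to $n \le 25$ pairs.
* `shapiro_wilk()` covers $3 \le n \le 50$, the range its published
  coefficient approximation targets.
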