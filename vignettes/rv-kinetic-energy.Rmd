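---
title: "Quantifying right-ventricular blood-flow kinetic energy from 4D flow CMR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying right-ventricular blood-flow kinetic energy from 4D flow CMR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rvkinergy)
```

## The measurement problem

Right-ventricular (RV) diastolic function is hard to assess with standard
two-dimensional imaging: the RV inflow is not aligned with any standard
imaging plane and Doppler-style measurements suffer from through-plane
motion of the tricuspid annulus. Whole-heart 4D flow cardiovascular MR
acquires a time-resolved, three-directional velocity field over the entire
ventricle, which permits two complementary quantifications:

* **intracavity blood-flow kinetic energy (KE)** — the voxel-wise kinetic
  energy of the blood inside the time-resolved RV cavity, summed per
  cardiac phase, and
* **retrospective valve tracking (RVT)** — through-plane flow on a
  measurement plane that follows the tricuspid annulus, perpendicular to
  inflow, yielding transvalvular stroke volume and E/A inflow velocities.

For every voxel the kinetic energy is

$$KE = \tfrac{1}{2}\,\rho_{blood}\,V_{voxel}\,v_{voxel}^2 ,$$

with $\rho_{blood} = 1.06\ \mathrm{g/cm^3}$, $V_{voxel}$ the voxel volume
and $v_{voxel}$ the velocity magnitude. With $\rho$ in g/cm³, $V$ in cm³
and $v$ in cm/s the product is in erg; 1 erg = 0.1 µJ. This unit chain is
the most error-prone step of the whole computation and is therefore kept in
a single internal constant used by `voxel_ke()` and everything above it
(100 cm/s in a 3 mm isotropic voxel gives 14.31 µJ).

Total KE per phase is normalised to the end-diastolic volume (KEi_EDV,
µJ/ml) so hearts of different sizes are comparable. From the
time-resolved KEi_EDV curve six summary parameters are derived: the global
mean over the cycle, the systolic and diastolic means, the cycle minimum,
the peak during early (E-wave) and late (A-wave) tricuspid filling, and
the E/A peak ratio — the last being the diastolic-function index of
primary interest, because a stiffening ventricle fills less passively
(smaller E peak) and relies more on atrial contraction (larger A peak).

## Pipeline

`run_subject()` sequences the stages; each is exported on its own.

**Velocity preprocessing.** Three corrections are supported, mirroring
standard 4D-flow quality control:

1. *Phase unwrapping* (`unwrap_velocity()`). Velocities beyond the
   velocity-encoding limit VENC alias by $2\,\mathrm{VENC}$. A voxel whose
   value differs from the median of its 3×3×3 spatial + adjacent-phase
   neighbourhood by more than VENC is shifted by $2\,\mathrm{VENC}$, and
   the sweep repeats until stable, so wrapped regions are corrected from
   their rim inwards. Only single wraps are corrected; apparent double
   wraps (jumps beyond $3\,\mathrm{VENC}$) are counted and left, since a
   shift of $4\,\mathrm{VENC}$ from a median reference is more likely
   noise than physiology at cardiac velocities. Every alteration is an
   exact integer multiple of $2\,\mathrm{VENC}$.
2. *Local phase correction* (`local_phase_correction()`), removing
   residual eddy-current background offsets. Static signal-bearing tissue
   is found by `detect_static_mask()` (temporal speed SD below 2 cm/s and
   magnitude at least 20% of the volume median — the concept is standard,
   the two numbers are this package's defaults). Slice by slice, the
   offset surface is the magnitude-weighted moving average of velocity
   over static voxels in a 24 mm window (≈8 voxels at 3 mm), subtracted
   everywhere. A weighted mean rather than a polynomial fit was chosen to
   behave as a genuine spatial low-pass filter; the window width trades
   offset smoothness against edge bias and is exposed as `kernel_mm`.
   Positions with no static tissue in the window fall back to the
   slice-wide weighted mean, and the correction is only claimed valid
   where static reference tissue exists.
3. *Rigid cine-to-flow alignment* (`apply_rigid_transform()`), trilinear
   resampling plus rotation of the velocity vectors. Estimating the
   transform (by image registration) is out of scope; the six parameters
   are supplied.

**Geometry.** Endocardial contours are drawn on short-axis keyframe phases
(1, 6, 12, 18, 24 of 30 by convention) and propagated to all phases by
`propagate_contours()`: contours are resampled to a fixed vertex count by
arc length, anchored at the angle-0 boundary point from the area centroid,
and matched vertices are interpolated linearly in phase, cyclically across
the R-R wrap. Radius-versus-phase linear interpolation was chosen to
mirror the cylindrical mesh construction that consumes the contours.
`build_mesh()` converts per-slice polygons into cylindrical coordinates —
per level and uniform angle, the radius is the distance from the centroid
to the boundary along that ray, interpolated linearly between slice planes
and extended constantly over the outermost half-slices (the disc model) —
and `mesh_to_mask()` marks every voxel whose centre lies inside the
surface. Boundary centres count as inside radially; along the long axis
the extent is half-open so commensurate grids do not double-count both
end-cap planes. Ventricular volumes, EF and the end-systolic phase come
from disc summation of the contours (`compute_volumes()`); EDV for KE
normalisation always comes from this cine-derived volumetry, not from the
flow-grid mask, since manual cine segmentation is the accuracy reference.
TAPSE (`compute_tapse()`) is the long-axis projection of the lateral
annulus displacement between end-diastole and end-systole, and right
atrial area (`compute_raa()`) is the shoelace area of the four-chamber
contour just before tricuspid opening, reported in cm² (the natural unit
for a ~23 cm² atrium) raw and BSA-indexed.

**KE mapping.** `ke_curve()` sums `voxel_ke()` over the per-phase masks;
`detect_cardiac_phases()` places end-systole at the volume minimum
(earliest phase on ties) and splits diastole into E and A windows at the
KE trough between the two dominant diastolic maxima, falling back to the
temporal midpoint (flagged) when no two distinct maxima exist; diastasis
is not separately modelled. `extract_ke_parameters()` reports the six
summaries. Whether the "systolic" and "diastolic" summaries are window
means or window peaks is genuinely ambiguous in the field; the default is
the mean and `window_stat = "peak"` is exposed.

**Valve flow.** `track_plane()` builds the measurement plane per phase
(centre = mean of the four annular landmarks from the two- and
four-chamber views, normal = unit vector toward the apex landmark, i.e.
the inflow direction). `reformat_plane_velocity()` samples the field on an
in-plane grid at half the smallest voxel pitch (oversampling stabilises
the integration) and projects onto the normal, apex-ward positive.
`background_correct_plane()` subtracts the mean through-plane velocity of
a myocardial ring ROI per phase, cancelling both residual offsets and the
annular through-plane motion the plane shares with the myocardium.
`tv_flow_metrics()` integrates forward flow over diastole for the
tricuspid stroke volume — forward-only by default because the synthetic
cohorts are healthy and regurgitation is out of scope; `net = TRUE` is
retained.

**Cohort statistics.** `build_report()` reproduces the standard analysis
set: mean ± SD descriptives by sex with pooled t-tests; Spearman rank
correlations (mid-ranks, two-sided t-approximation p) of every metric with
age; univariate regression of age on each metric followed by
forward-conditional selection over the univariately significant ones
(entry p &lt; 0.05, removal p &gt; 0.10 — the conventional thresholds, since
only the method is fixed by practice); and median ± IQR across five age
groups with Kruskal–Wallis H and Dunn pairwise letters. Dunn p-values are
reported unadjusted by default with a Bonferroni option; the letter
annotation marks, per group, which other groups it differs from at 0.05.
Reproducibility statistics use Lin's concordance coefficient
(population-variance form), its precision/accuracy decomposition, the
coefficient of variability `100·sd(x−y)/mean((x+y)/2)` and the percentage
bias on the same denominator — the paired-mean denominator is one of
several conventions in use and is stated in the function documentation.
"Average" reproducibility across KE parameters, where needed, is a simple
mean.

## The synthetic phantom

No subject-level 4D-flow data are publicly deposited for this kind of
study, so validation rests on an analytic phantom (`phantom_spec()`,
`make_phantom()`) with closed-form ground truth, emulating the target
acquisition: 30 reconstructed phases, 3 mm isotropic voxels, VENC
150 cm/s. The cavity is a tapered solid of revolution over 10 short-axis
discs (apical radius 30% of basal — a crude but convex RV); its volume
follows EDV → ESV → EDV (defaults 150 → 60 ml, i.e. EF 60% and SV 90 ml,
upper-normal values chosen so discretisation errors are exercised at
realistic voxel counts). The intracavity speed follows a three-peak
program — systolic $\sin^2$ bump to `v_sys` (60 cm/s), then raised-cosine
E and A bumps (defaults 50 and 38 cm/s, the healthy tricuspid inflow
range) centred at 30% and 78% of diastole with widths 50% and 36% —
uniform in space per phase so that total KE has the closed form
$0.05\,\rho\,V(t)\,v(t)^2$ µJ. A `parabolic` profile option gives a
spatially smooth field (needed to exercise unwrapping, whose neighbourhood
logic presumes smoothness); its truth KE then comes from the voxel oracle
rather than the closed form.

The phantom is volumetrically closed: the tricuspid aperture area is
derived as $A = (EDV-ESV)/\int_{diastole} v\,dt$, so the programmed
through-plane flow refills exactly the programmed stroke volume and
valve-plane stroke volume must equal the cine volume change up to pipeline
error — flow conservation is a property of the phantom, not an assumption
of the analysis. The annular landmarks, aperture polygon and myocardial
ring ROI are emitted alongside. `calibrate_phantom_ea()` retunes `v_a` by
root search so the discrete truth curve hits a requested KE E/A ratio,
which is how parameter-recovery experiments across the physiological span
(2.1 down to 0.7) are constructed.

What the phantom deliberately does not model: MR physics (k-space,
eddy-current fields beyond additive constant/linear offsets, Maxwell
terms — corrected on-scanner in practice), respiratory motion,
trabeculation and papillary muscles, non-convex cavity shapes, valve
leaflets, and intracavity velocity profiles beyond uniform/parabolic
(the true profile shape is unknown; uniform is an acknowledged
idealisation). Passing phantom tests therefore demonstrates correctness
of the numerics and the processing chain, not clinical accuracy on real
anatomy.

Synthetic cohorts (`cohort_spec()`, `make_cohort()`) stand in for a
53-volunteer healthy cohort, ages 20–80 (truncated normal 45 ± 17,
21/53 female, BSA 1.70 ± 0.20 / 1.94 ± 0.13 m² by sex). Each metric's
marginal is a truncated normal at its healthy reference mean ± SD
(truncation keeps physiological positivity, and only means and SDs are
reliably known), and the joint distribution is a Gaussian copula whose age
row is calibrated through $r = 2\sin(\pi\rho_s/6)$ so the *population
Spearman* correlation with age equals the programmed target exactly —
quantile transforms are monotone, so rank correlations survive the
marginals untouched. Metric–metric structure is a design choice with two
options: `one_factor` (metrics correlate only through age; always
feasible; the realistic default) and `independent` (identity metric
block, for selection experiments that require predictors carrying
independent information; rejected with a specification error when the
implied matrix is not positive semi-definite). Seeds are explicit fields
everywhere; nothing reads global random state.

## Numerical choices and conventions

* Arrays are `v[x, y, z, phase, component]` in cm/s; indices are 1-based
  (R convention) with voxel-centre physical mapping
  `x_mm = origin + (i−1)·spacing`.
* Diastolic inflow (apex-ward) is positive through the annular plane.
* End-systole ties break to the earliest phase.
* Mesh: 64 angles and 3 levels per slice by default; ray–polygon
  intersections take the nearest boundary on non-star-shaped polygons with
  a warning.
* The LPC box filter uses integral images (exact truncated-window means);
  the unwrap median filter is a small C++ kernel.
* Degenerate inputs error early and specifically: empty masks, monotone
  volume curves (no refilling), collinear annular landmarks, zero-variance
  series in the statistics, non-PSD cohort specifications.

## Problem sizes

The shipped tests and the acceptance script run phantoms of 24–96 voxels
per side (up to 1 mm grids for the refinement study), 8–30 phases, and
cohorts of 53 subjects with 100–1000 replicates for the calibration
experiments — sizes chosen so the full validation suite completes in a few
minutes on a single CPU while leaving every discretisation effect visible
at the 3 mm working resolution.

## Known limitations

* Mesh levels interpolate radii linearly between slice centres while the
  disc model steps at slab boundaries, so on strongly tapered shapes a
  thin band of mask voxels near slab transitions can carry no flow; on
  convex phantoms the induced KE error is a few percent and vanishes on
  straight cylinders. Partial-volume basal discs are not modelled.
* Voxel-centre masks fluctuate by 1–4% of volume at 3 mm for small
  end-systolic radii; this is inherent to centre-in/centre-out counting
  and shrinks with grid refinement.
* Double velocity wraps are flagged, never fixed.
* The forward-conditional selector refits with `lm()` at every step and is
  not meant for more than a few dozen candidates.
* Sex is generated independently of the metric latents, so synthetic
  cohorts carry no programmed sex differences; the sex-comparison table
  machinery is exercised, but its effects are null by construction.
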