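---
title: "Active thermography for hidden structure: models and methods"
author: "ThermoTrace"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Active thermography for hidden structure: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The physical model

Both studies share one physical mechanism.  A sample is heated from
above with a constant flux pulse and then cools naturally.  Hidden
structure — roots in soil, an air void in plexiglass — differs from its
surroundings in volumetric heat capacity $\rho c_p$ and conductivity
$k$, so it stores and releases heat at a different rate, and that
difference diffuses to the imaged surface as a faint spatial temperature
pattern.  Roots, whose specific heat far exceeds the soil's, act as heat
sinks: the surface above a shallow root runs measurably *cooler* during
cooling, and the deeper the root, the weaker and smoother the imprint.
An air void insulates: heat deposited above it cannot escape downward,
so the surface above a bubble runs *warmer*, the more so the larger the
cone's volume.

The solver integrates transient heat conduction

$$\rho c_p \frac{\partial T}{\partial t} = \nabla\cdot(k \nabla T)$$

on a voxel grid, with a prescribed flux $q$ on the top surface during
heating, convection $h\,(T-T_\infty)$ there throughout (plus radiation
$\epsilon\sigma(T^4-T_\infty^4)$ when enabled), and zero flux on every
other face.  Assumptions worth stating explicitly:

* materials are homogeneous with constant properties (no moisture
  transport in the soil, no temperature dependence);
* the air in the void conducts but does not convect — at millimetre
  scales the Rayleigh number is far below the convective threshold, and
  only conduction properties are defined for it;
* contact between layers is perfect (no interfacial resistance);
* the sample's lateral and back faces are perfectly insulated, as in
  the physical container.

## Geometry and rasterization

Samples are voxelized with a uniform in-plane pitch and a *per-layer*
depth thickness vector.  Depth layering is snapped to every material
interface (cover bottom, root-slab faces, tape, plate interface), so a
burial depth of 4.5 mm is represented exactly even at 1 mm pitch — the
grid refines locally instead of rounding the geometry.  Sub-voxel
membership is decided by the voxel centre (no partial-volume
weighting), which matches a 1 mm element-size discretization and keeps
rasterized and analytic volumes within discretization error of each
other; the tests pin the cone-volume error at 0.25 mm pitch to under
10%.

The taproot architecture is procedural: one central vertical primary,
lateral primaries leaving it at alternating sides (about 45° with a
seeded jitter), and short secondary laterals spread along all
primaries.  Primary segments are 1 mm in diameter, secondaries 0.5 mm,
both rasterized as 2-D capsules inside a 1-mm root slab.  The same
architecture (fixed seed) is reused across all nine burial depths, so
inter-depth comparisons isolate the depth effect.  Segments that would
leave the footprint are shortened at build time and rejected at
validation time.

## Solver numerics

The spatial discretization is a conservative finite-volume stencil with
**harmonic-mean face conductances**, the correct way to couple voxels of
dissimilar conductivity (soil–root, plexiglass–air, tape–plexiglass).
Two time-stepping paths share it:

* **Explicit FTCS.**  Step size bounded by the Gershgorin stability
  limit $\min_i C_i/\sum_j G_{ij}$ (a per-voxel capacity over total face
  conductance); the solver uses a 0.8 safety factor and auto-shrinks a
  too-large request with a log message.  This path serves the root
  sample, whose stable step at 1 mm pitch is about 0.5 s.
* **Dimensionally split backward Euler.**  The bubble sample contains a
  0.152 mm tape layer and air voxels whose stable explicit step is a few
  milliseconds, so the implicit path performs sequential implicit sweeps
  along x, y and z; each sweep is a tridiagonal solve, vectorized across
  all lines at once.  The scheme is unconditionally stable; because
  every one-dimensional operator has zero column sums, each sweep — and
  therefore the full step — conserves energy exactly.  Splitting error
  is $O(\Delta t^2)$ per step; the tests verify agreement with the
  explicit path on a shared grid to within a few hundredths of a
  kelvin.

Boundary sources (flux, convective sink, radiation) enter the z-sweep;
convection is treated implicitly (it joins the diagonal), radiation
explicitly from the current surface temperature.  Energy bookkeeping —
the summed enthalpy change $\sum_i \rho c_p V_i (T_i - T_0)$ — is
recorded at every frame, and the insulated-heating test requires it to
match $q A t_{heat}$ to 0.1% (both paths are in fact exact to rounding).
The solver is additionally validated against the semi-infinite-solid
constant-flux law $T_s(t) = \frac{2q}{k}\sqrt{\alpha t/\pi}$ on a graded
1-D acrylic column, which must hold within 3% over the first five
seconds.

Degenerate inputs are handled explicitly: an empty sample, non-finite
temperatures (aborts with step diagnostics), a heating duration that is
not a multiple of the frame interval (rejected so frame times align
with the heating end), and a zero-variance series wherever an $R^2$
would be undefined.

## Tunable parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| heat flux (root / bubble) | 0.0005 / 0.0012 | W mm⁻² | study conditions |
| heating, total (root) | 10, 120 | s | study conditions |
| heating, total (bubble) | 30, 150 | s | study conditions |
| initial/ambient (root / bubble) | 296.15 / 298.15 | K | study conditions |
| convection $h$ | 10 | W m⁻² K⁻¹ | typical still-air value; never stated in the source conditions, affects levels but not orderings |
| emissivity $\epsilon$ | 0 (root), 0.95 (bubble) | — | radiation is part of the bubble conditions only; 0.95 suits the taped surface |
| voxel pitch | 1 (root), 0.5 (bubble) | mm | 1 mm matches the element size of the reference discretization; 0.5 mm is needed so the smallest cones retain air voxels |
| frame interval | 1 (3 for bubble grids) | s | features are sampled every 3 s |
| smoothing window | 5 | px | single centred moving-average pass; edges truncate |
| tape $\rho, k, c_p$ | 1350, 0.19, 1350 | SI | typical vinyl tape; not pinned by any source table, flagged as such |

## The line scan and its detection limit

`detectRoots()` is deliberately literal: time-average the cooling
frames per pixel, smooth each line with one centred moving average, and
mark local minima found by the difference/sign/difference rule.  The
plateau semantics of that rule (with `sign(0) = 0`, both edges of a
flat valley fire) are preserved rather than reduced to strict valleys,
and are pinned by an exhaustive enumeration test against an independent
strict-valley oracle.  No noise filtering is applied by default — the
scatter of spurious minima is characteristic of the method — though an
isolated-pixel filter can be switched on.

A noiseless simulation, however, has no measurement-noise floor: the
minima sit on the root columns at *every* depth, however faint the dip,
so "how deep can the method see?" must be asked relative to an imaging
chain.  The packaged protocol (`deepestDetectableDepth()`) declares a
branch row *resolved* when (a) the detection map marks a pixel within
1 px of the central branch at that row and (b) the dip of the smoothed
time-averaged profile there exceeds the imaging noise floor

$$\sigma_{map} = \mathrm{NETD} / \sqrt{n_{frames}} / \sqrt{w},$$

i.e. the camera's thermal sensitivity improved by averaging the
$n_{frames}$ cooling frames and the $w$-pixel smoothing.  NETD defaults
to 0.02 K — a typical uncooled-camera figure and the same noise quantum
used by the robustness battery — and was fixed before the depth scan
was run.  A depth succeeds when a majority of branch rows resolve;
the reported limit is the deepest depth reached without an intervening
failure.  Positional criteria alone (recall against the dilated branch
under injected frame noise) were evaluated and rejected during
development: spurious minima are dense enough that position-only hit
rates sit near their chance level at every depth and cannot localise a
transition.

## Feature extraction and predictors

Per-point root features sample the cooling trace every 3 s from the
first recorded cooling frame, truncated to exactly 34 values; the
bubble features are the mean surface temperature every 3 s from the end
of heating (40 values) minus the initial temperature.  Baseline
subtraction makes bubble features exactly invariant to a uniform
ambient shift under the linear physics; with radiation enabled the
invariance is approximate (the $T^4$ term knows the absolute
temperature), which the tests bound at 1%.

* **Polynomial regression** uses the mean surface temperature at
  60–120 s (7 features) of eight models to predict the ninth; the
  8 × 8 normal system is solved by minimum-norm least squares so rank
  deficiency degrades gracefully rather than fatally.  Interior
  (interpolation) targets are compared against the two boundary
  (extrapolation) targets.
* **SVM**: one-vs-one RBF classifier over the nine literal depths as
  classes; cost and γ are grid-searched (2⁻¹⁰…2¹⁰, log₂ steps of 2)
  by 5-fold cross-validated accuracy, ties broken toward the smaller
  cost then smaller γ.
* **Neural networks**: single hidden layer (`nnet`, BFGS optimizer with
  MSE loss), features standardized by training statistics, hidden size
  selected by K-fold cross-validation with K = 5 (a conventional choice;
  the source protocol leaves K open) over 2–33 neurons for the depth
  model, 3–39 (MIMO) and 2–39 (MISO) for the bubble models.  Fold
  predictions are pooled before computing the selection $R^2$, which
  keeps the criterion defined down to leave-one-out.  The final model is
  refit on the 2/3 training split and scored on the untouched third
  with the relative-error accuracy $100(1-\overline{|ŷ-y|/y})$ — note
  the absolute value: without it, signed errors could cancel, and the
  metric's characteristic negative values for extrapolation failures
  would be unreachable.

## The noise battery

Fault tolerance is probed by adding zero-mean Gaussian noise of a
stated SD to a stated fraction (10/20/30%) of *training rows only*
(whole rows, every feature — "training input" granularity), retraining
with the model's usual recipe, and scoring on clean validation data.
Injecting into 100% of rows is rejected, since it would sever the
input–output relationship entirely.  The SD ladder is 0.02/0.04/0.06 K
for the root models and 0.1/0.2/0.3 K for the bubble models.  "SD
addition" is interpreted as the SD of the *added* noise, not a
rescaling of the data's own SD.  Wall-clock times are logged per cell
but never asserted.

## What the tests run, and what passing shows

The suite re-simulates the nine-depth battery at the full 65 × 95 mm
footprint and 1 mm pitch, and the complete 77 + 12 bubble grids at
0.5 mm pitch with 3 s implicit steps; unit tests use scaled-down
footprints (10–21 mm) where only solver mechanics are at stake, and the
network searches use thinned hidden-size candidate lists spanning the
full ranges.  These sizes are the package's own accuracy/runtime
trade-off and are stated here so they can be scaled up knowingly.

Passing shows that the *relative* structure of the study reproduces
under this package's independent numerics: orderings with depth and
bubble volume, the detection-limit transition, interpolation beating
extrapolation, network recovery of the buried parameters, and the
robustness contrast between the regression and the networks.  It does
not show agreement in absolute temperatures with any particular
commercial solver's nodal values — a different discretization family,
contact treatment and convection coefficient shift absolute levels —
nor does it certify behaviour on real imagery, which carries optical
effects (reflections, emissivity variation, vignetting) that the
generator does not emulate.

## Known limitations

* Air is a conducting solid; for cones much larger than studied here,
  internal convection would start to matter.
* The radiation term breaks exact ambient-shift invariance of bubble
  features (bounded at 1% in the tests).
* The single-output diameter network is not reliably better than the
  joint network at every seed; the two sit within a few accuracy points
  of each other on this generator's data.
* The procedural taproot is a stand-in: real root systems branch
  irregularly, taper, and contact the cover plane unevenly.
* Soil is dry and homogeneous; moisture gradients would both blur and
  bias the thermal contrast.
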