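---
title: "Angular-dependence correction of a 2D chamber array: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Angular-dependence correction of a 2D chamber array: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(arrayqa)
```

This vignette explains the models behind `arrayqa`: what is being corrected,
how the correction factors are defined and applied, how the gamma comparison
is computed, what the synthetic test bench does and does not emulate, and
which numerical and design choices were open and how they were settled.

## The correction model

A 32×32 ionization chamber array reads dose correctly for beams normal to
its surface, but its response depends on the beam's gantry angle θ: air
cavities and high-Z construction materials perturb the signal most where the
beam runs in the detector plane. The correction model assigns each detector
a multiplicative angular correction factor

$$\mathrm{CF}_{ij}(\theta) \;=\; N_{ij}\,
  \frac{D^{\mathrm{meas}}_{ij}(\theta)}{D^{\mathrm{ref}}_{ij}(\theta)},$$

the ratio of the array reading to a trusted reference dose at the same
point, normalised by $N_{ij}$ so that $\mathrm{CF}(0^\circ)=1$: at vertical
incidence the array is taken at face value, and the CF captures only the
*relative* angular effect. A corrected reading is the measured dose
*divided* by the CF interpolated at the acquisition angle.

Assumptions built into this model:

* **Row invariance.** CFs are characterised along the two central rows
  (16, 17) per column and broadcast over all rows of that column. The
  in-line (row) direction is parallel to the gantry rotation axis, so all
  rows of a column see the beam at the same angle; residual row-to-row
  differences are known to be small and are not modelled. `derive_cf()`
  therefore produces one curve per column plus a central curve (mean of the
  four central detectors), never a full 32×32×θ table.
* **Mirror symmetry.** CFs are measured over 0°–180° only;
  `predict(table, theta)` maps θ > 180° to 360° − θ. This presumes a
  symmetric setup (no couch in the beam during calibration, array centred).
* **Field-size independence.** CFs derived from one 30×10 cm² calibration
  geometry are applied to all field sizes. This holds to the extent the
  angular perturbation is a detector property rather than a scatter
  property.

Two application schemes exist. *Central* correction divides every detector
by the central curve — correct on average, wrong in shape wherever columns
deviate. *Entire* correction divides each column by its own curve. They
coincide exactly when all column curves equal the central curve (a tested
invariant), and differ most for lateral beams.

Movie-mode data (a sequence of ~0.2 s frames, each tagged by the gantry
angle sensor) are corrected frame by frame at the frame's own angle, then
accumulated; `correct_movie()` is exactly `accumulate ∘ map(apply_correction)`.
This is what makes arcs work: a 350° arc is a sequence of frames whose CFs
sweep the whole table.

## Calibration angle grid and interpolation

The calibration grid is 10° steps over 0°–180° plus 1° steps over 90°–110°
(37 distinct angles, `calibration_angles()`). The dense section brackets the
sharp features: the over-response peak at 90° and the deep under-response at
92° are only two degrees apart, so a 10° grid would alias them away.
Between grid angles CFs are interpolated piecewise-linearly; the
interpolation is exact at grid angles, and frames tagged between calibration
angles (arcs, arbitrary sensor readings) use the interpolated value. Linear
interpolation was chosen over splines deliberately: the 90°→92° transition
is nearly discontinuous and spline overshoot there would manufacture CFs
never measured.

Normalisation is realised as a per-column scalar
$N_j = D^{\mathrm{ref}}_j(0°)/D^{\mathrm{meas}}_j(0°)$ (and one for the
central curve), which is the only reading under which every curve equals 1
at 0° identically; `validate_cf_table()` enforces CF(0°) = 1 to 10⁻⁹ and
positivity on every table entering the apply path.

## Gamma evaluation

`gamma_map()` implements the standard dose-difference / distance-to-agreement
composite. For each reference pixel $r$ above the low-dose threshold,

$$\gamma(r) = \min_{e}\ \sqrt{\left(\frac{D_e - D_r}{\Delta D}\right)^2 +
  \frac{\lVert r - e\rVert^2}{\mathrm{dta}^2}},$$

minimised over evaluated-distribution positions $e$ within a search radius.
Choices that were genuinely open and how they were settled:

* **Normalisation dose**: default `global_max` — ΔD is `dose_tol`% of the
  reference maximum, the behaviour of the vendor analysis software this
  workflow replaces. A `local` mode (ΔD relative to the local reference
  dose) is provided but flagged experimental.
* **Threshold side**: the low-dose threshold excludes *reference* pixels
  (the distribution defining where dose was planned); configurable via the
  criteria object. A reference that is identically zero leaves nothing
  evaluable and returns a flagged result with an undefined pass rate.
* **Inclusive pass**: a pixel with γ exactly 1 passes (γ ≤ 1). Vendor
  software may differ at the margin; comparisons of printed pass rates
  should keep this in mind.
* **Search discretisation**: evaluated values between pixels are obtained by
  bilinear interpolation on a sub-grid of step `dta/10` (configurable),
  capped at a radius of `3·dta`. Reference pixels near the boundary search
  the clipped neighbourhood. The offset loop runs in order of increasing
  distance and stops once the pure spatial penalty exceeds the largest γ²
  still in play — an exact early termination, not an approximation.
* **Resampling**: both distributions are bilinearly resampled to a common
  isotropic grid (default 1 mm) over the intersection of their extents
  before comparison. Bilinear interpolation reproduces affine dose fields
  exactly (a tested property).

One numerical subtlety is worth knowing. Because the default sub-sampling
step scales with DTA, a 2%/2 mm and a 3%/3 mm evaluation probe *different*
discrete offset grids. Loosening the criteria can therefore, on pathological
inputs, flip an isolated pixel sitting exactly on the γ = 1 boundary even
though the continuous γ is monotone in the criteria. The test suite verifies
strict monotonicity with the sampling grid held fixed, and separately that
refining the sub-sampling step never increases any γ (finer grids are
supersets when the coarse step is a multiple of the fine one).

## The synthetic test bench

Nothing measured ships with the package, so all validation runs against a
parametric simulator with a known ground truth.

**Dose model** (`true_dose_plane()`): primary fluence as a product of
error-function penumbra profiles of the nominal field size in the beam's
rotated frame, times $e^{-\mu\,\mathrm{depth}}$ along the ray from the
phantom entry surface, times inverse-square fall-off from a point source at
SAD 1000 mm. The phantom is the 340×314×220 mm solid-water block that houses
the array, detector plane at mid-height. Defaults: penumbra σ = 3 mm,
μ = 0.0049 mm⁻¹ (6 MV) and 0.0041 mm⁻¹ (10 MV), dose scale 100 cGy per unit
beam weight — all stand-in values chosen to give realistic magnitudes and
gradients, all configurable. This is a *test harness*, not a dose engine:
it is smooth, deterministic and geometrically faithful (depth and obliquity
behave correctly), but has no scatter, no spectral hardening, no
heterogeneity, no MLC transmission.

**Response model** (`default_response_model()`): per-column relative
response $R_j(\theta)$ on the calibration grid. The central curve anchors at
1 at 0° and passes through the characterised extrema (+6%/−15%/−8% at
90°/92°/180° for 6 MV; +4%/−11%/−5% for 10 MV); between anchors it follows a
plausible smooth shape (slight sub-unity response at oblique angles,
recovery after the 92° dip, gentle decline to 180°). Column offsets vanish
at the two central columns, grow monotonically outward, and are scaled so
the central-vs-off-axis difference spans −6.1% to +7.0% (6 MV; −3.7% to
+6.0% for 10 MV) near 90° and stays within the small characterised ranges
elsewhere. Intermediate-angle values are linear interpolations between
anchors and are not claimed to match any measured device beyond the anchors
themselves.

**Measurement simulation** (`simulate_measurement()`): static beams are
split into 5 equal frames; arcs are discretised at 2° per frame using
segment-midpoint angles (so a 350° arc gives 175 frames). Frame dose =
true dose fraction × $R_j(\theta)$ × (1 + ε) with ε ~ N(0, 0.003)
independent per detector per frame — a 0.3% multiplicative noise floor
typical of chamber-array repeatability. Everything is reproducible
bit-for-bit under a seed. The arc ground truth uses the *same* midpoint
discretisation, so discretisation error cancels in round-trip tests;
convergence of the 2° step itself is a separate question from correction
accuracy and is not asserted.

**What passing tests do and do not show.** Round-trip recovery (derive CFs
from simulated calibration → correct an independently simulated plan →
match ground truth) validates the estimator, the interpolation, the mirror
logic, the per-frame application and the accumulation. It does not validate
the response model against a physical device, the dose model against a
Monte Carlo engine, or the behaviour under detector-to-detector calibration
drift, none of which are modelled.

## ROI averaging and absolute-dose comparison

Central-axis doses are compared through `roi_mean()`: the mean of the
bilinearly interpolated plane over a 1×1 cm² square (matched to a thimble
chamber's sensitive region), sampled on a 0.5 mm sub-grid. Averaging on the
interpolated plane (rather than on raw detector values) was an open choice;
it was selected because it is well-defined for ROIs not centred on a
detector and reduces to the detector value for uniform fields. Both the ROI
side and the sampling density are configurable.

## Problem sizes used by the shipped tests

The test-bench geometries are full-size: the complete 37-angle calibration
grid, 32×32 detector planes, the six standard multi-beam plan geometries
(opposed vertical/lateral, four- and six-field, 350° arc at 2°/frame), and
gamma analysis on ~236×236 mm planes at 1 mm pixels. Oracle comparisons for
the gamma implementation use 100 random 20×20 plane pairs against an
exhaustive all-pairs search; the noise model is checked on 10⁴ repeated
frames. These sizes were chosen to exercise every code path at the scale the
workflow actually runs.

## Known limitations

* One CF table per energy; no field-size- or depth-dependent CFs, and no
  per-row CF variation.
* The `local` gamma normalisation mode is experimental and untested against
  external software.
* Arc frames carry a single tagged angle; intra-frame angular spread during
  a 0.2 s snapshot is not modelled.
* No DICOM import: reference planes enter through the package's JSON format.
* The synthetic dose model's absolute calibration (dose scale, μ, penumbra
  width, SAD) is nominal; only relative comparisons are meaningful.
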