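---
title: "Curvature-driven cortical alignment at desk scale: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Curvature-driven cortical alignment at desk scale}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`cortexalign` evaluates how the choice of inter-subject alignment —
volumetric normalisation, surface-based analysis without macroanatomical
alignment, or curvature-driven cortex-based alignment (CBA) — changes the
group-level statistics of a visual field localizer experiment. This
vignette is the package's own account of the models it implements, the
parameters that matter, and the choices made where the design was
genuinely open. Everything quantitative said here is computed by the test
suite or by `scripts/acceptance.R`; nothing is asserted from memory.

## 1. Surface model

All subjects share one spherical mesh: an icosphere built by repeated 4-to-1
subdivision of the icosahedron, with `10 * 4^k + 2` vertices at level `k`.
Level 6 reproduces the 40,962-vertex standard meshes used in surface-based
fMRI packages (≈1.5 mm vertex spacing on a real hemisphere); the package
defaults to level 4 (2,562 vertices, ≈5 mm at an 80-mm cortex radius) so a
full experiment runs in minutes on one CPU. Coarser levels are vertex
*prefixes* of finer ones, which the alignment exploits as a natural
multiresolution hierarchy. The synthetic study uses one merged sphere; the
hemisphere-by-hemisphere bookkeeping of scanner pipelines is represented by
analysing a single combined mesh.

Curvature on a folded mesh is estimated per vertex by fitting an algebraic
sphere to the 1-ring (exact on a true sphere, hence the map is exactly
constant there), taking the fitted gradient as a refined surface normal,
and projecting the umbrella (uniform Laplacian) vector onto it. The value
is normalised by the global mean edge length — making it invariant under
uniform rescaling of the anatomy — and squashed with `tanh` into `[-1, 1]`,
convex (gyral) positive. Any smooth folding-sensitive scalar would do for
alignment; this one was chosen because it has exact degenerate-case
behaviour that the tests can pin down.

One smoothing "iteration" replaces each vertex value by the unweighted mean
of itself and its 1-ring; at 1.5-mm spacing one iteration approximates a
2D Gaussian of ≈3 mm FWHM, which is why the surface arms smooth functional
data by exactly one iteration.

## 2. Synthetic cohort

The generator's defaults *are* the study conditions; they were fixed before
the acceptance checks were first run and are not tuned per run.

* **Template anatomy.** Curvature is a zero-mean, lightly smoothed sum of
  `n_ridges = 60` oriented Gaussian ridges with alternating sign. Sixty
  ridges make folds tile the sphere the way gyri and sulci tile cortex;
  with sparse patterns (say 24) large featureless regions make the
  alignment problem locally underdetermined. The folded mesh displaces the
  sphere radially by `fold_amplitude_mm = 6` mm per unit curvature around a
  `radius_mm = 80` mm base.
* **Quadrant ROIs.** Four geodesic discs (`roi_radius = 0.18` rad ≈ 20
  vertices at level 4) at mirror-symmetric positions 25° from the
  "occipital" pole. The disc centers sit on mirror planes of the
  icosahedral symmetry group, so opposing ROIs have *exactly* equal vertex
  counts and the template's asymmetry indices are exactly zero.
* **Anatomical variability.** Each subject's warp composes 24 localized
  rotations (random axis, random center, Gaussian angular falloff with
  `warp_smoothness = 0.8` rad, per-rotation angle in `[0.7, 1] x
  warp_magnitude`, default magnitude 0.15 rad). Two properties motivated
  this shape. First, with broad, numerous rotations the field is globally
  coherent and near-isometric — emulating what is left after volumetric
  normalisation: residual global misalignment plus smooth local
  variability — and it is statistically stable across cohorts (8 narrow
  bumps leave the four ROIs nearly untouched under some master seeds,
  which would abolish the very variability the study is about). Second,
  individual warped ROI sizes then vary by up to ±40%, consistent with the
  well-known ~twofold inter-individual variation of early visual areas;
  the transport is unbiased, so cohort-mean ROI counts stay within a few
  percent of the template counts (the conservation property the tests
  assert).
* **BOLD.** `bold(v, t) = X(t, ·) β(v, ·) + baseline + AR(1) noise`, with
  `β = signal_amplitude` (default 1) inside a condition's warped ROI and 0
  elsewhere, AR(1) coefficient 0.3, and marginal noise SD 6 — calibrated so
  single-subject ROI t values land in the 4–8 range typical of
  attention-enhanced checkerboard localizers, giving detection rates of
  90–100% and an unaligned-arm peak overlap well below 100% (the partial-
  overlap regime the study design is about). The GLM deliberately ignores
  the autocorrelation, as the summary-statistic random-effects analysis
  absorbs it.

What the generator does **not** emulate: hemodynamic nonlinearity,
physiological noise, head motion, susceptibility distortion, or any
systematic upper/lower-hemifield asymmetry (`true_amplitude` is a knob, and
symmetric by default — whether to emulate asymmetric hemifields is a user
choice, not an assumption). Passing tests therefore demonstrate the
correctness and behaviour of the *pipeline*, not the physiology of real
data.

## 3. Paradigm and GLM

The localizer timeline is 144 2-s trials (36 per quadrant, uniformly
shuffled), 36 target trials (9 per condition), regular 0-ms ITI with a
2000-ms prolonged ITI after gaps drawn uniformly from 10–14 trials (11
overall, redrawn until the schedule fits), a 10-s lead-in and 20-s
lead-out: 340 s exactly, concurrent with 170 2-s volumes of which the
first 4 are discarded (the lead-in covers them).

The design convolves per-condition box-cars at 0.1-s resolution with a
two-gamma kernel — gamma densities with rate 1 and shapes 6 and 16 (peaks
at 5 s and 15 s), response:undershoot ratio 6, truncated at 32 s, unit
peak. These are the standard two-gamma defaults; the source experiment's
exact kernel parameters are not published, so they are configurable.
Because of the undershoot, condition regressors are necessarily negative in
places; the tests bound them by `HRF peak x maximal trial overlap` above
and by the undershoot amplitude below. Temporal preprocessing removes the
per-series linear trend and zeroes all Fourier bins strictly below
0.00903 Hz (the mean is kept). Note that FFT bin zeroing removes
bin-aligned components to machine precision but leaves spectral leakage for
off-bin frequencies — an inherent property of the method, not an
implementation artefact.

The GLM is ordinary least squares per vertex/voxel with predictors = 4
condition regressors + constant (filtering happens beforehand, so no trend
column). The position-of-interest contrast assigns +3 to the target
quadrant and −1 to each other quadrant; the published description uses a
ratio notation for this construct, which is read as "versus" since a ratio
is not a linear contrast. t statistics with numerically zero residual
variance are capped at ±1e6 and flagged (and numerically-zero effect
estimates stay at t = 0, so noiseless degenerate cohorts behave exactly).

## 4. The alignment algorithm

**Rigid stage.** The rotation maximising the Pearson correlation between
target curvature and rotation-resampled subject curvature, both at the
heaviest smoothing level. The search evaluates the full 15° Euler grid
(7,488 rotations, vectorised) on the 42-vertex icosahedral prefix, refines
the best six candidates by Nelder–Mead at the 642-vertex prefix, and
polishes the winner at full resolution with barycentric (smooth)
resampling. Near-ties are broken by the smallest rotation angle. Recovery
of a known rotation is within 2° at level 4.

**Non-rigid stage.** Each subject minimises
`E(w) = Σ_v [c_s(w(v)) − c_t(v)]² + λ Σ_e (ℓ/ℓ₀ − 1)²` by projected
gradient descent on the sphere with backtracking line search; steps that
invert a spherical face or increase E are halved, so the accepted-step
trace is non-increasing by construction. Two numerical choices matter:

* the descent direction is smoothed over the mesh before stepping
  (a Sobolev-gradient preconditioner, 6 averaging iterations by default).
  This leaves the objective and its monotone line search untouched while
  propagating matched motion along iso-curvature contours, where the raw
  data gradient vanishes (the aperture problem of curvature matching);
* `λ = 0.02`. With curvature normalised to `[-1, 1]`, stronger
  regularisation (0.1) freezes the warp at 55–70% of the initial
  correspondence error on known-warp subjects, while much weaker values
  (0.002) overfit curvature noise. 0.02 recovers known warps to under 40%
  of the initial error while still rejecting face inversions.

**Group schedule.** Four coarse-to-fine levels with smoothing iterations
(200, 80, 20, 2) at level-4 resolution, scaled with vertex count. The two
heaviest levels run on the next-coarser mesh prefix (their smoothing scales
carry no information beyond it) and the warp is upsampled through the
subdivision midpoints — the same physical schedule at a quarter of the
cost. Per level, 4 moving-target updates alternate with up to 25 morph
iterations per subject. The recorded group objective is non-increasing
within each level because morphs are monotone and the target update (the
mean of the warped curvatures) minimises the summed data term. The full
procedure runs twice; pass 1 exists only to manufacture an unbiased
average curvature as pass 2's rigid target, so no individual's anatomy
biases the group space.

Ground truth makes alignment quality measurable: each synthetic subject
stores its true warp, and `correspondence_error()` composes the estimated
correspondence with it, giving a per-vertex geodesic error that equals the
raw displacement for the identity estimate and ≈0 for perfect recovery.

## 5. The volume arm

The volumetric analog reduces volume-based analysis to its statistically
relevant differences — 3D smoothing across folds and voxel-level analysis
without cortical correspondence — because there is no scanner data to
correct. Per subject, the surface time series are rasterised into a shared
3-mm grid (mirror-symmetric about the origin, like a scanner iso-centre)
using that subject's folded anatomy, smoothed with a 3D Gaussian of 3 mm
FWHM (missing voxels excluded with weight renormalisation, to avoid edge
attenuation on the thin cortical shell), filtered and analysed per voxel
with the identical GLM. Group statistics are computed in volume space over
the voxels common to all subjects — which are fewer than the surface
vertices, reproducing the smaller volumetric analysis space and hence its
more lenient Bonferroni threshold — and thresholded group maps and
probability maps are then projected onto the average folded surface by
trilinear sampling at 9 depths from −1 to +3 mm along vertex normals
(thresholding happens in volume space, before projection).

## 6. Evaluation statistics

All of the study's evaluation machinery is implemented as composable
functions returning tibbles: random-effects one-sample t maps (df = n−1,
zero-variance guard), Bonferroni thresholds (`alpha / n_tests` over each
arm's own analysis space), group-ROI extraction (edge-connected components
of the suprathreshold set; the component containing or nearest the
expected quadrant seed wins over larger components; in synthetic runs the
seed is the ground-truth ROI overlap maximum, mirroring the anatomical
expectation an analyst would use), ROI size change
(`(after − before)/before × 100`, integer rounding), asymmetry index
(`|a − b|/(a + b) × 100`, one decimal), single-subject thresholding at
one-sided p < .05 uncorrected, probability maps (per-vertex percentage of
active subjects; display threshold 10%, cluster filter 100 vertices applied
after the threshold), probability difference maps (from unthresholded PMs,
±5% reporting threshold, antisymmetric by construction), peak-vertex
distributions with lowest-index tie-breaking, detection rates, and the
position-selectivity comparison across arms — implemented as
repeated-measures ANOVA (arm effect with subject blocks), with a
random-intercept mixed model available via `method = "lmm"`; on balanced
complete data the two coincide, which a test verifies. Single-subject ROI
detection additionally requires the candidate cluster within 0.35 rad of
the expected seed — without a locality constraint a p < .05 uncorrected
threshold would "detect" every subject from noise alone.

Report tables mirror the structure of the study's published tables
(group ROIs, size changes, selectivity, asymmetry, PM extents and maxima,
PDM summaries, peak distributions, detection rates) and are written as CSV
by `write_report()`.

## 7. Problem sizes and limitations

Default experiments use 20 subjects on 2,562-vertex meshes; unit tests use
4–6 subjects on 642-vertex meshes; the recovery benchmarks run at level 4.
These sizes were chosen so that the full pipeline — including two-pass
alignment of 20 subjects — completes in roughly ten minutes on a single
CPU, which is what makes the package usable as a teaching and
method-development sandbox.

Known limitations: the non-rigid optimiser is first-order (tens of
iterations per level, not a Newton scheme); curvature matching cannot
determine correspondence along iso-curvature contours beyond what the
distortion penalty and the Sobolev smoothing interpolate; the volume arm
omits every scanner-side correction by design; Talairach coordinates are
out of reach of a synthetic sphere, so ROI centers are reported in mesh
coordinates; and the generator's noise model (AR(1) + white) is a
deliberate simplification of fMRI noise.
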