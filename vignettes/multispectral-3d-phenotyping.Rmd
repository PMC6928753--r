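---
title: "Multispectral 3D plant phenotyping: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multispectral 3D plant phenotyping: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msplant3d)
```

# The problem

Canopy nutrient status (nitrogen, phosphorus, potassium) is classically
measured destructively by wet chemistry — Kjeldahl titration for N,
molybdenum-antimony spectrophotometry for P, flame atomic absorption for K
(`nitrogenMassFraction()` and friends implement those mass-fraction
formulas). A nondestructive alternative images a potted plant on a motorised
turntable with a depth camera and a hyperspectral imager, fuses the two
modalities into a *multispectral 3D point cloud* — every surface point
carries reflectance at selected wavelengths — and regresses nutrient content
on the mean canopy reflectance of the reconstructed model. msplant3d
implements that pipeline end to end, together with a fully synthetic scene
generator so every stage can be validated without hardware.

The pipeline has five stages, each a package module:

1. **Spectral registration.** The spectral imager and the depth camera view
   the scene from different positions with different optics, so each
   spectral image is displaced, rotated and scaled relative to the depth
   frame. Translation is estimated by phase correlation (the peak of the
   inverse FFT of the normalised cross-power spectrum); rotation and scale
   by the Fourier–Mellin method (phase correlation on log-polar resampled
   FFT magnitude spectra, which converts rotation/scale into translation).
   One shared transform is applied to all bands of the cube.
2. **Turntable self-calibration.** Two RGB-D frames of the empty turntable,
   180° apart, show a yellow and a red calibration sticker. A half-turn maps
   each sticker centre to its antipode, so the midpoint of each pair lies on
   the rotation axis and the normalised cross product of the two chords is
   the axis direction.
3. **Reconstruction.** Each depth frame is back-projected through the
   pinhole model ($x = (i-c_x)z/f_x$, $y = -(j-c_y)z/f_y$, $z$ in metres
   from millimetre depth). Views are *rough-registered* by translating the
   axis centre to the origin, rotating the axis onto +Y, and undoing each
   view's turntable angle about Y; sequential point-to-point ICP then
   refines residual misalignment (plants are not perfectly rigid during
   rotation). Spectral attributes ride along unchanged.
4. **Quality metrics.** Registration quality: normalised grayscale
   similarity $D = 1 - \sum|M - F| / (mn \cdot 255)$ and spectral overlap
   $C = 100\,|F_2 \wedge M_2|/|F_2|$. Reconstruction accuracy: the directed
   Hausdorff distance set (per reconstructed point, the distance to its
   nearest reference-cloud neighbour), summarised by mean, population
   standard deviation, maximum, and the proportion of distances in the
   segments (0, 0.1], (0.1, 0.3], (0.3, 0.6], (0.6, 1.0] and > 1 cm.
5. **Wavelength selection and regression.** Characteristic wavelengths per
   nutrient come from a combined PCA / correlation-coefficient / random-frog
   procedure; nutrient models are a back-propagation neural network, an
   epsilon-SVR with Gaussian kernel, and a Gaussian-process regression with
   rational-quadratic kernel, evaluated by $R_c^2$, $R_p^2$, RMSEC, RMSEP
   and the mean relative prediction error RE.

# Conventions that matter

Image geometry uses x = column, y = row, 0-based, with rotations measured
from +x towards +y and scale/rotation acting about the image centre,
translation applied last. `registerImage(fixed, moving)` returns the
transform that maps the moving image *into the fixed frame*:
`applyTransform(moving, t)` is aligned with `fixed`. The lower-level
`phaseCorrelation()` and `fourierMellin()` instead report the
shift/rotation/scale *of the moving content relative to fixed* (the two
directions are inverses; both are documented on each function).

The camera frame has x right, y up (the back-projection negates $j - c_y$),
z forward. `axisAngles()` returns the signed angles $\alpha$ (about X) and
$\beta$ (about Z) such that $R_x(\alpha)R_z(\beta)$ maps the axis direction
onto +Y with the package's rotation matrices; for an axis tilted towards +Z,
$\alpha$ is negative under this convention. The rough-registration rotation
is composed as $R_y(\gamma) R_x(\alpha) R_z(\beta)$ — the turntable angle is
undone *after* the axis is aligned with Y, which is the only order that can
undo a rotation about a tilted axis; the synthetic round-trip test (a
physically rotated view must land on the reference view to <1 mm,
noise-free) pins the convention and the sign of $\gamma$.

# Numerical choices

**Windowing and spectra.** Images are Hann-windowed before FFTs used for
rotation/scale estimation (suppresses wrap-around edges); plain phase
correlation is unwindowed by default so exact circular shifts are recovered
exactly. The log-polar grid uses 0.5° angle bins over [0°, 180°) (the
magnitude spectrum is conjugate-symmetric) and 256 logarithmic radius bins
over [5, min(m,n)/2] pixels. The radial range starts at 5 px because the
DC-adjacent core of the spectrum is nearly rotation-invariant and otherwise
dominates compact-object images. Magnitudes are log-compressed (`log1p`).
Both images receive a 1 px Gaussian pre-smoothing before the spectral
analysis: point-splat renders (and other resampled imagery) carry pixel-grid
combs that are identical in both images and would anchor the spectrum
correlation at the identity. Subpixel refinement is a three-point parabolic
fit around the correlation peak — always on inside the log-polar step,
opt-in for plain translation (`subpixel = TRUE`).

**The 180° ambiguity.** A half-spectrum cannot distinguish θ from θ+180°;
both candidates are used to de-rotate/de-scale the moving image and the one
with the higher final translation-correlation peak wins.

**Resampling.** `applyTransform()` inverse-maps every output pixel and
samples bilinearly; an output pixel whose source is outside the image or
touches an invalid source pixel is marked invalid in the cube mask —
reflectance is never zero-filled. Accuracy on band-limited textures:
rotation within ~0.05°, scale within ~0.3%, translation subpixel; the
contract tested everywhere is (1 px, 1°, 2%).

**Axis estimation.** The two sticker midpoints must agree within 5 mm
(configurable) and the chords must subtend at least 5°; violations raise
classed errors rather than returning an ill-conditioned axis. Sticker
colour gates are simple RGB min/max boxes (defaults target saturated
yellow/red) — the colour threshold is deliberately configuration, not
hard-coded.

**ICP.** Point-to-point, correspondences from a k-d tree gated at 1 cm,
least-squares update by Kabsch, stopping at 50 iterations or when the
inlier RMSE improves by less than 1e-6. No voxel downsampling by default —
the clouds involved (10⁴–10⁵ points) are comfortably within k-d tree range.

**Hausdorff statistics.** Distances are Euclidean (configurable choices were
considered and rejected — nothing in the evaluation needs another metric),
the set is *directed* (reconstruction → reference; the maximum equals the
classical directed Hausdorff distance), the standard deviation uses the
population (divide-by-N) convention, and exact zeros count in the first
segment. Coordinates are metres internally; HD is reported in cm.

**Grayscale similarity region.** $D$ is computed over the full common frame
by default with an optional crop applied identically to both images — which
pixels constitute "the registered region" is a parameter, not an assumption.

# Wavelength selection

Spectra are smoothed per curve with a Gaussian kernel; the "data window 6"
smoothing convention is interpreted as a kernel of width 6 samples with
$\sigma = \text{width}/3 = 2$ (reflective boundary). Six
infrared-interference bands (841.42–868.65 nm, contaminated by the depth
camera's active illumination) are dropped, mapping the 128-band instrument
grid to 122 usable bands.

PCA runs on centred, unscaled reflectance (all bands share one unit);
per-component contributions are percentages of total variance and candidate
wavelengths are local extrema of the absolute loadings aggregated across the
top components, weighted by contribution (the per-component-versus-aggregate
choice is not fixed by the procedure's description; aggregation is the
package's default and the loadings are returned for per-component use).

Random frog is a reversible-jump-style stochastic search over wavelength
subsets: propose a subset size from $N(q, 0.3q)$, shrink by keeping the
largest absolute PLS coefficients or grow by sampling a 3× pool from the
complement and keeping the best, accept on cross-validated RMSE (worse
candidates with probability $0.1 \cdot \mathrm{RMSE}/\mathrm{RMSE}^*$), and
report per-wavelength selection frequencies. The inner model is SIMPLS with
up to 5 latent variables; candidates are scored at the *full* depth
$\min(5, |V|)$ rather than the CV-optimal depth — scoring at the optimal
depth lets noise variables ride along in a smaller latent space, leaving
candidate subsets near-tied and the chain sticky. Cross-validation folds
are redrawn every iteration and shared by the current and candidate subset:
the comparison inside an iteration stays fair, while no subset can occupy
the chain indefinitely by owning a lucky fixed split (with frozen folds the
chain collapses onto the single best-scoring variable even on pure noise).
The whole procedure is deterministic given its seed.

The combination rule (`selectWavelengths()`): take local peaks of the
random-frog probability; require the peak's neighbours to be strongly
correlated bands (|r| ≥ 0.9 adjacency screen — a peak in a decorrelated
region is likelier noise); drop peaks that fail both the nutrient
correlation screen (default |r| ≥ 0.5) and proximity (≤10 nm) to a PCA
loading peak; append any supplement wavelengths justified by PCA-CC
evidence, flagged `PCA-CC-supplement` in the per-wavelength provenance.

# Nutrient models

All three learners standardise inputs (and response) internally.

* **BPANN** — three layers, 15 tanh hidden units, linear output, seeded
  initialisation, trained by BFGS (quasi-Newton) on mean-squared error in
  chunks of 100 iterations up to 500, stopping early when the standardised
  MSE reaches 1e-4. A small L2 penalty (1e-6) stabilises the Hessian
  approximation.
* **SVMR** — epsilon-SVR, RBF kernel with gamma $= 1/(2\,ks^2)$; the default
  kernel scale 0.56 reproduces the fine-Gaussian preset of the original
  modelling toolbox, and `kernelScale = "auto"` substitutes the median
  pairwise distance of the standardised features. "Automatic" box constraint
  and epsilon follow the iqr(y)/1.349 rule expressed relative to sd(y)
  (the svm backend standardises the response, so a Gaussian response yields
  cost 1 and epsilon 0.1). Note the fine-Gaussian scale is very local: on a
  few dozen standardised samples it approaches a lookup table, which is
  visible in its weaker prediction R² — use `"auto"` when generalisation
  matters.
* **GPR** — constant mean (absorbed by centring), isotropic
  rational-quadratic kernel
  $k(r) = \sigma_f^2 (1 + r^2/(2\alpha\ell^2))^{-\alpha}$ plus noise,
  hyperparameters by L-BFGS-B maximisation of the log marginal likelihood
  from seeded restarts, Cholesky jitter escalation (1e-10 → 1e-4) before
  declaring failure.

Evaluation: $R^2$ is the squared Pearson correlation between measured and
predicted values (matching a measured-vs-predicted correlation analysis; the
$1-\mathrm{SSE}/\mathrm{SST}$ convention is available via `r2 =
"variance"`). RE is defined here as the mean absolute relative error over
the prediction set in percent — the quantity is often left undefined in
applied reports, so the definition is part of the package contract.
`calibrationSplit()` defaults to a seeded 42/18 shuffle, the
modelling/verification split used with 60 samples. `runModelMatrix()` fits
the full nutrients × sources (AOV1–4, 3DROI) × learners grid — 45 models for
the full design — and emits one evaluated row each.

The mechanism behind the stability advantage of 3DROI features is directly
testable: when each single view sees a biased subset of an unevenly
reflective canopy, per-view mean reflectances differ while the full-cloud
mean is view-independent; the test suite asserts exactly that.

# The synthetic generator

`sceneSpec()` fixes the study conditions: four views 90° apart, a 512 × 424
depth camera (f ≈ 365 px) about 1.2 m from the plant, depth quantisation
1 mm and depth noise σ = 2 mm (consumer depth-camera class; both
configurable, tests use 0 where a noise-free contract is asserted), a
five-band cube, and a known spectral corruption transform (default shift
(10, 6) px, rotation 5°, scale 1.08) whose recovery is a test contract.
The plant is a rigid parametric surface — cylindrical stem along the
rotation axis, eight elliptical leaf patches on a golden-angle phyllotaxis,
a pot whose points carry *no* reflectance (the spectral imager frames only
the canopy; pot points are reflectance-invalid, not zero). Surfaces are
sampled at 1e6 points/m², emulating a dense handheld-scanner reference
(0.1 mm class) so that reference sampling does not dominate the
reconstruction error being measured.

Rendering is a z-buffer with 1-pixel splats; within a 3 mm band of each
pixel's front surface the point nearest the pixel centre supplies the depth,
which best represents the surface along the back-projection ray (plain
min-z sampling injects up to half a pixel of lateral error, ~1.6 mm at this
geometry). Depth is noised then quantised. The sticker calibration frames
observe one rigid disc + sticker point set at 0° and 180°, as a real
turntable would.

What the generator does *not* emulate: BRDF/illumination effects, lens
distortion, depth-sensor systematic biases (flying pixels, multipath), and
non-rigid plant motion (stem/leaf shaking — the known dominant error source
on real plants; per-view rigid jitter can emulate a mild version). Passing
the synthetic contracts therefore demonstrates geometric and algorithmic
correctness, not field performance.

Two spectra generators serve different purposes. `makeNpkDataset()`
emulates the study design: five nutrient doses (25–200% of standard), 12
plants per dose, saturating monotone dose responses with 5% per-plant
jitter, nutrient-linked Gaussian signatures at planted bands and smooth
correlated noise — use it for pipeline-shape tests (with zero noise each
nutrient correlates ±1 with its planted bands). Because all three nutrients
share the one-dimensional dose signal, *exact* subset recovery is not
well-posed on it: any planted band is a complete proxy for its nutrient,
and correlated noise makes some unplanted bands genuinely useful for noise
cancellation. Selector validation therefore uses
`makePlantedSignalSpectra()`, where the response is constructed as a linear
map of exactly five spectral columns plus noise at a stated SNR — there the
planted set is identifiable and the random-frog top-8 contract holds across
seeds.

# Problem sizes and determinism

The test suite and the acceptance script run synthetic scenes with ~10⁵
ground-truth points and ~1.5 × 10⁴ reconstructed points, 20-pair transform
recovery at 256², 100-trial noisy axis calibration, 20-seed × 1000-iteration
random frog at n = 200 × 122 bands, and the full 42/18 regression grid —
sizes chosen so each contract is exercised at meaningful scale while a full
run stays in the minutes range on one CPU. Every stochastic stage takes an
explicit seed and restores the caller's RNG state; full-pipeline
determinism (identical outputs from identical seeds, byte-identical CLI
reports) is itself a tested property.

# Known limitations

* Rotation/scale estimation assumes the two modalities share enough mutual
  structure after graying; strongly divergent content (e.g. pot visible in
  one modality only) degrades the Fourier–Mellin estimate — the package
  registers reflectance-derived grays against reflectance-derived
  references in its own tests for exactly this reason.
* Large rotations (≫20°) on compact low-texture objects are less reliable;
  the hardware this models has a fixed rig with small inter-sensor rotation.
* ICP is point-to-point with sequential chaining; there is no global pose
  graph, so errors can accumulate over many views (four views keep this
  negligible).
* The nutrient models are interpolators; extrapolation beyond the
  calibration dose range is not meaningful, and the fine-Gaussian SVR
  default is intentionally faithful rather than optimal.
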