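---
title: "Quantifying regional lung function with xvlung"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying regional lung function with xvlung}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xvlung)
```

## The measurement problem

Muco-obstructive lung diseases are patchy: mucus plugs obstruct some
airways while others ventilate normally, so a single global number (a
spirometric volume, an impedance parameter) can look nearly normal while
parts of the lung have stopped moving. X-ray velocimetry (XV) addresses
this by imaging the breathing lung as a time-resolved series of 3D
volumes and tracking the speckled lung texture from phase to phase. The
result is a displacement vector field over the lung at every breath
phase, from which regional expansion — and hence a spatial map of lung
function — follows.

`xvlung` implements the quantification chain downstream of image
acquisition: velocimetry, expansion mapping, histogram-based disease
scoring, global volume–time analysis, orientation/segmentation
preprocessing, and quality control, validated end-to-end on a built-in
synthetic breathing-lung phantom.

## Velocimetry

`estimateDisplacements()` tiles each pair of consecutive volumes into
cubic interrogation windows (default 64³ voxels at 50 % overlap, the
setting used for mouse lung CT at full resolution; the XV grid stride is
then 32 voxels). Each window pair is mean-subtracted and
cross-correlated in the spectral domain; the correlation peak gives the
integer displacement, refined per axis by three-point Gaussian
interpolation of the peak ordinates. Two numerical details matter:

* **Overlap-taper correction.** Circular FFT correlation of finite
  windows implicitly weights lag `d` by the window overlap
  `(N−|d|)/N` per axis, which biases sub-voxel peaks toward zero. The
  three ordinates used for interpolation are divided by this weight
  before the fit. Ties at the integer peak are broken toward zero
  displacement.
* **Validation.** Each vector carries a peak-quality ratio
  (tallest over second-tallest correlation peak, the second peak sought
  outside a 7³ neighbourhood because band-limited speckle has a broad
  main lobe). Vectors under 1.2 are flagged invalid and replaced by the
  component-wise median of their valid 3³ neighbours. Windows with under
  50 % lung-mask coverage are not correlated at all and stay `NA`.

Displacements are expressed in voxels per frame and accumulated across
phases by summation on the fixed XV grid. This small-displacement
(Eulerian) accumulation is a documented approximation: it is accurate
while per-frame motion is well under the window size, which holds for
breath sequences sampled at 15 phases, but it is not Lagrangian
tracking.

The original XV literature couples correlation to the CT reconstruction
itself; that algorithm is proprietary and undocumented, so this package
implements a declared, standard baseline (pairwise windowed
cross-correlation) and states its accuracy on phantoms rather than
claiming equivalence.

## From displacement to regional expansion

`fractionalExpansion()` accumulates the fields from breath start to peak
inspiration and computes per XV voxel the local volume change
`det(I + ∇u) − 1`, the continuum equivalent of (change in region
volume)/(region volume). Gradients use central differences on the XV
grid, falling back to one-sided differences at mask borders so that
vectors outside the lung (invalid or meaningless) never contaminate the
interior. On affine fields the determinant is exact: a uniform dilation
`u = αx` yields `(1+α)³ − 1` to machine precision, and a rigid
translation yields 0 — both are fixed oracles in the test suite. Peak
inspiration is the phase of maximum global fractional volume, ties
broken to the earlier phase. The mainstem bronchi (or any other region)
can be excluded with `applyExclusion()`; all downstream statistics
ignore excluded voxels.

## Histogram, double-Gaussian fit, and disease scores

`expansionHistogram()` bins the raw in-mask expansion values over their
range (default 50 bins) and normalises the area under the histogram to
one, so lungs of different sizes are comparable. The IQR is computed
from the raw, unbinned values with linear-interpolation quantiles — the
histogram is the visualisation, but quantiles of the underlying values
are bin-count-independent and carry no discretisation noise. A
configurable floor (default 100 values) flags histograms built from too
few regions.

`fitDoubleGaussian()` fits `a₁G(μ₁,σ₁) + a₂G(μ₂,σ₂)` to the normalised
density over bin centres by bounded least squares
(Levenberg–Marquardt), with amplitudes constrained non-negative and
spreads bounded below by half a bin width. The double Gaussian is a
smooth two-mode basis, not a distributional claim. Initialisation is
multi-start: moment-based starts (single-mode mean ± one SD) and a start
seeded by the two tallest local maxima of a lightly smoothed density;
the best residual wins, and parameters are reported in canonical order
`μ₁ ≤ μ₂` with `R² = 1 − SS_res/SS_tot`. A fit that fails from every
start raises an error rather than returning a silent fallback. By
design the model has exactly two modes; histograms with three distinct
regions fold the extra structure into the nearest fitted mode — a known,
intentional limitation of the two-mode summary.

Scores:

* **HD** = animal IQR / arithmetic mean of the littermate IQRs. The
  mean-normalisation makes the littermate average exactly 1 by algebra,
  a property the tests assert exactly, and leaves HD invariant to any
  uniform rescaling of expansion values. The littermate median is
  offered as an option.
* **CD** = `(μ₂ − μ₁)/μ₂` for `μ₂ > 0`. When the fitted minor component
  is negligible — amplitude ratio below 1 % or below 2 % of the fitted
  area — the histogram is declared unimodal and CD is 0. The threshold
  rule is this package's choice: healthy animals should score near zero
  even when the optimiser splits a single mode into two coincident
  Gaussians, but no published rule exists for that case.

Heart-blurred animals keep their HD (flagged) but receive no CD, since
a frozen zero-displacement region would fake a low-expansion mode.

## Global function

`volumeTimeCurve()` integrates the signed regional volume change
(accumulated expansion × XV-voxel volume) over the lung per phase and
divides by the mask-derived total lung volume, giving the volume of air
breathed as a fraction of lung volume; the curve starts at 0 by
construction. A literal "sum of vector magnitudes" estimator is
retained behind `magnitude = TRUE` for comparison, but it is not
dimensionally a volume, so the signed integral is the primary
estimator.

`expiratoryTimeConstant()` returns τ, the time from peak inspiration
until 67 % of the tidal volume is expired, located by linear
interpolation between bracketing phases. The printed convention 0.67
sits alongside the approximation 1/√2 ≈ 0.707 in the field's usage;
both are exposed through the `threshold` argument and 0.67 is the
default. If expiration never reaches the threshold within the breath,
τ is censored at the expiration duration with a warning and a flag. τ
depends only on volume fractions and is invariant to rescaling the
volume axis; on an exponential expiration with rate `k` it converges to
`−ln(0.33)/k` as phase sampling densifies (within 2 % at 15 phases per
breath).

## Orientation, segmentation, and QC

`findSymmetryAxis()` projects the volume along the cranial–caudal axis
(maximum intensity), thresholds to bone, and scores every candidate
axis angle (default −90°..90° in 0.5° steps) by the Pearson correlation
between the thresholded projection and its reflection about a line
through the image centre. Numerical choices: the bone threshold is an
intensity quantile (default 0.99) taken over the *3D volume* — bone is
rare in the volume even when its projection covers much of the image;
values above threshold are kept graded (not binarised) so
partial-volume edges contribute sub-voxel information; and the best
grid angle is refined by parabolic interpolation of the three
neighbouring scores. The spine is the larger connected bone component
along the axis, which fixes which end is dorsal; `orientAndCrop()`
rotates the symmetry line vertical with the spine at the bottom and
crops to the bone bounding box, keeping the crop symmetric in x about
the rotation centre so the axis stays on the image centre line.
Structureless inputs (e.g. uniform noise) score below the acceptance
floor (default 0.5) and are flagged unreliable. On 72–96-pixel phantom
projections the estimator recovers rotations well within 1° and a
second pass after correction returns angles at the scoring noise floor
(< 1°).

`segmentLungs()` thresholds dark (air-filled) voxels (Otsu by default),
keeps those enclosed by the body (flood fill from the volume border),
applies 3D morphological opening and closing, drops components that
break slice-to-slice continuity (consecutive-slice overlap below 30 %
of the smaller slice, or spanning fewer than 3 slices), and keeps the
two largest components. `lungVolume()` is simply mask voxel count ×
voxel volume — the total lung volume used to normalise the volume–time
curve.

`detectHeartBlur()` marks in-mask XV vectors with magnitude below
`zeroTol` (default 0.05 voxels/frame), labels contiguous marked
regions, and flags the sample when the largest region exceeds
`blobThreshold` (default 5 %) of the lung. The thresholds are declared
defaults — the numeric criterion is announced but not specified in the
source literature — and the region centroid is reported so the expected
lower-left locality can be checked.

## The phantom: what it emulates, and what it does not

All validation rests on the seeded phantom (`phantomConfig()` and the
`make*()` generators). It emulates: a two-lobed lung with speckled
texture; per-voxel fractional expansion drawn from the three archetypal
profiles (healthy: narrow unimodal, σ = 0.01; heterogeneous: wide
unimodal, σ = 0.03; clustered: a second low mode, μ_low = 0.05 at 30 %
volume fraction, grown as contiguous blobs by morphological dilation
from seeded voxels); a 0.5 s breath (0.15 s inspiration, 0.35 s
expiration) sampled at 15 phases; a bilaterally symmetric
ribcage/spine/sternum bone structure; and an optional lower-left
zero-displacement "heart blur" region. The principal-mode mean defaults
to 0.1 — a plausible working magnitude, since true murine expansion
magnitudes are not established.

Construction details that matter for interpretation:

* Spatial correlation of the expansion noise comes from smoothing white
  noise with a Gaussian kernel (default 3 voxels), giving smooth
  histograms; in-mask values are standardised before scaling so the
  realised moments equal the configured ones exactly.
* Displacement fields are gradients of a potential (hence curl-free and
  integrable), solved spectrally with the discrete central-difference
  symbol and calibrated by a short fixed-point iteration so that the
  *discrete* `det(I+∇u) − 1` of the synthesized field reproduces the
  target map (relative RMS ≈ 0.1 %, asserted at 2 % in tests).
* The configured tidal fraction and the scene's mean expansion both
  describe the peak volume change and generically disagree; the
  generator resolves this by rescaling the displacement basis so the
  integrated volume change matches the configured tidal fraction, and
  stores the rescaled map as the ground truth. HD and CD are invariant
  to this overall scale.
* The speckle grain defaults to 4 voxels, sized for 64³ windows; tests
  that analyse at 16³ windows scale the grain down proportionally
  (`speckleGrain = 2.7`) so windows contain comparable numbers of
  independent grains.
* Heart-blur regions are forced to zero displacement (not merely zero
  expansion), matching the artefact being emulated.
* All randomness derives from one seed through fixed child streams
  (mask perturbation, scene noise, blob seeds, texture, bone noise,
  per-animal cohort streams), so identical configurations are
  bit-identical.

What the phantom does **not** contain: X-ray projection physics,
phase-contrast fringes, CT reconstruction artefacts, cardiac motion
proper (only its frozen end state), airway trees, or lobar fissures.
Passing the phantom suite therefore demonstrates the correctness of the
quantification chain, not the fidelity of any upstream imaging system.
Two further limits are documented by the tests themselves: windows that
straddle the static background are biased toward zero displacement (an
aperture effect inherent to masked correlation), so expansion-map
recovery is asserted on fully lung-covered windows; and at desk-scale
grids the interrogation window is necessarily large relative to the
lung, which is why test geometries use 16³ windows where the full-scale
setting would use 64³.

## Problem sizes used in the checks

The bundled tests and `scripts/acceptance.R` run phantoms at 96³ (mask,
scenes, cohorts of 5 per group, 6-animal pipeline runs) and one
128×128×96 breathing sequence for the full velocimetry chain; these
sizes keep every stage's behaviour measurable — hundreds of XV voxels
per lung, ≥ 10⁴ in-mask scene voxels for Monte-Carlo moment checks —
while the whole acceptance script completes in about a minute on one
CPU. The same code paths run unchanged on full-resolution data; only
the grid and window sizes differ.
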