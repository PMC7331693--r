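#' @import methods
NULL

#' A 3D scalar image with voxel spacing
#'
#' Container for CT-like grayscale volumes. Arrays are indexed `[x, y, z]`
#' with `x` = left--right, `y` = ventral--dorsal (the spine sits at high
#' `y`), and `z` = cranial--caudal. Voxel indices are 1-based.
#'
#' @slot data 3D numeric array of intensities.
#' @slot voxelSize numeric length-3, physical edge length of one voxel (mm).
#' @exportClass VoxelGrid3D
setClass("VoxelGrid3D",
  representation(data = "array", voxelSize = "numeric"),
  prototype(data = array(0, c(1, 1, 1)), voxelSize = c(1, 1, 1))
)

setValidity("VoxelGrid3D", function(object) {
  if (length(dim(object@data)) != 3L) return("data must be a 3D array")
  if (length(object@voxelSize) != 3L || any(!is.finite(object@voxelSize)) ||
      any(object@voxelSize <= 0))
    return("voxelSize must be three positive finite numbers (mm)")
  TRUE
})

#' Per-phase 3D displacement field on the XV grid
#'
#' One displacement vector per interrogation window, in voxels/frame, between
#' two consecutive breath phases. The XV grid is the lattice of window
#' centres: `gridOrigin + (i-1) * gridStride` in fine-voxel coordinates.
#'
#' @slot vectors 4D numeric array `[nx, ny, nz, 3]`, voxels/frame.
#' @slot gridOrigin numeric length-3, fine-voxel coordinate of the first
#'   window centre (1-based).
#' @slot gridStride numeric length-3, window-centre spacing in fine voxels
#'   (equal to `window * (1 - overlap)`).
#' @slot phaseIndex integer, index of the earlier phase of the pair.
#' @slot peakQuality 3D array of correlation peak-height ratios
#'   (tallest / second tallest); `NA` where no correlation was computed.
#' @slot valid 3D logical array; `FALSE` for windows with insufficient mask
#'   coverage or an unreliable correlation peak.
#' @exportClass DisplacementField
setClass("DisplacementField",
  representation(vectors = "array", gridOrigin = "numeric",
                 gridStride = "numeric", phaseIndex = "integer",
                 peakQuality = "array", valid = "array")
)

setValidity("DisplacementField", function(object) {
  d <- dim(object@vectors)
  if (length(d) != 4L || d[4] != 3L)
    return("vectors must be a 4D array with 3 components in the last margin")
  if (!identical(dim(object@peakQuality), d[1:3]) ||
      !identical(dim(object@valid), d[1:3]))
    return("peakQuality and valid must match the vector grid shape")
  if (length(object@gridStride) != 3L || any(object@gridStride <= 0))
    return("gridStride must be three positive numbers")
  TRUE
})

#' Regional fractional-expansion map
#'
#' Unitless fractional expansion (change in ROI volume over ROI volume) per
#' grid cell, with the lung mask and an optional exclusion mask (e.g. the
#' mainstem bronchi, which are removed before histogram analysis).
#'
#' @slot values 3D numeric array; meaningful only inside `mask`.
#' @slot mask 3D logical array, the lung mask on the same grid.
#' @slot exclusion 3D logical array of cells removed from analysis.
#' @slot voxelVolume physical volume of one grid cell (mm^3).
#' @exportClass ExpansionMap
setClass("ExpansionMap",
  representation(values = "array", mask = "array", exclusion = "array",
                 voxelVolume = "numeric")
)

setValidity("ExpansionMap", function(object) {
  if (!identical(dim(object@values), dim(object@mask)))
    return("values and mask must share dimensions")
  if (!identical(dim(object@exclusion), dim(object@mask)))
    return("exclusion must share dimensions with mask")
  if (any(object@exclusion & !object@mask))
    return("exclusion must be a subset of mask")
  v <- object@values[object@mask & !object@exclusion]
  if (any(is.finite(v) & v <= -1))
    return("fractional expansion must exceed -1 (tissue cannot invert)")
  if (length(object@voxelVolume) != 1L || object@voxelVolume <= 0)
    return("voxelVolume must be a positive scalar")
  TRUE
})

#' Area-normalised expansion histogram
#'
#' Density of in-mask fractional-expansion values with the area under the
#' histogram normalised to 1, plus the interquartile range of the raw
#' (unbinned) values.
#'
#' @slot binEdges numeric, bin boundaries (unitless expansion).
#' @slot density numeric, one density value per bin; integrates to 1.
#' @slot iqr interquartile range of the underlying raw values.
#' @slot nValues number of in-mask values summarised.
#' @slot flagged `TRUE` when fewer values than the configured floor entered
#'   the histogram.
#' @exportClass ExpansionHistogram
setClass("ExpansionHistogram",
  representation(binEdges = "numeric", density = "numeric", iqr = "numeric",
                 nValues = "integer", flagged = "logical")
)

setValidity("ExpansionHistogram", function(object) {
  if (length(object@binEdges) != length(object@density) + 1L)
    return("binEdges must have one more element than density")
  area <- sum(object@density * diff(object@binEdges))
  if (abs(area - 1) > 1e-9)
    return(sprintf("histogram area must be 1 (got %.12f)", area))
  if (object@iqr < 0) return("iqr must be non-negative")
  TRUE
})

#' Least-squares double-Gaussian decomposition of an expansion histogram
#'
#' Parameters of `a1*exp(-(x-mu1)^2/(2*sigma1^2)) +
#' a2*exp(-(x-mu2)^2/(2*sigma2^2))` fitted to the normalised density, in
#' canonical order `mu1 <= mu2`.
#'
#' @slot a1,a2 non-negative amplitudes (peak heights).
#' @slot mu1,mu2 mode means, unitless expansion, `mu1 <= mu2`.
#' @slot sigma1,sigma2 positive spreads.
#' @slot rSquared goodness of fit, `1 - SS_res/SS_tot`.
#' @slot converged whether the optimiser converged from at least one start.
#' @exportClass DoubleGaussianFit
setClass("DoubleGaussianFit",
  representation(a1 = "numeric", mu1 = "numeric", sigma1 = "numeric",
                 a2 = "numeric", mu2 = "numeric", sigma2 = "numeric",
                 rSquared = "numeric", converged = "logical")
)

setValidity("DoubleGaussianFit", function(object) {
  if (object@mu1 > object@mu2) return("modes must be ordered mu1 <= mu2")
  if (object@sigma1 <= 0 || object@sigma2 <= 0)
    return("sigmas must be positive")
  if (object@a1 < 0 || object@a2 < 0) return("amplitudes must be non-negative")
  if (is.finite(object@rSquared) && object@rSquared > 1 + 1e-12)
    return("rSquared cannot exceed 1")
  TRUE
})

#' Whole-lung volume--time curve
#'
#' Inspired air volume per breath phase, expressed as a fraction of the
#' mask-derived total lung volume. `tau` (the expiratory time constant: the
#' time from peak inspiration for `expiredThreshold` of the tidal volume to
#' be expired) is `NA` until computed by [expiratoryTimeConstant()].
#'
#' @slot times seconds from breath start, one per phase.
#' @slot fractionalVolume inspired volume / total lung volume per phase;
#'   zero at the first phase by construction.
#' @slot tidalFraction maximum of `fractionalVolume`.
#' @slot tau expiratory time constant (s), `NA` until computed.
#' @slot tauCensored `TRUE` when expiration never reached the threshold and
#'   `tau` was set to the expiration duration.
#' @slot expiredThreshold expired fraction of tidal volume that defines
#'   `tau` (default 0.67).
#' @slot magnitudeVolume optional alternative per-phase estimate formed from
#'   the summed magnitudes of the displacement vectors (same normalisation);
#'   empty unless requested.
#' @exportClass VolumeTimeCurve
setClass("VolumeTimeCurve",
  representation(times = "numeric", fractionalVolume = "numeric",
                 tidalFraction = "numeric", tau = "numeric",
                 tauCensored = "logical", expiredThreshold = "numeric",
                 magnitudeVolume = "numeric")
)

setValidity("VolumeTimeCurve", function(object) {
  if (length(object@times) != length(object@fractionalVolume))
    return("times and fractionalVolume must have equal length")
  if (is.unsorted(object@times, strictly = TRUE))
    return("times must be strictly increasing")
  if (length(object@fractionalVolume) &&
      abs(object@fractionalVolume[1]) > 1e-12)
    return("fractionalVolume must start at 0 (breath start reference)")
  if (!isTRUE(all.equal(object@tidalFraction,
                        max(object@fractionalVolume), tolerance = 1e-9)))
    return("tidalFraction must equal max(fractionalVolume)")
  TRUE
})

#' Synthetic breathing-lung phantom configuration
#'
#' All phantom generators are pure functions of a `PhantomConfig`; identical
#' configurations (including `seed`) give bit-identical output. The three
#' `profile`s reproduce the archetypal expansion histograms: `healthy`
#' (tall/narrow unimodal), `heterogeneous` (low/wide unimodal), and
#' `clustered` (bimodal, with spatially contiguous low-expansion blobs).
#'
#' @slot gridShape integer length-3 grid size in voxels.
#' @slot voxelSize numeric length-3 voxel edge length (mm).
#' @slot profile one of `"healthy"`, `"heterogeneous"`, `"clustered"`.
#' @slot muMain mean fractional expansion of the principal mode.
#' @slot sigmaMain its spread.
#' @slot muLow,sigmaLow,weightLow low-expansion mode parameters (clustered
#'   profile only); `weightLow` is the volume fraction of the low mode.
#' @slot nBlobs number of contiguous low-expansion regions.
#' @slot heartBlur optional list `(centre = fractional xyz, radius =
#'   fraction of grid extent)` describing a zero-displacement region, or an
#'   empty list.
#' @slot inspTime,expTime inspiration/expiration durations (s).
#' @slot nPhases breath phases per cycle.
#' @slot tidalFraction tidal volume as a fraction of total lung volume.
#' @slot smoothSigma width (voxels) of the Gaussian kernel imposing spatial
#'   correlation on the expansion noise.
#' @slot speckleGrain characteristic speckle grain size (voxels); chosen so
#'   interrogation windows contain ample unique structure (default 4 for
#'   64-voxel windows; scale down with the window).
#' @slot seed integer master seed; all child streams derive from it.
#' @exportClass PhantomConfig
setClass("PhantomConfig",
  representation(gridShape = "integer", voxelSize = "numeric",
                 profile = "character", muMain = "numeric",
                 sigmaMain = "numeric", muLow = "numeric",
                 sigmaLow = "numeric", weightLow = "numeric",
                 nBlobs = "integer", heartBlur = "list",
                 inspTime = "numeric", expTime = "numeric",
                 nPhases = "integer", tidalFraction = "numeric",
                 smoothSigma = "numeric", speckleGrain = "numeric",
                 seed = "integer")
)

setValidity("PhantomConfig", function(object) {
  if (length(object@gridShape) != 3L || any(object@gridShape < 1L))
    return("gridShape must be three positive integers")
  if (!object@profile %in% c("healthy", "heterogeneous", "clustered"))
    return("profile must be healthy, heterogeneous or clustered")
  if (object@sigmaMain < 0) return("sigmaMain must be non-negative")
  if (object@weightLow < 0 || object@weightLow >= 1)
    return("weightLow must lie in [0, 1)")
  if (object@profile == "clustered" && object@muLow >= object@muMain)
    return("clustered profile requires muLow < muMain")
  if (object@inspTime <= 0 || object@expTime <= 0)
    return("inspTime and expTime must be positive")
  if (object@nPhases < 3L) return("nPhases must be at least 3")
  if (object@tidalFraction < 0) return("tidalFraction must be non-negative")
  TRUE
})

#' Ground truth bundle for a generated phantom scene
#'
#' Carries the true per-voxel expansion, the lung mask, the injected blur
#' region, and the displacement construction. Per-phase displacement is
#' stored compactly as a spatial basis `displacementBasis` (voxels) times a
#' per-phase scale `phaseScale`; materialise phases with
#' [truePhaseDisplacement()].
#'
#' @slot expansionMap [ExpansionMap-class] of true fractional expansion at
#'   peak inspiration.
#' @slot lungMask 3D logical array.
#' @slot blurRegion 3D logical array (all `FALSE` when no heart blur).
#' @slot displacementBasis 4D array `[x, y, z, 3]` of the peak-inspiration
#'   displacement (voxels), or a zero-length array before
#'   [makeSpeckleSequence()] runs.
#' @slot phaseScale numeric, per-phase multiplier of the basis in `[0, 1]`.
#' @slot params list of generating parameters (mixture means/weights,
#'   achieved blob fraction, seeds).
#' @exportClass GroundTruth
setClass("GroundTruth",
  representation(expansionMap = "ExpansionMap", lungMask = "array",
                 blurRegion = "array", displacementBasis = "array",
                 phaseScale = "numeric", params = "list")
)

#' Result of mirror-symmetry orientation estimation
#'
#' @slot angle correction angle in degrees; rotating the volume by `angle`
#'   in the axial plane makes the symmetry line vertical.
#' @slot symmetryScore Pearson correlation between the thresholded
#'   cranial--caudal projection and its mirror at the best axis, in [-1, 1].
#' @slot spineEnd `"high"` or `"low"`: which end of the symmetry line (in y,
#'   after correction) holds the larger bone blob (the spine).
#' @slot cropBox integer matrix `3 x 2` of voxel bounds enclosing the bones
#'   plus margin (columns: lower, upper).
#' @slot reliable `FALSE` when the best symmetry score fell below the
#'   acceptance floor.
#' @exportClass OrientationResult
setClass("OrientationResult",
  representation(angle = "numeric", symmetryScore = "numeric",
                 spineEnd = "character", cropBox = "matrix",
                 reliable = "logical")
)

#' Heart-blur quality-control result
#'
#' Heart blur manifests as contiguous regions of near-zero displacement in
#' the XV output; samples where the largest such region exceeds a volume
#' threshold are flagged and excluded from CD scoring.
#'
#' @slot zeroFraction fraction of in-mask XV voxels with near-zero
#'   displacement.
#' @slot largestBlobFraction largest contiguous near-zero region as a
#'   fraction of the in-mask volume.
#' @slot heartBlurFlag `largestBlobFraction >= blobThreshold`.
#' @slot centroid XV-grid centroid (fractional, per axis) of the largest
#'   near-zero region, for locality checks; `NA` when there is none.
#' @slot zeroTol,blobThreshold the thresholds used (voxels/frame; mask
#'   fraction).
#' @exportClass QCResult
setClass("QCResult",
  representation(zeroFraction = "numeric", largestBlobFraction = "numeric",
                 heartBlurFlag = "logical", centroid = "numeric",
                 zeroTol = "numeric", blobThreshold = "numeric")
)

setValidity("QCResult", function(object) {
  if (object@zeroFraction < 0 || object@zeroFraction > 1)
    return("zeroFraction must lie in [0, 1]")
  if (!identical(object@heartBlurFlag,
                 object@largestBlobFraction >= object@blobThreshold))
    return("heartBlurFlag must equal largestBlobFraction >= blobThreshold")
  TRUE
})
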