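#' @include AllClasses.R
NULL

#' Accessors for xvlung classes
#'
#' Small accessor generics; user code should prefer these over slot access.
#'
#' @param x an xvlung object.
#' @return The slot value; `expansionValues()` returns the raw numeric
#'   vector of in-mask, non-excluded values.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("gridData", function(x) standardGeneric("gridData"))
#' @rdname accessors
#' @export
setGeneric("voxelSize", function(x) standardGeneric("voxelSize"))
#' @rdname accessors
#' @export
setGeneric("vectors", function(x) standardGeneric("vectors"))
#' @rdname accessors
#' @export
setGeneric("gridOrigin", function(x) standardGeneric("gridOrigin"))
#' @rdname accessors
#' @export
setGeneric("gridStride", function(x) standardGeneric("gridStride"))
#' @rdname accessors
#' @export
setGeneric("peakQuality", function(x) standardGeneric("peakQuality"))
#' @rdname accessors
#' @export
setGeneric("validVectors", function(x) standardGeneric("validVectors"))
#' @rdname accessors
#' @export
setGeneric("expansionValues", function(x) standardGeneric("expansionValues"))
#' @rdname accessors
#' @export
setGeneric("analysisMask", function(x) standardGeneric("analysisMask"))
#' @rdname accessors
#' @export
setGeneric("iqr", function(x) standardGeneric("iqr"))
#' @rdname accessors
#' @export
setGeneric("fitParameters", function(x) standardGeneric("fitParameters"))
#' @rdname accessors
#' @export
setGeneric("rSquared", function(x) standardGeneric("rSquared"))
#' @rdname accessors
#' @export
setGeneric("phaseTimes", function(x) standardGeneric("phaseTimes"))
#' @rdname accessors
#' @export
setGeneric("fractionalVolume", function(x) standardGeneric("fractionalVolume"))
#' @rdname accessors
#' @export
setGeneric("tidalFraction", function(x) standardGeneric("tidalFraction"))

#' @rdname accessors
#' @export
setMethod("gridData", "VoxelGrid3D", function(x) x@data)
#' @rdname accessors
#' @export
setMethod("voxelSize", "VoxelGrid3D", function(x) x@voxelSize)
#' @rdname accessors
#' @export
setMethod("vectors", "DisplacementField", function(x) x@vectors)
#' @rdname accessors
#' @export
setMethod("gridOrigin", "DisplacementField", function(x) x@gridOrigin)
#' @rdname accessors
#' @export
setMethod("gridStride", "DisplacementField", function(x) x@gridStride)
#' @rdname accessors
#' @export
setMethod("peakQuality", "DisplacementField", function(x) x@peakQuality)
#' @rdname accessors
#' @export
setMethod("validVectors", "DisplacementField", function(x) x@valid)
#' @rdname accessors
#' @export
setMethod("expansionValues", "ExpansionMap",
          function(x) x@values[x@mask & !x@exclusion])
#' @rdname accessors
#' @export
setMethod("analysisMask", "ExpansionMap", function(x) x@mask & !x@exclusion)
#' @rdname accessors
#' @export
setMethod("iqr", "ExpansionHistogram", function(x) x@iqr)
#' @rdname accessors
#' @export
setMethod("fitParameters", "DoubleGaussianFit", function(x)
  c(a1 = x@a1, mu1 = x@mu1, sigma1 = x@sigma1,
    a2 = x@a2, mu2 = x@mu2, sigma2 = x@sigma2))
#' @rdname accessors
#' @export
setMethod("rSquared", "DoubleGaussianFit", function(x) x@rSquared)
#' @rdname accessors
#' @export
setMethod("phaseTimes", "VolumeTimeCurve", function(x) x@times)
#' @rdname accessors
#' @export
setMethod("fractionalVolume", "VolumeTimeCurve", function(x)
  x@fractionalVolume)
#' @rdname accessors
#' @export
setMethod("tidalFraction", "VolumeTimeCurve", function(x) x@tidalFraction)

setMethod("show", "VoxelGrid3D", function(object) {
  d <- dim(object@data)
  cat(sprintf("VoxelGrid3D: %d x %d x %d voxels, voxel size %s mm\n",
              d[1], d[2], d[3],
              paste(signif(object@voxelSize, 3), collapse = " x ")))
})

setMethod("show", "DisplacementField", function(object) {
  d <- dim(object@vectors)
  cat(sprintf(
    "DisplacementField: %d x %d x %d vectors (phase %d), stride %s voxels, %d/%d valid\n",
    d[1], d[2], d[3], object@phaseIndex,
    paste(object@gridStride, collapse = "/"),
    sum(object@valid), prod(d[1:3])))
})

setMethod("show", "ExpansionMap", function(object) {
  v <- expansionValues(object)
  cat(sprintf(
    "ExpansionMap: %s grid, %d in-mask cells (%d excluded), mean expansion %.4g\n",
    paste(dim(object@values), collapse = " x "), length(v),
    sum(object@exclusion), mean(v)))
})

setMethod("show", "ExpansionHistogram", function(object) {
  cat(sprintf(
    "ExpansionHistogram: %d bins over [%.4g, %.4g], n = %d, IQR = %.4g%s\n",
    length(object@density), min(object@binEdges), max(object@binEdges),
    object@nValues, object@iqr,
    if (object@flagged) " [flagged: few values]" else ""))
})

setMethod("show", "DoubleGaussianFit", function(object) {
  cat(sprintf(
    "DoubleGaussianFit: mu1 = %.4g (a1 = %.3g, s1 = %.3g), mu2 = %.4g (a2 = %.3g, s2 = %.3g), R^2 = %.4f\n",
    object@mu1, object@a1, object@sigma1,
    object@mu2, object@a2, object@sigma2, object@rSquared))
})

setMethod("show", "VolumeTimeCurve", function(object) {
  cat(sprintf(
    "VolumeTimeCurve: %d phases over %.3g s, tidal fraction %.4g, tau = %s s%s\n",
    length(object@times), max(object@times), object@tidalFraction,
    if (is.na(object@tau)) "not computed" else sprintf("%.4g", object@tau),
    if (isTRUE(object@tauCensored)) " [censored]" else ""))
})

setMethod("show", "PhantomConfig", function(object) {
  cat(sprintf(
    "PhantomConfig: %s grid, profile '%s' (mu = %.3g, sigma = %.3g), %d phases (%.2g s insp / %.2g s exp), seed %d\n",
    paste(object@gridShape, collapse = "x"), object@profile,
    object@muMain, object@sigmaMain, object@nPhases,
    object@inspTime, object@expTime, object@seed))
})

setMethod("show", "GroundTruth", function(object) {
  cat(sprintf(
    "GroundTruth: %d lung voxels, blur region %d voxels, displacement basis %s\n",
    sum(object@lungMask), sum(object@blurRegion),
    if (length(object@displacementBasis)) "present" else "absent"))
})

setMethod("show", "OrientationResult", function(object) {
  cat(sprintf(
    "OrientationResult: correction %.2f deg, symmetry score %.3f, spine at %s y%s\n",
    object@angle, object@symmetryScore, object@spineEnd,
    if (!object@reliable) " [unreliable]" else ""))
})

setMethod("show", "QCResult", function(object) {
  cat(sprintf(
    "QCResult: zero fraction %.3f, largest blob %.3f of mask -> heart blur %s\n",
    object@zeroFraction, object@largestBlobFraction,
    if (object@heartBlurFlag) "FLAGGED" else "clear"))
})
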