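## Whole-lung volume--time curve and the expiratory time constant tau.

#' Whole-lung fractional volume--time curve
#'
#' Per breath phase, integrates the signed regional volume change
#' (accumulated expansion times XV-voxel volume) over the lung and divides
#' by the mask-derived total lung volume, giving the volume of air breathed
#' as a fraction of total lung volume. The first phase is the breath-start
#' reference (fraction 0). A "magnitude-sum" estimator -- the summed
#' magnitudes of the accumulated displacement vectors under the same
#' normalisation -- can be reported alongside for comparison; it is not
#' dimensionally a volume and is retained only as the literal reading of
#' the global displacement measure.
#'
#' @param fields list of [DisplacementField-class] between consecutive
#'   phases, in time order (length `nPhases - 1`).
#' @param times phase times (s), length `nPhases`.
#' @param totalLungVolume mask-derived total lung volume, in the same units
#'   as `xvVoxelVolume`.
#' @param mask optional XV-grid logical mask (defaults to jointly valid
#'   windows).
#' @param xvVoxelVolume physical volume of one XV voxel; defaults to
#'   `prod(gridStride)` (fine voxels cubed).
#' @param magnitude also compute the magnitude-sum estimator.
#' @param expiredThreshold expired fraction of tidal volume that will
#'   define tau (stored on the curve; default 0.67).
#' @return A [VolumeTimeCurve-class] (with `tau` not yet computed).
#' @export
volumeTimeCurve <- function(fields, times, totalLungVolume, mask = NULL,
                            xvVoxelVolume = NULL, magnitude = FALSE,
                            expiredThreshold = 0.67) {
  if (totalLungVolume <= 0) stop("normalization error: zero lung volume")
  nPhases <- length(fields) + 1L
  if (length(times) != nPhases)
    stop("times must have one entry per phase (length(fields) + 1)")
  stride <- fields[[1]]@gridStride
  if (is.null(xvVoxelVolume)) xvVoxelVolume <- prod(stride)
  derivMask <- Reduce(`&`, lapply(fields, function(f) !is.na(f@peakQuality)))
  if (is.null(mask)) mask <- derivMask
  mask <- mask & derivMask
  d <- dim(mask)
  u <- array(0, c(d, 3))
  fv <- numeric(nPhases)
  mv <- numeric(nPhases)
  for (p in 2:nPhases) {
    vec <- fields[[p - 1L]]@vectors
    vec[!is.finite(vec)] <- 0
    u <- u + vec
    e <- jacobianExpansionMasked(u, derivMask, stride)
    fv[p] <- sum(e[mask]) * xvVoxelVolume / totalLungVolume
    if (magnitude) {
      mag <- sqrt(u[, , , 1]^2 + u[, , , 2]^2 + u[, , , 3]^2)
      mv[p] <- sum(mag[mask]) * xvVoxelVolume / totalLungVolume
    }
  }
  new("VolumeTimeCurve", times = times, fractionalVolume = fv,
      tidalFraction = max(fv), tau = NA_real_, tauCensored = FALSE,
      expiredThreshold = expiredThreshold,
      magnitudeVolume = if (magnitude) mv else numeric(0))
}

#' Expiratory time constant
#'
#' tau is the time elapsed from peak inspiration until `threshold` (default
#' 67\%, approximately 1 - 1/sqrt(2) of the printed convention) of the tidal
#' volume has been expired, located by linear interpolation between the
#' bracketing sampled phases. Peak inspiration is the phase of maximum
#' fractional volume, ties broken to the earlier phase. tau depends only on
#' volume fractions, so it is invariant to uniform rescaling of the volume
#' axis. If expiration never reaches the threshold within the breath, tau
#' is censored at the expiration duration, with a warning.
#'
#' @param curve a [VolumeTimeCurve-class] with a peak followed by at least
#'   two phases.
#' @param threshold expired fraction of tidal volume defining tau.
#' @return The curve with `tau` (seconds), `tauCensored` and
#'   `expiredThreshold` filled in.
#' @examples
#' cv <- expiratoryTimeConstant(makeBreathCurve(phantomConfig()))
#' cv@tau
#' @export
expiratoryTimeConstant <- function(curve, threshold = 0.67) {
  fv <- curve@fractionalVolume
  peak <- which.max(fv)  # which.max already takes the earliest tie
  if (peak > length(fv) - 2L)
    stop("curve needs at least two phases after the peak")
  tidal <- fv[peak]
  if (tidal <= 0) stop("curve has no inspiration (tidal volume is zero)")
  expired <- (tidal - fv[peak:length(fv)]) / tidal
  tPost <- curve@times[peak:length(fv)] - curve@times[peak]
  hit <- which(expired >= threshold)
  if (!length(hit)) {
    warning("expiration never reached the threshold; tau censored at the expiration duration")
    curve@tau <- tPost[length(tPost)]
    curve@tauCensored <- TRUE
  } else {
    j <- hit[1]
    if (j == 1L) {
      curve@tau <- tPost[1]
    } else if (expired[j] == threshold) {
      curve@tau <- tPost[j]
    } else {
      frac <- (threshold - expired[j - 1]) / (expired[j] - expired[j - 1])
      curve@tau <- tPost[j - 1] + frac * (tPost[j] - tPost[j - 1])
    }
    curve@tauCensored <- FALSE
  }
  curve@expiredThreshold <- threshold
  curve
}
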