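## Standard-format I/O: NIfTI / multipage TIFF volumes, 4D NIfTI vector
## fields with JSON grid metadata, CSV tables with JSON sidecars, and
## histogram/curve figure export.
##
## Coordinate convention (documented in every JSON sidecar): voxel indices
## are 0-based in sidecars, axis order x = left--right, y = ventral--dorsal,
## z = cranial--caudal.

axisNote <- function() {
  list(indexBase = 0L,
       axes = c(x = "left-right", y = "ventral-dorsal",
                z = "cranial-caudal"))
}

#' Read a 3D volume from NIfTI or multipage TIFF
#'
#' @param path file path (`.nii`, `.nii.gz`, `.tif`/`.tiff`).
#' @param voxelSize fallback voxel size (mm) when the file has none.
#' @return A [VoxelGrid3D-class].
#' @export
readVolume <- function(path, voxelSize = c(1, 1, 1)) {
  if (!file.exists(path)) stop("input file not found: ", path)
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("reading TIFF requires the 'tiff' package")
    pages <- tiff::readTIFF(path, all = TRUE)
    arr <- simplify2array(pages)            # [y, x, z] as read
    arr <- aperm(arr, c(2, 1, 3))
    return(asVoxelGrid(arr, voxelSize))
  }
  img <- RNifti::readNifti(path)
  vs <- tryCatch(RNifti::pixdim(img)[1:3], error = function(e) voxelSize)
  if (any(!is.finite(vs)) || any(vs <= 0)) vs <- voxelSize
  asVoxelGrid(array(as.numeric(img), dim(img)[1:3]), vs)
}

#' Write a 3D volume as NIfTI
#'
#' @param vol a [VoxelGrid3D-class] or 3D array.
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
writeVolume <- function(vol, path) {
  arr <- if (is(vol, "VoxelGrid3D")) gridData(vol) else vol
  vs <- if (is(vol, "VoxelGrid3D")) voxelSize(vol) else c(1, 1, 1)
  img <- RNifti::asNifti(array(as.numeric(arr), dim(arr)))
  RNifti::pixdim(img) <- vs
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write a displacement field as 4D NIfTI plus a JSON grid sidecar
#'
#' The three vector components are stacked in the fourth dimension; XV grid
#' origin/stride and the coordinate convention go to `<path>.json`.
#'
#' @param field a [DisplacementField-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeDisplacementField <- function(field, path) {
  img <- RNifti::asNifti(field@vectors)
  RNifti::writeNifti(img, path)
  meta <- list(gridOrigin = field@gridOrigin - 1,  # 0-based in sidecars
               gridStride = field@gridStride,
               phaseIndex = field@phaseIndex,
               units = "voxels/frame",
               convention = axisNote())
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(path)
}

#' Read a displacement field written by [writeDisplacementField()]
#' @param path path to the 4D NIfTI.
#' @return A [DisplacementField-class].
#' @export
readDisplacementField <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path)
  img <- RNifti::readNifti(path)
  vec <- array(as.numeric(img), dim(img))
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  d <- dim(vec)[1:3]
  new("DisplacementField", vectors = vec,
      gridOrigin = as.numeric(meta$gridOrigin) + 1,
      gridStride = as.numeric(meta$gridStride),
      phaseIndex = as.integer(meta$phaseIndex),
      peakQuality = array(NA_real_, d),
      valid = array(TRUE, d))
}

#' Write a cohort table as CSV with a JSON sidecar
#'
#' @param tab cohort `data.frame` from [cohortScores()].
#' @param path CSV output path; the sidecar goes to `<path>.json`.
#' @return `path`, invisibly.
#' @export
writeCohortTable <- function(tab, path) {
  utils::write.csv(format(tab, digits = 10, trim = TRUE), path,
                   row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(iqr_L = attr(tab, "iqr_L"), rows = tab, convention = axisNote()),
    paste0(path, ".json"), auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

#' Plot an expansion histogram with its double-Gaussian fit
#'
#' Grey histogram trace, dashed fitted curve, annotated with HD, CD and
#' R-squared when supplied.
#'
#' @param hist an [ExpansionHistogram-class].
#' @param fit optional [DoubleGaussianFit-class].
#' @param hd,cd optional scores for the annotation.
#' @param main plot title.
#' @return `NULL`, invisibly.
#' @export
plotExpansionFit <- function(hist, fit = NULL, hd = NA, cd = NA,
                             main = "Expansion histogram") {
  x <- (hist@binEdges[-1] + hist@binEdges[-length(hist@binEdges)]) / 2
  graphics::plot(x, hist@density, type = "l", col = "grey40", lwd = 2,
                 xlab = "fractional expansion", ylab = "normalised density",
                 main = main)
  lab <- c(if (!is.na(hd)) sprintf("HD = %.2f", hd),
           if (!is.na(cd)) sprintf("CD = %.2f", cd))
  if (!is.null(fit)) {
    graphics::lines(x, doubleGaussian(x, fitParameters(fit)), lty = 2,
                    lwd = 2)
    lab <- c(lab, sprintf("R2 = %.3f", fit@rSquared))
  }
  if (length(lab))
    graphics::legend("topright", legend = lab, bty = "n")
  invisible(NULL)
}

#' Plot a volume--time curve with its expiratory time constant
#'
#' @param curve a [VolumeTimeCurve-class].
#' @param main plot title.
#' @return `NULL`, invisibly.
#' @export
plotVolumeTimeCurve <- function(curve, main = "Fractional volume") {
  graphics::plot(curve@times, curve@fractionalVolume, type = "b", pch = 16,
                 xlab = "time (s)", ylab = "fractional volume", main = main)
  if (!is.na(curve@tau)) {
    peak <- which.max(curve@fractionalVolume)
    graphics::abline(v = curve@times[peak] + curve@tau, lty = 3)
    graphics::mtext(sprintf("tau = %.3f s%s", curve@tau,
                            if (curve@tauCensored) " (censored)" else ""),
                    side = 3, line = 0, adj = 1, cex = 0.8)
  }
  invisible(NULL)
}
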