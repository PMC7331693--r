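## Automatic orientation by mirror symmetry, cropping, lung segmentation,
## lung volume, and heart-blur quality control.

# Maximum-intensity projection along the cranial--caudal (z) axis.
axialProjection <- function(arr) {
  d <- dim(arr)
  out <- arr[, , 1]
  for (k in seq_len(d[3])[-1]) out <- pmax(out, arr[, , k])
  out
}

# Pearson correlation between a 2D image and its reflection about a line
# through the image centre at `angle` degrees from vertical (the y axis).
mirrorScore <- function(img, angle) {
  d <- dim(img)
  ctr <- (d + 1) / 2
  th <- (90 - angle) * pi / 180  # line direction in (x, y)
  dir <- c(cos(th), sin(th))
  gx <- rep(seq_len(d[1]), times = d[2]) - ctr[1]
  gy <- rep(seq_len(d[2]), each = d[1]) - ctr[2]
  proj <- gx * dir[1] + gy * dir[2]
  rx <- 2 * proj * dir[1] - gx + ctr[1]
  ry <- 2 * proj * dir[2] - gy + ctr[2]
  refl <- bilinear(img, rx, ry)
  ok <- !is.na(refl)
  if (sum(ok) < 16 || stats::sd(img[ok]) == 0 || stats::sd(refl[ok]) == 0)
    return(0)
  stats::cor(as.vector(img)[ok], refl[ok])
}

#' Find the line of best mirror symmetry of a thoracic volume
#'
#' Projects the volume in the cranial--caudal direction (maximum intensity),
#' thresholds the projection to bone (intensity quantile), and scores every
#' candidate axis angle by the Pearson correlation between the thresholded
#' projection and its reflection about a line through the image centre at
#' that angle. The best-scoring line passes through spine and sternum; the
#' spine is identified as the larger connected bone component along the
#' line, which disambiguates the two ends. Results whose best score falls
#' below `scoreFloor` are flagged unreliable (e.g. structureless noise
#' volumes).
#'
#' @param ct a [VoxelGrid3D-class] (or 3D array).
#' @param angleGrid candidate axis angles in degrees from vertical.
#' @param boneQuantile intensity quantile defining the bone threshold.
#' @param scoreFloor minimum acceptable symmetry score.
#' @return An [OrientationResult-class]. `angle` is the rotation to apply
#'   (via [orientAndCrop()]) to make the symmetry line vertical.
#' @export
findSymmetryAxis <- function(ct, angleGrid = seq(-90, 90, by = 0.5),
                             boneQuantile = 0.99, scoreFloor = 0.5) {
  arr <- if (is(ct, "VoxelGrid3D")) gridData(ct) else ct
  if (!length(arr) || all(arr == arr[1]))
    stop("segmentation-input error: volume is empty or constant")
  proj <- axialProjection(arr)
  # quantile of the 3D intensities: bone is rare in the volume even when
  # its projection covers a sizeable image fraction
  thr <- stats::quantile(arr, boneQuantile, type = 7)
  # graded threshold: zero below the bone threshold, proportional above;
  # retains partial-volume edge information for sub-voxel symmetry scoring
  bone <- pmax(proj - thr, 0)
  if (!sum(bone > 0)) bone <- (proj >= thr) * 1  # flat-topped projections
  if (!sum(bone > 0))
    stop("segmentation-input error: no voxels above the bone threshold")
  scores <- vapply(angleGrid, function(a) mirrorScore(bone, a), numeric(1))
  best <- which.max(scores)
  axisAngle <- angleGrid[best]
  score <- scores[best]
  # parabolic refinement of the angle between grid steps
  if (best > 1L && best < length(angleGrid)) {
    den <- scores[best - 1] + scores[best + 1] - 2 * scores[best]
    if (is.finite(den) && den < 0) {
      delta <- 0.5 * (scores[best - 1] - scores[best + 1]) / den
      if (abs(delta) <= 1)
        axisAngle <- axisAngle + delta * mean(diff(angleGrid))
    }
  }
  # spine end: larger bone component near the symmetry line
  d <- dim(bone)
  ctr <- (d + 1) / 2
  th <- (90 - axisAngle) * pi / 180
  dir <- c(cos(th), sin(th))
  lab2 <- labelComponents3D(array(bone > 0, c(d, 1L)))[, , 1]
  labs <- setdiff(unique(as.vector(lab2)), 0L)
  onAxis <- vapply(labs, function(l) {
    pos <- which(lab2 == l, arr.ind = TRUE)
    cx <- colMeans(pos) - ctr
    perp <- abs(cx[1] * dir[2] - cx[2] * dir[1])
    perp <= 0.08 * max(d)
  }, logical(1))
  spineEnd <- "high"
  if (any(onAxis)) {
    axisLabs <- labs[onAxis]
    sizes <- vapply(axisLabs, function(l) sum(lab2 == l), numeric(1))
    big <- axisLabs[which.max(sizes)]
    pos <- which(lab2 == big, arr.ind = TRUE)
    cx <- colMeans(pos) - ctr
    spineEnd <- if ((cx[1] * dir[1] + cx[2] * dir[2]) >= 0) "high" else "low"
  }
  # crop box: bone bounding box in 3D, padded
  thr3 <- stats::quantile(arr, boneQuantile, type = 7)
  idx <- which(arr >= thr3, arr.ind = TRUE)
  pad <- 4L
  box <- cbind(pmax(apply(idx, 2, min) - pad, 1L),
               pmin(apply(idx, 2, max) + pad, dim(arr)))
  storage.mode(box) <- "integer"
  new("OrientationResult", angle = axisAngle, symmetryScore = score,
      spineEnd = spineEnd, cropBox = box, reliable = score >= scoreFloor)
}

# Rotate every axial (z) slice by `angle` degrees about the slice centre,
# bilinear interpolation, constant fill.
rotateAxial <- function(arr, angle, fill = 0) {
  if (angle == 0) return(arr)
  d <- dim(arr)
  ctr <- (d[1:2] + 1) / 2
  th <- angle * pi / 180
  gx <- rep(seq_len(d[1]), times = d[2]) - ctr[1]
  gy <- rep(seq_len(d[2]), each = d[1]) - ctr[2]
  # sample source at the inverse rotation
  sx <- cos(th) * gx + sin(th) * gy + ctr[1]
  sy <- -sin(th) * gx + cos(th) * gy + ctr[2]
  out <- array(fill, d)
  for (k in seq_len(d[3])) {
    v <- bilinear(arr[, , k], sx, sy, fill = fill)
    out[, , k] <- v
  }
  out
}

#' Rotate a volume to canonical orientation and crop to the bones
#'
#' Applies the correction from [findSymmetryAxis()]: rotates each axial
#' slice so the line of best symmetry is vertical, flips (180 degree
#' rotation) if needed so the spine sits at the bottom (high y) of the
#' image, then crops to the bone bounding box plus margin. The bones act as
#' the boundary for lung tissue, so the crop retains the full thorax.
#'
#' @param ct a [VoxelGrid3D-class] (or 3D array).
#' @param result an [OrientationResult-class].
#' @param pad crop margin in voxels.
#' @return The oriented, cropped [VoxelGrid3D-class].
#' @export
orientAndCrop <- function(ct, result, pad = 4L) {
  vg <- asVoxelGrid(if (is(ct, "VoxelGrid3D")) gridData(ct) else ct,
                    if (is(ct, "VoxelGrid3D")) voxelSize(ct) else c(1, 1, 1))
  ang <- result@angle
  if (result@spineEnd == "low") ang <- ang + 180
  rot <- rotateAxial(vg@data, ang, fill = min(vg@data))
  # re-derive the crop box on the rotated volume
  thr <- stats::quantile(rot, 0.99, type = 7)
  idx <- which(rot >= thr, arr.ind = TRUE)
  if (!nrow(idx)) stop("crop box empty after rotation")
  box <- cbind(pmax(apply(idx, 2, min) - as.integer(pad), 1L),
               pmin(apply(idx, 2, max) + as.integer(pad), dim(rot)))
  # keep the crop symmetric about the rotation centre in x, so the
  # symmetry axis remains the vertical centre line of the cropped volume
  cx <- (dim(rot)[1] + 1) / 2
  half <- max(cx - box[1, 1], box[1, 2] - cx)
  box[1, ] <- c(max(floor(cx - half), 1L), min(ceiling(cx + half),
                                               dim(rot)[1]))
  out <- rot[box[1, 1]:box[1, 2], box[2, 1]:box[2, 2], box[3, 1]:box[3, 2]]
  asVoxelGrid(out, vg@voxelSize)
}

#' Automatic lung segmentation
#'
#' Segments the air-filled lungs from an oriented thoracic volume by
#' thresholding (Otsu on the intensity histogram separates dark, air-filled
#' voxels from tissue), retaining dark voxels enclosed by the body (cavity
#' filling from the volume border), applying 3D morphological
#' opening/closing, enforcing slice-to-slice continuity (components whose
#' consecutive-slice overlap breaks are dropped), and keeping the two
#' largest surviving components (left and right lung).
#'
#' @param ct a [VoxelGrid3D-class] (or 3D array).
#' @param threshold optional absolute intensity threshold; defaults to the
#'   Otsu threshold.
#' @param openRadius radius (voxels) of the morphological opening/closing.
#' @param minSliceOverlap minimum consecutive-slice overlap fraction (of
#'   the smaller slice area) for the continuity check.
#' @param minSlices minimum cranial--caudal extent (slices) of a component.
#' @return A [VoxelGrid3D-class] whose data is the binary lung mask.
#' @export
segmentLungs <- function(ct, threshold = NULL, openRadius = 1L,
                         minSliceOverlap = 0.3, minSlices = 3L) {
  arr <- if (is(ct, "VoxelGrid3D")) gridData(ct) else ct
  vs <- if (is(ct, "VoxelGrid3D")) voxelSize(ct) else c(1, 1, 1)
  if (diff(range(arr)) == 0)
    stop("segmentation-failure: volume has no contrast")
  if (is.null(threshold)) threshold <- otsuThreshold(as.vector(arr))
  dark <- arr < threshold
  # background = dark region connected to the volume border
  d <- dim(arr)
  lab <- labelComponents3D(dark)
  border <- unique(c(lab[1, , ], lab[d[1], , ], lab[, 1, ], lab[, d[2], ],
                     lab[, , 1], lab[, , d[3]]))
  border <- setdiff(border, 0L)
  cavity <- dark & !(lab %in% border)
  dim(cavity) <- d
  cavity <- binaryDilate(binaryErode(cavity, openRadius), openRadius)
  cavity <- binaryErode(binaryDilate(cavity, openRadius), openRadius)
  lab <- labelComponents3D(cavity)
  keep <- logical(0)
  labs <- setdiff(sort(unique(as.vector(lab))), 0L)
  for (l in labs) {
    comp <- lab == l
    zsum <- apply(comp, 3, sum)
    zs <- which(zsum > 0)
    if (length(zs) < minSlices) { keep[l] <- FALSE; next }
    ok <- TRUE
    for (k in zs[-length(zs)]) {
      if (!((k + 1) %in% zs)) { ok <- FALSE; break }
      ov <- sum(comp[, , k] & comp[, , k + 1])
      if (ov / min(zsum[k], zsum[k + 1]) < minSliceOverlap) {
        ok <- FALSE; break
      }
    }
    keep[l] <- ok
  }
  survivors <- labs[keep[labs]]
  if (!length(survivors))
    stop("segmentation-failure: no component survived the continuity checks")
  sizes <- vapply(survivors, function(l) sum(lab == l), numeric(1))
  top <- survivors[order(sizes, decreasing = TRUE)][seq_len(min(2L,
                                                     length(survivors)))]
  mask <- array(lab %in% top, d)
  asVoxelGrid(mask, vs)
}

#' Mask-derived lung volume
#'
#' Total lung volume evaluated as the volume of the segmentation mask:
#' in-mask voxel count times the physical voxel volume.
#'
#' @param mask a [VoxelGrid3D-class] (or logical array).
#' @param voxelSize voxel edge length(s) (mm); taken from the grid when
#'   `mask` is a [VoxelGrid3D-class].
#' @return Volume in mm^3.
#' @examples
#' lungVolume(array(TRUE, c(10, 10, 10)), voxelSize = 0.1)  # 1 mm^3
#' @export
lungVolume <- function(mask, voxelSize = NULL) {
  if (is(mask, "VoxelGrid3D")) {
    if (is.null(voxelSize)) voxelSize <- voxelSize(mask)
    mask <- gridData(mask)
  }
  if (is.null(voxelSize)) voxelSize <- c(1, 1, 1)
  if (length(voxelSize) == 1L) voxelSize <- rep(voxelSize, 3)
  n <- sum(mask > 0)
  if (!n) stop("empty mask")
  n * prod(voxelSize)
}

#' Detect heart blur from near-zero displacement regions
#'
#' Cardiac motion blurs the image near the heart, causing the velocimetry
#' to record zero tissue displacement there. This check marks in-mask XV
#' vectors with magnitude below `zeroTol`, finds contiguous marked regions,
#' and flags the sample when the largest region exceeds `blobThreshold` of
#' the in-mask volume. The centroid of the largest region is reported (as
#' fractional XV-grid coordinates) so the expected lower-left locality can
#' be verified.
#'
#' @param field a [DisplacementField-class] at (or accumulated to) peak
#'   inspiration.
#' @param mask XV-grid logical mask; defaults to the field's computed
#'   windows.
#' @param zeroTol vector magnitude (voxels/frame) below which displacement
#'   counts as zero.
#' @param blobThreshold mask fraction above which the largest contiguous
#'   zero region triggers the flag.
#' @return A [QCResult-class].
#' @export
detectHeartBlur <- function(field, mask = NULL, zeroTol = 0.05,
                            blobThreshold = 0.05) {
  vec <- field@vectors
  if (is.null(mask)) mask <- !is.na(field@peakQuality)
  mask <- mask & TRUE
  if (!sum(mask)) stop("empty mask: zero fraction undefined")
  mag <- sqrt(vec[, , , 1]^2 + vec[, , , 2]^2 + vec[, , , 3]^2)
  zero <- mask & is.finite(mag) & (mag < zeroTol)
  zf <- sum(zero) / sum(mask)
  blobFrac <- 0
  centroid <- rep(NA_real_, 3)
  if (any(zero)) {
    lab <- labelComponents3D(zero)
    blobFrac <- sum(lab == 1L) / sum(mask)
    pos <- which(lab == 1L, arr.ind = TRUE)
    centroid <- colMeans(pos) / dim(zero)
  }
  new("QCResult", zeroFraction = zf, largestBlobFraction = blobFrac,
      heartBlurFlag = blobFrac >= blobThreshold, centroid = centroid,
      zeroTol = zeroTol, blobThreshold = blobThreshold)
}
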