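## Windowed volumetric cross-correlation between consecutive breath phases.
## The correlation engine is a declared baseline: spectral cross-correlation
## per interrogation window with mean subtraction, three-point Gaussian
## sub-voxel peak refinement, and a peak-height-ratio validity test.

# Signed circular shift corresponding to a 0-based DFT index.
signedShift <- function(idx0, n) ifelse(idx0 > n / 2, idx0 - n, idx0)

# Cross-correlation of two equally sized windows; returns the displacement
# of b relative to a (b(x) ~ a(x - d)) with sub-voxel refinement, plus the
# peak-height ratio.
correlateWindow <- function(a, b) {
  d <- dim(a)
  a <- a - mean(a)
  b <- b - mean(b)
  R <- Re(fft(Conj(fft(a)) * fft(b), inverse = TRUE)) / prod(d)
  pk <- which(R == max(R))
  if (length(pk) > 1L) {
    # ties broken toward zero displacement
    cand <- arrayInd(pk, d) - 1L
    mags <- rowSums(sapply(1:3, function(ax)
      signedShift(cand[, ax], d[ax]))^2)
    pk <- pk[which.min(mags)]
  }
  p <- as.integer(arrayInd(pk, d)) - 1L
  disp <- numeric(3)
  Rmin <- min(R)
  # unbias ordinates: circular correlation of finite windows carries a
  # triangular overlap taper that biases the sub-voxel peak toward zero
  unbias <- function(idx0) {
    s <- vapply(1:3, function(a) signedShift(idx0[a], d[a]), numeric(1))
    prod(d / pmax(d - abs(s), 1))
  }
  for (ax in 1:3) {
    ip <- (p[ax] + 1L) %% d[ax]
    im <- (p[ax] - 1L) %% d[ax]
    sel <- function(i) {
      j <- p; j[ax] <- i
      R[j[1] + 1L, j[2] + 1L, j[3] + 1L] * unbias(j)
    }
    c0 <- sel(p[ax]); cp <- sel(ip); cm <- sel(im)
    delta <- 0
    if (c0 > 0 && cp > 0 && cm > 0) {
      # 3-point Gaussian interpolation on the raw correlation ordinates
      l0 <- log(c0); lp <- log(cp); lm <- log(cm)
      den <- 2 * (lm + lp - 2 * l0)
      if (is.finite(den) && den < 0) delta <- (lm - lp) / den
      if (!is.finite(delta) || abs(delta) > 1) delta <- 0
    } else if (cp != c0 || cm != c0) {
      # parabolic fallback when an ordinate is non-positive
      den <- 2 * (cm + cp - 2 * c0)
      if (is.finite(den) && den < 0) delta <- (cm - cp) / den
      if (!is.finite(delta) || abs(delta) > 0.5) delta <- 0
    }
    disp[ax] <- signedShift(p[ax], d[ax]) + delta
  }
  # second-tallest peak outside a 7^3 neighbourhood of the main peak (the
  # correlation peak of band-limited speckle spans several voxels)
  nb <- as.matrix(expand.grid(-3:3, -3:3, -3:3))
  nbi <- t((t(nb) + p) %% d) + 1L
  Rex <- R
  Rex[nbi] <- NA
  second <- max(Rex, na.rm = TRUE)
  ratio <- (max(R) - Rmin) / max(second - Rmin, .Machine$double.eps)
  list(disp = disp, ratio = ratio)
}

# Median fill of low-quality vectors from their valid 3^3 neighbours;
# windows that were never correlated (insufficient mask coverage) stay NA.
fillInvalid <- function(vec, valid, fillable) {
  d <- dim(valid)
  bad <- which(fillable)
  if (!length(bad)) return(vec)
  pos <- arrayInd(bad, d)
  for (r in seq_along(bad)) {
    p <- pos[r, ]
    rng <- lapply(1:3, function(ax) max(1, p[ax] - 1):min(d[ax], p[ax] + 1))
    nbhd <- as.matrix(expand.grid(rng[[1]], rng[[2]], rng[[3]]))
    ok <- valid[nbhd]
    if (!any(ok)) next
    for (cmp in 1:3)
      vec[p[1], p[2], p[3], cmp] <-
        stats::median(vec[cbind(nbhd[ok, , drop = FALSE], cmp)])
  }
  vec
}

#' Estimate 3D displacement fields by windowed cross-correlation
#'
#' For each consecutive pair of volumes, tiles the (optionally masked)
#' volume into overlapping cubic interrogation windows, locates the
#' cross-correlation peak of each window in the spectral domain, refines it
#' to sub-voxel precision by per-axis three-point Gaussian interpolation,
#' and returns one displacement vector per window centre in voxels/frame.
#' The default geometry (64-voxel windows, 50\% overlap) yields an XV grid
#' stride of 32 voxels per axis. Windows with less than `minCoverage` mask
#' coverage are flagged invalid (`NA` vectors); windows whose
#' tallest-to-second-tallest correlation peak ratio falls below
#' `minPeakRatio` are flagged invalid and filled by the local median of
#' valid neighbours.
#'
#' @param volumes list of [VoxelGrid3D-class] (or 3D arrays) of identical
#'   shape, one per breath phase, in time order.
#' @param windowSize interrogation window edge length (voxels, >= 8).
#' @param overlap overlap fraction between successive windows in [0, 1).
#' @param mask optional binary volume restricting analysis to the lung.
#' @param minCoverage minimum in-window mask fraction for a valid vector.
#' @param minPeakRatio peak-quality threshold below which vectors are
#'   replaced by the local median.
#' @return A list of [DisplacementField-class], one per consecutive pair.
#' @export
estimateDisplacements <- function(volumes, windowSize = 64L, overlap = 0.5,
                                  mask = NULL, minCoverage = 0.5,
                                  minPeakRatio = 1.2) {
  if (length(volumes) < 2L) stop("need at least two volumes")
  arrs <- lapply(volumes, function(v)
    if (is(v, "VoxelGrid3D")) gridData(v) else v)
  d <- dim(arrs[[1]])
  if (!all(vapply(arrs, function(a) identical(dim(a), d), logical(1))))
    stop("shape error: volumes must share dimensions")
  if (windowSize < 8L) stop("windowSize must be >= 8")
  if (overlap < 0 || overlap >= 1) stop("overlap must lie in [0, 1)")
  if (any(windowSize > d)) stop("sizing error: window larger than volume")
  w <- as.integer(windowSize)
  stride <- as.integer(round(w * (1 - overlap)))
  if (stride < 1L) stop("overlap too large for this window")
  starts <- lapply(d, function(n) seq(1L, n - w + 1L, by = stride))
  nv <- vapply(starts, length, integer(1))
  if (!is.null(mask) && is(mask, "VoxelGrid3D")) mask <- gridData(mask)
  origin <- (w + 1) / 2
  fields <- vector("list", length(arrs) - 1L)
  # precompute mask coverage per window
  cover <- array(1, nv)
  if (!is.null(mask)) {
    for (i in seq_len(nv[1])) for (j in seq_len(nv[2]))
      for (k in seq_len(nv[3])) {
        sx <- starts[[1]][i]; sy <- starts[[2]][j]; sz <- starts[[3]][k]
        cover[i, j, k] <- mean(mask[sx:(sx + w - 1L), sy:(sy + w - 1L),
                                    sz:(sz + w - 1L)])
      }
  }
  for (f in seq_along(fields)) {
    A <- arrs[[f]]; B <- arrs[[f + 1L]]
    vec <- array(NA_real_, c(nv, 3L))
    qual <- array(NA_real_, nv)
    valid <- array(FALSE, nv)
    for (i in seq_len(nv[1])) for (j in seq_len(nv[2]))
      for (k in seq_len(nv[3])) {
        if (cover[i, j, k] < minCoverage) next
        sx <- starts[[1]][i]; sy <- starts[[2]][j]; sz <- starts[[3]][k]
        wa <- A[sx:(sx + w - 1L), sy:(sy + w - 1L), sz:(sz + w - 1L)]
        wb <- B[sx:(sx + w - 1L), sy:(sy + w - 1L), sz:(sz + w - 1L)]
        res <- correlateWindow(wa, wb)
        vec[i, j, k, ] <- res$disp
        qual[i, j, k] <- res$ratio
        valid[i, j, k] <- res$ratio >= minPeakRatio
      }
    vec <- fillInvalid(vec, valid, !valid & !is.na(qual))
    fields[[f]] <- new("DisplacementField", vectors = vec,
                       gridOrigin = rep(origin, 3),
                       gridStride = rep(as.numeric(stride), 3),
                       phaseIndex = as.integer(f), peakQuality = qual,
                       valid = valid)
  }
  fields
}

#' XV-grid lung mask for a displacement field
#'
#' Marks XV voxels whose interrogation window had at least `minCoverage`
#' lung-mask coverage (equivalently, where a correlation was attempted).
#'
#' @param field a [DisplacementField-class].
#' @return 3D logical array on the XV grid.
#' @export
xvGridMask <- function(field) {
  !is.na(field@peakQuality)
}
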