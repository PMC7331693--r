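## Regional fractional expansion: (change in ROI volume) / (ROI volume) per
## XV voxel, computed as det(J) - 1 of the accumulated displacement.

# Sum displacement fields on a common XV grid (small-displacement Eulerian
# accumulation).
accumulateFields <- function(fields) {
  u <- fields[[1]]@vectors
  if (length(fields) > 1L)
    for (f in fields[-1L]) u <- u + f@vectors
  u
}

#' Regional fractional expansion at peak inspiration
#'
#' Accumulates the per-frame displacement fields from breath start to peak
#' inspiration on the XV grid, forms the deformation-gradient tensor
#' `J = I + grad(u)` by central differences (one-sided at the grid border),
#' and returns the per-XV-voxel local volume change `det(J) - 1` restricted
#' to the lung mask. This is the continuum equivalent of the ratio of the
#' deformed to undeformed region-of-interest volume, minus one.
#'
#' @param fields list of [DisplacementField-class] covering breath start to
#'   peak inspiration (vectors in fine-image voxels per frame).
#' @param mask optional logical array on the XV grid; defaults to the XV
#'   voxels where all fields hold valid or filled vectors.
#' @param voxelVolume physical volume of one XV voxel (defaults to
#'   `prod(gridStride)` fine voxels).
#' @return An [ExpansionMap-class] on the XV grid.
#' @examples
#' # a uniform dilation u = alpha * x expands every ROI by (1+alpha)^3 - 1
#' @export
fractionalExpansion <- function(fields, mask = NULL, voxelVolume = NULL) {
  if (!length(fields)) stop("need at least one displacement field")
  u <- accumulateFields(fields)
  d <- dim(u)[1:3]
  stride <- fields[[1]]@gridStride
  if (is.null(mask)) {
    mask <- Reduce(`&`, lapply(fields, function(f) !is.na(f@peakQuality)))
  }
  mask <- mask & TRUE
  badIdx <- which(mask & (!is.finite(u[, , , 1]) | !is.finite(u[, , , 2]) |
                            !is.finite(u[, , , 3])))
  if (length(badIdx)) {
    pos <- arrayInd(badIdx[seq_len(min(5L, length(badIdx)))], d)
    stop("propagation error: non-finite displacement inside mask at XV voxels ",
         paste(apply(pos, 1, paste, collapse = ","), collapse = "; "))
  }
  u[!is.finite(u)] <- 0
  e <- jacobianExpansionMasked(u, mask, stride)
  e[!mask] <- 0
  if (is.null(voxelVolume)) voxelVolume <- prod(stride)
  new("ExpansionMap", values = e, mask = mask,
      exclusion = array(FALSE, d), voxelVolume = voxelVolume)
}

#' Remove excluded regions (e.g. mainstem bronchi) from an expansion map
#'
#' The mainstem bronchi are removed from expansion maps before analysis;
#' all downstream statistics (histogram, IQR, fits, scores) ignore the
#' excluded voxels.
#'
#' @param map an [ExpansionMap-class].
#' @param exclusion logical array on the same grid marking voxels to drop.
#' @return The map with the exclusion applied (accumulative with any prior
#'   exclusion).
#' @export
applyExclusion <- function(map, exclusion) {
  if (!identical(dim(exclusion), dim(map@mask)))
    stop("exclusion must share the map grid")
  exclusion <- exclusion & TRUE
  if (any(exclusion & !map@mask)) {
    warning("exclusion extends outside the mask; using the intersection")
    exclusion <- exclusion & map@mask
  }
  map@exclusion <- map@exclusion | exclusion
  map
}
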