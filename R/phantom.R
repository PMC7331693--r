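#' Configure the synthetic breathing-lung phantom
#'
#' Builds a validated [PhantomConfig-class]. Defaults emulate the ventilated
#' mouse preparation the method targets: a 0.15 s inspiration and 0.35 s
#' expiration sampled at 15 breath phases, and three expansion-histogram
#' archetypes. `healthy` draws per-voxel fractional expansion from a narrow
#' unimodal distribution, `heterogeneous` from a wide one, and `clustered`
#' additionally paints spatially contiguous low-expansion blobs whose values
#' come from a second, lower mode (emulating mucus-obstructed regions).
#'
#' The mean expansion of the principal mode defaults to 0.1; true expansion
#' magnitudes in mice are not established, so this is a plausible working
#' value, not a measured one.
#'
#' @param gridShape integer length-3 grid size (voxels).
#' @param voxelSize voxel edge length(s), mm.
#' @param profile `"healthy"`, `"heterogeneous"` or `"clustered"`.
#' @param muMain,sigmaMain mean and spread of the principal expansion mode.
#'   `sigmaMain` defaults to 0.01 (healthy/clustered) or 0.03
#'   (heterogeneous).
#' @param muLow,sigmaLow,weightLow low mode mean/spread and its volume
#'   fraction (clustered profile).
#' @param nBlobs number of contiguous low-expansion regions.
#' @param heartBlur `NULL`, `TRUE` (default lower-left region), or a list
#'   `(centre = fractional xyz, radius = fraction)`.
#' @param inspTime,expTime inspiration and expiration durations (s).
#' @param nPhases breath phases per cycle (>= 3).
#' @param tidalFraction tidal volume as a fraction of total lung volume.
#' @param smoothSigma width (voxels) of the Gaussian kernel that imposes
#'   spatial correlation on the expansion noise.
#' @param speckleGrain characteristic speckle grain size (voxels).
#' @param seed master seed; every generator is a pure function of
#'   (config, seed).
#' @return A [PhantomConfig-class] object.
#' @examples
#' cfg <- phantomConfig(profile = "clustered", seed = 7)
#' cfg
#' @export
phantomConfig <- function(gridShape = c(96L, 96L, 96L),
                          voxelSize = c(0.1, 0.1, 0.1),
                          profile = c("healthy", "heterogeneous", "clustered"),
                          muMain = 0.1,
                          sigmaMain = NULL,
                          muLow = 0.05, sigmaLow = 0.01, weightLow = 0.3,
                          nBlobs = 4L,
                          heartBlur = NULL,
                          inspTime = 0.15, expTime = 0.35,
                          nPhases = 15L,
                          tidalFraction = 0.15,
                          smoothSigma = 3,
                          speckleGrain = 4,
                          seed = 1L) {
  profile <- match.arg(profile)
  if (is.null(sigmaMain))
    sigmaMain <- if (profile == "heterogeneous") 0.03 else 0.01
  if (isTRUE(heartBlur))
    heartBlur <- list(centre = c(0.32, 0.42, 0.68), radius = 0.16)
  if (is.null(heartBlur)) heartBlur <- list()
  if (length(voxelSize) == 1L) voxelSize <- rep(voxelSize, 3)
  new("PhantomConfig",
      gridShape = as.integer(gridShape), voxelSize = as.numeric(voxelSize),
      profile = profile, muMain = muMain, sigmaMain = sigmaMain,
      muLow = muLow, sigmaLow = sigmaLow, weightLow = weightLow,
      nBlobs = as.integer(nBlobs), heartBlur = heartBlur,
      inspTime = inspTime, expTime = expTime, nPhases = as.integer(nPhases),
      tidalFraction = tidalFraction, smoothSigma = smoothSigma,
      speckleGrain = speckleGrain, seed = as.integer(seed))
}

# Analytic two-lobe geometry, evaluated at (possibly rotated) coordinates
# given as fractions of the grid; returns a logical vector.
lobeIndicator <- function(xf, yf, zf, perturb = 0) {
  lobe <- function(cx) {
    m <- ((xf - cx) / 0.16)^2 + ((yf - 0.5) / 0.26)^2 +
      ((zf - 0.5) / 0.34)^2
    m <= (1 + perturb)^2
  }
  left <- lobe(0.30) & xf < 0.485
  right <- lobe(0.70) & xf > 0.515
  left | right
}

#' Generate a two-lobed synthetic lung mask
#'
#' Produces a binary mask of two lung-like ellipsoidal lobes separated by a
#' midline gap, with a seeded smooth boundary perturbation so repeated
#' configurations differ realistically across seeds while remaining
#' bit-identical for a fixed seed.
#'
#' @param config a [PhantomConfig-class].
#' @return A [VoxelGrid3D-class] whose data is a logical array.
#' @examples
#' mask <- makeLungMask(phantomConfig(gridShape = c(64, 64, 64)))
#' sum(gridData(mask))
#' @export
makeLungMask <- function(config) {
  d <- config@gridShape
  if (min(d) < 32L)
    stop("grid too small to fit two lung lobes (need >= 32 voxels per axis)")
  xf <- array(rep((seq_len(d[1]) - 0.5) / d[1], times = d[2] * d[3]), d)
  yf <- array(rep(rep((seq_len(d[2]) - 0.5) / d[2], each = d[1]),
                  times = d[3]), d)
  zf <- array(rep((seq_len(d[3]) - 0.5) / d[3], each = d[1] * d[2]), d)
  perturb <- withSeed(childSeed(config@seed, 1L), {
    p <- gaussianSmooth3D(array(stats::rnorm(prod(d)), d), max(d) / 12)
    0.08 * p / max(stats::sd(p), 1e-12)
  })
  mask <- lobeIndicator(xf, yf, zf, perturb)
  if (!sum(mask)) stop("grid too small to fit two lung lobes")
  # guard: keep exactly the two largest components (perturbation could in
  # principle pinch off slivers)
  lab <- labelComponents3D(mask)
  mask <- lab == 1L | lab == 2L
  asVoxelGrid(mask, config@voxelSize)
}

heartBlurRegion <- function(config, mask) {
  if (!length(config@heartBlur)) return(array(FALSE, dim(mask)))
  d <- dim(mask)
  ctr <- config@heartBlur$centre * d
  rad <- config@heartBlur$radius * min(d)
  xf <- array(rep(seq_len(d[1]), times = d[2] * d[3]), d)
  yf <- array(rep(rep(seq_len(d[2]), each = d[1]), times = d[3]), d)
  zf <- array(rep(seq_len(d[3]), each = d[1] * d[2]), d)
  sphere <- (xf - ctr[1])^2 + (yf - ctr[2])^2 + (zf - ctr[3])^2 <= rad^2
  sphere & mask
}

# Grow nBlobs contiguous regions inside the mask by repeated dilation from
# seeded voxels until the target volume fraction is reached.
growBlobs <- function(mask, nBlobs, targetFraction, seed) {
  total <- sum(mask)
  target <- targetFraction * total
  idx <- which(mask)
  seeds <- withSeed(seed, sample(idx, min(nBlobs, length(idx))))
  blob <- array(FALSE, dim(mask))
  blob[seeds] <- TRUE
  while (sum(blob) < target) {
    grown <- binaryDilate(blob) & mask
    if (sum(grown) == sum(blob)) break
    blob <- grown
  }
  blob
}

#' Generate a regional expansion scene with known ground truth
#'
#' Draws a spatially smoothed per-voxel fractional-expansion field inside
#' the lung mask according to the configured profile. Clustered profiles
#' paint `nBlobs` contiguous low-expansion regions grown by morphological
#' dilation from seeded voxels (mimicking the spatial grouping of
#' low-expansion voxels behind obstructed airways). A configured heart-blur
#' region is forced to exactly zero, as cardiac blur records zero tissue
#' displacement.
#'
#' In-mask values are standardised before scaling, so the realised mode
#' means and spreads match the configured ones.
#'
#' @param config a [PhantomConfig-class].
#' @param mask a [VoxelGrid3D-class] lung mask (or logical array), e.g. from
#'   [makeLungMask()].
#' @return A list with `map` (the true [ExpansionMap-class]) and `truth`
#'   (a [GroundTruth-class]).
#' @examples
#' cfg <- phantomConfig(gridShape = c(64, 64, 64), seed = 2)
#' scene <- makeExpansionScene(cfg, makeLungMask(cfg))
#' scene$map
#' @export
makeExpansionScene <- function(config, mask) {
  m <- if (is(mask, "VoxelGrid3D")) gridData(mask) else mask
  m <- m > 0
  if (!sum(m)) stop("mask is empty")
  if (config@profile == "clustered" && config@weightLow == 0)
    stop("configuration error: clustered profile requires weightLow > 0")
  d <- dim(m)
  z <- withSeed(childSeed(config@seed, 2L),
                gaussianSmooth3D(array(stats::rnorm(prod(d)), d),
                                 config@smoothSigma))
  zin <- z[m]
  zsd <- stats::sd(zin)
  z <- if (zsd > 0) (z - mean(zin)) / zsd else z * 0
  values <- array(0, d)
  values[m] <- config@muMain + config@sigmaMain * z[m]
  blob <- array(FALSE, d)
  if (config@profile == "clustered") {
    blob <- growBlobs(m, config@nBlobs, config@weightLow,
                      childSeed(config@seed, 3L))
    values[blob] <- config@muLow + config@sigmaLow * z[blob]
  }
  blur <- heartBlurRegion(config, m)
  values[blur] <- 0
  values[values <= -0.95] <- -0.95
  values[!m] <- 0
  map <- new("ExpansionMap", values = values, mask = m,
             exclusion = array(FALSE, d),
             voxelVolume = prod(config@voxelSize))
  truth <- new("GroundTruth", expansionMap = map, lungMask = m,
               blurRegion = blur,
               displacementBasis = array(0, c(0, 0, 0, 0)),
               phaseScale = numeric(0),
               params = list(
                 profile = config@profile, muMain = config@muMain,
                 sigmaMain = config@sigmaMain, muLow = config@muLow,
                 sigmaLow = config@sigmaLow, weightLow = config@weightLow,
                 blobFraction = sum(blob) / sum(m),
                 blurFraction = sum(blur) / sum(m),
                 maskVolume = sum(m) * prod(config@voxelSize),
                 seed = config@seed))
  list(map = map, truth = truth)
}

#' Generate a fractional volume--time breath curve
#'
#' The curve rises monotonically from 0 to `tidalFraction` over the
#' inspiration, then decays back toward 0 over the expiration, sampled at
#' `nPhases` uniformly spaced time points across the breath. The sampled
#' phase nearest the configured inspiration time is treated as the peak, so
#' the curve attains `tidalFraction` exactly at a sampled phase. The rise is
#' a quarter-sine (smooth start and finish); the decay is exponential with
#' rate `decayRate` or linear (full emptying over the expiration).
#'
#' @param config a [PhantomConfig-class].
#' @param decay `"exponential"` or `"linear"`.
#' @param decayRate expiratory rate constant (1/s) for exponential decay;
#'   default empties to 5\% of tidal volume by end-expiration.
#' @return A [VolumeTimeCurve-class].
#' @examples
#' makeBreathCurve(phantomConfig())
#' @export
makeBreathCurve <- function(config, decay = c("exponential", "linear"),
                            decayRate = NULL) {
  decay <- match.arg(decay)
  n <- config@nPhases
  if (n < 3L) stop("nPhases must be at least 3")
  period <- config@inspTime + config@expTime
  times <- seq(0, period, length.out = n)
  peak <- which.min(abs(times - config@inspTime))
  if (peak == 1L) peak <- 2L
  tPeak <- times[peak]
  if (is.null(decayRate)) decayRate <- -log(0.05) / config@expTime
  fv <- numeric(n)
  rise <- times <= tPeak
  fv[rise] <- config@tidalFraction * sin(pi / 2 * times[rise] / tPeak)
  post <- times > tPeak
  if (decay == "exponential") {
    fv[post] <- config@tidalFraction * exp(-decayRate * (times[post] - tPeak))
  } else {
    fv[post] <- config@tidalFraction *
      pmax(0, 1 - (times[post] - tPeak) / config@expTime)
  }
  fv[peak] <- config@tidalFraction
  fv[1] <- 0
  new("VolumeTimeCurve", times = times, fractionalVolume = fv,
      tidalFraction = max(fv), tau = NA_real_, tauCensored = FALSE,
      expiredThreshold = 0.67, magnitudeVolume = numeric(0))
}

# Calibrate a curl-free displacement basis whose discrete Jacobian
# expansion matches the target field; fixed-point refinement against the
# central-difference determinant.
displacementBasisFor <- function(target, iterations = 3L) {
  g <- target
  u <- poissonDisplacement(g)
  for (i in seq_len(iterations)) {
    e <- jacobianExpansion(u)
    g <- g + (target - e)
    u <- poissonDisplacement(g)
  }
  u
}

#' Synthesize a breathing speckle image sequence with true displacements
#'
#' Builds a band-passed speckle texture (grain `speckleGrain` voxels, so
#' interrogation windows contain ample unique structure) inside the lung
#' mask, then warps it per breath phase by a smooth curl-free displacement
#' field. The field is the gradient of a potential calibrated so that its
#' local volume change reproduces the scene's expansion map at peak
#' inspiration, scaled through the breath by the volume--time curve. The
#' peak field is rescaled globally so the integrated volume change matches
#' the configured tidal fraction, and the rescaled map is stored back on
#' the returned ground truth (the downstream disease scores are invariant
#' to overall scale). True per-frame displacement fields are recoverable
#' via [truePhaseDisplacement()] and are expressed in voxels/frame.
#'
#' @param scene output of [makeExpansionScene()] (the list, or its `truth`).
#' @param curve a [VolumeTimeCurve-class] from [makeBreathCurve()].
#' @param config the generating [PhantomConfig-class].
#' @param phases phase indices to synthesize (default all); the truth's
#'   per-phase scales always cover the whole breath.
#' @return A list with `volumes` (list of [VoxelGrid3D-class], one per
#'   requested phase) and `truth` (the [GroundTruth-class] with the
#'   displacement basis and per-phase scales filled in).
#' @export
makeSpeckleSequence <- function(scene, curve, config,
                                phases = seq_len(config@nPhases)) {
  truth <- if (is(scene, "GroundTruth")) scene else scene$truth
  nPhases <- length(curve@times)
  if (nPhases != config@nPhases)
    stop("scene and curve must share the phase count")
  m <- truth@lungMask
  d <- dim(m)
  emap <- truth@expansionMap@values
  tf <- curve@tidalFraction
  s <- if (tf > 0) curve@fractionalVolume / tf else numeric(nPhases) * 0
  # scale the peak expansion so the integrated volume change matches the
  # configured tidal fraction; scores downstream are scale-invariant
  meanE <- sum(emap[m]) / sum(m)
  kappa <- 1
  if (tf > 0 && meanE > 0) kappa <- tf / meanE
  target <- pmax(emap * kappa, -0.95)
  truth@expansionMap@values <- target
  U <- if (tf > 0 && any(target != 0))
    displacementBasisFor(target) else array(0, c(d, 3))
  truth@params$tidalScale <- kappa
  if (any(truth@blurRegion)) {
    # heart blur records zero tissue displacement, not just zero expansion
    for (cmp in 1:3) {
      comp <- U[, , , cmp]
      comp[truth@blurRegion] <- 0
      U[, , , cmp] <- comp
    }
  }
  # boundary check: peak displacement must stay inside the grid margin
  margin <- 2
  maxdisp <- max(abs(U))
  if (maxdisp > min(d) / 2 - margin)
    stop("boundary error: requested warp pushes texture outside the grid")
  texture <- withSeed(childSeed(config@seed, 4L), {
    # band-passed noise: suppressing low frequencies keeps the correlation
    # peak sharp inside interrogation windows
    n <- array(stats::rnorm(prod(d)), d)
    g <- gaussianSmooth3D(n, 0.3 * config@speckleGrain) -
      gaussianSmooth3D(n, 0.75 * config@speckleGrain)
    g <- g / stats::sd(g)
    tex <- array(0.05, d)
    tex[m] <- 0.5 + 0.15 * g[m]
    tex
  })
  X <- array(rep(seq_len(d[1]), times = d[2] * d[3]), d)
  Y <- array(rep(rep(seq_len(d[2]), each = d[1]), times = d[3]), d)
  Z <- array(rep(seq_len(d[3]), each = d[1] * d[2]), d)
  volumes <- vector("list", length(phases))
  names(volumes) <- paste0("phase", phases)
  for (vi in seq_along(phases)) {
    p <- phases[vi]
    if (s[p] == 0) {
      volumes[[vi]] <- asVoxelGrid(texture, config@voxelSize)
      next
    }
    coords <- cbind(as.vector(X - s[p] * U[, , , 1]),
                    as.vector(Y - s[p] * U[, , , 2]),
                    as.vector(Z - s[p] * U[, , , 3]))
    vol <- array(trilinear(texture, coords), d)
    volumes[[vi]] <- asVoxelGrid(vol, config@voxelSize)
  }
  truth@displacementBasis <- U
  truth@phaseScale <- s
  list(volumes = volumes, truth = truth)
}

#' True displacement between consecutive phases of a phantom sequence
#'
#' Materialises the ground-truth per-frame displacement field (voxels/frame)
#' between phases `phase` and `phase + 1` from the stored basis, optionally
#' sampled at XV window centres.
#'
#' @param truth a [GroundTruth-class] with a displacement basis.
#' @param phase index of the earlier phase.
#' @param origin,stride optional XV grid geometry (fine-voxel units); when
#'   given, the field is subsampled at `origin + (i-1)*stride`.
#' @return A 4D array `[x, y, z, 3]` of displacements in voxels/frame.
#' @export
truePhaseDisplacement <- function(truth, phase, origin = NULL,
                                  stride = NULL) {
  if (!length(truth@displacementBasis))
    stop("ground truth carries no displacement basis; run makeSpeckleSequence")
  s <- truth@phaseScale
  if (phase < 1L || phase >= length(s))
    stop("phase out of range")
  u <- truth@displacementBasis * (s[phase + 1] - s[phase])
  if (is.null(origin)) return(u)
  d <- dim(u)[1:3]
  ii <- lapply(1:3, function(ax) {
    ctr <- seq(origin[ax], d[ax], by = stride[ax])
    round(ctr)
  })
  u[ii[[1]], ii[[2]], ii[[3]], , drop = FALSE]
}

# Rotated fractional coordinates in the axial (x, y) plane; angle in
# degrees, positive = anatomy rotated counter-clockwise in the (x, y) frame.
rotatedFractions <- function(d, angle) {
  th <- angle * pi / 180
  xf <- array(rep((seq_len(d[1]) - 0.5) / d[1], times = d[2] * d[3]), d)
  yf <- array(rep(rep((seq_len(d[2]) - 0.5) / d[2], each = d[1]),
                  times = d[3]), d)
  zf <- array(rep((seq_len(d[3]) - 0.5) / d[3], each = d[1] * d[2]), d)
  xr <- 0.5 + cos(th) * (xf - 0.5) + sin(th) * (yf - 0.5)
  yr <- 0.5 - sin(th) * (xf - 0.5) + cos(th) * (yf - 0.5)
  list(x = xr, y = yr, z = zf)
}

boneIndicator <- function(co) {
  spine <- ((co$x - 0.5) / 0.055)^2 + ((co$y - 0.80) / 0.055)^2 <= 1
  sternum <- ((co$x - 0.5) / 0.028)^2 + ((co$y - 0.17) / 0.028)^2 <= 1
  r <- sqrt(((co$x - 0.5) / 0.36)^2 + ((co$y - 0.5) / 0.33)^2)
  nz <- 6L
  zc <- (seq_len(nz) - 0.5) / nz
  ribBand <- Reduce(`|`, lapply(zc, function(z) abs(co$z - z) < 0.022))
  ribs <- abs(r - 1) < 0.05 & ribBand
  list(spine = spine, sternum = sternum, ribs = ribs)
}

#' Generate a bilaterally symmetric bone phantom
#'
#' High-intensity spine, sternum and rib structures embedded in a
#' soft-tissue ellipse, mirror-symmetric about a line through spine and
#' sternum, rotated in the axial plane by `angle` degrees. The spine blob is
#' distinctly larger than the sternum so the two ends of the symmetry line
#' are distinguishable. Used to exercise the mirror-symmetry orientation
#' search.
#'
#' @param angle in-plane rotation of the anatomy, degrees, |angle| <= 90.
#'   At 0 the symmetry line is vertical with the spine at high y.
#' @param seed noise seed.
#' @param gridShape integer length-3 grid size.
#' @param voxelSize voxel edge length(s), mm.
#' @param noiseSd additive Gaussian intensity noise.
#' @return A list with `volume` (a [VoxelGrid3D-class]) and `angle` (the
#'   ground-truth rotation applied).
#' @examples
#' bp <- makeBonePhantom(17, seed = 3, gridShape = c(64, 64, 32))
#' bp$volume
#' @export
makeBonePhantom <- function(angle, seed = 1L, gridShape = c(96L, 96L, 48L),
                            voxelSize = c(0.1, 0.1, 0.1),
                            noiseSd = 0.02) {
  if (abs(angle) > 90) stop("|angle| must be <= 90 degrees")
  d <- as.integer(gridShape)
  co <- rotatedFractions(d, angle)
  body <- ((co$x - 0.5) / 0.44)^2 + ((co$y - 0.5) / 0.42)^2 <= 1
  bones <- boneIndicator(co)
  vol <- array(0.02, d)
  vol[body] <- 0.3
  vol[bones$ribs] <- 0.9
  vol[bones$spine] <- 1.0
  vol[bones$sternum] <- 1.0
  if (noiseSd > 0)
    vol <- vol + withSeed(seed, array(stats::rnorm(prod(d), 0, noiseSd), d))
  list(volume = asVoxelGrid(vol, voxelSize), angle = angle)
}

#' Generate a full synthetic chest volume
#'
#' Combines the soft-tissue body, two darker air-filled lung lobes with
#' speckle texture, and the bone structures of [makeBonePhantom()] into one
#' CT-like volume, for exercising segmentation and orientation end to end.
#'
#' @param config a [PhantomConfig-class] (grid, voxel size, seed).
#' @param angle axial-plane rotation of the anatomy (degrees).
#' @param noiseSd additive Gaussian intensity noise.
#' @return A list with `volume` (a [VoxelGrid3D-class]), `lungMask`
#'   (logical array at `angle`), and `angle`.
#' @export
makeChestPhantom <- function(config, angle = 0, noiseSd = 0) {
  d <- config@gridShape
  co <- rotatedFractions(d, angle)
  body <- ((co$x - 0.5) / 0.44)^2 + ((co$y - 0.5) / 0.42)^2 <= 1
  lungs <- lobeIndicator(co$x, co$y, co$z)
  bones <- boneIndicator(co)
  speckle <- withSeed(childSeed(config@seed, 4L), {
    g <- gaussianSmooth3D(array(stats::rnorm(prod(d)), d), 1.4)
    (g - min(g)) / (max(g) - min(g))
  })
  vol <- array(0.02, d)
  vol[body] <- 0.6
  vol[lungs] <- 0.12 + 0.10 * speckle[lungs]
  vol[bones$ribs & !lungs] <- 0.9
  vol[bones$spine] <- 1.0
  vol[bones$sternum] <- 1.0
  if (noiseSd > 0)
    vol <- vol + withSeed(childSeed(config@seed, 5L),
                          array(stats::rnorm(prod(d), 0, noiseSd), d))
  list(volume = asVoxelGrid(vol, config@voxelSize), lungMask = lungs,
       angle = angle)
}
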