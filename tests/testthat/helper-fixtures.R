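# Shared fixtures, memoised so expensive phantoms are generated once per
# test run. All fixtures are pure functions of fixed seeds.

.fixtures <- new.env(parent = emptyenv())

memo <- function(name, maker) {
  if (!exists(name, envir = .fixtures))
    assign(name, maker(), envir = .fixtures)
  get(name, envir = .fixtures)
}

# Band-passed periodic speckle volume (grain ~2.7 voxels).
speckleVolume <- function(n = 48L, seed = 1L, grain = 2.7) {
  set.seed(seed)
  w <- array(stats::rnorm(n^3), c(n, n, n))
  g <- xvlung:::gaussianSmooth3D(w, 0.3 * grain) -
    xvlung:::gaussianSmooth3D(w, 0.75 * grain)
  g / stats::sd(g)
}

circShift <- function(a, d) {
  n <- dim(a)
  a[(seq_len(n[1]) - 1 - d[1]) %% n[1] + 1,
    (seq_len(n[2]) - 1 - d[2]) %% n[2] + 1,
    (seq_len(n[3]) - 1 - d[3]) %% n[3] + 1]
}

# Full measurement-chain fixture: phantom breathing sequence to peak
# inspiration plus its velocimetry fields and window-coverage map.
chainFixture <- function() memo("chain", function() {
  cfg <- phantomConfig(gridShape = c(128L, 128L, 96L), seed = 5,
                       profile = "heterogeneous", smoothSigma = 8,
                       speckleGrain = 2.7)
  mask <- makeLungMask(cfg)
  m <- gridData(mask)
  d <- dim(m)
  scene <- makeExpansionScene(cfg, mask)
  curve <- makeBreathCurve(cfg)
  peak <- which.max(fractionalVolume(curve))
  sq <- makeSpeckleSequence(scene, curve, cfg, phases = seq_len(peak))
  fields <- estimateDisplacements(sq$volumes, windowSize = 16,
                                  overlap = 0.5, mask = m)
  or <- gridOrigin(fields[[1]])
  st <- gridStride(fields[[1]])
  nv <- dim(vectors(fields[[1]]))[1:3]
  w <- 16L
  starts <- lapply(1:3, function(ax) seq(1, d[ax] - w + 1, by = st[ax]))
  cover <- array(0, nv)
  for (i in seq_len(nv[1])) for (j in seq_len(nv[2]))
    for (k in seq_len(nv[3]))
      cover[i, j, k] <- mean(m[starts[[1]][i]:(starts[[1]][i] + w - 1),
                               starts[[2]][j]:(starts[[2]][j] + w - 1),
                               starts[[3]][k]:(starts[[3]][k] + w - 1)])
  ii <- lapply(1:3, function(ax)
    round(seq(or[ax], by = st[ax], length.out = nv[ax])))
  Uxv <- sq$truth@displacementBasis[ii[[1]], ii[[2]], ii[[3]], ,
                                    drop = FALSE]
  list(cfg = cfg, mask = m, scene = scene, curve = curve, truth = sq$truth,
       volumes = sq$volumes, fields = fields, origin = or, stride = st,
       nv = nv, cover = cover, idx = ii, Uxv = Uxv, peak = peak)
})

# Ground-truth DisplacementField objects for the chain fixture phases.
truthFields <- function(ch) {
  nPh <- length(ch$truth@phaseScale)
  lapply(seq_len(nPh - 1L), function(p) {
    uu <- truePhaseDisplacement(ch$truth, p)[ch$idx[[1]], ch$idx[[2]],
                                             ch$idx[[3]], , drop = FALSE]
    new("DisplacementField", vectors = uu, gridOrigin = ch$origin,
        gridStride = ch$stride, phaseIndex = as.integer(p),
        peakQuality = array(2, ch$nv), valid = array(TRUE, ch$nv))
  })
}

# In-mask expansion values for seeded phantom scenes (disease scoring).
sceneValues <- function(profile, seed, gridShape = c(96L, 96L, 96L)) {
  cfg <- phantomConfig(gridShape = gridShape, profile = profile,
                       seed = seed)
  expansionValues(makeExpansionScene(cfg, makeLungMask(cfg))$map)
}

cohortValues <- function() memo("cohortValues", function() {
  list(healthy = lapply(1:5, function(s) sceneValues("healthy", s)),
       heterogeneous = lapply(1:5, function(s)
         sceneValues("heterogeneous", 100 + s)),
       clustered = lapply(1:5, function(s)
         sceneValues("clustered", 200 + s)))
})

# A DisplacementField holding an arbitrary vector array on a regular grid.
fieldFromArray <- function(vec, stride = c(8, 8, 8),
                           origin = (stride + 1) / 2) {
  nv <- dim(vec)[1:3]
  new("DisplacementField", vectors = vec, gridOrigin = origin,
      gridStride = stride, phaseIndex = 1L,
      peakQuality = array(2, nv), valid = array(TRUE, nv))
}

# Uniform-dilation displacement field u = alpha * (x - x0) on an XV grid.
dilationField <- function(alpha, nv = c(7L, 7L, 7L), stride = c(8, 8, 8)) {
  origin <- (stride + 1) / 2
  ctr <- origin + (nv - 1) / 2 * stride
  vec <- array(0, c(nv, 3))
  for (ax in 1:3) {
    pos <- origin[ax] + (slice.index(array(0, nv), ax) - 1) * stride[ax]
    vec[, , , ax] <- alpha * (pos - ctr[ax])
  }
  fieldFromArray(vec, stride, origin)
}

# Independent connected-component count: iterative minimum-label
# propagation over the 6-neighbourhood (no shared code with the package's
# igraph-based labelling).
countComponents <- function(mask) {
  lab <- array(seq_along(mask), dim(mask))
  lab[!mask] <- 0L
  sh <- function(a, ax, by) {
    d <- dim(a)
    out <- array(Inf, d)
    src <- dst <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
    if (by > 0) { dst[[ax]] <- (by + 1):d[ax]; src[[ax]] <- 1:(d[ax] - by) }
    else { dst[[ax]] <- 1:(d[ax] + by); src[[ax]] <- (1 - by):d[ax] }
    do.call(`[<-`, c(list(out), dst, list(do.call(`[`, c(list(a), src)))))
  }
  repeat {
    nb <- lab
    nb[!mask] <- Inf
    best <- nb
    for (ax in 1:3) for (by in c(-1L, 1L)) {
      cand <- sh(nb, ax, by)
      best <- pmin(best, cand)
    }
    best[best == Inf | !mask] <- 0
    newlab <- pmin(lab, best)
    newlab[!mask] <- 0L
    if (identical(newlab, lab)) break
    lab <- newlab
  }
  length(unique(lab[mask]))
}
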