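test_that("lung mask is deterministic, two-lobed, and rejects tiny grids", {
  cfg <- phantomConfig(gridShape = c(64L, 64L, 64L), seed = 1)
  m1 <- makeLungMask(cfg)
  m2 <- makeLungMask(cfg)
  expect_identical(gridData(m1), gridData(m2))
  expect_gt(sum(gridData(m1)), 0)
  # independent label-propagation oracle for the component count
  expect_equal(countComponents(gridData(m1)), 2L)
  expect_equal(countComponents(gridData(makeLungMask(
    phantomConfig(gridShape = c(72L, 48L, 64L), seed = 9)))), 2L)
  expect_error(makeLungMask(phantomConfig(gridShape = c(8L, 8L, 8L))),
               "too small")
})

test_that("expansion scenes honour the configured mixture", {
  cfg0 <- phantomConfig(gridShape = c(48L, 48L, 48L), sigmaMain = 0,
                        seed = 2)
  mask <- makeLungMask(cfg0)
  sc0 <- makeExpansionScene(cfg0, mask)
  expect_true(all(expansionValues(sc0$map) == cfg0@muMain))

  cfg <- phantomConfig(gridShape = c(64L, 64L, 64L), profile = "clustered",
                       muMain = 0.10, muLow = 0.05, weightLow = 0.3,
                       seed = 3)
  mask <- makeLungMask(cfg)
  sc <- makeExpansionScene(cfg, mask)
  v <- expansionValues(sc$map)
  expect_gt(length(v), 1e4)
  # mixture-mean closed form, 3 standard errors of the sample mean
  mixMean <- 0.3 * 0.05 + 0.7 * 0.10
  expect_lt(abs(mean(v) - mixMean), 3 * stats::sd(v) / sqrt(length(v)) +
              abs(sc$truth@params$blobFraction - 0.3) * (0.10 - 0.05))
  # blob growth hits the target volume fraction closely
  expect_lt(abs(sc$truth@params$blobFraction - 0.3), 0.05)
  expect_error(makeExpansionScene(
    phantomConfig(profile = "clustered", weightLow = 0, seed = 1), mask),
    "weightLow")
})

test_that("heart-blur regions are forced to exactly zero", {
  cfg <- phantomConfig(gridShape = c(48L, 48L, 48L), heartBlur = TRUE,
                       seed = 4)
  mask <- makeLungMask(cfg)
  sc <- makeExpansionScene(cfg, mask)
  blur <- sc$truth@blurRegion
  expect_gt(sum(blur), 0)
  expect_true(all(sc$map@values[blur] == 0))
  expect_true(all(sc$map@values[gridData(mask) & !blur] != 0))
})

test_that("breath curve peaks at the tidal fraction and decays as stated", {
  cfg <- phantomConfig(seed = 1)
  cv <- makeBreathCurve(cfg)
  peak <- which.max(fractionalVolume(cv))
  expect_equal(phaseTimes(cv)[peak],
               phaseTimes(cv)[which.min(abs(phaseTimes(cv) - cfg@inspTime))])
  expect_identical(fractionalVolume(cv)[peak], cfg@tidalFraction)
  expect_identical(fractionalVolume(cv)[1], 0)
  expect_true(all(diff(fractionalVolume(cv)[1:peak]) >= 0))
  # exponential decay closed form at every sampled phase after the peak
  k <- 4
  cvk <- makeBreathCurve(cfg, decay = "exponential", decayRate = k)
  post <- (peak + 1):length(phaseTimes(cvk))
  dt <- phaseTimes(cvk)[post] - phaseTimes(cvk)[peak]
  expect_equal(fractionalVolume(cvk)[post],
               cfg@tidalFraction * exp(-k * dt), tolerance = 1e-12)
  flat <- makeBreathCurve(phantomConfig(tidalFraction = 0))
  expect_true(all(fractionalVolume(flat) == 0))
  expect_error(phantomConfig(nPhases = 2), "nPhases")
})

test_that("speckle sequences are deterministic and warp as requested", {
  cfg <- phantomConfig(gridShape = c(48L, 48L, 48L), nPhases = 5L,
                       seed = 6)
  mask <- makeLungMask(cfg)
  sc <- makeExpansionScene(cfg, mask)
  cv <- makeBreathCurve(cfg)
  s1 <- makeSpeckleSequence(sc, cv, cfg, phases = 1:3)
  s2 <- makeSpeckleSequence(sc, cv, cfg, phases = 1:3)
  expect_identical(gridData(s1$volumes[[3]]), gridData(s2$volumes[[3]]))

  # zero-expansion scene: every phase identical to phase 0
  cfg0 <- phantomConfig(gridShape = c(48L, 48L, 48L), nPhases = 4L,
                        muMain = 0, sigmaMain = 0, seed = 6)
  sc0 <- makeExpansionScene(cfg0, mask)
  s0 <- makeSpeckleSequence(sc0, makeBreathCurve(cfg0), cfg0)
  expect_identical(gridData(s0$volumes[[1]]), gridData(s0$volumes[[4]]))

  # warp agrees with an independent scalar trilinear oracle at spot checks
  tru <- s1$truth
  p <- 3
  u <- tru@displacementBasis * tru@phaseScale[p]
  tex <- gridData(s1$volumes[[1]])  # phase 1 has scale 0: the raw texture
  interp <- function(a, x, y, z) {
    x0 <- floor(x); y0 <- floor(y); z0 <- floor(z)
    fx <- x - x0; fy <- y - y0; fz <- z - z0
    acc <- 0
    for (dx in 0:1) for (dy in 0:1) for (dz in 0:1)
      acc <- acc + a[x0 + dx, y0 + dy, z0 + dz] *
        (if (dx) fx else 1 - fx) * (if (dy) fy else 1 - fy) *
        (if (dz) fz else 1 - fz)
    acc
  }
  set.seed(1)
  pts <- cbind(sample(10:38, 20, TRUE), sample(10:38, 20, TRUE),
               sample(10:38, 20, TRUE))
  got <- gridData(s1$volumes[[3]])[pts]
  want <- vapply(seq_len(nrow(pts)), function(r) {
    q <- pts[r, ]
    interp(tex, q[1] - u[q[1], q[2], q[3], 1],
           q[2] - u[q[1], q[2], q[3], 2], q[3] - u[q[1], q[2], q[3], 3])
  }, numeric(1))
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("true displacement reproduces the stored expansion map", {
  ch <- chainFixture()
  e <- xvlung:::jacobianExpansion(ch$truth@displacementBasis)
  tv <- ch$truth@expansionMap@values
  m <- ch$mask
  relRMS <- sqrt(mean((e[m] - tv[m])^2)) / sqrt(mean(tv[m]^2))
  expect_lt(relRMS, 0.02)
  # integrated volume change matches the configured tidal fraction
  expect_equal(sum(tv[m]) / sum(m), ch$cfg@tidalFraction,
               tolerance = 1e-6)
})

test_that("scene moments match configured parameters within Monte Carlo error", {
  v <- sceneValues("heterogeneous", 31, gridShape = c(64L, 64L, 64L))
  n <- length(v)
  expect_gt(n, 1e4)
  expect_lt(abs(mean(v) - 0.1), 3 * stats::sd(v) / sqrt(n))
  # spread is standardised to the configured sigma exactly
  expect_equal(stats::sd(v), 0.03, tolerance = 1e-6)
})

test_that("bone phantom is mirror symmetric and seed-stable", {
  b0 <- makeBonePhantom(0, seed = 3, gridShape = c(64L, 64L, 32L))
  b0b <- makeBonePhantom(0, seed = 3, gridShape = c(64L, 64L, 32L))
  expect_identical(gridData(b0$volume), gridData(b0b$volume))
  # noise-free: the projection is mirror symmetric by construction
  bn <- makeBonePhantom(0, seed = 3, gridShape = c(64L, 64L, 32L),
                        noiseSd = 0)
  proj <- apply(gridData(bn$volume), c(1, 2), max)
  mirrorCor <- function(p) stats::cor(as.vector(p),
                                      as.vector(p[nrow(p):1, ]))
  c0 <- mirrorCor(proj >= stats::quantile(proj, 0.99))
  b17 <- makeBonePhantom(17, seed = 3, gridShape = c(64L, 64L, 32L),
                         noiseSd = 0)
  proj17 <- apply(gridData(b17$volume), c(1, 2), max)
  c17 <- mirrorCor(proj17 >= stats::quantile(proj17, 0.99))
  expect_gt(c0, 0.99)
  expect_lt(c17, c0 - 0.05)
  expect_error(makeBonePhantom(120), "90")
})
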