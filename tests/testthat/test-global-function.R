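test_that("volume-time curve integrates regional expansion", {
  nv <- c(5L, 5L, 5L)
  zero <- fieldFromArray(array(0, c(nv, 3)))
  cv <- volumeTimeCurve(list(zero, zero), times = c(0, 0.1, 0.2),
                        totalLungVolume = 1000)
  expect_true(all(fractionalVolume(cv) == 0))

  # single-region lung: expansion alpha in one XV voxel of volume v
  alpha <- (1.02)^3 - 1
  dil <- dilationField(0.02, nv = nv)
  mask <- array(FALSE, nv)
  mask[3, 3, 3] <- TRUE
  v <- prod(gridStride(dil))
  V <- 10 * v
  cv2 <- volumeTimeCurve(list(dil), times = c(0, 0.1),
                         totalLungVolume = V, mask = mask)
  expect_equal(tidalFraction(cv2), alpha * v / V, tolerance = 1e-9)
  expect_error(volumeTimeCurve(list(dil), times = c(0, 0.1),
                               totalLungVolume = 0), "zero lung volume")

  # magnitude-sum estimator is reported alongside when requested
  cv3 <- volumeTimeCurve(list(dil), times = c(0, 0.1), totalLungVolume = V,
                         mask = mask, magnitude = TRUE)
  expect_length(cv3@magnitudeVolume, 2)
})

test_that("phantom ground-truth fields reproduce the configured tidal fraction", {
  ch <- chainFixture()
  fieldsT <- truthFields(ch)
  cv <- volumeTimeCurve(fieldsT, phaseTimes(ch$curve),
                        totalLungVolume = sum(ch$mask),
                        xvVoxelVolume = prod(ch$stride))
  expect_lt(abs(tidalFraction(cv) - ch$cfg@tidalFraction) /
              ch$cfg@tidalFraction, 0.05)
  # tau from the full ground-truth curve matches the exponential closed form
  cv <- expiratoryTimeConstant(cv)
  kDefault <- -log(0.05) / ch$cfg@expTime
  expect_lt(abs(cv@tau - (-log(0.33) / kDefault)) /
              (-log(0.33) / kDefault), 0.05)
})

test_that("tau honours its threshold definition", {
  # crossing exactly at a sampled phase: tau is that phase offset
  cv <- new("VolumeTimeCurve", times = seq(0, 0.5, by = 0.1),
            fractionalVolume = c(0, 0.2, 0.2 * 0.33, 0.01, 0.005, 0),
            tidalFraction = 0.2, tau = NA_real_, tauCensored = FALSE,
            expiredThreshold = 0.67, magnitudeVolume = numeric(0))
  cv <- expiratoryTimeConstant(cv)
  expect_equal(cv@tau, 0.1)

  # linear emptying over 0.35 s: tau = 0.67 * 0.35
  cfg <- phantomConfig(nPhases = 15L)
  lin <- expiratoryTimeConstant(makeBreathCurve(cfg, decay = "linear"))
  expect_equal(lin@tau, 0.67 * 0.35, tolerance = 1e-9)

  # exponential with rate k: tau = -ln(0.33)/k within 2% at 15 phases
  for (k in c(6, 9, 12)) {
    cv <- expiratoryTimeConstant(makeBreathCurve(cfg, decayRate = k))
    expect_lt(abs(cv@tau - (-log(0.33) / k)) / (-log(0.33) / k), 0.02)
  }

  # denser sampling converges tau towards the closed form
  errAt <- function(n) {
    cvn <- expiratoryTimeConstant(makeBreathCurve(
      phantomConfig(nPhases = n), decayRate = 9))
    abs(cvn@tau - (-log(0.33) / 9))
  }
  expect_lt(errAt(60L), errAt(15L))

  # invariant to rescaling the volume axis
  sc <- makeBreathCurve(cfg, decayRate = 9)
  sc2 <- sc
  sc2@fractionalVolume <- sc@fractionalVolume * 5
  sc2@tidalFraction <- sc@tidalFraction * 5
  expect_equal(expiratoryTimeConstant(sc)@tau,
               expiratoryTimeConstant(sc2)@tau)

  # censoring when expiration never reaches the threshold
  slow <- makeBreathCurve(cfg, decayRate = 0.5)
  expect_warning(slowT <- expiratoryTimeConstant(slow), "censored")
  expect_true(slowT@tauCensored)
  expect_equal(slowT@tau,
               max(phaseTimes(slow)) -
                 phaseTimes(slow)[which.max(fractionalVolume(slow))])
})
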