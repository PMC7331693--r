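test_that("XV grid geometry follows the window/overlap setting", {
  g <- speckleVolume(96, seed = 2)
  f <- estimateDisplacements(list(g, g), windowSize = 64, overlap = 0.5)
  expect_equal(gridStride(f[[1]]), c(32, 32, 32))
  expect_equal(dim(vectors(f[[1]]))[1:3], c(2L, 2L, 2L))
  # vectors-per-axis formula across geometries
  for (spec in list(c(48, 16, 0.5), c(48, 16, 0.75), c(48, 24, 0))) {
    n <- spec[1]; w <- spec[2]; ov <- spec[3]
    g2 <- speckleVolume(n, seed = 3)
    fld <- estimateDisplacements(list(g2, g2), windowSize = w,
                                 overlap = ov)[[1]]
    stride <- round(w * (1 - ov))
    expect_equal(dim(vectors(fld))[1:3],
                 rep(floor((n - w) / stride) + 1, 3))
    expect_equal(gridStride(fld), rep(stride, 3))
  }
})

test_that("identical volumes give exactly zero displacement", {
  g <- speckleVolume(48, seed = 4)
  f <- estimateDisplacements(list(g, g), windowSize = 16, overlap = 0.5)
  expect_lt(max(abs(vectors(f[[1]]))), 1e-12)
  expect_true(all(validVectors(f[[1]])))
})

test_that("integer and sub-voxel shifts are recovered", {
  g <- speckleVolume(64, seed = 5)
  shift <- c(3, -2, 1)
  f <- estimateDisplacements(list(g, circShift(g, shift)),
                             windowSize = 32, overlap = 0.5)
  err <- sweep(matrix(vectors(f[[1]]), ncol = 3), 2, shift)
  expect_lt(max(abs(err)), 0.1)

  # 0.4-voxel shift via spectral resampling
  n <- 64
  ph <- exp(-2i * pi * xvlung:::fftFreq(n) * 0.4)
  PH <- array(rep(ph, times = n * n), c(n, n, n))
  B <- Re(fft(fft(g) * PH, inverse = TRUE)) / n^3
  f2 <- estimateDisplacements(list(g, B), windowSize = 32, overlap = 0.5)
  v <- vectors(f2[[1]])
  expect_lt(abs(mean(v[, , , 1]) - 0.4), 0.1)
  expect_lt(max(abs(v[, , , 2:3])), 0.2)
})

test_that("shifting both inputs by one stride leaves estimates unchanged", {
  g <- speckleVolume(64, seed = 6)
  shift <- c(2, -1, 1)
  B <- circShift(g, shift)
  f1 <- estimateDisplacements(list(g, B), windowSize = 32,
                              overlap = 0.5)[[1]]
  f2 <- estimateDisplacements(list(circShift(g, c(16, 0, 0)),
                                   circShift(B, c(16, 0, 0))),
                              windowSize = 32, overlap = 0.5)[[1]]
  # window grid realigns with the content one stride over
  expect_equal(vectors(f1)[1:2, , , ], vectors(f2)[2:3, , , ],
               tolerance = 1e-10)
})

test_that("masking, shape and sizing errors behave as specified", {
  g <- speckleVolume(48, seed = 7)
  mask <- array(FALSE, dim(g))
  mask[1:20, , ] <- TRUE
  f <- estimateDisplacements(list(g, g), windowSize = 16, overlap = 0.5,
                             mask = mask)[[1]]
  expect_true(all(is.na(peakQuality(f)[5, , ])))  # windows outside mask
  expect_false(any(validVectors(f)[5, , ]))
  expect_true(all(validVectors(f)[1, , ]))         # fully covered column
  expect_error(estimateDisplacements(list(g, g[1:32, , ])), "shape")
  expect_error(estimateDisplacements(list(g, g), windowSize = 64),
               "sizing")
  expect_error(estimateDisplacements(list(g)), "two volumes")
  expect_error(estimateDisplacements(list(g, g), windowSize = 4), ">= 8")
})

test_that("vector magnitudes are bounded by half the window", {
  g <- speckleVolume(48, seed = 8)
  set.seed(8)
  h <- array(stats::rnorm(48^3), c(48, 48, 48))  # unrelated content
  f <- estimateDisplacements(list(g, h), windowSize = 16,
                             overlap = 0.5)[[1]]
  expect_lte(max(abs(vectors(f)), na.rm = TRUE), 8 + 1)
})

test_that("phantom sequences are tracked within 0.2 voxels/frame", {
  ch <- chainFixture()
  ok <- ch$cover >= 0.99
  rms <- vapply(seq_along(ch$fields), function(p) {
    tru <- ch$Uxv * (ch$truth@phaseScale[p + 1] - ch$truth@phaseScale[p])
    est <- vectors(ch$fields[[p]])
    sqrt(mean((est - tru)[rep(ok, 3)]^2))
  }, numeric(1))
  expect_lt(max(rms), 0.2)
})

test_that("low-quality vectors are flagged and median-filled", {
  vec <- array(1, c(3, 3, 3, 3))
  vec[2, 2, 2, ] <- 40
  valid <- array(TRUE, c(3, 3, 3))
  valid[2, 2, 2] <- FALSE
  filled <- xvlung:::fillInvalid(vec, valid, !valid)
  expect_equal(filled[2, 2, 2, ], c(1, 1, 1))
  expect_equal(filled[1, 1, 1, ], c(1, 1, 1))
})
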