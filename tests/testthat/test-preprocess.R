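test_that("mirror symmetry finds the bone axis and flags noise", {
  b0 <- makeBonePhantom(0, seed = 1, gridShape = c(96L, 96L, 48L))
  r0 <- findSymmetryAxis(gridData(b0$volume))
  expect_lte(abs(r0@angle), 0.5)
  expect_gt(r0@symmetryScore, 0.7)
  expect_true(r0@reliable)
  expect_identical(r0@spineEnd, "high")

  b17 <- makeBonePhantom(17, seed = 2, gridShape = c(96L, 96L, 48L))
  r17 <- findSymmetryAxis(gridData(b17$volume))
  expect_lt(abs(r17@angle - (-17)), 1)

  set.seed(3)
  noise <- array(stats::runif(64^3), c(64, 64, 64))
  rn <- findSymmetryAxis(noise)
  expect_false(rn@reliable)
  expect_lt(rn@symmetryScore, 0.5)
  expect_error(findSymmetryAxis(array(1, c(8, 8, 8))), "constant")
})

test_that("orientation correction is idempotent and puts the spine down", {
  b <- makeBonePhantom(17, seed = 4, gridShape = c(96L, 96L, 48L))
  r <- findSymmetryAxis(gridData(b$volume))
  oc <- orientAndCrop(b$volume, r)
  r2 <- findSymmetryAxis(oc)
  expect_lte(abs(r2@angle), 1)
  # largest bone blob (the spine) sits in the bottom (high-y) third
  proj <- apply(gridData(oc), c(1, 2), max)
  bone <- proj >= stats::quantile(proj, 0.97)
  lab <- xvlung:::labelComponents3D(array(bone, c(dim(bone), 1L)))[, , 1]
  pos <- which(lab == 1L, arr.ind = TRUE)
  expect_gt(mean(pos[, 2]) / dim(proj)[2], 2 / 3)

  # already-correct volume passes through with only crop-margin changes
  b0 <- makeBonePhantom(0, seed = 4, gridShape = c(96L, 96L, 48L))
  r0 <- findSymmetryAxis(gridData(b0$volume))
  oc0 <- orientAndCrop(b0$volume, r0)
  expect_lte(abs(findSymmetryAxis(oc0)@angle), 1)
})

test_that("orientation recovery stays within a degree across angles", {
  set.seed(5)
  angles <- stats::runif(8, -60, 60)
  errs <- vapply(seq_along(angles), function(i) {
    b <- makeBonePhantom(angles[i], seed = i,
                         gridShape = c(72L, 72L, 36L))
    abs(findSymmetryAxis(gridData(b$volume))@angle + angles[i])
  }, numeric(1))
  expect_lt(max(errs), 1)
})

test_that("lung segmentation recovers the phantom mask", {
  cfg <- phantomConfig(gridShape = c(96L, 96L, 96L), seed = 6)
  ch <- makeChestPhantom(cfg)
  seg <- segmentLungs(ch$volume)
  dice <- 2 * sum(gridData(seg) & ch$lungMask) /
    (sum(gridData(seg)) + sum(ch$lungMask))
  expect_gte(dice, 0.95)
  # determinism
  expect_identical(gridData(seg), gridData(segmentLungs(ch$volume)))
  # graceful degradation under 5% additive noise
  chN <- makeChestPhantom(cfg, noiseSd = 0.05)
  segN <- segmentLungs(chN$volume)
  diceN <- 2 * sum(gridData(segN) & ch$lungMask) /
    (sum(gridData(segN)) + sum(ch$lungMask))
  expect_gte(diceN, 0.85)
  expect_error(segmentLungs(array(0.5, c(32, 32, 32))), "contrast")
})

test_that("lung volume is the mask volume", {
  m <- array(FALSE, c(20, 20, 20))
  m[1:10, 1:10, 1:10] <- TRUE
  expect_equal(lungVolume(m, voxelSize = 0.1), 1000 * 0.1^3)
  expect_equal(lungVolume(m, voxelSize = 0.2), 1000 * 0.2^3)
  cfg <- phantomConfig(gridShape = c(48L, 48L, 48L), seed = 7)
  mask <- makeLungMask(cfg)
  sc <- makeExpansionScene(cfg, mask)
  expect_identical(lungVolume(mask), sc$truth@params$maskVolume)
  expect_error(lungVolume(array(FALSE, c(4, 4, 4))), "empty")
})

test_that("heart blur is detected from contiguous zero-displacement blobs", {
  nv <- c(10L, 10L, 10L)
  moving <- array(0.5, c(nv, 3))
  fClean <- fieldFromArray(moving)
  qc <- detectHeartBlur(fClean)
  expect_false(qc@heartBlurFlag)
  expect_equal(qc@zeroFraction, 0)

  still <- array(0, c(nv, 3))
  qcAll <- detectHeartBlur(fieldFromArray(still))
  expect_true(qcAll@heartBlurFlag)
  expect_equal(qcAll@zeroFraction, 1)

  # a 10% contiguous blob with a 5% threshold: flagged, centroid inside
  blob <- moving
  blob[1:5, 1:5, 1:4, ] <- 0
  qcB <- detectHeartBlur(fieldFromArray(blob), blobThreshold = 0.05)
  expect_true(qcB@heartBlurFlag)
  expect_equal(qcB@largestBlobFraction, 100 / 1000)
  expect_true(all(qcB@centroid <= c(0.5, 0.5, 0.4)))

  # monotonicity: growing the blob never lowers the zero fraction
  zf <- vapply(2:6, function(r) {
    v <- moving
    v[1:r, 1:r, 1:r, ] <- 0
    detectHeartBlur(fieldFromArray(v))@zeroFraction
  }, numeric(1))
  expect_true(all(diff(zf) >= 0))
  expect_error(detectHeartBlur(fClean, mask = array(FALSE, nv)), "empty")
})

test_that("phantom heart blur survives the displacement synthesis", {
  cfg <- phantomConfig(gridShape = c(64L, 64L, 64L), heartBlur = TRUE,
                       seed = 8, nPhases = 4L)
  mask <- makeLungMask(cfg)
  sc <- makeExpansionScene(cfg, mask)
  sq <- makeSpeckleSequence(sc, makeBreathCurve(cfg), cfg, phases = 1L)
  # sample the true peak displacement on a stride-8 XV grid
  ii <- round(seq(4.5, 64, by = 8))
  u <- sq$truth@displacementBasis[ii, ii, ii, , drop = FALSE]
  mXV <- sc$truth@lungMask[ii, ii, ii]
  f <- fieldFromArray(u)
  qc <- detectHeartBlur(f, mask = mXV, zeroTol = 0.15, blobThreshold = 0.05)
  expect_true(qc@heartBlurFlag)
})
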