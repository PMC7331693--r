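test_that("histogram area is one and the IQR is bin-independent", {
  set.seed(11)
  v <- stats::rnorm(2e4, 0.1, 0.02)
  for (nb in c(20L, 50L, 200L)) {
    h <- expansionHistogram(v, nBins = nb)
    expect_lt(abs(sum(h@density * diff(h@binEdges)) - 1), 1e-9)
    expect_identical(h@iqr, unname(stats::quantile(v, 0.75) -
                                     stats::quantile(v, 0.25)))
  }
  expect_identical(expansionHistogram(rep(0.1, 500))@iqr, 0)
  expect_warning(expansionHistogram(stats::rnorm(50)), "flagged")
  expect_error(expansionHistogram(numeric(0)), "empty")
})

test_that("IQR of a Gaussian matches the normal-quantile closed form", {
  set.seed(12)
  sigma <- 0.015
  n <- 1e5
  v <- stats::rnorm(n, 0.1, sigma)
  h <- expansionHistogram(v)
  # asymptotic variance of the IQR of a normal sample:
  # Var = [p1(1-p1) + p2(1-p2) - 2 p1 (1-p2)] / (n f^2) with p = 1/4, 3/4
  # and equal density f at the two quartiles
  f1 <- stats::dnorm(stats::qnorm(0.25)) / sigma
  se <- sqrt((0.1875 + 0.1875 - 2 * 0.0625) / (n * f1^2))
  expect_lt(abs(h@iqr - 2 * stats::qnorm(0.75) * sigma), 3 * se)
})

test_that("double-Gaussian fit is self-consistent on noise-free densities", {
  p <- c(1.5, 0.05, 0.010, 3, 0.12, 0.015)
  edges <- seq(0, 0.2, length.out = 61)
  mids <- (edges[-1] + edges[-61]) / 2
  dens <- xvlung:::doubleGaussian(mids, p)
  dens <- dens / sum(dens * diff(edges))
  h <- new("ExpansionHistogram", binEdges = edges, density = dens,
           iqr = 0.02, nValues = 10000L, flagged = FALSE)
  fit <- fitDoubleGaussian(h)
  got <- fitParameters(fit)
  scale <- sum(dens * diff(edges)) / sum(xvlung:::doubleGaussian(mids, p) *
                                           diff(edges))
  want <- p * c(scale, 1, 1, scale, 1, 1)
  expect_equal(unname(got), unname(want), tolerance = 0.01)
  expect_gte(rSquared(fit), 0.999)
})

test_that("fitting a single Gaussian yields a negligible second mode", {
  set.seed(13)
  v <- stats::rnorm(1e5, 0.1, 0.015)
  fit <- fitDoubleGaussian(expansionHistogram(v))
  cd <- cdScore(fit)
  sep <- (fit@mu2 - fit@mu1) / fit@mu2
  minorShare <- min(fit@a1, fit@a2) / max(fit@a1, fit@a2)
  expect_true(sep <= 0.02 || minorShare <= 0.01 || as.numeric(cd) == 0)
})

test_that("bimodal mixtures are recovered within 5%", {
  set.seed(14)
  v <- c(stats::rnorm(3e4, 0.05, 0.01), stats::rnorm(7e4, 0.12, 0.01))
  fit <- fitDoubleGaussian(expansionHistogram(v))
  expect_lt(abs(fit@mu1 - 0.05) / 0.05, 0.05)
  expect_lt(abs(fit@mu2 - 0.12) / 0.12, 0.05)
  expect_gt(rSquared(fit), 0.98)
})

test_that("the CD score implements the fractional mode separation", {
  mkFit <- function(mu1, mu2, a1 = 1, a2 = 2, s1 = 0.01, s2 = 0.01)
    new("DoubleGaussianFit", a1 = a1, mu1 = mu1, sigma1 = s1,
        a2 = a2, mu2 = mu2, sigma2 = s2, rSquared = 1, converged = TRUE)
  expect_equal(as.numeric(cdScore(mkFit(0.1, 0.1))), 0)
  expect_equal(as.numeric(cdScore(mkFit(0.05, 0.10))), 0.5)
  # the most clustered example: mu1 = 0.033, mu2 = 0.05 -> 0.34
  expect_equal(as.numeric(cdScore(mkFit(0.033, 0.05))), 0.34)
  expect_error(cdScore(mkFit(-0.2, 0)), "mu2 > 0")
  # negligible minor component => unimodal, CD 0
  weak <- cdScore(mkFit(0.05, 0.10, a1 = 0.001, a2 = 2))
  expect_equal(as.numeric(weak), 0)
  expect_true(attr(weak, "unimodal"))
  # monotone in the lower mode position
  cds <- vapply(seq(0.09, 0.01, by = -0.02), function(m1)
    as.numeric(cdScore(mkFit(m1, 0.10))), numeric(1))
  expect_true(all(diff(cds) > 0))
})

test_that("cohort HD normalises by the littermate-average IQR", {
  withIqr <- function(target, n = 2000, seed = 1) {
    set.seed(seed)
    z <- stats::rnorm(n)
    0.1 + z * (target / unname(diff(stats::quantile(z, c(0.25, 0.75)))))
  }
  recs <- list(
    list(id = "L1", group = "littermate", map = withIqr(0.008, seed = 1)),
    list(id = "L2", group = "littermate", map = withIqr(0.010, seed = 2)),
    list(id = "L3", group = "littermate", map = withIqr(0.012, seed = 3)),
    list(id = "D1", group = "disease",    map = withIqr(0.0178, seed = 4)),
    list(id = "D2", group = "disease",    map = withIqr(0.010, seed = 5)))
  tab <- cohortScores(recs)
  expect_equal(attr(tab, "iqr_L"), 0.010, tolerance = 1e-12)
  # the most heterogeneous example: IQR 0.0178 over IQR_L 0.010 -> 1.78
  expect_equal(tab$hd[tab$id == "D1"], 1.78, tolerance = 1e-9)
  # an animal whose IQR equals IQR_L scores exactly 1
  expect_equal(tab$hd[tab$id == "D2"], 1, tolerance = 1e-9)
  # mean littermate HD is exactly 1 by the algebra of mean-normalisation
  expect_equal(mean(tab$hd[tab$group == "littermate"]), 1,
               tolerance = 1e-12)
  expect_error(cohortScores(recs[4:5]), "littermate")
})

test_that("HD is invariant to a uniform rescaling of expansion", {
  vals <- cohortValues()
  recs <- c(
    lapply(1:3, function(i) list(id = paste0("L", i), group = "littermate",
                                 map = vals$healthy[[i]])),
    list(list(id = "D1", group = "disease", map = vals$heterogeneous[[1]])))
  t1 <- cohortScores(recs)
  recs2 <- lapply(recs, function(r) { r$map <- r$map * 3.7; r })
  t2 <- cohortScores(recs2)
  expect_equal(t1$hd, t2$hd, tolerance = 1e-9)
})

test_that("heart-blur animals carry no CD score", {
  set.seed(15)
  recs <- list(
    list(id = "L1", group = "littermate", map = stats::rnorm(2000, 0.1, 0.01)),
    list(id = "D1", group = "disease", map = stats::rnorm(2000, 0.1, 0.02),
         heartBlur = TRUE))
  tab <- cohortScores(recs)
  expect_true(is.na(tab$cd[tab$id == "D1"]))
  expect_true(tab$heart_blur_flag[tab$id == "D1"])
  expect_false(is.na(tab$hd[tab$id == "D1"]))
})
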