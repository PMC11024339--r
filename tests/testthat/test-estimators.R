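test_that("Wald ratios follow the first-order formulas", {
  h <- new("HarmonizedSet", exposureId = "E", outcomeId = "O",
           outcomeType = "continuous",
           pairs = data.frame(rsid = c("a", "b"), beta_exp = c(0.5, -0.5),
                              se_exp = 0.01, beta_out = 0.1, se_out = 0.05,
                              eaf_exp = 0.5, eaf_out = 0.5,
                              action = "kept_as_is"),
           dropLog = data.frame(rsid = character(), reason = character()))
  r <- waldRatios(h)
  expect_equal(r$ratio, c(0.2, -0.2))
  expect_equal(r$se, c(0.1, 0.1))
})

test_that("zero exposure effects are dropped from the ratio set", {
  h <- randomHarmonized(5, seed = 41)
  h@pairs$beta_exp[2] <- 0
  expect_warning(r <- waldRatios(h), "beta_exp = 0")
  expect_identical(nrow(r), 4L)
})

test_that("ratio weights equal an element-wise recomputation", {
  h <- randomHarmonized(100, seed = 42)
  r <- waldRatios(h)
  p <- harmonizedPairs(h)
  expect_equal(r$w, 1 / (p$se_out / abs(p$beta_exp))^2, tolerance = 1e-12)
})

test_that("IVW reproduces the hand-checked two-SNP weighted mean", {
  h <- harmonizedFromRatios(c(0.5, 0.3), c(0.1, 0.1))
  out <- mrIvw(h)
  expect_equal(mrBeta(out$result), 0.4)
  expect_equal(mrSe(out$result), sqrt(1 / 200))
  expect_identical(out$result@ivwModel, "fixed")
})

test_that("identical ratios give zero heterogeneity and the fixed model", {
  h <- harmonizedFromRatios(rep(0.25, 4), c(0.1, 0.2, 0.1, 0.3))
  out <- mrIvw(h, model = "auto")
  expect_equal(out$diagnostics@cochranQ, 0)
  expect_equal(out$diagnostics@qPval, 1)
  expect_identical(out$result@ivwModel, "fixed")
})

test_that("IVW and MR-Egger match brute-force WLS on 200 random instances", {
  for (s in 1:200) {
    k <- 3 + (s %% 28)
    h <- randomHarmonized(k, seed = 1000 + s)
    p <- harmonizedPairs(h)
    w <- 1 / p$se_out^2
    ivw <- mrIvw(h, model = "fixed")$result
    o <- oracleWlsOrigin(p$beta_exp, p$beta_out, w)
    expect_equal(mrBeta(ivw), o$beta, tolerance = 1e-10)
    expect_equal(mrSe(ivw), o$se, tolerance = 1e-10)
    eg <- mrEgger(h)
    oe <- oracleEgger(p$beta_exp, p$beta_out, w)
    expect_equal(mrBeta(eg$result), oe$slope, tolerance = 1e-10)
    expect_equal(mrSe(eg$result), oe$seSlope, tolerance = 1e-10)
    expect_equal(eg$diagnostics@eggerIntercept, oe$intercept,
                 tolerance = 1e-10)
    expect_equal(eg$diagnostics@interceptSe, oe$seIntercept,
                 tolerance = 1e-10)
  }
})

test_that("an exact linear fit is recovered without residual inflation", {
  x <- c(0.1, 0.2, 0.3)
  h <- harmonizedFromRatios(rep(0, 3), rep(0.1, 3))
  h@pairs$beta_exp <- x
  h@pairs$beta_out <- 0.1 + 0.6 * x
  out <- suppressWarnings(mrEgger(h))  # R warns on the perfect fit itself
  expect_equal(mrBeta(out$result), 0.6, tolerance = 1e-9)
  expect_equal(out$diagnostics@eggerIntercept, 0.1, tolerance = 1e-9)
})

test_that("the Egger intercept is calibrated under no pleiotropy", {
  hits <- 0L
  n <- 500
  for (s in seq_len(n)) {
    cfg <- simulationConfig(nSnp = 30, nInstrument = 30, theta = 0.3,
                            fracPalindromic = 0, fracStrandFlipped = 0,
                            seed = 5000 + s)
    h <- harmonizeSim(simulatePair(cfg))
    d <- mrEgger(h)$diagnostics
    if (abs(d@eggerIntercept) < 3 * d@interceptSe) hits <- hits + 1L
  }
  expect_gte(hits / n, 0.98)
})

test_that("the weighted median interpolates the cumulative weight midpoint", {
  h <- harmonizedFromRatios(c(0.2, 0.4, 0.6), rep(0.1, 3))
  wm <- mrWeightedMedian(h, nBoot = 50, seed = 1)
  expect_equal(mrBeta(wm), 0.4)
  for (s in 1:50) {
    k <- 3 + (s %% 23)
    h <- randomHarmonized(k, seed = 2000 + s)
    r <- waldRatios(h)
    got <- mrBeta(mrWeightedMedian(h, nBoot = 10, seed = 1))
    expect_equal(got, oracleWeightedMedian(r$ratio, r$w), tolerance = 1e-12)
  }
})

test_that("with many equal weights the weighted median nears the median", {
  set.seed(7)
  ratio <- rnorm(401, 0.3, 0.05)
  h <- harmonizedFromRatios(ratio, rep(0.1, 401))
  wm <- mrBeta(mrWeightedMedian(h, nBoot = 10, seed = 1))
  expect_equal(wm, median(ratio), tolerance = 0.005)
})

test_that("penalization is inactive for concordant ratios", {
  h <- harmonizedFromRatios(c(0.29, 0.3, 0.31, 0.3), rep(0.2, 4))
  wm <- mrBeta(mrWeightedMedian(h, nBoot = 10, seed = 1))
  pwm <- mrBeta(mrPenalizedWeightedMedian(h, nBoot = 10, seed = 1))
  expect_equal(pwm, wm)
  expect_error(mrPenalizedWeightedMedian(h, penaltyK = 0, nBoot = 10),
               class = "degenerateWeights")
})

test_that("penalization beats IVW given one gross outlier ratio", {
  wins <- 0L
  n <- 200
  theta <- 0.3
  for (s in seq_len(n)) {
    set.seed(6000 + s)
    ratio <- c(rnorm(20, theta, 0.15), 3)   # 20 concordant, 1 gross
    h <- harmonizedFromRatios(ratio, rep(0.15, 21))
    ivw <- mrBeta(mrIvw(h, model = "fixed")$result)
    pwm <- mrBeta(mrPenalizedWeightedMedian(h, nBoot = 2, seed = 1))
    if (abs(pwm - theta) < abs(ivw - theta)) wins <- wins + 1L
  }
  expect_gte(wins / n, 0.95)
})

test_that("profile likelihood agrees with a fine grid search", {
  h <- randomHarmonized(12, seed = 51, theta = 0.25)
  ml <- mrBeta(mrMaxLikelihood(h))
  p <- harmonizedPairs(h)
  L <- function(theta) {
    vapply(theta, function(t)
      sum((p$beta_out - t * p$beta_exp)^2 /
            (p$se_out^2 + t^2 * p$se_exp^2)), 0)
  }
  coarse <- seq(ml - 0.5, ml + 0.5, by = 1e-3)
  c0 <- coarse[which.min(L(coarse))]
  fine <- seq(c0 - 2e-3, c0 + 2e-3, by = 1e-6)
  expect_equal(ml, fine[which.min(L(fine))], tolerance = 1e-5)
})

test_that("profile likelihood collapses to IVW when exposure noise vanishes", {
  h <- randomHarmonized(15, seed = 52, theta = 0.3)
  h@pairs$se_exp <- 1e-8
  ml <- mrMaxLikelihood(h)
  ivw <- mrIvw(h, model = "fixed")$result
  expect_equal(mrBeta(ml), mrBeta(ivw), tolerance = 1e-6)
  expect_equal(mrSe(ml), mrSe(ivw), tolerance = 1e-4)
})

test_that("odds-ratio reporting exponentiates monotonically", {
  r <- new("MrResult", method = "ivw", nSnp = 5L, beta = 0, se = 0.1,
           ciLow = -0.196, ciHigh = 0.196, pval = 1, effectScale = "beta",
           ivwModel = "fixed")
  or <- toOddsRatio(r)
  expect_equal(mrBeta(or), 1)
  expect_identical(or@effectScale, "or")
  r2 <- initialize(r, beta = log(2), ciLow = log(2) - 0.1,
                   ciHigh = log(2) + 0.1, pval = 0.01)
  or2 <- toOddsRatio(r2)
  expect_equal(mrBeta(or2), 2)
  expect_true(or2@ciLow <= mrBeta(or2) && mrBeta(or2) <= or2@ciHigh)
  expect_equal(or2@pval, 0.01)
  expect_error(toOddsRatio(r, outcomeType = "continuous"),
               class = "contractViolation")
})

test_that("estimates are equivariant to rescaling the exposure", {
  h <- randomHarmonized(12, seed = 53, theta = 0.4)
  c0 <- 3.7
  h2 <- h
  h2@pairs$beta_exp <- h@pairs$beta_exp * c0
  h2@pairs$se_exp <- h@pairs$se_exp * c0
  expect_equal(mrBeta(mrIvw(h2)$result), mrBeta(mrIvw(h)$result) / c0,
               tolerance = 1e-10)
  expect_equal(mrBeta(mrEgger(h2)$result), mrBeta(mrEgger(h)$result) / c0,
               tolerance = 1e-10)
  expect_equal(mrBeta(mrWeightedMedian(h2, nBoot = 20, seed = 2)),
               mrBeta(mrWeightedMedian(h, nBoot = 20, seed = 2)) / c0,
               tolerance = 1e-10)
  expect_equal(mrBeta(mrPenalizedWeightedMedian(h2, nBoot = 20, seed = 2)),
               mrBeta(mrPenalizedWeightedMedian(h, nBoot = 20, seed = 2)) / c0,
               tolerance = 1e-10)
  expect_equal(mrBeta(mrMaxLikelihood(h2)),
               mrBeta(mrMaxLikelihood(h)) / c0, tolerance = 1e-6)
})

test_that("method minimum instrument counts are enforced", {
  h2 <- randomHarmonized(2, seed = 54)
  expect_error(mrEgger(h2), class = "insufficientInstruments")
  expect_error(mrWeightedMedian(h2), class = "insufficientInstruments")
  h1 <- randomHarmonized(1, seed = 55)
  expect_error(mrIvw(h1), class = "insufficientInstruments")
  expect_error(mrMaxLikelihood(h1), class = "insufficientInstruments")
})
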