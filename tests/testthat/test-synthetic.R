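test_that("pullback generation is deterministic under a fixed seed", {
  cfg <- smallConfig()
  a <- generatePullback(cfg, seed = 42)
  b <- generatePullback(cfg, seed = 42)
  expect_identical(octStack(a$pullback), octStack(b$pullback))
  expect_identical(nirfRaw(a$pullback), nirfRaw(b$pullback))
  expect_identical(sourceMap(a$truth), sourceMap(b$truth))
  c <- generatePullback(cfg, seed = 43)
  expect_false(identical(nirfRaw(a$pullback), nirfRaw(c$pullback)))
})

test_that("raw NIRF follows the distance-decay law exactly when noiseless", {
  cfg <- cleanConfig(decayMu = 1.5)
  sim <- generatePullback(cfg, seed = 7)
  d <- lumenRadii(sim$truth) - cfg@catheterRadius
  cTrue <- exp(-cfg@decayMu * d)  # pointwise oracle for the decay law
  expect_lt(max(abs(nirfRaw(sim$pullback) - sourceMap(sim$truth) * cTrue)),
            1e-12)
  # dividing raw by c(d) recovers the source to <= 1e-9 relative error
  rel <- abs(nirfRaw(sim$pullback) / cTrue - sourceMap(sim$truth)) /
    pmax(sourceMap(sim$truth), 1e-12)
  expect_lt(max(rel), 1e-9)
})

test_that("zero decay and zero noise reproduce the source map identically", {
  sim <- generatePullback(cleanConfig(decayMu = 0), seed = 3)
  expect_equal(nirfRaw(sim$pullback), sourceMap(sim$truth), tolerance = 1e-14)
})

test_that("serial pair honours the configured effect model", {
  # a = 0, b = 0, sd = 0: follow-up source identical to baseline
  p0 <- generateSerialPair(cleanConfig(effectA = 0, effectB = 0,
                                       effectSD = 0), seed = 5)
  expect_equal(sourceMap(p0$day7$truth), sourceMap(p0$day0$truth))

  # b = -0.5, a = 0, sd = 0: per-frame delta / baseline = -0.5 on the plaque
  p1 <- generateSerialPair(cleanConfig(effectA = 0, effectB = -0.5,
                                       effectSD = 0), seed = 5)
  expect_equal(p1$effect$delta / p1$effect$baseline,
               rep(-0.5, nrow(p1$effect)))

  # follow-up fluorescence is never negative even for crushing effects
  p2 <- generateSerialPair(smallConfig(effectA = -50, effectB = -2,
                                       effectSD = 1), seed = 5)
  expect_true(all(sourceMap(p2$day7$truth) >= 0))
})

test_that("a longitudinal shift moves the emitted landmarks by that amount", {
  p <- generateSerialPair(cleanConfig(serialShift = 10L,
                                      landmarkFrames = c(5L, 30L, 45L)),
                          seed = 2)
  expect_identical(p$day7$truth@landmarkFrames,
                   p$day0$truth@landmarkFrames + 10L)
})

test_that("serial effect parameters are recoverable from the truth", {
  cfg <- smallConfig(nFrames = 150L, plaqueRange = c(25L, 135L),
                     normalRanges = list(c(0L, 20L), c(140L, 150L)),
                     landmarkFrames = c(10L, 75L, 145L),
                     effectA = 1, effectB = -0.5, effectSD = 0.8)
  p <- generateSerialPair(cfg, seed = 21)
  fit <- summary(lm(delta ~ baseline, data = p$effect))$coefficients
  expect_lt(abs(fit["baseline", "Estimate"] - (-0.5)),
            3 * fit["baseline", "Std. Error"])
  expect_lt(abs(fit["(Intercept)", "Estimate"] - 1),
            3 * fit["(Intercept)", "Std. Error"])
})

test_that("stained-image generator renders the exact positive pixel count", {
  s0 <- generateStainedImage("IHC", positiveFraction = 0, seed = 1)
  expect_identical(sum(s0$truthMask), 0L)
  s1 <- generateStainedImage("ORO", positiveFraction = 1, seed = 1)
  expect_identical(s1$truthMask, s1$tissueMask)
  s3 <- generateStainedImage("PSR_brightfield", positiveFraction = 0.3,
                             seed = 1)
  expect_identical(sum(s3$truthMask),
                   as.integer(round(0.3 * sum(s3$tissueMask))))
  expect_error(generateStainedImage("IHC", positiveFraction = 1.2),
               "positiveFraction")
})

test_that("PK series follows the biexponential half-life definition", {
  # A2 = 0, noiseless, thalf1 = 10: intensity at t = 10 is A1 / 2
  pk <- generatePKSeries(6, 10, 0, 1, timepoints = c(0, 10), noiseSD = 0)
  expect_equal(pk$intensity, c(6, 3))
  # t = 0 intercept is A1 + A2
  pk2 <- generatePKSeries(8, 2, 2, 30, timepoints = 0, noiseSD = 0)
  expect_equal(pk2$intensity, 10)
  # fixed-seed reproducibility
  a <- generatePKSeries(8, 2, 2, 30, noiseSD = 0.5, seed = 9)
  b <- generatePKSeries(8, 2, 2, 30, noiseSD = 0.5, seed = 9)
  expect_identical(a, b)
  expect_error(generatePKSeries(8, -1, 2, 30), "half-lives")
})

test_that("invalid simulation configurations are rejected", {
  expect_error(smallConfig(plaqueRange = c(15L, 55L)), "disjoint")
  expect_error(smallConfig(normalRanges = list(c(0L, 4L))), "5 frames")
  expect_error(smallConfig(noiseSD = -0.1), "noise")
  expect_error(smallConfig(plaqueRange = c(40L, 70L)), "within")
})
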