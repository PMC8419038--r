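mkScene <- function(img, plaque, normal, lm = c(0, ncol(img) - 1)) {
  new("FRIScene", image = img, mmPerPixel = 0.1, plaqueMask = plaque,
      normalMask = normal, landmarksPx = lm)
}

test_that("ex vivo mean pTBR is the plaque/normal ROI intensity ratio", {
  img <- matrix(2, 10, 20)
  plaque <- matrix(FALSE, 10, 20); plaque[, 1:8] <- TRUE
  normal <- matrix(FALSE, 10, 20); normal[, 15:20] <- TRUE
  img[plaque] <- 8
  sc <- mkScene(img, plaque, normal)
  expect_equal(friMeanPTBR(sc), 4)
  # invariance to global intensity scaling
  expect_equal(friMeanPTBR(mkScene(img * 7.3, plaque, normal)), 4)
  # plaque ROI equal to the normal ROI intensity -> ratio 1
  expect_equal(friMeanPTBR(mkScene(matrix(5, 10, 20), plaque, normal)), 1)
  expect_error(friMeanPTBR(mkScene(img, plaque, matrix(FALSE, 10, 20))),
               "empty")
})

test_that("paired profiles sample a shared 0.5 mm grid between landmarks", {
  map2d <- matrix(rexp(40 * 16), 40, 16)
  img <- matrix(1, 8, 120)
  sc <- new("FRIScene", image = img, mmPerPixel = 0.1,
            plaqueMask = matrix(FALSE, 8, 120),
            normalMask = matrix(FALSE, 8, 120), landmarksPx = c(0, 100))
  # landmark-identical axes, 10 mm overlap -> 21 positions at 0.5 mm
  lp <- data.frame(frame = c(0, 50), px = c(0, 100))  # framePitch 0.2 mm
  prof <- samplePairedProfiles(map2d, 0.2, sc, lp)
  expect_identical(nrow(prof), 21L)
  expect_equal(prof$position_mm, seq(0, 10, by = 0.5))
  # in vivo samples are the frame maxima of the nearest frame
  expect_equal(prof$invivo[1], max(map2d[1, ]))
  # interval larger than the overlap -> a single position
  prof1 <- samplePairedProfiles(map2d, 0.2, sc, lp, interval_mm = 20)
  expect_identical(nrow(prof1), 1L)
  expect_error(samplePairedProfiles(map2d, 0.2, sc, lp[1, , drop = FALSE]),
               "2 matched")
})

test_that("in vivo and ex vivo profiles from shared truth correlate strongly", {
  cfg <- cleanConfig(plaqueAmpSD = 1.2)
  sim <- generatePullback(cfg, seed = 9)
  scene <- generateFRIScene(sim$truth, framePitch = cfg@framePitch)
  ct <- segmentLumen(sim$pullback)
  comp <- compensate(nirfRaw(sim$pullback), contourToDistances(ct),
                     defaultCurve())
  res <- quantifyPTBR(comp, annotationFromTruth(sim$truth))
  lp <- data.frame(frame = sim$truth@landmarkFrames, px = scene@landmarksPx)
  prof <- samplePairedProfiles(ptbrMap(res), cfg@framePitch, scene, lp)
  g <- gatedCorrelation(prof$invivo, prof$exvivo)
  expect_gte(g$r, 0.95)
  # and the ex vivo TBR itself matches the configured amplitude ratio
  expect_lt(abs(friMeanPTBR(scene) - 9) / 9, 0.15)
})

test_that("DAB deconvolution recovers the rendered antibody intensity", {
  s <- generateStainedImage("IHC", positiveFraction = 0.3,
                            positiveIntensity = 0.5, seed = 2)
  dm <- dabIntensityMap(s$rgb)
  expect_lt(max(abs(mean(dm$intensity[s$truthMask]) - 0.5)), 0.05)
  expect_true(all(abs(dm$intensity[s$truthMask] - 0.5) < 0.2))
  # counter-stain-only tissue carries (almost) no antibody signal
  bgOnly <- s$tissueMask & !s$truthMask
  expect_lt(stats::quantile(dm$intensity[bgOnly], 0.99), 0.05)
  # pure white slide -> empty tissue mask
  white <- array(1, dim = c(8, 8, 3))
  expect_false(any(dabIntensityMap(white)$tissueMask))
  expect_error(dabIntensityMap(matrix(1, 4, 4)), "RGB")
})

test_that("positive ratio sums strictly-suprathreshold intensities", {
  tissue <- matrix(TRUE, 100, 100)
  # all intensities below threshold -> ratio 0
  expect_equal(quantifyPositiveRatio(matrix(0.05, 100, 100), tissue)$positiveRatio, 0)
  # half of 10,000 px at 0.5, rest 0 -> sum/count = 0.25
  m <- matrix(0, 100, 100); m[, 1:50] <- 0.5
  q <- quantifyPositiveRatio(m, tissue)
  expect_equal(q$positiveRatio, 0.25)
  expect_identical(q$nPositive, 5000L)
  # exactly 0.1 is excluded: the rule is strictly greater-than
  m2 <- matrix(0.1, 100, 100)
  expect_equal(quantifyPositiveRatio(m2, tissue)$positiveRatio, 0)
  expect_error(quantifyPositiveRatio(m, matrix(FALSE, 100, 100)), "empty")
})

test_that("positive ratio is monotone in intensity and threshold", {
  set.seed(4)
  m <- matrix(runif(400), 20, 20)
  tissue <- matrix(TRUE, 20, 20)
  r1 <- quantifyPositiveRatio(m, tissue)$positiveRatio
  r2 <- quantifyPositiveRatio(pmin(m + 0.1, 1), tissue)$positiveRatio
  expect_gte(r2, r1)
  r3 <- quantifyPositiveRatio(m, tissue, threshold = 0.5)$positiveRatio
  expect_lte(r3, r1)
})

test_that("stain segmentation recovers the rendered positive fraction", {
  for (stain in c("ORO", "PSR_brightfield", "PSR_polarized")) {
    s <- generateStainedImage(stain, positiveFraction = 0.3, seed = 6)
    q <- segmentStainFraction(s$rgb, stain)
    expect_lt(abs(q$positiveRatio - 0.3), 0.01)
  }
  sFull <- generateStainedImage("ORO", positiveFraction = 1, seed = 7)
  expect_gte(segmentStainFraction(sFull$rgb, "ORO")$positiveRatio, 0.99)
  blank <- array(1, dim = c(16, 16, 3))
  expect_warning(q0 <- segmentStainFraction(blank, "ORO"), "no tissue")
  expect_equal(q0$positiveRatio, 0)
})
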