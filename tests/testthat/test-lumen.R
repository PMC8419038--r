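# Render one polar frame with a wall at the given per-A-line radii (mm),
# independent of the pullback generator.
renderFrame <- function(radii, nD = 120L, pitch = 0.01, catheter = 0.45,
                        noiseSD = 0) {
  nA <- length(radii)
  idx <- round((radii - catheter) / pitch)
  k <- matrix(seq_len(nD) - 1L, nA, nD, byrow = TRUE)
  rel <- (k - idx) * pitch
  fr <- 0.05 + 0.85 * exp(-pmax(rel, 0) / 0.15) * (rel >= 0)
  if (noiseSD > 0) fr <- fr + rnorm(length(fr), 0, noiseSD)
  pmin(pmax(fr, 0), 1)
}

test_that("a circular lumen is segmented to within one depth pixel", {
  radii <- rep(1.5, 128)
  ct <- segmentLumenFrame(renderFrame(radii), pixelPitch = 0.01,
                          catheterRadius = 0.45)
  expect_lte(mean(abs(lumenRadii(ct) - 1.5)) / 0.01, 1)
})

test_that("an elliptical lumen is segmented to within two pixels at SNR >= 10", {
  theta <- 2 * pi * (0:127) / 128
  # 1.2 x 1.8 mm axes -> semi-axes 0.6 and 0.9 mm
  radii <- (0.9 * 0.6) / sqrt((0.6 * cos(theta))^2 + (0.9 * sin(theta))^2)
  pitch <- 0.01
  truth <- 0.45 + round((radii - 0.45) / pitch) * pitch  # on-grid truth
  set.seed(8)
  fr <- renderFrame(truth, noiseSD = 0.085)  # wall amplitude 0.85 -> SNR 10
  ct <- segmentLumenFrame(fr, pixelPitch = pitch, catheterRadius = 0.45)
  expect_lte(max(abs(lumenRadii(ct) - truth)) / pitch, 2)
})

test_that("segmentation is equivariant under circular A-line shifts", {
  sim <- generatePullback(cleanConfig(), seed = 12)
  fr <- octStack(sim$pullback)[20, , ]
  ct <- segmentLumenFrame(fr, 0.01, 0.45)
  shift <- 37L
  frS <- fr[c((shift + 1):nrow(fr), 1:shift), ]
  ctS <- segmentLumenFrame(frS, 0.01, 0.45)
  r <- as.vector(lumenRadii(ct))
  expect_equal(as.vector(lumenRadii(ctS)),
               r[c((shift + 1):length(r), 1:shift)], tolerance = 1e-12)
})

test_that("segmentation is invariant to positive intensity rescaling", {
  sim <- generatePullback(smallConfig(), seed = 13)
  fr <- octStack(sim$pullback)[10, , ]
  ct1 <- segmentLumenFrame(fr, 0.01, 0.45)
  ct2 <- segmentLumenFrame(fr * 3.7, 0.01, 0.45)
  expect_identical(lumenRadii(ct1), lumenRadii(ct2))
})

test_that("median radius error over 100 noiseless generated frames is <= 1 px", {
  cfg <- cleanConfig(nFrames = 100L, plaqueRange = c(30L, 70L),
                     normalRanges = list(c(0L, 20L), c(80L, 100L)),
                     landmarkFrames = c(5L, 50L, 95L))
  sim <- generatePullback(cfg, seed = 31)
  ct <- segmentLumen(sim$pullback)
  err <- abs(lumenRadii(ct) - lumenRadii(sim$truth)) / cfg@pixelPitch
  expect_lte(median(err), 1)
})

test_that("frames without a detectable wall raise a segmentation failure", {
  expect_error(segmentLumenFrame(matrix(0, 64, 100), 0.01, 0.45),
               "segmentation failed")
  # wall on fewer than half the A-lines
  fr <- renderFrame(rep(1.5, 64))
  fr[1:40, ] <- 0.05
  expect_error(segmentLumenFrame(fr, 0.01, 0.45), "segmentation failed")
})

test_that("guidewire-shadow A-lines are flagged and filled by interpolation", {
  cfg <- cleanConfig(guidewireAlines = 12L, lumenEccentricity = 0,
                     lumenDrift = 0)
  sim <- generatePullback(cfg, seed = 4)
  ct <- segmentLumenFrame(octStack(sim$pullback)[30, , ], cfg@pixelPitch,
                          cfg@catheterRadius)
  expect_false(all(validALines(ct)))
  err <- abs(lumenRadii(ct) - lumenRadii(sim$truth)[30, ]) / cfg@pixelPitch
  expect_lte(max(err), 1)  # circular fill recovers the round lumen
})

test_that("contour distances are radius minus catheter radius, never negative", {
  ct <- new("LumenContour", radii = matrix(c(1.5, 0.4), 1),
            valid = matrix(c(TRUE, TRUE), 1), catheterRadius = 0.4,
            frameIndex = 0L)
  expect_equal(as.vector(contourToDistances(ct)), c(1.1, 0))
  # vector input matches the scalar oracle elementwise
  radii <- seq(0.5, 2, length.out = 32)
  ctv <- new("LumenContour", radii = matrix(radii, 1),
             valid = matrix(rep(TRUE, 32), 1), catheterRadius = 0.45,
             frameIndex = 0L)
  expect_equal(as.vector(contourToDistances(ctv)),
               vapply(radii, function(r) r - 0.45, numeric(1)))
  bad <- new("LumenContour", radii = matrix(0.3, 1),
             valid = matrix(FALSE, 1), catheterRadius = 0.45,
             frameIndex = 0L)
  expect_error(contourToDistances(bad), "inconsistent geometry")
})
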