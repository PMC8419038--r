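test_that("exponential curve fit recovers the calibration decay rate", {
  d <- seq(0, 2.5, by = 0.25)
  cal <- data.frame(distance_mm = d, intensity = 12 * exp(-1.5 * d))
  cur <- fitCompensationCurve(cal, "exponential")
  expect_lt(abs(cur@mu - 1.5) / 1.5, 0.01)
  expect_equal(evalCompensation(cur, cur@dRef), 1,
               ignore_attr = TRUE)  # c(dRef) = 1
})

test_that("constant calibration intensities give the identity curve", {
  cal <- data.frame(distance_mm = c(0, 1, 2), intensity = c(4, 4, 4))
  cur <- fitCompensationCurve(cal)
  expect_equal(cur@mu, 0)
  expect_equal(as.vector(evalCompensation(cur, c(0, 0.5, 2))), c(1, 1, 1))
})

test_that("degenerate or rising calibrations are rejected or projected", {
  expect_error(fitCompensationCurve(
    data.frame(distance_mm = c(0, 1), intensity = c(2, 1))), "3 distinct")
  expect_error(fitCompensationCurve(
    data.frame(distance_mm = 0:3, intensity = c(1, 2, -1, 1))), "> 0")
  expect_warning(fitCompensationCurve(
    data.frame(distance_mm = 0:3, intensity = c(1, 2, 4, 8))), "increase")
  expect_warning(
    cur <- fitCompensationCurve(
      data.frame(distance_mm = 0:3, intensity = c(4, 2, 3, 1)), "tabulated"),
    "monotone")
  expect_true(all(diff(cur@values) <= 1e-9))
})

test_that("tabulated curves interpolate the normalised calibration", {
  d <- c(0, 0.5, 1, 2)
  cal <- data.frame(distance_mm = d, intensity = c(10, 6, 4, 2))
  cur <- fitCompensationCurve(cal, "tabulated")
  expect_equal(as.vector(evalCompensation(cur, d)), c(10, 6, 4, 2) / 10)
  expect_equal(as.vector(evalCompensation(cur, 0.75)), (0.6 + 0.4) / 2)
})

test_that("compensation divides by c(d) and inverts a constructed decay", {
  cur <- defaultCurve()
  d <- matrix(runif(60, 0, 2.5), 6, 10)
  raw <- 7 * exp(-1.5 * d)  # source 7 everywhere under the true law
  comp <- compensate(raw, d, cur)
  expect_lt(max(abs(comp - 7)), 1e-9)

  # identity curve leaves the input unchanged; zeros stay zero
  id <- compensationCurve(mu = 0, range = c(0, 3))
  raw2 <- matrix(rexp(24), 4, 6); raw2[2, 3] <- 0
  expect_equal(compensate(raw2, matrix(1, 4, 6), id), raw2,
               ignore_attr = TRUE)
  expect_identical(compensate(raw2, matrix(1, 4, 6), id)[2, 3], 0)
  expect_error(compensate(raw2, matrix(1, 3, 6), id), "shapes")
})

test_that("compensation is linear and monotone in distance", {
  cur <- defaultCurve()
  d <- matrix(runif(40, 0, 2.5), 4, 10)
  raw <- matrix(rexp(40), 4, 10)
  expect_equal(compensate(3 * raw, d, cur), 3 * compensate(raw, d, cur),
               ignore_attr = TRUE)
  # amplification factor 1/c(d) never decreases with distance
  dd <- seq(0, 3, by = 0.1)
  amp <- 1 / as.vector(evalCompensation(cur, dd))
  expect_true(all(diff(amp) >= 0))
  tab <- fitCompensationCurve(
    data.frame(distance_mm = c(0, 1, 2, 3), intensity = c(8, 4, 3, 2.5)),
    "tabulated")
  ampT <- 1 / as.vector(evalCompensation(tab, dd))
  expect_true(all(diff(ampT) >= -1e-12))
})

test_that("out-of-range distances are clamped with a warning summary", {
  cur <- compensationCurve(mu = 1, range = c(0, 1))
  raw <- matrix(1, 2, 2)
  d <- matrix(c(0.5, 1.5, 2, 0.2), 2, 2)
  expect_warning(comp <- compensate(raw, d, cur), "clamped")
  expect_identical(attr(comp, "nClamped"), 2L)
  expect_equal(comp[cbind(c(1, 2), c(2, 1))],
               rep(1 / exp(-1), 2))  # both clamped to d = 1
})

test_that("round trip: applying c then compensating is the identity", {
  for (cur in list(defaultCurve(),
                   fitCompensationCurve(data.frame(
                     distance_mm = c(0, 0.6, 1.4, 2.8),
                     intensity = c(9, 5, 3, 1)), "tabulated"))) {
    d <- matrix(runif(50, 0.05, 2.5), 5, 10)
    x <- matrix(rexp(50) + 0.1, 5, 10)
    attenuated <- x * evalCompensation(cur, d)
    expect_equal(compensate(attenuated, d, cur), x, ignore_attr = TRUE,
                 tolerance = 1e-12)
  }
})
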