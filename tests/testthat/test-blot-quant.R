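test_that("standard curve fitting recovers constructed lines", {
  amounts <- c(5, 20, 50, 80)
  sc <- fitStandardCurve(data.frame(amount = amounts,
                                    intensity = 5 * amounts + 2))
  expect_equal(sc@slope, 5)
  expect_equal(sc@intercept, 2)
  expect_equal(sc@rSquared, 1)
  # hand least squares on {1,2,3} -> {3,5,7}
  sc2 <- fitStandardCurve(data.frame(amount = 1:3, intensity = c(3, 5, 7)))
  expect_equal(sc2@slope, 2)
  expect_equal(sc2@intercept, 1)
  expect_error(fitStandardCurve(data.frame(amount = c(1, 2),
                                           intensity = c(3, 5))),
               "insufficient standards")
  expect_error(fitStandardCurve(data.frame(amount = c(1, 2, 3),
                                           intensity = c(7, 5, 3))),
               "not positive")
})

test_that("noisy standard curves recover the line within 2 standard errors", {
  set.seed(51)
  amounts <- rep(c(5, 20, 50, 80), each = 3)
  intensity <- (5 * amounts + 2) * rlnorm(length(amounts), 0, 0.02)
  sc <- fitStandardCurve(data.frame(amount = amounts, intensity = intensity))
  fit <- lm(intensity ~ amounts)
  se <- coef(summary(fit))[, "Std. Error"]
  expect_lt(abs(sc@slope - 5), 2 * se[2])
  expect_lt(abs(sc@intercept - 2), 2 * se[1])
})

test_that("interpolation inverts the fitted line on its range", {
  amounts <- c(5, 20, 50, 80)
  sc <- fitStandardCurve(data.frame(amount = amounts,
                                    intensity = 5 * amounts + 2))
  expect_equal(as.numeric(interpolateAmount(sc, 27)), 5)
  # intensity equal to the intercept maps to amount 0 (flagged extrapolation)
  expect_equal(as.numeric(suppressWarnings(
    interpolateAmount(sc, sc@intercept))), 0)
  # round trip across the standard range
  probe <- seq(5, 80, by = 5)
  expect_equal(as.numeric(interpolateAmount(sc, 5 * probe + 2)), probe)
  expect_warning(v <- interpolateAmount(sc, 1000), "extrapolating")
  expect_true(attr(v, "extrapolated"))
  z <- suppressWarnings(interpolateAmount(sc, 0))
  expect_equal(as.numeric(z), 0)
  expect_true(attr(z, "clipped"))
})

test_that("molecules per cell follows Avogadro bookkeeping", {
  expect_equal(moleculesPerCell(0, 158000, 1, 1e6), 0)
  expect_equal(moleculesPerCell(1, 158000, 1, 1e6),
               1e-9 / 158000 * 6.02214076e23 / 1e6)
  # ~3.81e3 molecules/cell for 1 ng of a 158 kDa protein over 1e6 cells
  expect_equal(round(moleculesPerCell(1, 158000, 1, 1e6)), 3811)
  expect_equal(moleculesPerCell(1, 158000, 1, 5e5),
               2 * moleculesPerCell(1, 158000, 1, 1e6))
  expect_error(moleculesPerCell(1, 158000, 1, 0), "zero cells")
  expect_error(moleculesPerCell(1, 0, 1, 1e6), "molarMass")
  expect_error(moleculesPerCell(1, 158000, 0, 1e6), "lysateFraction")
})

test_that("synthetic blots round-trip through quantifyBlot", {
  g0 <- genBlotData(syntheticConfig(seed = 8, noiseCv = 0))
  q0 <- quantifyBlot(g0$standards, g0$samples, molarMass = g0$truth$molarMass)
  expect_equal(q0$molecules_per_cell, g0$truth$moleculesPerCell)
  # 2% densitometry noise: recovery within 5%
  relErr <- vapply(1:10, function(s) {
    g <- genBlotData(syntheticConfig(seed = s, noiseCv = 0.02))
    q <- quantifyBlot(g$standards, g$samples, molarMass = g$truth$molarMass)
    abs(q$molecules_per_cell - g$truth$moleculesPerCell) /
      g$truth$moleculesPerCell
  }, numeric(1))
  expect_lt(median(relErr), 0.05)
})
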