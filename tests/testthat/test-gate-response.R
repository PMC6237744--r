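test_that("evalHill matches the closed form and its limits", {
  rf <- ResponseFunction(yMin = 2, yMax = 100, K = 10, n = 1.6)
  expect_identical(evalHill(rf, 0), 100)
  expect_identical(evalHill(rf, 10), 51)          # arithmetic mean at x = K
  expect_lt(abs(evalHill(rf, 1e6 * 10) - 2) / 2, 1e-4)  # saturation
  x <- 10^seq(-2, 4, length.out = 60)
  expect_equal(evalHill(rf, x), bruteHill(x, 2, 100, 10, 1.6))
  expect_error(evalHill(rf, -1), "must be finite and >= 0")
})

test_that("evalHill is monotone non-increasing for random valid gates", {
  set.seed(11)
  for (i in 1:30) {
    rf <- randomGate()
    y <- evalHill(rf, c(0, 10^seq(-3, 5, length.out = 300)))
    expect_true(all(diff(y) <= 0))
    expect_true(all(y >= yMin(rf) - 1e-12 & y <= yMax(rf) + 1e-12))
  }
})

test_that("ResponseFunction validity rejects degenerate parameters", {
  expect_error(ResponseFunction(-1, 100, 10, 1.6), "yMin")
  expect_error(ResponseFunction(5, 5, 10, 1.6), "yMax")
  expect_error(ResponseFunction(2, 100, 0, 1.6), "K")
  expect_error(ResponseFunction(2, 100, 10, 0), "n")
})

test_that("fitHill round-trips noise-free curves to 1e-6 relative", {
  for (nTrue in c(1.6, 0.9, 1.3, 2.5)) {
    truth <- ResponseFunction(2, 100, 10, nTrue)
    x <- exp(seq(log(0.1), log(1000), length.out = 15))
    fit <- fitHill(data.frame(input_activity = x,
                              output_activity = evalHill(truth, x)))
    expect_lt(abs(coopN(fit) - nTrue) / nTrue, 1e-6)
    expect_lt(abs(thresholdK(fit) - 10) / 10, 1e-6)
    expect_lt(abs(yMin(fit) - 2) / 2, 1e-6)
    expect_lt(abs(yMax(fit) - 100) / 100, 1e-6)
  }
})

test_that("fitHill pools replicates and works on either residual scale", {
  truth <- ResponseFunction(5, 200, 20, 1.4)
  g <- genGateCurves(syntheticConfig(seed = 4, noiseCv = 0, nReplicates = 3),
                     truth = truth)
  expect_equal(nrow(g$data), 45)
  for (scale in c("log", "linear")) {
    fit <- fitHill(g$data, residualScale = scale)
    expect_lt(abs(coopN(fit) - 1.4) / 1.4, 1e-6)
  }
  expect_named(fitDiagnostics(fitHill(g$data)),
               c("residualNorm", "residualScale", "stdErrors", "nPoints"))
})

test_that("fitHill names the defect on degenerate data", {
  x <- exp(seq(log(0.1), log(100), length.out = 10))
  expect_error(fitHill(data.frame(input_activity = x,
                                  output_activity = rep(50, 10))),
               "no repression signal")
  expect_error(fitHill(data.frame(input_activity = rep(c(1, 2, 3), 4),
                                  output_activity = runif(12, 1, 100))),
               "fewer than 4 distinct input levels")
  expect_error(fitHill(data.frame(input_activity = x,
                                  output_activity = c(-1, runif(9, 1, 100)))),
               "background handling")
})

test_that("noisy Hill fits recover cooperativity with small median error", {
  # multiplicative log-normal noise, CV 10%, 3 replicates per point
  truth <- ResponseFunction(2, 100, 10, 1.6)
  relErr <- vapply(1:25, function(s) {
    g <- genGateCurves(syntheticConfig(seed = s, noiseCv = 0.1,
                                       nReplicates = 3), truth = truth)
    abs(coopN(fitHill(g$data)) - 1.6) / 1.6
  }, numeric(1))
  expect_lte(median(relErr), 0.10)
})

test_that("gateSummary reports dynamic range and flags yMin = 0", {
  s <- gateSummary(ResponseFunction(2, 100, 10, 1.6))
  expect_equal(s$dynamicRange, 50)
  expect_false(s$infiniteRange)
  rfZero <- ResponseFunction(0, 100, 10, 1.6)
  expect_warning(s0 <- gateSummary(rfZero), "infinite")
  expect_identical(s0$dynamicRange, Inf)
  # no-gate limit: vanishing separation drives the range to 1
  eps <- 1e-9
  sEps <- gateSummary(ResponseFunction(50, 50 + eps, 10, 1.6))
  expect_lt(abs(sEps$dynamicRange - 1), 1e-9)
})

test_that("a synthetic gate library refits inside the generator bounds", {
  g <- genGateCurves(syntheticConfig(seed = 9, noiseCv = 0, nReplicates = 1),
                     truth = NULL, nGates = 30)
  fits <- lapply(split(g$data, g$data$gate_id), fitHill)
  tab <- gateLibrarySummary(fits)
  expect_equal(nrow(tab), 30)
  expect_true(all(tab$coop_n >= 1.3 - 1e-6 & tab$coop_n <= 1.8 + 1e-6))
})
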