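test_that("empty and single-layer cascades behave as identity and gate", {
  expect_identical(composeCascade(Cascade(), 7.3), 7.3)
  rf <- ResponseFunction(2, 100, 10, 1.6)
  x <- c(0, 10^seq(-2, 4, length.out = 40))
  expect_identical(composeCascade(Cascade(list(rf)), x), evalHill(rf, x))
})

test_that("composition matches brute-force layer-by-layer evaluation", {
  rf <- ResponseFunction(2, 100, 10, 1.6)
  cc <- Cascade(list(rf, rf))
  expect_identical(composeCascade(cc, 10), evalHill(rf, 51))
  set.seed(21)
  stack <- replicate(4, randomGate())
  params <- do.call(rbind, lapply(stack, function(g)
    data.frame(yMin = yMin(g), yMax = yMax(g), K = thresholdK(g),
               n = coopN(g))))
  x <- 10^seq(-2, 4, length.out = 50)
  expect_equal(composeCascade(Cascade(stack), x), bruteCompose(params, x))
})

test_that("cascade composition is associative over sub-cascades", {
  set.seed(22)
  stack <- replicate(5, randomGate())
  x <- c(0, 10^seq(-1, 3, length.out = 25))
  whole <- composeCascade(Cascade(stack), x)
  split2 <- composeCascade(Cascade(stack[4:5]),
                           composeCascade(Cascade(stack[1:3]), x))
  expect_identical(whole, split2)
})

test_that("parity law: odd stacks invert, even stacks preserve direction", {
  set.seed(23)
  x <- c(0, 10^seq(-2, 4, length.out = 200))
  for (i in 1:30) {
    k <- sample(1:5, 1)
    y <- composeCascade(Cascade(replicate(k, randomGate())), x)
    if (k %% 2 == 1) expect_true(all(diff(y) <= 1e-12))
    else expect_true(all(diff(y) >= -1e-12))
  }
})

test_that("cascade output lies within the final layer's range", {
  set.seed(24)
  for (i in 1:20) {
    stack <- replicate(sample(1:4, 1), randomGate())
    last <- stack[[length(stack)]]
    y <- composeCascade(Cascade(stack), 10^seq(-3, 5, length.out = 100))
    expect_true(all(y >= yMin(last) - 1e-12 & y <= yMax(last) + 1e-12))
  }
})

test_that("predictCascadeCurve maps inducer through the transfer table", {
  rf <- ResponseFunction(2, 100, 10, 1.6)
  grid <- c(0.5, 1, 5, 10, 50, 100)
  ident <- data.frame(inducer = grid, activity = grid)
  cc <- Cascade(list(rf), ident)
  out <- predictCascadeCurve(cc, grid)
  expect_equal(out$predicted_output, composeCascade(Cascade(list(rf)), grid))
  expect_equal(out$input_activity, grid)
  expect_error(predictCascadeCurve(cc, 200), "no extrapolation")
  expect_error(predictCascadeCurve(Cascade(list(rf)), grid),
               "no input transfer")
})

test_that("predicted curves inherit the parity of the layer count", {
  set.seed(25)
  inducer <- c(0, 10^seq(-1, 2, length.out = 80))
  transfer <- data.frame(inducer = inducer,
                         activity = 0.1 + 5 * inducer^0.8)  # monotone
  for (k in 1:4) {
    cc <- Cascade(replicate(k, randomGate()), transfer)
    y <- predictCascadeCurve(cc, inducer)$predicted_output
    if (k %% 2 == 1) expect_true(all(diff(y) <= 1e-12))
    else expect_true(all(diff(y) >= -1e-12))
  }
})

test_that("Cascade validity enforces a monotone transfer curve", {
  rf <- ResponseFunction(2, 100, 10, 1.6)
  expect_error(Cascade(list(rf),
                       data.frame(inducer = c(0, 1, 2),
                                  activity = c(5, 3, 8))),
               "monotone")
  expect_error(Cascade(list(rf, "not a gate")), "ResponseFunction")
})
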