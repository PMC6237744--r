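phlfModel <- function(cTot = 1e-6) {
  SharingModel(cTot = cTot, alpha1 = 7.6e-12, alphaX = 2.3e-11,
               beta = 3.0e-11, kProm = 1.7e-8, nHill = 0.9)
}

kineticModel <- function(cTot = 1e-6, kOn = 1e4, kOff = 1e-3,
                         deltaS = 3e-3) {
  SharingModel(cTot = cTot, alpha1 = 7.6e-12, alphaX = 2.3e-11,
               kProm = 1.7e-8, nHill = 0.9,
               kOn = kOn, kOff = kOff, deltaS = deltaS)
}

test_that("free sgRNA steady state is transcription over degradation", {
  expect_identical(steadyStateSgRNA(0, 2e-3), 0)
  expect_identical(steadyStateSgRNA(2 * 2e-3, 2e-3), 2)
  expect_error(steadyStateSgRNA(1e-12, 0), "no steady state")
  # ODE oracle: the simulated free sgRNA relaxes to alpha/deltaS
  m <- kineticModel()
  al <- c(7.6e-12, 2.3e-11)
  term <- tail(simulateSharing(m, al, tEnd = 2e5), 1)
  expect_lt(abs(term$s1 - al[1] / 3e-3) / (al[1] / 3e-3), 1e-3)
  expect_lt(abs(term$s2 - al[2] / 3e-3) / (al[2] / 3e-3), 1e-3)
})

test_that("complex concentration follows the competition closed form", {
  m <- phlfModel()
  # direct arithmetic with the dCas9*_PhlF characterization rates
  expect_equal(complexConcentration(m, 0),
               7.6e-12 / (3.0e-11 + 7.6e-12) * 1e-6)
  expect_equal(complexConcentration(m, 0:16),
               7.6e-12 * 1e-6 / (3.0e-11 + 7.6e-12 + (0:16) * 2.3e-11))
  expect_true(all(diff(complexConcentration(m, 0:50)) < 0))
  # saturation: alpha1 dominating the denominator pulls in the whole pool
  mSat <- SharingModel(1e-6, alpha1 = 1e6 * 3.0e-11, alphaX = 2.3e-11,
                       beta = 3.0e-11, kProm = 1.7e-8, nHill = 0.9)
  expect_lt(abs(complexConcentration(mSat, 0) - 1e-6) / 1e-6, 1e-4)
  expect_error(complexConcentration(m, -1), "non-negative")
})

test_that("N = 1 competition equals the explicit two-sgRNA closed form", {
  m <- phlfModel()
  two <- closedFormComplexes(m, c(7.6e-12, 2.3e-11))
  expect_equal(complexConcentration(m, 1L), two[1], tolerance = 1e-15)
})

test_that("fold-repression model is the occupancy form 1 + (Cs1/K)^n", {
  m <- phlfModel()
  expect_identical(foldRepressionModel(m, 0), 1)
  expect_equal(foldRepressionModel(m, m@kProm), 2)
  mHalf <- SharingModel(1e-6, 7.6e-12, 2.3e-11, 3.0e-11,
                        kProm = 1.7e-8, nHill = 0.5)
  expect_equal(foldRepressionModel(mHalf, 4 * 1.7e-8), 3)
  cs <- seq(0, 1e-6, length.out = 50)
  expect_true(all(diff(foldRepressionModel(m, cs)) > 0))
})

test_that("ODE right-hand side conserves the dCas9 pool by construction", {
  m <- kineticModel()
  set.seed(31)
  for (i in 1:100) {
    k <- sample(1:4, 1)
    st <- sharingState(s = runif(k, 0, 1e-6), Cs = runif(k, 0, 1e-6),
                       CF = runif(1, 0, 1e-6))
    d <- odeRHS(m, st, alphas = runif(k, 0, 1e-10))
    expect_equal(d$CF + sum(d$Cs), 0)
  }
  # all rates and inputs zero -> static system
  m0 <- SharingModel(1e-6, 0, 0, kProm = 1.7e-8, nHill = 0.9,
                     kOn = 0, kOff = 0, deltaS = 0)
  st <- sharingState(c(1e-8, 1e-8), c(1e-8, 1e-8), 1e-7)
  expect_equal(unlist(odeRHS(m0, st, c(0, 0))), rep(0, 5),
               ignore_attr = TRUE)
  expect_error(odeRHS(m, st, 1e-12), "dimension mismatch")
})

test_that("the closed-form steady state is a fixed point of the dynamics", {
  m <- kineticModel()
  al <- c(7.6e-12, 2.3e-11, 5e-12)
  cs <- closedFormComplexes(m, al)
  st <- sharingState(steadyStateSgRNA(al, m@deltaS), cs, m@cTot - sum(cs))
  d <- odeRHS(m, st, al)
  scale <- max(al, m@deltaS * st$s)
  expect_lt(max(abs(unlist(d))) / scale, 1e-12)
})

test_that("trajectories reach the closed forms and conserve the pool", {
  set.seed(32)
  for (i in 1:10) {
    m <- SharingModel(cTot = 10^runif(1, -7, -5),
                      alpha1 = 10^runif(1, -12, -10),
                      alphaX = 10^runif(1, -12, -10),
                      kProm = 1.7e-8, nHill = 0.9,
                      kOn = 10^runif(1, 3, 5), kOff = 10^runif(1, -4, -2),
                      deltaS = 10^runif(1, -3, -2))
    k <- sample(1:3, 1)
    al <- 10^runif(k, -12, -10)
    tr <- simulateSharing(m, al, tEnd = 2e3 / min(m@deltaS, m@kOff))
    term <- unlist(tail(tr, 1)[, paste0("Cs", seq_len(k))])
    cf <- closedFormComplexes(m, al)
    expect_lt(max(abs(term - cf) / cf), 1e-3)
    expect_lt(attr(tr, "conservationDrift"), 1e-6)
  }
})

test_that("a trajectory started at equilibrium stays there", {
  m <- kineticModel()
  al <- c(7.6e-12, 2.3e-11)
  cs <- closedFormComplexes(m, al)
  init <- sharingState(steadyStateSgRNA(al, m@deltaS), cs, m@cTot - sum(cs))
  tr <- simulateSharing(m, al, tEnd = 1e5, init = init)
  for (col in c("s1", "s2", "Cs1", "Cs2", "CF"))
    expect_lt(max(abs(tr[[col]] - tr[[col]][1])) / tr[[col]][1], 1e-6)
})

test_that("raising a competitor's transcription lowers the reporter complex", {
  m <- kineticModel()
  t1 <- tail(simulateSharing(m, c(7.6e-12, 2.3e-11), tEnd = 2e5), 1)$Cs1
  t2 <- tail(simulateSharing(m, c(7.6e-12, 4.6e-11), tEnd = 2e5), 1)$Cs1
  expect_lt(t2, t1)
})

test_that("predictions depend only on the identifiable combinations", {
  m <- phlfModel()
  # common rescaling of all transcription/turnover rates
  lam <- 7.3
  mScaled <- SharingModel(m@cTot, m@alpha1 * lam, m@alphaX * lam,
                          m@beta * lam, kProm = m@kProm, nHill = m@nHill)
  expect_equal(foldVsN(mScaled, 0:16), foldVsN(m, 0:16))
  # ridge transformation (R, b, x) -> (lR, l(1+b)-1, lx) at fixed q, p, n
  l <- 2.5
  b <- m@beta / m@alpha1
  mRidge <- SharingModel(cTot = m@cTot * l, alpha1 = m@alpha1,
                         alphaX = m@alphaX * l,
                         beta = (l * (1 + b) - 1) * m@alpha1,
                         kProm = m@kProm, nHill = m@nHill)
  expect_equal(foldVsN(mRidge, 0:16), foldVsN(m, 0:16))
  ic <- identifiableCombos(m)
  icR <- identifiableCombos(mRidge)
  expect_equal(ic[c("q", "p", "nHill")], icR[c("q", "p", "nHill")])
})

test_that("fitSharing round-trips noise-free data under the anchor", {
  # truth expressed through the ratios b = 4, x = 3, R = 500, n = 0.9
  alpha1 <- 7.6e-12; kProm <- 1.7e-8
  truth <- SharingModel(cTot = 500 * kProm, alpha1 = alpha1,
                        alphaX = 3 * alpha1, beta = 4 * alpha1,
                        kProm = kProm, nHill = 0.9)
  d <- data.frame(N = 0:16, fold_repression = foldVsN(truth, 0:16),
                  replicate = 1L)
  fit <- fitSharing(d, betaOverAlpha1 = 4, alpha1 = alpha1, kProm = kProm)
  ic <- fit$identifiable; icT <- identifiableCombos(truth)
  for (nm in c("cTotOverKProm", "betaOverAlpha1", "alphaXOverAlpha1",
               "nHill", "q", "p"))
    expect_lt(abs(ic[[nm]] - icT[[nm]]) / icT[[nm]], 1e-2)
})

test_that("fitSharing validates its inputs and flags anomalies", {
  d <- data.frame(N = c(1, 2, 4), fold_repression = c(30, 20, 10))
  expect_error(fitSharing(d), "N = 0")
  expect_error(fitSharing(data.frame(N = c(0, 1), fold_repression = c(50, 30))),
               "insufficient N coverage")
  dBad <- data.frame(N = c(0, 1, 2, 4), fold_repression = c(50, 0.5, 20, 10))
  w <- capture_warnings(fitSharing(dBad))
  expect_true(any(grepl("floored", w)))
  expect_true(any(grepl("not monotone", w)))
})

test_that("a fitted curve through 58-fold solo data decreases in N", {
  g <- genCompetitionData(syntheticConfig(seed = 5, noiseCv = 0))
  expect_equal(g$data$fold_repression[g$data$N == 0][1], 58)
  fit <- fitSharing(g$data)
  pred <- foldVsN(fit$model, 0:30)
  expect_true(all(diff(pred) < 0))
  expect_lt(abs(pred[1] - 58) / 58, 1e-3)
})

test_that("threshold crossing matches an exhaustive scan and is sane", {
  alpha1 <- 7.6e-12; kProm <- 1.7e-8
  m <- SharingModel(cTot = 500 * kProm, alpha1 = alpha1,
                    alphaX = 3 * alpha1, beta = 4 * alpha1,
                    kProm = kProm, nHill = 0.9)
  nStar <- minSgRNAsBelowThreshold(m, 10)
  brute <- min(which(bruteFold(m@cTot, m@alpha1, m@alphaX, m@beta,
                               m@kProm, m@nHill, 0:10000) < 10)) - 1
  expect_identical(as.integer(nStar), as.integer(brute))
  expect_warning(n0 <- minSgRNAsBelowThreshold(m, 1e6), "already below")
  expect_identical(as.integer(n0), 0L)
  # a larger pool never lowers the tolerated competitor count
  nByPool <- vapply(c(1, 2, 5, 10, 20), function(f)
    as.integer(minSgRNAsBelowThreshold(initialize(m, cTot = m@cTot * f), 10)),
    integer(1))
  expect_true(all(diff(nByPool) >= 0))
})

test_that("calibrateCtot reproduces the requested solo fold-repression", {
  m <- calibrateCtot(phlfModel(), 58)
  expect_equal(foldVsN(m, 0), 58)
  expect_error(calibrateCtot(phlfModel(), 1), "> 1")
})

test_that("SharingModel validity checks beta against the kinetic rates", {
  expect_error(SharingModel(1e-6, 7.6e-12, 2.3e-11, beta = 1e-9,
                            kProm = 1.7e-8, nHill = 0.9,
                            kOn = 1e4, kOff = 1e-3, deltaS = 3e-3),
               "inconsistent")
  m <- kineticModel()
  expect_equal(m@beta, 3e-3 * 1e-3 / 1e4)
})
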