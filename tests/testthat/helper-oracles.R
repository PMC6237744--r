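# Independent oracles kept deliberately naive: direct transcription of the
# closed forms, never calls into the code paths they check.

# repressing Hill curve written as K^n / (x^n + K^n), the textbook form
bruteHill <- function(x, yMin, yMax, K, n) {
  yMin + (yMax - yMin) * K^n / (x^n + K^n)
}

# cascade output by explicit loop over layer parameter rows
bruteCompose <- function(paramRows, x) {
  for (i in seq_len(nrow(paramRows))) {
    p <- paramRows[i, ]
    x <- bruteHill(x, p$yMin, p$yMax, p$K, p$n)
  }
  x
}

# fold-repression vs N straight from the printed formulas
bruteFold <- function(cTot, alpha1, alphaX, beta, kProm, nHill, N) {
  cs1 <- alpha1 * cTot / (beta + alpha1 + N * alphaX)
  1 + (cs1 / kProm)^nHill
}

randomGate <- function() {
  yMax <- runif(1, 20, 500)
  ResponseFunction(yMin = yMax / runif(1, 5, 100), yMax = yMax,
                   K = exp(runif(1, log(1), log(100))),
                   n = runif(1, 0.5, 3))
}
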