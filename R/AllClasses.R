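#' @import methods
#' @importFrom stats coef residuals setNames
NULL

## Central value classes. Tabular inputs (response curves, competition
## tables, event samples) stay validated data.frames -- see io.R.

#' Hill response function of a transcriptional NOT gate
#'
#' Parameterizes the steady-state map from input promoter activity x to
#' output promoter activity y of a repressing (NOT) gate,
#' \deqn{y = y_{min} + (y_{max} - y_{min}) \frac{K^n}{x^n + K^n}}{
#'   y = yMin + (yMax - yMin) * K^n / (x^n + K^n)}
#' where \code{K} is the input threshold (half-maximal input) and \code{n}
#' the Hill cooperativity. Activities are in arbitrary fluorescence units.
#'
#' @slot yMin numeric(1), minimal output activity (au), \code{>= 0}.
#' @slot yMax numeric(1), maximal output activity (au), \code{> yMin}.
#' @slot K numeric(1), input threshold (au), \code{> 0}.
#' @slot n numeric(1), Hill cooperativity (dimensionless), \code{> 0}.
#' @slot gateId character(1) label.
#' @slot diagnostics list of fit diagnostics (empty for hand-built objects).
#'
#' @seealso [evalHill()], [fitHill()], [gateSummary()]
#' @export
setClass("ResponseFunction",
  representation(
    yMin = "numeric",
    yMax = "numeric",
    K = "numeric",
    n = "numeric",
    gateId = "character",
    diagnostics = "list"
  ),
  prototype(yMin = 0, yMax = 1, K = 1, n = 1, gateId = "", diagnostics = list())
)

setValidity("ResponseFunction", function(object) {
  msg <- character()
  for (s in c("yMin", "yMax", "K", "n")) {
    v <- slot(object, s)
    if (length(v) != 1L || !is.finite(v))
      msg <- c(msg, sprintf("'%s' must be a finite numeric scalar", s))
  }
  if (length(msg) == 0L) {
    if (object@yMin < 0) msg <- c(msg, "'yMin' must be >= 0")
    if (object@yMax <= object@yMin) msg <- c(msg, "'yMax' must exceed 'yMin'")
    if (object@K <= 0) msg <- c(msg, "threshold 'K' must be > 0")
    if (object@n <= 0) msg <- c(msg, "cooperativity 'n' must be > 0")
  }
  if (length(object@gateId) != 1L) msg <- c(msg, "'gateId' must be character(1)")
  if (length(msg)) msg else TRUE
})

#' Construct a ResponseFunction
#'
#' @param yMin,yMax minimal and maximal output promoter activity (au).
#' @param K input threshold (au).
#' @param n Hill cooperativity.
#' @param gateId optional label.
#' @param diagnostics optional list of fit diagnostics.
#' @return A [ResponseFunction-class] object.
#' @examples
#' rf <- ResponseFunction(yMin = 2, yMax = 100, K = 10, n = 1.6)
#' evalHill(rf, c(0, 10, 1000))
#' @export
ResponseFunction <- function(yMin, yMax, K, n, gateId = "",
                             diagnostics = list()) {
  new("ResponseFunction", yMin = as.numeric(yMin), yMax = as.numeric(yMax),
      K = as.numeric(K), n = as.numeric(n), gateId = as.character(gateId),
      diagnostics = diagnostics)
}

#' Layered NOT-gate cascade
#'
#' An ordered stack of [ResponseFunction-class] layers composed head to
#' tail: the output activity of layer i is the input activity of layer
#' i + 1, in the same arbitrary units (all promoters are characterized
#' with the same reporter). An empty cascade is the identity map. An
#' optional tabulated inducer-to-activity transfer curve (measured
#' separately for the input promoter) maps inducer concentration onto the
#' first layer's input axis.
#'
#' @slot layers list of [ResponseFunction-class] objects, first layer first.
#' @slot inputTransfer data.frame with columns \code{inducer} and
#'   \code{activity}; zero rows mean no transfer curve. Must be monotone
#'   non-decreasing in inducer.
#'
#' @seealso [composeCascade()], [predictCascadeCurve()]
#' @export
setClass("Cascade",
  representation(layers = "list", inputTransfer = "data.frame"),
  prototype(layers = list(),
            inputTransfer = data.frame(inducer = numeric(), activity = numeric()))
)

setValidity("Cascade", function(object) {
  msg <- character()
  ok <- vapply(object@layers, is, logical(1), class2 = "ResponseFunction")
  if (!all(ok)) msg <- c(msg, "all layers must be ResponseFunction objects")
  tr <- object@inputTransfer
  if (!all(c("inducer", "activity") %in% names(tr))) {
    msg <- c(msg, "inputTransfer needs columns 'inducer' and 'activity'")
  } else if (nrow(tr) > 0L) {
    if (any(!is.finite(tr$inducer)) || any(!is.finite(tr$activity)))
      msg <- c(msg, "inputTransfer values must be finite")
    else {
      o <- order(tr$inducer)
      if (any(diff(tr$activity[o]) < 0))
        msg <- c(msg, "inputTransfer must be monotone non-decreasing")
      if (anyDuplicated(tr$inducer))
        msg <- c(msg, "inputTransfer inducer values must be distinct")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct a Cascade
#'
#' @param layers list of [ResponseFunction-class] objects (may be empty).
#' @param inputTransfer optional data.frame with columns \code{inducer},
#'   \code{activity} giving the measured inducer-to-input-activity curve.
#' @return A [Cascade-class] object.
#' @examples
#' rf <- ResponseFunction(2, 100, 10, 1.6)
#' cc <- Cascade(list(rf, rf))
#' composeCascade(cc, 10)
#' @export
Cascade <- function(layers = list(), inputTransfer = NULL) {
  if (is.null(inputTransfer))
    inputTransfer <- data.frame(inducer = numeric(), activity = numeric())
  inputTransfer <- inputTransfer[order(inputTransfer$inducer), , drop = FALSE]
  rownames(inputTransfer) <- NULL
  new("Cascade", layers = layers, inputTransfer = inputTransfer)
}

#' Resource-sharing model of a shared dCas9 pool
#'
#' Parameters of the pool-competition (retroactivity) model in which
#' co-expressed sgRNAs titrate a finite pool of dCas9. The total pool
#' \code{cTot} is conserved between free dCas9 and sgRNA::dCas9 complexes.
#' Each sgRNA i is transcribed at rate alpha_i, degrades (free form only)
#' at rate \code{deltaS}, and binds free dCas9 with association constant
#' K1 = kOn/kOff. The composite \code{beta} = deltaS/K1 (M/s) controls, at
#' steady state, the concentration of the reporter-targeting complex
#' \deqn{C_{s1} = \frac{\alpha_1 C_{TOT}}{\beta + \alpha_1 + N \alpha_x}}
#' for N equal competing sgRNAs, and the fold-repression of the targeted
#' promoter follows a quasi-equilibrium (Shea-Ackers) occupancy form
#' \code{1 + (Cs1/kProm)^nHill}.
#'
#' Either the kinetic triplet (\code{kOn}, \code{kOff}, \code{deltaS}) or
#' the composite \code{beta} may be supplied; when both are populated they
#' must agree.
#'
#' @slot cTot total dCas9 concentration (M), \code{> 0}.
#' @slot alpha1 transcription rate of the reporter-targeting sgRNA (M/s).
#' @slot alphaX transcription rate of each competing sgRNA (M/s).
#' @slot beta composite deltaS/K1 (M/s).
#' @slot kProm dissociation constant of complex-promoter binding (M).
#' @slot nHill promoter-occupancy cooperativity (dimensionless).
#' @slot kOn sgRNA-dCas9 association rate (1/(M s)); NA if unspecified.
#' @slot kOff dissociation rate (1/s); NA if unspecified.
#' @slot deltaS free-sgRNA degradation rate (1/s); NA if unspecified.
#'
#' @seealso [complexConcentration()], [foldRepressionModel()],
#'   [simulateSharing()], [fitSharing()], [minSgRNAsBelowThreshold()]
#' @export
setClass("SharingModel",
  representation(
    cTot = "numeric", alpha1 = "numeric", alphaX = "numeric",
    beta = "numeric", kProm = "numeric", nHill = "numeric",
    kOn = "numeric", kOff = "numeric", deltaS = "numeric"
  ),
  prototype(cTot = 1e-6, alpha1 = 7.6e-12, alphaX = 2.3e-11, beta = 3.0e-11,
            kProm = 1.7e-8, nHill = 0.9,
            kOn = NA_real_, kOff = NA_real_, deltaS = NA_real_)
)

setValidity("SharingModel", function(object) {
  msg <- character()
  for (s in c("cTot", "alpha1", "alphaX", "beta", "kProm", "nHill",
              "kOn", "kOff", "deltaS")) {
    v <- slot(object, s)
    if (length(v) != 1L)
      msg <- c(msg, sprintf("'%s' must be a scalar", s))
    else if (!is.na(v) && v < 0)
      msg <- c(msg, sprintf("'%s' must be non-negative", s))
  }
  if (length(msg) == 0L) {
    if (object@cTot <= 0) msg <- c(msg, "'cTot' must be > 0")
    if (object@kProm <= 0) msg <- c(msg, "'kProm' must be > 0")
    if (object@nHill <= 0) msg <- c(msg, "'nHill' must be > 0")
    kin <- c(object@kOn, object@kOff, object@deltaS)
    if (all(!is.na(kin)) && object@kOn > 0) {
      betaKin <- object@deltaS * object@kOff / object@kOn
      # relative comparison: these are tiny molar rates, so all.equal's
      # absolute-difference shortcut would pass almost anything
      if (abs(betaKin - object@beta) > 1e-8 * max(betaKin, object@beta))
        msg <- c(msg, sprintf(
          "'beta' (%g) inconsistent with deltaS/K1 = %g from kinetic rates",
          object@beta, betaKin))
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct a SharingModel
#'
#' @param cTot total dCas9 concentration (M).
#' @param alpha1 transcription rate of the reporter-targeting sgRNA (M/s).
#' @param alphaX transcription rate of each competing sgRNA (M/s).
#' @param beta composite deltaS/K1 (M/s); derived from the kinetic rates
#'   when those are given and \code{beta} is missing.
#' @param kProm complex-promoter dissociation constant (M).
#' @param nHill promoter-occupancy cooperativity.
#' @param kOn,kOff,deltaS optional kinetic rates (1/(M s), 1/s, 1/s);
#'   required for ODE simulation, not for the steady-state closed forms.
#' @return A [SharingModel-class] object.
#' @examples
#' m <- SharingModel(cTot = 1e-6, alpha1 = 7.6e-12, alphaX = 2.3e-11,
#'                   beta = 3.0e-11, kProm = 1.7e-8, nHill = 0.9)
#' foldRepressionModel(m, complexConcentration(m, N = 0:5))
#' @export
SharingModel <- function(cTot, alpha1, alphaX, beta = NULL,
                         kProm, nHill,
                         kOn = NA_real_, kOff = NA_real_, deltaS = NA_real_) {
  if (is.null(beta)) {
    if (any(is.na(c(kOn, kOff, deltaS))))
      stop("supply 'beta' or the full kinetic triplet kOn, kOff, deltaS")
    beta <- deltaS * kOff / kOn
  }
  new("SharingModel", cTot = as.numeric(cTot), alpha1 = as.numeric(alpha1),
      alphaX = as.numeric(alphaX), beta = as.numeric(beta),
      kProm = as.numeric(kProm), nHill = as.numeric(nHill),
      kOn = as.numeric(kOn), kOff = as.numeric(kOff),
      deltaS = as.numeric(deltaS))
}

#' Densitometry standard curve
#'
#' Ordinary least-squares calibration line relating known protein amounts
#' per lane to band intensity, used to interpolate unknown lane amounts.
#'
#' @slot points data.frame with columns \code{amount} (e.g. ng/lane) and
#'   \code{intensity} (densitometry au).
#' @slot slope,intercept fitted line \code{intensity = slope * amount +
#'   intercept}; slope must be positive (signal increases with amount).
#' @slot rSquared coefficient of determination of the fit.
#'
#' @seealso [fitStandardCurve()], [interpolateAmount()]
#' @export
setClass("StandardCurve",
  representation(points = "data.frame", slope = "numeric",
                 intercept = "numeric", rSquared = "numeric"),
  prototype(points = data.frame(amount = numeric(), intensity = numeric()),
            slope = 1, intercept = 0, rSquared = NA_real_)
)

setValidity("StandardCurve", function(object) {
  msg <- character()
  if (!all(c("amount", "intensity") %in% names(object@points)))
    msg <- c(msg, "points need columns 'amount' and 'intensity'")
  else if (any(object@points$amount < 0))
    msg <- c(msg, "standard amounts must be >= 0")
  if (length(object@slope) != 1L || !is.finite(object@slope) ||
      object@slope <= 0)
    msg <- c(msg, "fitted slope must be a positive scalar")
  if (length(object@intercept) != 1L || !is.finite(object@intercept))
    msg <- c(msg, "intercept must be a finite scalar")
  if (length(msg)) msg else TRUE
})
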