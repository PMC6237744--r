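#' Evaluate a NOT-gate Hill response function
#'
#' Computes the output promoter activity
#' \code{yMin + (yMax - yMin) * K^n / (x^n + K^n)} for input activities
#' \code{x}. Implemented as \code{yMin + (yMax - yMin) / (1 + (x/K)^n)},
#' which is overflow-safe for large \code{x} and gives exactly
#' \code{yMax} at \code{x = 0} and the arithmetic mean of \code{yMin} and
#' \code{yMax} at \code{x = K}.
#'
#' @param rf a [ResponseFunction-class].
#' @param x numeric vector of input promoter activities (au), \code{>= 0}.
#' @return Numeric vector of output activities (au), monotone
#'   non-increasing in \code{x}.
#' @examples
#' rf <- ResponseFunction(yMin = 2, yMax = 100, K = 10, n = 1.6)
#' evalHill(rf, c(0, 10, 1e6))
#' @export
evalHill <- function(rf, x) {
  stopifnot(is(rf, "ResponseFunction"))
  if (any(!is.finite(x)) || any(x < 0))
    stop("input activity 'x' must be finite and >= 0")
  rf@yMin + (rf@yMax - rf@yMin) / (1 + (x / rf@K)^rf@n)
}

hillPredict <- function(x, yMin, yMax, K, n) {
  yMin + (yMax - yMin) / (1 + (x / K)^n)
}

#' Fit a Hill response function to NOT-gate measurements
#'
#' Fits the four-parameter repressing Hill model to pooled replicate
#' measurements by bounded Levenberg-Marquardt least squares
#' ([minpack.lm::nlsLM()]). Residuals are taken on the log(output) scale
#' by default, because fluorescence spans decades and gate metrics are
#' ratios; this equalizes relative error across the curve. Initialization
#' is deterministic (yMax = max observed, yMin = min observed, K =
#' geometric midpoint of positive inputs, n = 1) so identical data give
#' identical fits.
#'
#' @param data data.frame with columns \code{input_activity} and
#'   \code{output_activity} (au); extra columns such as \code{replicate}
#'   and \code{gate_id} are carried but replicates are fit jointly through
#'   pooled residuals, never averaged first.
#' @param residualScale \code{"log"} (default) or \code{"linear"}.
#' @param gateId optional label stored on the result (defaults to a
#'   \code{gate_id} column when present).
#' @return A [ResponseFunction-class] whose \code{diagnostics} list holds
#'   \code{residualNorm}, \code{residualScale}, per-parameter standard
#'   errors \code{stdErrors}, and the number of points \code{nPoints}.
#' @section Errors:
#' Fewer than 4 distinct input levels, a flat response ("no repression
#' signal"), or non-positive outputs under log residuals raise errors
#' naming the defect.
#' @examples
#' truth <- ResponseFunction(2, 100, 10, 1.6)
#' x <- 10^seq(-1, 3, length.out = 15)
#' fit <- fitHill(data.frame(input_activity = x,
#'                           output_activity = evalHill(truth, x)))
#' coopN(fit)
#' @export
fitHill <- function(data, residualScale = c("log", "linear"), gateId = NULL) {
  residualScale <- match.arg(residualScale)
  stopifnot(is.data.frame(data),
            all(c("input_activity", "output_activity") %in% names(data)))
  x <- as.numeric(data$input_activity)
  y <- as.numeric(data$output_activity)
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("non-finite measurement values")
  if (any(x < 0)) stop("input activities must be >= 0")
  if (length(unique(x)) < 4L)
    stop("degenerate data: fewer than 4 distinct input levels")
  if (any(y <= 0) && residualScale == "log")
    stop("non-positive outputs: background handling must precede log-scale fitting")
  if (max(y) / max(min(y), .Machine$double.xmin) < 1.05)
    stop("degenerate data: no repression signal (flat output)")

  xPos <- x[x > 0]
  start <- list(yMin = max(min(y), 1e-12), yMax = max(y),
                K = exp(mean(log(range(xPos)))), n = 1)
  lower <- c(yMin = 0, yMax = max(y) * 0.1,
             K = min(xPos) * 0.01, n = 0.1)
  upper <- c(yMax = max(y) * 10, yMin = max(y),
             K = max(x) * 100, n = 10)[c("yMin", "yMax", "K", "n")]

  obs <- if (residualScale == "log") log(y) else y
  form <- if (residualScale == "log")
    obs ~ log(hillPredict(x, yMin, yMax, K, n))
  else obs ~ hillPredict(x, yMin, yMax, K, n)

  fit <- tryCatch(
    minpack.lm::nlsLM(form, start = start, lower = lower, upper = upper,
                      control = minpack.lm::nls.lm.control(
                        maxiter = 500, ftol = 1e-14, ptol = 1e-14)),
    error = function(e) stop("Hill fit did not converge: ",
                             conditionMessage(e), call. = FALSE))
  est <- coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) setNames(rep(NA_real_, 4), names(est)))
  if (is.null(gateId))
    gateId <- if ("gate_id" %in% names(data))
      as.character(data$gate_id[1]) else ""
  ResponseFunction(
    yMin = est[["yMin"]], yMax = est[["yMax"]], K = est[["K"]], n = est[["n"]],
    gateId = gateId,
    diagnostics = list(residualNorm = sqrt(sum(residuals(fit)^2)),
                       residualScale = residualScale,
                       stdErrors = se, nPoints = length(x)))
}

#' Summary statistics of a fitted NOT gate
#'
#' @param rf a [ResponseFunction-class].
#' @return Named list with \code{dynamicRange} (= yMax/yMin, the
#'   fold-change between fully-off and fully-on output; \code{Inf} with a
#'   warning when yMin is 0), \code{coopN} and \code{thresholdK}, plus a
#'   logical \code{infiniteRange} flag.
#' @examples
#' gateSummary(ResponseFunction(2, 100, 10, 1.6))
#' @export
gateSummary <- function(rf) {
  stopifnot(is(rf, "ResponseFunction"))
  infinite <- rf@yMin == 0
  if (infinite)
    warning("yMin is 0: dynamic range reported as infinite")
  list(dynamicRange = if (infinite) Inf else rf@yMax / rf@yMin,
       coopN = rf@n, thresholdK = rf@K, infiniteRange = infinite)
}

#' Summarize a library of gates
#'
#' @param rfs list of [ResponseFunction-class] objects.
#' @return data.frame with one row per gate: \code{gate_id},
#'   \code{y_min}, \code{y_max}, \code{dynamic_range}, \code{threshold_K},
#'   \code{coop_n}.
#' @export
gateLibrarySummary <- function(rfs) {
  stopifnot(all(vapply(rfs, is, logical(1), class2 = "ResponseFunction")))
  do.call(rbind, lapply(rfs, function(rf) {
    data.frame(gate_id = rf@gateId, y_min = rf@yMin, y_max = rf@yMax,
               dynamic_range = if (rf@yMin > 0) rf@yMax / rf@yMin else Inf,
               threshold_K = rf@K, coop_n = rf@n)
  }))
}
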