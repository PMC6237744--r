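#' Compose a NOT-gate cascade
#'
#' Evaluates the end-to-end response of a layered cascade by functional
#' composition: the output activity of each layer is fed directly, in the
#' same arbitrary units, as the input activity of the next
#' (f_L(...f_2(f_1(x))...)). A cascade with zero layers is the identity.
#'
#' @param cascade a [Cascade-class].
#' @param x numeric vector of input promoter activities (au), \code{>= 0}.
#' @return Numeric vector of predicted output activities (au).
#' @examples
#' rf <- ResponseFunction(2, 100, 10, 1.6)
#' composeCascade(Cascade(list(rf, rf)), 10) # == evalHill(rf, evalHill(rf, 10))
#' @export
composeCascade <- function(cascade, x) {
  stopifnot(is(cascade, "Cascade"))
  if (any(!is.finite(x)) || any(x < 0))
    stop("input activity 'x' must be finite and >= 0")
  for (rf in cascade@layers) x <- evalHill(rf, x)
  x
}

#' Interpolate an inducer-to-activity transfer curve
#'
#' Monotone piecewise-linear interpolation in log-inducer space; an
#' inducer value of 0 is kept as an explicit floor point on a linear
#' segment to the smallest positive tabulated inducer. No extrapolation:
#' values outside the tabulated range raise an error.
#'
#' @param transfer data.frame with columns \code{inducer}, \code{activity}.
#' @param inducer numeric vector of inducer concentrations.
#' @return Interpolated input promoter activities (au).
#' @keywords internal
interpolateTransfer <- function(transfer, inducer) {
  if (nrow(transfer) < 2L)
    stop("input transfer curve needs at least 2 points")
  o <- order(transfer$inducer)
  ind <- transfer$inducer[o]
  act <- transfer$activity[o]
  if (any(inducer < min(ind)) || any(inducer > max(ind)))
    stop(sprintf(
      "inducer outside tabulated transfer range [%g, %g]; no extrapolation",
      min(ind), max(ind)))
  # piecewise-linear in log-inducer space; inducer 0 sits at a floor
  # coordinate one decade below the smallest positive tabulated point
  hasZero <- ind[1] == 0
  floorLog <- if (hasZero) log(ind[2]) - log(10) else NA_real_
  toLog <- function(v) ifelse(v == 0, floorLog, log(v))
  stats::approx(toLog(ind), act, xout = toLog(inducer), ties = "ordered")$y
}

#' Predict a cascade response over an inducer grid
#'
#' Maps each inducer concentration to input promoter activity through the
#' cascade's separately-measured transfer curve (monotone piecewise-linear
#' interpolation in log-inducer space), then composes all layers.
#'
#' @param cascade a [Cascade-class] carrying an \code{inputTransfer} table.
#' @param inducer numeric vector of inducer concentrations covering only
#'   the tabulated transfer range (no extrapolation).
#' @return data.frame with columns \code{inducer}, \code{input_activity},
#'   \code{predicted_output}.
#' @examples
#' rf <- ResponseFunction(2, 100, 10, 1.6)
#' tr <- data.frame(inducer = c(0, 1, 10, 100), activity = c(0.1, 1, 20, 200))
#' predictCascadeCurve(Cascade(list(rf), tr), c(1, 10, 100))
#' @export
predictCascadeCurve <- function(cascade, inducer) {
  stopifnot(is(cascade, "Cascade"))
  if (nrow(cascade@inputTransfer) == 0L)
    stop("cascade has no input transfer curve")
  xin <- interpolateTransfer(cascade@inputTransfer, inducer)
  data.frame(inducer = inducer, input_activity = xin,
             predicted_output = composeCascade(cascade, xin))
}
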