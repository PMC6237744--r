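#' Fit a densitometry standard curve
#'
#' Ordinary least squares line \code{intensity = slope * amount +
#' intercept} through the standards ([stats::lm()]). The line is fitted
#' with a free intercept: straight-line interpolation with an offset
#' accommodates membrane background without forcing the origin.
#'
#' @param points data.frame with columns \code{amount} (known protein per
#'   lane, e.g. ng) and \code{intensity} (densitometry au); at least 3
#'   distinct amounts.
#' @return A [StandardCurve-class].
#' @examples
#' fitStandardCurve(data.frame(amount = 1:3, intensity = c(3, 5, 7)))
#' @export
fitStandardCurve <- function(points) {
  stopifnot(is.data.frame(points),
            all(c("amount", "intensity") %in% names(points)))
  if (length(unique(points$amount)) < 3L)
    stop("insufficient standards: need at least 3 distinct amounts")
  if (any(points$amount < 0)) stop("standard amounts must be >= 0")
  fit <- stats::lm(intensity ~ amount, data = points)
  cf <- stats::coef(fit)
  # suppress the "essentially perfect fit" note on noise-free standards
  r2 <- suppressWarnings(summary(fit)$r.squared)
  if (!is.finite(cf[["amount"]]) || cf[["amount"]] <= 0)
    stop("standard curve slope is not positive; signal must increase with amount")
  new("StandardCurve", points = points[, c("amount", "intensity")],
      slope = cf[["amount"]], intercept = cf[["(Intercept)"]],
      rSquared = r2)
}

#' Interpolate a lane amount from its band intensity
#'
#' Inverts the fitted calibration line: \code{(intensity - intercept) /
#' slope}. Intensities outside the standard range are still converted but
#' flagged with an extrapolation warning; negative inverted amounts are
#' clipped to 0 and flagged.
#'
#' @param curve a [StandardCurve-class].
#' @param intensity band intensity (au), vectorized.
#' @return Amount per lane in the standards' units, with attributes
#'   \code{"extrapolated"} and \code{"clipped"} (logical vectors).
#' @export
interpolateAmount <- function(curve, intensity) {
  stopifnot(is(curve, "StandardCurve"))
  if (curve@slope <= 0) stop("standard curve slope must be > 0")
  amount <- (intensity - curve@intercept) / curve@slope
  rng <- range(curve@points$intensity)
  extrapolated <- intensity < rng[1] | intensity > rng[2]
  if (any(extrapolated))
    warning("intensity outside the standard range; extrapolating the line")
  clipped <- amount < 0
  if (any(clipped)) {
    warning("negative interpolated amount clipped to 0")
    amount[clipped] <- 0
  }
  structure(amount, extrapolated = extrapolated, clipped = clipped)
}

#' Molecules per cell from a lane amount
#'
#' Converts a per-lane protein mass to molecules via the molar mass and
#' Avogadro's number, scales up by the lysate fraction loaded in the
#' lane, and divides by the number of cells the lane represents:
#' \code{molecules = amountNg * 1e-9 / molarMass * 6.02214076e23 /
#' lysateFraction / cellsRepresented}.
#'
#' @param amountNg protein mass in the lane (ng).
#' @param molarMass protein molar mass (g/mol), \code{> 0}.
#' @param lysateFraction fraction of the culture lysate loaded in the
#'   lane, in (0, 1].
#' @param cellsRepresented number of cells whose protein the full lysate
#'   contains, \code{> 0}.
#' @return Molecules per cell.
#' @examples
#' moleculesPerCell(1, 158000, 1, 1e6)  # ~3811 molecules/cell
#' @export
moleculesPerCell <- function(amountNg, molarMass, lysateFraction,
                             cellsRepresented) {
  if (molarMass <= 0) stop("'molarMass' must be > 0")
  if (any(lysateFraction <= 0) || any(lysateFraction > 1))
    stop("'lysateFraction' must be in (0, 1]")
  if (any(cellsRepresented <= 0)) stop("zero cells represented")
  if (any(amountNg < 0)) stop("'amountNg' must be >= 0")
  molecules <- amountNg * 1e-9 / molarMass * 6.02214076e23
  molecules / lysateFraction / cellsRepresented
}

#' End-to-end blot quantification
#'
#' Fits the standard curve, interpolates each sample lane, and converts
#' to molecules per cell.
#'
#' @param standards data.frame with columns \code{amount_ng},
#'   \code{intensity}.
#' @param samples data.frame with columns \code{sample_id},
#'   \code{intensity}, \code{lysate_fraction}, \code{cells_represented}.
#' @param molarMass protein molar mass (g/mol).
#' @return data.frame with columns \code{sample_id}, \code{amount_ng},
#'   \code{molecules_per_cell}.
#' @export
quantifyBlot <- function(standards, samples, molarMass) {
  stopifnot(is.data.frame(standards), is.data.frame(samples),
            all(c("amount_ng", "intensity") %in% names(standards)),
            all(c("sample_id", "intensity", "lysate_fraction",
                  "cells_represented") %in% names(samples)))
  curve <- fitStandardCurve(data.frame(amount = standards$amount_ng,
                                       intensity = standards$intensity))
  amount <- as.numeric(interpolateAmount(curve, samples$intensity))
  data.frame(
    sample_id = samples$sample_id,
    amount_ng = amount,
    molecules_per_cell = moleculesPerCell(amount, molarMass,
                                          samples$lysate_fraction,
                                          samples$cells_represented))
}
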