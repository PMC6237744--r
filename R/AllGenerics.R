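#' Accessors for model objects
#'
#' Small accessor generics so user code never touches slots directly.
#'
#' @param object a package model object.
#' @return The corresponding parameter value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("yMin", function(object) standardGeneric("yMin"))
#' @rdname accessors
#' @export
setGeneric("yMax", function(object) standardGeneric("yMax"))
#' @rdname accessors
#' @export
setGeneric("thresholdK", function(object) standardGeneric("thresholdK"))
#' @rdname accessors
#' @export
setGeneric("coopN", function(object) standardGeneric("coopN"))
#' @rdname accessors
#' @export
setGeneric("gateId", function(object) standardGeneric("gateId"))
#' @rdname accessors
#' @export
setGeneric("fitDiagnostics", function(object) standardGeneric("fitDiagnostics"))

#' @rdname accessors
#' @export
setMethod("yMin", "ResponseFunction", function(object) object@yMin)
#' @rdname accessors
#' @export
setMethod("yMax", "ResponseFunction", function(object) object@yMax)
#' @rdname accessors
#' @export
setMethod("thresholdK", "ResponseFunction", function(object) object@K)
#' @rdname accessors
#' @export
setMethod("coopN", "ResponseFunction", function(object) object@n)
#' @rdname accessors
#' @export
setMethod("gateId", "ResponseFunction", function(object) object@gateId)
#' @rdname accessors
#' @export
setMethod("fitDiagnostics", "ResponseFunction",
          function(object) object@diagnostics)

#' @rdname accessors
#' @export
setGeneric("layers", function(object) standardGeneric("layers"))
#' @rdname accessors
#' @export
setMethod("layers", "Cascade", function(object) object@layers)
#' @rdname accessors
#' @export
setGeneric("nLayers", function(object) standardGeneric("nLayers"))
#' @rdname accessors
#' @export
setMethod("nLayers", "Cascade", function(object) length(object@layers))

#' @rdname accessors
#' @export
setGeneric("totalPool", function(object) standardGeneric("totalPool"))
#' @rdname accessors
#' @export
setMethod("totalPool", "SharingModel", function(object) object@cTot)

#' Identifiable parameter combinations of a SharingModel
#'
#' Fold-repression versus competitor count determines the model only
#' through three combinations: the occupancy cooperativity \code{nHill},
#' \code{q = (alpha1 * cTot / (beta + alpha1)) / kProm} (the scaled
#' reporter-complex concentration with no competitors) and
#' \code{p = alphaX / (beta + alpha1)} (the per-competitor dilution of the
#' denominator). Any two parameter vectors sharing \code{(q, p, nHill)}
#' predict identical fold-repression for every N.
#'
#' @param object a [SharingModel-class].
#' @return Named numeric vector with elements \code{q}, \code{p},
#'   \code{nHill}, plus the conventional ratios \code{cTotOverKProm},
#'   \code{betaOverAlpha1} and \code{alphaXOverAlpha1}.
#' @examples
#' identifiableCombos(SharingModel(1e-6, 7.6e-12, 2.3e-11, 3.0e-11,
#'                                 kProm = 1.7e-8, nHill = 0.9))
#' @export
setGeneric("identifiableCombos",
           function(object) standardGeneric("identifiableCombos"))

#' @rdname identifiableCombos
#' @export
setMethod("identifiableCombos", "SharingModel", function(object) {
  denom0 <- object@beta + object@alpha1
  c(q = object@alpha1 * object@cTot / denom0 / object@kProm,
    p = object@alphaX / denom0,
    nHill = object@nHill,
    cTotOverKProm = object@cTot / object@kProm,
    betaOverAlpha1 = object@beta / object@alpha1,
    alphaXOverAlpha1 = object@alphaX / object@alpha1)
})

setMethod("show", "ResponseFunction", function(object) {
  cat(sprintf("ResponseFunction%s\n",
              if (nzchar(object@gateId)) paste0(" '", object@gateId, "'") else ""))
  cat(sprintf("  yMin = %.4g au, yMax = %.4g au (dynamic range %.3g-fold)\n",
              object@yMin, object@yMax,
              if (object@yMin > 0) object@yMax / object@yMin else Inf))
  cat(sprintf("  threshold K = %.4g au, cooperativity n = %.3g\n",
              object@K, object@n))
  if (length(object@diagnostics))
    cat(sprintf("  fitted (residual norm %.4g on %s scale)\n",
                object@diagnostics$residualNorm %||% NA_real_,
                object@diagnostics$residualScale %||% "?"))
  invisible(object)
})

setMethod("show", "Cascade", function(object) {
  cat(sprintf("Cascade of %d NOT-gate layer(s)%s\n", length(object@layers),
              if (nrow(object@inputTransfer) > 0)
                sprintf(" with %d-point input transfer curve",
                        nrow(object@inputTransfer)) else ""))
  for (i in seq_along(object@layers)) {
    rf <- object@layers[[i]]
    cat(sprintf("  [%d] %s K = %.4g, n = %.3g, range [%.4g, %.4g]\n", i,
                if (nzchar(rf@gateId)) rf@gateId else "(unnamed)",
                rf@K, rf@n, rf@yMin, rf@yMax))
  }
  invisible(object)
})

setMethod("show", "SharingModel", function(object) {
  cat("SharingModel (dCas9 pool competition)\n")
  cat(sprintf("  cTot = %.3g M, alpha1 = %.3g M/s, alphaX = %.3g M/s\n",
              object@cTot, object@alpha1, object@alphaX))
  cat(sprintf("  beta = %.3g M/s, kProm = %.3g M, nHill = %.3g\n",
              object@beta, object@kProm, object@nHill))
  if (!any(is.na(c(object@kOn, object@kOff, object@deltaS))))
    cat(sprintf("  kinetics: kOn = %.3g /(M s), kOff = %.3g /s, deltaS = %.3g /s\n",
                object@kOn, object@kOff, object@deltaS))
  ic <- identifiableCombos(object)
  cat(sprintf("  identifiable: q = %.4g, p = %.4g, nHill = %.3g\n",
              ic[["q"]], ic[["p"]], ic[["nHill"]]))
  invisible(object)
})

setMethod("show", "StandardCurve", function(object) {
  cat(sprintf(
    "StandardCurve: intensity = %.4g * amount + %.4g (R^2 = %.4f, %d standards)\n",
    object@slope, object@intercept, object@rSquared, nrow(object@points)))
  invisible(object)
})

`%||%` <- function(a, b) if (is.null(a)) b else a
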