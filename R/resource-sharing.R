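#' Steady-state free sgRNA concentration
#'
#' At steady state the net binding flux between free sgRNA and the dCas9
#' pool cancels against complex formation, so the free sgRNA level is set
#' by transcription and degradation alone: \code{alpha / deltaS}.
#'
#' @param alpha transcription rate (M/s), vectorized.
#' @param deltaS free-sgRNA degradation rate (1/s), \code{> 0}.
#' @return Free sgRNA concentration (M).
#' @export
steadyStateSgRNA <- function(alpha, deltaS) {
  if (length(deltaS) != 1L || !is.finite(deltaS) || deltaS <= 0)
    stop("'deltaS' must be > 0: no steady state without sgRNA turnover")
  if (any(alpha < 0)) stop("transcription rates must be >= 0")
  alpha / deltaS
}

#' Steady-state reporter-targeting complex concentration
#'
#' Closed form for the concentration of the sgRNA1::dCas9 complex when N
#' additional competing sgRNAs (each transcribed at \code{alphaX}, with no
#' DNA targets of their own) share the same dCas9 pool:
#' \deqn{C_{s1} = \frac{\alpha_1 C_{TOT}}{\beta + \alpha_1 + N \alpha_x}}
#' with \code{beta = deltaS/K1}. At \code{N = 1} this reduces exactly to
#' the two-sgRNA closed form with \code{alpha2 = alphaX}.
#'
#' @param model a [SharingModel-class].
#' @param N integer vector, number of additional co-expressed competing
#'   sgRNAs (\code{>= 0}).
#' @return Complex concentration (M), strictly decreasing in \code{N}
#'   when \code{alphaX > 0}.
#' @examples
#' m <- SharingModel(1e-6, 7.6e-12, 2.3e-11, 3.0e-11, kProm = 1.7e-8,
#'                   nHill = 0.9)
#' complexConcentration(m, 0:16)
#' @export
complexConcentration <- function(model, N) {
  stopifnot(is(model, "SharingModel"))
  if (any(N < 0) || any(N != round(N)))
    stop("'N' must be non-negative integers")
  denom <- model@beta + model@alpha1 + N * model@alphaX
  if (any(denom == 0))
    stop("beta + alpha1 + N*alphaX is zero: complex concentration undefined")
  model@alpha1 * model@cTot / denom
}

#' General multi-sgRNA steady-state complex concentrations
#'
#' For arbitrary per-sgRNA transcription rates \code{alphas}, the steady
#' state of the mass-action system gives
#' \code{Cs_i = alpha_i * cTot / (beta + sum(alphas))}.
#'
#' @param model a [SharingModel-class].
#' @param alphas numeric vector of transcription rates (M/s), one per
#'   sgRNA species.
#' @return Numeric vector of complex concentrations (M).
#' @export
closedFormComplexes <- function(model, alphas) {
  stopifnot(is(model, "SharingModel"))
  if (any(alphas < 0)) stop("transcription rates must be >= 0")
  alphas * model@cTot / (model@beta + sum(alphas))
}

#' Fold-repression from complex concentration
#'
#' Quasi-equilibrium (Shea-Ackers) promoter occupancy: fold-repression of
#' the targeted promoter is \code{1 + (Cs1/kProm)^nHill}, always
#' \code{>= 1} and strictly increasing in the complex concentration.
#'
#' @param model a [SharingModel-class].
#' @param cs1 complex concentration(s) (M), \code{>= 0}.
#' @return Fold-repression (dimensionless).
#' @export
foldRepressionModel <- function(model, cs1) {
  stopifnot(is(model, "SharingModel"))
  if (any(cs1 < 0)) stop("complex concentration must be >= 0")
  1 + (cs1 / model@kProm)^model@nHill
}

#' Predicted fold-repression versus competitor count
#'
#' @param model a [SharingModel-class].
#' @param N integer vector of competing-sgRNA counts.
#' @return Fold-repression (dimensionless), non-increasing in \code{N}.
#' @export
foldVsN <- function(model, N) {
  foldRepressionModel(model, complexConcentration(model, N))
}

#' Construct a sharing-model state
#'
#' @param s free sgRNA concentrations (M), one per species.
#' @param Cs sgRNA::dCas9 complex concentrations (M), same length.
#' @param CF free dCas9 concentration (M).
#' @return A validated list of class \code{"SharingState"}.
#' @export
sharingState <- function(s, Cs, CF) {
  if (length(s) != length(Cs))
    stop("'s' and 'Cs' must have one entry per sgRNA species")
  if (length(CF) != 1L) stop("'CF' must be a scalar")
  if (any(c(s, Cs, CF) < 0)) stop("state components must be >= 0")
  structure(list(s = as.numeric(s), Cs = as.numeric(Cs), CF = as.numeric(CF)),
            class = "SharingState")
}

#' Time derivatives of the pool-competition mass-action system
#'
#' Implements, for each sgRNA species i,
#' \code{ds_i/dt = alpha_i - deltaS*s_i - kOn*CF*s_i + kOff*Cs_i},
#' \code{dCs_i/dt = kOn*CF*s_i - kOff*Cs_i}, and
#' \code{dCF/dt = -sum(kOn*CF*s_i) + sum(kOff*Cs_i)}. The derivative of
#' \code{CF + sum(Cs)} is identically zero: the total dCas9 pool is
#' conserved by construction.
#'
#' @param model a [SharingModel-class] with kinetic rates populated.
#' @param state a \code{SharingState} (see [sharingState()]).
#' @param alphas transcription rates (M/s), one per species in the state.
#' @return A \code{SharingState}-shaped list of time derivatives.
#' @export
odeRHS <- function(model, state, alphas) {
  stopifnot(is(model, "SharingModel"), inherits(state, "SharingState"))
  if (length(alphas) != length(state$s))
    stop("dimension mismatch between state and 'alphas'")
  if (any(is.na(c(model@kOn, model@kOff, model@deltaS))))
    stop("kinetic rates kOn, kOff, deltaS required for dynamics")
  bind <- model@kOn * state$CF * state$s
  unbind <- model@kOff * state$Cs
  list(s = alphas - model@deltaS * state$s - bind + unbind,
       Cs = bind - unbind,
       CF = -sum(bind) + sum(unbind))
}

#' Simulate the pool-competition dynamics
#'
#' Adaptive stiff-capable integration ([deSolve::lsoda()]) of the
#' mass-action system at relative tolerance 1e-9 and absolute tolerance
#' \code{1e-12 * cTot}, tight enough that the conservation law
#' \code{CF + sum(Cs) = const} drifts by less than 1e-6 relative along
#' any trajectory. The default initial condition is an empty system: no
#' free sgRNA, no complexes, all dCas9 free (\code{CF = cTot}).
#'
#' @param model a [SharingModel-class] with kinetic rates populated.
#' @param alphas transcription rates (M/s), one per sgRNA species.
#' @param tEnd final time (s), \code{> 0}.
#' @param init optional \code{SharingState} initial condition.
#' @param nOut number of output time points (log-ish spacing plus t = 0).
#' @return data.frame with columns \code{time}, \code{s1...}, \code{Cs1...},
#'   \code{CF}, and attribute \code{"conservationDrift"} (max relative
#'   drift of the conserved total).
#' @examples
#' m <- SharingModel(1e-6, 7.6e-12, 2.3e-11, kProm = 1.7e-8, nHill = 0.9,
#'                   kOn = 1e4, kOff = 1e-3, deltaS = 3e-3)
#' tr <- simulateSharing(m, alphas = c(7.6e-12, 2.3e-11), tEnd = 1e5)
#' tail(tr, 1)
#' @export
simulateSharing <- function(model, alphas, tEnd, init = NULL, nOut = 200L) {
  stopifnot(is(model, "SharingModel"))
  if (any(is.na(c(model@kOn, model@kOff, model@deltaS))))
    stop("kinetic rates kOn, kOff, deltaS required for simulation")
  if (tEnd <= 0) stop("'tEnd' must be > 0")
  k <- length(alphas)
  if (is.null(init)) init <- sharingState(rep(0, k), rep(0, k), model@cTot)
  stopifnot(inherits(init, "SharingState"), length(init$s) == k)

  y0 <- c(init$s, init$Cs, init$CF)
  names(y0) <- c(paste0("s", seq_len(k)), paste0("Cs", seq_len(k)), "CF")
  rhs <- function(t, y, p) {
    st <- list(s = y[seq_len(k)], Cs = y[k + seq_len(k)], CF = y[2 * k + 1])
    bind <- model@kOn * st$CF * st$s
    unbind <- model@kOff * st$Cs
    list(c(alphas - model@deltaS * st$s - bind + unbind,
           bind - unbind,
           -sum(bind) + sum(unbind)))
  }
  times <- unique(c(0, exp(seq(log(tEnd / 1e4), log(tEnd),
                               length.out = nOut - 1L))))
  sol <- deSolve::lsoda(y0, times, rhs, parms = NULL,
                        rtol = 1e-9, atol = 1e-12 * model@cTot)
  if (attr(sol, "istate")[1] < 0)
    stop("ODE integration failed: ",
         paste(attr(sol, "istate"), collapse = " "))
  out <- as.data.frame(unclass(sol))
  total <- out$CF + rowSums(out[, k + 1L + seq_len(k), drop = FALSE])
  attr(out, "conservationDrift") <-
    max(abs(total - total[1])) / total[1]
  out
}

#' Fit the sharing model to fold-repression versus competitor count
#'
#' Fold-vs-N data constrain the model only through three identifiable
#' combinations (see [identifiableCombos()]): the occupancy cooperativity
#' \code{n}, \code{q} (scaled solo complex concentration) and \code{p}
#' (per-competitor denominator growth), with
#' \code{fold(N) = 1 + (q / (1 + p N))^n}. The fitter estimates
#' \code{(q, p, n)} by bounded Levenberg-Marquardt least squares on the
#' log(fold) scale, then reconstructs a full parameter vector under an
#' anchoring convention: \code{betaOverAlpha1}, \code{alpha1} and
#' \code{kProm} are taken as supplied (defaults follow the dCas9*_PhlF
#' characterization), giving \code{alphaX = p*(1+b)*alpha1},
#' \code{cTot = q*(1+b)*kProm}.
#'
#' @param data data.frame with columns \code{N} (integer competitor
#'   counts including 0, at least 3 distinct values) and
#'   \code{fold_repression} (\code{>= 1}; smaller values are floored with
#'   a warning); an optional \code{replicate} column is pooled.
#' @param betaOverAlpha1 anchoring ratio beta/alpha1 used to reconstruct
#'   the full parameter vector (not identifiable from the data).
#' @param alpha1 fixed transcription rate of the reporter-targeting sgRNA
#'   (M/s), the unit of the rate scale.
#' @param kProm fixed promoter dissociation constant (M).
#' @return list with \code{model} (reconstructed [SharingModel-class]),
#'   \code{identifiable} (named vector \code{q}, \code{p}, \code{nHill}
#'   plus conventional ratios), and \code{diagnostics} (residual norm,
#'   standard errors, n points).
#' @examples
#' truth <- SharingModel(1e-6, 7.6e-12, 2.3e-11, 3.0e-11,
#'                       kProm = 1.7e-8, nHill = 0.9)
#' d <- data.frame(N = c(0, 1, 2, 4, 7, 10, 13, 16))
#' d$fold_repression <- foldVsN(truth, d$N)
#' fitSharing(d)$identifiable
#' @export
fitSharing <- function(data, betaOverAlpha1 = 3.0e-11 / 7.6e-12,
                       alpha1 = 7.6e-12, kProm = 1.7e-8) {
  stopifnot(is.data.frame(data),
            all(c("N", "fold_repression") %in% names(data)))
  N <- as.numeric(data$N)
  fold <- as.numeric(data$fold_repression)
  if (any(N < 0) || any(N != round(N))) stop("'N' must be integers >= 0")
  if (!any(N == 0)) stop("data must include the N = 0 (no competitor) condition")
  if (length(unique(N)) < 3L)
    stop("insufficient N coverage: need at least 3 distinct competitor counts")
  if (any(fold < 1)) {
    warning(sum(fold < 1), " fold-repression value(s) < 1 floored to 1")
    fold <- pmax(fold, 1)
  }
  meanByN <- tapply(fold, N, mean)
  if (any(diff(meanByN[order(as.numeric(names(meanByN)))]) > 0.1 * meanByN[1]))
    warning("fold-repression not monotone decreasing in N beyond noise level")

  # deterministic init: with n = 1, 1/(fold-1) is linear in N; points at
  # or near the floor carry no shape information and are left out
  use <- fold > 1.01
  if (sum(use) >= 2L && length(unique(N[use])) >= 2L) {
    cf <- stats::coef(stats::lm(I(1 / (fold[use] - 1)) ~ N[use]))
  } else cf <- c(1 / max(max(fold) - 1, 1e-3), 1)
  q0 <- min(max(1 / max(cf[1], 1e-12), 1e-3), 1e9)
  p0 <- min(max(cf[2] * q0, 1e-4), 1e3)
  obs <- log(pmax(fold, 1 + 1e-9))
  fit <- tryCatch(
    minpack.lm::nlsLM(
      obs ~ log(1 + (q / (1 + p * N))^n),
      start = list(q = q0, p = p0, n = 1),
      lower = c(q = 1e-9, p = 0, n = 0.1),
      upper = c(q = Inf, p = Inf, n = 10),
      control = minpack.lm::nls.lm.control(maxiter = 500,
                                           ftol = 1e-14, ptol = 1e-14)),
    error = function(e) stop("sharing-model fit did not converge: ",
                             conditionMessage(e), call. = FALSE))
  est <- stats::coef(fit)
  b <- betaOverAlpha1
  model <- SharingModel(
    cTot = est[["q"]] * (1 + b) * kProm,
    alpha1 = alpha1,
    alphaX = est[["p"]] * (1 + b) * alpha1,
    beta = b * alpha1,
    kProm = kProm, nHill = est[["n"]])
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) setNames(rep(NA_real_, 3), names(est)))
  list(model = model,
       identifiable = identifiableCombos(model),
       diagnostics = list(residualNorm = sqrt(sum(stats::residuals(fit)^2)),
                          stdErrors = se, nPoints = length(N)))
}

#' Smallest competitor count driving repression below a threshold
#'
#' Scans N = 0, 1, 2, ... and returns the first count at which the
#' predicted fold-repression falls strictly below \code{threshold}.
#' Because \code{fold(N) -> 1} as \code{N -> Inf} (for \code{alphaX > 0})
#' the scan always terminates.
#'
#' @param model a [SharingModel-class] with \code{alphaX > 0}.
#' @param threshold fold-repression threshold, \code{> 1}.
#' @return Integer N; 0 carries attribute \code{alreadyBelow = TRUE} (and
#'   a warning) when even the solo gate is below threshold.
#' @examples
#' m <- SharingModel(1e-6, 7.6e-12, 2.3e-11, 3.0e-11, kProm = 1.7e-8,
#'                   nHill = 0.9)
#' minSgRNAsBelowThreshold(m, 10)
#' @export
minSgRNAsBelowThreshold <- function(model, threshold) {
  stopifnot(is(model, "SharingModel"))
  if (threshold <= 1) stop("'threshold' must be > 1")
  if (model@alphaX <= 0)
    stop("'alphaX' must be > 0 for repression to decline with N")
  if (foldVsN(model, 0) < threshold) {
    warning("solo gate already below threshold")
    return(structure(0L, alreadyBelow = TRUE))
  }
  N <- 0L
  repeat {
    N <- N + 1L
    if (foldVsN(model, N) < threshold) return(N)
    if (N > 1e7) stop("no crossing found below N = 1e7")
  }
}

#' Calibrate the total dCas9 pool to a solo fold-repression
#'
#' Solves \code{foldVsN(model, 0) = fold0} for \code{cTot} and returns
#' the model with that pool size. Used when the pool size is unknown but
#' the repression of the lone gate has been measured.
#'
#' @param model a [SharingModel-class] (its \code{cTot} is replaced).
#' @param fold0 measured solo fold-repression, \code{> 1}.
#' @return The calibrated [SharingModel-class].
#' @export
calibrateCtot <- function(model, fold0) {
  stopifnot(is(model, "SharingModel"))
  if (fold0 <= 1) stop("'fold0' must be > 1")
  cs1 <- model@kProm * (fold0 - 1)^(1 / model@nHill)
  cTot <- cs1 * (model@beta + model@alpha1) / model@alpha1
  initialize(model, cTot = cTot)
}
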