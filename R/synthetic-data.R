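#' Configuration for the synthetic-data generators
#'
#' Every generator draws from a fixed-seed RNG stream and a multiplicative
#' log-normal noise model (fluorescence and densitometry are ratio-scale
#' measurements, so noise is proportional). A given config produces
#' bit-identical output on every call.
#'
#' @param seed integer RNG seed.
#' @param noiseCv coefficient of variation of the multiplicative
#'   log-normal measurement noise (0 = noise-free).
#' @param nReplicates replicate measurements per condition.
#' @return A list of class \code{"SyntheticConfig"}.
#' @export
syntheticConfig <- function(seed = 1L, noiseCv = 0.1, nReplicates = 3L) {
  if (noiseCv < 0) stop("'noiseCv' must be >= 0")
  if (nReplicates < 1L) stop("'nReplicates' must be >= 1")
  structure(list(seed = as.integer(seed), noiseCv = noiseCv,
                 nReplicates = as.integer(nReplicates)),
            class = "SyntheticConfig")
}

# mean-one-on-log-scale multiplicative log-normal noise
noiseFactor <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  stats::rlnorm(n, meanlog = 0, sdlog = sqrt(log(1 + cv^2)))
}

#' Generate NOT-gate response curves with known ground truth
#'
#' Emulates gate characterization assays: log-spaced input promoter
#' activity grids, Hill-shaped outputs, multiplicative log-normal noise,
#' replicates. With \code{truth = NULL} a gate library is drawn with
#' cooperativities uniform in \code{coopRange} (default 1.3-1.8, the
#' range observed across a 30-gate library), maximal activities uniform
#' in [50, 200] au and dynamic ranges log-normal around 47-fold.
#'
#' @param cfg a [syntheticConfig()].
#' @param truth a single [ResponseFunction-class] used as ground truth,
#'   or \code{NULL} to draw a library.
#' @param nGates library size when \code{truth} is NULL (default 30).
#' @param coopRange cooperativity bounds for library draws.
#' @param nPoints input levels per curve (log-spaced over
#'   \code{K * [1e-2, 1e2]}).
#' @return list with \code{data} (data.frame \code{gate_id},
#'   \code{input_activity}, \code{output_activity}, \code{replicate}) and
#'   \code{truth} (list of [ResponseFunction-class]).
#' @examples
#' g <- genGateCurves(syntheticConfig(seed = 7, noiseCv = 0),
#'                    truth = ResponseFunction(2, 100, 10, 1.6))
#' head(g$data)
#' @export
genGateCurves <- function(cfg, truth = NULL, nGates = 30L,
                          coopRange = c(1.3, 1.8), nPoints = 15L) {
  stopifnot(inherits(cfg, "SyntheticConfig"))
  set.seed(cfg$seed)
  if (is.null(truth)) {
    truth <- lapply(seq_len(nGates), function(i) {
      yMax <- stats::runif(1, 50, 200)
      dr <- stats::rlnorm(1, meanlog = log(47), sdlog = 0.3)
      ResponseFunction(yMin = yMax / dr, yMax = yMax,
                       K = exp(stats::runif(1, log(5), log(20))),
                       n = stats::runif(1, coopRange[1], coopRange[2]),
                       gateId = sprintf("gate%02d", i))
    })
  } else if (is(truth, "ResponseFunction")) {
    if (!nzchar(truth@gateId)) truth@gateId <- "gate01"
    truth <- list(truth)
  }
  data <- do.call(rbind, lapply(truth, function(rf) {
    x <- exp(seq(log(rf@K * 1e-2), log(rf@K * 1e2), length.out = nPoints))
    do.call(rbind, lapply(seq_len(cfg$nReplicates), function(r) {
      data.frame(gate_id = rf@gateId, input_activity = x,
                 output_activity = evalHill(rf, x) *
                   noiseFactor(length(x), cfg$noiseCv),
                 replicate = r)
    }))
  }))
  rownames(data) <- NULL
  list(data = data, truth = truth)
}

#' Generate fold-repression versus competitor-count data
#'
#' Emulates the titration of a shared dCas9 pool: fold-repression of a
#' reporter gate measured while 0 to 16 untargeted competing sgRNAs are
#' co-expressed. The default ground truth uses the dCas9*_PhlF
#' characterization rates (beta = 3.0e-11, alpha1 = 7.6e-12,
#' alphaX = 2.3e-11 M/s, kProm = 1.7e-8 M, nHill = 0.9) with the pool
#' calibrated so the lone gate represses 58-fold. Noisy values are
#' floored at 1 (repression cannot be measured below parity).
#'
#' @param cfg a [syntheticConfig()].
#' @param truth a [SharingModel-class] ground truth, or \code{NULL} for
#'   the default.
#' @param Nset integer vector of competitor counts.
#' @return list with \code{data} (data.frame \code{N},
#'   \code{fold_repression}, \code{replicate}) and \code{truth}.
#' @export
genCompetitionData <- function(cfg, truth = NULL,
                               Nset = c(0, 1, 2, 4, 7, 10, 13, 16)) {
  stopifnot(inherits(cfg, "SyntheticConfig"))
  set.seed(cfg$seed + 1L)
  if (is.null(truth)) {
    truth <- SharingModel(cTot = 1, alpha1 = 7.6e-12, alphaX = 2.3e-11,
                          beta = 3.0e-11, kProm = 1.7e-8, nHill = 0.9)
    truth <- calibrateCtot(truth, 58)
  }
  stopifnot(is(truth, "SharingModel"))
  fold <- foldVsN(truth, Nset)
  data <- do.call(rbind, lapply(seq_len(cfg$nReplicates), function(r) {
    data.frame(N = Nset,
               fold_repression = pmax(fold * noiseFactor(length(fold),
                                                         cfg$noiseCv), 1),
               replicate = r)
  }))
  rownames(data) <- NULL
  list(data = data, truth = truth)
}

#' Generate immunoblot densitometry data with known ground truth
#'
#' Emulates a quantification blot: a linear standard curve over known
#' protein amounts and sample lanes whose intensities correspond to a
#' chosen true molecules-per-cell, given the lysate fraction loaded and
#' cells represented.
#'
#' @param cfg a [syntheticConfig()]; its \code{noiseCv} applies
#'   multiplicatively to intensities (densitometry noise is small; 0.02
#'   is typical).
#' @param trueMoleculesPerCell ground-truth copy number (default 9600,
#'   the tolerated dCas9*_PhlF pool).
#' @param molarMass protein molar mass (g/mol; default 1.6e5, a
#'   dCas9-scale protein).
#' @param cellsRepresented cells in the lysate (default 5.6e8, ~700 ul of
#'   an OD 1 culture).
#' @param lysateFraction fraction of the lysate loaded per lane (default
#'   0.0375: 3 of 40 ul diluted 1:2, 10 of 20 ul loaded).
#' @param standardsNg known standard amounts per lane (ng).
#' @param slope,intercept true calibration line (au/ng, au).
#' @return list with \code{standards} (data.frame \code{amount_ng},
#'   \code{intensity}), \code{samples} (data.frame \code{sample_id},
#'   \code{intensity}, \code{lysate_fraction}, \code{cells_represented})
#'   and \code{truth} (list incl. \code{moleculesPerCell}).
#' @export
genBlotData <- function(cfg, trueMoleculesPerCell = 9600,
                        molarMass = 1.6e5, cellsRepresented = 5.6e8,
                        lysateFraction = 0.0375,
                        standardsNg = c(5, 20, 50, 80),
                        slope = 5, intercept = 2) {
  stopifnot(inherits(cfg, "SyntheticConfig"))
  set.seed(cfg$seed + 2L)
  standards <- data.frame(
    amount_ng = standardsNg,
    intensity = (slope * standardsNg + intercept) *
      noiseFactor(length(standardsNg), cfg$noiseCv))
  laneMolecules <- trueMoleculesPerCell * cellsRepresented * lysateFraction
  laneNg <- laneMolecules / 6.02214076e23 * molarMass * 1e9
  samples <- data.frame(
    sample_id = "sample1",
    intensity = (slope * laneNg + intercept) * noiseFactor(1, cfg$noiseCv),
    lysate_fraction = lysateFraction,
    cells_represented = cellsRepresented)
  list(standards = standards, samples = samples,
       truth = list(moleculesPerCell = trueMoleculesPerCell,
                    laneNg = laneNg, molarMass = molarMass,
                    slope = slope, intercept = intercept))
}

#' Generate flow-cytometry event samples with known ground truth
#'
#' Emulates log-normal fluorescence event clouds: a white-cell
#' (autofluorescence-only) background strain, an induced (repressed)
#' strain and an uninduced strain whose background-subtracted geometric
#' means differ by \code{trueFold}.
#'
#' @param cfg a [syntheticConfig()].
#' @param trueFold ground-truth fold-repression between uninduced and
#'   induced background-subtracted signals (default 50).
#' @param autofluorGM geometric mean of the autofluorescence (au).
#' @param inducedSignal background-subtracted geometric-mean signal of
#'   the induced (repressed) strain (au).
#' @param sdLog log-scale standard deviation of the event clouds.
#' @param nEvents events per sample.
#' @return list with \code{events} (data.frame \code{sample_id},
#'   \code{fluorescence}; samples \code{"background"}, \code{"induced"},
#'   \code{"uninduced"}) and \code{truth}.
#' @export
genEventSamples <- function(cfg, trueFold = 50, autofluorGM = 50,
                            inducedSignal = 100, sdLog = 0.8,
                            nEvents = 1e5) {
  stopifnot(inherits(cfg, "SyntheticConfig"))
  set.seed(cfg$seed + 3L)
  gms <- c(background = autofluorGM,
           induced = autofluorGM + inducedSignal,
           uninduced = autofluorGM + trueFold * inducedSignal)
  events <- do.call(rbind, lapply(names(gms), function(id) {
    data.frame(sample_id = id,
               fluorescence = stats::rlnorm(nEvents, meanlog = log(gms[[id]]),
                                            sdlog = sdLog))
  }))
  list(events = events,
       truth = list(trueFold = trueFold, autofluorGM = autofluorGM,
                    inducedSignal = inducedSignal, sdLog = sdLog))
}
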