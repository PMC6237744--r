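## argv-style dispatcher binding all stages, so the package can be driven
## from a thin Rscript wrapper (inst/scripts/crispr-circuits) or called
## directly with a character vector of arguments.

parseArgs <- function(args) {
  if (length(args) < 1L)
    stop("usage: <subcommand> [--key value ...]; subcommands: ",
         paste(names(pipelineStages), collapse = ", "))
  sub <- args[[1]]
  rest <- args[-1]
  opts <- list()
  i <- 1L
  while (i <= length(rest)) {
    key <- rest[[i]]
    if (!startsWith(key, "--"))
      stop("expected --option, got '", key, "'")
    if (i == length(rest) || startsWith(rest[[i + 1L]], "--"))
      stop("missing value for option '", key, "'")
    opts[[substring(key, 3L)]] <- rest[[i + 1L]]
    i <- i + 2L
  }
  list(subcommand = sub, opts = opts)
}

opt <- function(opts, name, default = NULL, numeric = FALSE) {
  v <- opts[[name]]
  if (is.null(v)) {
    if (is.null(default)) stop("required option --", name, " missing")
    return(default)
  }
  if (numeric) as.numeric(v) else v
}

writeProvenance <- function(outPath, cfg) {
  cfgJson <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA)
  tmp <- tempfile(); writeLines(cfgJson, tmp)
  prov <- list(config = cfg,
               config_md5 = unname(tools::md5sum(tmp)),
               package_version = as.character(
                 utils::packageVersion("crisprCircuits")),
               timestamp = format(Sys.time(), tz = "UTC"))
  unlink(tmp)
  jsonlite::write_json(prov, paste0(outPath, ".provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

pipelineStages <- list(
  `gen-data` = function(opts) {
    recipe <- opt(opts, "recipe")
    out <- opt(opts, "out")
    cfg <- syntheticConfig(seed = opt(opts, "seed", 1, numeric = TRUE),
                           noiseCv = opt(opts, "noise-cv", 0.1, numeric = TRUE),
                           nReplicates = opt(opts, "replicates", 3,
                                             numeric = TRUE))
    dir.create(out, showWarnings = FALSE, recursive = TRUE)
    switch(recipe,
      gates = {
        g <- genGateCurves(cfg)
        utils::write.csv(g$data, file.path(out, "gates.csv"),
                         row.names = FALSE)
        jsonlite::write_json(
          lapply(g$truth, function(rf)
            list(gate_id = rf@gateId, y_min = rf@yMin, y_max = rf@yMax,
                 K = rf@K, n = rf@n)),
          file.path(out, "gates_truth.json"),
          auto_unbox = TRUE, digits = NA, pretty = TRUE)
      },
      competition = {
        g <- genCompetitionData(cfg)
        utils::write.csv(g$data, file.path(out, "competition.csv"),
                         row.names = FALSE)
        writeSharingModel(g$truth, file.path(out, "competition_truth.json"))
      },
      blot = {
        g <- genBlotData(cfg)
        utils::write.csv(g$standards, file.path(out, "standards.csv"),
                         row.names = FALSE)
        utils::write.csv(g$samples, file.path(out, "lanes.csv"),
                         row.names = FALSE)
        jsonlite::write_json(g$truth, file.path(out, "blot_truth.json"),
                             auto_unbox = TRUE, digits = NA, pretty = TRUE)
      },
      events = {
        g <- genEventSamples(cfg)
        utils::write.csv(g$events, file.path(out, "events.csv"),
                         row.names = FALSE)
        jsonlite::write_json(g$truth, file.path(out, "events_truth.json"),
                             auto_unbox = TRUE, digits = NA, pretty = TRUE)
      },
      stop("unknown recipe '", recipe,
           "'; expected gates|competition|blot|events"))
    writeProvenance(file.path(out, recipe), c(recipe = recipe, cfg))
    out
  },
  `fit-gate` = function(opts) {
    data <- readGateCurves(opt(opts, "in"))
    rf <- fitHill(data, residualScale = opt(opts, "residual-scale", "log"))
    out <- opt(opts, "out")
    writeResponseFunction(rf, out)
    writeProvenance(out, list(stage = "fit-gate", input = opt(opts, "in")))
    out
  },
  `predict-cascade` = function(opts) {
    gates <- strsplit(opt(opts, "gates"), ",", fixed = TRUE)[[1]]
    transfer <- readMeasurementTable(opt(opts, "transfer"),
                                     tableSchemas$transfer)
    cc <- Cascade(lapply(gates, readResponseFunction), transfer)
    grid <- transfer$inducer
    out <- opt(opts, "out")
    utils::write.csv(predictCascadeCurve(cc, grid), out, row.names = FALSE)
    writeProvenance(out, list(stage = "predict-cascade", gates = gates))
    out
  },
  `fit-sharing` = function(opts) {
    data <- readCompetitionTable(opt(opts, "in"))
    fit <- fitSharing(data,
                      betaOverAlpha1 = opt(opts, "beta-over-alpha1",
                                           3.0e-11 / 7.6e-12, numeric = TRUE),
                      alpha1 = opt(opts, "fix-alpha1", 7.6e-12,
                                   numeric = TRUE),
                      kProm = opt(opts, "fix-kprom", 1.7e-8, numeric = TRUE))
    out <- opt(opts, "out")
    writeSharingModel(fit$model, out)
    writeProvenance(out, list(stage = "fit-sharing", input = opt(opts, "in")))
    out
  },
  simulate = function(opts) {
    model <- readSharingModel(opt(opts, "model"))
    alphas <- as.numeric(strsplit(opt(opts, "alphas"), ",",
                                  fixed = TRUE)[[1]])
    traj <- simulateSharing(model, alphas,
                            tEnd = opt(opts, "t-end", 1e5, numeric = TRUE))
    out <- opt(opts, "out")
    utils::write.csv(traj, out, row.names = FALSE)
    writeProvenance(out, list(stage = "simulate", alphas = alphas))
    out
  },
  `min-n` = function(opts) {
    model <- readSharingModel(opt(opts, "model"))
    n <- minSgRNAsBelowThreshold(model,
                                 opt(opts, "threshold", 10, numeric = TRUE))
    cat(n, "\n")
    n
  },
  `summarize-events` = function(opts) {
    events <- readMeasurementTable(opt(opts, "in"), tableSchemas$events)
    background <- if (!is.null(opts[["background"]]))
      readMeasurementTable(opts[["background"]],
                           tableSchemas$events)$fluorescence
    out <- opt(opts, "out")
    utils::write.csv(summarizeEvents(events, background), out,
                     row.names = FALSE)
    writeProvenance(out, list(stage = "summarize-events",
                              input = opt(opts, "in")))
    out
  },
  `quantify-blot` = function(opts) {
    standards <- readMeasurementTable(opt(opts, "standards"),
                                      tableSchemas$standards)
    samples <- readMeasurementTable(opt(opts, "samples"),
                                    tableSchemas$lanes)
    quant <- quantifyBlot(standards, samples,
                          molarMass = opt(opts, "molar-mass", numeric = TRUE))
    out <- opt(opts, "out")
    jsonlite::write_json(quant, out, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, dataframe = "rows")
    writeProvenance(out, list(stage = "quantify-blot"))
    out
  },
  `atp-cost` = function(opts) {
    ci <- costInputs(nAa = opt(opts, "n-aa", numeric = TRUE),
                     aaSynthesisNetCost = opt(opts, "aa-net-cost", 0,
                                              numeric = TRUE))
    res <- proteinAtpCost(ci)
    json <- jsonlite::toJSON(
      list(mrna_cost = res$mrnaCost, per_protein_mrna = res$perProteinMrna,
           translation = res$translation, total = res$total,
           total_rounded = res$totalRounded),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
    if (!is.null(opts[["out"]])) writeLines(json, opts[["out"]])
    else cat(json, "\n")
    res
  }
)

#' Run a pipeline stage from argv-style arguments
#'
#' Dispatches to the package's analysis stages:
#' \code{gen-data}, \code{fit-gate}, \code{predict-cascade},
#' \code{fit-sharing}, \code{simulate}, \code{min-n},
#' \code{summarize-events}, \code{quantify-blot}, \code{atp-cost}.
#' Every stage that writes a file also writes a
#' \code{*.provenance.json} record (config hash, seed, package version)
#' next to its output. Errors propagate with stage context.
#'
#' @param args character vector: subcommand followed by \code{--key
#'   value} pairs, e.g. \code{c("fit-gate", "--in", "curve.csv", "--out",
#'   "gate.json")}.
#' @return The stage's result, invisibly.
#' @examples
#' \dontrun{
#' runPipeline(c("gen-data", "--recipe", "gates", "--out", "data/",
#'               "--seed", "1", "--noise-cv", "0"))
#' }
#' @export
runPipeline <- function(args) {
  parsed <- parseArgs(args)
  stage <- pipelineStages[[parsed$subcommand]]
  if (is.null(stage))
    stop("unknown subcommand '", parsed$subcommand, "'; expected one of: ",
         paste(names(pipelineStages), collapse = ", "))
  res <- tryCatch(stage(parsed$opts),
                  error = function(e) stop("[", parsed$subcommand, "] ",
                                           conditionMessage(e),
                                           call. = FALSE))
  invisible(res)
}
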