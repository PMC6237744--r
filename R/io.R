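## Shared table/config readers and writers. CSV dialect: comma-separated,
## UTF-8, header row required, '.' decimal. JSON is pretty-printed with
## stable key order so outputs diff cleanly.

#' Read and validate a measurement table
#'
#' @param path CSV file path.
#' @param schema named character vector mapping required column names to
#'   types (\code{"numeric"}, \code{"integer"} or \code{"character"}).
#' @return data.frame with validated columns (extra columns preserved).
#' @section Errors:
#' Missing file, empty file ("no rows"), missing columns and
#' non-numeric cells in numeric columns are each reported by name.
#' @export
readMeasurementTable <- function(path, schema) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("no rows in ", path)
  missing <- setdiff(names(schema), names(df))
  if (length(missing))
    stop("missing column(s) in ", path, ": ", paste(missing, collapse = ", "))
  for (col in names(schema)) {
    v <- df[[col]]
    if (schema[[col]] %in% c("numeric", "integer")) {
      num <- suppressWarnings(as.numeric(v))
      if (any(is.na(num) & !is.na(v)))
        stop("non-numeric value(s) in column '", col, "' of ", path)
      if (any(is.na(num))) stop("missing value(s) in column '", col, "'")
      if (schema[[col]] == "integer" && any(num != round(num)))
        stop("non-integer value(s) in column '", col, "'")
      df[[col]] <- num
    } else df[[col]] <- as.character(v)
  }
  df
}

# column schemas for the pipeline's tabular formats
tableSchemas <- list(
  gate = c(gate_id = "character", input_activity = "numeric",
           output_activity = "numeric", replicate = "integer"),
  competition = c(N = "integer", fold_repression = "numeric",
                  replicate = "integer"),
  events = c(sample_id = "character", fluorescence = "numeric"),
  standards = c(amount_ng = "numeric", intensity = "numeric"),
  lanes = c(sample_id = "character", intensity = "numeric",
            lysate_fraction = "numeric", cells_represented = "numeric"),
  transfer = c(inducer = "numeric", activity = "numeric")
)

#' Read a gate response dataset
#'
#' @param path CSV with columns \code{gate_id}, \code{input_activity},
#'   \code{output_activity}, \code{replicate}.
#' @return Validated data.frame.
#' @export
readGateCurves <- function(path) {
  df <- readMeasurementTable(path, tableSchemas$gate)
  if (any(df$input_activity < 0)) stop("input_activity must be >= 0")
  if (any(!is.finite(df$output_activity))) stop("output_activity must be finite")
  df
}

#' Read a competition (fold versus N) dataset
#'
#' @param path CSV with columns \code{N}, \code{fold_repression},
#'   \code{replicate}.
#' @return Validated data.frame; fold values below 1 are flagged with a
#'   warning.
#' @export
readCompetitionTable <- function(path) {
  df <- readMeasurementTable(path, tableSchemas$competition)
  if (any(df$N < 0)) stop("competitor counts 'N' must be >= 0")
  if (any(df$fold_repression < 1))
    warning("fold_repression value(s) < 1 present; flagged for the fitter")
  df
}

#' Serialize a ResponseFunction to JSON
#'
#' @param rf a [ResponseFunction-class].
#' @param path output file.
#' @export
writeResponseFunction <- function(rf, path) {
  stopifnot(is(rf, "ResponseFunction"))
  obj <- list(gate_id = rf@gateId, y_min = rf@yMin, y_max = rf@yMax,
              K = rf@K, n = rf@n, diagnostics = rf@diagnostics)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a ResponseFunction from JSON
#'
#' @param path JSON written by [writeResponseFunction()].
#' @return A [ResponseFunction-class].
#' @export
readResponseFunction <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  ResponseFunction(yMin = obj$y_min, yMax = obj$y_max, K = obj$K, n = obj$n,
                   gateId = obj$gate_id %||% "",
                   diagnostics = as.list(obj$diagnostics))
}

#' Serialize a SharingModel to JSON
#'
#' Writes both the raw parameter block and the identifiable-combination
#' block.
#'
#' @param model a [SharingModel-class].
#' @param path output file.
#' @export
writeSharingModel <- function(model, path) {
  stopifnot(is(model, "SharingModel"))
  obj <- list(
    raw = list(c_tot = model@cTot, alpha_1 = model@alpha1,
               alpha_x = model@alphaX, beta = model@beta,
               k_prom = model@kProm, n_hill = model@nHill,
               k_on = model@kOn, k_off = model@kOff, delta_s = model@deltaS),
    identifiable = as.list(identifiableCombos(model)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' Read a SharingModel from JSON
#'
#' @param path JSON written by [writeSharingModel()].
#' @return A [SharingModel-class].
#' @export
readSharingModel <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)$raw
  SharingModel(cTot = raw$c_tot, alpha1 = raw$alpha_1, alphaX = raw$alpha_x,
               beta = raw$beta, kProm = raw$k_prom, nHill = raw$n_hill,
               kOn = raw$k_on %||% NA_real_, kOff = raw$k_off %||% NA_real_,
               deltaS = raw$delta_s %||% NA_real_)
}

#' Convert molecules per cell to a molar concentration
#'
#' Uses a configurable cell volume (default 1 fL, a standard E. coli
#' assumption that must be explicit because copy numbers alone carry no
#' volume): \code{conc = molecules / Avogadro / volume}.
#'
#' @param molecules molecules per cell.
#' @param cellVolumeL cell volume in litres (default 1e-15).
#' @return Concentration (M).
#' @examples
#' moleculesToMolar(9600)  # ~1.6e-5 M
#' @export
moleculesToMolar <- function(molecules, cellVolumeL = 1e-15) {
  if (cellVolumeL <= 0) stop("'cellVolumeL' must be > 0")
  molecules / 6.02214076e23 / cellVolumeL
}
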