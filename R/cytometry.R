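#' Geometric mean of a fluorescence event sample
#'
#' \code{exp(mean(log(events)))}, the summary statistic used for
#' log-normally distributed cytometry distributions. Flow data can
#' contain non-positive events after compensation; by policy these are
#' either dropped with a warning (default) or rejected.
#'
#' @param events numeric vector of fluorescence values (au).
#' @param nonPositive \code{"drop"} (default) or \code{"error"}.
#' @return Geometric mean (au), with attribute \code{"nDropped"}.
#' @examples
#' geometricMean(c(1, 100))  # 10
#' @export
geometricMean <- function(events, nonPositive = c("drop", "error")) {
  nonPositive <- match.arg(nonPositive)
  if (length(events) < 1L) stop("empty event sample")
  if (any(!is.finite(events))) stop("events must be finite")
  bad <- events <= 0
  if (any(bad)) {
    if (nonPositive == "error")
      stop(sum(bad), " non-positive event(s); geometric mean undefined")
    warning(sum(bad), " non-positive event(s) dropped")
    events <- events[!bad]
    if (length(events) == 0L) stop("no events remain after dropping non-positive values")
  }
  structure(exp(mean(log(events))), nDropped = sum(bad))
}

#' Subtract autofluorescence background
#'
#' Subtraction is performed on geometric means (not per event), matching
#' how white-cell autofluorescence is removed from sample summaries.
#' Negative results are clipped at \code{floor} with a warning.
#'
#' @param sampleGM geometric mean of the sample (au), \code{>= 0}.
#' @param autofluorGM geometric mean of the background strain (au).
#' @param floor clip value for negative differences (default 0).
#' @return Background-subtracted value (au) with attribute
#'   \code{"clipped"}.
#' @export
backgroundSubtract <- function(sampleGM, autofluorGM, floor = 0) {
  if (any(c(sampleGM, autofluorGM) < 0)) stop("geometric means must be >= 0")
  out <- sampleGM - autofluorGM
  clipped <- out < floor
  if (any(clipped)) {
    warning("background exceeds signal; clipped to floor")
    out[clipped] <- floor
  }
  structure(out, clipped = clipped)
}

#' Fold-repression from uninduced and induced fluorescence
#'
#' The uninduced divided by the induced background-subtracted value.
#'
#' @param uninduced,induced background-subtracted fluorescence (au).
#' @return Fold-repression (dimensionless).
#' @export
foldRepression <- function(uninduced, induced) {
  if (any(induced <= 0))
    stop("induced fluorescence below detection; fold-repression undefined")
  if (any(uninduced < 0)) stop("uninduced fluorescence must be >= 0")
  as.numeric(uninduced) / as.numeric(induced)
}

#' Fold-change with and without an sgRNA plasmid
#'
#' Repression of a promoter quantified as fluorescence without the
#' sgRNA-expressing plasmid divided by fluorescence with it.
#'
#' @param withoutSgRNA,withSgRNA fluorescence values (au), \code{> 0}.
#' @return Fold-change (dimensionless).
#' @export
sgRNAFoldChange <- function(withoutSgRNA, withSgRNA) {
  if (any(withSgRNA <= 0))
    stop("fluorescence with sgRNA below detection; fold-change undefined")
  if (any(withoutSgRNA <= 0)) stop("fluorescence values must be > 0")
  as.numeric(withoutSgRNA) / as.numeric(withSgRNA)
}

#' Summarize event samples against a background strain
#'
#' Computes per-sample geometric means and background-subtracted values
#' from long-format event tables.
#'
#' @param events data.frame with columns \code{sample_id},
#'   \code{fluorescence}.
#' @param background optional numeric vector of background-strain events
#'   (white cells); when given, its geometric mean is subtracted.
#' @param nonPositive policy for non-positive events, see
#'   [geometricMean()].
#' @return data.frame with columns \code{sample_id}, \code{gm},
#'   \code{gm_bg_subtracted}, \code{n_events}, \code{n_dropped}.
#' @export
summarizeEvents <- function(events, background = NULL,
                            nonPositive = c("drop", "error")) {
  nonPositive <- match.arg(nonPositive)
  stopifnot(is.data.frame(events),
            all(c("sample_id", "fluorescence") %in% names(events)))
  bgGM <- if (is.null(background)) 0
          else as.numeric(geometricMean(background, nonPositive))
  ids <- unique(as.character(events$sample_id))
  do.call(rbind, lapply(ids, function(id) {
    ev <- events$fluorescence[events$sample_id == id]
    gm <- geometricMean(ev, nonPositive)
    data.frame(sample_id = id, gm = as.numeric(gm),
               gm_bg_subtracted = as.numeric(
                 suppressWarnings(backgroundSubtract(as.numeric(gm), bgGM))),
               n_events = length(ev), n_dropped = attr(gm, "nDropped"))
  }))
}
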