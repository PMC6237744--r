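#' ATP cost inputs for a regulator protein
#'
#' Bundles the bookkeeping terms of the per-protein ATP budget. The codon
#' count is taken as the protein length in amino acids (the stop codon
#' and untranslated regions are neglected), the convention under which
#' a 207-residue repressor gives a 207 * 6 = 1242 ATP mRNA.
#'
#' @param nAa protein length in amino acids, \code{> 0}.
#' @param mrnaCostPerCodon ATP per codon of mRNA synthesis (default 6).
#' @param proteinsPerMrna proteins translated per mRNA before decay
#'   (default 30).
#' @param translationCostPerAa ATP per peptide bond (default 4).
#' @param aaSynthesisNetCost signed net ATP of synthesizing the amino
#'   acids (negative = net ATP gain); supply directly or compute with
#'   [aaNetCostFromComposition()].
#' @return A validated list of class \code{"CostInputs"}.
#' @export
costInputs <- function(nAa, mrnaCostPerCodon = 6, proteinsPerMrna = 30,
                       translationCostPerAa = 4, aaSynthesisNetCost = 0) {
  if (nAa <= 0 || nAa != round(nAa)) stop("'nAa' must be a positive integer")
  if (proteinsPerMrna <= 0) stop("'proteinsPerMrna' must be > 0")
  if (mrnaCostPerCodon < 0 || translationCostPerAa < 0)
    stop("per-unit costs must be >= 0")
  structure(list(nAa = nAa, mrnaCostPerCodon = mrnaCostPerCodon,
                 proteinsPerMrna = proteinsPerMrna,
                 translationCostPerAa = translationCostPerAa,
                 aaSynthesisNetCost = aaSynthesisNetCost),
            class = "CostInputs")
}

#' ATP cost of the mRNA
#'
#' \code{nAa * mrnaCostPerCodon}: transcription cost of the message,
#' counting one codon per residue.
#'
#' @param inputs a \code{CostInputs} (see [costInputs()]).
#' @return ATP count.
#' @examples
#' mrnaCost(costInputs(207))  # 1242 ATP
#' @export
mrnaCost <- function(inputs) {
  stopifnot(inherits(inputs, "CostInputs"))
  inputs$nAa * inputs$mrnaCostPerCodon
}

#' Total ATP cost per protein
#'
#' Sums the amortized transcription share, the amino-acid synthesis net
#' cost, and the translation cost:
#' \code{mrnaCost/proteinsPerMrna + aaSynthesisNetCost +
#' translationCostPerAa * nAa}. Full precision is carried internally; the
#' rounded total is reported alongside. \code{roundIntermediates = TRUE}
#' rounds the per-protein mRNA share to the nearest integer first, which
#' reproduces display-rounded worked examples (e.g. 1242/30 shown as 41).
#'
#' @param inputs a \code{CostInputs} (see [costInputs()]).
#' @param roundIntermediates round the mRNA share before summing.
#' @return list with \code{mrnaCost}, \code{perProteinMrna},
#'   \code{translation}, \code{aaSynthesis}, \code{total} (full
#'   precision) and \code{totalRounded}.
#' @examples
#' # TetR: 207 aa, amino-acid synthesis nets -307 ATP
#' protein_atp <- proteinAtpCost(costInputs(207, aaSynthesisNetCost = -307))
#' protein_atp$totalRounded  # 562 ATP
#' @export
proteinAtpCost <- function(inputs, roundIntermediates = FALSE) {
  stopifnot(inherits(inputs, "CostInputs"))
  m <- mrnaCost(inputs)
  share <- m / inputs$proteinsPerMrna
  if (roundIntermediates) share <- round(share)
  transl <- inputs$translationCostPerAa * inputs$nAa
  total <- share + inputs$aaSynthesisNetCost + transl
  list(mrnaCost = m, perProteinMrna = share, translation = transl,
       aaSynthesis = inputs$aaSynthesisNetCost,
       total = total, totalRounded = round(total))
}

#' Net amino-acid synthesis cost from a composition
#'
#' Sums \code{count * perResidueCost} over an amino-acid composition.
#' Per-residue net costs are signed: residues whose synthesis pathway
#' yields ATP contribute negatively.
#'
#' @param composition named numeric vector of residue counts
#'   (non-negative), names are residue codes.
#' @param costTable named numeric vector of signed per-residue net ATP
#'   costs covering every residue in \code{composition}.
#' @return Signed ATP count.
#' @examples
#' aaNetCostFromComposition(c(A = 2), c(A = -1.5))  # -3
#' @export
aaNetCostFromComposition <- function(composition, costTable) {
  if (length(composition) == 0L) return(0)
  if (is.null(names(composition)) || is.null(names(costTable)))
    stop("composition and cost table must be named by residue")
  if (any(composition < 0)) stop("residue counts must be >= 0")
  missing <- setdiff(names(composition), names(costTable))
  if (length(missing))
    stop("residue(s) missing from cost table: ",
         paste(missing, collapse = ", "))
  sum(composition * costTable[names(composition)])
}
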