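#' SnpPanel: a tiered pigmentation SNP marker panel
#'
#' Holds the marker panel as one row per SNP with its dbSNP identifier,
#' GRCh38 coordinates, allele pair, the effect allele counted in dosages,
#' variant class, selection tier (\code{candidate} < \code{associated} <
#' \code{final}), prediction rank (final tier only), and the association
#' statistics recorded for the panel (squared partial correlation with the
#' ordinal skin colour scale and its p value, plus an auxiliary fitted-glm
#' coefficient kept as metadata only).
#'
#' Tiers are nested: every final-tier SNP is also associated, and every
#' associated SNP is also a candidate. A row's \code{tier} records the
#' deepest tier the SNP reached.
#'
#' @slot snps data.frame with columns \code{rsid}, \code{chrom},
#'   \code{position}, \code{locus}, \code{allele1}, \code{allele2},
#'   \code{effect_allele}, \code{variant_class}, \code{tier}, \code{rank},
#'   \code{assoc_r2}, \code{assoc_p}, \code{glm_coefficient},
#'   \code{synonyms}.
#' @slot provenance free-text note on where the panel content came from.
#'
#' @seealso [loadPanel()], [skinPanel()], [subsetTier()]
#' @exportClass SnpPanel
setClass("SnpPanel",
  slots = c(snps = "data.frame", provenance = "character"))

panelColumns <- c("rsid", "chrom", "position", "locus", "allele1", "allele2",
                  "effect_allele", "variant_class", "tier", "rank",
                  "assoc_r2", "assoc_p", "glm_coefficient", "synonyms")

panelTiers <- c("candidate", "associated", "final")

setValidity("SnpPanel", function(object) {
  df <- object@snps
  msgs <- character(0)
  missing <- setdiff(panelColumns, names(df))
  if (length(missing))
    return(paste("missing panel columns:", paste(missing, collapse = ", ")))
  if (anyDuplicated(df$rsid))
    msgs <- c(msgs, paste0("duplicate rsid: ",
      paste(unique(df$rsid[duplicated(df$rsid)]), collapse = ", ")))
  if (nrow(df)) {
    if (!all(df$tier %in% panelTiers))
      msgs <- c(msgs, "tier must be candidate, associated or final")
    bad <- df$rsid[df$effect_allele != df$allele1 &
                   df$effect_allele != df$allele2]
    if (length(bad))
      msgs <- c(msgs, paste0("effect allele not among alleles for: ",
                             paste(bad, collapse = ", ")))
    if (any(!is.finite(df$position) | df$position <= 0))
      msgs <- c(msgs, "position must be a positive integer")
    rankPresent <- !is.na(df$rank)
    wrong <- xor(rankPresent, df$tier == "final")
    if (any(wrong))
      msgs <- c(msgs, paste0(
        "rank must be present exactly for final-tier SNPs; offending: ",
        paste(df$rsid[wrong], collapse = ", ")))
    ranks <- df$rank[rankPresent]
    if (length(ranks) && !identical(sort(as.integer(ranks)),
                                    seq_len(length(ranks))))
      msgs <- c(msgs, "final-tier ranks are not a permutation of 1..n_final")
  }
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' SkinGenotypes: effect-allele dosages with sample metadata
#'
#' A \linkS4class{SummarizedExperiment} whose single assay \code{"dosage"}
#' stores the count of panel effect alleles per (SNP, sample) cell: 0, 1, 2
#' or \code{NA} for a missing genotype. Rows are SNPs (rsid rownames),
#' columns are samples; \code{colData} carries per-sample metadata
#' (\code{sex}, \code{population}, optional \code{fitzpatrick} skin type
#' 1-6 and \code{lab_L} CIE L* lightness).
#'
#' @seealso [readDosageCsv()], [readGenotypeVcf()], [completeCaseFilter()]
#' @exportClass SkinGenotypes
setClass("SkinGenotypes", contains = "SummarizedExperiment")

setValidity("SkinGenotypes", function(object) {
  if (!"dosage" %in% SummarizedExperiment::assayNames(object))
    return("assay 'dosage' is required")
  d <- SummarizedExperiment::assay(object, "dosage")
  ok <- is.na(d) | d == 0 | d == 1 | d == 2
  if (!all(ok))
    return("dosages must be 0, 1, 2 or NA")
  if (is.null(rownames(object)) && nrow(object) > 0)
    return("SNP rownames (rsids) are required")
  if (is.null(colnames(object)) && ncol(object) > 0)
    return("sample colnames are required")
  if (anyDuplicated(colnames(object)))
    return("duplicate sample identifiers")
  TRUE
})

#' SkinColourModel: multinomial logistic regression over skin colour
#'
#' Parameterizes K ordered skin colour categories by K-1 linear predictors
#' against a reference category. For non-reference category m the predicted
#' probability of a dosage vector x is
#' \deqn{\pi_m = \exp(\alpha_m + \beta_m' x) / (1 + \sum_{m'} \exp(\alpha_{m'} + \beta_{m'}' x))}
#' and the reference category receives the remaining mass.
#'
#' @slot categories ordered character vector of category labels (K >= 2);
#'   the order encodes lightness descending and fixes tie-breaking.
#' @slot reference index into \code{categories} of the reference category.
#' @slot snpIds rsids of the k SNP predictors, in model column order.
#' @slot intercepts named numeric, one alpha per non-reference category.
#' @slot coefficients (K-1) x k numeric matrix of betas; rows named by
#'   non-reference category, columns by rsid.
#' @slot fit list of fitting diagnostics (log-likelihood, convergence,
#'   iterations, standard errors, n); empty for hand-constructed models.
#'
#' @seealso [fitMlr()], [predictProbabilities()], [skinModel()]
#' @exportClass SkinColourModel
setClass("SkinColourModel",
  slots = c(categories = "character", reference = "integer",
            snpIds = "character", intercepts = "numeric",
            coefficients = "matrix", fit = "list"))

setValidity("SkinColourModel", function(object) {
  K <- length(object@categories)
  k <- length(object@snpIds)
  msgs <- character(0)
  if (K < 2) msgs <- c(msgs, "at least two categories required")
  if (anyDuplicated(object@categories))
    msgs <- c(msgs, "duplicate category labels")
  if (length(object@reference) != 1L || is.na(object@reference) ||
      object@reference < 1L || object@reference > K)
    msgs <- c(msgs, "reference must index one category")
  if (anyDuplicated(object@snpIds)) msgs <- c(msgs, "duplicate snp ids")
  if (length(object@intercepts) != K - 1L)
    msgs <- c(msgs, "need exactly K-1 intercepts")
  if (!identical(dim(object@coefficients), c(K - 1L, k)))
    msgs <- c(msgs, "coefficients must be a (K-1) x k matrix")
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})
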