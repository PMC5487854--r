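#' @rdname SnpPanel-class
#' @param snps data.frame of panel rows (see \linkS4class{SnpPanel}).
#' @param provenance free-text source note.
#' @export
SnpPanel <- function(snps, provenance = "unspecified") {
  snps$rank <- as.integer(snps$rank)
  snps$position <- as.integer(snps$position)
  rownames(snps) <- NULL
  methods::new("SnpPanel", snps = snps, provenance = provenance)
}

#' @describeIn SnpPanel-class data.frame of SNP definitions.
#' @param x,object a \code{SnpPanel}.
#' @export
panelSnps <- function(x) x@snps

#' @describeIn SnpPanel-class provenance note.
#' @export
panelProvenance <- function(x) x@provenance

#' @describeIn SnpPanel-class rsids in panel order.
#' @export
panelRsids <- function(x) x@snps$rsid

setMethod("show", "SnpPanel", function(object) {
  df <- object@snps
  cat("SnpPanel with", nrow(df), "SNPs\n")
  for (t in panelTiers)
    cat(sprintf("  %-10s %d\n", t, sum(tierDepth(df$tier) >= tierDepth(t))))
  cat("provenance:", object@provenance, "\n")
})

## internal: tier label -> nesting depth
tierDepth <- function(tier) match(tier, panelTiers)

#' Construct a SkinGenotypes object
#'
#' @param dosage numeric matrix of effect-allele dosages with SNPs as rows
#'   (rsid rownames) and samples as columns, values in \{0, 1, 2, NA\}.
#' @param sampleData optional data.frame/DataFrame of per-sample metadata,
#'   one row per sample (columns such as \code{sex}, \code{population},
#'   \code{fitzpatrick}, \code{lab_L}).
#' @param snpData optional data.frame of per-SNP annotation.
#' @return A \linkS4class{SkinGenotypes}.
#' @examples
#' d <- matrix(c(0, 1, 2, NA), nrow = 2,
#'             dimnames = list(c("rs1", "rs2"), c("s1", "s2")))
#' SkinGenotypes(d)
#' @export
SkinGenotypes <- function(dosage, sampleData = NULL, snpData = NULL) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "double"
  args <- list(assays = S4Vectors::SimpleList(dosage = dosage))
  if (!is.null(sampleData)) args$colData <- S4Vectors::DataFrame(sampleData)
  if (!is.null(snpData)) args$rowData <- S4Vectors::DataFrame(snpData)
  se <- do.call(SummarizedExperiment::SummarizedExperiment, args)
  methods::new("SkinGenotypes", se)
}

#' @describeIn SkinGenotypes dosage matrix, SNPs x samples.
#' @param x a \code{SkinGenotypes}.
#' @export
dosageMatrix <- function(x) SummarizedExperiment::assay(x, "dosage")

#' @describeIn SkinGenotypes dosage matrix transposed to samples x SNPs,
#'   the orientation used by the model-fitting functions.
#' @export
sampleDosages <- function(x) t(SummarizedExperiment::assay(x, "dosage"))

#' @describeIn SkinGenotypes per-sample metadata as a data.frame.
#' @export
sampleMetadata <- function(x) {
  as.data.frame(SummarizedExperiment::colData(x))
}

setMethod("show", "SkinGenotypes", function(object) {
  d <- dosageMatrix(object)
  cat("SkinGenotypes:", nrow(d), "SNPs x", ncol(d), "samples;",
      sum(is.na(d)), "missing dosages\n")
  if (ncol(SummarizedExperiment::colData(object)))
    cat("sample metadata:",
        paste(names(SummarizedExperiment::colData(object)), collapse = ", "),
        "\n")
})

#' Construct a SkinColourModel
#'
#' @param categories ordered category labels (lightness descending).
#' @param intercepts numeric vector of K-1 intercepts for the non-reference
#'   categories, in category order.
#' @param coefficients (K-1) x k matrix of per-SNP betas (columns named by
#'   rsid) or, for an intercept-only model, a 0-column matrix.
#' @param reference reference category label; defaults to the first.
#' @param snpIds rsids of the predictors; defaults to
#'   \code{colnames(coefficients)}.
#' @param fit optional list of fit diagnostics.
#' @return A \linkS4class{SkinColourModel}.
#' @examples
#' skinModel(c("Light", "Dark"), intercepts = 0,
#'           coefficients = matrix(log(3), 1, 1,
#'                                 dimnames = list("Dark", "rs1426654")))
#' @export
skinModel <- function(categories, intercepts, coefficients,
                      reference = categories[1L], snpIds = NULL,
                      fit = list()) {
  coefficients <- as.matrix(coefficients)
  if (is.null(snpIds)) snpIds <- colnames(coefficients)
  if (is.null(snpIds)) snpIds <- character(0)
  ref <- match(reference, categories)
  if (is.na(ref)) stop("reference category not among categories")
  nonRef <- categories[-ref]
  intercepts <- stats::setNames(as.numeric(intercepts), nonRef)
  dimnames(coefficients) <- list(nonRef,
                                 if (ncol(coefficients)) snpIds else NULL)
  methods::new("SkinColourModel", categories = categories,
               reference = as.integer(ref), snpIds = as.character(snpIds),
               intercepts = intercepts, coefficients = coefficients,
               fit = fit)
}

#' @describeIn skinModel ordered category labels.
#' @param model a \code{SkinColourModel}.
#' @export
modelCategories <- function(model) model@categories

#' @describeIn skinModel label of the reference category.
#' @export
referenceCategory <- function(model) model@categories[model@reference]

#' @describeIn skinModel rsids of the SNP predictors.
#' @export
modelSnpIds <- function(model) model@snpIds

#' @describeIn skinModel named intercept vector (non-reference categories).
#' @export
modelIntercepts <- function(model) model@intercepts

#' @describeIn skinModel (K-1) x k beta matrix.
#' @export
modelCoefficients <- function(model) model@coefficients

#' @describeIn skinModel fit diagnostics list (empty unless fitted).
#' @export
fitDetails <- function(model) model@fit

setMethod("show", "SkinColourModel", function(object) {
  cat("SkinColourModel:", length(object@categories), "categories (",
      paste(object@categories, collapse = " > "), "), reference",
      referenceCategory(object), "\n")
  cat(length(object@snpIds), "SNP predictors\n")
  if (length(object@fit))
    cat(sprintf("fitted: logLik %.3f, converged %s (%d iterations), n = %d\n",
                object@fit$logLik, object@fit$converged,
                object@fit$iterations, object@fit$n))
})
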