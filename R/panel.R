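#' Load a SNP panel from its tab-separated file
#'
#' Reads the canonical panel dialect: one header line naming the columns
#' \code{rsid, chrom, position_grch38, locus, allele1, allele2,
#' effect_allele, variant_class, tier, rank, assoc_r2, assoc_p,
#' glm_coefficient, synonyms}, one row per SNP, tab-separated, with absent
#' optional values encoded as \code{"."}. All panel invariants are checked
#' on load; violations raise errors naming the offending rsid.
#'
#' @param path path to a panel TSV file.
#' @param provenance provenance note to record; defaults to the file path.
#' @return A validated \linkS4class{SnpPanel}.
#' @examples
#' panel <- skinPanel()
#' nrow(panelSnps(panel))  # 77 candidate SNPs
#' @export
loadPanel <- function(path, provenance = path) {
  if (!file.exists(path)) stop("panel file not found: ", path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character", check.names = FALSE,
                          na.strings = NULL, quote = "")
  fileCols <- c("rsid", "chrom", "position_grch38", "locus", "allele1",
                "allele2", "effect_allele", "variant_class", "tier", "rank",
                "assoc_r2", "assoc_p", "glm_coefficient", "synonyms")
  if (!identical(names(df), fileCols))
    stop("malformed panel header; expected columns: ",
         paste(fileCols, collapse = ", "))
  if (nrow(df) == 0L) stop("no panel entries")
  dot <- function(x) ifelse(x == ".", NA, x)
  num <- function(x) suppressWarnings(as.numeric(dot(x)))
  snps <- data.frame(
    rsid = df$rsid,
    chrom = df$chrom,
    position = suppressWarnings(as.integer(dot(df$position_grch38))),
    locus = df$locus,
    allele1 = df$allele1,
    allele2 = df$allele2,
    effect_allele = df$effect_allele,
    variant_class = df$variant_class,
    tier = df$tier,
    rank = suppressWarnings(as.integer(dot(df$rank))),
    assoc_r2 = num(df$assoc_r2),
    assoc_p = num(df$assoc_p),
    glm_coefficient = num(df$glm_coefficient),
    synonyms = dot(df$synonyms),
    stringsAsFactors = FALSE)
  badRank <- !is.na(snps$rank) & (snps$rank < 1L | snps$rank > nrow(snps))
  if (any(badRank))
    stop("rank out of range for: ", paste(snps$rsid[badRank], collapse = ", "))
  SnpPanel(snps, provenance = provenance)
}

#' Write a SNP panel in the canonical dialect
#'
#' Inverse of [loadPanel()]: writing a freshly loaded canonical panel file
#' reproduces it byte-identically.
#'
#' @param panel a \linkS4class{SnpPanel}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writePanel <- function(panel, path) {
  df <- panelSnps(panel)
  chr <- function(x) ifelse(is.na(x), ".", as.character(x))
  out <- data.frame(
    rsid = df$rsid, chrom = df$chrom,
    position_grch38 = chr(df$position), locus = df$locus,
    allele1 = df$allele1, allele2 = df$allele2,
    effect_allele = df$effect_allele, variant_class = df$variant_class,
    tier = df$tier, rank = chr(df$rank),
    assoc_r2 = formatPanelNumber(df$assoc_r2),
    assoc_p = formatPanelNumber(df$assoc_p),
    glm_coefficient = formatPanelNumber(df$glm_coefficient),
    synonyms = chr(df$synonyms),
    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = ".")
  invisible(path)
}

#' The packaged pigmentation SNP panel
#'
#' Loads the panel shipped with the package: 77 candidate pigmentation SNPs,
#' of which 53 passed the sex- and population-adjusted association filter
#' (associated tier) and 36 form the final prediction model (final tier,
#' ranked 1-36 by predictive contribution, spanning 16 gene labels).
#'
#' @return A \linkS4class{SnpPanel}.
#' @examples
#' subsetTier(skinPanel(), "final")
#' @export
skinPanel <- function() {
  loadPanel(system.file("extdata", "skin_colour_panel.tsv",
                        package = "skintyper", mustWork = TRUE),
            provenance = "packaged pigmentation panel (77/53/36 tiers)")
}

#' Subset a panel to a selection tier
#'
#' Returns the SNPs at or above the requested tier: \code{candidate} keeps
#' all rows, \code{associated} those that passed the association filter, and
#' \code{final} the ranked prediction-model SNPs (ordered by rank
#' ascending). Other tiers keep panel order.
#'
#' @param panel a \linkS4class{SnpPanel}.
#' @param tier one of \code{"candidate"}, \code{"associated"},
#'   \code{"final"}.
#' @return A \linkS4class{SnpPanel} restricted to the tier.
#' @examples
#' nrow(panelSnps(subsetTier(skinPanel(), "associated")))  # 53
#' @export
subsetTier <- function(panel, tier) {
  if (length(tier) != 1L || !tier %in% panelTiers)
    stop("unknown tier label: ", paste(tier, collapse = ", "))
  df <- panelSnps(panel)
  keep <- tierDepth(df$tier) >= tierDepth(tier)
  df <- df[keep, , drop = FALSE]
  if (tier == "final") df <- df[order(df$rank), , drop = FALSE]
  SnpPanel(df, provenance = paste0(panelProvenance(panel), " [", tier, "]"))
}

#' Count distinct locus labels in a panel
#'
#' Number of distinct gene / locus labels among the panel's SNPs. Intergenic
#' and missing (\code{NA}) labels each count as their own literal label.
#'
#' @param panel a non-empty \linkS4class{SnpPanel}.
#' @return integer count of distinct labels.
#' @examples
#' countDistinctLoci(subsetTier(skinPanel(), "final"))  # 16 genes
#' @export
countDistinctLoci <- function(panel) {
  df <- panelSnps(panel)
  if (nrow(df) == 0L) stop("panel is empty")
  length(unique(df$locus))
}
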