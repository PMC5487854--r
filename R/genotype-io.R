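## Genotype input/output: effect-allele dosage CSV, VCF extraction with
## allele reconciliation, sample metadata CSV, complete-case filtering.

## internal: accept a SnpPanel or a plain rsid vector wherever a panel is
## expected; returns the rsids defining column order.
panelIds <- function(panel) {
  if (methods::is(panel, "SnpPanel")) panelRsids(panel) else as.character(panel)
}

#' Read effect-allele dosages from CSV
#'
#' Expects a \code{sample_id} column plus one column per panel rsid with
#' cells in \{0, 1, 2, NA\} (empty cells also count as missing). Columns
#' not in the panel are dropped, each with a warning; the result is aligned
#' to panel order (restricted to the rsids present in the file).
#'
#' @param path CSV path.
#' @param panel a \linkS4class{SnpPanel} or character vector of rsids.
#' @return A \linkS4class{SkinGenotypes}.
#' @export
readDosageCsv <- function(path, panel) {
  ids <- panelIds(panel)
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  if (!"sample_id" %in% names(df))
    stop("dosage CSV needs a sample_id column")
  samples <- df$sample_id
  if (anyDuplicated(samples))
    stop("duplicate sample IDs: ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "))
  snpCols <- setdiff(names(df), "sample_id")
  extra <- setdiff(snpCols, ids)
  for (colName in extra)
    warning("ignoring column not in panel: ", colName, call. = FALSE)
  keep <- ids[ids %in% snpCols]
  if (!length(keep)) stop("no panel SNP columns found in ", path)
  d <- matrix(NA_real_, length(keep), length(samples),
              dimnames = list(keep, samples))
  for (rs in keep) {
    cell <- df[[rs]]
    cell[cell == ""] <- NA
    val <- suppressWarnings(as.numeric(cell))
    bad <- which(!is.na(cell) & (is.na(val) | !val %in% c(0, 1, 2)))
    if (length(bad))
      stop(sprintf("invalid dosage '%s' for sample %s at %s",
                   cell[bad[1]], samples[bad[1]], rs))
    d[rs, ] <- val
  }
  SkinGenotypes(d)
}

#' Write effect-allele dosages to CSV
#'
#' Inverse of [readDosageCsv()]; missing dosages are written as \code{NA}.
#'
#' @param genotypes a \linkS4class{SkinGenotypes}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeDosageCsv <- function(genotypes, path) {
  d <- t(dosageMatrix(genotypes))
  out <- data.frame(sample_id = rownames(d), check.names = FALSE)
  for (rs in colnames(d)) out[[rs]] <- d[, rs]
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}

## internal: DNA complement for strand-flip checks (SNV alleles only)
flipAllele <- function(a) {
  map <- c(A = "T", C = "G", G = "C", T = "A")
  out <- map[a]
  ifelse(is.na(out), a, out)
}

## internal: is the allele pair strand-ambiguous (A/T or C/G)?
isAmbiguousPair <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
  (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

#' Read panel genotypes from a VCF file
#'
#' Extracts effect-allele dosages for the panel SNPs from VCF GT fields.
#' Records are matched to panel SNPs by rsid (the VCF ID column) and,
#' failing that, by (chromosome, position); the \code{chr} prefix is
#' ignored when comparing chromosomes.
#'
#' Allele reconciliation per record: an exact REF/ALT match against the
#' panel allele pair is used directly; a swapped match (panel effect allele
#' equals REF) counts reference alleles instead, which complements the
#' dosage; a strand-flipped match is accepted only for non-ambiguous SNVs.
#' Strand-ambiguous pairs (A/T, C/G) must match exactly or the SNP is set
#' missing with a warning, as are records with irreconcilable alleles.
#' Genotypes containing an allele outside the panel pair, half-calls, and
#' \code{./.} are missing. Panel SNPs absent from the file become
#' all-missing columns (with a warning).
#'
#' @param path VCF (4.x) path; plain text or bgzipped.
#' @param panel a \linkS4class{SnpPanel} (alleles are required, so a bare
#'   rsid vector is not enough here).
#' @return A \linkS4class{SkinGenotypes} aligned to panel order.
#' @export
readGenotypeVcf <- function(path, panel) {
  if (!methods::is(panel, "SnpPanel"))
    stop("readGenotypeVcf needs a SnpPanel (allele information required)")
  if (!file.exists(path)) stop("unreadable VCF: ", path)
  vcf <- VariantAnnotation::readVcf(path, genome = "GRCh38")
  gt <- VariantAnnotation::geno(vcf)$GT
  if (is.null(gt)) stop("VCF has no GT genotypes: ", path)
  rr <- SummarizedExperiment::rowRanges(vcf)
  vcfIds <- names(rr)
  vcfChrom <- sub("^chr", "", as.character(GenomicRanges::seqnames(rr)))
  vcfPos <- GenomicRanges::start(rr)
  refAll <- as.character(VariantAnnotation::ref(vcf))
  altList <- VariantAnnotation::alt(vcf)

  df <- panelSnps(panel)
  samples <- colnames(gt)
  d <- matrix(NA_real_, nrow(df), length(samples),
              dimnames = list(df$rsid, samples))

  for (i in seq_len(nrow(df))) {
    rs <- df$rsid[i]
    hit <- which(vcfIds == rs)
    if (!length(hit))
      hit <- which(vcfChrom == sub("^chr", "", df$chrom[i]) &
                   vcfPos == df$position[i])
    if (!length(hit)) {
      warning("panel SNP ", rs, " not found in VCF; set missing",
              call. = FALSE)
      next
    }
    hit <- hit[1]
    ref <- refAll[hit]
    alts <- as.character(altList[[hit]])
    rec <- c(ref, alts)                       # VCF allele codes 0, 1, 2, ...
    pair <- c(df$allele1[i], df$allele2[i])
    eff <- df$effect_allele[i]
    isSnv <- df$variant_class[i] == "SNV"

    match_codes <- function(alleles, effect) {
      # 0-based codes of the panel pair among this record's alleles
      list(codes = match(alleles, rec) - 1L,
           effCode = match(effect, rec) - 1L)
    }
    rc <- NULL
    if (all(pair %in% rec)) {
      rc <- match_codes(pair, eff)            # exact (or swapped) match
    } else if (isSnv && !isAmbiguousPair(df$allele1[i], df$allele2[i]) &&
               all(flipAllele(pair) %in% rec)) {
      rc <- match_codes(flipAllele(pair), flipAllele(eff))
    }
    if (is.null(rc)) {
      warning("irreconcilable alleles for ", rs, " (VCF ",
              paste(rec, collapse = "/"), " vs panel ",
              paste(pair, collapse = "/"), "); set missing", call. = FALSE)
      next
    }
    codes <- strsplit(gt[hit, ], "[/|]")
    d[rs, ] <- vapply(codes, function(cc) {
      if (length(cc) != 2L || any(cc == ".")) return(NA_real_)
      cc <- suppressWarnings(as.integer(cc))
      if (anyNA(cc)) return(NA_real_)
      if (!all(cc %in% rc$codes)) return(NA_real_)  # non-panel allele
      sum(cc == rc$effCode)
    }, numeric(1))
  }
  SkinGenotypes(d)
}

#' Keep only samples with complete genotypes
#'
#' Retains exactly the samples with no missing dosage over \code{snpIds}
#' (default: all panel SNPs in the object), preserving sample order. This
#' is the complete-genotype rule required before model fitting and marker
#' selection; it is idempotent and may return an empty object.
#'
#' @param genotypes a \linkS4class{SkinGenotypes}.
#' @param snpIds rsids over which completeness is required.
#' @return The filtered \linkS4class{SkinGenotypes}.
#' @export
completeCaseFilter <- function(genotypes, snpIds = rownames(genotypes)) {
  missingSnps <- setdiff(snpIds, rownames(genotypes))
  if (length(missingSnps))
    stop("snpIds not in genotypes: ", paste(missingSnps, collapse = ", "))
  d <- dosageMatrix(genotypes)[snpIds, , drop = FALSE]
  keep <- colSums(is.na(d)) == 0L
  genotypes[, keep]
}

#' Read and write sample metadata CSV
#'
#' Columns: \code{sample_id}, \code{sex} (male/female/unknown),
#' \code{population}, \code{fitzpatrick} (integer 1-6 or NA),
#' \code{lab_L} (CIE L* in (0,100) or NA).
#'
#' @param path CSV path.
#' @return data.frame of validated metadata.
#' @export
readSampleMetadata <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE,
                        colClasses = c(sample_id = "character",
                                       sex = "character",
                                       population = "character"))
  need <- c("sample_id", "sex", "population", "fitzpatrick", "lab_L")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("metadata CSV lacks columns: ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample_id)) stop("duplicate sample IDs in metadata")
  badSex <- !df$sex %in% c("male", "female", "unknown")
  if (any(badSex)) stop("invalid sex value: ",
                        paste(unique(df$sex[badSex]), collapse = ", "))
  ft <- df$fitzpatrick
  if (any(!is.na(ft) & !ft %in% 1:6))
    stop("fitzpatrick values must be integers in 1..6 or NA")
  L <- df$lab_L
  if (any(!is.na(L) & (L <= 0 | L >= 100)))
    stop("lab_L values must lie in (0, 100) or be NA")
  df[need]
}

#' @rdname readSampleMetadata
#' @param metadata data.frame as returned by \code{readSampleMetadata}.
#' @export
writeSampleMetadata <- function(metadata, path) {
  utils::write.csv(metadata, path, row.names = FALSE, quote = FALSE,
                   na = "NA")
  invisible(path)
}
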