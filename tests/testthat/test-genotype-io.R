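# Genotype input/output: dosage CSV, VCF extraction, complete-case rule.

tinyPanel <- function() {
  df <- data.frame(
    rsid = c("rsA", "rsB", "rsC", "rsD"),
    chrom = c("1", "1", "2", "2"),
    position = c(100L, 200L, 300L, 400L),
    locus = c("G1", "G1", "G2", "G3"),
    allele1 = c("A", "A", "C", "C"),
    allele2 = c("G", "G", "T", "G"),
    effect_allele = c("G", "G", "T", "G"),
    variant_class = "SNV",
    tier = "candidate",
    rank = NA_integer_, assoc_r2 = NA_real_, assoc_p = NA_real_,
    glm_coefficient = NA_real_, synonyms = NA_character_,
    stringsAsFactors = FALSE)
  SnpPanel(df, provenance = "test fixture")
}

writeTinyCsv <- function(lines) {
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

test_that("dosage CSV reading aligns to the panel and validates cells", {
  path <- writeTinyCsv(c("sample_id,rsB,rsA,rsC,rsD",
                         "s1,0,1,2,0",
                         "s2,2,0,NA,1",
                         "s3,1,,2,2"))
  g <- readDosageCsv(path, tinyPanel())
  expect_identical(rownames(g), c("rsA", "rsB", "rsC", "rsD"))  # panel order
  expect_identical(colnames(g), c("s1", "s2", "s3"))
  d <- dosageMatrix(g)
  expect_equal(d["rsA", "s1"], 1)
  expect_equal(d["rsB", "s2"], 2)
  expect_true(is.na(d["rsC", "s2"]))  # NA sentinel
  expect_true(is.na(d["rsA", "s3"]))  # empty cell also missing
})

test_that("dosage CSV errors name the offending sample and SNP", {
  bad <- writeTinyCsv(c("sample_id,rsA", "s1,3"))
  expect_error(readDosageCsv(bad, tinyPanel()), "s1.*rsA")
  dup <- writeTinyCsv(c("sample_id,rsA", "s1,1", "s1,2"))
  expect_error(readDosageCsv(dup, tinyPanel()), "duplicate sample")
  none <- writeTinyCsv(c("sample_id,rsX", "s1,1"))
  expect_warning(expect_error(readDosageCsv(none, tinyPanel()),
                              "no panel SNP columns"),
                 "not in panel")
})

test_that("columns outside the panel are dropped with one warning each", {
  path <- writeTinyCsv(c("sample_id,rsA,rsB,rsC,rsD,x1,x2,x3,x4",
                         "s1,0,1,2,0,9,9,9,9"))
  warns <- testthat::capture_warnings(g <- readDosageCsv(path, tinyPanel()))
  expect_length(warns, 4)
  expect_true(all(grepl("not in panel", warns)))
  expect_equal(nrow(g), 4)
})

test_that("dosage CSVs round-trip exactly", {
  path <- writeTinyCsv(c("sample_id,rsA,rsB,rsC,rsD",
                         "s1,0,1,2,NA",
                         "s2,2,0,1,1"))
  g <- readDosageCsv(path, tinyPanel())
  out <- withr::local_tempfile(fileext = ".csv")
  writeDosageCsv(g, out)
  g2 <- readDosageCsv(out, tinyPanel())
  expect_identical(dosageMatrix(g), dosageMatrix(g2))
})

test_that("complete-case filtering keeps exactly the fully typed samples", {
  d <- matrix(c(0, 1, 2, 1,
                NA, 1, 0, 2,
                1, 1, 1, 1,
                2, NA, 0, 0,
                0, 0, 0, 0), nrow = 4,
              dimnames = list(c("rsA", "rsB", "rsC", "rsD"),
                              paste0("s", 1:5)))
  g <- SkinGenotypes(d)
  filtered <- completeCaseFilter(g)
  expect_identical(colnames(filtered), c("s1", "s3", "s5"))
  # idempotent, never increases the sample count
  expect_identical(dosageMatrix(completeCaseFilter(filtered)),
                   dosageMatrix(filtered))
  # completeness over a subset of SNPs keeps more samples
  sub <- completeCaseFilter(g, snpIds = c("rsB", "rsC", "rsD"))
  expect_identical(colnames(sub), c("s1", "s2", "s3", "s5"))
  # fully missing column -> empty result allowed
  dAll <- d; dAll[1, ] <- NA
  expect_equal(ncol(completeCaseFilter(SkinGenotypes(dAll))), 0)
  expect_error(completeCaseFilter(g, snpIds = "rsZ"), "not in genotypes")
})

writeTinyVcf <- function(records) {
  path <- withr::local_tempfile(fileext = ".vcf",
                                .local_envir = parent.frame())
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=1>",
    "##contig=<ID=2>",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "s1", "s2"), collapse = "\t"),
    records), path)
  path
}

test_that("VCF dosages count effect alleles with allele reconciliation", {
  vcf <- writeTinyVcf(c(
    # exact match, ALT is the effect allele
    "1\t100\trsA\tA\tG\t.\tPASS\t.\tGT\t1/1\t0/1",
    # swapped REF/ALT: effect allele is REF, 0/0 counts two
    "1\t200\trsB\tG\tA\t.\tPASS\t.\tGT\t0/0\t./.",
    # strand-flipped non-ambiguous SNP: panel C/T appears as G/A
    "2\t300\trsC\tG\tA\t.\tPASS\t.\tGT\t0/1\t1/1",
    # ambiguous C/G pair with non-matching alleles: must go missing
    "2\t400\trsD\tA\tT\t.\tPASS\t.\tGT\t0/1\t0/0"))
  expect_warning(g <- readGenotypeVcf(vcf, tinyPanel()), "irreconcilable")
  d <- dosageMatrix(g)
  expect_equal(d["rsA", ], c(s1 = 2, s2 = 1))
  expect_equal(d["rsB", "s1"], 2)        # complemented dosage
  expect_true(is.na(d["rsB", "s2"]))     # ./. is missing
  # flipped effect allele T -> A (code 1): 0/1 counts one, 1/1 two
  expect_equal(d["rsC", ], c(s1 = 1, s2 = 2))
  expect_true(all(is.na(d["rsD", ])))
})

test_that("VCF matching falls back to coordinates and flags absences", {
  vcf <- writeTinyVcf(c(
    "1\t100\t.\tA\tG\t.\tPASS\t.\tGT\t0/1\t1/1",  # matched by chrom+pos
    "1\t200\trsB\tA\tG\t.\tPASS\t.\tGT\t0/.\t1/1"))
  warns <- testthat::capture_warnings(g <- readGenotypeVcf(vcf, tinyPanel()))
  expect_true(any(grepl("rsC.*not found", warns)))
  d <- dosageMatrix(g)
  expect_equal(d["rsA", ], c(s1 = 1, s2 = 2))
  expect_true(is.na(d["rsB", "s1"]))     # half-call is missing
  expect_equal(d["rsB", "s2"], 2)
  expect_true(all(is.na(d["rsC", ])))
  expect_error(readGenotypeVcf("/nonexistent.vcf", tinyPanel()),
               "unreadable")
})

test_that("VCF and CSV readers agree on the same genotypes", {
  vcf <- writeTinyVcf(c(
    "1\t100\trsA\tA\tG\t.\tPASS\t.\tGT\t1/1\t0/1",
    "1\t200\trsB\tA\tG\t.\tPASS\t.\tGT\t0/1\t0/0",
    "2\t300\trsC\tC\tT\t.\tPASS\t.\tGT\t0/0\t1/1",
    "2\t400\trsD\tC\tG\t.\tPASS\t.\tGT\t0/1\t./."))
  gVcf <- readGenotypeVcf(vcf, tinyPanel())
  csv <- writeTinyCsv(c("sample_id,rsA,rsB,rsC,rsD",
                        "s1,2,1,0,1",
                        "s2,1,0,2,NA"))
  gCsv <- readDosageCsv(csv, tinyPanel())
  expect_identical(dosageMatrix(gVcf), dosageMatrix(gCsv))
})

test_that("sample metadata validates its fields", {
  meta <- writeTinyCsv(c("sample_id,sex,population,fitzpatrick,lab_L",
                         "s1,female,Poland,2,NA",
                         "s2,male,Nigeria,6,33.5",
                         "s3,unknown,Greece,NA,61.2"))
  df <- readSampleMetadata(meta)
  expect_equal(nrow(df), 3)
  expect_identical(df$sex, c("female", "male", "unknown"))
  out <- withr::local_tempfile(fileext = ".csv")
  writeSampleMetadata(df, out)
  expect_identical(readSampleMetadata(out), df)

  badFt <- writeTinyCsv(c("sample_id,sex,population,fitzpatrick,lab_L",
                          "s1,female,Poland,9,NA"))
  expect_error(readSampleMetadata(badFt), "1\\.\\.6")
  badSex <- writeTinyCsv(c("sample_id,sex,population,fitzpatrick,lab_L",
                           "s1,N,Poland,2,NA"))
  expect_error(readSampleMetadata(badSex), "sex")
})
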