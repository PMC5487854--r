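## Synthetic multi-population genotype-phenotype cohorts: Hardy-Weinberg
## binomial genotypes within populations, categorical phenotypes drawn from
## a true multinomial model, optional completely-at-random missingness.

#' Simulation configuration for synthetic cohorts
#'
#' @param populations list of populations, each a list with \code{name},
#'   \code{n} (>= 1) and \code{freq} (effect-allele frequency per SNP of
#'   the true model, in [0, 1]).
#' @param trueModel the generating \linkS4class{SkinColourModel}.
#' @param sexRatio proportion of females.
#' @param missingRate completely-at-random missing dosage rate in [0, 1).
#' @param seed integer seed; the whole cohort is reproducible from it.
#' @return validated list of class \code{skintyperSimConfig}.
#' @export
simulationConfig <- function(populations, trueModel, sexRatio = 0.5,
                             missingRate = 0, seed = 1L) {
  k <- length(modelSnpIds(trueModel))
  for (p in populations) {
    if (is.null(p$name) || is.null(p$n) || is.null(p$freq))
      stop("each population needs name, n and freq")
    if (p$n < 1) stop("population n must be >= 1")
    if (length(p$freq) != k)
      stop("population ", p$name, ": freq length ", length(p$freq),
           " does not match the true model's ", k, " SNPs")
    if (any(p$freq < 0 | p$freq > 1))
      stop("population ", p$name, ": frequencies must lie in [0, 1]")
  }
  if (missingRate < 0 || missingRate >= 1)
    stop("missingRate must lie in [0, 1)")
  if (sexRatio < 0 || sexRatio > 1) stop("sexRatio must lie in [0, 1]")
  structure(list(populations = populations, trueModel = trueModel,
                 sexRatio = sexRatio, missingRate = missingRate,
                 seed = as.integer(seed)),
            class = "skintyperSimConfig")
}

#' Simulate a multi-population genotype-phenotype cohort
#'
#' Dosages are drawn per population as Binomial(2, f) under Hardy-Weinberg
#' (no linkage between SNPs); each sample's skin colour category is drawn
#' from the true model's predicted probabilities given its genotypes; sex
#' is Bernoulli(\code{sexRatio}). Missingness is applied uniformly at
#' random after phenotype generation, so the phenotypes always reflect the
#' complete genotype. Fully reproducible under the config seed.
#'
#' @param config a [simulationConfig()].
#' @return list with \code{genotypes} (a \linkS4class{SkinGenotypes} whose
#'   colData holds \code{sex}, \code{population}, \code{fitzpatrick}),
#'   \code{categories} (true category factor) and \code{config}.
#' @export
simulateCohort <- function(config) {
  if (!inherits(config, "skintyperSimConfig"))
    stop("config must come from simulationConfig()")
  model <- config$trueModel
  snpIds <- modelSnpIds(model)
  cats <- modelCategories(model)
  withSeed(config$seed, {
    parts <- lapply(config$populations, function(p) {
      d <- vapply(p$freq, function(f) stats::rbinom(p$n, 2, f),
                  numeric(p$n))
      d <- matrix(d, nrow = p$n, dimnames = list(NULL, snpIds))
      list(dosage = d, population = rep(p$name, p$n))
    })
    X <- do.call(rbind, lapply(parts, `[[`, "dosage"))
    population <- unlist(lapply(parts, `[[`, "population"))
    n <- nrow(X)
    rownames(X) <- sprintf("S%04d", seq_len(n))
    probs <- predictProbabilities(model, X)
    u <- stats::runif(n)
    cum <- t(apply(probs, 1, cumsum))
    catIdx <- rowSums(u > cum) + 1L
    categories <- factor(cats[catIdx], levels = cats)
    sex <- ifelse(stats::runif(n) < config$sexRatio, "female", "male")
    if (config$missingRate > 0) {
      mask <- matrix(stats::runif(n * ncol(X)) < config$missingRate,
                     n, ncol(X))
      X[mask] <- NA_real_
    }
    meta <- data.frame(sex = sex, population = population,
                       fitzpatrick = categoryToFitzpatrick(categories),
                       lab_L = NA_real_, row.names = rownames(X))
    list(genotypes = SkinGenotypes(t(X), sampleData = meta),
         categories = categories, config = config)
  })
}

## internal: representative Fitzpatrick type per five-category label, used
## so simulated phenotypes flow through the documented metadata CSV
## (fitzpatrickTo5cat() inverts it).
categoryToFitzpatrick <- function(categories) {
  map <- c(VeryPale = 1L, Pale = 2L, Intermediate = 3L, Dark = 5L,
           DarkBlack = 6L)
  unname(map[as.character(categories)])
}

#' Build a generating model with graded allele effects
#'
#' Construct a plausible true multinomial model for simulations: SNP j
#' carries a weight w_j declining with rank, category m scales it by an
#' increasing darkness coefficient, and intercepts are centred so that at
#' the average dosage (from \code{freqMeans}) the category probabilities
#' match \code{targetProps}. Used by the canned fixtures; exported so
#' simulations can vary effect strength.
#'
#' @param snpIds rsids of the simulated SNPs.
#' @param freqMeans expected effect-allele frequency per SNP (averaged over
#'   populations), used to centre the intercepts.
#' @param categories category labels; default five-category scale.
#' @param targetProps target category proportions at the mean genotype;
#'   default mirrors a predominantly European study cohort
#'   (6/44/42/3/5 percent from Very Pale to Dark-Black).
#' @param strength multiplier on all allele effects.
#' @return A \linkS4class{SkinColourModel}.
#' @export
makeTrueModel <- function(snpIds, freqMeans = rep(0.5, length(snpIds)),
                          categories = skinCategories5(),
                          targetProps = c(0.06, 0.44, 0.42, 0.03, 0.05),
                          strength = 1) {
  k <- length(snpIds)
  K <- length(categories)
  if (length(targetProps) != K) stop("targetProps must match categories")
  targetProps <- targetProps / sum(targetProps)
  w <- seq(1.4, 0.25, length.out = k)
  darkness <- seq(0, 2.5, length.out = K)[-1]
  beta <- outer(darkness, w) * strength
  xbar <- 2 * freqMeans
  alpha <- log(targetProps[-1] / targetProps[1]) - as.numeric(beta %*% xbar)
  skinModel(categories, intercepts = alpha, coefficients = beta,
            snpIds = snpIds)
}

#' Canned deterministic simulation fixtures
#'
#' Three bundled cohorts regenerated identically on every call:
#' \describe{
#'   \item{small}{3 populations x 50 samples, 6 SNPs (the top-ranked panel
#'     SNPs), moderate effects; quick end-to-end runs.}
#'   \item{medium}{5 populations x 300 samples, the 36 final-panel SNPs;
#'     emulates the scale and structure of a multi-population training
#'     cohort.}
#'   \item{confounded}{2 populations x 250, 6 SNPs of which the last
#'     (\code{null_snp}) has no phenotype effect but strongly
#'     population-stratified frequencies; exercises the covariate
#'     adjustment of the association filter.}
#' }
#'
#' @param name \code{"small"}, \code{"medium"} or \code{"confounded"}.
#' @param seed integer seed (fixture defaults are fixed per name).
#' @return the [simulateCohort()] output list.
#' @export
makeFixture <- function(name = c("small", "medium", "confounded"),
                        seed = NULL) {
  name <- match.arg(name)
  finalIds <- c("rs1426654", "rs12203592", "rs1805007", "rs1800414",
                "rs16891982", "rs1667394")
  popFreqs <- function(nSnps, nPops, spread, seed) {
    withSeed(seed, {
      base <- stats::runif(nSnps, 0.15, 0.85)
      dir <- sample(c(-1, 1), nSnps, replace = TRUE)
      shift <- seq(-1, 1, length.out = nPops)
      lapply(shift, function(s)
        stats::plogis(stats::qlogis(base) + spread * s * dir))
    })
  }
  if (name == "small") {
    if (is.null(seed)) seed <- 101L
    freqs <- popFreqs(6, 3, 1.2, seed + 1L)
    model <- makeTrueModel(finalIds, freqMeans = Reduce(`+`, freqs) / 3,
                           strength = 1.2)
    pops <- mapply(function(nm, f) list(name = nm, n = 50L, freq = f),
                   c("POP_A", "POP_B", "POP_C"), freqs, SIMPLIFY = FALSE)
    cfg <- simulationConfig(pops, model, seed = seed)
  } else if (name == "medium") {
    if (is.null(seed)) seed <- 202L
    panel <- subsetTier(skinPanel(), "final")
    ids <- panelRsids(panel)
    freqs <- popFreqs(length(ids), 5, 1.5, seed + 1L)
    model <- makeTrueModel(ids, freqMeans = Reduce(`+`, freqs) / 5,
                           strength = 0.6)
    pops <- mapply(function(nm, f) list(name = nm, n = 300L, freq = f),
                   c("EUR_N", "EUR_S", "MENA", "EAS", "AFR"), freqs,
                   SIMPLIFY = FALSE)
    cfg <- simulationConfig(pops, model, seed = seed)
  } else {
    if (is.null(seed)) seed <- 303L
    ids <- c(finalIds[1:5], "null_snp")
    freqs <- popFreqs(6, 2, 1.6, seed + 1L)
    # the null SNP: no effect, strongly stratified frequencies
    freqs[[1]][6] <- 0.9
    freqs[[2]][6] <- 0.1
    model <- makeTrueModel(ids, freqMeans = Reduce(`+`, freqs) / 2,
                           strength = 1.2)
    cf <- modelCoefficients(model)
    cf[, "null_snp"] <- 0
    model <- skinModel(modelCategories(model),
                       intercepts = modelIntercepts(model),
                       coefficients = cf, snpIds = ids)
    pops <- mapply(function(nm, f) list(name = nm, n = 250L, freq = f),
                   c("POP_A", "POP_B"), freqs, SIMPLIFY = FALSE)
    cfg <- simulationConfig(pops, model, seed = seed)
  }
  simulateCohort(cfg)
}

#' Write a simulated cohort to its interchange files
#'
#' Emits the dosage CSV and metadata CSV consumed by the other modules
#' (the simulated category is carried through the metadata's
#' \code{fitzpatrick} column).
#'
#' @param cohort output of [simulateCohort()] / [makeFixture()].
#' @param dir output directory (created if needed).
#' @return named character vector of file paths, invisibly.
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dosPath <- file.path(dir, "dosages.csv")
  metaPath <- file.path(dir, "metadata.csv")
  writeDosageCsv(cohort$genotypes, dosPath)
  meta <- sampleMetadata(cohort$genotypes)
  meta <- data.frame(sample_id = rownames(meta), meta, row.names = NULL)
  writeSampleMetadata(meta, metaPath)
  invisible(c(dosages = dosPath, metadata = metaPath))
}
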