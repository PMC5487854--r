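# Independent oracles used to cross-check the package implementations.

# AUC by explicit enumeration of all (positive, negative) pairs.
bruteForceAuc <- function(scores, labels) {
  pos <- scores[labels]
  neg <- scores[!labels]
  wins <- 0
  for (a in pos) for (b in neg) wins <- wins + (a > b) + 0.5 * (a == b)
  wins / (length(pos) * length(neg))
}

# AUC as the trapezoidal area under the empirical ROC curve from a
# threshold sweep over the observed scores.
trapezoidAuc <- function(scores, labels) {
  th <- sort(unique(scores), decreasing = TRUE)
  tpr <- c(0, vapply(th, function(t) mean(scores[labels] >= t), numeric(1)))
  fpr <- c(0, vapply(th, function(t) mean(scores[!labels] >= t), numeric(1)))
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

# Exhaustive best-subset AIC search (including the intercept-only model);
# the oracle for the greedy stepwise selection.
exhaustiveBestSubset <- function(X, y, candidates, categories = NULL) {
  bestAic <- Inf
  bestSet <- character(0)
  for (mask in 0:(2^length(candidates) - 1)) {
    snps <- candidates[bitwAnd(mask, 2^(seq_along(candidates) - 1)) > 0]
    Xs <- X[, snps, drop = FALSE]
    aic <- tryCatch(
      modelAIC(fitMlr(Xs, y, categories = categories), Xs, y),
      error = function(e) NA_real_)
    if (!is.na(aic) && aic < bestAic) {
      bestAic <- aic
      bestSet <- snps
    }
  }
  list(selected = bestSet, aic = bestAic)
}

# Strongly separable 3-category data: each non-reference category has its
# own block of large-effect SNPs, so every category (including the
# reference) is well discriminated one-vs-rest.
makeStrongSignalData <- function(n, seed) {
  k <- 6
  snps <- sprintf("snp%02d", seq_len(k))
  model <- skinModel(c("Light", "Dark", "DarkBlack"),
                     intercepts = c(-9, -9),
                     coefficients = rbind(c(5, 5, 5, 0, 0, 0),
                                          c(0, 0, 0, 5, 5, 5)),
                     snpIds = snps)
  cohort <- simulateCohort(simulationConfig(
    list(list(name = "POP", n = n, freq = rep(0.4, k))), model,
    seed = seed))
  list(X = sampleDosages(cohort$genotypes), y = cohort$categories,
       model = model)
}

# Small labelled multinomial data set with chosen per-SNP effect strengths
# (3 categories unless stated otherwise); used by the selection tests.
makeLabelledData <- function(n, effects, seed, freq = NULL,
                             categories = c("Light", "Dark", "DarkBlack")) {
  k <- length(effects)
  snps <- sprintf("snp%02d", seq_len(k))
  if (is.null(freq)) freq <- rep(0.4, k)
  beta <- rbind(effects, 2 * effects)
  model <- skinModel(categories,
                     intercepts = c(-0.3, -1.2),
                     coefficients = beta, snpIds = snps)
  cohort <- simulateCohort(simulationConfig(
    list(list(name = "POP", n = n, freq = freq)), model, seed = seed))
  list(X = sampleDosages(cohort$genotypes), y = cohort$categories,
       model = model)
}
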