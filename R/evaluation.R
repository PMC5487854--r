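## Multiclass evaluation: one-vs-rest AUC, confusion matrices and derived
## metrics, the naive Bayes genotype-classifier baseline, and the
## side-by-side model comparison report.

#' One-vs-rest AUC by pair counting
#'
#' Mann-Whitney formulation: the fraction of (positive, negative) sample
#' pairs in which the positive sample scores higher, with ties counted as
#' one half. Computed from midranks, which is deterministic and free of
#' ROC interpolation choices; 0.5 designates a random score, 1 a perfect
#' one. Single-class labels yield \code{NA} with a warning.
#'
#' @param scores numeric score (e.g. predicted category probability) per
#'   sample.
#' @param labels logical (or 0/1) indicator of the positive class.
#' @return AUC in [0, 1], or \code{NA} if undefined.
#' @examples
#' aucOneVsRest(c(0.9, 0.4, 0.6, 0.2), c(TRUE, TRUE, FALSE, FALSE))  # 0.75
#' @export
aucOneVsRest <- function(scores, labels) {
  labels <- as.logical(labels)
  if (length(scores) != length(labels)) stop("scores/labels length mismatch")
  if (anyNA(scores) || anyNA(labels)) stop("NA in scores or labels")
  nPos <- sum(labels)
  nNeg <- sum(!labels)
  if (nPos == 0L || nNeg == 0L) {
    warning("AUC undefined: labels contain a single class", call. = FALSE)
    return(NA_real_)
  }
  r <- rank(scores)  # midranks handle ties as 0.5 pair wins
  (sum(r[labels]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
}

#' Confusion matrix of predicted versus observed categories
#'
#' \code{counts[i, j]} is the number of samples observed in category i and
#' predicted as category j.
#'
#' @param pred predicted categories.
#' @param obs observed categories (same length).
#' @param categories ordered category labels; defaults to the union of
#'   factor levels.
#' @return K x K integer matrix, rows = observed, columns = predicted.
#' @export
confusionTable <- function(pred, obs, categories = NULL) {
  if (length(pred) != length(obs)) stop("pred/obs length mismatch")
  if (is.null(categories)) {
    categories <- if (is.factor(obs)) levels(obs)
      else unique(c(as.character(obs), as.character(pred)))
  }
  pred <- as.character(pred)
  obs <- as.character(obs)
  bad <- unique(c(pred[!pred %in% categories], obs[!obs %in% categories]))
  if (length(bad)) stop("labels outside category set: ",
                        paste(bad, collapse = ", "))
  m <- table(factor(obs, levels = categories),
             factor(pred, levels = categories))
  out <- matrix(as.integer(m), nrow(m), ncol(m),
                dimnames = list(observed = categories,
                                predicted = categories))
  out
}

#' One-vs-rest metrics from a confusion matrix
#'
#' Sensitivity TP/(TP+FN), specificity TN/(TN+FP), positive predictive
#' value TP/(TP+FP) and negative predictive value TN/(TN+FN) for one
#' category against the rest. Zero denominators yield \code{NA}
#' (explicitly undefined, never 0 by convention).
#'
#' @param m confusion matrix from [confusionTable()].
#' @param category the category to evaluate one-vs-rest.
#' @return data.frame row: \code{category}, \code{sensitivity},
#'   \code{specificity}, \code{ppv}, \code{npv}.
#' @export
metricsFromConfusion <- function(m, category) {
  cats <- rownames(m)
  if (!category %in% cats) stop("unknown category: ", category)
  i <- match(category, cats)
  tp <- m[i, i]
  fn <- sum(m[i, -i])
  fp <- sum(m[-i, i])
  tn <- sum(m[-i, -i])
  ratio <- function(a, b) if (b == 0) NA_real_ else a / b
  data.frame(category = category,
             sensitivity = ratio(tp, tp + fn),
             specificity = ratio(tn, tn + fp),
             ppv = ratio(tp, tp + fp),
             npv = ratio(tn, tn + fn),
             stringsAsFactors = FALSE)
}

#' Naive Bayes genotype classifier baseline
#'
#' The class of classifier used by earlier web-based skin colour
#' predictors: class priors are category frequencies and each SNP
#' contributes an independent categorical likelihood over its genotype
#' state (dosage 0/1/2), estimated with an additive pseudo-count
#' \code{smoothing} (default 0.5). Posteriors are prior times the product
#' of per-SNP state probabilities, normalized. With \code{smoothing = 0} an
#' unseen state yields a zero-probability warning.
#'
#' @param X samples x SNPs complete dosage matrix or
#'   \linkS4class{SkinGenotypes}.
#' @param y category labels.
#' @param categories ordered category labels.
#' @param smoothing additive pseudo-count (>= 0).
#' @return object of class \code{skintyperNB}.
#' @export
fitNaiveBayes <- function(X, y, categories = NULL, smoothing = 0.5) {
  if (methods::is(X, "SkinGenotypes")) X <- sampleDosages(X)
  X <- as.matrix(X)
  if (anyNA(X)) stop("naive Bayes training requires complete dosages")
  if (smoothing < 0) stop("smoothing must be >= 0")
  if (is.null(categories))
    categories <- if (is.factor(y)) levels(y) else unique(as.character(y))
  y <- as.character(y)
  if (!all(y %in% categories)) stop("labels outside categories")
  k <- ncol(X)
  priors <- table(factor(y, levels = categories)) / length(y)
  # cond[cat, snp, state]: P(dosage state | category), smoothed
  cond <- array(NA_real_, c(length(categories), k, 3),
                dimnames = list(categories, colnames(X), 0:2))
  for (cc in categories) {
    Xc <- X[y == cc, , drop = FALSE]
    nc <- nrow(Xc)
    for (s in 0:2)
      cond[cc, , as.character(s)] <-
        (colSums(Xc == s) + smoothing) / (nc + 3 * smoothing)
  }
  structure(list(categories = categories, priors = as.numeric(priors),
                 cond = cond, smoothing = smoothing,
                 snpIds = colnames(X)),
            class = "skintyperNB")
}

#' @rdname fitNaiveBayes
#' @param model a fitted \code{skintyperNB}.
#' @param dosages named dosage vector, samples x SNPs matrix, or
#'   \linkS4class{SkinGenotypes} (complete at the model SNPs).
#' @return \code{predictNaiveBayes}: probability matrix (or named vector
#'   for a single sample) over the categories.
#' @export
predictNaiveBayes <- function(model, dosages) {
  single <- is.null(dim(dosages)) && !methods::is(dosages, "SkinGenotypes")
  X <- alignDosages(dosages, model$snpIds)
  if (anyNA(X)) stop("naive Bayes prediction requires complete dosages")
  n <- nrow(X)
  K <- length(model$categories)
  logPost <- matrix(rep(log(model$priors), each = n), n, K,
                    dimnames = list(rownames(X), model$categories))
  for (j in seq_along(model$snpIds)) {
    stateProb <- model$cond[, j, , drop = TRUE]  # K x 3
    pj <- t(stateProb)[cbind(X[, j] + 1L, rep(seq_len(K), each = n))]
    pj <- matrix(pj, n, K)
    if (any(pj == 0))
      warning("zero-probability genotype state under smoothing = 0",
              call. = FALSE)
    logPost <- logPost + log(pj)
  }
  mx <- apply(logPost, 1, max)
  p <- exp(logPost - mx)
  p <- p / rowSums(p)
  if (single) return(p[1, ])
  p
}

#' Side-by-side comparison of two prediction models
#'
#' Computes the per-category one-vs-rest metrics table (AUC, sensitivity,
#' specificity, PPV, NPV) for two sets of predicted probabilities against
#' the same observed labels, in the shape used for published model
#' comparisons: one row per (model, category). AUC is computed from the
#' category probabilities by default, or from hard calls (0/1 indicator
#' scores) with \code{aucFrom = "calls"}.
#'
#' @param predA,predB probability matrices (samples x categories) from the
#'   two models, same samples in the same order.
#' @param obs observed categories.
#' @param categories ordered category labels.
#' @param modelNames labels for the two models in the report.
#' @param aucFrom \code{"probabilities"} or \code{"calls"}.
#' @return data.frame with 2K rows: \code{model}, \code{category},
#'   \code{auc}, \code{sensitivity}, \code{specificity}, \code{ppv},
#'   \code{npv}.
#' @export
compareModels <- function(predA, predB, obs, categories = NULL,
                          modelNames = c("A", "B"),
                          aucFrom = c("probabilities", "calls")) {
  aucFrom <- match.arg(aucFrom)
  if (nrow(predA) != nrow(predB) || nrow(predA) != length(obs))
    stop("models must be evaluated on the same samples")
  if (is.null(categories)) categories <- colnames(predA)
  obs <- as.character(obs)
  one <- function(pred, name) {
    calls <- classifyProbabilities(pred[, categories, drop = FALSE])$category
    cm <- confusionTable(calls, obs, categories)
    do.call(rbind, lapply(categories, function(cc) {
      row <- metricsFromConfusion(cm, cc)
      score <- if (aucFrom == "probabilities") pred[, cc]
        else as.numeric(calls == cc)
      pos <- obs == cc
      row$auc <- if (any(pos) && !all(pos)) aucOneVsRest(score, pos)
        else NA_real_
      cbind(model = name, row[c("category", "auc", "sensitivity",
                                "specificity", "ppv", "npv")])
    }))
  }
  out <- rbind(one(predA, modelNames[1]), one(predB, modelNames[2]))
  rownames(out) <- NULL
  out
}

#' Write a metrics table as CSV
#'
#' Serializes a comparison or metrics data.frame with undefined metrics
#' written as \code{NA}, never 0.
#'
#' @param metrics data.frame (e.g. from [compareModels()]).
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeMetricsCsv <- function(metrics, path) {
  utils::write.csv(metrics, path, row.names = FALSE, quote = FALSE,
                   na = "NA")
  invisible(path)
}
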