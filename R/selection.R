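## Marker selection and validation: sex/population-adjusted partial
## correlation filter, stepwise AIC subset selection, the replicated 80/20
## cross-validation protocol, and the incremental per-rank AUC curve.

## internal: covariate design matrix (intercept + sex + population
## indicators), dropping collinear columns with a warning.
covariateDesign <- function(metadata, n) {
  C <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  addFactor <- function(C, x, label) {
    x <- factor(x)
    if (nlevels(x) < 2) {
      warning(label, " covariate is constant; skipped", call. = FALSE)
      return(C)
    }
    ind <- stats::model.matrix(~ x)[, -1, drop = FALSE]
    colnames(ind) <- paste0(label, levels(x)[-1])
    cbind(C, ind)
  }
  if (!is.null(metadata$sex)) C <- addFactor(C, metadata$sex, "sex")
  if (!is.null(metadata$population)) {
    if (length(unique(metadata$population)) < 2)
      warning("fewer than 2 populations; population covariate skipped",
              call. = FALSE)
    else C <- addFactor(C, metadata$population, "population")
  }
  qrC <- qr(C)
  if (qrC$rank < ncol(C)) {
    dropped <- colnames(C)[qrC$pivot[(qrC$rank + 1):ncol(C)]]
    warning("dropping collinear covariate columns: ",
            paste(dropped, collapse = ", "), call. = FALSE)
    C <- C[, qrC$pivot[seq_len(qrC$rank)], drop = FALSE]
  }
  C
}

#' Association filter: partial correlation with ordinal skin colour
#'
#' For each SNP, the dosage and the ordinal-coded five-category phenotype
#' (Very Pale = 1 ... Dark-Black = 5) are residualized on an intercept,
#' a sex indicator and population indicator columns; the partial
#' correlation r of the residuals is squared, and its p value comes from
#' \eqn{t = r \sqrt{(n - 2 - c) / (1 - r^2)}} with c covariate columns
#' (beyond the intercept). A SNP is kept when p < \code{alpha}
#' (uncorrected, matching the selection protocol). Constant dosage columns
#' report r2 = 0, p = 1.
#'
#' @param X samples x SNPs complete dosage matrix or
#'   \linkS4class{SkinGenotypes}.
#' @param y categorical phenotype; a factor is ordinal-coded by its level
#'   order (lightness descending), plain labels must belong to
#'   [skinCategories5()].
#' @param metadata data.frame with \code{sex} and \code{population} for the
#'   same samples (covariates; either may be skipped with a warning if
#'   constant).
#' @param alpha significance threshold (default 0.05).
#' @return data.frame with columns \code{rsid}, \code{partial_r2},
#'   \code{p_value}, \code{kept}.
#' @export
associationFilter <- function(X, y, metadata = NULL, alpha = 0.05) {
  if (methods::is(X, "SkinGenotypes")) {
    if (is.null(metadata)) metadata <- sampleMetadata(X)
    X <- sampleDosages(X)
  }
  X <- as.matrix(X)
  if (anyNA(X)) stop("association filter requires complete cases")
  # ordinal lightness coding: factor level order, or the five-category
  # scale (VeryPale = 1 ... DarkBlack = 5) for plain labels
  yOrd <- if (is.factor(y)) as.integer(y)
    else match(as.character(y), skinCategories5())
  if (anyNA(yOrd))
    stop("phenotype labels must be ordered factor levels or five-category labels")
  n <- nrow(X)
  C <- covariateDesign(metadata, n)
  cCols <- ncol(C) - 1L
  fitC <- stats::lm.fit(C, cbind(yOrd, X))
  res <- fitC$residuals
  ry <- res[, 1]
  out <- data.frame(rsid = colnames(X), partial_r2 = 0, p_value = 1,
                    kept = FALSE, stringsAsFactors = FALSE)
  sdY <- stats::sd(ry)
  df <- n - 2L - cCols
  for (j in seq_len(ncol(X))) {
    rx <- res[, j + 1L]
    # constant (or covariate-determined) dosage columns are degenerate;
    # the 1e-10 guard absorbs floating-point residue of exact collinearity
    if (stats::sd(X[, j]) == 0 || stats::sd(rx) < 1e-10 || sdY == 0) next
    r <- stats::cor(rx, ry)
    r <- max(min(r, 1), -1)
    if (abs(r) >= 1) {
      out$partial_r2[j] <- 1
      out$p_value[j] <- 0
    } else {
      tstat <- r * sqrt(df / (1 - r^2))
      out$partial_r2[j] <- r^2
      out$p_value[j] <- 2 * stats::pt(-abs(tstat), df)
    }
  }
  out$kept <- out$p_value < alpha
  out
}

#' Stepwise AIC subset selection of SNP predictors
#'
#' Greedy stepwise search over SNP subsets minimizing the multinomial
#' model's AIC. \code{"backward"} starts from the full candidate set and
#' considers single drops; \code{"bidirectional"} additionally considers
#' re-adding dropped candidates. The search stops when no single move
#' lowers the AIC; the intercept-only model is reachable. Failed fits at a
#' step are skipped with a warning and recorded in the trace.
#'
#' @param X samples x SNPs complete dosage matrix (superset of
#'   \code{candidateSnps}) or \linkS4class{SkinGenotypes}.
#' @param y category labels.
#' @param candidateSnps rsids to search over.
#' @param strategy \code{"backward"} or \code{"bidirectional"}.
#' @param categories ordered category labels (default \code{levels(y)}).
#' @param ridge ridge passed to [fitMlr()].
#' @return list with \code{selected} (rsids, in candidate order),
#'   \code{aic} (final AIC) and \code{trace} (data.frame of visited steps:
#'   step, action, rsid, k, aic, accepted).
#' @export
aicSelect <- function(X, y, candidateSnps,
                      strategy = c("backward", "bidirectional"),
                      categories = NULL, ridge = 1e-6) {
  strategy <- match.arg(strategy)
  if (methods::is(X, "SkinGenotypes")) X <- sampleDosages(X)
  X <- as.matrix(X)
  if (!length(candidateSnps)) stop("need at least one candidate SNP")
  missing <- setdiff(candidateSnps, colnames(X))
  if (length(missing)) stop("candidates not in X: ",
                            paste(missing, collapse = ", "))
  if (is.null(categories))
    categories <- if (is.factor(y)) levels(y) else unique(as.character(y))

  fitAic <- function(snps) {
    Xs <- X[, snps, drop = FALSE]
    tryCatch(
      modelAIC(fitMlr(Xs, y, categories = categories, ridge = ridge), Xs, y),
      error = function(e) {
        warning("fit failed for subset {",
                paste(snps, collapse = ","), "}: ",
                conditionMessage(e), call. = FALSE)
        NA_real_
      })
  }

  current <- candidateSnps
  currentAic <- fitAic(current)
  trace <- data.frame(step = 0L, action = "start", rsid = NA_character_,
                      k = length(current), aic = currentAic,
                      accepted = TRUE, stringsAsFactors = FALSE)
  if (is.na(currentAic)) stop("initial fit on the full candidate set failed")
  step <- 0L
  repeat {
    step <- step + 1L
    moves <- data.frame(action = character(0), rsid = character(0))
    if (length(current))
      moves <- rbind(moves, data.frame(action = "drop", rsid = current))
    addable <- setdiff(candidateSnps, current)
    if (strategy == "bidirectional" && length(addable))
      moves <- rbind(moves, data.frame(action = "add", rsid = addable))
    if (!nrow(moves)) break
    aics <- numeric(nrow(moves))
    for (i in seq_len(nrow(moves))) {
      snps <- if (moves$action[i] == "drop")
        setdiff(current, moves$rsid[i])
      else union(current, moves$rsid[i])
      snps <- candidateSnps[candidateSnps %in% snps]
      aics[i] <- fitAic(snps)
    }
    best <- which.min(aics)
    improved <- length(best) == 1L && !is.na(aics[best]) &&
      aics[best] < currentAic - 1e-10
    trace <- rbind(trace, data.frame(
      step = step, action = moves$action, rsid = moves$rsid,
      k = NA_integer_, aic = aics,
      accepted = improved & seq_len(nrow(moves)) == best,
      stringsAsFactors = FALSE))
    if (!improved) break
    current <- if (moves$action[best] == "drop")
      setdiff(current, moves$rsid[best])
    else union(current, moves$rsid[best])
    current <- candidateSnps[candidateSnps %in% current]
    currentAic <- aics[best]
  }
  list(selected = current, aic = currentAic, trace = trace)
}

#' Randomized 80/20 train/test split
#'
#' Uniformly random permutation split: the training set takes
#' \code{floor(0.8 n)} samples and the test set the remainder; the two are
#' disjoint and exhaustive. With n = 1423 the sizes are (1138, 285), the
#' replicate design used by the cross-validation protocol.
#'
#' @param n number of samples (>= 5).
#' @param seed integer seed controlling the permutation.
#' @return list with integer index vectors \code{train} and \code{test}.
#' @examples
#' lengths(split8020(1423, seed = 1))  # 1138, 285
#' @export
split8020 <- function(n, seed = NULL) {
  if (n < 5) stop("need at least 5 samples to split 80/20")
  perm <- withSeed(seed, sample.int(n))
  nTrain <- floor(0.8 * n)
  list(train = sort(perm[seq_len(nTrain)]),
       test = sort(perm[(nTrain + 1L):n]))
}

## internal: per-category one-vs-rest AUCs of a probability matrix against
## observed labels; NA where the test labels are single-class.
perCategoryAuc <- function(probs, y, categories) {
  vapply(categories, function(cc) {
    pos <- y == cc
    if (!any(pos) || all(pos)) return(NA_real_)
    aucOneVsRest(probs[, cc], pos)
  }, numeric(1))
}

#' Replicated cross-validation of a SNP prediction model
#'
#' In each replicate the samples are split 80/20 ([split8020()]), the
#' multinomial model is fitted on the training set and per-category
#' one-vs-rest AUCs are computed from predicted probabilities on the test
#' set. Splits whose training set lacks a category are redrawn (counted in
#' the report). The per-category mean and standard deviation of the AUCs
#' over replicates are reported; a category that never has both a positive
#' and a negative test sample reports \code{NA}.
#'
#' @param X samples x SNPs complete dosage matrix or
#'   \linkS4class{SkinGenotypes}.
#' @param y category labels (every category must have >= 2 samples).
#' @param snpIds SNPs to use (default: all columns of \code{X}).
#' @param replicates number of randomized replicates (the full protocol
#'   uses 1000).
#' @param seed integer base seed; replicate r uses seed + r.
#' @param categories ordered category labels.
#' @param ridge ridge passed to [fitMlr()].
#' @return data.frame (one row per category) with \code{category},
#'   \code{mean_auc}, \code{sd_auc}, \code{n_defined}; attributes
#'   \code{replicates}, \code{train_fraction}, \code{seed},
#'   \code{redraws}, and \code{auc} (the replicates x K AUC matrix).
#' @export
crossValidate <- function(X, y, snpIds = NULL, replicates = 1000L,
                          seed = 1L, categories = NULL, ridge = 1e-6) {
  if (methods::is(X, "SkinGenotypes")) X <- sampleDosages(X)
  X <- as.matrix(X)
  if (is.null(snpIds)) snpIds <- colnames(X)
  X <- X[, snpIds, drop = FALSE]
  if (is.null(categories))
    categories <- if (is.factor(y)) levels(y) else unique(as.character(y))
  y <- as.character(y)
  if (any(table(factor(y, levels = categories)) < 2))
    stop("every category needs at least 2 samples")
  n <- nrow(X)
  aucs <- matrix(NA_real_, replicates, length(categories),
                 dimnames = list(NULL, categories))
  redraws <- 0L
  for (r in seq_len(replicates)) {
    withSeed(seed + r, {
      repeat {
        sp <- list(train = NULL, test = NULL)
        perm <- sample.int(n)
        nTrain <- floor(0.8 * n)
        sp$train <- perm[seq_len(nTrain)]
        sp$test <- perm[(nTrain + 1L):n]
        if (all(categories %in% y[sp$train])) break
        redraws <- redraws + 1L
        if (redraws > 100L * replicates)
          stop("too many redraws: a category is too rare for 80% training splits")
      }
      fit <- fitMlr(X[sp$train, , drop = FALSE], y[sp$train],
                    categories = categories, ridge = ridge)
      probs <- predictProbabilities(fit, X[sp$test, , drop = FALSE])
      aucs[r, ] <- perCategoryAuc(probs, y[sp$test], categories)
    })
  }
  report <- data.frame(
    category = factor(categories, levels = categories),
    mean_auc = colMeans(aucs, na.rm = TRUE),
    sd_auc = apply(aucs, 2, stats::sd, na.rm = TRUE),
    n_defined = colSums(!is.na(aucs)),
    row.names = NULL)
  report$mean_auc[report$n_defined == 0] <- NA_real_
  attr(report, "replicates") <- replicates
  attr(report, "train_fraction") <- 0.8
  attr(report, "seed") <- seed
  attr(report, "redraws") <- redraws
  attr(report, "auc") <- aucs
  report
}

#' Write a cross-validation report as CSV
#'
#' @param report output of [crossValidate()].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeCvReport <- function(report, path) {
  utils::write.csv(report[c("category", "mean_auc", "sd_auc")], path,
                   row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}

#' Incremental AUC by prediction rank
#'
#' Adds SNPs to the model one by one in the given rank order, refits on the
#' full data at each size m = 1..k, and records the in-sample per-category
#' one-vs-rest AUC, tracing each marker's accumulated contribution to
#' prediction accuracy. Failed fits leave an NA row with a warning.
#'
#' @param X samples x SNPs complete dosage matrix or
#'   \linkS4class{SkinGenotypes}.
#' @param y category labels.
#' @param rankedSnpIds rsids in descending prediction-rank order (rank 1
#'   first).
#' @param categories ordered category labels.
#' @param ridge ridge passed to [fitMlr()].
#' @return k x K matrix of AUCs, rows named by model size.
#' @export
incrementalAucCurve <- function(X, y, rankedSnpIds, categories = NULL,
                                ridge = 1e-6) {
  if (!length(rankedSnpIds)) stop("ranked SNP list is empty")
  if (methods::is(X, "SkinGenotypes")) X <- sampleDosages(X)
  X <- as.matrix(X)
  if (is.null(categories))
    categories <- if (is.factor(y)) levels(y) else unique(as.character(y))
  y <- as.character(y)
  k <- length(rankedSnpIds)
  out <- matrix(NA_real_, k, length(categories),
                dimnames = list(seq_len(k), categories))
  for (m in seq_len(k)) {
    Xm <- X[, rankedSnpIds[seq_len(m)], drop = FALSE]
    fit <- tryCatch(fitMlr(Xm, y, categories = categories, ridge = ridge),
                    error = function(e) {
                      warning("fit failed at model size ", m, ": ",
                              conditionMessage(e), call. = FALSE)
                      NULL
                    })
    if (is.null(fit)) next
    probs <- predictProbabilities(fit, Xm)
    out[m, ] <- perCategoryAuc(probs, y, categories)
  }
  out
}
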