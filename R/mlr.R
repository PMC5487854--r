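## Multinomial logistic regression core: prediction, likelihood, AIC,
## Newton-Raphson fitting, and the model file format.

## internal: coerce dosage input (named vector, matrix, SkinGenotypes) to a
## samples x SNPs matrix aligned to the model's snpIds.
alignDosages <- function(dosages, snpIds) {
  if (methods::is(dosages, "SkinGenotypes")) dosages <- sampleDosages(dosages)
  if (is.null(dim(dosages))) {
    if (length(snpIds) && is.null(names(dosages)) &&
        length(dosages) == length(snpIds))
      names(dosages) <- snpIds
    dosages <- matrix(dosages, nrow = 1,
                      dimnames = list(NULL, names(dosages)))
  }
  dosages <- as.matrix(dosages)
  if (length(snpIds)) {
    absent <- setdiff(snpIds, colnames(dosages))
    if (length(absent))
      stop("dosages lack model SNPs: ", paste(absent, collapse = ", "))
    dosages <- dosages[, snpIds, drop = FALSE]
  } else {
    dosages <- dosages[, integer(0), drop = FALSE]
  }
  bad <- !(is.na(dosages) | dosages == 0 | dosages == 1 | dosages == 2)
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1, ]
    stop(sprintf("dosage outside {0,1,2,NA} at sample %s, SNP %s",
                 if (!is.null(rownames(dosages))) rownames(dosages)[idx[1]]
                 else idx[1], colnames(dosages)[idx[2]]))
  }
  dosages
}

## internal: linear predictors for all categories (reference column = 0),
## n x K, stable for later softmax. NA dosages contribute 0 to every eta.
linearPredictors <- function(model, X) {
  K <- length(model@categories)
  X0 <- X
  X0[is.na(X0)] <- 0
  eta <- matrix(0, nrow(X), K, dimnames = list(rownames(X),
                                               model@categories))
  nonRef <- setdiff(seq_len(K), model@reference)
  if (length(model@snpIds)) {
    eta[, nonRef] <- sweep(X0 %*% t(model@coefficients), 2,
                           model@intercepts, "+")
  } else {
    eta[, nonRef] <- matrix(model@intercepts, nrow(X), K - 1, byrow = TRUE)
  }
  if (any(!is.finite(eta))) stop("non-finite linear predictor")
  eta
}

#' Predict per-category skin colour probabilities
#'
#' Applies the multinomial logistic model to effect-allele dosages. For a
#' non-reference category m the probability is
#' \eqn{\exp(\alpha_m + \sum_j \beta_{mj} x_j)} divided by one plus the sum
#' of those exponentials over all non-reference categories; the reference
#' category takes the remaining mass. Probabilities therefore always sum
#' to one.
#'
#' Missing dosages are rejected under \code{"require_complete"} (the
#' default, matching the complete-genotype rule used for model fitting).
#' Under \code{"drop_terms"} the terms of missing SNPs are omitted from
#' every linear predictor and the affected samples are flagged as degraded
#' in the \code{"degraded"} attribute of the result.
#'
#' @param model a \linkS4class{SkinColourModel}.
#' @param dosages named dosage vector for one sample, a samples x SNPs
#'   matrix with rsid colnames, or a \linkS4class{SkinGenotypes}.
#' @param missingPolicy \code{"require_complete"} or \code{"drop_terms"}.
#' @return For a single sample, a named probability vector over the model
#'   categories; otherwise an n x K probability matrix. Both carry a
#'   logical \code{"degraded"} attribute (one flag per sample).
#' @examples
#' m <- skinModel(c("Light", "Dark"), intercepts = 0,
#'                coefficients = matrix(log(3), 1, 1,
#'                                      dimnames = list(NULL, "rs1")))
#' predictProbabilities(m, c(rs1 = 1))  # (0.25, 0.75)
#' @export
predictProbabilities <- function(model, dosages,
                                 missingPolicy = c("require_complete",
                                                   "drop_terms")) {
  missingPolicy <- match.arg(missingPolicy)
  single <- is.null(dim(dosages)) && !methods::is(dosages, "SkinGenotypes")
  X <- alignDosages(dosages, model@snpIds)
  degraded <- rowSums(is.na(X)) > 0
  if (missingPolicy == "require_complete" && any(degraded))
    stop("missing dosages for sample(s): ",
         paste(utils::head(which(degraded), 5), collapse = ", "),
         " (use missingPolicy = \"drop_terms\" to tolerate them)")
  eta <- linearPredictors(model, X)
  mx <- apply(eta, 1, max)
  ex <- exp(eta - mx)
  p <- ex / rowSums(ex)
  if (single) {
    out <- p[1, ]
    attr(out, "degraded") <- unname(degraded[1])
    return(out)
  }
  attr(p, "degraded") <- unname(degraded)
  p
}

#' Call the most probable skin colour category
#'
#' Argmax over a probability vector or matrix. Exact ties resolve to the
#' earliest category in the fixed (lightness-descending) order and are
#' flagged.
#'
#' @param p probability vector (named by category) or n x K matrix.
#' @return data.frame with columns \code{category} (factor in category
#'   order) and \code{tie} (logical), one row per sample.
#' @examples
#' classifyProbabilities(c(VeryPale = 0.1, Pale = 0.6, Intermediate = 0.2,
#'                         Dark = 0.05, DarkBlack = 0.05))
#' @export
classifyProbabilities <- function(p) {
  if (is.null(dim(p))) p <- matrix(p, 1, dimnames = list(NULL, names(p)))
  cats <- colnames(p)
  if (is.null(cats)) stop("probability columns must be named by category")
  best <- apply(p, 1, which.max)
  tie <- apply(p, 1, function(r) sum(r == max(r)) > 1L)
  data.frame(category = factor(cats[best], levels = cats), tie = tie)
}

#' Log-likelihood of observed categories under a model
#'
#' \eqn{\sum_i \log \pi_{y_i}(x_i)} over complete-genotype samples. A zero
#' predicted probability at an observed label yields \code{-Inf} (reported
#' explicitly, not an error).
#'
#' @param model a \linkS4class{SkinColourModel}.
#' @param X samples x SNPs dosage matrix (or \linkS4class{SkinGenotypes})
#'   with no missing values at the model SNPs.
#' @param y observed categories (factor or character, within the model's
#'   category set).
#' @return numeric scalar log-likelihood.
#' @export
logLikelihood <- function(model, X, y) {
  y <- as.character(y)
  bad <- !y %in% model@categories
  if (any(bad)) stop("labels outside model categories: ",
                     paste(unique(y[bad]), collapse = ", "))
  p <- predictProbabilities(model, X, missingPolicy = "require_complete")
  if (is.null(dim(p))) p <- matrix(p, 1, dimnames = list(NULL, names(p)))
  pi_obs <- p[cbind(seq_along(y), match(y, colnames(p)))]
  sum(ifelse(pi_obs > 0, log(pi_obs), -Inf))
}

#' Akaike Information Criterion of a skin colour model
#'
#' \eqn{2p - 2\ln L} with \eqn{p = (K-1)(k+1)} free parameters (K
#' categories, k SNPs; one intercept plus k betas per non-reference
#' category).
#'
#' @inheritParams logLikelihood
#' @return numeric AIC (lower is better).
#' @export
modelAIC <- function(model, X, y) {
  K <- length(model@categories)
  k <- length(model@snpIds)
  p <- (K - 1) * (k + 1)
  2 * p - 2 * logLikelihood(model, X, y)
}

#' Fit a multinomial logistic skin colour model
#'
#' Maximum-likelihood fitting by Newton-Raphson on the full observed
#' information matrix, with an optional small ridge penalty on the betas
#' (never the intercepts) to stabilize quasi-separated data. Convergence is
#' declared when the largest absolute parameter update falls below
#' \code{tol}. The reference category is the first of \code{categories},
#' matching the package-wide convention (Very Pale for the 5-category
#' scale, Light for the 3-category scale).
#'
#' @param X samples x SNPs dosage matrix (rsid colnames) or
#'   \linkS4class{SkinGenotypes}; complete cases only.
#' @param y observed categories, one per sample.
#' @param categories ordered category labels; defaults to \code{levels(y)}
#'   for a factor. Every declared category must occur in \code{y}.
#' @param maxIter maximum Newton iterations.
#' @param tol convergence tolerance on the parameter update.
#' @param ridge ridge penalty on betas (default \code{1e-6}; set 0 for a
#'   pure ML fit).
#' @return A fitted \linkS4class{SkinColourModel}; \code{fitDetails()}
#'   carries \code{logLik}, \code{converged}, \code{iterations},
#'   \code{se} (standard errors in the same layout as the parameters),
#'   \code{n} and \code{ridge}. Non-convergence raises an error of class
#'   \code{skintyperNonconvergence} carrying the last iterate in its
#'   \code{model} field.
#' @examples
#' set.seed(1)
#' X <- matrix(rbinom(200, 2, 0.4), 100, 2,
#'             dimnames = list(NULL, c("rs1", "rs2")))
#' y <- ifelse(runif(100) < stats::plogis(-1 + X[, 1]), "Dark", "Light")
#' fitMlr(X, factor(y, levels = c("Light", "Dark")))
#' @export
fitMlr <- function(X, y, categories = NULL, maxIter = 100L, tol = 1e-8,
                   ridge = 1e-6) {
  if (methods::is(X, "SkinGenotypes")) X <- sampleDosages(X)
  X <- as.matrix(X)
  if (is.null(categories))
    categories <- if (is.factor(y)) levels(y) else unique(as.character(y))
  y <- as.character(y)
  if (length(y) != nrow(X)) stop("length(y) must equal nrow(X)")
  if (anyNA(X)) stop("X must contain complete genotypes (no missing dosages)")
  if (!all(y %in% categories))
    stop("labels outside declared categories")
  absent <- setdiff(categories, y)
  if (length(absent))
    stop("category absent from y: ", paste(absent, collapse = ", "))
  K <- length(categories)
  if (K < 2) stop("need at least two categories")
  k <- ncol(X)
  n <- nrow(X)
  if (n <= (K - 1) + k)
    stop(sprintf("too few samples (n = %d) for K = %d categories and k = %d SNPs",
                 n, K, k))
  snpIds <- colnames(X)
  if (k > 0 && is.null(snpIds)) stop("X must have rsid colnames")

  Z <- cbind(`(Intercept)` = 1, X)
  pZ <- k + 1L
  nonRef <- categories[-1L]
  Y <- vapply(nonRef, function(cc) as.numeric(y == cc), numeric(n))
  penMask <- c(0, rep(1, k))  # ridge applies to betas only

  theta <- matrix(0, pZ, K - 1L,
                  dimnames = list(colnames(Z), nonRef))
  penLogLik <- function(theta) {
    eta <- cbind(0, Z %*% theta)
    mx <- apply(eta, 1, max)
    lse <- mx + log(rowSums(exp(eta - mx)))
    etaObs <- eta[cbind(seq_len(n), match(y, categories))]
    sum(etaObs - lse) - ridge * sum((penMask * theta)^2)
  }
  probs <- function(theta) {
    eta <- cbind(0, Z %*% theta)
    mx <- apply(eta, 1, max)
    ex <- exp(eta - mx)
    ex / rowSums(ex)
  }

  ll <- penLogLik(theta)
  converged <- FALSE
  iter <- 0L
  info <- NULL
  while (iter < maxIter) {
    iter <- iter + 1L
    P <- probs(theta)[, -1L, drop = FALSE]  # n x (K-1), non-reference
    grad <- numeric(pZ * (K - 1L))
    info <- matrix(0, pZ * (K - 1L), pZ * (K - 1L))
    for (m in seq_len(K - 1L)) {
      idx <- ((m - 1L) * pZ + 1L):(m * pZ)
      grad[idx] <- crossprod(Z, Y[, m] - P[, m]) -
        2 * ridge * penMask * theta[, m]
      for (mp in m:(K - 1L)) {
        w <- P[, m] * ((m == mp) - P[, mp])
        blk <- crossprod(Z, w * Z)
        jdx <- ((mp - 1L) * pZ + 1L):(mp * pZ)
        info[idx, jdx] <- blk
        info[jdx, idx] <- t(blk)
      }
    }
    info <- info + diag(rep(2 * ridge * penMask, K - 1L), nrow(info))
    step <- tryCatch(solve(info, grad), error = function(e)
      solve(info + diag(1e-8, nrow(info)), grad))
    stepM <- matrix(step, pZ, K - 1L)
    newTheta <- theta + stepM
    newLL <- penLogLik(newTheta)
    halvings <- 0L
    while ((!is.finite(newLL) || newLL < ll - 1e-10) && halvings < 30L) {
      stepM <- stepM / 2
      newTheta <- theta + stepM
      newLL <- penLogLik(newTheta)
      halvings <- halvings + 1L
    }
    theta <- newTheta
    ll <- newLL
    if (max(abs(stepM)) < tol) {
      converged <- TRUE
      break
    }
  }

  se <- tryCatch({
    v <- diag(solve(info))
    matrix(sqrt(pmax(v, 0)), pZ, K - 1L,
           dimnames = list(colnames(Z), nonRef))
  }, error = function(e) NULL)
  lnL <- ll + ridge * sum((penMask * theta)^2)
  model <- skinModel(categories,
                     intercepts = theta[1L, ],
                     coefficients = t(theta[-1L, , drop = FALSE]),
                     snpIds = snpIds,
                     fit = list(logLik = lnL, converged = converged,
                                iterations = iter, se = se, n = n,
                                ridge = ridge))
  if (!converged) {
    cond <- structure(
      class = c("skintyperNonconvergence", "error", "condition"),
      list(message = sprintf(
             "MLR fit did not converge in %d iterations (last max update %.3g)",
             maxIter, max(abs(theta))),
           call = sys.call(-1), model = model))
    stop(cond)
  }
  model
}

#' Read and write skin colour model files
#'
#' Tab-separated model format: two comment header lines recording the
#' category order and the reference category, then a \code{term} table with
#' one column per non-reference category, an \code{(Intercept)} row, and
#' one row per SNP. Numbers are written at full precision
#' (\code{\%.17g}), so write/read round-trips are bit-exact.
#'
#' @param model a \linkS4class{SkinColourModel}.
#' @param path file path.
#' @return \code{writeModel} returns \code{path} invisibly;
#'   \code{readModel} returns a \linkS4class{SkinColourModel}.
#' @export
writeModel <- function(model, path) {
  nonRef <- rownames(model@coefficients)
  lines <- c(
    paste0("#categories\t", paste(model@categories, collapse = ",")),
    paste0("#reference\t", referenceCategory(model)),
    paste(c("term", nonRef), collapse = "\t"),
    paste(c("(Intercept)", formatExact(model@intercepts)), collapse = "\t"))
  for (j in seq_along(model@snpIds))
    lines <- c(lines, paste(c(model@snpIds[j],
                              formatExact(model@coefficients[, j])),
                            collapse = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname writeModel
#' @export
readModel <- function(path) {
  lines <- readLines(path)
  getHeader <- function(key) {
    ln <- grep(paste0("^#", key, "\t"), lines, value = TRUE)
    if (length(ln) != 1L) stop("model file lacks #", key, " header")
    sub(paste0("^#", key, "\t"), "", ln)
  }
  categories <- strsplit(getHeader("categories"), ",", fixed = TRUE)[[1]]
  reference <- getHeader("reference")
  body <- lines[!startsWith(lines, "#")]
  tab <- utils::read.delim(text = body, sep = "\t", header = TRUE,
                           check.names = FALSE, colClasses = "character")
  if (names(tab)[1] != "term" || tab$term[1] != "(Intercept)")
    stop("malformed model file: expected a term table starting at (Intercept)")
  vals <- apply(as.matrix(tab[, -1, drop = FALSE]), c(1, 2), as.numeric)
  skinModel(categories, intercepts = vals[1, ],
            coefficients = t(vals[-1, , drop = FALSE]),
            reference = reference, snpIds = tab$term[-1])
}
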