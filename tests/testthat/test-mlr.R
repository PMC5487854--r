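# The multinomial logistic regression core.

cats5 <- skinCategories5()

randomModel <- function(K, k, seed) {
  withr::with_seed(seed, {
    skinModel(paste0("C", seq_len(K)),
              intercepts = rnorm(K - 1),
              coefficients = matrix(rnorm((K - 1) * k), K - 1, k),
              snpIds = sprintf("rs%03d", seq_len(k)))
  })
}

test_that("predicted probabilities follow the softmax form", {
  # all parameters zero -> uniform over categories
  m0 <- skinModel(cats5, intercepts = rep(0, 4),
                  coefficients = matrix(0, 4, 3),
                  snpIds = c("a", "b", "c"))
  p <- predictProbabilities(m0, c(a = 2, b = 0, c = 1))
  expect_equal(as.numeric(p), rep(0.2, 5), tolerance = 1e-12)

  # two categories, single SNP with beta = ln 3, dosage 1 -> (0.25, 0.75)
  m <- skinModel(c("Light", "Dark"), intercepts = 0,
                 coefficients = matrix(log(3), 1, 1,
                                       dimnames = list(NULL, "rs1")))
  expect_equal(as.numeric(predictProbabilities(m, c(rs1 = 1))),
               c(0.25, 0.75), tolerance = 1e-12)

  # normalization for random models and dosages
  for (seed in 1:25) {
    m <- randomModel(K = sample(2:5, 1), k = 4, seed = seed)
    x <- withr::with_seed(seed + 1000,
      setNames(sample(0:2, 4, replace = TRUE), modelSnpIds(m)))
    p <- predictProbabilities(m, x)
    expect_equal(sum(p), 1, tolerance = 1e-9)
    expect_true(all(p >= 0 & p <= 1))
  }
})

test_that("probabilities are invariant to a reference-category change", {
  m <- randomModel(K = 4, k = 3, seed = 7)
  x <- c(rs001 = 1, rs002 = 2, rs003 = 0)
  p <- predictProbabilities(m, x)
  # re-parameterize against category 3: subtract its linear predictor
  a <- c(0, modelIntercepts(m))          # include old reference's zero
  B <- rbind(0, modelCoefficients(m))
  newRef <- 3L
  a2 <- (a - a[newRef])[-newRef]
  B2 <- sweep(B, 2, B[newRef, ])[-newRef, ]
  m2 <- skinModel(modelCategories(m), intercepts = a2, coefficients = B2,
                  reference = modelCategories(m)[newRef],
                  snpIds = modelSnpIds(m))
  expect_equal(as.numeric(predictProbabilities(m2, x)), as.numeric(p),
               tolerance = 1e-12)
})

test_that("missing-dosage policies behave as documented", {
  m <- randomModel(K = 3, k = 3, seed = 11)
  x <- c(rs001 = 1, rs002 = NA, rs003 = 2)
  expect_error(predictProbabilities(m, x), "missing dosages")
  p <- predictProbabilities(m, x, missingPolicy = "drop_terms")
  expect_true(attr(p, "degraded"))
  # dropping terms equals zeroing that SNP's contribution
  x0 <- c(rs001 = 1, rs002 = 0, rs003 = 2)
  pZero <- predictProbabilities(m, x0)
  expect_equal(as.numeric(p), as.numeric(pZero), tolerance = 1e-12)
  # with no missing values, both policies agree exactly
  pa <- predictProbabilities(m, x0)
  pb <- predictProbabilities(m, x0, missingPolicy = "drop_terms")
  expect_identical(as.numeric(pa), as.numeric(pb))
  expect_false(attr(pb, "degraded"))
  expect_error(predictProbabilities(m, c(rs001 = 3, rs002 = 0, rs003 = 0)),
               "outside")
})

test_that("classification takes the argmax with flagged ties", {
  p <- c(0.1, 0.6, 0.2, 0.05, 0.05)
  names(p) <- cats5
  call <- classifyProbabilities(p)
  expect_identical(as.character(call$category), "Pale")
  expect_false(call$tie)

  uni <- setNames(rep(0.2, 5), cats5)
  call <- classifyProbabilities(uni)
  expect_identical(as.character(call$category), "VeryPale")
  expect_true(call$tie)

  # argmax invariant under positive rescaling before normalization
  for (seed in 1:20) {
    raw <- withr::with_seed(seed, runif(5))
    s <- withr::with_seed(seed + 99, runif(1, 0.1, 10))
    a <- classifyProbabilities(setNames(raw / sum(raw), cats5))
    b <- classifyProbabilities(setNames(s * raw / sum(s * raw), cats5))
    expect_identical(a$category, b$category)
  }
})

test_that("two-category fits agree with binary logistic regression", {
  withr::with_seed(42, {
    X <- matrix(rbinom(1500, 2, 0.35), 500, 3,
                dimnames = list(NULL, c("rs1", "rs2", "rs3")))
    eta <- -0.5 + 0.8 * X[, 1] - 0.4 * X[, 2]
    y <- ifelse(runif(500) < plogis(eta), "Dark", "Light")
  })
  fit <- fitMlr(X, factor(y, levels = c("Light", "Dark")), ridge = 0)
  oracle <- glm(I(y == "Dark") ~ X, family = binomial,
                control = list(epsilon = 1e-12))
  est <- c(modelIntercepts(fit), modelCoefficients(fit))
  expect_equal(unname(est), unname(coef(oracle)), tolerance = 1e-6)
  expect_equal(fitDetails(fit)$logLik, as.numeric(logLik(oracle)),
               tolerance = 1e-9)
})

test_that("multi-category fits agree with an independent optimizer", {
  skip_if_not_installed("nnet")
  d <- makeLabelledData(n = 1200, effects = c(0.9, -0.6, 0.4), seed = 5)
  fit <- fitMlr(d$X, d$y, ridge = 0)
  oracle <- nnet::multinom(d$y ~ d$X, trace = FALSE, maxit = 500,
                           reltol = 1e-14)
  expect_equal(fitDetails(fit)$logLik, -oracle$value, tolerance = 1e-6)
  est <- cbind(modelIntercepts(fit), modelCoefficients(fit))
  expect_equal(unname(est), unname(coef(oracle)), tolerance = 1e-4)
})

test_that("fitting recovers generating parameters from simulated data", {
  d <- makeLabelledData(n = 5000, effects = c(0.8, -0.5, 0.3, 0, 0.6),
                        seed = 8)
  fit <- fitMlr(d$X, d$y)
  se <- fitDetails(fit)$se
  expect_false(is.null(se))
  truth <- t(cbind(modelIntercepts(d$model), modelCoefficients(d$model)))
  est <- t(cbind(modelIntercepts(fit), modelCoefficients(fit)))
  expect_true(all(abs(est - truth) < 3 * se))
})

test_that("degenerate fits are rejected", {
  X <- matrix(rbinom(100, 2, 0.5), 50, 2,
              dimnames = list(NULL, c("rs1", "rs2")))
  expect_error(fitMlr(X, rep("Light", 50)), "at least two|absent")
  expect_error(fitMlr(X, factor(rep("Light", 50),
                                levels = c("Light", "Dark"))),
               "absent")
  expect_error(fitMlr(X[1:3, ], c("L", "D", "L")), "too few")
  Xna <- X; Xna[1, 1] <- NA
  expect_error(fitMlr(Xna, rep(c("L", "D"), 25)), "complete")
})

test_that("log-likelihood and AIC follow their definitions", {
  # uniform five-category model, n = 10 -> 10 * log(1/5)
  m0 <- skinModel(cats5, intercepts = rep(0, 4),
                  coefficients = matrix(0, 4, 0))
  X <- matrix(numeric(0), 10, 0)
  y <- rep(c("Pale", "Dark"), 5)
  expect_equal(logLikelihood(m0, X, y), 10 * log(1 / 5), tolerance = 1e-12)
  expect_equal(modelAIC(m0, X, y), 2 * 4 - 2 * 10 * log(1 / 5),
               tolerance = 1e-12)

  # additivity over disjoint subsets
  m <- randomModel(K = 3, k = 2, seed = 3)
  Xr <- withr::with_seed(4, matrix(sample(0:2, 40, TRUE), 20, 2,
                                   dimnames = list(NULL, modelSnpIds(m))))
  yr <- withr::with_seed(5, sample(paste0("C", 1:3), 20, TRUE))
  expect_equal(logLikelihood(m, Xr, yr),
               logLikelihood(m, Xr[1:8, ], yr[1:8]) +
                 logLikelihood(m, Xr[9:20, ], yr[9:20]),
               tolerance = 1e-10)

  # a certain model scores 0; an impossible observation scores -Inf
  sure <- skinModel(c("Light", "Dark"), intercepts = -800,
                    coefficients = matrix(0, 1, 0))
  expect_equal(logLikelihood(sure, matrix(numeric(0), 3, 0),
                             rep("Light", 3)), 0)
  expect_identical(logLikelihood(sure, matrix(numeric(0), 1, 0), "Dark"),
                   -Inf)
})

test_that("adding a null SNP raises AIC by exactly 2(K-1)", {
  m <- randomModel(K = 4, k = 2, seed = 9)
  Xr <- withr::with_seed(10, matrix(sample(0:2, 60, TRUE), 30, 2,
                                    dimnames = list(NULL, modelSnpIds(m))))
  yr <- withr::with_seed(11, sample(paste0("C", 1:4), 30, TRUE))
  mPlus <- skinModel(modelCategories(m), intercepts = modelIntercepts(m),
                     coefficients = cbind(modelCoefficients(m),
                                          rs_null = 0),
                     snpIds = c(modelSnpIds(m), "rs_null"))
  XPlus <- cbind(Xr, rs_null = withr::with_seed(12, sample(0:2, 30, TRUE)))
  expect_equal(modelAIC(mPlus, XPlus, yr) - modelAIC(m, Xr, yr), 2 * 3,
               tolerance = 1e-10)
})

test_that("model files round-trip bit-exactly", {
  d <- makeLabelledData(n = 600, effects = c(0.7, -0.3), seed = 21)
  fit <- fitMlr(d$X, d$y)
  path <- withr::local_tempfile(fileext = ".tsv")
  writeModel(fit, path)
  back <- readModel(path)
  expect_identical(modelCategories(back), modelCategories(fit))
  expect_identical(referenceCategory(back), referenceCategory(fit))
  expect_identical(modelSnpIds(back), modelSnpIds(fit))
  expect_identical(unname(modelIntercepts(back)),
                   unname(modelIntercepts(fit)))
  expect_identical(unname(modelCoefficients(back)),
                   unname(modelCoefficients(fit)))
})
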