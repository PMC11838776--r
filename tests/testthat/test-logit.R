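test_that("logistic IRLS agrees with glm on regular designs", {
  d <- toyLogisticDesign(120, c(1.2, -0.8), seed = 21)
  fit <- fitLogit(d, c("f1", "f2"))
  ref <- glm(outcome ~ f1 + f2, data = d, family = binomial())
  expect_equal(unname(coef(fit)), unname(coef(ref)), tolerance = 1e-7)
  expect_equal(fit@deviance, deviance(ref), tolerance = 1e-9)
  expect_equal(unname(fit@se),
               unname(sqrt(diag(vcov(ref)))), tolerance = 1e-5)
  # predict-after-fit reproduces the fitted probabilities
  p <- predictPtspo(fit, d)
  expect_equal(p$p_tspo, unname(fitted(ref)), tolerance = 1e-10)
})

test_that("symmetric data give the null fit, separation is diagnosed", {
  d <- data.frame(subject_id = paste0("s", 1:4), roi_id = "r",
                  dataset_id = "d1", outcome = c(0, 1, 0, 1),
                  f1 = c(0, 0, 1, 1))
  fit <- fitLogit(d, "f1")
  expect_equal(unname(coef(fit)), c(0, 0), tolerance = 1e-8)

  sep <- data.frame(subject_id = paste0("s", 1:8), roi_id = "r",
                    dataset_id = "d1",
                    outcome = rep(c(0, 1), each = 4),
                    f1 = c(1:4, 6:9) / 10)
  expect_error(fitLogit(sep, "f1"), "separation")
  fr <- fitLogit(sep, "f1", ridge = 1e-4)
  expect_true(all(is.finite(coef(fr))))
  expect_true(fr@converged)

  dup <- d; dup$f2 <- dup$f1
  expect_error(fitLogit(dup, c("f1", "f2")), "collinearity")
  const <- d; const$f2 <- 1
  expect_error(fitLogit(const, c("f1", "f2")), "constant")
})

test_that("rescaling a feature leaves fitted probabilities unchanged", {
  d <- toyLogisticDesign(150, c(1, -1.5), seed = 8)
  f1 <- fitLogit(d, c("f1", "f2"))
  d2 <- d; d2$f1 <- (d$f1 - 0.2) / 3
  f2 <- fitLogit(d2, c("f1", "f2"))
  expect_equal(coef(f2)[["f1"]], 3 * coef(f1)[["f1"]], tolerance = 1e-6)
  expect_equal(predictPtspo(f2, d2)$p_tspo, predictPtspo(f1, d)$p_tspo,
               tolerance = 1e-8)
})

test_that("prediction follows the closed-form logistic map", {
  spec <- featureSpec(gridMinutes = numeric(0), covariates = "age")
  mk <- function(b0, b1 = 0) {
    sel <- c(age = TRUE)
    new("TspoLogitModel",
        coefficients = c(`(Intercept)` = b0, age = b1),
        se = c(1, 1), zstat = c(b0, b1), deviance = 0, nullDeviance = 0,
        converged = TRUE, iterations = 1L,
        randomIntercepts = numeric(0), randomSD = numeric(0),
        featureSpec = spec, fitInfo = list())
  }
  nd <- data.frame(age = 0)
  expect_equal(predictPtspo(mk(0), nd)$p_tspo, 0.5)
  expect_equal(predictPtspo(mk(2), nd)$p_tspo, 1 / (1 + exp(-2)),
               tolerance = 1e-12)
  expect_equal(round(predictPtspo(mk(2), nd)$p_tspo, 4), 0.8808)
  # monotonicity in a positive-coefficient feature
  nd2 <- data.frame(age = seq(0, 1, 0.1))
  p <- predictPtspo(mk(0, 3), nd2)$p_tspo
  expect_true(all(diff(p) > 0))
  expect_error(predictPtspo(mk(0, 1), data.frame(x = 1)),
               "missing feature")
})

test_that("Wald screening keeps strong predictors and drops null ones", {
  d <- toyLogisticDesign(400, c(2.5, 0), seed = 5)
  fit <- fitLogit(d, c("f1", "f2"))
  kept <- waldScreen(fit)
  expect_true("f1" %in% kept)
  expect_false("f2" %in% kept)
  expect_setequal(waldScreen(fit, 0), c("f1", "f2"))
})

test_that("hierarchical fit degenerates to the plain fit and detects
           null heterogeneity", {
  d1 <- toyLogisticDesign(300, c(1, -1), seed = 31)
  expect_message(h1 <- fitHierLogit(d1, c("f1", "f2")), "single dataset")
  p1 <- fitLogit(d1, c("f1", "f2"))
  expect_equal(coef(h1), coef(p1), tolerance = 1e-8)

  # three identical-offset datasets: between-dataset sd is near zero
  d0 <- toyLogisticDesign(900, c(1, -1), seed = 32,
                          datasetOffsets = c(0, 0, 0))
  h0 <- fitHierLogit(d0, c("f1", "f2"))
  expect_lt(h0@randomSD, 0.1)
  expect_lt(abs(mean(h0@randomIntercepts)), 1e-6)
})

test_that("model bundles round-trip through JSON", {
  d <- toyLogisticDesign(200, c(1, -1), seed = 33,
                         datasetOffsets = c(-0.5, 0.5))
  fit <- fitHierLogit(d, c("f1", "f2"))
  f <- tempfile(fileext = ".json")
  writeModelBundle(fit, f)
  back <- readModelBundle(f)
  expect_equal(coef(back), coef(fit), tolerance = 1e-12)
  expect_equal(back@randomIntercepts, fit@randomIntercepts,
               tolerance = 1e-12)
  expect_equal(predictPtspo(back, d)$p_tspo,
               predictPtspo(fit, d)$p_tspo, tolerance = 1e-12)
  unlink(f)
})
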