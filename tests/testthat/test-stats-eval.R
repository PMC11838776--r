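test_that("ROC analysis matches the pairwise concordance oracle", {
  # perfectly separated scores
  roc <- rocAnalysis(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1))
  expect_equal(auc(roc), 1)
  # random instances with ties: trapezoid AUC == O(n^2) concordance
  set.seed(17)
  for (rep in 1:3) {
    sc <- round(runif(50), 1)          # coarse scores force ties
    lb <- rbinom(50, 1, 0.4)
    if (length(unique(lb)) < 2) lb[1:2] <- c(0, 1)
    roc <- rocAnalysis(sc, lb)
    pos <- sc[lb == 1]; neg <- sc[lb == 0]
    conc <- 0
    for (p in pos) for (n in neg)
      conc <- conc + (p > n) + 0.5 * (p == n)
    expect_equal(auc(roc), conc / (length(pos) * length(neg)),
                 tolerance = 1e-12)
    # invariance under strictly monotone transforms of the scores
    expect_equal(auc(rocAnalysis(qlogis(pmin(pmax(sc, 1e-3), 1 - 1e-3)),
                                 lb)),
                 auc(roc), tolerance = 1e-12)
  }
  expect_error(rocAnalysis(1:4, rep(1, 4)), "undefined-AUC")
  # sensitivity is non-increasing as the threshold rises
  roc <- rocAnalysis(runif(30), rbinom(30, 1, 0.5))
  expect_true(all(diff(roc@sensitivity[order(roc@thresholds)]) <= 0))
})

test_that("Delta_P identities: null, full displacement, antisymmetry", {
  x <- runif(40)
  same <- deltaP(x, x)
  expect_equal(deltaPValue(same), 0)
  expect_equal(sum(same@histCase), 1, tolerance = 1e-12)
  expect_equal(sum(same@deviation), 0, tolerance = 1e-12)

  up <- deltaP(rep(0.9, 25), rep(0.1, 25))
  expect_equal(deltaPValue(up), 100)
  down <- deltaP(rep(0.1, 25), rep(0.9, 25))
  expect_equal(deltaPValue(down), -100)

  set.seed(2)
  a <- runif(30); b <- runif(35)
  expect_equal(deltaPValue(deltaP(a, b)), -deltaPValue(deltaP(b, a)),
               tolerance = 1e-12)
  expect_error(deltaP(a, b, binWidth = 0.07), "config error")
})

test_that("Wilcoxon wrapper gives exact small-sample p-values", {
  expect_equal(groupTest(1:3, 4:6)$p_value, 0.1, tolerance = 1e-12)
  expect_equal(groupTest(1:3, 4:6)$test, "rank-sum")
  same <- groupTest(c(1, 2, 3), c(1, 2, 3), paired = TRUE)
  expect_equal(same$p_value, 1)
  expect_equal(same$test, "signed-rank")
  expect_error(groupTest(1:3, 1:4, paired = TRUE), "equal-length")
  # shifted cohorts are detected
  set.seed(19)
  a <- rnorm(50, 1); b <- rnorm(50, 0)
  expect_lt(groupTest(a, b)$p_value, 0.01)
})

test_that("ICC(A,1) matches the ANOVA mean-squares oracle", {
  expect_equal(iccTestRetest(1:10, 1:10)$icc, 1, tolerance = 1e-12)
  # constructed 2 x 10 table against independent aov() arithmetic
  set.seed(23)
  t1 <- rnorm(10, 5, 2); t2 <- t1 + rnorm(10, 0.3, 0.8)
  got <- iccTestRetest(t1, t2)
  long <- data.frame(y = c(t1, t2),
                     subj = factor(rep(1:10, 2)),
                     sess = factor(rep(1:2, each = 10)))
  ms <- summary(stats::aov(y ~ subj + sess, data = long))[[1]][
    , "Mean Sq"]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  ref <- (msr - mse) / (msr + mse + (2 / 10) * (msc - mse))
  expect_equal(got$icc, unname(ref), tolerance = 1e-10)
  # pure noise retest: near-zero ICC at large n
  set.seed(24)
  big <- rnorm(2000)
  expect_lt(abs(iccTestRetest(big, rnorm(2000))$icc), 0.08)
  # zero between-subject variance is flagged, not fabricated
  expect_true(is.na(iccTestRetest(rep(1, 5), rep(1, 5))$icc))
})

test_that("expression concordance is a rank correlation over common ROIs", {
  em <- data.frame(roi_id = paste0("r", 1:8),
                   expression = c(1, 3, 2, 7, 5, 8, 6, 4))
  p <- setNames(plogis(em$expression - 4), em$roi_id)  # monotone map
  expect_equal(expressionConcordance(p, em)$rho, 1)
  expect_equal(expressionConcordance(setNames(-p, names(p)), em)$rho, -1)
  expect_error(expressionConcordance(p[1:3], em), "insufficient-data")
})

test_that("BH-FDR follows the step-up rule", {
  r <- fdrAdjust(c(0.01, 0.02, 0.03), q = 0.05)
  expect_true(all(r$reject))            # 0.03 <= (3/3) * 0.05
  expect_equal(r$adjusted, c(0.03, 0.03, 0.03))
  expect_false(any(fdrAdjust(rep(1, 5))$reject))
  expect_equal(fdrAdjust(0.2)$adjusted, 0.2)    # single p unchanged
  expect_error(fdrAdjust(c(0.1, 1.2)), "\\[0, 1\\]")
  # adjusted values are monotone in the raw ordering
  set.seed(29)
  p <- runif(20)
  adj <- fdrAdjust(p)$adjusted
  expect_true(all(diff(adj[order(p)]) >= -1e-15))
})

test_that("hemispheric screen selects nothing under the null", {
  set.seed(31)
  base <- matrix(rnorm(4 * 13, 100, 1), 4, 13,
                 dimnames = list(NULL, ratRegionRoster()))
  sc <- hemisphericAucScreen(base + rnorm(52, 0, 1), base)
  expect_equal(sum(sc$selected), 0L)
  expect_error(hemisphericAucScreen(base[1, , drop = FALSE],
                                    base[1, , drop = FALSE]),
               "3 animals")
})
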