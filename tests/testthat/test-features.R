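test_that("SUV conversion follows the dose-over-weight definition", {
  fs <- tinySchedule(4)
  te <- TacExperiment(matrix(10, 1, 4), fs, "s1", "roi",
                      subjects = demoSubjects("s1", dose = 500,
                                              weight = 50))
  suv <- toSUV(te)
  expect_equal(unname(activity(suv)[1, ]), rep(1, 4))  # 10 / (500/50)
  expect_identical(metadata(suv)$units, "SUV")

  # doubling the dose halves the SUV
  te2 <- TacExperiment(matrix(10, 1, 4), fs, "s1", "roi",
                       subjects = demoSubjects("s1", dose = 1000,
                                               weight = 50))
  expect_equal(unname(activity(toSUV(te2))[1, ]), rep(0.5, 4))

  # all-zero TAC stays all-zero
  te3 <- TacExperiment(matrix(0, 1, 4), fs, "s1", "roi",
                       subjects = demoSubjects("s1"))
  expect_equal(unname(activity(toSUV(te3))[1, ]), rep(0, 4))

  bad <- demoSubjects("s1"); bad$injected_dose <- 0
  te4 <- TacExperiment(matrix(1, 1, 4), fs, "s1", "roi", subjects = bad)
  expect_error(toSUV(te4), "covariate error")
})

test_that("sparse-grid sampling interpolates linearly with a strict range", {
  fs <- FrameSchedule(start = c(0.5, 1.5), duration = c(1, 1))
  expect_equal(sampleOnGrid(c(0, 10), fs, 1.25), 2.5)
  fsc <- tinySchedule(10)
  expect_equal(sampleOnGrid(rep(3, 10), fsc, c(1.25, 4.5, 7)),
               rep(3, 3))
  # the 60-minute schedule serves 1.25/13.5/50 but not 75 by default
  s60 <- pbr28ShortSchedule()
  y <- seq_len(nFrames(s60))
  expect_silent(sampleOnGrid(y, s60, c(1.25, 13.5, 50)))
  expect_error(sampleOnGrid(y, s60, 75), "outside the sampled range")
  expect_warning(v <- sampleOnGrid(y, s60, 75, policy = "nearest"),
                 "nearest")
  expect_equal(v, y[nFrames(s60)])
})

test_that("min-max normalization is invertible and never clips", {
  set.seed(3)
  X <- matrix(runif(40, -5, 9), 10, 4,
              dimnames = list(NULL, paste0("f", 1:4)))
  Xn <- normalizeFeatures(X)
  b <- attr(Xn, "bounds")
  expect_equal(unname(apply(Xn, 2, min)), rep(0, 4))
  expect_equal(unname(apply(Xn, 2, max)), rep(1, 4))
  expect_equal(denormalizeFeatures(Xn, b), unname(X) * 1,
               tolerance = 1e-12, ignore_attr = TRUE)
  # applying training bounds to larger values exceeds 1 and is retained
  Xbig <- X; Xbig[1, 1] <- max(X[, 1]) + 5
  Xn2 <- normalizeFeatures(Xbig, b)
  expect_gt(Xn2[1, 1], 1)
  expect_error(normalizeFeatures(cbind(X, const = 1)),
               "degenerate-feature")
})

test_that("design assembly encodes outcomes, covariates and bounds", {
  coh <- generateCohort(smallCohortConfig(n = 5L, seed = 4L))
  k1 <- estimateCohortK1(coh$tacs, coh$inputs, window = 4)
  d <- buildDesign(coh$tacs, k1, labels = coh$expressionMap)
  spec <- attr(d, "spec")
  expect_s4_class(spec, "FeatureSpec")
  feats <- spec@featureNames
  expect_setequal(feats, c(paste0("tac_", c(1.25, 4.5, 13.5, 30, 50, 75)),
                           "K1", "age", "sex", "genotype",
                           "dose_over_weight"))
  # outcome labels: low -> 0, high -> 1, rest unlabelled
  lab <- coh$expressionMap
  expect_true(all(d$outcome[d$roi_id %in%
                              lab$roi_id[lab$class_label == "low"]] == 0))
  expect_true(all(d$outcome[d$roi_id %in%
                              lab$roi_id[lab$class_label == "high"]] == 1))
  expect_true(all(is.na(d$outcome[d$roi_id %in%
                                    lab$roi_id[lab$class_label ==
                                                 "unlabelled"]])))
  # fit mode: every feature spans [0, 1] on the training rows
  tr <- d[!is.na(d$outcome), feats]
  expect_equal(unname(apply(tr, 2, min)), rep(0, length(feats)))
  expect_equal(unname(apply(tr, 2, max)), rep(1, length(feats)))

  # permutation invariance up to row order
  perm <- sample(nrow(coh$tacs))
  d2 <- buildDesign(coh$tacs[perm, ], k1, labels = coh$expressionMap)
  key <- function(x) x[order(x$subject_id, x$roi_id), , drop = FALSE]
  expect_equal(key(d2), key(d), ignore_attr = TRUE)

  # apply mode keeps the persisted bounds
  d3 <- buildDesign(coh$tacs, k1, labels = coh$expressionMap,
                    bounds = attr(d, "bounds"))
  expect_equal(d3[feats], d[feats], ignore_attr = TRUE)

  # missing K1 rows are a hard error
  expect_error(buildDesign(coh$tacs, k1[-1, ],
                           labels = coh$expressionMap), "missing K1")
})
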