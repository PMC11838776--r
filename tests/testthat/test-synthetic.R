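test_that("expression map orders the training classes by construction", {
  em <- generateExpressionMap()
  expect_identical(em$class_label[which.min(em$expression)], "low")
  expect_identical(em$class_label[which.max(em$expression)], "high")
  expect_identical(generateExpressionMap(), em)   # deterministic
  # scores and the generating binding rates are rank-identical: k3 is an
  # increasing linear map of expression
  k3 <- 0.02 + 0.13 * em$expression
  expect_equal(cor(k3, em$expression, method = "spearman"), 1)
})

test_that("cohorts are seed-deterministic with seed-invariant structure", {
  cfgA <- smallCohortConfig(n = 3L, seed = 5L)
  a <- generateCohort(cfgA)
  b <- generateCohort(cfgA)
  expect_identical(activity(a$tacs), activity(b$tacs))
  c2 <- generateCohort(smallCohortConfig(n = 3L, seed = 6L))
  expect_false(identical(activity(a$tacs), activity(c2$tacs)))
  # ground-truth structure (labels, expression, roster) is seed-invariant
  expect_identical(a$expressionMap, c2$expressionMap)
  expect_identical(a$roster, c2$roster)
  expect_identical(a$truth$class_label, c2$truth$class_label)
})

test_that("generated activity is non-negative with physiological SUV", {
  coh <- generateCohort(smallCohortConfig(n = 5L, seed = 7L))
  expect_true(all(activity(coh$tacs) >= 0))
  suv <- activity(toSUV(coh$tacs))
  late <- suv[, nFrames(coh$tacs)]
  expect_true(all(late > 0.02 & late < 12))
  expect_true(all(quantile(late, c(0.05, 0.95)) > 0.1 &
                    quantile(late, c(0.05, 0.95)) < 5))
})

test_that("zero variability and noise give identical TACs within dataset", {
  cfg <- smallCohortConfig(n = 3L, seed = 8L, ageRange = c(40, 40),
                           maleFraction = 1, habFraction = 1,
                           doseSd = 0, weightSd = 0,
                           subjectBindingSd = 0, regionJitterSd = 0,
                           inputJitterSd = 0, k1JitterSd = 0,
                           noiseScale = 0)
  coh <- generateCohort(cfg)
  a <- activity(coh$tacs)
  rd <- rowData(coh$tacs)
  r1 <- a[rd$subject_id == "ds1_s01", ]
  r2 <- a[rd$subject_id == "ds1_s02", ]
  expect_equal(unname(r1), unname(r2), tolerance = 1e-14)
})

test_that("mixed-affinity binders show lower high-region late uptake", {
  cfg <- smallCohortConfig(n = 16L, seed = 9L, noiseScale = 0,
                           subjectBindingSd = 0, regionJitterSd = 0,
                           inputJitterSd = 0, k1JitterSd = 0,
                           ageRange = c(40, 40), maleFraction = 1,
                           doseSd = 0, weightSd = 0, habFraction = 0.5)
  coh <- generateCohort(cfg)
  suv <- activity(toSUV(coh$tacs))
  rd <- rowData(coh$tacs)
  sub <- as.data.frame(coh$subjects)
  hiRois <- coh$roster$roi_id[coh$roster$class_label == "high"]
  geno <- sub$genotype[match(rd$subject_id, sub$subject_id)]
  hi <- rd$roi_id %in% hiRois
  late <- suv[, nFrames(coh$tacs)]
  skip_if(length(unique(geno)) < 2)    # both genotypes present at n = 16
  expect_lt(mean(late[hi & geno == "MAB"]),
            mean(late[hi & geno == "HAB"]))
})

test_that("noiseless generated uptake phase recovers the generating K1", {
  cfg <- smallCohortConfig(n = 2L, seed = 10L, noiseScale = 0)
  coh <- generateCohort(cfg)
  k1 <- estimateCohortK1(coh$tacs, coh$inputs, window = 4)
  m <- merge(k1, coh$truth, by = c("subject_id", "roi_id"))
  expect_lt(median(abs(m$K1.x - m$K1.y) / m$K1.y), 0.02)
  expect_lt(max(abs(m$K1.x - m$K1.y) / m$K1.y), 0.05)
})

test_that("rat phantom groups carry the configured lesion structure", {
  ph <- generateRatPhantom(ratConfig(nIc = 3L, nIp = 3L, nVehicle = 3L,
                                     seed = 15L))
  expect_equal(nrow(ph$tacs), 9L * 13L * 2L)
  tr <- ph$truth
  expect_setequal(unique(tr$group), c("ic-LPS", "ip-LPS", "Vehicle"))
  les <- tr[tr$lesioned, ]
  expect_true(all(les$group == "ic-LPS"))
  expect_setequal(unique(sub("_(ipsi|contra)$", "", les$roi_id)),
                  ratRegionRoster()[1:7])
  # lesioned k3 elevated 3-fold over the homologous contralateral ROI
  one <- tr[tr$subject_id == tr$subject_id[tr$lesioned][1] &
              grepl("^cortex", tr$roi_id), ]
  expect_equal(one$k3[grepl("ipsi", one$roi_id)],
               3 * one$k3[grepl("contra", one$roi_id)])
})
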