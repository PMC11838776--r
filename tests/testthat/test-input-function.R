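test_that("blood voxel selection finds the hot carotid voxels", {
  fs <- tinySchedule(6, 0.5)
  dims <- c(10, 10, 10)
  img <- array(1, c(dims, 6))          # flat background
  hot <- cbind(rep(1:5, 2), rep(1:2, each = 5), 3)   # 10 carotid voxels
  for (i in 1:10) img[hot[i, 1], hot[i, 2], hot[i, 3], ] <-
      c(80, 120, 60, 20, 10, 5)        # sharp early peak
  vox <- selectBloodVoxels(img, fs, earlyWindow = c(0, 1.5),
                           thresholdQuantile = 0.99, keepFraction = 1)
  want <- sort(hot[, 1] + (hot[, 2] - 1) * 10 + (hot[, 3] - 1) * 100)
  expect_identical(sort(vox), as.integer(want))

  # keepFraction = 1 returns every threshold-passing voxel
  expect_length(vox, 10L)
  # the correlation stage keeps the requested fraction deterministically
  vox2 <- selectBloodVoxels(img, fs, earlyWindow = c(0, 1.5),
                            thresholdQuantile = 0.99, keepFraction = 0.5)
  expect_length(vox2, 5L)
  expect_true(all(vox2 %in% vox))
  expect_identical(vox2, selectBloodVoxels(img, fs,
                                           earlyWindow = c(0, 1.5),
                                           thresholdQuantile = 0.99,
                                           keepFraction = 0.5))
  expect_error(selectBloodVoxels(array(0, c(dims, 6)), fs),
               "extraction error")
})

test_that("tri-exponential fit recovers noiseless parameters", {
  fs <- pbr28Schedule()
  truth <- triExpInput(c(100, 50, 10), c(4, 0.5, 0.02), peakTime = 1)
  blood <- evalInput(truth, frameMid(fs))
  fit <- fitTriExp(blood, fs, peakTime = 1)
  expect_lt(max(abs(fit@amplitudes - c(100, 50, 10)) / c(100, 50, 10)),
            1e-4)
  expect_lt(max(abs(fit@rates - c(4, 0.5, 0.02)) / c(4, 0.5, 0.02)),
            1e-4)
  expect_lt(fit@rss, 1e-8)
  # canonical ordering and positivity are enforced by the class
  expect_true(all(diff(fit@rates) < 0) && all(fit@rates > 0))
  # the fitted model integrates finitely on [0, Inf)
  expect_true(is.finite(sum(fit@amplitudes / fit@rates)))
})

test_that("tri-exponential fit is scale equivariant and flags degeneracy", {
  fs <- pbr28Schedule()
  truth <- triExpInput(c(100, 50, 10), c(4, 0.5, 0.02), peakTime = 1)
  blood <- evalInput(truth, frameMid(fs))
  f1 <- fitTriExp(blood, fs, peakTime = 1)
  f2 <- fitTriExp(2 * blood, fs, peakTime = 1)
  expect_equal(f2@amplitudes, 2 * f1@amplitudes, tolerance = 1e-6)
  expect_equal(f2@rates, f1@rates, tolerance = 1e-6)

  # single-exponential data: nested-model limit, two amplitudes ~ 0
  single <- triExpInput(c(1e-9, 50, 1e-9), c(4, 0.5, 0.02), peakTime = 1)
  bs <- evalInput(single, frameMid(fs))
  fd <- fitTriExp(bs, fs, peakTime = 1)
  expect_lt(fd@rss, 1e-6)
  expect_equal(sum(fd@amplitudes > 1e-3 * max(fd@amplitudes)), 1L)

  # too few post-peak samples is a precondition error
  short <- FrameSchedule(duration = rep(1, 5))
  expect_error(fitTriExp(evalInput(truth, frameMid(short)), short),
               "7 post-peak")
  expect_error(fitTriExp(c(-5, rep(1, 25)), fs), "negative")
})

test_that("analytic input integral matches numerical quadrature", {
  inp <- triExpInput(c(40, 8, 4), c(3.5, 0.35, 0.015), peakTime = 1)
  for (tt in c(0.5, 1, 2.5, 10, 60)) {
    num <- stats::integrate(function(x) evalInput(inp, x), 0, tt,
                            rel.tol = 1e-12, subdivisions = 500L)$value
    expect_equal(inputIntegral(inp, tt), num, tolerance = 1e-8)
  }
})
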