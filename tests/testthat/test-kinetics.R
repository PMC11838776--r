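inp <- triExpInput(c(40, 8, 4), c(3.5, 0.35, 0.015), peakTime = 1)

test_that("compartment simulator honours closed-form limits", {
  fs <- pbr28Schedule()
  # irreversible uptake: tissue = K1 * running integral of the input
  ct <- simulateTissueTac(compartmentParams(K1 = 0.1), inp, fs,
                          frameAverage = FALSE)
  expect_equal(ct, 0.1 * inputIntegral(inp, frameMid(fs)),
               tolerance = 1e-12)
  # K1 = 0 gives a zero TAC
  expect_equal(simulateTissueTac(compartmentParams(K1 = 0), inp, fs),
               rep(0, 26), tolerance = 1e-15)
  expect_error(compartmentParams(K1 = 0.1, k2 = -1), "parameter error")
  expect_error(compartmentParams(K1 = 0.1, vb = 0.5), "vb")
})

test_that("two-tissue solution matches an independent stiff ODE solver", {
  skip_if_not_installed("deSolve")
  fs <- pbr28Schedule()
  t <- frameMid(fs)
  set.seed(7)
  for (rep in 1:4) {
    p <- compartmentParams(K1 = runif(1, 0.05, 0.2),
                           k2 = runif(1, 0.01, 0.15),
                           k3 = runif(1, 0.01, 0.2),
                           k4 = runif(1, 0.005, 0.1))
    rhs <- function(tt, y, parms) {
      cp <- evalInput(inp, tt)
      list(c(p$K1 * cp - (p$k2 + p$k3) * y[1] + p$k4 * y[2],
             p$k3 * y[1] - p$k4 * y[2]))
    }
    ode <- deSolve::lsoda(c(0, 0), c(0, t), rhs, parms = NULL,
                          rtol = 1e-10, atol = 1e-12)
    ref <- rowSums(ode[-1, 2:3])
    ana <- simulateTissueTac(p, inp, fs, frameAverage = FALSE)
    expect_lt(max(abs(ana - ref) / pmax(abs(ref), 1e-9)), 1e-6)
  }
})

test_that("frame values equal the time-average of the instantaneous curve", {
  fs <- pbr28Schedule()
  p <- compartmentParams(K1 = 0.12, k2 = 0.05, k3 = 0.08, k4 = 0.02,
                         vb = 0.03)
  fa <- simulateTissueTac(p, inp, fs)
  st <- frameStart(fs); du <- frameDuration(fs)
  for (j in c(2L, 9L, 17L, 26L)) {     # spans the kink and late frames
    tt <- seq(st[j], st[j] + du[j], length.out = 4001)
    dt <- tt[2] - tt[1]
    grid <- FrameSchedule(start = tt - dt / 2, duration = rep(dt, 4001))
    inst <- simulateTissueTac(p, inp, grid, frameAverage = FALSE)
    quad <- sum(diff(tt) * (inst[-1] + inst[-4001]) / 2) / du[j]
    expect_equal(fa[j], quad, tolerance = 1e-8)
  }
})

test_that("K1 estimator is exact on model-matched data and linear", {
  fs <- pbr28Schedule()
  ct <- simulateTissueTac(compartmentParams(K1 = 0.10), inp, fs)
  e <- estimateK1(ct, inp, fs, window = 4)
  expect_lt(abs(e$K1 - 0.10) / 0.10, 1e-10)
  # linearity in the tissue activity
  e2 <- estimateK1(2 * ct, inp, fs, window = 4)
  expect_equal(e2$K1, 2 * e$K1, tolerance = 1e-12)
  # exact for any admissible window on model-matched data
  for (w in c(1, 2, 8)) {
    expect_lt(abs(estimateK1(ct, inp, fs, window = w)$K1 - 0.10), 1e-10)
  }
  # the 4-minute window uses exactly the frames with mid-time <= 4 min
  expect_equal(e$n_points, sum(frameMid(fs) <= 4))
  expect_error(estimateK1(ct, inp, fs, window = 12), "<= 10")
  expect_error(estimateK1(ct[1:2], inp, tinySchedule(2, 5), window = 4),
               "at least 2 frames")
  expect_warning(eneg <- estimateK1(-ct, inp, fs, window = 4), "clamped")
  expect_equal(eneg$K1, 0)
  expect_true(eneg$clamped)
})

test_that("reversible kinetics bias K1 low, shrinking with the window", {
  fs <- pbr28Schedule()
  p <- compartmentParams(K1 = 0.11, k2 = 0.04, k3 = 0.07, k4 = 0.02)
  ct <- simulateTissueTac(p, inp, fs)
  bias <- sapply(c(1, 2, 4, 8), function(w)
    (estimateK1(ct, inp, fs, window = w)$K1 - p$K1) / p$K1)
  expect_true(all(bias < 0))               # biased low vs the true K1
  expect_true(all(diff(abs(bias)) > 0))    # |bias| grows with the window
})

test_that("cohort K1 estimation joins subjects with their own inputs", {
  coh <- generateCohort(smallCohortConfig(n = 3L, seed = 2L,
                                          noiseScale = 0))
  k1 <- estimateCohortK1(coh$tacs, coh$inputs, window = 4)
  expect_equal(nrow(k1), nrow(coh$tacs))
  m <- merge(k1, coh$truth, by = c("subject_id", "roi_id"))
  expect_lt(median(abs(m$K1.x - m$K1.y) / m$K1.y), 0.02)
  expect_error(estimateCohortK1(coh$tacs, coh$inputs[-1]), "input")
})
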