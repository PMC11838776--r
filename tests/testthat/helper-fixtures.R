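# Shared fixtures: small deterministic designs, schedules and phantoms
# built in code at test time.

# logistic toy: one row per subject, features ~ U(-1, 1)
toyLogisticDesign <- function(n, beta, seed = 1L, datasetOffsets = 0,
                              intercept = 0) {
  set.seed(seed)
  p <- length(beta)
  X <- matrix(stats::runif(n * p, -1, 1), n, p,
              dimnames = list(NULL, paste0("f", seq_len(p))))
  ds <- rep(paste0("d", seq_along(datasetOffsets)), length.out = n)
  eta <- intercept + drop(X %*% beta) +
    datasetOffsets[match(ds, paste0("d", seq_along(datasetOffsets)))]
  y <- stats::rbinom(n, 1, stats::plogis(eta))
  data.frame(subject_id = sprintf("s%04d", seq_len(n)),
             roi_id = "roi", dataset_id = ds, outcome = y, X)
}

# deviance of a logistic model evaluated independently of the package
refDeviance <- function(beta0, beta, X, y) {
  eta <- beta0 + drop(as.matrix(X) %*% beta)
  mu <- 1 / (1 + exp(-eta))
  mu <- pmin(pmax(mu, 1e-12), 1 - 1e-12)
  -2 * sum(y * log(mu) + (1 - y) * log(1 - mu))
}

# coarse-to-fine grid minimizer of the logistic deviance (oracle)
gridSearchDeviance <- function(X, y, span = 8, npts = 13L, iters = 24L) {
  X <- as.matrix(X)
  centre <- rep(0, ncol(X) + 1L)
  best <- Inf
  for (it in seq_len(iters)) {
    grids <- lapply(centre, function(c0)
      seq(c0 - span, c0 + span, length.out = npts))
    pts <- as.matrix(expand.grid(grids))
    devs <- apply(pts, 1L, function(b)
      refDeviance(b[1], b[-1], X, y))
    i <- which.min(devs)
    centre <- pts[i, ]
    best <- devs[i]
    span <- span * 2.2 / (npts - 1)   # shrink around the winner
  }
  list(deviance = best, par = centre)
}

tinySchedule <- function(n = 6, dt = 1) FrameSchedule(duration = rep(dt, n))

demoSubjects <- function(ids, dataset = "d1", age = 40, sex = "male",
                         genotype = "HAB", dose = 330, weight = 75) {
  data.frame(subject_id = ids, age = age, sex = sex, genotype = genotype,
             injected_dose = dose, weight = weight, dataset_id = dataset,
             group_label = "HC")
}

smallCohortConfig <- function(n = 6L, seed = 1L, ...) {
  cohortConfig(nSubjects = c(ds1 = n), datasetOffsets = c(ds1 = 0),
               seed = seed, ...)
}
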