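## Forward compartmental simulation (1- and 2-tissue) driven by the
## analytic input model, and the 1T1K-IDIF K1 estimator.

## Gauss-Legendre nodes/weights on [-1, 1] (Golub-Welsch), cached per n.
.glenv <- new.env(parent = emptyenv())
.gauleg <- function(n) {
  key <- as.character(n)
  if (!is.null(.glenv[[key]])) return(.glenv[[key]])
  i <- seq_len(n - 1)
  b <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- b; J[cbind(i + 1, i)] <- b
  e <- eigen(J, symmetric = TRUE)
  gl <- list(x = e$values, w = 2 * e$vectors[1, ]^2)
  .glenv[[key]] <- gl
  gl
}

## mean of f over [a, b] by 20-point Gauss-Legendre, splitting at the
## input-model kink `tp` when it falls inside the interval
.segMean <- function(f, a, b, tp) {
  gl <- .gauleg(20L)
  one <- function(lo, hi) {
    x <- (hi - lo) / 2 * gl$x + (lo + hi) / 2
    (hi - lo) / 2 * sum(gl$w * f(x))
  }
  tot <- if (tp > a && tp < b) one(a, tp) + one(tp, b) else one(a, b)
  tot / (b - a)
}

#' Compartment model parameters
#'
#' Parameter set of the serial two-tissue compartment model: delivery `K1`
#' (mL/cm3/min), efflux `k2`, binding `k3`, dissociation `k4` (1/min) and
#' fractional blood volume `vb`. `k3 = k4 = 0` gives the one-tissue model;
#' `k2 = k3 = k4 = 0` the irreversible single-compartment (1T1K) model.
#'
#' @param K1,k2,k3,k4 non-negative rate constants.
#' @param vb blood volume fraction in `[0, maxVb]`.
#' @param maxVb upper bound enforced on `vb` (default 0.2).
#' @return a validated named list of class `"CompartmentParams"`.
#' @examples
#' compartmentParams(K1 = 0.1, k2 = 0.05, k3 = 0.08, k4 = 0.02, vb = 0.03)
#' @export
compartmentParams <- function(K1, k2 = 0, k3 = 0, k4 = 0, vb = 0,
                              maxVb = 0.2) {
  p <- c(K1 = K1, k2 = k2, k3 = k3, k4 = k4, vb = vb)
  if (any(!is.finite(p))) stop("parameter error: non-finite parameter")
  if (any(p < 0)) stop("parameter error: rate constants must be >= 0")
  if (vb > maxVb) stop("parameter error: vb exceeds ", maxVb)
  structure(as.list(p), class = "CompartmentParams")
}

## Instantaneous total tissue activity for a tri-exponential input:
## eigen-decomposition of the 2x2 rate matrix gives the impulse response as
## two exponentials, each convolved analytically with the input model.
.tissueInstant <- function(params, input, t) {
  K1 <- params$K1; k2 <- params$k2; k3 <- params$k3; k4 <- params$k4
  vb <- params$vb
  s <- k2 + k3 + k4
  ct <- if (K1 == 0) {
    numeric(length(t))
  } else if (s == 0) {
    K1 * .convExpInput(input, 0, t)           # irreversible uptake
  } else {
    disc <- s^2 - 4 * k2 * k4
    if (disc < 0) disc <- 0
    a1 <- (s - sqrt(disc)) / 2
    a2 <- (s + sqrt(disc)) / 2
    if (a2 - a1 < 1e-8 * max(1, a2)) a2 <- a1 + 1e-8 * max(1, a2)
    f1 <- K1 * (k3 + k4 - a1) / (a2 - a1)
    f2 <- K1 * (a2 - k3 - k4) / (a2 - a1)
    f1 * .convExpInput(input, a1, t) + f2 * .convExpInput(input, a2, t)
  }
  (1 - vb) * ct + vb * evalInput(input, t)
}

#' Simulate a tissue time-activity curve
#'
#' Solves the one- or two-tissue compartment system analytically for a
#' tri-exponential input model (linear rise, then three exponentials) and
#' returns per-frame values, by default the time-average of the
#' instantaneous curve over each frame interval (what a PET scanner
#' reports). A fractional blood signal `vb * Cp(t)` is mixed in as
#' `(1 - vb) * Ct + vb * Cp`.
#'
#' @param params a [compartmentParams()] set.
#' @param input a [TriExpFit-class] input model.
#' @param schedule a [FrameSchedule-class].
#' @param frameAverage logical; `FALSE` samples the instantaneous curve at
#'   frame mid-times instead of averaging.
#' @return numeric, one activity value (kBq/mL) per frame.
#' @seealso [estimateK1()], [triExpInput()]
#' @export
simulateTissueTac <- function(params, input, schedule,
                              frameAverage = TRUE) {
  stopifnot(inherits(params, "CompartmentParams"), is(input, "TriExpFit"),
            is(schedule, "FrameSchedule"))
  if (!frameAverage)
    return(.tissueInstant(params, input, frameMid(schedule)))
  st <- frameStart(schedule); en <- st + frameDuration(schedule)
  vapply(seq_along(st), function(j)
    .segMean(function(x) .tissueInstant(params, input, x),
             st[j], en[j], input@peakTime),
    numeric(1))
}

#' Estimate K1 with the irreversible one-compartment (1T1K) IDIF model
#'
#' Fits the first minutes of the tissue kinetics with a single irreversible
#' compartment driven by the fitted input function: `Ct(t) = K1 *
#' int_0^t Cp`. The estimate is the duration-weighted least-squares slope of
#' the frame activity against the frame-averaged running integral of the
#' input, restricted to frames with mid-time inside the fit window
#' (closed form with `vb` fixed at 0; an optional blood-volume term can be
#' co-estimated). Negative slopes are clamped to 0 and flagged.
#'
#' Recommended windows are 4 minutes for PBR28-like kinetics and 5 minutes
#' for DPA-714/PK11195-like kinetics; the window must not exceed 10 minutes
#' for the irreversible approximation to hold.
#'
#' @param tac numeric TAC (one region) or a [TacExperiment-class].
#' @param input a [TriExpFit-class] fitted input function.
#' @param schedule a [FrameSchedule-class] (ignored for a `TacExperiment`,
#'   which carries its own).
#' @param window fit window end, minutes (default 4, max 10).
#' @param fitVb logical, co-estimate a fractional blood term (default
#'   FALSE).
#' @param weights optional per-frame weights; default frame durations.
#' @return for a numeric TAC, a one-row data.frame with `K1` (mL/cm3/min),
#'   `vb`, `rss`, `n_points`, `window`, `clamped`; for a `TacExperiment`,
#'   one such row per (subject, ROI) trace with `subject_id`/`roi_id`.
#' @export
estimateK1 <- function(tac, input, schedule = NULL, window = 4,
                       fitVb = FALSE, weights = NULL) {
  stopifnot(is(input, "TriExpFit"))
  if (window > 10)
    stop("window must be <= 10 minutes for the 1T1K approximation")
  if (is(tac, "TacExperiment")) {
    sched <- schedule(tac)
    a <- activity(tac)
    pre <- .k1basis(input, sched, window, fitVb, weights)
    rows <- lapply(seq_len(nrow(a)), function(i)
      .k1one(a[i, ], pre, window, fitVb))
    out <- do.call(rbind, rows)
    out <- cbind(as.data.frame(rowData(tac)[, c("subject_id", "roi_id")]),
                 out)
    rownames(out) <- NULL
    return(out)
  }
  stopifnot(is(schedule, "FrameSchedule"))
  .k1one(tac, .k1basis(input, schedule, window, fitVb, weights),
         window, fitVb)
}

## frame-averaged running input integral (and blood curve) on the window
.k1basis <- function(input, schedule, window, fitVb, weights) {
  mid <- frameMid(schedule)
  sel <- which(mid <= window)
  if (length(sel) < 2L)
    stop("need at least 2 frames with mid-time inside the ", window,
         "-minute window")
  if (is.null(weights)) weights <- frameDuration(schedule)
  st <- frameStart(schedule); en <- st + frameDuration(schedule)
  x <- vapply(sel, function(j)
    .segMean(function(t) inputIntegral(input, t), st[j], en[j],
             input@peakTime), numeric(1))
  cp <- if (fitVb) vapply(sel, function(j)
    .segMean(function(t) evalInput(input, t), st[j], en[j],
             input@peakTime), numeric(1)) else 0
  list(sel = sel, x = x, cp = cp, w = weights[sel])
}

.k1one <- function(y, pre, window, fitVb) {
  sel <- pre$sel; x <- pre$x; cp <- pre$cp; w <- pre$w
  yv <- y[sel]
  clamped <- FALSE; vb <- 0
  if (fitVb) {
    co <- stats::lm.wfit(cbind(intl = x, blood = cp), yv, w)$coefficients
    K1 <- co[["intl"]]; vb <- co[["blood"]]
    if (!is.finite(K1)) K1 <- 0
    if (!is.finite(vb)) vb <- 0
  } else {
    K1 <- sum(w * x * yv) / sum(w * x^2)
  }
  if (K1 < 0) {
    warning("negative fitted K1 clamped to 0")
    K1 <- 0; clamped <- TRUE
  }
  pred <- K1 * x + vb * cp
  data.frame(K1 = K1, vb = vb, rss = sum(w * (yv - pred)^2),
             n_points = length(sel), window = window, clamped = clamped)
}

#' Read / write K1 tables
#'
#' CSV with columns `subject_id, roi_id, K1, rss, n_points, window`.
#'
#' @param x a data.frame as returned by [estimateK1()] on a
#'   [TacExperiment-class].
#' @param path CSV path.
#' @return `readK1Table` a data.frame; `writeK1Table` `path`, invisibly.
#' @export
writeK1Table <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeK1Table
#' @export
readK1Table <- function(path) utils::read.csv(path)
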