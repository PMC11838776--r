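## Image-derived input function: blood-voxel selection, tri-exponential
## fitting, and analytic evaluation/convolution of the fitted input model.

#' Construct a tri-exponential input model directly
#'
#' Builds a [TriExpFit-class] from known parameters, e.g. for simulation.
#' The model rises linearly from 0 at t = 0 to `sum(amplitudes)` at
#' `peakTime`, then decays as the sum of three exponentials.
#'
#' @param amplitudes numeric(3), kBq/mL.
#' @param rates numeric(3), 1/min (any order; stored decreasing).
#' @param peakTime numeric(1), minutes (0 for an instantaneous bolus peak).
#' @return a [TriExpFit-class].
#' @examples
#' triExpInput(c(100, 50, 10), c(4, 0.5, 0.02), peakTime = 1)
#' @export
triExpInput <- function(amplitudes, rates, peakTime = 1) {
  o <- order(rates, decreasing = TRUE)
  new("TriExpFit", amplitudes = as.numeric(amplitudes[o]),
      rates = as.numeric(rates[o]), peakTime = as.numeric(peakTime),
      rss = 0, nPoints = 0L)
}

#' Evaluate and integrate a fitted input function
#'
#' `evalInput` evaluates the continuous input model at arbitrary times.
#' `inputIntegral` returns the running integral `int_0^t Cp(s) ds`
#' analytically (used by the K1 estimator so coarse early frames add no
#' quadrature error).
#'
#' @param fit a [TriExpFit-class].
#' @param t numeric, times in minutes.
#' @return numeric of `length(t)`; kBq/mL (`evalInput`) or kBq/mL*min
#'   (`inputIntegral`).
#' @export
evalInput <- function(fit, t) {
  tp <- fit@peakTime
  peak <- sum(fit@amplitudes)
  out <- numeric(length(t))
  pre <- t <= tp & t >= 0
  if (tp > 0) out[pre] <- peak * t[pre] / tp
  post <- t > tp
  if (any(post)) {
    v <- t[post] - tp
    out[post] <- drop(exp(outer(v, -fit@rates)) %*% fit@amplitudes)
  }
  out
}

## int_0^t tau * exp(-a (t - tau)) dtau, stable for small a*t
.philin <- function(a, t) {
  if (a == 0) return(t^2 / 2)
  x <- a * t
  small <- x < 1e-4
  out <- numeric(length(t))
  out[small] <- t[small]^2 / 2 - a * t[small]^3 / 6 + a^2 * t[small]^4 / 24
  out[!small] <- (x[!small] + expm1(-x[!small])) / a^2
  out
}

## F_a(t) = int_0^t exp(-a (t - tau)) Cp(tau) dtau for the piecewise model
.convExpInput <- function(fit, a, t) {
  tp <- fit@peakTime
  peak <- sum(fit@amplitudes)
  s <- if (tp > 0) peak / tp else 0
  out <- numeric(length(t))
  pre <- t >= 0 & t <= tp
  if (tp > 0 && any(pre)) out[pre] <- s * .philin(a, t[pre])
  post <- t > tp
  if (any(post)) {
    v <- t[post] - tp
    lin <- if (tp > 0) {
      s * .philin(a, tp) * (if (a == 0) 1 else exp(-a * v))
    } else 0
    expo <- 0
    for (i in 1:3) {
      A <- fit@amplitudes[i]; l <- fit@rates[i]
      expo <- expo + if (abs(a - l) < 1e-9 * max(a, l, 1)) {
        A * v * exp(-a * v)
      } else if (a == 0) {
        A * (1 - exp(-l * v)) / l
      } else {
        A * (exp(-l * v) - exp(-a * v)) / (a - l)
      }
    }
    out[post] <- lin + expo
  }
  out
}

#' @rdname evalInput
#' @export
inputIntegral <- function(fit, t) .convExpInput(fit, 0, t)

#' Select carotid blood voxels from a dynamic image
#'
#' Two-stage selection mirroring IDIF extraction from the carotid siphons:
#' (1) intensity thresholding of the duration-weighted early-window sum at a
#' high quantile; (2) retention of the candidate voxels whose TACs correlate
#' best with the candidate-mean TAC. Both stages are deterministic; ties are
#' broken by voxel order (R linear indexing, 1-based).
#'
#' @param image4d 4D array (x, y, z, frame) or path to a 4D NIfTI.
#' @param schedule a [FrameSchedule-class] matching the 4th dimension.
#' @param earlyWindow numeric(2), minutes; frames with mid-time inside this
#'   window form the intensity image (default first 2 minutes).
#' @param thresholdQuantile numeric in (0,1), quantile of the early-sum
#'   image used as intensity threshold (default 0.99).
#' @param keepFraction numeric in (0,1], fraction of threshold-passing
#'   voxels retained by the correlation stage (default 0.5; 1 keeps all).
#' @return integer vector of linear voxel indices into the 3D grid.
#' @seealso [extractIdif()]
#' @export
selectBloodVoxels <- function(image4d, schedule, earlyWindow = c(0, 2),
                              thresholdQuantile = 0.99, keepFraction = 0.5) {
  if (is.character(image4d)) image4d <- RNifti::readNifti(image4d)
  image4d <- unclass(image4d)
  stopifnot(length(dim(image4d)) == 4L,
            thresholdQuantile > 0, thresholdQuantile < 1,
            keepFraction > 0, keepFraction <= 1)
  if (dim(image4d)[4] != nFrames(schedule))
    stop("dimension error: frame count does not match schedule")
  mid <- frameMid(schedule); dur <- frameDuration(schedule)
  inwin <- mid >= earlyWindow[1] & mid <= earlyWindow[2]
  if (!any(inwin)) stop("early window contains no frames")
  flat <- matrix(image4d, ncol = dim(image4d)[4])
  early <- drop(flat[, inwin, drop = FALSE] %*% dur[inwin])
  if (all(early == 0))
    stop("extraction error: all-zero early-window image (threshold ",
         "quantile ", thresholdQuantile, ")")
  thr <- stats::quantile(early, thresholdQuantile, names = FALSE)
  cand <- which(early > thr)
  if (!length(cand))
    stop("extraction error: no voxels above the intensity threshold ",
         format(thr), " (quantile ", thresholdQuantile, ")")
  if (keepFraction >= 1 || length(cand) == 1L) return(cand)
  ctacs <- flat[cand, , drop = FALSE]
  m <- colMeans(ctacs)
  r <- suppressWarnings(apply(ctacs, 1L, stats::cor, y = m))
  r[is.na(r)] <- -Inf
  nkeep <- max(1L, ceiling(keepFraction * length(cand)))
  cand[order(-r, seq_along(cand))[seq_len(nkeep)]]
}

#' Extract and fit an image-derived input function
#'
#' Convenience wrapper: selects blood voxels with [selectBloodVoxels()],
#' averages their TACs into a whole-blood curve and fits the tri-exponential
#' model with [fitTriExp()].
#'
#' @inheritParams selectBloodVoxels
#' @param ... passed to [selectBloodVoxels()].
#' @return list with elements `voxels` (indices), `blood` (mean TAC,
#'   kBq/mL per frame) and `fit` (a [TriExpFit-class]).
#' @export
extractIdif <- function(image4d, schedule, ...) {
  if (is.character(image4d)) image4d <- RNifti::readNifti(image4d)
  image4d <- unclass(image4d)
  vox <- selectBloodVoxels(image4d, schedule, ...)
  flat <- matrix(image4d, ncol = dim(image4d)[4])
  blood <- colMeans(flat[vox, , drop = FALSE])
  list(voxels = vox, blood = blood,
       fit = fitTriExp(blood, schedule))
}

#' Fit a tri-exponential model to a blood curve
#'
#' Weighted least-squares fit of `A1 exp(-l1 v) + A2 exp(-l2 v) +
#' A3 exp(-l3 v)` (v = time past the empirical peak) to the post-peak frames
#' of a blood TAC, with a linear rise from zero before the peak. Weights
#' default to frame durations (longer frames carry more counts). The fit is
#' run from a deterministic grid of multi-start rate initialisations
#' (Levenberg-Marquardt in log-parameter space, so amplitudes and rates stay
#' positive) and the best solution by weighted RSS is returned with rates in
#' canonical decreasing order.
#'
#' @param blood numeric, blood activity per frame (kBq/mL).
#' @param schedule a [FrameSchedule-class].
#' @param weights optional per-frame weights; default frame durations.
#' @param peakTime optional known peak time (minutes); by default the
#'   mid-time of the maximum frame is used as the empirical peak.
#' @param negTolerance most-negative activity tolerated, as a fraction of
#'   the curve maximum (default 1e-6); worse data raise an error.
#' @return a [TriExpFit-class].
#' @export
fitTriExp <- function(blood, schedule, weights = NULL, peakTime = NULL,
                      negTolerance = 1e-6) {
  stopifnot(is(schedule, "FrameSchedule"),
            length(blood) == nFrames(schedule))
  if (any(!is.finite(blood))) stop("data error: non-finite blood activity")
  if (min(blood) < -negTolerance * max(abs(blood)))
    stop("data error: negative blood activity beyond tolerance")
  mid <- frameMid(schedule)
  if (is.null(weights)) weights <- frameDuration(schedule)
  tp <- if (is.null(peakTime)) mid[which.max(blood)] else peakTime
  post <- which(mid >= tp)
  if (length(post) < 7L)
    stop("need at least 7 post-peak samples to fit 6 parameters (have ",
         length(post), ")")
  v <- mid[post] - tp
  y <- blood[post]
  w <- weights[post]
  sw <- sqrt(w)

  resid_fn <- function(p) {
    mu <- drop(exp(outer(v, -exp(p[4:6]))) %*% exp(p[1:3]))
    sw * (y - mu)
  }
  starts <- expand.grid(l1 = c(1, 3, 6, 12), l2 = c(0.1, 0.3, 0.8),
                        l3 = c(0.005, 0.02, 0.06))
  best <- NULL
  for (k in seq_len(nrow(starts))) {
    l0 <- unlist(starts[k, ])
    basis <- exp(outer(v, -l0))
    A0 <- tryCatch(
      stats::lm.wfit(basis, y, w)$coefficients,
      error = function(e) rep(max(y) / 3, 3))
    A0[!is.finite(A0) | A0 < 1e-8 * max(y, 1e-12)] <-
      1e-8 * max(y, 1e-12)
    p0 <- c(log(A0), log(l0))
    fit <- tryCatch(
      minpack.lm::nls.lm(p0, fn = resid_fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 200, ftol = 1e-14, ptol = 1e-14)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(fit$fvec^2)
    if (is.null(best) || rss < best$rss - 1e-15)
      best <- list(par = fit$par, rss = rss, conv = fit$info %in% 1:4)
  }
  if (is.null(best))
    stop("fit error: tri-exponential fit failed from every start")
  if (!best$conv && best$rss > 1e-6 * sum((sw * y)^2))
    stop("fit error: no start converged; best weighted rss = ",
         format(best$rss))
  A <- exp(best$par[1:3]); l <- exp(best$par[4:6])
  ## degenerate components (amplitude ~ 0) can drift to extreme rates;
  ## clamp into a finite physiological range
  l <- pmin(pmax(l, 1e-6), 1e4)
  A[!is.finite(A)] <- 0
  o <- order(l, decreasing = TRUE)
  new("TriExpFit", amplitudes = A[o], rates = l[o], peakTime = tp,
      rss = best$rss, nPoints = length(post))
}

#' Read / write blood curves and tri-exponential parameters
#'
#' Blood curves travel as two-column CSV (`mid_time`, `activity`; minutes
#' and kBq/mL). Fitted input parameters are serialised as JSON.
#'
#' @param path file path.
#' @param blood numeric activity per frame; `schedule` its
#'   [FrameSchedule-class].
#' @param schedule a [FrameSchedule-class].
#' @param fit a [TriExpFit-class].
#' @return readers return a data.frame (`readBloodCurve`) or
#'   [TriExpFit-class] (`readTriExpFit`); writers return `path` invisibly.
#' @export
writeBloodCurve <- function(blood, schedule, path) {
  utils::write.csv(data.frame(mid_time = frameMid(schedule),
                              activity = blood),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeBloodCurve
#' @export
readBloodCurve <- function(path) utils::read.csv(path)

#' @rdname writeBloodCurve
#' @export
writeTriExpFit <- function(fit, path) {
  jsonlite::write_json(list(amplitudes = fit@amplitudes, rates = fit@rates,
                            peak_time = fit@peakTime, rss = fit@rss,
                            n_points = fit@nPoints),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeBloodCurve
#' @export
readTriExpFit <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- triExpInput(j$amplitudes, j$rates, j$peak_time)
  out@rss <- as.numeric(j$rss)
  out@nPoints <- as.integer(j$n_points)
  out
}
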