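#' Accessors for schedules, TAC containers and fitted objects
#'
#' Small generic accessors used across the package: frame timing for
#' [FrameSchedule-class] and [TacExperiment-class], the activity matrix and
#' subject covariate table of a `TacExperiment`, and coefficient extraction
#' for [TspoLogitModel-class].
#'
#' @param x the object.
#' @param object a fitted model (for `coef`).
#' @param ... ignored.
#' @return `frameStart`, `frameDuration`, `frameMid` return numeric vectors
#'   in minutes; `nFrames` an integer; `scanEnd` the end time of the last
#'   frame; `activity` the frames-in-columns numeric matrix; `schedule` a
#'   `FrameSchedule`; `subjectData` a `DataFrame`.
#' @name accessors
#' @aliases frameStart frameDuration frameMid nFrames scanEnd activity
#'   schedule subjectData
#' @examples
#' fs <- pbr28Schedule()
#' nFrames(fs)
#' head(frameMid(fs))
NULL

#' @rdname accessors
#' @export
setGeneric("frameStart", function(x) standardGeneric("frameStart"))
#' @rdname accessors
#' @export
setGeneric("frameDuration", function(x) standardGeneric("frameDuration"))
#' @rdname accessors
#' @export
setGeneric("frameMid", function(x) standardGeneric("frameMid"))
#' @rdname accessors
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))
#' @rdname accessors
#' @export
setGeneric("scanEnd", function(x) standardGeneric("scanEnd"))
#' @rdname accessors
#' @export
setGeneric("activity", function(x) standardGeneric("activity"))
#' @rdname accessors
#' @export
setGeneric("schedule", function(x) standardGeneric("schedule"))
#' @rdname accessors
#' @export
setGeneric("subjectData", function(x) standardGeneric("subjectData"))

#' @rdname accessors
setMethod("frameStart", "FrameSchedule", function(x) x@start)
#' @rdname accessors
setMethod("frameDuration", "FrameSchedule", function(x) x@duration)
#' @rdname accessors
setMethod("frameMid", "FrameSchedule", function(x) x@start + x@duration / 2)
#' @rdname accessors
setMethod("nFrames", "FrameSchedule", function(x) length(x@start))
#' @rdname accessors
setMethod("scanEnd", "FrameSchedule",
  function(x) x@start[length(x@start)] + x@duration[length(x@duration)])

#' @rdname accessors
setMethod("frameStart", "TacExperiment",
  function(x) colData(x)$frameStart)
#' @rdname accessors
setMethod("frameDuration", "TacExperiment",
  function(x) colData(x)$frameDuration)
#' @rdname accessors
setMethod("frameMid", "TacExperiment", function(x) colData(x)$frameMid)
#' @rdname accessors
setMethod("nFrames", "TacExperiment", function(x) ncol(x))
#' @rdname accessors
setMethod("activity", "TacExperiment", function(x) assay(x, "activity"))
#' @rdname accessors
setMethod("schedule", "TacExperiment", function(x)
  FrameSchedule(start = colData(x)$frameStart,
                duration = colData(x)$frameDuration))
#' @rdname accessors
setMethod("subjectData", "TacExperiment", function(x) x@subjects)

#' @rdname accessors
#' @export
setMethod("coef", "TspoLogitModel", function(object, ...) object@coefficients)

setMethod("show", "FrameSchedule", function(object) {
  cat("FrameSchedule:", nFrames(object), "frames,",
      format(scanEnd(object)), "min scan\n")
  cat("  durations (min):",
      paste(rle(object@duration)$lengths, "x",
            rle(object@duration)$values, collapse = ", "), "\n")
})

setMethod("show", "TacExperiment", function(object) {
  callNextMethod()
  cat("subjects(", nrow(object@subjects), "): ",
      paste(utils::head(object@subjects$subject_id, 5), collapse = ", "),
      if (nrow(object@subjects) > 5) ", ..." else "", "\n", sep = "")
})

setMethod("show", "TriExpFit", function(object) {
  cat("TriExpFit: peak at", format(object@peakTime, digits = 4), "min\n")
  cat("  A (kBq/mL):", paste(format(object@amplitudes, digits = 4),
                             collapse = ", "), "\n")
  cat("  lambda (1/min):", paste(format(object@rates, digits = 4),
                                 collapse = ", "), "\n")
  cat("  rss:", format(object@rss, digits = 4),
      " n post-peak:", object@nPoints, "\n")
})

setMethod("show", "FeatureSpec", function(object) {
  cat("FeatureSpec:", length(object@featureNames), "features (",
      sum(object@selected), "active )\n")
  cat("  TAC grid (min):", paste(object@gridMinutes, collapse = ", "), "\n")
  cat("  covariates:", paste(object@covariates, collapse = ", "), "\n")
  cat("  bounds:", if (ncol(object@bounds)) "fitted" else "not fitted", "\n")
})

setMethod("show", "TspoLogitModel", function(object) {
  hier <- length(object@randomSD) > 0L
  cat(if (hier) "Hierarchical" else "Plain",
      "logistic model for p_TSPO\n")
  print(round(rbind(coef = object@coefficients, se = object@se,
                    z = object@zstat), 4))
  cat("deviance:", format(object@deviance, digits = 6),
      " null:", format(object@nullDeviance, digits = 6),
      " converged:", object@converged, "\n")
  if (hier)
    cat("random intercept sd:", format(object@randomSD, digits = 4),
        "over", length(object@randomIntercepts), "datasets\n")
})

setMethod("show", "RocCurve", function(object) {
  cat("RocCurve: AUC =", format(object@auc, digits = 4),
      "over", length(object@thresholds), "thresholds\n")
})

setMethod("show", "GroupComparison", function(object) {
  cat("GroupComparison (", object@test, "): n_case=", object@nCase,
      " n_control=", object@nControl, "\n", sep = "")
  cat("  Delta_P =", sprintf("%+.1f%%", object@deltaP),
      " p =", format.pval(object@pValue, digits = 3), "\n")
})

setMethod("show", "SelectionReport", function(object) {
  cat("SelectionReport:", object@nIterations, "bootstrap iterations,",
      "threshold >", object@threshold, "\n")
  print(round(sort(object@frequency, decreasing = TRUE), 3))
  cat("retained:", if (length(object@retained))
    paste(object@retained, collapse = ", ") else "(none)", "\n")
})

#' Area under a fitted ROC curve
#'
#' @param x a [RocCurve-class] object.
#' @return numeric(1), the trapezoidal AUC.
#' @export
auc <- function(x) {
  stopifnot(is(x, "RocCurve"))
  x@auc
}

#' Delta_P of a cohort comparison
#'
#' @param x a [GroupComparison-class] object.
#' @return numeric(1), percent shift of relative probability mass above 0.5
#'   (case minus control).
#' @export
deltaPValue <- function(x) {
  stopifnot(is(x, "GroupComparison"))
  x@deltaP
}
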