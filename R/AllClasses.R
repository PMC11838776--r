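#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @import SummarizedExperiment
#' @importFrom stats coef
NULL

#' Frame schedule of a dynamic PET acquisition
#'
#' A `FrameSchedule` holds the frame start times and durations (minutes) of a
#' dynamic acquisition. Frame mid-times are derived as `start + duration / 2`.
#' Frames must be strictly ordered and non-overlapping; gaps are allowed.
#'
#' @slot start numeric, frame start times in minutes.
#' @slot duration numeric, frame durations in minutes.
#'
#' @seealso [FrameSchedule()], [pbr28Schedule()]
#' @export
setClass("FrameSchedule",
  representation(start = "numeric", duration = "numeric"))

setValidity("FrameSchedule", function(object) {
  s <- object@start; d <- object@duration
  if (length(s) != length(d)) return("start and duration lengths differ")
  if (length(s) == 0L) return("schedule has no frames")
  if (any(!is.finite(s)) || any(!is.finite(d))) return("non-finite frame times")
  if (any(d <= 0)) return("frame durations must be > 0")
  if (length(s) > 1L) {
    if (any(diff(s) <= 0)) return("start times must be strictly increasing")
    if (any(s[-1L] < (s[-length(s)] + d[-length(d)]) - 1e-9))
      return("frames overlap")
  }
  TRUE
})

#' Regional time-activity curves as a SummarizedExperiment
#'
#' A `TacExperiment` stores one regional TAC per row (a subject/ROI pair) and
#' one frame per column. The assay `"activity"` holds activity concentration
#' in kBq/mL (or dimensionless SUV after [toSUV()]). `colData` carries the
#' frame schedule (`frameStart`, `frameDuration`, `frameMid`, minutes);
#' `rowData` carries at least `subject_id` and `roi_id`. Subject covariates
#' (age, sex, genotype, dose, weight, dataset) live in the `subjects` slot,
#' one row per subject.
#'
#' @slot subjects a [S4Vectors::DataFrame] of per-subject covariates with a
#'   `subject_id` column.
#' @seealso [TacExperiment()], [readTacTable()], [extractRoiTacs()]
#' @export
setClass("TacExperiment",
  contains = "SummarizedExperiment",
  representation(subjects = "DataFrame"))

setValidity("TacExperiment", function(object) {
  if (!"activity" %in% assayNames(object)) return("assay 'activity' missing")
  cd <- colData(object)
  need <- c("frameStart", "frameDuration", "frameMid")
  if (!all(need %in% colnames(cd)))
    return("colData must carry frameStart, frameDuration, frameMid")
  rd <- rowData(object)
  if (!all(c("subject_id", "roi_id") %in% colnames(rd)))
    return("rowData must carry subject_id and roi_id")
  a <- assay(object, "activity")
  if (any(!is.finite(a))) return("activity values must be finite")
  sub <- object@subjects
  if (nrow(sub) > 0L) {
    if (!"subject_id" %in% colnames(sub))
      return("subjects table lacks subject_id")
    if (anyDuplicated(sub$subject_id))
      return("duplicated subject_id in subjects table")
  }
  TRUE
})

#' Tri-exponential fit of a blood input function
#'
#' Parametric model of an image-derived input function: linear rise from zero
#' to the empirical peak, then a sum of three decaying exponentials
#' `A1 exp(-l1 (t - tp)) + A2 exp(-l2 (t - tp)) + A3 exp(-l3 (t - tp))`.
#' Rates are stored in canonical decreasing order `l1 > l2 > l3 > 0`.
#'
#' @slot amplitudes numeric(3), kBq/mL.
#' @slot rates numeric(3), 1/min, decreasing.
#' @slot peakTime numeric(1), minutes.
#' @slot rss numeric(1), weighted residual sum of squares of the fit.
#' @slot nPoints integer(1), number of post-peak samples used.
#' @seealso [fitTriExp()], [evalInput()], [inputIntegral()]
#' @export
setClass("TriExpFit",
  representation(amplitudes = "numeric", rates = "numeric",
                 peakTime = "numeric", rss = "numeric", nPoints = "integer"))

setValidity("TriExpFit", function(object) {
  if (length(object@amplitudes) != 3L || length(object@rates) != 3L)
    return("amplitudes and rates must have length 3")
  if (any(!is.finite(object@amplitudes))) return("non-finite amplitudes")
  r <- object@rates
  if (any(!is.finite(r)) || any(r <= 0)) return("rates must be finite and > 0")
  if (is.unsorted(rev(r), strictly = FALSE)) return("rates must be decreasing")
  if (object@peakTime < 0) return("peakTime must be >= 0")
  TRUE
})

#' Feature specification for the logistic design matrix
#'
#' Records the sparse TAC sampling grid, the covariates entering the model,
#' the persisted min-max normalization bounds and the active-feature mask, so
#' that a fitted model can be re-applied reproducibly to unseen data.
#'
#' @slot gridMinutes numeric, strictly increasing TAC sampling times (min).
#' @slot covariates character, covariate feature names.
#' @slot featureNames character, full feature roster (grid + covariates).
#' @slot bounds numeric matrix with rows `min`,`max` and one column per
#'   feature (empty until fitted).
#' @slot selected logical mask over `featureNames`.
#' @seealso [featureSpec()], [buildDesign()]
#' @export
setClass("FeatureSpec",
  representation(gridMinutes = "numeric", covariates = "character",
                 featureNames = "character", bounds = "matrix",
                 selected = "logical"))

setValidity("FeatureSpec", function(object) {
  g <- object@gridMinutes
  if (length(g) && (any(!is.finite(g)) || is.unsorted(g, strictly = TRUE)))
    return("gridMinutes must be finite and strictly increasing")
  if (length(object@selected) != length(object@featureNames))
    return("selected mask length must equal featureNames length")
  b <- object@bounds
  if (ncol(b) > 0L) {
    if (!identical(rownames(b), c("min", "max")))
      return("bounds must have rows 'min' and 'max'")
    if (any(b["max", ] <= b["min", ]))
      return("degenerate normalization bounds (min >= max)")
  }
  TRUE
})

#' Fitted (hierarchical) logistic model for p_TSPO
#'
#' Stores intercept and per-feature coefficients of the logistic model
#' `logit(p) = b0 + sum_j b_j X_j`, optionally augmented with per-dataset
#' random intercepts (hierarchical fit), plus the feature specification
#' needed to rebuild the design for prediction.
#'
#' @slot coefficients named numeric, `(Intercept)` plus active features.
#' @slot se named numeric, standard errors (same order as coefficients).
#' @slot zstat named numeric, Wald z statistics.
#' @slot deviance numeric(1), residual deviance.
#' @slot nullDeviance numeric(1).
#' @slot converged logical(1).
#' @slot iterations integer(1).
#' @slot randomIntercepts named numeric, per-dataset offsets (length 0 for a
#'   plain fit); centred so their mean is ~0.
#' @slot randomSD numeric, between-dataset standard deviation (length 0 for a
#'   plain fit).
#' @slot featureSpec a [FeatureSpec-class] object.
#' @slot fitInfo list of engine details (encodings, ridge, messages).
#' @seealso [fitLogit()], [fitHierLogit()], [predictPtspo()], [waldScreen()]
#' @export
setClass("TspoLogitModel",
  representation(coefficients = "numeric", se = "numeric", zstat = "numeric",
                 deviance = "numeric", nullDeviance = "numeric",
                 converged = "logical", iterations = "integer",
                 randomIntercepts = "numeric", randomSD = "numeric",
                 featureSpec = "FeatureSpec", fitInfo = "list"))

setValidity("TspoLogitModel", function(object) {
  if (any(!is.finite(object@coefficients))) return("non-finite coefficients")
  if (length(object@deviance) && object@deviance < -1e-8)
    return("deviance must be >= 0")
  if (length(object@randomIntercepts) &&
      abs(mean(object@randomIntercepts)) > 1e-6 + 1e-6)
    return("random intercepts must be centred")
  TRUE
})

#' ROC curve of p_TSPO classification
#'
#' @slot thresholds numeric, decision thresholds swept over the scores.
#' @slot sensitivity numeric per threshold.
#' @slot specificity numeric per threshold.
#' @slot auc numeric(1), trapezoidal area under the curve.
#' @seealso [rocAnalysis()]
#' @export
setClass("RocCurve",
  representation(thresholds = "numeric", sensitivity = "numeric",
                 specificity = "numeric", auc = "numeric"))

setValidity("RocCurve", function(object) {
  if (object@auc < -1e-12 || object@auc > 1 + 1e-12)
    return("auc must lie in [0, 1]")
  if (length(object@sensitivity) != length(object@thresholds) ||
      length(object@specificity) != length(object@thresholds))
    return("sensitivity/specificity must match thresholds in length")
  TRUE
})

#' Two-cohort comparison of p_TSPO distributions
#'
#' Holds the relative-probability histograms of two cohorts of per-ROI
#' p_TSPO values, their bin-by-bin deviation (case minus control), the
#' Delta_P summary (percent mass shift above p = 0.5) and the Wilcoxon test
#' result.
#'
#' @slot binEdges numeric, histogram bin edges spanning [0, 1].
#' @slot histCase,histControl numeric, relative-probability histograms
#'   (each sums to 1).
#' @slot deviation numeric, `histCase - histControl` (sums to 0).
#' @slot deltaP numeric(1), percent; positive when the case cohort carries
#'   more mass above 0.5.
#' @slot test character(1), `"rank-sum"` or `"signed-rank"`.
#' @slot pValue numeric(1), two-sided.
#' @slot statistic numeric(1).
#' @slot nCase,nControl integer(1).
#' @slot cohensD numeric(1), optional effect size (NA if not computed).
#' @seealso [deltaP()], [compareCohorts()]
#' @export
setClass("GroupComparison",
  representation(binEdges = "numeric", histCase = "numeric",
                 histControl = "numeric", deviation = "numeric",
                 deltaP = "numeric", test = "character", pValue = "numeric",
                 statistic = "numeric", nCase = "integer",
                 nControl = "integer", cohensD = "numeric"))

setValidity("GroupComparison", function(object) {
  nb <- length(object@binEdges) - 1L
  if (length(object@histCase) != nb || length(object@histControl) != nb)
    return("histogram length must equal number of bins")
  if (abs(sum(object@histCase) - 1) > 1e-12 ||
      abs(sum(object@histControl) - 1) > 1e-12)
    return("relative histograms must sum to 1")
  if (abs(sum(object@deviation)) > 1e-12)
    return("deviation histogram must sum to 0")
  if (object@deltaP < -100 - 1e-9 || object@deltaP > 100 + 1e-9)
    return("deltaP must lie in [-100, 100]")
  TRUE
})

#' Bootstrap stepwise selection report
#'
#' @slot frequency named numeric, per-feature selection frequency in [0, 1].
#' @slot retained character, features with frequency strictly above the
#'   threshold.
#' @slot nIterations integer(1).
#' @slot threshold numeric(1).
#' @slot seed integer(1).
#' @slot nSkipped integer(1), resamples skipped for having one outcome class.
#' @seealso [bootstrapSelection()]
#' @export
setClass("SelectionReport",
  representation(frequency = "numeric", retained = "character",
                 nIterations = "integer", threshold = "numeric",
                 seed = "integer", nSkipped = "integer"))

setValidity("SelectionReport", function(object) {
  f <- object@frequency
  if (any(f < -1e-12) || any(f > 1 + 1e-12))
    return("frequencies must lie in [0, 1]")
  want <- names(f)[f > object@threshold]
  if (!setequal(want, object@retained))
    return("retained set inconsistent with frequencies/threshold")
  TRUE
})
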