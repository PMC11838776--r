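## Design-matrix assembly: SUV conversion, sparse-grid sampling, covariate
## encoding, persisted min-max normalization.

#' Create a feature specification
#'
#' The default sparse TAC sampling grid is `[1.25, 4.5, 13.5, 30, 50, 75]`
#' minutes, chosen to limit collinearity between neighbouring frames, and
#' the default covariates are the regional `K1`, `age`, `sex`, `genotype`
#' and `dose_over_weight`. Grid features are named `tac_<minutes>`.
#'
#' @param gridMinutes strictly increasing sampling times, minutes.
#' @param covariates character, covariate feature names (subset of
#'   `c("K1", "age", "sex", "genotype", "dose_over_weight")`).
#' @return a [FeatureSpec-class] with all features active and unfitted
#'   bounds.
#' @examples
#' featureSpec()
#' @export
featureSpec <- function(gridMinutes = c(1.25, 4.5, 13.5, 30, 50, 75),
                        covariates = c("K1", "age", "sex", "genotype",
                                       "dose_over_weight")) {
  known <- c("K1", "age", "sex", "genotype", "dose_over_weight")
  if (!all(covariates %in% known))
    stop("unknown covariate(s): ",
         paste(setdiff(covariates, known), collapse = ", "))
  fn <- c(paste0("tac_", gridMinutes), covariates)
  sel <- rep(TRUE, length(fn)); names(sel) <- fn
  b <- matrix(numeric(0), nrow = 2, ncol = 0,
              dimnames = list(c("min", "max"), NULL))
  new("FeatureSpec", gridMinutes = as.numeric(gridMinutes),
      covariates = covariates, featureNames = fn, bounds = b,
      selected = sel)
}

#' Convert activity to standardized uptake value (SUV)
#'
#' `SUV(t) = C(t) / (injected dose / body weight)` with `C` in kBq/mL, dose
#' in MBq and weight in kg: the MBq-to-kBq and kg-to-g factors cancel, so
#' `SUV = C * weight / dose` in the conventional g/mL units. Dose-over-
#' weight differences between subjects are thereby removed.
#'
#' @param tac a [TacExperiment-class]; its `subjects` table must carry
#'   `injected_dose` (MBq) and `weight` (kg) for every subject present.
#' @return the [TacExperiment-class] with activity replaced by SUV (units
#'   recorded as `"SUV"`).
#' @export
toSUV <- function(tac) {
  stopifnot(is(tac, "TacExperiment"))
  sub <- as.data.frame(subjectData(tac))
  if (!nrow(sub) || !all(c("injected_dose", "weight") %in% names(sub)))
    stop("covariate error: subjects table with injected_dose and weight ",
         "is required for SUV conversion")
  idx <- match(rowData(tac)$subject_id, sub$subject_id)
  if (anyNA(idx))
    stop("covariate error: no covariates for subject(s) ",
         paste(unique(rowData(tac)$subject_id[is.na(idx)]), collapse = ", "))
  dose <- sub$injected_dose[idx]; wt <- sub$weight[idx]
  if (any(dose <= 0) || any(wt <= 0))
    stop("covariate error: dose and weight must be > 0")
  assay(tac, "activity") <- activity(tac) * wt / dose
  metadata(tac)$units <- "SUV"
  tac
}

#' Sample a TAC on a sparse time grid
#'
#' Linear interpolation of the per-frame values against frame mid-times at
#' the requested grid points. Grid points outside `[first mid-time, last
#' mid-time]` raise an error under the default policy, or take the nearest
#' frame value with a warning under `policy = "nearest"`. A 60-minute
#' schedule therefore still serves the 1.25/13.5/50-minute points used by a
#' reduced model, while a request at 75 minutes fails loudly.
#'
#' @param y numeric, per-frame values.
#' @param schedule a [FrameSchedule-class].
#' @param grid numeric, sampling times in minutes.
#' @param policy `"error"` (default) or `"nearest"` for out-of-range points.
#' @return numeric of `length(grid)`.
#' @export
sampleOnGrid <- function(y, schedule, grid, policy = c("error", "nearest")) {
  policy <- match.arg(policy)
  mid <- frameMid(schedule)
  stopifnot(length(y) == length(mid))
  out <- stats::approx(mid, y, xout = grid, rule = 1)$y
  if (anyNA(out)) {
    bad <- grid[is.na(out)]
    if (policy == "error")
      stop("grid point(s) ", paste(bad, collapse = ", "),
           " min outside the sampled range [", min(mid), ", ", max(mid),
           "] min")
    warning("grid point(s) ", paste(bad, collapse = ", "),
            " min outside the sampled range; nearest value used")
    out[is.na(out)] <- stats::approx(mid, y, xout = bad, rule = 2)$y
  }
  out
}

#' Min-max normalization with persisted bounds
#'
#' @param X numeric matrix (rows = observations).
#' @param bounds matrix with rows `min`, `max` and one column per feature;
#'   if `NULL`, bounds are computed from `X`.
#' @return for `normalizeFeatures`, the normalized matrix with the bounds
#'   attached as `attr(, "bounds")`; values outside the training range map
#'   outside `[0, 1]` and are deliberately not clipped. For
#'   `denormalizeFeatures`, the original-scale matrix.
#' @export
normalizeFeatures <- function(X, bounds = NULL) {
  X <- as.matrix(X)
  if (is.null(bounds)) {
    bounds <- rbind(min = apply(X, 2, min), max = apply(X, 2, max))
    colnames(bounds) <- colnames(X)
  }
  bounds <- bounds[, colnames(X), drop = FALSE]
  rng <- bounds["max", ] - bounds["min", ]
  if (any(rng <= 0))
    stop("degenerate-feature error: min == max for ",
         paste(colnames(X)[rng <= 0], collapse = ", "))
  out <- sweep(sweep(X, 2, bounds["min", ]), 2, rng, "/")
  attr(out, "bounds") <- bounds
  out
}

#' @rdname normalizeFeatures
#' @param Xn normalized matrix.
#' @export
denormalizeFeatures <- function(Xn, bounds) {
  bounds <- bounds[, colnames(Xn), drop = FALSE]
  rng <- bounds["max", ] - bounds["min", ]
  sweep(sweep(as.matrix(Xn), 2, rng, "*"), 2, bounds["min", ], "+")
}

.encodeSex <- function(x) {
  if (!all(x %in% c("male", "female")))
    stop("covariate error: sex must be 'male'/'female'")
  as.numeric(x == "male")           # male = 1, female = 0
}

.encodeGenotype <- function(x) {
  if (!all(x %in% c("HAB", "MAB")))
    stop("covariate error: genotype must be 'HAB'/'MAB'")
  as.numeric(x == "HAB")            # HAB = 1, MAB = 0
}

#' Assemble the logistic design matrix
#'
#' Builds one design row per (subject, ROI) trace: SUV TAC samples on the
#' sparse grid, the regional `K1`, and the encoded subject covariates
#' (age in years; sex male = 1 / female = 0; genotype HAB = 1 / MAB = 0;
#' dose over weight in MBq/kg). Features are min-max normalized to `[0, 1]`
#' with bounds computed in fit mode (from training rows by default, or from
#' all rows with `boundsFrom = "all"`) and persisted for apply mode, where
#' out-of-range values are carried unclipped. Training outcomes come from
#' the expression map: `low` ROIs get outcome 0, `high` ROIs outcome 1,
#' anything else `NA` (rows kept for prediction).
#'
#' @param tacs a [TacExperiment-class] in SUV units (or raw kBq/mL with
#'   `suv = TRUE`, the default, to convert on the fly).
#' @param k1 data.frame from [estimateK1()] with `subject_id, roi_id, K1`.
#' @param spec a [FeatureSpec-class].
#' @param labels expression-map data.frame (`roi_id, expression,
#'   class_label`) or `NULL` for prediction-only designs.
#' @param bounds persisted bounds matrix for apply mode; `NULL` fits them.
#' @param boundsFrom `"training"` (default) or `"all"`: rows used to fit
#'   bounds.
#' @param suv logical, convert to SUV first (skipped if the container is
#'   already in SUV units).
#' @param gridPolicy passed to [sampleOnGrid()].
#' @return data.frame with id columns `subject_id, roi_id, dataset_id`,
#'   `outcome` (0/1/NA) and one column per feature in `spec`; the fitted
#'   [FeatureSpec-class] (bounds filled) is attached as `attr(, "spec")`
#'   and the bounds as `attr(, "bounds")`.
#' @export
buildDesign <- function(tacs, k1, spec = featureSpec(), labels = NULL,
                        bounds = NULL, boundsFrom = c("training", "all"),
                        suv = TRUE, gridPolicy = "error") {
  stopifnot(is(tacs, "TacExperiment"), is(spec, "FeatureSpec"))
  boundsFrom <- match.arg(boundsFrom)
  if (suv && !identical(metadata(tacs)$units, "SUV")) tacs <- toSUV(tacs)
  sub <- as.data.frame(subjectData(tacs))
  .checkSubjects(sub)
  rd <- as.data.frame(rowData(tacs))
  idx <- match(rd$subject_id, sub$subject_id)
  if (anyNA(idx))
    stop("covariate error: missing covariates for subject(s) ",
         paste(unique(rd$subject_id[is.na(idx)]), collapse = ", "))
  a <- activity(tacs)
  sched <- schedule(tacs)
  G <- t(apply(a, 1L, sampleOnGrid, schedule = sched,
               grid = spec@gridMinutes, policy = gridPolicy))
  colnames(G) <- paste0("tac_", spec@gridMinutes)

  key <- paste(rd$subject_id, rd$roi_id, sep = "\r")
  k1idx <- match(key, paste(k1$subject_id, k1$roi_id, sep = "\r"))
  if (anyNA(k1idx) && "K1" %in% spec@covariates)
    stop("missing K1 for ",
         paste(utils::head(key[is.na(k1idx)], 5), collapse = "; "))
  cov <- data.frame(
    K1 = if (anyNA(k1idx)) NA_real_ else k1$K1[k1idx],
    age = sub$age[idx],
    sex = .encodeSex(sub$sex[idx]),
    genotype = .encodeGenotype(sub$genotype[idx]),
    dose_over_weight = sub$injected_dose[idx] / sub$weight[idx])
  X <- cbind(G, as.matrix(cov[, spec@covariates, drop = FALSE]))
  X <- X[, spec@featureNames, drop = FALSE]

  outcome <- rep(NA_real_, nrow(X))
  if (!is.null(labels)) {
    li <- match(rd$roi_id, labels$roi_id)
    cls <- ifelse(is.na(li), "unlabelled", labels$class_label[li])
    outcome[cls == "low"] <- 0
    outcome[cls == "high"] <- 1
  }
  if (is.null(bounds)) {
    fitRows <- if (boundsFrom == "training" && any(!is.na(outcome)))
      which(!is.na(outcome)) else seq_len(nrow(X))
    Xn <- normalizeFeatures(X[fitRows, , drop = FALSE])
    bounds <- attr(Xn, "bounds")
  }
  Xn <- normalizeFeatures(X, bounds)
  out <- data.frame(subject_id = rd$subject_id, roi_id = rd$roi_id,
                    dataset_id = sub$dataset_id[idx], outcome = outcome,
                    as.data.frame(unclass(Xn)), check.names = FALSE)
  spec@bounds <- bounds
  attr(out, "bounds") <- bounds
  attr(out, "spec") <- spec
  rownames(out) <- NULL
  out
}

#' Feature columns of a design
#'
#' @param design a data.frame from [buildDesign()].
#' @param spec optional [FeatureSpec-class]; defaults to the one attached
#'   to the design. Only active (`selected`) features are returned.
#' @return numeric matrix of the active feature columns.
#' @export
designMatrix <- function(design, spec = attr(design, "spec")) {
  feats <- if (is.null(spec)) {
    setdiff(colnames(design),
            c("subject_id", "roi_id", "dataset_id", "outcome"))
  } else spec@featureNames[spec@selected]
  as.matrix(design[, feats, drop = FALSE])
}
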