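## The p_TSPO logistic model: plain IRLS fit with optional ridge rescue,
## hierarchical fit with a per-dataset random intercept (Laplace ML via
## lme4), prediction, and Wald screening of predictors.

.binDeviance <- function(y, mu) {
  eps <- 1e-12
  mu <- pmin(pmax(mu, eps), 1 - eps)
  -2 * sum(y * log(mu) + (1 - y) * log(1 - mu))
}

.designFeatures <- function(design, features = NULL) {
  if (is.null(features)) {
    spec <- attr(design, "spec")
    features <- if (is.null(spec)) {
      setdiff(colnames(design),
              c("subject_id", "roi_id", "dataset_id", "outcome"))
    } else spec@featureNames[spec@selected]
  }
  miss <- setdiff(features, colnames(design))
  if (length(miss))
    stop("prediction error: design lacks feature(s) ",
         paste(miss, collapse = ", "))
  features
}

.specFor <- function(design, features) {
  spec <- attr(design, "spec")
  if (is.null(spec)) {
    sel <- rep(TRUE, length(features)); names(sel) <- features
    spec <- new("FeatureSpec", gridMinutes = numeric(0),
                covariates = character(0), featureNames = features,
                bounds = matrix(numeric(0), 2, 0,
                                dimnames = list(c("min", "max"), NULL)),
                selected = sel)
  } else {
    spec@selected <- spec@featureNames %in% features
    names(spec@selected) <- spec@featureNames
  }
  spec
}

#' Fit the logistic model by maximum likelihood (IRLS)
#'
#' Fits `logit P(outcome = 1) = b0 + sum_j b_j X_j` on the labelled rows of
#' a design by iteratively reweighted least squares, reporting deviance,
#' per-coefficient standard errors and Wald z statistics. An optional ridge
#' penalty (excluded from the intercept) rescues fits with perfect
#' separation, which otherwise abort with an error naming the most
#' suspicious feature.
#'
#' @param design data.frame from [buildDesign()] (or any frame with an
#'   `outcome` column in {0,1} and numeric feature columns).
#' @param features character, feature columns to use; defaults to the
#'   active features of the attached [FeatureSpec-class], else all feature
#'   columns.
#' @param ridge non-negative penalty on the squared coefficients
#'   (default 0 = plain maximum likelihood).
#' @param maxit,tol IRLS iteration cap and relative deviance tolerance.
#' @return a [TspoLogitModel-class].
#' @seealso [fitHierLogit()], [predictPtspo()], [waldScreen()]
#' @export
fitLogit <- function(design, features = NULL, ridge = 0, maxit = 100L,
                     tol = 1e-10) {
  features <- .designFeatures(design, features)
  rows <- !is.na(design$outcome)
  y <- design$outcome[rows]
  if (!all(y %in% c(0, 1))) stop("outcome must be 0/1 on training rows")
  if (length(unique(y)) < 2L)
    stop("need at least one row per outcome class")
  X <- cbind(`(Intercept)` = 1,
             as.matrix(design[rows, features, drop = FALSE]))
  storage.mode(X) <- "double"
  csd <- apply(X[, -1, drop = FALSE], 2, stats::sd)
  if (any(csd == 0))
    stop("constant feature(s): ",
         paste(features[csd == 0], collapse = ", "))
  if (qr(X)$rank < ncol(X))
    stop("collinearity error: design matrix is rank deficient")
  p <- ncol(X)
  pen <- diag(c(0, rep(ridge, p - 1L)), p)
  beta <- numeric(p)
  dev <- .binDeviance(y, rep(mean(y), length(y)))
  conv <- FALSE; it <- 0L
  repeat {
    it <- it + 1L
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-12)
    z <- eta + (y - mu) / w
    XtW <- t(X * w)
    beta <- drop(solve(XtW %*% X + pen, XtW %*% z))
    newdev <- .binDeviance(y, stats::plogis(drop(X %*% beta))) +
      drop(t(beta) %*% pen %*% beta)
    if (abs(newdev - dev) < tol * (abs(dev) + tol)) {
      dev <- newdev; conv <- TRUE; break
    }
    dev <- newdev
    if (it >= maxit) break
    if (ridge == 0 && max(abs(beta)) > 1e3) break
  }
  nullDev <- .binDeviance(y, rep(mean(y), length(y)))
  separated <- ridge == 0 && max(abs(beta)) > 50 &&
    (!conv || dev < max(1e-6 * nullDev, 1e-8))
  if (separated) {
    worst <- features[which.max(abs(beta[-1]))]
    stop("divergence error: apparent perfect separation (feature '",
         worst, "'); refit with a small ridge penalty")
  }
  eta <- drop(X %*% beta)
  mu <- stats::plogis(eta)
  w <- pmax(mu * (1 - mu), 1e-12)
  info <- t(X * w) %*% X + pen
  se <- sqrt(diag(solve(info)))
  names(beta) <- names(se) <- colnames(X)
  zstat <- beta / se
  new("TspoLogitModel",
      coefficients = beta, se = se, zstat = zstat,
      deviance = .binDeviance(y, mu),
      nullDeviance = nullDev,
      converged = conv, iterations = it,
      randomIntercepts = numeric(0), randomSD = numeric(0),
      featureSpec = .specFor(design, features),
      fitInfo = list(engine = "irls", ridge = ridge, n = length(y),
                     encodings = c(sex = "male=1", genotype = "HAB=1")))
}

#' Fit the hierarchical logistic model (per-dataset random intercept)
#'
#' Adds a Gaussian random intercept per `dataset_id` to the logistic model
#' to absorb batch differences between scanners/protocols, fitted by
#' Laplace-approximate maximum likelihood ([lme4::glmer()]). With a single
#' dataset the fit falls back to [fitLogit()] with a message; datasets
#' missing one outcome class are flagged.
#'
#' @inheritParams fitLogit
#' @param nAGQ integer, quadrature points for [lme4::glmer()] (1 =
#'   Laplace; larger values give adaptive Gauss-Hermite verification fits).
#' @return a [TspoLogitModel-class] with `randomIntercepts` (centred
#'   per-dataset modes) and `randomSD` filled.
#' @export
fitHierLogit <- function(design, features = NULL, nAGQ = 1L) {
  features <- .designFeatures(design, features)
  rows <- !is.na(design$outcome)
  d <- design[rows, , drop = FALSE]
  if (is.null(d$dataset_id)) stop("design lacks dataset_id")
  ds <- unique(d$dataset_id)
  if (length(ds) < 2L) {
    message("single dataset; falling back to the plain logistic fit")
    return(fitLogit(design, features))
  }
  oneClass <- vapply(split(d$outcome, d$dataset_id),
                     function(y) length(unique(y)) < 2L, logical(1))
  if (any(oneClass))
    warning("dataset(s) with a single outcome class: ",
            paste(names(oneClass)[oneClass], collapse = ", "))
  df <- data.frame(.y = d$outcome,
                   .g = factor(d$dataset_id),
                   as.matrix(d[, features, drop = FALSE]))
  fn <- paste0("f", seq_along(features))
  names(df)[-(1:2)] <- fn
  fml <- stats::as.formula(paste(".y ~", paste(fn, collapse = " + "),
                                 "+ (1 | .g)"))
  fit <- lme4::glmer(fml, data = df, family = stats::binomial(),
                     nAGQ = nAGQ)
  beta <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  names(beta) <- names(se) <- c("(Intercept)", features)
  re <- lme4::ranef(fit)$.g[[1]]
  names(re) <- rownames(lme4::ranef(fit)$.g)
  m <- mean(re)
  beta[1] <- beta[1] + m            # fold residual mean into the intercept
  re <- re - m
  sdre <- sqrt(as.numeric(lme4::VarCorr(fit)$.g))
  conv <- length(fit@optinfo$conv$lme4) == 0L
  mu <- stats::fitted(fit)
  new("TspoLogitModel",
      coefficients = beta, se = se, zstat = beta / se,
      deviance = .binDeviance(df$.y, mu),
      nullDeviance = .binDeviance(df$.y, rep(mean(df$.y), nrow(df))),
      converged = conv, iterations = NA_integer_,
      randomIntercepts = re, randomSD = sdre,
      featureSpec = .specFor(design, features),
      fitInfo = list(engine = "glmer-laplace", nAGQ = nAGQ,
                     n = nrow(df), datasets = levels(df$.g),
                     encodings = c(sex = "male=1", genotype = "HAB=1")))
}

#' Predict p_TSPO for design rows
#'
#' Computes the linear predictor `b0 + sum_j b_j X_j` (plus the dataset's
#' random intercept under `datasetPolicy = "random"` for datasets seen in
#' training; unseen datasets get the population level, offset 0) and maps
#' it through the logistic function.
#'
#' @param model a [TspoLogitModel-class].
#' @param design data.frame carrying the model's active feature columns
#'   (already normalized with the training bounds) and, ideally,
#'   `subject_id`/`roi_id`/`dataset_id`.
#' @param datasetPolicy `"random"` (default; apply known per-dataset
#'   offsets) or `"population"` (offset 0 everywhere).
#' @return data.frame with `subject_id`, `roi_id`, `dataset_id`,
#'   `linear_predictor` and `p_tspo` in `[0, 1]`.
#' @export
predictPtspo <- function(model, design,
                         datasetPolicy = c("random", "population")) {
  stopifnot(is(model, "TspoLogitModel"))
  datasetPolicy <- match.arg(datasetPolicy)
  feats <- names(model@coefficients)[-1]
  miss <- setdiff(feats, colnames(design))
  if (length(miss))
    stop("prediction error: missing feature(s) ",
         paste(miss, collapse = ", "))
  X <- as.matrix(design[, feats, drop = FALSE])
  eta <- model@coefficients[1] + drop(X %*% model@coefficients[-1])
  if (datasetPolicy == "random" && length(model@randomIntercepts) &&
      !is.null(design$dataset_id)) {
    off <- model@randomIntercepts[as.character(design$dataset_id)]
    off[is.na(off)] <- 0
    eta <- eta + off
  }
  data.frame(
    subject_id = if (is.null(design$subject_id)) NA else design$subject_id,
    roi_id = if (is.null(design$roi_id)) NA else design$roi_id,
    dataset_id = if (is.null(design$dataset_id)) NA else design$dataset_id,
    linear_predictor = eta,
    p_tspo = stats::plogis(eta))
}

#' Wald screening of model predictors
#'
#' Retains the features whose Wald statistic `|z| = |beta / se|` exceeds
#' the threshold (default 1.96, the two-sided 5% point). The intercept is
#' never screened.
#'
#' @param model a fitted [TspoLogitModel-class] with standard errors.
#' @param zThreshold numeric(1), default 1.96; 0 retains everything.
#' @return character vector of retained feature names.
#' @export
waldScreen <- function(model, zThreshold = 1.96) {
  stopifnot(is(model, "TspoLogitModel"))
  if (!length(model@se) || any(!is.finite(model@se)))
    stop("model carries no finite standard errors")
  z <- model@zstat[-1]
  names(z)[abs(z) > zThreshold]
}

#' Serialize / restore a fitted model bundle
#'
#' The bundle (coefficients, standard errors, random intercepts, feature
#' spec with normalization bounds, fit info) is written as JSON so that
#' predictions are reproducible across sessions.
#'
#' @param model a [TspoLogitModel-class].
#' @param path JSON file path.
#' @return `readModelBundle` returns the restored
#'   [TspoLogitModel-class]; `writeModelBundle` returns `path` invisibly.
#' @export
writeModelBundle <- function(model, path) {
  spec <- model@featureSpec
  jsonlite::write_json(list(
    coefficients = as.list(model@coefficients),
    se = as.list(model@se), zstat = as.list(model@zstat),
    deviance = model@deviance, null_deviance = model@nullDeviance,
    converged = model@converged,
    random_intercepts = as.list(model@randomIntercepts),
    random_sd = model@randomSD,
    feature_spec = list(grid_minutes = spec@gridMinutes,
                        covariates = spec@covariates,
                        feature_names = spec@featureNames,
                        selected = as.list(spec@selected),
                        bounds_min = as.list(spec@bounds["min", ]),
                        bounds_max = as.list(spec@bounds["max", ])),
    fit_info = model@fitInfo),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname writeModelBundle
#' @export
readModelBundle <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  fs <- j$feature_spec
  bounds <- rbind(min = unlist(fs$bounds_min), max = unlist(fs$bounds_max))
  if (is.null(bounds) || !length(bounds))
    bounds <- matrix(numeric(0), 2, 0,
                     dimnames = list(c("min", "max"), NULL))
  spec <- new("FeatureSpec", gridMinutes = as.numeric(fs$grid_minutes),
              covariates = as.character(fs$covariates),
              featureNames = as.character(fs$feature_names),
              bounds = bounds,
              selected = unlist(fs$selected))
  new("TspoLogitModel",
      coefficients = unlist(j$coefficients), se = unlist(j$se),
      zstat = unlist(j$zstat), deviance = as.numeric(j$deviance),
      nullDeviance = as.numeric(j$null_deviance),
      converged = isTRUE(j$converged), iterations = NA_integer_,
      randomIntercepts = if (length(j$random_intercepts))
        unlist(j$random_intercepts) else numeric(0),
      randomSD = as.numeric(j$random_sd),
      featureSpec = spec, fitInfo = as.list(j$fit_info))
}
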