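## Config-driven orchestration: stratified splitting, model training with
## bootstrap selection, leave-one-out prediction, cohort comparison, and
## the rat LPS workflow.

#' Per-subject K1 estimation across a cohort
#'
#' Runs [estimateK1()] on each subject's regional TACs with that subject's
#' fitted input function.
#'
#' @param tacs a [TacExperiment-class] in kBq/mL.
#' @param inputs named list of [TriExpFit-class] input models, one per
#'   subject.
#' @param window fit window in minutes (4 for PBR28-like kinetics, 5 for
#'   DPA-714/PK11195-like).
#' @param ... passed to [estimateK1()].
#' @return data.frame with `subject_id, roi_id, K1, vb, rss, n_points,
#'   window, clamped`.
#' @export
estimateCohortK1 <- function(tacs, inputs, window = 4, ...) {
  stopifnot(is(tacs, "TacExperiment"))
  subj <- unique(rowData(tacs)$subject_id)
  miss <- setdiff(subj, names(inputs))
  if (length(miss))
    stop("no input function for subject(s) ",
         paste(utils::head(miss, 5), collapse = ", "))
  out <- lapply(subj, function(s) {
    estimateK1(tacs[rowData(tacs)$subject_id == s, ], inputs[[s]],
               window = window, ...)
  })
  do.call(rbind, out)
}

#' Stratified train/test split of subjects
#'
#' Splits subjects into train and test sets of sizes `(1 - testFraction)`
#' / `testFraction` while balancing the composite strata formed by sex,
#' genotype, the age dichotomy (under 30 vs 30 and older; boundary age 30
#' goes to the older stratum) and dataset. Test counts are allocated per
#' stratum by largest fractional remainder; within-stratum picks are a
#' seeded shuffle. Strata with fewer than 2 subjects degrade gracefully
#' with a warning.
#'
#' @param subjects data.frame/DataFrame with `subject_id, sex, genotype,
#'   age, dataset_id`.
#' @param testFraction fraction of subjects held out (default 0.2); the
#'   test set size is `round(testFraction * n)`.
#' @param ageCut dichotomization age in years (default 30).
#' @param seed integer.
#' @return list with character vectors `train` and `test`.
#' @export
stratifiedSplit <- function(subjects, testFraction = 0.2, ageCut = 30,
                            seed = 1L) {
  subjects <- as.data.frame(subjects)
  n <- nrow(subjects)
  nTest <- round(testFraction * n)
  key <- paste(subjects$sex, subjects$genotype,
               ifelse(subjects$age >= ageCut, "older", "younger"),
               subjects$dataset_id, sep = "|")
  strata <- split(subjects$subject_id, key)
  if (any(lengths(strata) < 2L))
    warning("stratum/strata with < 2 subjects; stratification degrades ",
            "gracefully")
  oldseed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(oldseed))
    assign(".Random.seed", oldseed, globalenv()))
  set.seed(seed)
  sizes <- lengths(strata)
  exact <- sizes * nTest / n
  base <- floor(exact)
  rem <- nTest - sum(base)
  if (rem > 0) {
    o <- order(exact - base, sizes, decreasing = TRUE)
    base[o[seq_len(rem)]] <- base[o[seq_len(rem)]] + 1L
  }
  base <- pmin(base, sizes)
  short <- nTest - sum(base)
  if (short > 0) {      # some strata were capped; top up from the largest
    o <- order(sizes - base, decreasing = TRUE)
    for (i in o) {
      add <- min(short, sizes[i] - base[i])
      base[i] <- base[i] + add; short <- short - add
      if (short == 0) break
    }
  }
  test <- unlist(lapply(seq_along(strata), function(i) {
    ids <- sample(strata[[i]])
    ids[seq_len(base[i])]
  }), use.names = FALSE)
  list(train = setdiff(subjects$subject_id, test), test = test)
}

#' Train the p_TSPO model end to end
#'
#' Full training workflow: stratified 80/20 subject split, min-max bounds
#' fitted on the training subjects' labelled (low/high) rows,
#' bootstrap-stabilised stepwise feature selection on the training design,
#' final (hierarchical when several datasets are present) logistic fit,
#' and ROC evaluation of the held-out labelled rows.
#'
#' @param tacs a [TacExperiment-class] (kBq/mL; converted to SUV
#'   internally) with subject covariates attached.
#' @param k1 data.frame of regional K1 estimates (see
#'   [estimateCohortK1()]).
#' @param labels expression map with low/high training classes.
#' @param spec a [FeatureSpec-class].
#' @param hierarchical logical; default `TRUE` when 2+ datasets present.
#' @param select logical, run bootstrap selection (default TRUE).
#' @param nBoot,freqThreshold bootstrap selection settings (defaults 100
#'   and 0.80).
#' @param testFraction held-out subject fraction (default 0.2).
#' @param ridge ridge penalty for the plain logistic fit (default 0);
#'   when a plain maximum-likelihood fit diverges through perfect
#'   separation the fit is retried once with a 1e-4 ridge and a message.
#' @param seed integer, controls split and bootstrap.
#' @return list with `model` ([TspoLogitModel-class]), `selection`
#'   ([SelectionReport-class] or NULL), `features` (active set), `roc`
#'   ([RocCurve-class] on held-out labelled rows), `split`, `design`
#'   (full normalized design) and `bounds`.
#' @export
trainTspoModel <- function(tacs, k1, labels, spec = featureSpec(),
                           hierarchical = NULL, select = TRUE,
                           nBoot = 100L, freqThreshold = 0.80,
                           testFraction = 0.2, ridge = 0, seed = 1L) {
  sub <- as.data.frame(subjectData(tacs))
  if (is.null(hierarchical))
    hierarchical <- length(unique(sub$dataset_id)) >= 2L
  split <- stratifiedSplit(sub, testFraction = testFraction, seed = seed)
  trTac <- tacs[rowData(tacs)$subject_id %in% split$train, ]
  trDesign <- buildDesign(trTac, k1, spec = spec, labels = labels)
  bounds <- attr(trDesign, "bounds")
  design <- buildDesign(tacs, k1, spec = spec, labels = labels,
                        bounds = bounds)

  selection <- NULL
  features <- .designFeatures(trDesign)
  if (select) {
    selection <- bootstrapSelection(trDesign, nIter = nBoot,
                                    freqThreshold = freqThreshold,
                                    seed = seed)
    if (length(selection@retained)) features <- selection@retained
  }
  fit <- if (hierarchical) {
    fitHierLogit(trDesign, features)
  } else {
    tryCatch(fitLogit(trDesign, features, ridge = ridge),
             error = function(e) {
               if (!grepl("separation", conditionMessage(e))) stop(e)
               message("separation rescue: refitting with ridge 1e-4")
               fitLogit(trDesign, features, ridge = 1e-4)
             })
  }
  fit@featureSpec@bounds <- bounds

  teRows <- design$subject_id %in% split$test & !is.na(design$outcome)
  roc <- NULL
  if (any(teRows)) {
    p <- predictPtspo(fit, design[teRows, , drop = FALSE])
    roc <- rocAnalysis(p$p_tspo, design$outcome[teRows])
  }
  list(model = fit, selection = selection, features = features,
       roc = roc, split = split, design = design, bounds = bounds)
}

#' Leave-one-subject-out prediction of p_TSPO
#'
#' For each subject, refits the model on the labelled rows of every other
#' subject and predicts that subject's ROIs (by default the CC prediction
#' domain, i.e. every ROI in the design). Non-convergent folds are
#' flagged and skipped rather than aborting the run.
#'
#' @param design full normalized design (e.g. from [trainTspoModel()]'s
#'   `design` element, or [buildDesign()]).
#' @param features character, active features of the model.
#' @param rois optional character, ROIs to predict per fold (default all
#'   of the subject's rows).
#' @param hierarchical logical, refit with the random intercept per fold.
#' @param ridge ridge penalty for the per-fold plain fits (default 0).
#' @return list with `p` (stacked prediction data.frame), `coefficients`
#'   (fold x coefficient matrix) and `failed` (subject ids of
#'   non-convergent folds).
#' @export
looPredict <- function(design, features = NULL, rois = NULL,
                       hierarchical = FALSE, ridge = 0) {
  features <- .designFeatures(design, features)
  subj <- unique(design$subject_id)
  if (length(subj) < 3L) stop("leave-one-out needs at least 3 subjects")
  preds <- list(); coefs <- list(); failed <- character(0)
  for (s in subj) {
    tr <- design[design$subject_id != s, , drop = FALSE]
    attr(tr, "spec") <- attr(design, "spec")
    fit <- tryCatch(
      if (hierarchical) fitHierLogit(tr, features)
      else fitLogit(tr, features, ridge = ridge),
      error = function(e) NULL)
    if (is.null(fit) || !fit@converged) {
      failed <- c(failed, s)
      next
    }
    rows <- design$subject_id == s
    if (!is.null(rois)) rows <- rows & design$roi_id %in% rois
    preds[[s]] <- predictPtspo(fit, design[rows, , drop = FALSE])
    coefs[[s]] <- coef(fit)
  }
  if (!length(preds)) stop("every leave-one-out fold failed")
  list(p = do.call(rbind, c(preds, list(make.row.names = FALSE))),
       coefficients = do.call(rbind, coefs), failed = failed)
}

#' Compare two cohorts' p_TSPO, whole-domain and per lobe
#'
#' Runs [deltaP()] on the pooled per-ROI p_TSPO values of the two cohorts
#' and, when a lobe table is supplied, repeats the comparison within each
#' lobe (frontal, temporal, parietal, occipital, cerebellum in the
#' intended use).
#'
#' @param pCase,pControl prediction data.frames (from [predictPtspo()] or
#'   [looPredict()]) with `roi_id` and `p_tspo`.
#' @param lobeMap optional data.frame `roi_id, lobe`; if missing, only
#'   the whole-domain comparison is returned, with a warning.
#' @param paired logical, passed to [deltaP()].
#' @param binWidth histogram bin width (default 0.05).
#' @return list with `whole` (a [GroupComparison-class]) and `perLobe`
#'   (named list of [GroupComparison-class], possibly empty).
#' @export
compareCohorts <- function(pCase, pControl, lobeMap = NULL,
                           paired = FALSE, binWidth = 0.05) {
  whole <- deltaP(pCase$p_tspo, pControl$p_tspo, binWidth = binWidth,
                  paired = paired)
  perLobe <- list()
  if (is.null(lobeMap)) {
    warning("no lobe table supplied; whole-domain comparison only")
  } else {
    for (lb in unique(lobeMap$lobe)) {
      rois <- lobeMap$roi_id[lobeMap$lobe == lb]
      a <- pCase$p_tspo[pCase$roi_id %in% rois]
      b <- pControl$p_tspo[pControl$roi_id %in% rois]
      if (length(a) && length(b))
        perLobe[[lb]] <- deltaP(a, b, binWidth = binWidth,
                                paired = paired)
    }
  }
  list(whole = whole, perLobe = perLobe)
}

#' Rat LPS analysis pipeline
#'
#' (1) Hemispheric TAC-AUC screen on the ic-LPS animals selects the
#' training ROIs (paired t-test + BH-FDR); (2) the logistic model is
#' trained on those ROIs (ipsilateral = outcome 1, contralateral = 0)
#' with the reduced rodent predictor set (TAC grid samples, K1, dose over
#' weight - no age, sex or genotype); (3) predictors are screened by Wald
#' test and the model refitted on the survivors; (4) per-ROI p_TSPO of
#' ip-LPS vs vehicle animals is compared by rank-sum + BH-FDR.
#'
#' @param phantom list from [generateRatPhantom()] (or equivalently
#'   structured real data).
#' @param window K1 fit window, minutes (default 5 for DPA-714-like
#'   kinetics).
#' @param q FDR level (default 0.05).
#' @param zThreshold Wald retention threshold (default 1.96). With a
#'   strongly separated lesion at very small n the likelihood can be so
#'   flat that no predictor passes; the single predictor whose
#'   one-feature model has the lowest deviance is then retained, keeping
#'   the final rodent model sparse.
#' @param ridge ridge penalty stabilising the near-separated rodent fit.
#' @param grid TAC sampling grid for the rodent design; the default drops
#'   the 75-minute point, which a 60-minute acquisition cannot serve.
#' @return list with `screen` (per-ROI screen table), `trainingRois`,
#'   `model`, `retained` (Wald survivors), `perRoi` (ip-LPS vs vehicle
#'   table with `p_adj` and `elevated`), and `design`.
#' @export
ratPipeline <- function(phantom, window = 5, q = 0.05, zThreshold = 1.96,
                        grid = c(1.25, 4.5, 13.5, 30, 50), ridge = 1e-2) {
  tacs <- phantom$tacs
  sub <- as.data.frame(subjectData(tacs))
  suv <- toSUV(tacs)
  sched <- schedule(tacs)
  rois <- ratRegionRoster()

  icIds <- sub$subject_id[sub$group_label == "ic-LPS"]
  if (length(icIds) < 3L) stop("need at least 3 ic-LPS animals")
  a <- activity(suv)
  rd <- as.data.frame(rowData(suv))
  aucOf <- function(ids, hemi) {
    m <- sapply(rois, function(r) {
      vapply(ids, function(s) {
        i <- which(rd$subject_id == s &
                     rd$roi_id == paste(r, hemi, sep = "_"))
        tacAuc(a[i, ], sched)
      }, numeric(1))
    })
    matrix(m, nrow = length(ids), dimnames = list(ids, rois))
  }
  screen <- hemisphericAucScreen(aucOf(icIds, "ipsi"),
                                 aucOf(icIds, "contra"), q = q)
  trainingRois <- screen$roi[screen$selected]
  if (!length(trainingRois))
    stop("hemispheric screen selected no ROIs")

  spec <- featureSpec(gridMinutes = grid,
                      covariates = c("K1", "dose_over_weight"))
  k1 <- estimateCohortK1(tacs, phantom$inputs, window = window)
  labels <- data.frame(
    roi_id = c(paste(trainingRois, "ipsi", sep = "_"),
               paste(trainingRois, "contra", sep = "_")),
    expression = rep(c(1, 0), each = length(trainingRois)),
    class_label = rep(c("high", "low"), each = length(trainingRois)))

  icTacs <- tacs[rd$subject_id %in% icIds, ]
  trDesign <- buildDesign(icTacs, k1, spec = spec, labels = labels)
  fit0 <- fitLogit(trDesign, ridge = ridge)
  retained <- waldScreen(fit0, zThreshold)
  if (!length(retained)) {
    feats <- names(fit0@zstat)[-1]
    uni <- lapply(feats, function(f) fitLogit(trDesign, f, ridge = ridge))
    devs <- vapply(uni, function(m) m@deviance, numeric(1))
    ## near-ties (within one chi-square(1) unit scale) resolved by the
    ## univariate Wald statistic
    tie <- devs - min(devs) < 2
    zuni <- vapply(uni, function(m) abs(m@zstat[2]), numeric(1))
    retained <- feats[tie][which.max(zuni[tie])]
    message("no predictor passed |z| > ", zThreshold,
            "; retaining the most informative single predictor (",
            retained, ")")
  }
  fit <- fitLogit(trDesign, retained, ridge = ridge)

  design <- buildDesign(tacs, k1, spec = spec, labels = labels,
                        bounds = attr(trDesign, "bounds"))
  p <- predictPtspo(fit, design)
  base <- sub("_(ipsi|contra)$", "", p$roi_id)
  grp <- sub$group_label[match(p$subject_id, sub$subject_id)]
  perRoi <- do.call(rbind, lapply(rois, function(r) {
    lps <- p$p_tspo[base == r & grp == "ip-LPS"]
    veh <- p$p_tspo[base == r & grp == "Vehicle"]
    ## rank on the linear predictor: identical ordering, but immune to
    ## double-precision saturation of p_tspo at 0/1
    gt <- groupTest(p$linear_predictor[base == r & grp == "ip-LPS"],
                    p$linear_predictor[base == r & grp == "Vehicle"])
    data.frame(roi = r, mean_lps = mean(lps), mean_vehicle = mean(veh),
               p = gt$p_value)
  }))
  fdr <- fdrAdjust(perRoi$p, q)
  perRoi$p_adj <- fdr$adjusted
  perRoi$elevated <- fdr$reject & perRoi$mean_lps > perRoi$mean_vehicle
  list(screen = screen, trainingRois = trainingRois, model = fit,
       retained = retained, perRoi = perRoi, design = design)
}

#' Write a run manifest
#'
#' Records the seed, package version and run parameters as JSON so that
#' deterministic runs can be reproduced bit for bit.
#'
#' @param dir output directory (created if needed).
#' @param params named list of run parameters (must include `seed`).
#' @return the manifest path, invisibly.
#' @export
writeManifest <- function(dir, params) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  stopifnot(!is.null(params$seed))
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(
    list(package = "tspoquant",
         version = as.character(utils::packageVersion("tspoquant")),
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
         params = params),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
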