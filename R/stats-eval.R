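## Evaluation battery: ROC/AUC, relative-probability histograms and
## Delta_P, Wilcoxon group tests, test-retest ICC, expression concordance,
## BH-FDR, and the rat hemispheric TAC-AUC screen.

#' ROC analysis of p_TSPO classification
#'
#' Sweeps a decision threshold over the unique scores, records sensitivity
#' and specificity at each, and integrates the curve by the trapezoidal
#' rule (which equals the Mann-Whitney concordance probability, ties
#' counted 1/2).
#'
#' @param scores numeric classifier scores (e.g. p_TSPO).
#' @param labels 0/1 (or logical) true classes, 1 = positive.
#' @return a [RocCurve-class] including the (0,1)/(1,0) endpoints.
#' @export
rocAnalysis <- function(scores, labels) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels),
            all(labels %in% c(0L, 1L)))
  if (length(unique(labels)) < 2L)
    stop("undefined-AUC error: both classes must be present")
  thr <- c(-Inf, sort(unique(scores)), Inf)
  npos <- sum(labels == 1L); nneg <- sum(labels == 0L)
  sens <- vapply(thr, function(t) sum(scores >= t & labels == 1L) / npos,
                 numeric(1))
  spec <- vapply(thr, function(t) sum(scores < t & labels == 0L) / nneg,
                 numeric(1))
  fpr <- 1 - spec
  o <- order(fpr, sens)
  a <- sum(diff(fpr[o]) * (sens[o][-1] + sens[o][-length(sens)]) / 2)
  new("RocCurve", thresholds = thr, sensitivity = sens,
      specificity = spec, auc = a)
}

#' Operating points of an ROC curve
#'
#' Reports sensitivity and specificity at a fixed probability threshold
#' (default 0.5) and at the Youden-optimal threshold
#' (max sensitivity + specificity - 1).
#'
#' @param roc a [RocCurve-class].
#' @param at numeric threshold for the fixed operating point.
#' @return data.frame with rows `fixed` and `youden`.
#' @export
rocOperatingPoints <- function(roc, at = 0.5) {
  i <- max(which(roc@thresholds <= at))
  j <- which.max(roc@sensitivity + roc@specificity - 1)
  data.frame(point = c("fixed", "youden"),
             threshold = c(at, roc@thresholds[j]),
             sensitivity = c(roc@sensitivity[i], roc@sensitivity[j]),
             specificity = c(roc@specificity[i], roc@specificity[j]))
}

#' Compare two cohorts of p_TSPO values (histograms, Delta_P, Wilcoxon)
#'
#' Bins both cohorts' per-ROI p_TSPO values into relative-probability
#' histograms on `[0, 1]`, forms the bin-by-bin deviation (case minus
#' control) and summarises it as `Delta_P`: 100 times the summed deviation
#' over the bins whose lower edge is at or above 0.5, i.e. the percent
#' excess relative probability of high p_TSPO in the case cohort. A
#' Wilcoxon test (rank-sum, or signed-rank when `paired = TRUE`) tests the
#' distributional difference.
#'
#' @param case,control numeric vectors of p_TSPO values in `[0, 1]`.
#' @param binWidth histogram bin width (default 0.05; bins must partition
#'   `[0, 1]`).
#' @param paired logical; paired cohorts use the signed-rank test and must
#'   be of equal length in matched order.
#' @return a [GroupComparison-class].
#' @export
deltaP <- function(case, control, binWidth = 0.05, paired = FALSE) {
  stopifnot(length(case) > 0L, length(control) > 0L)
  nb <- 1 / binWidth
  if (abs(nb - round(nb)) > 1e-9)
    stop("config error: bin width must partition [0, 1]")
  edges <- seq(0, 1, by = binWidth)
  if (any(case < 0 | case > 1) || any(control < 0 | control > 1))
    stop("p_TSPO values must lie in [0, 1]")
  ## bins are [edge, edge) with 1.0 folded into the last bin
  cutRel <- function(x) {
    i <- pmin(floor(x / binWidth) + 1L, length(edges) - 1L)
    tabulate(i, nbins = length(edges) - 1L) / length(x)
  }
  hA <- cutRel(case); hB <- cutRel(control)
  dev <- hA - hB
  dp <- 100 * sum(dev[edges[-length(edges)] >= 0.5 - 1e-12])
  tst <- groupTest(case, control, paired = paired)
  pooled <- sqrt(((length(case) - 1) * stats::var(case) +
                  (length(control) - 1) * stats::var(control)) /
                 (length(case) + length(control) - 2))
  d <- if (is.finite(pooled) && pooled > 0)
    (mean(case) - mean(control)) / pooled else NA_real_
  new("GroupComparison", binEdges = edges, histCase = hA,
      histControl = hB, deviation = dev, deltaP = dp,
      test = tst$test, pValue = tst$p_value, statistic = tst$statistic,
      nCase = length(case), nControl = length(control), cohensD = d)
}

#' Wilcoxon comparison of two cohorts
#'
#' Rank-sum (unpaired) or signed-rank (paired) test, two-sided; exact null
#' distribution for small samples (both groups <= 25, no ties), normal
#' approximation with tie correction otherwise.
#'
#' @param a,b numeric cohorts; paired tests require equal lengths in
#'   matched order.
#' @param paired logical.
#' @return list with `test` ("rank-sum"/"signed-rank"), `statistic`,
#'   `p_value`.
#' @export
groupTest <- function(a, b, paired = FALSE) {
  if (paired && length(a) != length(b))
    stop("paired comparison requires equal-length cohorts")
  if (length(unique(c(a, b))) == 1L)    # fully tied: no evidence either way
    return(list(test = if (paired) "signed-rank" else "rank-sum",
                statistic = NA_real_, p_value = 1))
  exact <- length(a) <= 25 && length(b) <= 25
  wt <- suppressWarnings(
    stats::wilcox.test(a, b, paired = paired, exact = exact,
                       correct = !exact))
  list(test = if (paired) "signed-rank" else "rank-sum",
       statistic = unname(wt$statistic),
       p_value = if (paired && all(a == b)) 1 else unname(wt$p.value))
}

#' Test-retest intraclass correlation (ICC(A,1))
#'
#' Two-way mixed-effects, absolute-agreement, single-measure ICC from the
#' mean squares of the subject x session table:
#' `ICC = (MSR - MSE) / (MSR + (k-1) MSE + k/n (MSC - MSE))` with k = 2
#' sessions. Zero between-subject variance makes the ICC undefined and is
#' flagged as `NA` rather than fabricated. The reported form (A,1) is
#' stated in the output.
#'
#' @param test,retest numeric vectors, matched by subject.
#' @return list with `icc`, mean squares (`msr`, `msc`, `mse`), `n`, and
#'   `form = "ICC(A,1)"`.
#' @seealso [iccByRoi()]
#' @export
iccTestRetest <- function(test, retest) {
  stopifnot(length(test) == length(retest), length(test) >= 2L)
  Y <- cbind(test, retest)
  n <- nrow(Y); k <- 2
  gm <- mean(Y)
  rm_ <- rowMeans(Y); cm <- colMeans(Y)
  ssr <- k * sum((rm_ - gm)^2)
  ssc <- n * sum((cm - gm)^2)
  sse <- sum((Y - outer(rm_, rep(1, k)) -
                outer(rep(1, n), cm) + gm)^2)
  msr <- ssr / (n - 1); msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  denom <- msr + (k - 1) * mse + k / n * (msc - mse)
  icc <- if (abs(msr) < 1e-300 || denom <= 0) NA_real_
         else (msr - mse) / denom
  if (!is.na(icc) && abs(msr - mse) < 1e-300 && msr < 1e-12)
    icc <- NA_real_   # no between-subject variance: undefined
  list(icc = icc, msr = msr, msc = msc, mse = mse, n = n,
       form = "ICC(A,1)")
}

#' Per-ROI test-retest ICC with a reliability summary
#'
#' @param test,retest data.frames with `subject_id`, `roi_id`, `p_tspo`
#'   (e.g. from [predictPtspo()]) for the test and retest sessions.
#' @param reliableAt summary cut-off (default 0.7).
#' @return list with `per_roi` (data.frame of ROI ICCs) and
#'   `fraction_reliable`, the fraction of ROIs with ICC >= `reliableAt`.
#' @export
iccByRoi <- function(test, retest, reliableAt = 0.7) {
  m <- merge(test[, c("subject_id", "roi_id", "p_tspo")],
             retest[, c("subject_id", "roi_id", "p_tspo")],
             by = c("subject_id", "roi_id"), suffixes = c("_t", "_r"))
  rois <- split(m, m$roi_id)
  per <- do.call(rbind, lapply(names(rois), function(r) {
    d <- rois[[r]]
    data.frame(roi_id = r, n = nrow(d),
               icc = iccTestRetest(d$p_tspo_t, d$p_tspo_r)$icc)
  }))
  ok <- !is.na(per$icc)
  list(per_roi = per,
       fraction_reliable = mean(per$icc[ok] >= reliableAt),
       form = "ICC(A,1)")
}

#' Concordance of mean p_TSPO with a regional expression map
#'
#' Spearman rank correlation between the across-subject mean p_TSPO per
#' ROI and the regional target-expression score, over the common ROIs
#' (cortex + cerebellum in the intended use).
#'
#' @param meanPtspo named numeric (ROI -> mean p_TSPO) or data.frame with
#'   `roi_id` and `p_tspo`.
#' @param expressionMap data.frame with `roi_id` and `expression`.
#' @param method `"spearman"` (default) or `"pearson"`.
#' @return list with `rho`, `p_value`, `n`, `method`.
#' @export
expressionConcordance <- function(meanPtspo, expressionMap,
                                  method = c("spearman", "pearson")) {
  method <- match.arg(method)
  if (is.data.frame(meanPtspo)) {
    v <- tapply(meanPtspo$p_tspo, meanPtspo$roi_id, mean)
    meanPtspo <- stats::setNames(as.numeric(v), names(v))
  }
  common <- intersect(names(meanPtspo), expressionMap$roi_id)
  if (length(common) < 5L)
    stop("insufficient-data error: need >= 5 common ROIs, have ",
         length(common))
  x <- meanPtspo[common]
  y <- expressionMap$expression[match(common, expressionMap$roi_id)]
  ct <- suppressWarnings(stats::cor.test(x, y, method = method))
  list(rho = unname(ct$estimate), p_value = ct$p.value,
       n = length(common), method = method)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values and the rejection mask at level `q`.
#'
#' @param p numeric p-values in `[0, 1]`.
#' @param q FDR level (default 0.05).
#' @return list with `adjusted` (monotone BH-adjusted p-values) and
#'   `reject` (logical mask `adjusted <= q`).
#' @export
fdrAdjust <- function(p, q = 0.05) {
  if (any(p < 0 | p > 1 | !is.finite(p)))
    stop("p-values must lie in [0, 1]")
  adj <- stats::p.adjust(p, method = "BH")
  list(adjusted = adj, reject = adj <= q)
}

#' Trapezoidal area under a TAC
#'
#' @param y per-frame values; `schedule` their [FrameSchedule-class].
#' @param schedule a [FrameSchedule-class].
#' @return numeric(1), the trapezoidal integral of `y` against frame
#'   mid-times.
#' @export
tacAuc <- function(y, schedule) {
  t <- frameMid(schedule)
  sum(diff(t) * (y[-1] + y[-length(y)]) / 2)
}

#' Hemispheric TAC-AUC screen for rat training ROIs
#'
#' For each bilateral ROI, compares the trapezoidal AUC of the SUV TACs
#' between the ipsilateral (lesioned) and contralateral hemisphere across
#' animals with a paired t-test; ROIs significant after Benjamini-Hochberg
#' FDR correction become the training classes (ipsilateral rows outcome 1,
#' contralateral rows outcome 0).
#'
#' @param aucIpsi,aucContra numeric matrices, animals x ROIs, of TAC AUCs
#'   for the two hemispheres (matching column names = ROI base names).
#' @param q FDR level (default 0.05).
#' @return data.frame per ROI: `roi`, `mean_diff`, `t`, `p`, `p_adj`,
#'   `selected`.
#' @export
hemisphericAucScreen <- function(aucIpsi, aucContra, q = 0.05) {
  aucIpsi <- as.matrix(aucIpsi); aucContra <- as.matrix(aucContra)
  stopifnot(identical(dim(aucIpsi), dim(aucContra)))
  if (nrow(aucIpsi) < 3L)
    stop("need at least 3 animals for the paired hemispheric screen")
  rois <- colnames(aucIpsi)
  if (is.null(rois)) rois <- paste0("roi", seq_len(ncol(aucIpsi)))
  res <- do.call(rbind, lapply(seq_along(rois), function(j) {
    tt <- stats::t.test(aucIpsi[, j], aucContra[, j], paired = TRUE)
    data.frame(roi = rois[j],
               mean_diff = mean(aucIpsi[, j] - aucContra[, j]),
               t = unname(tt$statistic), p = tt$p.value)
  }))
  fdr <- fdrAdjust(res$p, q)
  res$p_adj <- fdr$adjusted
  res$selected <- fdr$reject
  res
}
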