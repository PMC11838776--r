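## Bootstrap-stabilised stepwise feature selection by model deviance.

#' Stepwise feature selection by deviance
#'
#' Bidirectional stepwise selection starting from the intercept-only model:
#' at each step the candidate whose entry drops the deviance most is added
#' if its chi-squared(1) p-value is below `pEnter`, and the included feature
#' whose removal costs least is dropped if its p-value exceeds `pRemove`.
#' Steps that make the design non-identifiable (collinear duplicates,
#' separation) are skipped and recorded in the `"log"` attribute. The
#' procedure is deterministic given the design.
#'
#' @param design data.frame from [buildDesign()] with labelled rows.
#' @param scope character, candidate features; defaults to the active
#'   features of the attached [FeatureSpec-class].
#' @param pEnter,pRemove chi-squared(1) entry/removal p-value thresholds
#'   (defaults 0.05 / 0.10).
#' @param direction `"both"` (default) or `"forward"`.
#' @param maxSteps safety cap on the number of steps.
#' @return character vector of selected features (possibly empty), with a
#'   `"log"` attribute of skipped-step messages.
#' @seealso [bootstrapSelection()]
#' @export
stepwiseDeviance <- function(design, scope = NULL, pEnter = 0.05,
                             pRemove = 0.10,
                             direction = c("both", "forward"),
                             maxSteps = 50L) {
  direction <- match.arg(direction)
  scope <- .designFeatures(design, scope)
  rows <- !is.na(design$outcome)
  if (length(unique(design$outcome[rows])) < 2L)
    stop("design must contain both outcome classes")
  log <- character(0)
  devOf <- function(feats) {
    if (!length(feats)) {
      y <- design$outcome[rows]
      return(.binDeviance(y, rep(mean(y), length(y))))
    }
    tryCatch(fitLogit(design, feats)@deviance, error = function(e) NA_real_)
  }
  cur <- character(0)
  curDev <- devOf(cur)
  for (step in seq_len(maxSteps)) {
    changed <- FALSE
    cand <- setdiff(scope, cur)
    if (length(cand)) {
      devs <- vapply(cand, function(f) devOf(c(cur, f)), numeric(1))
      bad <- is.na(devs)
      if (any(bad)) {
        log <- c(log, paste0("step ", step, ": skipped non-identifiable ",
                             "candidate(s) ",
                             paste(cand[bad], collapse = ", ")))
        devs <- devs[!bad]; cand <- cand[!bad]
      }
      if (length(cand)) {
        pvals <- stats::pchisq(pmax(curDev - devs, 0), df = 1,
                               lower.tail = FALSE)
        best <- which.min(pvals)
        if (pvals[best] < pEnter) {
          cur <- c(cur, cand[best])
          curDev <- devs[best]
          changed <- TRUE
        }
      }
    }
    if (direction == "both" && length(cur) > 1L) {
      devs <- vapply(cur, function(f) devOf(setdiff(cur, f)), numeric(1))
      ok <- !is.na(devs)
      if (any(ok)) {
        pvals <- stats::pchisq(pmax(devs[ok] - curDev, 0), df = 1,
                               lower.tail = FALSE)
        worst <- which.max(pvals)
        if (pvals[worst] > pRemove) {
          drop <- cur[ok][worst]
          cur <- setdiff(cur, drop)
          curDev <- devs[ok][worst]
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  attr(cur, "log") <- log
  cur
}

#' Bootstrap-stabilised stepwise selection
#'
#' Repeats [stepwiseDeviance()] on subject-level bootstrap resamples (all
#' rows of a resampled subject move together, since a subject's ROIs share
#' covariates) and tallies how often each feature is selected. Features are
#' retained when their selection frequency is strictly above the threshold
#' (a frequency of exactly 0.80 at the default threshold is not retained).
#' Resamples containing a single outcome class are skipped and counted; a
#' warning is raised if more than 10% are skipped.
#'
#' @inheritParams stepwiseDeviance
#' @param nIter number of bootstrap iterations (default 100).
#' @param freqThreshold retention threshold on the selection frequency
#'   (default 0.80, strict inequality).
#' @param seed integer seed controlling the resampling.
#' @param ... passed to [stepwiseDeviance()].
#' @return a [SelectionReport-class].
#' @export
bootstrapSelection <- function(design, scope = NULL, nIter = 100L,
                               freqThreshold = 0.80, seed = 1L, ...) {
  stopifnot(nIter >= 1L)
  scope <- .designFeatures(design, scope)
  subj <- unique(design$subject_id)
  bySubj <- split(seq_len(nrow(design)), design$subject_id)
  counts <- stats::setNames(numeric(length(scope)), scope)
  done <- 0L; skipped <- 0L
  oldseed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(oldseed))
    assign(".Random.seed", oldseed, globalenv()))
  set.seed(seed)
  for (it in seq_len(nIter)) {
    take <- sample(subj, length(subj), replace = TRUE)
    idx <- unlist(bySubj[take], use.names = FALSE)
    res <- design[idx, , drop = FALSE]
    attr(res, "spec") <- attr(design, "spec")
    y <- res$outcome[!is.na(res$outcome)]
    if (length(unique(y)) < 2L) {
      skipped <- skipped + 1L
      next
    }
    sel <- stepwiseDeviance(res, scope = scope, ...)
    counts[sel] <- counts[sel] + 1
    done <- done + 1L
  }
  if (skipped > 0.1 * nIter)
    warning(skipped, " of ", nIter,
            " resamples skipped (single outcome class)")
  if (done == 0L) stop("all bootstrap resamples were skipped")
  freq <- counts / done
  new("SelectionReport", frequency = freq,
      retained = names(freq)[freq > freqThreshold],
      nIterations = as.integer(nIter), threshold = freqThreshold,
      seed = as.integer(seed), nSkipped = as.integer(skipped))
}

#' Export a selection report
#'
#' Writes the per-feature selection frequencies as CSV and the full report
#' (frequencies, retained set, iteration count, threshold, seed) as JSON.
#'
#' @param report a [SelectionReport-class].
#' @param csvPath,jsonPath output paths (either may be `NULL`).
#' @return invisibly, the report.
#' @export
writeSelectionReport <- function(report, csvPath = NULL, jsonPath = NULL) {
  if (!is.null(csvPath))
    utils::write.csv(data.frame(feature = names(report@frequency),
                                frequency = report@frequency),
                     csvPath, row.names = FALSE)
  if (!is.null(jsonPath))
    jsonlite::write_json(list(frequency = as.list(report@frequency),
                              retained = report@retained,
                              n_iterations = report@nIterations,
                              threshold = report@threshold,
                              seed = report@seed,
                              n_skipped = report@nSkipped),
                         jsonPath, auto_unbox = TRUE, digits = NA)
  invisible(report)
}
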