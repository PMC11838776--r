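#' Construct a TacExperiment
#'
#' @param activity numeric matrix of activity concentrations (kBq/mL), one
#'   row per (subject, ROI) trace, one column per frame.
#' @param schedule a [FrameSchedule-class] whose length matches
#'   `ncol(activity)`.
#' @param subjectId,roiId character vectors, one entry per row of `activity`.
#' @param subjects optional per-subject covariate table (data.frame or
#'   DataFrame) with columns `subject_id`, `age` (years), `sex`
#'   ("male"/"female"), `genotype` ("HAB"/"MAB"), `injected_dose` (MBq),
#'   `weight` (kg), `dataset_id`, and optionally `group_label`.
#' @param units character(1), recorded unit of the activity values.
#' @return a [TacExperiment-class].
#' @examples
#' fs <- FrameSchedule(duration = rep(1, 4))
#' te <- TacExperiment(matrix(1:8, 2, 4), fs,
#'                     subjectId = c("s1", "s1"), roiId = c("roiA", "roiB"))
#' activity(te)
#' @export
TacExperiment <- function(activity, schedule, subjectId, roiId,
                          subjects = S4Vectors::DataFrame(),
                          units = "kBq/mL") {
  activity <- as.matrix(activity)
  stopifnot(is(schedule, "FrameSchedule"))
  if (ncol(activity) != nFrames(schedule))
    stop("activity has ", ncol(activity), " frames but the schedule has ",
         nFrames(schedule))
  if (length(subjectId) != nrow(activity) || length(roiId) != nrow(activity))
    stop("subjectId/roiId must match the number of activity rows")
  cd <- S4Vectors::DataFrame(frameStart = frameStart(schedule),
                             frameDuration = frameDuration(schedule),
                             frameMid = frameMid(schedule))
  rd <- S4Vectors::DataFrame(subject_id = as.character(subjectId),
                             roi_id = as.character(roiId))
  dimnames(activity) <- list(paste(rd$subject_id, rd$roi_id, sep = "."),
                             paste0("frame", seq_len(ncol(activity))))
  se <- SummarizedExperiment(assays = list(activity = activity),
                             rowData = rd, colData = cd)
  if (is.data.frame(subjects)) subjects <- S4Vectors::DataFrame(subjects)
  out <- new("TacExperiment", se, subjects = subjects)
  metadata(out)$units <- units
  out
}

.checkSubjects <- function(sub) {
  need <- c("subject_id", "age", "sex", "genotype", "injected_dose",
            "weight", "dataset_id")
  miss <- setdiff(need, colnames(sub))
  if (length(miss))
    stop("subject table lacks column(s): ", paste(miss, collapse = ", "))
  if (any(sub$age <= 0)) stop("age must be > 0")
  if (any(sub$injected_dose <= 0)) stop("injected_dose must be > 0 (MBq)")
  if (any(sub$weight <= 0)) stop("weight must be > 0 (kg)")
  if (!all(sub$sex %in% c("male", "female")))
    stop("sex must be 'male' or 'female'")
  if (!all(sub$genotype %in% c("HAB", "MAB")))
    stop("genotype must be 'HAB' or 'MAB' (set PK11195-style scans to HAB)")
  invisible(sub)
}

#' Read and write regional TAC tables
#'
#' The canonical on-disk dialect is long format: a delimited file with
#' columns `subject_id, roi_id, frame_index, activity` (frame_index 1-based,
#' activity in kBq/mL) plus a schedule supplied separately. A wide layout
#' (`subject_id, roi_id, frame1..frameN`) is accepted as a convenience.
#'
#' @param path delimited text file (comma or tab separated by extension).
#' @param schedule a [FrameSchedule-class] declaring the frame grid.
#' @param subjects optional subject covariate table (see [TacExperiment()]).
#' @return `readTacTable` returns a [TacExperiment-class]; `writeTacTable`
#'   writes long format with full double precision and returns `path`
#'   invisibly, so a write/read round-trip reproduces activities bit-exactly.
#' @export
readTacTable <- function(path, schedule, subjects = S4Vectors::DataFrame()) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  d <- utils::read.table(path, header = TRUE, sep = sep,
                         stringsAsFactors = FALSE)
  nf <- nFrames(schedule)
  if (all(c("subject_id", "roi_id", "frame_index", "activity") %in% names(d))) {
    key <- interaction(d$subject_id, d$roi_id, drop = TRUE, sep = "\r")
    split_idx <- split(seq_len(nrow(d)), key)
    rows <- lapply(split_idx, function(i) {
      di <- d[i, ]
      if (nrow(di) != nf || !setequal(di$frame_index, seq_len(nf)))
        stop("TAC table format error: (", di$subject_id[1], ", ",
             di$roi_id[1], ") has ", nrow(di), " frames, expected ", nf)
      di$activity[order(di$frame_index)]
    })
    act <- do.call(rbind, rows)
    ids <- do.call(rbind, strsplit(names(split_idx), "\r", fixed = TRUE))
    return(TacExperiment(act, schedule, subjectId = ids[, 1],
                         roiId = ids[, 2], subjects = subjects))
  }
  fcols <- grep("^frame[0-9]+$", names(d), value = TRUE)
  if (!all(c("subject_id", "roi_id") %in% names(d)) || !length(fcols))
    stop("TAC table format error: need long columns (subject_id, roi_id, ",
         "frame_index, activity) or wide columns frame1..frameN")
  fcols <- fcols[order(as.integer(sub("frame", "", fcols)))]
  if (length(fcols) != nf)
    stop("TAC table format error: ", length(fcols),
         " frame columns, expected ", nf)
  TacExperiment(as.matrix(d[, fcols]), schedule,
                subjectId = d$subject_id, roiId = d$roi_id,
                subjects = subjects)
}

#' @rdname readTacTable
#' @param x a [TacExperiment-class] to write.
#' @export
writeTacTable <- function(x, path) {
  stopifnot(is(x, "TacExperiment"))
  a <- activity(x)
  rd <- rowData(x)
  long <- data.frame(
    subject_id = rep(rd$subject_id, each = ncol(a)),
    roi_id = rep(rd$roi_id, each = ncol(a)),
    frame_index = rep(seq_len(ncol(a)), times = nrow(a)),
    activity = sprintf("%.17g", as.vector(t(a))))
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  utils::write.table(long, path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read subject covariates or a regional expression map
#'
#' `readSubjectTable` reads a CSV of per-subject covariates (columns
#' `subject_id, age, sex, genotype, injected_dose, weight, dataset_id`, and
#' optionally `group_label`) and validates ranges and factor levels.
#' `readExpressionMap` reads a CSV with columns `roi_id, expression,
#' class_label` where `class_label` is `low`, `high` or `unlabelled`; the
#' low/high rows define the training classes of the logistic model.
#'
#' @param path CSV file path.
#' @return `readSubjectTable`: a [S4Vectors::DataFrame]; `readExpressionMap`:
#'   a data.frame.
#' @export
readSubjectTable <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  .checkSubjects(d)
  S4Vectors::DataFrame(d)
}

#' @rdname readSubjectTable
#' @export
readExpressionMap <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("roi_id", "expression", "class_label") %in% names(d)))
    stop("expression map needs columns roi_id, expression, class_label")
  if (!all(d$class_label %in% c("low", "high", "unlabelled")))
    stop("class_label must be low, high or unlabelled")
  if (any(!is.finite(d$expression))) stop("expression scores must be finite")
  d
}

#' @rdname readSubjectTable
#' @param x the expression-map data.frame to write.
#' @export
writeExpressionMap <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' Extract mean regional TACs from a 4D image and a label atlas
#'
#' For every atlas label > 0, averages the dynamic image over the voxels
#' carrying that label and (optionally) lying inside a grey-matter mask,
#' yielding one mean TAC per ROI. Labels whose voxel set is emptied by the
#' mask are excluded with a warning and listed in
#' `metadata(result)$excluded_rois`, never silently dropped.
#'
#' @param image4d 4D numeric array (x, y, z, frame) or path to a 4D NIfTI.
#' @param atlas 3D integer array or NIfTI path; label 0 is background.
#' @param mask optional 3D binary array or NIfTI path on the same grid.
#' @param schedule a [FrameSchedule-class] matching the 4th dimension.
#' @param subjectId character(1) recorded in the result.
#' @param roiNames optional named translation `c("1" = "roiA", ...)` from
#'   label values to ROI identifiers; defaults to `"roi<label>"`.
#' @return a [TacExperiment-class] with one row per surviving ROI.
#' @export
extractRoiTacs <- function(image4d, atlas, mask = NULL, schedule,
                           subjectId = "subject", roiNames = NULL) {
  if (is.character(image4d)) image4d <- RNifti::readNifti(image4d)
  if (is.character(atlas)) atlas <- RNifti::readNifti(atlas)
  if (!is.null(mask) && is.character(mask)) mask <- RNifti::readNifti(mask)
  image4d <- unclass(image4d); atlas <- unclass(atlas)
  if (length(dim(image4d)) != 4L)
    stop("dimension error: image4d must be 4D")
  if (!identical(dim(image4d)[1:3], dim(atlas)[1:3]))
    stop("dimension error: atlas grid does not match image grid")
  nf <- dim(image4d)[4]
  if (nf != nFrames(schedule))
    stop("dimension error: image has ", nf, " frames, schedule has ",
         nFrames(schedule))
  keep <- if (is.null(mask)) TRUE else (unclass(mask) != 0)
  if (!isTRUE(keep) && !identical(dim(atlas)[1:3], dim(keep)[1:3]))
    stop("dimension error: mask grid does not match image grid")
  labels <- sort(unique(as.integer(atlas[atlas > 0])))
  if (!length(labels)) stop("atlas contains no labels > 0")
  flat <- matrix(image4d, ncol = nf)  # voxels x frames
  tacs <- list(); excluded <- character(0)
  for (lab in labels) {
    roi <- if (is.null(roiNames)) paste0("roi", lab)
           else roiNames[[as.character(lab)]]
    vox <- which((atlas == lab) & keep)
    if (!length(vox)) {
      warning("ROI '", roi, "' has no voxels inside the mask; excluded")
      excluded <- c(excluded, roi)
      next
    }
    tacs[[roi]] <- colMeans(flat[vox, , drop = FALSE])
  }
  if (!length(tacs))
    stop("all ROIs were emptied by the mask")
  out <- TacExperiment(do.call(rbind, tacs), schedule,
                       subjectId = rep(subjectId, length(tacs)),
                       roiId = names(tacs))
  metadata(out)$excluded_rois <- excluded
  out
}
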