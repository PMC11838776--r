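#' Construct a frame schedule
#'
#' @param start numeric, frame start times (minutes). If missing, frames are
#'   assumed contiguous from `origin`.
#' @param duration numeric, frame durations (minutes).
#' @param origin numeric(1), start of the first frame when `start` is
#'   derived from durations (default 0).
#' @return a [FrameSchedule-class] object.
#' @examples
#' FrameSchedule(duration = c(rep(0.25, 8), rep(1, 3)))
#' @export
FrameSchedule <- function(start, duration, origin = 0) {
  if (missing(start))
    start <- origin + cumsum(c(0, duration[-length(duration)]))
  new("FrameSchedule", start = as.numeric(start),
      duration = as.numeric(duration))
}

#' Standard dynamic acquisition schedules
#'
#' `pbr28Schedule()` is the 90-minute, 26-frame binning used for full-length
#' scans (8x15s, 3x1min, 5x2min, 5x5min, 5x10min). `pbr28ShortSchedule()` is
#' the 60-minute, 23-frame variant (8x15s, 3x1min, 5x2min, 5x5min, 2x10min)
#' used for shorter clinical acquisitions.
#'
#' @return a [FrameSchedule-class].
#' @examples
#' scanEnd(pbr28Schedule())      # 90
#' scanEnd(pbr28ShortSchedule()) # 60
#' @export
pbr28Schedule <- function() {
  FrameSchedule(duration = c(rep(0.25, 8), rep(1, 3), rep(2, 5),
                             rep(5, 5), rep(10, 5)))
}

#' @rdname pbr28Schedule
#' @export
pbr28ShortSchedule <- function() {
  FrameSchedule(duration = c(rep(0.25, 8), rep(1, 3), rep(2, 5),
                             rep(5, 5), rep(10, 2)))
}

#' Read / write a frame schedule
#'
#' Schedules are stored either as a two-column CSV (`start,duration`, in
#' minutes) or as a YAML file with `start` and `duration` sequences (or just
#' `duration` for contiguous frames).
#'
#' @param path file path (`.csv`, `.yaml` or `.yml`).
#' @param x a [FrameSchedule-class] (for writing).
#' @return `readSchedule` returns a [FrameSchedule-class]; `writeSchedule`
#'   returns `path` invisibly.
#' @export
readSchedule <- function(path) {
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    y <- yaml::read_yaml(path)
    if (is.null(y$duration)) stop("schedule YAML lacks 'duration'")
    if (is.null(y$start)) return(FrameSchedule(duration = y$duration))
    return(FrameSchedule(start = y$start, duration = y$duration))
  }
  d <- utils::read.csv(path)
  if (!all(c("start", "duration") %in% names(d)))
    stop("schedule CSV must have columns 'start' and 'duration'")
  FrameSchedule(start = d$start, duration = d$duration)
}

#' @rdname readSchedule
#' @export
writeSchedule <- function(x, path) {
  stopifnot(is(x, "FrameSchedule"))
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::write_yaml(list(start = frameStart(x),
                          duration = frameDuration(x)), path)
  } else {
    utils::write.csv(data.frame(start = frameStart(x),
                                duration = frameDuration(x)),
                     path, row.names = FALSE)
  }
  invisible(path)
}
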