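#' Frame schedule for a dynamic PET acquisition
#'
#' A frame schedule records, per reconstructed frame, its start time and
#' duration in minutes from tracer injection (t = 0). The frame mid-time,
#' `start + duration / 2`, is derived and used throughout the package as the
#' nominal sampling time of each frame.
#'
#' @param start numeric vector of frame start times (minutes).
#' @param duration numeric vector of frame durations (minutes), same length.
#' @return A `frame_schedule` object: a data frame with columns `start`,
#'   `duration` and `mid` (all minutes).
#' @details Frames must be strictly ordered and non-overlapping:
#'   `start[i+1] >= start[i] + duration[i]` (to within 1e-9 min). Durations
#'   must be positive.
#' @examples
#' sch <- frame_schedule_fdopa()
#' nrow(sch)                      # 32 frames
#' sum(sch$duration)              # 95 minutes
#' @export
frame_schedule <- function(start, duration) {
  start <- as.numeric(start)
  duration <- as.numeric(duration)
  if (length(start) != length(duration))
    stop("'start' and 'duration' must have the same length", call. = FALSE)
  if (length(start) < 1L)
    stop("a frame schedule needs at least one frame", call. = FALSE)
  if (!all(is.finite(start)) || !all(is.finite(duration)))
    stop("frame times must be finite", call. = FALSE)
  if (any(duration <= 0))
    stop("frame durations must be positive", call. = FALSE)
  if (length(start) > 1L) {
    if (any(diff(start) <= 0))
      stop("frame start times must be strictly increasing", call. = FALSE)
    gap <- start[-1L] - (start[-length(start)] + duration[-length(duration)])
    if (any(gap < -1e-9))
      stop("frames overlap: start[i+1] must be >= start[i] + duration[i]",
           call. = FALSE)
  }
  out <- data.frame(start = start, duration = duration,
                    mid = start + duration / 2)
  class(out) <- c("frame_schedule", "data.frame")
  out
}

#' @rdname frame_schedule
#' @param durations_sec frame durations in seconds, assembled into a
#'   contiguous schedule starting at injection.
#' @export
frame_schedule_from_durations <- function(durations_sec) {
  d <- as.numeric(durations_sec) / 60
  frame_schedule(start = cumsum(c(0, d[-length(d)])), duration = d)
}

#' Default 32-frame bolus FDOPA schedule
#'
#' The 95-minute dynamic framing used for bolus FDOPA acquisitions:
#' 8 x 15 s, 3 x 60 s, 5 x 120 s, 16 x 300 s.
#' @export
frame_schedule_fdopa <- function() {
  frame_schedule_from_durations(c(rep(15, 8), rep(60, 3), rep(120, 5),
                                  rep(300, 16)))
}

#' @export
print.frame_schedule <- function(x, ...) {
  cat(sprintf("Frame schedule: %d frames, %.2f min total (%.2f-%.2f min)\n",
              nrow(x), sum(x$duration), x$start[1],
              x$start[nrow(x)] + x$duration[nrow(x)]))
  invisible(x)
}

#' Total scan duration of a schedule, in minutes
#' @param schedule a [frame_schedule()].
#' @export
scan_duration <- function(schedule) {
  n <- nrow(schedule)
  schedule$start[n] + schedule$duration[n] - schedule$start[1]
}
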