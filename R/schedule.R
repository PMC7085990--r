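#' Frame schedule of a dynamic PET acquisition
#'
#' Defines the timing of a dynamic acquisition as frame start times and
#' durations, both in minutes. Frames must be ascending and non-overlapping
#' (gaps are allowed); mid- and end-times are derived.
#'
#' @param start numeric vector of frame start times (minutes), ascending.
#' @param duration numeric vector of frame durations (minutes), all positive.
#' @return An object of class `frame_schedule`: a list with elements
#'   `start`, `duration`, `mid`, `end` (all minutes) and `n` (frame count).
#' @examples
#' fs <- frame_schedule(c(0, 1, 2), c(1, 1, 1))
#' fs$mid
#' @export
frame_schedule <- function(start, duration) {
  start <- as.numeric(start)
  duration <- as.numeric(duration)
  if (length(start) != length(duration) || length(start) == 0L)
    stop("start and duration must be non-empty vectors of equal length")
  if (any(!is.finite(start)) || any(!is.finite(duration)))
    stop("frame times must be finite")
  if (any(duration <= 0)) stop("all frame durations must be positive")
  if (is.unsorted(start, strictly = TRUE)) stop("start times must be strictly ascending")
  end <- start + duration
  if (any(end[-length(end)] > start[-1] + 1e-9))
    stop("frames overlap: end time exceeds the next start time")
  structure(
    list(start = start, duration = duration, mid = start + duration / 2,
         end = end, n = length(start)),
    class = "frame_schedule"
  )
}

#' Standard 45-minute abdominal dynamic framing
#'
#' The 22-frame schedule 6 x 10 s, 3 x 20 s, 3 x 60 s, 5 x 180 s, 5 x 300 s,
#' spanning 45 minutes from injection.
#'
#' @return A [frame_schedule()] with 22 frames covering 0-45 min.
#' @examples
#' fs <- dynamic_schedule_45min()
#' fs$n                # 22
#' fs$end[fs$n]        # 45
#' @export
dynamic_schedule_45min <- function() {
  dur_s <- c(rep(10, 6), rep(20, 3), rep(60, 3), rep(180, 5), rep(300, 5))
  start_s <- cumsum(c(0, dur_s[-length(dur_s)]))
  frame_schedule(start_s / 60, dur_s / 60)
}

#' @export
print.frame_schedule <- function(x, ...) {
  cat(sprintf("Frame schedule: %d frames, %.3g-%.3g min (span %.3g min)\n",
              x$n, x$start[1], x$end[x$n], x$end[x$n] - x$start[1]))
  invisible(x)
}

#' Total scan span of a frame schedule, in minutes
#' @param schedule a [frame_schedule()].
#' @return Last frame end minus first frame start (minutes).
#' @export
schedule_span <- function(schedule) {
  stopifnot(inherits(schedule, "frame_schedule"))
  schedule$end[schedule$n] - schedule$start[1]
}
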