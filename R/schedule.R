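#' PET frame schedule
#'
#' A frame schedule records the start and end time of every acquisition frame
#' of a dynamic PET scan, in minutes post-injection. Frames follow the
#' half-open convention `[start, end)`: they must be sorted, non-overlapping
#' and of positive duration. All kinetic computations in this package use the
#' frame mid-times.
#'
#' @param start numeric vector of frame start times (minutes).
#' @param end numeric vector of frame end times (minutes), same length.
#' @return An object of class `frame_schedule`: a list with elements
#'   `start`, `end`, `mid` (frame mid-times) and `dur` (frame durations).
#' @examples
#' fs <- frame_schedule(c(0, 1, 2), c(1, 2, 4))
#' mid_times(fs)
#' @export
frame_schedule <- function(start, end) {
  start <- as.numeric(start)
  end <- as.numeric(end)
  if (length(start) != length(end))
    stop("frame start and end vectors must have equal length")
  if (length(start) < 2L)
    stop("a frame schedule needs at least 2 frames")
  if (anyNA(start) || anyNA(end) || any(!is.finite(c(start, end))))
    stop("frame times must be finite")
  if (any(end <= start))
    stop("every frame must have end > start")
  if (is.unsorted(start, strictly = TRUE))
    stop("frames must be sorted by start time")
  if (any(start[-1L] < end[-length(end)] - 1e-9))
    stop("frames must not overlap")
  mid <- (start + end) / 2
  if (is.unsorted(mid, strictly = TRUE))
    stop("frame mid-times must be strictly increasing")
  structure(list(start = start, end = end, mid = mid, dur = end - start),
            class = "frame_schedule")
}

#' @rdname frame_schedule
#' @param x a `frame_schedule`.
#' @export
mid_times <- function(x) {
  stopifnot(inherits(x, "frame_schedule"))
  x$mid
}

#' @rdname frame_schedule
#' @export
frame_durations <- function(x) {
  stopifnot(inherits(x, "frame_schedule"))
  x$dur
}

#' @rdname frame_schedule
#' @export
n_frames <- function(x) {
  stopifnot(inherits(x, "frame_schedule"))
  length(x$start)
}

#' @export
print.frame_schedule <- function(x, ...) {
  cat(sprintf("<frame_schedule> %d frames, %.1f-%.1f min\n",
              n_frames(x), x$start[1L], x$end[length(x$end)]))
  invisible(x)
}

#' @export
format.frame_schedule <- function(x, ...) {
  sprintf("%d frames over [%.3g, %.3g] min", n_frames(x),
          x$start[1L], x$end[length(x$end)])
}

same_schedule <- function(a, b, tol = 1e-9) {
  n_frames(a) == n_frames(b) &&
    max(abs(a$start - b$start), abs(a$end - b$end)) <= tol
}

#' Default 90-minute mouse frame schedule
#'
#' The default dynamic framing used by the simulator: 6 x 0.5 min,
#' 3 x 1 min, 2 x 2 min, then 16 x 5 min, totalling 90 min. The uniform
#' 5-min late frames cover the 40-70, 50-80 and 60-90 min static windows
#' exactly.
#'
#' @return A [frame_schedule] with 27 frames spanning 0-90 min.
#' @export
default_schedule <- function() {
  dur <- c(rep(0.5, 6), rep(1, 3), rep(2, 2), rep(5, 16))
  end <- cumsum(dur)
  frame_schedule(c(0, end[-length(end)]), end)
}
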