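#' PET frame schedule
#'
#' A `time_grid` holds the frame timing shared by every time-activity curve
#' (TAC) in an analysis: frame start times, frame durations and the derived
#' frame mid-times, all in minutes. Frames must be non-overlapping and sorted;
#' gaps are permitted (e.g. interrupted acquisitions).
#'
#' @param frame_start numeric vector of frame start times (minutes, >= 0,
#'   strictly increasing).
#' @param frame_duration numeric vector of frame durations (minutes, > 0),
#'   same length as `frame_start`.
#' @return An object of class `time_grid`: a list with `frame_start`,
#'   `frame_duration` and `mid_time` (minutes).
#' @examples
#' g <- time_grid(c(0, 1, 2), c(1, 1, 2))
#' g$mid_time
#' @export
time_grid <- function(frame_start, frame_duration) {
  frame_start <- as.numeric(frame_start)
  frame_duration <- as.numeric(frame_duration)
  if (length(frame_start) != length(frame_duration))
    stop("frame_start and frame_duration must have equal length")
  if (length(frame_start) == 0L) stop("empty frame schedule")
  if (anyNA(frame_start) || anyNA(frame_duration) ||
      !all(is.finite(frame_start)) || !all(is.finite(frame_duration)))
    stop("frame times must be finite")
  if (any(frame_start < 0)) stop("frame_start must be non-negative")
  if (any(frame_duration <= 0)) stop("frame_duration must be positive")
  if (is.unsorted(frame_start, strictly = TRUE))
    stop("frame_start must be strictly increasing")
  ends <- frame_start + frame_duration
  if (length(frame_start) > 1L) {
    overlap <- which(frame_start[-1L] < ends[-length(ends)] - 1e-9)
    if (length(overlap))
      stop("overlapping frames at index ", overlap[1L] + 1L)
  }
  structure(list(frame_start = frame_start,
                 frame_duration = frame_duration,
                 mid_time = frame_start + frame_duration / 2),
            class = "time_grid")
}

#' @export
length.time_grid <- function(x) length(x$frame_start)

#' @export
print.time_grid <- function(x, ...) {
  cat(sprintf("<time_grid> %d frames, %.3g-%.3g min (total %.3g min scanned)\n",
              length(x), x$frame_start[1L],
              x$frame_start[length(x)] + x$frame_duration[length(x)],
              sum(x$frame_duration)))
  invisible(x)
}

#' Clinical 50-frame, 60-minute human FDG schedule
#'
#' The frame schedule used throughout the human examples and the built-in
#' simulation study: 15 x 2 s, 6 x 5 s, 8 x 15 s, 4 x 30 s, 5 x 60 s,
#' 3 x 120 s, 8 x 300 s and 1 x 240 s (50 frames, 60 min).
#'
#' @return A [time_grid].
#' @export
human_frame_grid <- function() {
  dur_s <- c(rep(2, 15), rep(5, 6), rep(15, 8), rep(30, 4),
             rep(60, 5), rep(120, 3), rep(300, 8), 240)
  start_s <- cumsum(c(0, dur_s[-length(dur_s)]))
  time_grid(start_s / 60, dur_s / 60)
}

#' Uniform fine grid
#'
#' Convenience constructor for dense simulation grids (e.g. `dt = 0.01` min).
#'
#' @param t_end end of the grid, minutes.
#' @param dt frame width, minutes.
#' @return A [time_grid] with contiguous frames of width `dt`.
#' @export
uniform_grid <- function(t_end, dt) {
  n <- floor(t_end / dt + 1e-9)
  time_grid(seq(0, by = dt, length.out = n), rep(dt, n))
}

#' Time-activity curve
#'
#' A `tac` pairs a [time_grid] with one activity-concentration value per frame
#' (kBq/mL, or arbitrary units for simulations) and a free-text label.
#'
#' @param grid a [time_grid].
#' @param values numeric vector, one value per frame; must be finite; the
#'   first-frame value must be >= 0.
#' @param label character label (e.g. `"WB"`, `"cluster-3"`).
#' @return An object of class `tac`.
#' @export
tac <- function(grid, values, label = "") {
  stopifnot(inherits(grid, "time_grid"))
  values <- as.numeric(values)
  if (length(values) != length(grid))
    stop("values length (", length(values), ") does not match grid (",
         length(grid), ")")
  if (!all(is.finite(values))) stop("TAC values must be finite")
  if (values[1L] < 0) stop("first-frame value must be non-negative")
  structure(list(grid = grid, values = values, label = as.character(label)[1L]),
            class = "tac")
}

#' @export
print.tac <- function(x, ...) {
  cat(sprintf("<tac> '%s': %d frames, peak %.4g at %.3g min\n",
              x$label, length(x$grid), max(x$values),
              x$grid$mid_time[which.max(x$values)]))
  invisible(x)
}

same_grid <- function(a, b, tol = 1e-9) {
  length(a) == length(b) &&
    max(abs(a$mid_time - b$mid_time)) < tol &&
    max(abs(a$frame_duration - b$frame_duration)) < tol
}

stop_if_grid_mismatch <- function(...) {
  tl <- list(...)
  g <- tl[[1L]]$grid
  for (x in tl[-1L]) if (!same_grid(g, x$grid))
    stop("TACs must share one time grid")
  invisible(g)
}

#' Interpolate a TAC at arbitrary times
#'
#' Linear interpolation between frame mid-times, with the curve pinned to
#' zero at t = 0 (no tracer before injection) and held constant beyond the
#' last mid-time.
#'
#' @param x a [tac].
#' @param t times in minutes.
#' @return numeric vector of interpolated values.
#' @export
interp_tac <- function(x, t) {
  stopifnot(inherits(x, "tac"))
  tm <- x$grid$mid_time
  v <- x$values
  if (tm[1L] > 0) { tm <- c(0, tm); v <- c(0, v) }
  stats::approx(tm, v, xout = t, rule = 2)$y
}
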