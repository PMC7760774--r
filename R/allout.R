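#' Mean speed over a time window of a speed trace
#'
#' Computes the arithmetic mean of the 1-Hz samples with
#' `window_start <= t < window_end` (half-open window, so the 30-s end-test
#' window `[150, 180)` contains exactly 30 samples).
#'
#' @param trace data frame with columns `time_s` (seconds, 1 Hz) and
#'   `speed_mps` (m/s)
#' @param window_start,window_end window bounds in seconds
#' @return mean speed in m/s
#' @export
mean_speed <- function(trace, window_start, window_end) {
  trace <- validate_trace(trace)
  stopifnot_scalar(window_start, "window_start")
  stopifnot_scalar(window_end, "window_end")
  if (window_end <= window_start)
    stop("window_end must be greater than window_start", call. = FALSE)
  rng <- range(trace$time_s)
  if (window_start < rng[1] || window_end > rng[2] + 1) {
    stop(sprintf(
      "window [%g, %g) extends outside the trace extent [%g, %g]",
      window_start, window_end, rng[1], rng[2]), call. = FALSE)
  }
  sel <- trace$time_s >= window_start & trace$time_s < window_end
  if (!any(sel))
    stop(sprintf("no samples in window [%g, %g)", window_start, window_end),
         call. = FALSE)
  mean(trace$speed_mps[sel])
}

#' Extract S150s, critical speed and D' from a 3-minute all-out trace
#'
#' The end-test (critical) speed is the mean speed over the final 30 s,
#' `[150, 180)`; S150s is the mean over the first 150 s, `[0, 150)`; and
#' `dprime = 150 * (s150 - cs)` metres. A negative D' is never silently
#' accepted: it sets the `"pacing-suspect"` flag (an all-out effort cannot end
#' faster than it averaged).
#'
#' The trace must cover at least `[0, 180]` s. Irregular timestamps are
#' linearly interpolated onto a 1-Hz grid; gaps longer than 2 s are rejected.
#' Samples beyond 180 s (recordings routinely run a few seconds long) are
#' ignored. The clock is re-zeroed at the first sample, so a uniform shift of
#' the time column does not change the result.
#'
#' @param trace data frame with columns `time_s`, `speed_mps`
#' @return object of class `allout_result`: list with `s150`, `cs`, `dprime`,
#'   `n_samples` and a character vector `flags`
#' @export
compute_allout <- function(trace) {
  trace <- validate_trace(trace)
  # re-zero the clock at test start
  trace$time_s <- trace$time_s - trace$time_s[1]
  if (max(trace$time_s) < 180)
    stop(sprintf("trace covers only [0, %g] s; need at least [0, 180] s",
                 max(trace$time_s)), call. = FALSE)
  gaps <- diff(trace$time_s)
  if (any(gaps > 2))
    stop(sprintf("trace has a gap of %g s (> 2 s tolerated)", max(gaps)),
         call. = FALSE)
  # resample onto the 1-Hz grid (identity for already-1-Hz traces)
  grid <- 0:180
  speed <- stats::approx(trace$time_s, trace$speed_mps, xout = grid,
                         method = "linear", rule = 1)$y
  allout_from_speeds(speed, n_input = nrow(trace))
}

# core extraction on a 1-Hz speed vector covering t = 0..180 (181 samples);
# shared with the generator's fast cohort path
allout_from_speeds <- function(speed, n_input = length(speed)) {
  s150 <- mean(speed[1:150])         # t = 0..149
  cs <- mean(speed[151:180])         # t = 150..179
  dprime <- 150 * (s150 - cs)
  flags <- character(0)
  if (dprime < 0) flags <- "pacing-suspect"
  structure(
    list(s150 = s150, cs = cs, dprime = dprime,
         n_samples = n_input, flags = flags),
    class = "allout_result")
}

#' @export
print.allout_result <- function(x, ...) {
  cat("3-minute all-out test result\n")
  cat(sprintf("  S150s: %.3f m/s\n", x$s150))
  cat(sprintf("  CS:    %.3f m/s\n", x$cs))
  cat(sprintf("  D':    %.1f m\n", x$dprime))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Read a 1-Hz speed trace CSV
#'
#' Expects columns `time_s` and `speed_mps` as written by the synthetic
#' generator.
#'
#' @param path CSV file path
#' @return data frame with `time_s`, `speed_mps`
#' @export
read_speed_trace <- function(path) {
  df <- utils::read.csv(path)
  validate_trace(df)
}

validate_trace <- function(trace) {
  if (!is.data.frame(trace) || !all(c("time_s", "speed_mps") %in% names(trace)))
    stop("trace must be a data frame with columns 'time_s' and 'speed_mps'",
         call. = FALSE)
  if (nrow(trace) < 2)
    stop("trace must contain at least 2 samples", call. = FALSE)
  if (is.unsorted(trace$time_s, strictly = TRUE))
    stop("trace time_s must be strictly increasing", call. = FALSE)
  if (any(trace$speed_mps < 0))
    stop("trace speeds must be non-negative", call. = FALSE)
  trace
}
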