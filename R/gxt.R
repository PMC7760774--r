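#' Graded exercise test protocol
#'
#' Describes an individualized treadmill ramp: start speed, constant grade,
#' per-minute speed increment, warm-up speed and stage length.
#'
#' @param start_speed ramp start speed, mph (default 5)
#' @param grade fractional incline held through the ramp (default 0.03)
#' @param increment_per_min speed increase per one-minute stage, mph
#' @param warmup_speed walking warm-up speed, mph
#' @param stage_length stage duration, seconds (default 60)
#' @return object of class `gxt_protocol`
#' @export
gxt_protocol <- function(start_speed = 5, grade = 0.03, increment_per_min,
                         warmup_speed = 3.25, stage_length = 60) {
  stopifnot_scalar(start_speed, "start_speed", positive = TRUE)
  stopifnot_scalar(increment_per_min, "increment_per_min", positive = TRUE)
  stopifnot_scalar(grade, "grade")
  if (grade < 0) stop("grade must be >= 0", call. = FALSE)
  structure(
    list(start_speed = start_speed, grade = grade,
         increment_per_min = increment_per_min,
         warmup_speed = warmup_speed, stage_length = stage_length),
    class = "gxt_protocol")
}

#' Average gas-exchange samples into consecutive 15-s bins
#'
#' Restricts the series to one phase and averages `vo2` and `vco2` over
#' consecutive, non-overlapping 15-s windows starting at the phase onset.
#' Bins are timestamped at the bin end. A trailing window with fewer samples
#' than a full bin is dropped.
#'
#' @param series gas-exchange data frame with columns `time_s`, `vo2`,
#'   `vco2`, `phase`
#' @param phase phase tag to bin (e.g. `"ramp"`, `"verification"`)
#' @return data frame with `time_s` (bin end, seconds), `vo2`, `vco2`, `n`
#' @export
bin_15s <- function(series, phase) {
  validate_gas_series(series)
  sel <- series$phase == phase
  if (!any(sel))
    stop(sprintf("phase '%s' not present in series", phase), call. = FALSE)
  sub <- series[sel, , drop = FALSE]
  t0 <- min(sub$time_s)
  idx <- floor((sub$time_s - t0) / 15)
  dt <- stats::median(diff(sort(unique(sub$time_s))))
  per_bin <- max(1L, round(15 / dt))
  counts <- tabulate(idx + 1L)
  keep_bins <- which(counts >= per_bin) - 1L
  if (!length(keep_bins))
    stop(sprintf("phase '%s' shorter than one 15-s bin", phase), call. = FALSE)
  out <- data.frame(
    time_s = t0 + 15 * (keep_bins + 1),
    vo2 = vapply(keep_bins, function(b) mean(sub$vo2[idx == b]), numeric(1)),
    vco2 = vapply(keep_bins, function(b) mean(sub$vco2[idx == b]), numeric(1)),
    n = counts[keep_bins + 1L])
  out[order(out$time_s), , drop = FALSE]
}

#' VO2max as the mean of the two highest consecutive 15-s averages
#'
#' Scans all adjacent bin pairs and returns the maximum pair mean; ties are
#' broken toward the earlier pair. The reported time is the end of the later
#' bin of the winning pair.
#'
#' @param binned 15-s binned series as returned by [bin_15s()]
#' @return list with `vo2max` (mL/kg/min) and `time_s` (seconds)
#' @export
vo2max_two_highest <- function(binned) {
  n <- nrow(binned)
  if (is.null(n) || n < 2)
    stop("need at least 2 bins to form a consecutive pair", call. = FALSE)
  pair_means <- (binned$vo2[-n] + binned$vo2[-1]) / 2
  best <- which.max(pair_means)   # which.max takes the earliest maximum
  list(vo2max = pair_means[best], time_s = binned$time_s[best + 1])
}

#' Gas exchange threshold by the v-slope method
#'
#' Fits two least-squares segments of VCO2 on VO2 for every candidate
#' breakpoint leaving at least `min_segment` points per segment and picks the
#' admissible split minimizing the pooled residual sum of squares; the GET is
#' the VO2 at the intersection of the two lines. A split is admissible when
#' (a) the upper slope exceeds the lower slope by at least `min_slope_gap`
#' (near-collinear segments are the degenerate no-threshold solution) and
#' (b) the fitted intersection lies within the VO2 range of the bins
#' `junction_slack` positions around its own junction (an intersection far
#' from the junction contradicts the two-segment model being fitted). With
#' no admissible split the series is reported as having no breakpoint.
#'
#' @param binned 15-s binned ramp series ([bin_15s()])
#' @param min_segment minimum points per segment (default 3)
#' @param min_slope_gap required excess of upper over lower slope (default 0.10)
#' @param junction_slack half-width, in bins, of the junction window the
#'   intersection must fall in (default 4; `Inf` disables the window)
#' @return list with `found` (logical), `get_vo2` (mL/kg/min, `NA` when not
#'   found), `split_index`, `slope_below`, `slope_above`, `rss`
#' @export
detect_get_vslope <- function(binned, min_segment = 3, min_slope_gap = 0.10,
                              junction_slack = 4L) {
  x <- binned$vo2
  y <- binned$vco2
  n <- length(x)
  if (n < 8)
    stop(sprintf("v-slope needs at least 8 ramp bins, got %d", n),
         call. = FALSE)
  # the slope-gap requirement is an admissibility constraint on candidate
  # breakpoints: splits whose two segments are near-collinear are the
  # degenerate no-threshold solution, not a threshold, so they never compete
  # on RSS
  best <- list(rss = Inf, k = NA_integer_)
  best_any <- list(rss = Inf, k = NA_integer_)
  for (k in seq(min_segment, n - min_segment)) {
    lo <- ols_line(x[1:k], y[1:k])
    hi <- ols_line(x[(k + 1):n], y[(k + 1):n])
    rss <- lo$rss + hi$rss
    if (rss < best_any$rss - 1e-12)
      best_any <- list(rss = rss, k = k, lo = lo, hi = hi)
    gap <- hi$slope - lo$slope
    if (!is.finite(gap) || gap < min_slope_gap) next
    bp <- (lo$intercept - hi$intercept) / gap
    # segmented-regression consistency: the fitted intersection must lie in
    # the neighbourhood of its own junction, otherwise the split contradicts
    # the two-segment model it claims to fit
    if (is.finite(junction_slack)) {
      win <- range(x[max(1, k - junction_slack):min(n, k + 1 + junction_slack)])
    } else {
      win <- range(x)
    }
    if (bp < win[1] || bp > win[2]) next
    if (rss < best$rss - 1e-12)
      best <- list(rss = rss, k = k, lo = lo, hi = hi, get_vo2 = bp)
  }
  if (!is.finite(best$rss)) {
    return(list(found = FALSE, get_vo2 = NA_real_, split_index = best_any$k,
                slope_below = best_any$lo$slope,
                slope_above = best_any$hi$slope, rss = best_any$rss))
  }
  list(found = TRUE, get_vo2 = best$get_vo2, split_index = best$k,
       slope_below = best$lo$slope, slope_above = best$hi$slope,
       rss = best$rss)
}

# simple-regression line with residual sum of squares; a segment with zero
# x-variance (stacked points) degenerates to the horizontal line through the
# segment mean
ols_line <- function(x, y) {
  xb <- mean(x); yb <- mean(y)
  sxx <- sum((x - xb)^2)
  slope <- if (sxx > 0) sum((x - xb) * (y - yb)) / sxx else 0
  intercept <- yb - slope * xb
  rss <- sum((y - intercept - slope * x)^2)
  list(slope = slope, intercept = intercept, rss = rss)
}

#' Protocol speed evoking a gas-exchange value measured at ramp time t
#'
#' The metabolic response lags the treadmill by about one minute, and with
#' 15-s averaging and one-minute stages the stage increment is spread over
#' quarter-stages: the speed assigned to 15-s sample index `j` (0-based from
#' ramp start) is `start_speed + increment_per_min * j / 4`, and a
#' measurement in the bin ending at `t` (index `j = t/15 - 1`) is attributed
#' to the speed at index `j - 4`. Indices before the ramp start clamp to the
#' start speed, recorded via the `"clamped"` attribute.
#'
#' @param protocol a [gxt_protocol()]
#' @param t seconds from ramp start (end time of the measurement bin)
#' @param ramp_duration optional ramp length in seconds; `t` beyond it errors
#' @return speed in mph, with logical attribute `"clamped"`
#' @export
lagged_speed_at <- function(protocol, t, ramp_duration = NULL) {
  stopifnot(inherits(protocol, "gxt_protocol"))
  stopifnot_scalar(t, "t")
  if (!is.null(ramp_duration) && t > ramp_duration)
    stop(sprintf("t = %g s is beyond the ramp end (%g s)", t, ramp_duration),
         call. = FALSE)
  j <- round(t / 15) - 1
  if (j < 0)
    stop("t precedes the end of the first 15-s ramp bin", call. = FALSE)
  idx <- j - 4
  clamped <- idx < 0
  if (clamped) idx <- 0
  speed <- protocol$start_speed + protocol$increment_per_min * idx / 4
  attr(speed, "clamped") <- clamped
  speed
}

#' Flat-equivalent outdoor speed of an inclined treadmill speed
#'
#' Uses metabolic equivalence under the running-demand equation
#' `demand = 3.5 + 0.2 S + 0.9 S G` (S in m/min): the flat speed with the
#' same demand as inclined speed S is `S * (1 + 4.5 G)`. The result is
#' returned in m/s.
#'
#' @param speed speed value
#' @param grade fractional incline (>= 0)
#' @param unit unit of `speed`: `"mph"` or `"mps"`
#' @return flat-equivalent speed in m/s
#' @export
flat_equivalent <- function(speed, grade, unit = c("mph", "mps")) {
  unit <- match.arg(unit)
  if (any(grade < 0)) stop("grade must be >= 0", call. = FALSE)
  flat <- speed * (1 + (DEMAND_VERT / DEMAND_SLOPE) * grade)
  if (unit == "mph") flat <- flat * MPH_TO_MS
  flat
}

#' Process a ramp gas-exchange series into VO2max, GET and 50%-delta speeds
#'
#' Pipeline: 15-s binning of the ramp phase, VO2max as the two-highest
#' consecutive bin average, GET by v-slope, time-to-speed mapping with the
#' one-minute lag and quarter-stage interpolation, flat-equivalent
#' conversion, and `fifty_delta` as the mean of the flat-equivalent speeds at
#' GET and at VO2max. The GET time is the end of the first bin whose VO2
#' reaches the v-slope GET value.
#'
#' @param series gas-exchange data frame (columns `time_s`, `vo2`, `vco2`,
#'   `phase`, plus speed/grade columns as written by the generator)
#' @param protocol the [gxt_protocol()] that produced the ramp
#' @return object of class `gxt_result`: list with `vo2max`, `vo2max_time`,
#'   `get_vo2`, `speed_at_get`, `speed_at_vo2max`, `fifty_delta` (all speeds
#'   m/s flat-equivalent), `binned`, `flags`
#' @export
process_gxt <- function(series, protocol) {
  stopifnot(inherits(protocol, "gxt_protocol"))
  if (!any(series$phase == "ramp"))
    stop("gxt stage 'bin': ramp phase missing from series", call. = FALSE)
  binned <- bin_15s(series, "ramp")
  ramp_start <- min(series$time_s[series$phase == "ramp"])
  ramp_dur <- max(binned$time_s) - ramp_start

  vm <- vo2max_two_highest(binned)
  vs <- detect_get_vslope(binned)
  if (!vs$found)
    stop("gxt stage 'v-slope': no gas exchange threshold breakpoint detected",
         call. = FALSE)
  if (vs$get_vo2 >= vm$vo2max)
    stop("gxt stage 'v-slope': GET at or above VO2max; series not a valid ramp",
         call. = FALSE)

  get_idx <- which(binned$vo2 >= vs$get_vo2)[1]
  if (is.na(get_idx))
    stop("gxt stage 'GET mapping': no bin reaches the GET VO2", call. = FALSE)
  get_time <- binned$time_s[get_idx]

  sp_get <- lagged_speed_at(protocol, get_time - ramp_start, ramp_dur)
  sp_max <- lagged_speed_at(protocol, vm$time_s - ramp_start, ramp_dur)
  flags <- character(0)
  if (isTRUE(attr(sp_get, "clamped")) || isTRUE(attr(sp_max, "clamped")))
    flags <- c(flags, "lag-clamped-to-ramp-start")

  speed_at_get <- flat_equivalent(as.numeric(sp_get), protocol$grade, "mph")
  speed_at_vo2max <- flat_equivalent(as.numeric(sp_max), protocol$grade, "mph")

  structure(
    list(vo2max = vm$vo2max, vo2max_time = vm$time_s,
         get_vo2 = vs$get_vo2, get_time = get_time,
         speed_at_get = speed_at_get, speed_at_vo2max = speed_at_vo2max,
         fifty_delta = (speed_at_get + speed_at_vo2max) / 2,
         binned = binned, flags = flags),
    class = "gxt_result")
}

#' Verify a ramp VO2max against a supramaximal verification bout
#'
#' The verification-phase VO2max is computed with the same two-highest
#' consecutive 15-s rule; the ramp maximum is accepted as a true maximum when
#' the relative difference is within 3% (inclusive).
#'
#' @param ramp_vo2max ramp-phase VO2max, mL/kg/min
#' @param vp_series gas-exchange series containing a `"verification"` phase
#' @return list with `vp_vo2max`, `relative_difference`, `accepted`
#' @export
process_verification <- function(ramp_vo2max, vp_series) {
  stopifnot_scalar(ramp_vo2max, "ramp_vo2max", positive = TRUE)
  if (!any(vp_series$phase == "verification"))
    stop("verification phase missing from series", call. = FALSE)
  binned <- bin_15s(vp_series, "verification")
  vp <- vo2max_two_highest(binned)
  rel <- abs(ramp_vo2max - vp$vo2max) / ramp_vo2max
  list(vp_vo2max = vp$vo2max, relative_difference = rel,
       accepted = rel <= 0.03)
}

#' Design an individualized ramp protocol from a predicted VO2max
#'
#' Inverts the running-demand equation at 3% grade to find the speed whose
#' demand equals the predicted VO2max, then divides the speed range above the
#' 5-mph start across `target_duration` one-minute stages so the test ends
#' within the 8-12 min window.
#'
#' @param predicted_vo2max predicted maximum, mL/kg/min
#' @param target_duration intended ramp duration, minutes (8-12)
#' @param start_speed ramp start speed, mph
#' @param grade fractional incline
#' @param economy_slope demand slope, (mL/kg/min)/(m/min); default 0.2
#' @return a [gxt_protocol()]
#' @export
design_protocol <- function(predicted_vo2max, target_duration = 10,
                            start_speed = 5, grade = 0.03,
                            economy_slope = DEMAND_SLOPE) {
  stopifnot_scalar(predicted_vo2max, "predicted_vo2max", positive = TRUE)
  if (target_duration < 8 || target_duration > 12)
    stop("target_duration must be within 8-12 minutes", call. = FALSE)
  peak_flat_mmin <- speed_for_demand(predicted_vo2max, economy_slope)
  peak_mph <- peak_flat_mmin / (MPH_TO_MMIN * (1 + (DEMAND_VERT / DEMAND_SLOPE) * grade))
  if (peak_mph <= start_speed)
    stop(sprintf(
      "predicted VO2max %.1f implies peak speed %.2f mph at or below the %.1f mph start",
      predicted_vo2max, peak_mph, start_speed), call. = FALSE)
  gxt_protocol(start_speed = start_speed, grade = grade,
               increment_per_min = (peak_mph - start_speed) / target_duration)
}

#' Read a gas-exchange series CSV
#'
#' @param path CSV path with columns `time_s`, `vo2`, `vco2`, `speed`,
#'   `speed_unit`, `grade`, `phase`
#' @return validated data frame
#' @export
read_gas_series <- function(path) {
  df <- utils::read.csv(path)
  validate_gas_series(df)
  df
}

validate_gas_series <- function(series) {
  need <- c("time_s", "vo2", "vco2", "phase")
  if (!is.data.frame(series) || !all(need %in% names(series)))
    stop("gas series must be a data frame with columns ",
         paste(need, collapse = ", "), call. = FALSE)
  if (any(series$vo2 < 0) || any(series$vco2 < 0))
    stop("gas values must be non-negative", call. = FALSE)
  invisible(series)
}
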