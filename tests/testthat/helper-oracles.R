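# Brute-force oracles used by the property suites. Deliberately written with
# different primitives than the shipped implementations (stats::lm, explicit
# normal equations) so agreement is evidence, not tautology.

# simple-regression line via lm(), with the same degenerate rule as the
# shipped ols_line: zero x-variance collapses to the horizontal line through
# the segment mean
oracle_line <- function(x, y) {
  if (stats::var(x) == 0) {
    slope <- 0
    intercept <- mean(y)
  } else {
    cf <- stats::coef(stats::lm(y ~ x))
    intercept <- cf[[1]]
    slope <- cf[[2]]
  }
  list(slope = slope, intercept = intercept,
       rss = sum((y - intercept - slope * x)^2))
}

# exhaustive v-slope breakpoint search mirroring the documented rule set:
# >= min_segment points per segment, earliest split wins ties, admissibility
# = slope gap >= min_slope_gap AND intersection inside the junction window
oracle_vslope <- function(binned, min_segment = 3, min_slope_gap = 0.10,
                          junction_slack = 4L) {
  x <- binned$vo2
  y <- binned$vco2
  n <- length(x)
  best <- list(rss = Inf, k = NA_integer_, get_vo2 = NA_real_)
  for (k in seq(min_segment, n - min_segment)) {
    lo <- oracle_line(x[1:k], y[1:k])
    hi <- oracle_line(x[(k + 1):n], y[(k + 1):n])
    gap <- hi$slope - lo$slope
    if (!is.finite(gap) || gap < min_slope_gap) next
    bp <- (lo$intercept - hi$intercept) / gap
    win <- if (is.finite(junction_slack)) {
      range(x[max(1, k - junction_slack):min(n, k + 1 + junction_slack)])
    } else range(x)
    if (bp < win[1] || bp > win[2]) next
    rss <- lo$rss + hi$rss
    if (rss < best$rss - 1e-12)
      best <- list(rss = rss, k = k, get_vo2 = bp)
  }
  best
}

# two-predictor OLS by explicit normal equations
oracle_ols <- function(y, x1, x2 = NULL) {
  X <- if (is.null(x2)) cbind(1, x1) else cbind(1, x1, x2)
  as.numeric(solve(crossprod(X), crossprod(X, y)))
}

# exhaustive adjacent-pair scan for the two-highest VO2max rule
oracle_two_highest <- function(vo2) {
  best <- -Inf
  best_i <- NA_integer_
  for (i in seq_len(length(vo2) - 1)) {
    m <- (vo2[i] + vo2[i + 1]) / 2
    if (m > best) {
      best <- m
      best_i <- i
    }
  }
  list(vo2max = best, index = best_i)
}

# a plain 1-Hz gas series wrapper for constructed phase data
make_series <- function(vo2, vco2 = vo2 * 0.85, phase = "ramp") {
  data.frame(time_s = seq_along(vo2) - 1, vo2 = vo2, vco2 = vco2,
             phase = phase)
}
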