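#' Typical error of paired measurements
#'
#' The within-pair standard deviation: sample SD of the differences divided
#' by sqrt(2).
#'
#' @param x,y paired measurement vectors of equal length (>= 2)
#' @return typical error, in the units of the inputs
#' @export
typical_error <- function(x, y) {
  check_pairs(x, y, min_n = 2)
  stats::sd(x - y) / sqrt(2)
}

#' Convert a regression SEE to a typical error
#'
#' A regression standard error of the estimate uses `n - k - 1` residual
#' degrees of freedom while the typical error convention divides the
#' residual SD (with `n - 1` df) by sqrt(2); this converts between the two:
#' `te = see * sqrt((n - k - 1) / (n - 1)) / sqrt(2)`.
#'
#' @param see standard error of the estimate
#' @param n sample size
#' @param k number of predictors
#' @return typical error in the units of `see`
#' @export
te_from_see <- function(see, n, k) {
  if (see < 0) stop("see must be >= 0", call. = FALSE)
  if (n <= k + 1) stop("need n > k + 1 residual degrees of freedom", call. = FALSE)
  see * sqrt((n - k - 1) / (n - 1)) / sqrt(2)
}

#' Coefficient of variation of paired measurements
#'
#' `method = "linear"`: 100 * typical error / grand mean of both vectors.
#' `method = "log"`: typical error of the natural-log transformed data,
#' back-transformed as `100 * (exp(te_log) - 1)` (the multiplicative-error
#' convention; default).
#'
#' @param x,y paired measurement vectors
#' @param method `"log"` (default) or `"linear"`
#' @return CV in percent
#' @export
cv_percent <- function(x, y, method = c("log", "linear")) {
  method <- match.arg(method)
  check_pairs(x, y, min_n = 2)
  if (method == "linear") {
    100 * typical_error(x, y) / mean(c(x, y))
  } else {
    if (any(x <= 0) || any(y <= 0))
      stop("log-method CV requires strictly positive data", call. = FALSE)
    100 * (exp(typical_error(log(x), log(y))) - 1)
  }
}

#' Intraclass correlation (two-way mixed, consistency, single measure)
#'
#' Computed from the two-column repeated-measures mean squares:
#' `(MS_subjects - MS_error) / (MS_subjects + (k - 1) * MS_error)` with
#' k = 2 trials. Consistency form: insensitive to a fixed offset between the
#' trials.
#'
#' @param x,y paired measurement vectors (n >= 3)
#' @return ICC in `[-1, 1]`; `NA` with a warning when between-subject
#'   variance is zero (undefined)
#' @export
icc_consistency <- function(x, y) {
  check_pairs(x, y, min_n = 3)
  n <- length(x)
  k <- 2
  dat <- cbind(x, y)
  subj_means <- rowMeans(dat)
  trial_means <- colMeans(dat)
  grand <- mean(dat)
  ss_subj <- k * sum((subj_means - grand)^2)
  ss_trial <- n * sum((trial_means - grand)^2)
  ss_tot <- sum((dat - grand)^2)
  ss_err <- ss_tot - ss_subj - ss_trial
  ms_subj <- ss_subj / (n - 1)
  ms_err <- ss_err / ((n - 1) * (k - 1))
  if (ms_subj <= 0) {
    warning("zero between-subject variance: ICC undefined")
    return(NA_real_)
  }
  (ms_subj - ms_err) / (ms_subj + (k - 1) * ms_err)
}

#' Pearson product-moment correlation with two-sided p-value
#'
#' @param x,y numeric vectors (n >= 3, nonzero variances)
#' @return list with `r` and `p` (t transform, n - 2 df)
#' @export
pearson_r <- function(x, y) {
  check_pairs(x, y, min_n = 3)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance: correlation undefined", call. = FALSE)
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Paired t-test
#'
#' `t = mean(d) / (sd(d) / sqrt(n))` with two-sided p on n - 1 df. With zero
#' difference variance the statistic is undefined and reported as `NA`.
#'
#' @param x,y paired vectors of equal length (>= 2)
#' @return list with `t`, `p`, `mean_diff`, `n`
#' @export
paired_t <- function(x, y) {
  check_pairs(x, y, min_n = 2)
  d <- x - y
  n <- length(d)
  sd_d <- stats::sd(d)
  if (sd_d == 0) {
    return(list(t = NA_real_, p = NA_real_, mean_diff = mean(d), n = n,
                note = "zero difference variance: t undefined"))
  }
  tt <- stats::t.test(x, y, paired = TRUE)
  list(t = unname(tt$statistic), p = tt$p.value, mean_diff = mean(d), n = n)
}

#' Full reliability report for two paired measurement columns
#'
#' Bundles typical error (with a chi-square 95% CI on the difference
#' variance), CV%, consistency ICC, Pearson r and the paired t-test.
#'
#' @param x,y paired measurement vectors
#' @param cv_method CV convention, `"log"` (default) or `"linear"`
#' @return object of class `reliability_report`
#' @export
reliability_report <- function(x, y, cv_method = "log") {
  check_pairs(x, y, min_n = 3)
  n <- length(x)
  te <- typical_error(x, y)
  # chi-square interval on the difference variance, carried through /sqrt(2)
  var_d <- stats::var(x - y)
  ci <- if (var_d > 0) {
    sqrt((n - 1) * var_d / stats::qchisq(c(0.975, 0.025), df = n - 1)) / sqrt(2)
  } else c(0, 0)
  pr <- pearson_r(x, y)
  tt <- paired_t(x, y)
  structure(
    list(te = te, ci_te_lower = ci[1], ci_te_upper = ci[2],
         cv_percent = cv_percent(x, y, cv_method),
         icc = icc_consistency(x, y),
         pearson_r = pr$r, pearson_p = pr$p,
         paired_t = tt$t, paired_p = tt$p, n = n),
    class = "reliability_report")
}

#' @export
print.reliability_report <- function(x, ...) {
  cat("Reliability report (n =", x$n, "pairs)\n")
  cat(sprintf("  TE   = %.3f (95%% CI %.3f-%.3f)\n",
              x$te, x$ci_te_lower, x$ci_te_upper))
  cat(sprintf("  CV%%  = %.2f\n", x$cv_percent))
  cat(sprintf("  ICC  = %.3f\n", x$icc))
  cat(sprintf("  r    = %.3f (p = %.3g)\n", x$pearson_r, x$pearson_p))
  cat(sprintf("  t    = %.3f (p = %.3g)\n", x$paired_t, x$paired_p))
  invisible(x)
}

check_pairs <- function(x, y, min_n) {
  if (length(x) != length(y))
    stop("x and y must have equal length", call. = FALSE)
  if (length(x) < min_n)
    stop(sprintf("need at least %d pairs", min_n), call. = FALSE)
  if (anyNA(x) || anyNA(y))
    stop("missing values not allowed", call. = FALSE)
  invisible(TRUE)
}
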