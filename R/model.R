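#' Reference coefficients of the CS + sex VO2max prediction equation
#'
#' The published field equation predicting relative VO2max (mL/kg/min) from
#' critical speed and sex in recreational HIFT athletes:
#' `VO2max = 8.449 * CS + 4.387 * sex + 14.683` with sex coded female = 0,
#' male = 1, SEE = 3.34 mL/kg/min.
#'
#' @return named list with `coef_cs`, `coef_sex`, `intercept`, `see`
#' @export
default_prediction_coefficients <- function() {
  list(coef_cs = 8.449, coef_sex = 4.387, intercept = 14.683, see = 3.34)
}

#' Stepwise fit of the VO2max prediction model
#'
#' Forward-entry stepwise regression with CS (the hypothesis variable) forced
#' first: Model 1 regresses observed VO2max on CS; Model 2 adds sex when its
#' partial t-test has p < `alpha_entry`. SEE uses the `n - k - 1` residual
#' degrees of freedom; standardized betas use predictor/response sample SDs.
#'
#' @param cohort data frame with columns `cs` (m/s), `sex` (0 = female,
#'   1 = male) and `vo2max` (mL/kg/min)
#' @param alpha_entry entry criterion for the sex step (default 0.05)
#' @return object of class `model_fit`: list with `coef_cs`, `coef_sex`,
#'   `intercept`, `se_cs`, `se_sex`, `beta_cs`, `beta_sex`, `see`,
#'   `r2_model1`, `r2_model2`, `n`, `included_terms`, `fitted`, `residuals`
#'   and the underlying `lm` object in `$lm`
#' @export
fit_stepwise <- function(cohort, alpha_entry = 0.05) {
  need <- c("cs", "sex", "vo2max")
  if (!all(need %in% names(cohort)))
    stop("cohort must have columns cs, sex, vo2max", call. = FALSE)
  n <- nrow(cohort)
  if (n < 5) stop("need at least 5 athletes to fit the model", call. = FALSE)
  if (!all(cohort$sex %in% c(0, 1)))
    stop("sex must be coded 0 (female) / 1 (male)", call. = FALSE)
  if (stats::sd(cohort$cs) == 0)
    stop("rank deficiency: CS has zero variance", call. = FALSE)

  m1 <- stats::lm(vo2max ~ cs, data = cohort)
  r2_model1 <- summary(m1)$r.squared

  both_sexes <- length(unique(cohort$sex)) == 2
  sex_entered <- FALSE
  note <- NULL
  if (both_sexes) {
    m2 <- stats::lm(vo2max ~ cs + sex, data = cohort)
    p_sex <- summary(m2)$coefficients["sex", "Pr(>|t|)"]
    sex_entered <- is.finite(p_sex) && p_sex < alpha_entry
  } else {
    note <- "single-sex cohort: sex step skipped"
  }

  final <- if (sex_entered) m2 else m1
  sm <- summary(final)
  cf <- sm$coefficients
  sd_y <- stats::sd(cohort$vo2max)

  fit <- list(
    coef_cs = cf["cs", "Estimate"],
    coef_sex = if (sex_entered) cf["sex", "Estimate"] else NA_real_,
    intercept = cf["(Intercept)", "Estimate"],
    se_cs = cf["cs", "Std. Error"],
    se_sex = if (sex_entered) cf["sex", "Std. Error"] else NA_real_,
    beta_cs = cf["cs", "Estimate"] * stats::sd(cohort$cs) / sd_y,
    beta_sex = if (sex_entered)
      cf["sex", "Estimate"] * stats::sd(cohort$sex) / sd_y else NA_real_,
    see = sm$sigma,
    r2_model1 = r2_model1,
    r2_model2 = if (sex_entered) sm$r.squared else NA_real_,
    n = n,
    included_terms = if (sex_entered) c("cs", "sex") else "cs",
    fitted = as.numeric(stats::fitted(final)),
    residuals = as.numeric(stats::residuals(final)),
    note = note,
    lm = final)
  class(fit) <- "model_fit"
  fit
}

#' @export
print.model_fit <- function(x, ...) {
  cat("VO2max prediction model (", paste(x$included_terms, collapse = " + "),
      ")\n", sep = "")
  cat(sprintf("  VO2max = %.3f * CS", x$coef_cs))
  if ("sex" %in% x$included_terms)
    cat(sprintf(" + %.3f * sex", x$coef_sex))
  cat(sprintf(" + %.3f\n", x$intercept))
  cat(sprintf("  SEE = %.3f mL/kg/min, n = %d, R2 = %.3f\n",
              x$see, x$n,
              if ("sex" %in% x$included_terms) x$r2_model2 else x$r2_model1))
  invisible(x)
}

#' Predict relative VO2max from critical speed and sex
#'
#' Evaluates the linear prediction equation. With no fitted model supplied
#' the reference coefficients of [default_prediction_coefficients()] are
#' used.
#'
#' @param cs critical speed, m/s (vectorized)
#' @param sex 0 = female, 1 = male (vectorized)
#' @param fit a `model_fit` or a coefficient list with `coef_cs`,
#'   `coef_sex`, `intercept`
#' @return predicted VO2max, mL/kg/min
#' @export
predict_vo2max <- function(cs, sex, fit = default_prediction_coefficients()) {
  if (!all(sex %in% c(0, 1)))
    stop("sex must be coded 0 (female) / 1 (male)", call. = FALSE)
  if (any(cs < 0)) stop("cs must be non-negative", call. = FALSE)
  coef_sex <- if (is.null(fit$coef_sex) || is.na(fit$coef_sex)) 0 else fit$coef_sex
  fit$coef_cs * cs + coef_sex * sex + fit$intercept
}

#' Compare observed against model-fitted VO2max values
#'
#' Paired t-test of observed values against the model's fitted values. For a
#' least-squares fit with intercept on the same cohort the residuals sum to
#' zero, so t = 0 and p = 1 up to floating point; applying coefficients from
#' another sample generally breaks this.
#'
#' @param cohort the data frame the model was fitted to (column `vo2max`)
#' @param fit a `model_fit` from [fit_stepwise()]
#' @return list with `t`, `p`, `mean_observed`, `mean_fitted`, `sd_observed`,
#'   `sd_fitted`, `n`
#' @export
compare_observed_predicted <- function(cohort, fit) {
  if (!inherits(fit, "model_fit"))
    stop("fit must be a model_fit", call. = FALSE)
  if (nrow(cohort) != fit$n)
    stop("cohort size does not match the fitted model", call. = FALSE)
  observed <- cohort$vo2max
  fitted <- fit$fitted
  tt <- paired_t(observed, fitted)
  list(t = tt$t, p = tt$p,
       mean_observed = mean(observed), mean_fitted = mean(fitted),
       sd_observed = stats::sd(observed), sd_fitted = stats::sd(fitted),
       n = fit$n)
}
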