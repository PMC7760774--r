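#' Synthetic-cohort generator configuration
#'
#' Holds every distributional parameter of the synthetic cohort. The
#' sex-specific CS means/SDs default to `NA` and are filled by
#' [calibrate_sex_cs_distributions()], which targets the pooled CS moments
#' (mean 3.56, SD 0.55 m/s) and the pooled CS-VO2max correlation (0.819).
#'
#' @param n_athletes number of athletes to generate
#' @param male_fraction probability of sex = male (default 17/25)
#' @param cs_mean,cs_sd pooled CS calibration targets, m/s
#' @param cs_mean_male,cs_sd_male,cs_mean_female,cs_sd_female sex-specific CS
#'   distribution parameters (filled by calibration)
#' @param dprime_mean,dprime_sd D' distribution, metres
#' @param residual_sd residual SD of the VO2max linear model, mL/kg/min
#' @param coef_cs,coef_sex,intercept linear-model coefficients generating
#'   VO2max from CS and sex
#' @param target_r pooled CS-VO2max correlation the calibration targets
#' @param tau all-out speed-decay time constant, seconds
#' @param gps_noise_sd additive speed noise per 1-Hz sample, m/s
#' @param gas_noise_sd additive gas noise per 1-Hz sample, mL/kg/min
#' @param get_fraction gas exchange threshold as a fraction of VO2max
#' @param vslope_slope_below,vslope_slope_above VCO2-on-VO2 slopes below and
#'   above the threshold
#' @param vp_noise_sd athlete-level proportional SD of the verification-bout
#'   plateau around true VO2max
#' @param fifty_delta_ratio ratio of the protocol-measured 50%-delta to true
#'   CS the economy calibration targets (default 3.59/3.56)
#' @param gxt_target_duration intended ramp duration, minutes
#' @param mass_mean,mass_sd body-mass distribution, kg
#' @param n_pacing_violators,n_vp_violators number of athletes rendered with
#'   injected pacing / verification violations
#' @param seed integer seed; all randomness derives from it
#' @return object of class `gen_config` (a validated named list)
#' @export
gen_config <- function(n_athletes = 25,
                       male_fraction = 17 / 25,
                       cs_mean = 3.56, cs_sd = 0.55,
                       cs_mean_male = NA_real_, cs_sd_male = NA_real_,
                       cs_mean_female = NA_real_, cs_sd_female = NA_real_,
                       dprime_mean = 208.5, dprime_sd = 54.3,
                       residual_sd = 3.34,
                       coef_cs = 8.449, coef_sex = 4.387, intercept = 14.683,
                       target_r = 0.819,
                       tau = 35,
                       gps_noise_sd = 0.05,
                       gas_noise_sd = 1.0,
                       get_fraction = 0.65,
                       vslope_slope_below = 0.85, vslope_slope_above = 1.15,
                       vp_noise_sd = 0.008,
                       fifty_delta_ratio = 3.59 / 3.56,
                       gxt_target_duration = 12,
                       mass_mean = 77.4, mass_sd = 14.8,
                       n_pacing_violators = 0, n_vp_violators = 0,
                       seed = 1L) {
  config <- list(
    n_athletes = n_athletes, male_fraction = male_fraction,
    cs_mean = cs_mean, cs_sd = cs_sd,
    cs_mean_male = cs_mean_male, cs_sd_male = cs_sd_male,
    cs_mean_female = cs_mean_female, cs_sd_female = cs_sd_female,
    dprime_mean = dprime_mean, dprime_sd = dprime_sd,
    residual_sd = residual_sd,
    coef_cs = coef_cs, coef_sex = coef_sex, intercept = intercept,
    target_r = target_r, tau = tau,
    gps_noise_sd = gps_noise_sd, gas_noise_sd = gas_noise_sd,
    get_fraction = get_fraction,
    vslope_slope_below = vslope_slope_below,
    vslope_slope_above = vslope_slope_above,
    vp_noise_sd = vp_noise_sd,
    fifty_delta_ratio = fifty_delta_ratio,
    gxt_target_duration = gxt_target_duration,
    mass_mean = mass_mean, mass_sd = mass_sd,
    n_pacing_violators = n_pacing_violators,
    n_vp_violators = n_vp_violators,
    seed = as.integer(seed))
  class(config) <- "gen_config"
  validate_gen_config(config)
  config
}

validate_gen_config <- function(config) {
  with(config, {
    if (n_athletes < 0) stop("n_athletes must be >= 0", call. = FALSE)
    if (male_fraction < 0 || male_fraction > 1)
      stop("male_fraction must be in [0, 1]", call. = FALSE)
    sds <- c(cs_sd, dprime_sd, residual_sd, gps_noise_sd, gas_noise_sd,
             vp_noise_sd, mass_sd)
    if (any(sds < 0)) stop("all SDs must be >= 0", call. = FALSE)
    if (tau <= 0) stop("tau must be > 0", call. = FALSE)
    if (get_fraction <= 0 || get_fraction >= 1)
      stop("get_fraction must be in (0, 1)", call. = FALSE)
    if (vslope_slope_above <= vslope_slope_below)
      stop("vslope_slope_above must exceed vslope_slope_below", call. = FALSE)
    if (n_pacing_violators < 0 || n_vp_violators < 0)
      stop("violator counts must be >= 0", call. = FALSE)
  })
  invisible(config)
}

#' Read a generator configuration from a YAML or JSON file
#'
#' Keys mirror the arguments of [gen_config()]; unspecified keys keep their
#' defaults.
#'
#' @param path YAML or JSON file
#' @return a [gen_config()]
#' @export
read_gen_config <- function(path) {
  vals <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  known <- names(formals(gen_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  do.call(gen_config, vals)
}

is_calibrated <- function(config) {
  !anyNA(c(config$cs_mean_male, config$cs_sd_male,
           config$cs_mean_female, config$cs_sd_female))
}

#' Calibrate the sex-specific CS distributions
#'
#' The cohort moments are pooled (CS mean 3.56, SD 0.55 m/s) and so is the
#' CS-VO2max correlation (0.819); sex-specific CS parameters are therefore a
#' modelling choice, pinned down here by a non-circular calibration: the
#' male-female CS mean gap is searched (bisection, common random numbers,
#' simulation size `n_sim`) until the simulated pooled correlation between CS
#' and generated VO2max matches the target, while the sex-specific means/SDs
#' are constrained so the pooled mean and SD match exactly
#' (`within-sex SD^2 = pooled SD^2 - p(1-p) gap^2`).
#'
#' @param config a [gen_config()]
#' @param n_sim simulated population size per evaluation (>= 1e5)
#' @param tol_r tolerance on the achieved correlation (default 0.01)
#' @param max_gap largest admissible male-female CS gap, m/s
#' @return the config with sex-specific CS fields filled; attributes
#'   `calibration` (achieved r, gap, simulated pooled moments) and
#'   `degenerate` (TRUE for the noiseless single-sex case where r = 1
#'   identically and no calibration is possible)
#' @export
calibrate_sex_cs_distributions <- function(config, n_sim = 1e5, tol_r = 0.01,
                                           max_gap = 1.5) {
  stopifnot(inherits(config, "gen_config"))
  if (n_sim < 1e5) stop("n_sim must be at least 1e5", call. = FALSE)
  p <- config$male_fraction
  single_sex <- p %in% c(0, 1)

  if (single_sex && config$residual_sd == 0) {
    # VO2max is a deterministic affine function of CS: r = 1 identically
    config$cs_mean_male <- config$cs_mean_female <- config$cs_mean
    config$cs_sd_male <- config$cs_sd_female <- config$cs_sd
    attr(config, "degenerate") <- TRUE
    attr(config, "calibration") <- list(r = 1, gap = 0)
    warning("noiseless single-sex model is deterministic in CS: r = 1, ",
            "no calibration possible")
    return(config)
  }

  # common random numbers shared across all gap evaluations
  old <- .Random.seed_store()
  on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(config$seed, 1001L))
  sex <- stats::rbinom(n_sim, 1, p)
  z_cs <- stats::rnorm(n_sim)
  z_res <- stats::rnorm(n_sim)

  r_for_gap <- function(gap) {
    wvar <- config$cs_sd^2 - p * (1 - p) * gap^2
    if (wvar <= 0) return(NA_real_)
    mu <- config$cs_mean + (sex - p) * gap
    cs <- pmax(mu + sqrt(wvar) * z_cs, 1.0)
    vo2 <- config$coef_cs * cs + config$coef_sex * sex + config$intercept +
      config$residual_sd * z_res
    stats::cor(cs, vo2)
  }

  if (single_sex) {
    r0 <- r_for_gap(0)
    if (abs(r0 - config$target_r) > tol_r)
      stop(sprintf(
        "single-sex cohort: correlation %.3f is fixed by residual_sd and cannot reach the target %.3f",
        r0, config$target_r), call. = FALSE)
    gap <- 0
  } else {
    gap_hi <- min(max_gap, config$cs_sd / sqrt(p * (1 - p)) - 1e-6)
    f_lo <- r_for_gap(0) - config$target_r
    f_hi <- r_for_gap(gap_hi) - config$target_r
    if (is.na(f_hi) || f_lo * f_hi > 0)
      stop(sprintf(
        "no CS mean gap in [0, %.2f] m/s reaches r = %.3f (r ranges %.3f to %.3f)",
        gap_hi, config$target_r, f_lo + config$target_r,
        f_hi + config$target_r), call. = FALSE)
    lo <- 0; hi <- gap_hi
    for (i in 1:50) {
      mid <- (lo + hi) / 2
      fm <- r_for_gap(mid) - config$target_r
      if (abs(fm) < tol_r / 10 || (hi - lo) < 1e-6) break
      if (fm * f_lo <= 0) hi <- mid else { lo <- mid; f_lo <- fm }
    }
    gap <- (lo + hi) / 2
  }

  wsd <- sqrt(config$cs_sd^2 - p * (1 - p) * gap^2)
  config$cs_mean_male <- config$cs_mean + (1 - p) * gap
  config$cs_mean_female <- config$cs_mean - p * gap
  config$cs_sd_male <- config$cs_sd_female <- wsd

  r_final <- r_for_gap(gap)
  mu <- config$cs_mean + (sex - p) * gap
  cs_sim <- pmax(mu + wsd * z_cs, 1.0)
  attr(config, "calibration") <- list(
    r = r_final, gap = gap,
    pooled_mean = mean(cs_sim), pooled_sd = stats::sd(cs_sim), n_sim = n_sim)
  if (abs(r_final - config$target_r) > tol_r)
    stop(sprintf("calibration failed: achieved r = %.4f, target %.4f",
                 r_final, config$target_r), call. = FALSE)
  config
}

# save/restore the global RNG state so calibration is a pure function
.Random.seed_store <- function() {
  if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Sample athlete truths from a calibrated configuration
#'
#' Sex ~ Bernoulli(male_fraction); CS ~ Normal(sex-specific mean, SD)
#' truncated above 1.0 m/s; D' ~ Normal truncated above 50 m; true VO2max is
#' the linear model in CS and sex plus Normal residual; the gas exchange
#' threshold is `get_fraction * VO2max`. The first `n_pacing_violators`
#' athletes and the following `n_vp_violators` are flagged for injected
#' violations.
#'
#' @param config a calibrated [gen_config()]
#' @return data frame of athlete truths: `id`, `sex` (0 = F, 1 = M),
#'   `true_cs`, `true_dprime`, `true_vo2max`, `true_get`, `mass_kg`,
#'   `is_pacing_violator`, `is_vp_violator`
#' @export
sample_athletes <- function(config) {
  stopifnot(inherits(config, "gen_config"))
  if (!is_calibrated(config))
    stop("config is not calibrated; run calibrate_sex_cs_distributions() first",
         call. = FALSE)
  n <- config$n_athletes
  nv <- config$n_pacing_violators + config$n_vp_violators
  if (nv > n)
    stop(sprintf("%d violators requested for only %d athletes", nv, n),
         call. = FALSE)
  if (n == 0) {
    return(data.frame(id = integer(0), sex = integer(0), true_cs = numeric(0),
                      true_dprime = numeric(0), true_vo2max = numeric(0),
                      true_get = numeric(0), mass_kg = numeric(0),
                      is_pacing_violator = logical(0),
                      is_vp_violator = logical(0)))
  }
  old <- .Random.seed_store()
  on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(config$seed, 2L))

  sex <- stats::rbinom(n, 1, config$male_fraction)
  mu <- ifelse(sex == 1, config$cs_mean_male, config$cs_mean_female)
  sd_cs <- ifelse(sex == 1, config$cs_sd_male, config$cs_sd_female)
  cs <- rnorm_trunc(n, mu, sd_cs, lower = 1.0)
  dprime <- rnorm_trunc(n, config$dprime_mean, config$dprime_sd, lower = 50)
  vo2 <- config$coef_cs * cs + config$coef_sex * sex + config$intercept +
    stats::rnorm(n, 0, config$residual_sd)
  mass <- rnorm_trunc(n, config$mass_mean, config$mass_sd, lower = 45)

  data.frame(
    id = seq_len(n), sex = sex, true_cs = cs, true_dprime = dprime,
    true_vo2max = vo2, true_get = config$get_fraction * vo2, mass_kg = mass,
    is_pacing_violator = seq_len(n) <= config$n_pacing_violators,
    is_vp_violator = seq_len(n) > config$n_pacing_violators &
      seq_len(n) <= nv)
}

# truncated-normal sampling by vectorized rejection (truncation sits far in
# the lower tail for all defaults, so resampling is rare)
rnorm_trunc <- function(n, mean, sd, lower) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x <= lower)
  guard <- 0L
  while (length(bad)) {
    x[bad] <- stats::rnorm(length(bad), if (length(mean) > 1) mean[bad] else mean,
                           if (length(sd) > 1) sd[bad] else sd)
    bad <- bad[x[bad] <= lower]
    guard <- guard + 1L
    if (guard > 1000L) { x[bad] <- lower + 1e-6; break }
  }
  x
}
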