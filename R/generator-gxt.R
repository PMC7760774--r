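# GXT renderer: emulates a ramp treadmill test with a one-minute metabolic
# lag, a VCO2-vs-VO2 breakpoint at the gas exchange threshold, volitional
# exhaustion shortly after demand exceeds VO2max, and a supramaximal
# square-wave verification bout.

GRADE_RAMP <- 0.03

flat_factor <- function(grade) 1 + (DEMAND_VERT / DEMAND_SLOPE) * grade

# Athlete-specific running-economy slope (demand per flat m/min), solved so
# the protocol-measured 50%-delta centres on fifty_delta_ratio * true CS.
# The quarter-stage binning and lag conventions of the extraction introduce
# a systematic +1 quarter-stage offset in the measured 50%-delta, corrected
# analytically inside the fixed-point iteration (the increment depends on
# the economy slope and vice versa).
athlete_economy <- function(truth, config) {
  vmax <- truth$true_vo2max
  cs <- truth$true_cs
  mid <- (1 + config$get_fraction) / 2
  target_ms <- config$fifty_delta_ratio * cs     # m/s flat
  dur <- config$gxt_target_duration
  bias <- 0
  c1 <- NA_real_
  for (it in 1:6) {
    c1 <- (mid * vmax - DEMAND_REST) / (60 * (target_ms - bias))
    prot <- generator_protocol(vmax, c1, dur, config$get_fraction)
    quarter_ms <- prot$increment_per_min / 4 * flat_factor(GRADE_RAMP) * MPH_TO_MS
    bias <- quarter_ms   # +1 quarter-stage measured-50%-delta offset
  }
  if (!is.finite(c1) || c1 < 0.05 || c1 > 0.5)
    stop(sprintf(
      "athlete economy slope %.3f outside plausible range; CS %.2f and VO2max %.1f are inconsistent",
      c1, cs, vmax), call. = FALSE)
  list(c1 = c1, protocol = prot)
}

# Individualized ramp: peak demand 5% above true VO2max at the target
# duration; start speed is 5 mph unless the athlete's threshold demand sits
# close to the 5-mph demand, in which case the start is lowered so a solid
# fraction of the ramp lies under the threshold and the v-slope lower
# segment has genuine support.
generator_protocol <- function(vmax, c1, dur, get_fraction) {
  get <- get_fraction * vmax
  margin <- max(2, 0.45 * (vmax - get))
  start_cap <- speed_for_demand(get - margin, c1) /
    (MPH_TO_MMIN * flat_factor(GRADE_RAMP))
  start <- min(5, start_cap)
  if (start < 1)
    stop("athlete too slow for a runnable ramp protocol", call. = FALSE)
  design_protocol(1.05 * vmax, target_duration = dur, start_speed = start,
                  grade = GRADE_RAMP, economy_slope = c1)
}

athlete_demand <- function(speed_mph, c1, grade = GRADE_RAMP) {
  DEMAND_REST + c1 * speed_mph * MPH_TO_MMIN * flat_factor(grade)
}

vco2_of_vo2 <- function(vo2, get, config) {
  ifelse(vo2 <= get,
         config$vslope_slope_below * vo2,
         config$vslope_slope_below * get +
           config$vslope_slope_above * (vo2 - get))
}

#' Render a ramp + verification gas-exchange series for one athlete
#'
#' Phases: rest (2 min), walking warm-up (5 min), individualized ramp
#' (terminated ~30 s after metabolic demand first exceeds true VO2max),
#' walking recovery (10 min) and a supramaximal square-wave verification
#' bout at 105% of the peak ramp speed. Ramp VO2 in each 15-s window is the
#' athlete's demand at the quarter-stage speed one minute earlier, capped at
#' true VO2max; VCO2 is piecewise linear in VO2 with the configured slopes
#' below/above the gas exchange threshold. The verification plateau is
#' `true VO2max * (1 + Normal(0, vp_noise_sd))` for non-violators and
#' `true VO2max * 1.05` for flagged verification violators. White noise
#' (`gas_noise_sd` per 1-Hz sample) is added to both gas channels.
#'
#' @param truth one-row athlete truth
#' @param config the [gen_config()]
#' @param protocol optional [gxt_protocol()]; designed from the athlete's
#'   economy when omitted
#' @param seed optional integer seed (defaults derived from `config$seed`
#'   and the athlete id)
#' @param noiseless logical; render without gas noise or verification-bout
#'   biological scatter (used for calibration and oracle tests)
#' @return data frame with columns `time_s`, `vo2`, `vco2`, `speed`,
#'   `speed_unit`, `grade`, `phase`; the protocol used is attached as
#'   attribute `"protocol"`
#' @export
render_gxt_series <- function(truth, config, protocol = NULL, seed = NULL,
                              noiseless = FALSE) {
  stopifnot(inherits(config, "gen_config"))
  eco <- athlete_economy(truth, config)
  c1 <- eco$c1
  if (is.null(protocol)) protocol <- eco$protocol
  vmax <- truth$true_vo2max
  get <- truth$true_get
  inc <- protocol$increment_per_min
  start <- protocol$start_speed

  quarter_speed <- function(i) start + inc * i / 4       # mph, i >= 0
  warm_speed <- protocol$warmup_speed
  warm_vo2 <- athlete_demand(warm_speed, c1, grade = 0)

  # ramp bins: VO2 of bin j responds to the quarter-stage speed at j - 4;
  # during the first minute the response rises smoothly from the warm-up
  # level toward the ramp-start demand (the lag is a first-order
  # on-transient, not a pure delay)
  d_start <- athlete_demand(quarter_speed(0), c1)
  demand_at_bin <- function(j) {
    ifelse(j < 4, warm_vo2 + (d_start - warm_vo2) * (j + 1) / 5,
           pmin(vmax, athlete_demand(quarter_speed(j - 4), c1)))
  }
  # first capped bin, then 1 more bin of sustained effort to exhaustion
  j <- 4
  while (athlete_demand(quarter_speed(j - 4), c1) < vmax) {
    j <- j + 1
    if (j > 120)
      stop("ramp would exceed 26 min: protocol mis-designed", call. = FALSE)
  }
  n_ramp_bins <- j + 2
  if (n_ramp_bins * 15 > 26 * 60)
    stop("ramp would exceed 26 min: protocol mis-designed", call. = FALSE)
  if (n_ramp_bins < 8)
    stop("ramp too short for threshold detection: protocol mis-designed",
         call. = FALSE)
  ramp_bin_vo2 <- demand_at_bin(seq_len(n_ramp_bins) - 1)
  ramp_bin_speed <- quarter_speed(seq_len(n_ramp_bins) - 1)
  peak_speed <- max(ramp_bin_speed)

  # seeded stream for this athlete's gas measurement (plateau scatter + noise)
  if (!noiseless) {
    old <- .Random.seed_store(); on.exit(.Random.seed_restore(old), add = TRUE)
    if (is.null(seed)) seed <- derive_seed(config$seed, 30000L + as.integer(truth$id))
    set.seed(seed)
  }
  # verification plateau level
  eps <- if (isTRUE(truth$is_vp_violator)) {
    0.05
  } else if (noiseless) {
    0
  } else {
    stats::rnorm(1, 0, config$vp_noise_sd)
  }
  vp_level <- vmax * (1 + eps)

  # assemble phases at 1 Hz; every phase length is a multiple of 15 s
  rest_vo2 <- rep(5, 120)
  warmup_vo2 <- rep(warm_vo2, 300)
  ramp_vo2 <- rep(ramp_bin_vo2, each = 15)
  last_ramp <- ramp_bin_vo2[n_ramp_bins]
  recovery_vo2 <- seq(last_ramp, 12, length.out = 600)
  # verification: 60-s on-transient then a 90-s plateau
  verif_vo2 <- c(seq(0.6 * vp_level, vp_level, length.out = 60),
                 rep(vp_level, 90))

  vo2 <- c(rest_vo2, warmup_vo2, ramp_vo2, recovery_vo2, verif_vo2)
  vco2 <- vco2_of_vo2(vo2, get, config)
  n_tot <- length(vo2)
  phase <- c(rep("rest", 120), rep("warmup", 300),
             rep("ramp", length(ramp_vo2)), rep("recovery", 600),
             rep("verification", 150))
  speed <- c(rep(0, 120), rep(warm_speed, 300),
             rep(ramp_bin_speed, each = 15), rep(2.5, 600),
             rep(1.05 * peak_speed, 150))
  grade <- c(rep(0, 120), rep(0, 300), rep(GRADE_RAMP, length(ramp_vo2)),
             rep(0, 600), rep(GRADE_RAMP, 150))

  if (!noiseless && config$gas_noise_sd > 0) {
    vo2 <- pmax(vo2 + stats::rnorm(n_tot, 0, config$gas_noise_sd), 0)
    vco2 <- pmax(vco2 + stats::rnorm(n_tot, 0, config$gas_noise_sd), 0)
  }

  out <- data.frame(
    time_s = seq_len(n_tot) - 1, vo2 = vo2, vco2 = vco2,
    speed = speed, speed_unit = "mph", grade = grade, phase = phase)
  attr(out, "protocol") <- protocol
  out
}

# deterministic expected 50%-delta: the noiseless series pushed through the
# real GXT processing path
expected_fifty_delta <- function(truth, config) {
  series <- render_gxt_series(truth, config, noiseless = TRUE)
  res <- process_gxt(series, attr(series, "protocol"))
  res$fifty_delta
}
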