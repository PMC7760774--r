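# All-out speed-profile family
#
# A valid all-out effort decays from a sprint start S0 exactly to CS at
# 150 s and holds CS to 180 s:
#   speed(t) = CS + (S0 - CS) * (exp(-t/tau) - exp(-150/tau)) /
#              (1 - exp(-150/tau))   for t in [0, 150)
#   speed(t) = CS                    for t in [150, 180]
# S0 is solved so the 1-Hz sum of (speed - CS) over t = 0..149 equals D',
# which makes the 3MT extraction recover CS and D' exactly on the noiseless
# profile (the discrete sum, not the continuous integral, is what the
# extraction measures).

# sum over t = 0..149 of (exp(-t/tau) - E)/(1 - E), E = exp(-150/tau)
allout_profile_factor <- function(tau) {
  E <- exp(-150 / tau)
  r1 <- exp(-1 / tau)
  ((1 - E) / (1 - r1) - 150 * E) / (1 - E)
}

# Solve the sprint start for a given decay constant; when the implied start
# exceeds 12 m/s (an implausible sprint) the decay constant is raised so the
# same D' is spread over a slower decay with start speed 11.5 m/s - athletes
# with a large D' hold back the opening sprint rather than run impossibly
# fast. CS/D' recovery is exact for any tau, so adaptation does not touch
# the round-trip contract. Truly inconsistent inputs still error.
solve_allout_s0 <- function(cs, dprime, tau, adapt = TRUE) {
  s0 <- cs + dprime / allout_profile_factor(tau)
  if (s0 > 12) {
    if (!adapt || cs >= 11.4 ||
        dprime / allout_profile_factor(300) > 11.5 - cs)
      stop(sprintf(
        "solved sprint start %.2f m/s exceeds 12 m/s: CS = %.2f, D' = %.0f and tau = %.0f are inconsistent",
        s0, cs, dprime, tau), call. = FALSE)
    tau <- stats::uniroot(
      function(tt) allout_profile_factor(tt) - dprime / (11.5 - cs),
      lower = tau, upper = 300, tol = 1e-6)$root
    s0 <- cs + dprime / allout_profile_factor(tau)
  }
  list(s0 = s0, tau = tau)
}

# noiseless 1-Hz profile over t = 0..180 (181 samples)
allout_profile_speeds <- function(cs, dprime, tau) {
  sol <- solve_allout_s0(cs, dprime, tau)
  E <- exp(-150 / sol$tau)
  t <- 0:149
  decay <- cs + (sol$s0 - cs) * (exp(-t / sol$tau) - E) / (1 - E)
  c(decay, rep(cs, 31))
}

#' Render a 3-minute all-out speed trace for one athlete
#'
#' Produces the noiseless decay-to-CS profile for the athlete's true CS and
#' D', adds white GPS speed noise (`gps_noise_sd` per 1-Hz sample, clipped at
#' zero). The noiseless profile round-trips through [compute_allout()]
#' exactly.
#'
#' @param truth one-row athlete data frame from [sample_athletes()] (or a
#'   list with `true_cs`, `true_dprime`, `id`)
#' @param config the [gen_config()]
#' @param seed optional integer seed; defaults to a seed derived from
#'   `config$seed` and the athlete id
#' @return data frame with `time_s` (0..180) and `speed_mps`
#' @export
render_allout_trace <- function(truth, config, seed = NULL) {
  stopifnot(inherits(config, "gen_config"))
  speeds <- allout_profile_speeds(truth$true_cs, truth$true_dprime, config$tau)
  noisy <- add_speed_noise(speeds, config, seed, truth$id, stream = 10000L)
  data.frame(time_s = 0:180, speed_mps = noisy)
}

#' Render a paced (held-back) all-out trace guaranteed to fail the screen
#'
#' A pacing violation is an effort that is held back early and finishes
#' above true CS. The trace is built from the same profile family but its
#' end-test speed equals `(1 + target_deviation)` times the athlete's
#' expected protocol-measured 50%-delta, so the downstream pacing screen
#' (threshold 3.5%) fails by construction for the default
#' `target_deviation = 0.05`.
#'
#' @param truth one-row athlete truth
#' @param config the [gen_config()]
#' @param target_deviation relative excess of the end-test speed over the
#'   athlete's 50%-delta (default 0.05; values below 0.035 produce a trace
#'   that passes the screen)
#' @param seed optional seed (defaults as in [render_allout_trace()])
#' @return data frame with `time_s`, `speed_mps`
#' @export
render_pacing_violation <- function(truth, config, target_deviation = 0.05,
                                    seed = NULL) {
  stopifnot(inherits(config, "gen_config"))
  if (target_deviation < 0)
    stop("target_deviation must be >= 0", call. = FALSE)
  fifty <- expected_fifty_delta(truth, config)
  cs_end <- (1 + target_deviation) * fifty
  # held-back effort: reduced early surplus above the (inflated) end speed
  dp <- max(0, 0.5 * truth$true_dprime)
  speeds <- allout_profile_speeds(cs_end, dp, config$tau)
  noisy <- add_speed_noise(speeds, config, seed, truth$id, stream = 20000L)
  data.frame(time_s = 0:180, speed_mps = noisy)
}

add_speed_noise <- function(speeds, config, seed, id, stream) {
  if (config$gps_noise_sd == 0) return(speeds)
  old <- .Random.seed_store()
  on.exit(.Random.seed_restore(old))
  if (is.null(seed)) seed <- derive_seed(config$seed, stream + as.integer(id))
  set.seed(seed)
  pmax(speeds + stats::rnorm(length(speeds), 0, config$gps_noise_sd), 0)
}

#' Extract CS for a whole cohort through the trace-rendering path
#'
#' Renders each athlete's all-out trace (noiseless profile plus GPS noise)
#' and runs the 3MT extraction, without materializing per-athlete data
#' frames; this is the path used for large parameter-recovery experiments.
#'
#' @param athletes athlete truths from [sample_athletes()]
#' @param config the [gen_config()]
#' @return data frame with `id`, `cs`, `s150`, `dprime` (extracted values)
#' @export
extract_cs_cohort <- function(athletes, config) {
  stopifnot(inherits(config, "gen_config"))
  n <- nrow(athletes)
  cs <- s150 <- dp <- numeric(n)
  factor <- allout_profile_factor(config$tau)
  E <- exp(-150 / config$tau)
  decay_shape <- (exp(-(0:149) / config$tau) - E) / (1 - E)
  old <- .Random.seed_store()
  on.exit(.Random.seed_restore(old))
  for (i in seq_len(n)) {
    s0 <- athletes$true_cs[i] + athletes$true_dprime[i] / factor
    if (s0 > 12) {
      # slow-decay fallback for large-D' athletes (see solve_allout_s0)
      speeds <- allout_profile_speeds(athletes$true_cs[i],
                                      athletes$true_dprime[i], config$tau)
    } else {
      speeds <- c(athletes$true_cs[i] + (s0 - athletes$true_cs[i]) * decay_shape,
                  rep(athletes$true_cs[i], 31))
    }
    if (config$gps_noise_sd > 0) {
      set.seed(derive_seed(config$seed, 10000L + as.integer(athletes$id[i])))
      speeds <- pmax(speeds + stats::rnorm(181, 0, config$gps_noise_sd), 0)
    }
    res <- allout_from_speeds(speeds)
    cs[i] <- res$cs; s150[i] <- res$s150; dp[i] <- res$dprime
  }
  data.frame(id = athletes$id, cs = cs, s150 = s150, dprime = dp)
}
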