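test_that("gen_config validates its invariants", {
  expect_error(gen_config(male_fraction = 1.2), "male_fraction")
  expect_error(gen_config(cs_sd = -1), "SDs")
  expect_error(gen_config(tau = 0), "tau")
  expect_error(gen_config(get_fraction = 1), "get_fraction")
  expect_error(gen_config(vslope_slope_below = 1.2, vslope_slope_above = 1.1),
               "exceed")
  expect_error(gen_config(n_pacing_violators = -1), "violator")
  expect_s3_class(gen_config(), "gen_config")
})

test_that("calibration hits the pooled CS moments and the target correlation", {
  cfg <- calibrate_sex_cs_distributions(gen_config(seed = 3))
  cal <- attr(cfg, "calibration")
  expect_true(is_calibrated <- !anyNA(c(cfg$cs_mean_male, cfg$cs_sd_male,
                                        cfg$cs_mean_female, cfg$cs_sd_female)))
  expect_equal(cal$r, cfg$target_r, tolerance = 0.01)
  expect_equal(cal$pooled_mean, cfg$cs_mean, tolerance = 0.02)
  expect_equal(cal$pooled_sd, cfg$cs_sd, tolerance = 0.02)
  # moment constraints hold analytically
  p <- cfg$male_fraction
  expect_equal(p * cfg$cs_mean_male + (1 - p) * cfg$cs_mean_female,
               cfg$cs_mean, tolerance = 1e-12)
  expect_equal(cfg$cs_sd_male^2 + p * (1 - p) * cal$gap^2, cfg$cs_sd^2,
               tolerance = 1e-12)
})

test_that("noiseless single-sex model is flagged degenerate (r = 1)", {
  expect_warning(
    cfg <- calibrate_sex_cs_distributions(
      gen_config(male_fraction = 1, residual_sd = 0)),
    "deterministic")
  expect_true(isTRUE(attr(cfg, "degenerate")))
})

test_that("athlete truths follow the linear model and truncations", {
  cfg <- calibrate_sex_cs_distributions(gen_config(n_athletes = 2000, seed = 8))
  ath <- sample_athletes(cfg)
  expect_equal(nrow(ath), 2000)
  expect_true(all(ath$true_cs > 1.0))
  expect_true(all(ath$true_dprime > 50))
  expect_true(all(ath$mass_kg > 45))
  expect_true(all(ath$sex %in% c(0, 1)))
  expect_equal(ath$true_get, cfg$get_fraction * ath$true_vo2max)
  expect_equal(mean(ath$true_cs), cfg$cs_mean, tolerance = 0.05)
  expect_equal(sd(ath$true_cs), cfg$cs_sd, tolerance = 0.05)
  expect_equal(mean(ath$true_dprime), cfg$dprime_mean, tolerance = 5)
  # residuals of the generating model match residual_sd
  resid <- ath$true_vo2max - (cfg$coef_cs * ath$true_cs +
                              cfg$coef_sex * ath$sex + cfg$intercept)
  expect_equal(sd(resid), cfg$residual_sd, tolerance = 0.15)
})

test_that("a noiseless male athlete at CS = 1 gets VO2max 27.519", {
  suppressWarnings(
    cfg <- calibrate_sex_cs_distributions(
      gen_config(n_athletes = 3, male_fraction = 1, residual_sd = 0,
                 cs_mean = 1.0, cs_sd = 0, seed = 4)))
  ath <- sample_athletes(cfg)
  expect_equal(ath$true_vo2max, rep(27.519, 3), tolerance = 1e-3)
})

test_that("violator flags cover the first 9 + 3 athletes and nothing else", {
  cfg <- calibrate_sex_cs_distributions(
    gen_config(n_athletes = 37, n_pacing_violators = 9, n_vp_violators = 3,
               seed = 42))
  ath <- sample_athletes(cfg)
  expect_equal(sum(ath$is_pacing_violator), 9)
  expect_equal(sum(ath$is_vp_violator), 3)
  expect_false(any(ath$is_pacing_violator & ath$is_vp_violator))
  expect_equal(which(ath$is_pacing_violator), 1:9)
  expect_equal(which(ath$is_vp_violator), 10:12)
})

test_that("more violators than athletes is rejected; n = 0 gives empty truths", {
  cfg <- calibrate_sex_cs_distributions(
    gen_config(n_athletes = 5, n_pacing_violators = 4, n_vp_violators = 3))
  expect_error(sample_athletes(cfg), "violators")
  cfg0 <- calibrate_sex_cs_distributions(gen_config(n_athletes = 0))
  expect_equal(nrow(sample_athletes(cfg0)), 0)
})

test_that("same seed gives identical athletes, traces and gas series", {
  cfg <- calibrate_sex_cs_distributions(gen_config(n_athletes = 3, seed = 21))
  a1 <- sample_athletes(cfg)
  a2 <- sample_athletes(cfg)
  expect_identical(a1, a2)
  t1 <- render_allout_trace(a1[1, ], cfg)
  t2 <- render_allout_trace(a1[1, ], cfg)
  expect_identical(t1, t2)
  g1 <- render_gxt_series(a1[1, ], cfg)
  g2 <- render_gxt_series(a1[1, ], cfg)
  expect_identical(g1, g2)
})

test_that("inconsistent CS/D'/tau combinations are rejected", {
  cfg <- gen_config(gps_noise_sd = 0)
  expect_error(
    render_allout_trace(list(id = 1L, true_cs = 11.45, true_dprime = 400), cfg),
    "exceeds 12")
})

test_that("large-D' athletes adapt the decay rather than sprint impossibly", {
  cfg <- gen_config(gps_noise_sd = 0)
  trace <- render_allout_trace(list(id = 1L, true_cs = 3.0,
                                    true_dprime = 330), cfg)
  expect_lt(max(trace$speed_mps), 12)
  res <- compute_allout(trace)
  expect_equal(res$cs, 3.0, tolerance = 1e-9)
  expect_lt(abs(res$dprime - 330), 2)
})

test_that("pacing violation renders to the requested end-test deviation", {
  cfg <- calibrate_sex_cs_distributions(gen_config(gps_noise_sd = 0, seed = 12))
  truth <- data.frame(id = 1L, sex = 1, true_cs = 3.6, true_dprime = 200,
                      true_vo2max = 8.449 * 3.6 + 4.387 + 14.683,
                      true_get = NA, is_pacing_violator = TRUE,
                      is_vp_violator = FALSE)
  truth$true_get <- cfg$get_fraction * truth$true_vo2max
  # measured 50%-delta reference from this athlete's noiseless GXT
  ser <- render_gxt_series(truth, cfg, noiseless = TRUE)
  fifty <- process_gxt(ser, attr(ser, "protocol"))$fifty_delta

  v <- render_pacing_violation(truth, cfg, target_deviation = 0.05)
  cs_v <- compute_allout(v)$cs
  expect_equal(abs(cs_v - fifty) / fifty, 0.05, tolerance = 1e-6)
  expect_false(pacing_check(cs_v, fifty)$pass)

  v0 <- render_pacing_violation(truth, cfg, target_deviation = 0)
  cs_v0 <- compute_allout(v0)$cs
  expect_true(pacing_check(cs_v0, fifty)$pass)
  expect_error(render_pacing_violation(truth, cfg, target_deviation = -0.1),
               ">= 0")
})

test_that("config files round-trip through YAML and JSON", {
  path_y <- tempfile(fileext = ".yaml")
  yaml::write_yaml(list(n_athletes = 12, seed = 77, gps_noise_sd = 0), path_y)
  cfg <- read_gen_config(path_y)
  expect_equal(cfg$n_athletes, 12)
  expect_equal(cfg$seed, 77L)
  expect_equal(cfg$gps_noise_sd, 0)
  path_j <- tempfile(fileext = ".json")
  jsonlite::write_json(list(n_athletes = 5, seed = 3), path_j,
                       auto_unbox = TRUE)
  expect_equal(read_gen_config(path_j)$n_athletes, 5)
  path_bad <- tempfile(fileext = ".yaml")
  yaml::write_yaml(list(not_a_key = 1), path_bad)
  expect_error(read_gen_config(path_bad), "unknown config keys")
  unlink(c(path_y, path_j, path_bad))
})
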