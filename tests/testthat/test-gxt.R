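test_that("bin_15s averages constant data into full bins", {
  ser <- make_series(rep(40, 60))
  b <- bin_15s(ser, "ramp")
  expect_equal(nrow(b), 4)
  expect_equal(b$vo2, rep(40, 4))
  expect_equal(b$time_s, c(15, 30, 45, 60))
})

test_that("bin_15s of a linear ramp equals the analytic mid-bin averages", {
  # vo2 rises linearly 30 -> 42 over 60 samples (t = 0..59)
  vo2 <- 30 + (42 - 30) * (0:59) / 59
  b <- bin_15s(make_series(vo2), "ramp")
  analytic <- vapply(0:3, function(k) mean(vo2[(15 * k + 1):(15 * k + 15)]),
                     numeric(1))
  expect_equal(b$vo2, analytic)
})

test_that("bin_15s drops a partial trailing bin and requires the phase", {
  b <- bin_15s(make_series(rep(40, 70)), "ramp")
  expect_equal(nrow(b), 4)
  expect_error(bin_15s(make_series(rep(40, 60)), "verification"),
               "not present")
  expect_error(bin_15s(make_series(rep(40, 10)), "ramp"), "shorter")
})

test_that("vo2max_two_highest matches the worked examples", {
  b <- data.frame(time_s = c(15, 30, 45, 60), vo2 = c(40, 45, 50, 48))
  vm <- vo2max_two_highest(b)
  expect_equal(vm$vo2max, 49)
  expect_equal(vm$time_s, 60)
  b2 <- data.frame(time_s = c(15, 30, 45, 60), vo2 = c(30, 35, 40, 45))
  expect_equal(vo2max_two_highest(b2)$vo2max, 42.5)
  expect_error(vo2max_two_highest(data.frame(time_s = 15, vo2 = 40)),
               "at least 2")
})

test_that("vo2max_two_highest breaks ties toward the earlier pair", {
  b <- data.frame(time_s = c(15, 30, 45, 60), vo2 = c(50, 48, 48, 50))
  expect_equal(vo2max_two_highest(b)$time_s, 30)
})

test_that("two-highest rule matches the exhaustive pair-scan oracle and is
           invariant to appending lower bins", {
  set.seed(33)
  for (i in 1:20) {
    vo2 <- stats::rnorm(sample(5:40, 1), 45, 4)
    b <- data.frame(time_s = 15 * seq_along(vo2), vo2 = vo2)
    vm <- vo2max_two_highest(b)
    orc <- oracle_two_highest(vo2)
    expect_equal(vm$vo2max, orc$vo2max)
    low <- min(vo2) - 5
    b2 <- rbind(b, data.frame(time_s = max(b$time_s) + c(15, 30),
                              vo2 = c(low, low)))
    expect_equal(vo2max_two_highest(b2)$vo2max, vm$vo2max)
  }
})

test_that("noisy plateau ramp recovers VO2max 50 within 1.0", {
  set.seed(91)
  true_vo2 <- c(seq(30, 50, length.out = 20), rep(50, 8))
  b <- data.frame(time_s = 15 * seq_along(true_vo2),
                  vo2 = true_vo2 + stats::rnorm(length(true_vo2), 0, 1))
  expect_lt(abs(vo2max_two_highest(b)$vo2max - 50), 1.0)
})

test_that("noiseless v-slope finds the true break within half a bin spacing", {
  vo2 <- seq(20, 45, by = 0.5)
  vco2 <- ifelse(vo2 <= 32.5, 0.85 * vo2,
                 0.85 * 32.5 + 1.15 * (vo2 - 32.5))
  b <- data.frame(time_s = 15 * seq_along(vo2), vo2 = vo2, vco2 = vco2)
  vs <- detect_get_vslope(b)
  expect_true(vs$found)
  expect_lt(abs(vs$get_vo2 - 32.5), 0.25)
  expect_equal(vs$slope_below, 0.85, tolerance = 1e-6)
  expect_equal(vs$slope_above, 1.15, tolerance = 1e-6)
})

test_that("perfectly linear VCO2-VO2 reports no breakpoint", {
  vo2 <- seq(20, 45, by = 0.5)
  b <- data.frame(time_s = 15 * seq_along(vo2), vo2 = vo2, vco2 = 0.9 * vo2)
  vs <- detect_get_vslope(b)
  expect_false(vs$found)
  expect_true(is.na(vs$get_vo2))
})

test_that("v-slope needs at least 8 ramp bins", {
  b <- data.frame(time_s = 15 * 1:7, vo2 = 1:7, vco2 = 1:7)
  expect_error(detect_get_vslope(b), "at least 8")
})

test_that("v-slope equals the brute-force breakpoint oracle (property)", {
  set.seed(17)
  for (i in 1:15) {
    n <- sample(12:60, 1)
    brk <- runif(1, 27, 38)
    vo2 <- seq(20, 45, length.out = n) + stats::rnorm(n, 0, 0.3)
    clean <- seq(20, 45, length.out = n)
    vco2 <- ifelse(clean <= brk, 0.85 * clean,
                   0.85 * brk + 1.15 * (clean - brk)) + stats::rnorm(n, 0, 0.3)
    b <- data.frame(time_s = 15 * seq_len(n), vo2 = vo2, vco2 = vco2)
    vs <- detect_get_vslope(b)
    orc <- oracle_vslope(b)
    expect_equal(vs$found, is.finite(orc$rss))
    if (vs$found) {
      expect_equal(vs$split_index, orc$k)
      expect_equal(vs$get_vo2, orc$get_vo2, tolerance = 1e-8)
      expect_equal(vs$rss, orc$rss, tolerance = 1e-8)
    }
  }
})

test_that("lagged_speed_at applies the one-minute lag in quarter-stages", {
  p <- gxt_protocol(start_speed = 5, increment_per_min = 0.5)
  # bin ending at t = 75 s has index j = 4; lag 4 -> speed index 0
  s <- lagged_speed_at(p, 75)
  expect_equal(as.numeric(s), 5)
  expect_false(attr(s, "clamped"))
  # one bin later: one quarter-stage up
  expect_equal(as.numeric(lagged_speed_at(p, 90)), 5 + 0.5 / 4)
  # early bins clamp to the ramp start
  s2 <- lagged_speed_at(p, 30)
  expect_equal(as.numeric(s2), 5)
  expect_true(attr(s2, "clamped"))
  expect_error(lagged_speed_at(p, 300, ramp_duration = 200), "beyond")
  expect_error(lagged_speed_at(p, 5), "precedes")
})

test_that("flat_equivalent implements metabolic equivalence at 3% grade", {
  # demand 3.5 + 0.2 S + 0.9 S G  ->  flat = S (1 + 4.5 G)
  expect_equal(flat_equivalent(2, 0, unit = "mps"), 2)
  expect_equal(flat_equivalent(2, 0.03, unit = "mps"), 2 * 1.135)
  expect_equal(flat_equivalent(5, 0.03, unit = "mph"),
               5 * 1.135 * 0.44704)
  expect_error(flat_equivalent(2, -0.01, "mps"), ">= 0")
})

test_that("noiseless generated GXT recovers VO2max, GET and 50%-delta", {
  cfg <- calibrate_sex_cs_distributions(gen_config(seed = 5))
  truth <- data.frame(id = 1L, sex = 0, true_cs = 3.56, true_dprime = 208,
                      true_vo2max = 8.449 * 3.56 + 14.683,
                      true_get = 0.65 * (8.449 * 3.56 + 14.683),
                      is_pacing_violator = FALSE, is_vp_violator = FALSE)
  ser <- render_gxt_series(truth, cfg, noiseless = TRUE)
  prot <- attr(ser, "protocol")
  res <- process_gxt(ser, prot)
  expect_equal(res$vo2max, truth$true_vo2max, tolerance = 1e-9)
  # GET within one bin's demand increment of the true threshold
  bin_inc <- diff(sort(res$binned$vo2))
  expect_lt(abs(res$get_vo2 - truth$true_get), max(bin_inc) + 1e-9)
  # 50%-delta within the honest discretization bound (2 quarter-stages)
  quarter <- prot$increment_per_min / 4 * 1.135 * 0.44704
  target <- cfg$fifty_delta_ratio * truth$true_cs
  expect_lt(abs(res$fifty_delta - target), 2 * quarter)
  expect_lt(abs(res$fifty_delta - target), 0.05)
})

test_that("verification acceptance is inclusive at 3%", {
  mk_vp <- function(level) {
    data.frame(time_s = 0:149, vo2 = rep(level, 150), vco2 = rep(level, 150),
               phase = "verification")
  }
  r <- process_verification(50, mk_vp(49))
  expect_equal(r$relative_difference, 0.02)
  expect_true(r$accepted)
  expect_true(process_verification(50, mk_vp(48.5))$accepted)   # exactly 3%
  expect_false(process_verification(50, mk_vp(47))$accepted)    # 6%
  expect_error(process_verification(50, make_series(rep(50, 60))), "missing")
})

test_that("design_protocol spans start speed to the demand-matched peak", {
  p <- design_protocol(47, target_duration = 10)
  expect_s3_class(p, "gxt_protocol")
  # peak speed after 10 min has demand equal to the predicted VO2max
  peak <- p$start_speed + p$increment_per_min * 10
  demand <- 3.5 + 0.2 * peak * 26.8224 * 1.135
  expect_equal(demand, 47, tolerance = 1e-9)
  expect_error(design_protocol(47, target_duration = 7), "8-12")
  expect_error(design_protocol(47, target_duration = 13), "8-12")
  expect_error(design_protocol(10), "at or below")
})

test_that("gas series read/validate round trip", {
  cfg <- calibrate_sex_cs_distributions(gen_config(seed = 6))
  truth <- data.frame(id = 2L, sex = 1, true_cs = 3.8, true_dprime = 190,
                      true_vo2max = 8.449 * 3.8 + 4.387 + 14.683,
                      true_get = 0.65 * (8.449 * 3.8 + 4.387 + 14.683),
                      is_pacing_violator = FALSE, is_vp_violator = FALSE)
  ser <- render_gxt_series(truth, cfg)
  path <- tempfile(fileext = ".csv")
  utils::write.csv(ser, path, row.names = FALSE)
  back <- read_gas_series(path)
  expect_equal(back$vo2, ser$vo2)
  expect_error(read_gas_series({
    p2 <- tempfile(fileext = ".csv")
    utils::write.csv(data.frame(a = 1), p2, row.names = FALSE)
    p2
  }), "columns")
  unlink(path)
})
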