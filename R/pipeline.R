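#' Simulate a full synthetic cohort
#'
#' Calibrates the configuration if needed, samples athlete truths and
#' renders per-athlete all-out traces (pacing violators through the
#' held-back renderer) and, optionally, ramp + verification gas-exchange
#' series (verification violators with the offset plateau).
#'
#' @param config a [gen_config()]
#' @param include_gxt render gas-exchange series as well as speed traces
#' @param out_dir optional directory; when given, traces and series are
#'   written as CSVs together with a `manifest.csv`
#' @return list with `config` (calibrated), `athletes`, `traces` (list of
#'   data frames) and `gxt` (list of series, or `NULL`)
#' @export
simulate_cohort <- function(config, include_gxt = TRUE, out_dir = NULL) {
  stopifnot(inherits(config, "gen_config"))
  if (!is_calibrated(config)) config <- calibrate_sex_cs_distributions(config)
  athletes <- sample_athletes(config)
  n <- nrow(athletes)
  traces <- vector("list", n)
  gxt <- if (include_gxt) vector("list", n) else NULL
  for (i in seq_len(n)) {
    truth <- athletes[i, ]
    traces[[i]] <- if (truth$is_pacing_violator) {
      # inject at 10% so the violation clears the 3.5% screen by many
      # multiples of the ~1.3% measurement noise on the 50%-delta reference
      render_pacing_violation(truth, config, target_deviation = 0.10)
    } else {
      render_allout_trace(truth, config)
    }
    if (include_gxt) gxt[[i]] <- render_gxt_series(truth, config)
  }
  out <- list(config = config, athletes = athletes, traces = traces, gxt = gxt)
  if (!is.null(out_dir)) write_cohort_files(out, out_dir)
  out
}

write_cohort_files <- function(sim, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  n <- nrow(sim$athletes)
  trace_file <- gxt_file <- character(n)
  for (i in seq_len(n)) {
    trace_file[i] <- sprintf("athlete%03d_3mt.csv", sim$athletes$id[i])
    utils::write.csv(sim$traces[[i]], file.path(out_dir, trace_file[i]),
                     row.names = FALSE)
    if (!is.null(sim$gxt)) {
      gxt_file[i] <- sprintf("athlete%03d_gxt.csv", sim$athletes$id[i])
      utils::write.csv(sim$gxt[[i]], file.path(out_dir, gxt_file[i]),
                       row.names = FALSE)
    }
  }
  manifest <- data.frame(id = sim$athletes$id, sex = sim$athletes$sex,
                         mass_kg = sim$athletes$mass_kg,
                         trace_file = trace_file, gxt_file = gxt_file)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(out_dir)
}

#' Run the full field-test analysis pipeline on a synthetic cohort
#'
#' Orchestrates simulate, 3MT processing, GXT + verification processing,
#' quality control, model fitting, prediction and reliability statistics as
#' one seeded, reproducible run.
#'
#' @param config a [gen_config()], or the path to a YAML/JSON config file
#' @param out_dir optional output directory for `cohort.csv` and
#'   `report.json`
#' @return object of class `run_report`: list with `config`, `cohort` (the
#'   per-athlete table), `qc_summary`, `fit` ([fit_stepwise()] result),
#'   `comparison` (observed vs fitted), `reliability`
#'   ([reliability_report()] of observed vs model-predicted VO2max) and
#'   `counts`
#' @export
run_full <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- read_gen_config(config)
  stopifnot(inherits(config, "gen_config"))
  if (config$n_athletes == 0)
    stop("empty cohort: nothing to analyse", call. = FALSE)

  sim <- simulate_cohort(config, include_gxt = TRUE)
  athletes <- sim$athletes
  n <- nrow(athletes)

  rows <- vector("list", n)
  for (i in seq_len(n)) {
    id <- athletes$id[i]
    allout <- tryCatch(compute_allout(sim$traces[[i]]),
      error = function(e) stop(sprintf("stage '3mt', athlete %d: %s",
                                       id, conditionMessage(e)), call. = FALSE))
    series <- sim$gxt[[i]]
    gres <- tryCatch(process_gxt(series, attr(series, "protocol")),
      error = function(e) stop(sprintf("stage 'gxt', athlete %d: %s",
                                       id, conditionMessage(e)), call. = FALSE))
    vres <- process_verification(gres$vo2max, series)
    rows[[i]] <- data.frame(
      id = id, sex = athletes$sex[i], mass_kg = athletes$mass_kg[i],
      cs = allout$cs, s150 = allout$s150, dprime = allout$dprime,
      vo2max_ramp = gres$vo2max, vo2max_vp = vres$vp_vo2max,
      get_vo2 = gres$get_vo2, fifty_delta = gres$fifty_delta)
  }
  cohort <- do.call(rbind, rows)

  qc <- apply_qc(cohort)
  valid <- qc$valid
  if (nrow(valid) < 5)
    stop(sprintf("only %d athletes passed QC; cannot fit the model",
                 nrow(valid)), call. = FALSE)
  valid$vo2max <- valid$vo2max_ramp
  fit <- fit_stepwise(valid)
  comparison <- compare_observed_predicted(valid, fit)
  predicted <- predict_vo2max(valid$cs, valid$sex, fit)
  reliability <- reliability_report(valid$vo2max, predicted)

  cohort$predicted_vo2max <- predict_vo2max(cohort$cs, cohort$sex, fit)
  qcall <- rbind(qc$valid, qc$excluded)
  qcall <- qcall[match(cohort$id, qcall$id), ]
  cohort$excluded <- qcall$excluded
  cohort$reason <- qcall$reason

  report <- structure(
    list(config = sim$config, cohort = cohort, qc_summary = qc$summary,
         fit = fit, comparison = comparison, reliability = reliability,
         counts = list(n_input = n, n_valid = qc$summary$n_valid,
                       n_excluded = qc$summary$n_excluded),
         seed = config$seed,
         version = as.character(utils::packageVersion("critspeed"))),
    class = "run_report")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_cohort(cohort, file.path(out_dir, "cohort.csv"))
    fit_json <- fit[c("coef_cs", "coef_sex", "intercept", "see",
                      "r2_model1", "r2_model2", "n", "included_terms")]
    jsonlite::write_json(
      list(counts = report$counts, qc = qc$summary, fit = fit_json,
           reliability = unclass(reliability), seed = config$seed),
      file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE)
  }
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("Field-test analysis run\n")
  cat(sprintf("  cohort: %d in, %d valid, %d excluded (%d pacing, %d verification, %d both)\n",
              x$counts$n_input, x$counts$n_valid, x$counts$n_excluded,
              x$qc_summary$n_pacing, x$qc_summary$n_verification,
              x$qc_summary$n_both))
  print(x$fit)
  print(x$reliability)
  invisible(x)
}

COHORT_REQUIRED <- c("id", "sex", "mass_kg", "cs", "s150", "dprime",
                     "vo2max_ramp", "vo2max_vp", "get_vo2", "fifty_delta")

#' Write a cohort table to CSV
#'
#' @param cohort cohort data frame (schema of [run_full()]'s `cohort`)
#' @param path output CSV path
#' @export
write_cohort <- function(cohort, path) {
  miss <- setdiff(COHORT_REQUIRED, names(cohort))
  if (length(miss))
    stop("cohort is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  utils::write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' Read a cohort table from CSV
#'
#' Speed columns carrying an `_mph` unit suffix (`cs_mph`, `s150_mph`,
#' `fifty_delta_mph`) are converted to m/s (factor 0.44704) and renamed to
#' the internal m/s names; unknown columns are preserved.
#'
#' @param path CSV path
#' @return cohort data frame with all speeds in m/s
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path)
  for (nm in grep("_mph$", names(df), value = TRUE)) {
    base <- sub("_mph$", "", nm)
    df[[base]] <- df[[nm]] * MPH_TO_MS
    df[[nm]] <- NULL
  }
  miss <- setdiff(COHORT_REQUIRED, names(df))
  if (length(miss))
    stop("cohort file is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(df$id))
    stop("cohort ids must be unique", call. = FALSE)
  df
}
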