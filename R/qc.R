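#' Pacing screen: critical speed against 50%-delta
#'
#' A valid all-out effort ends at a speed close to the mean of the speeds at
#' GET and VO2max (50%-delta). A relative deviation of 3.5% or more flags an
#' inaccurate and/or inflated CS due to pacing; the deviation is computed
#' against the GXT-derived 50%-delta.
#'
#' @param cs critical speed, m/s
#' @param fifty_delta 50%-delta speed, m/s
#' @return list with `pass` (logical) and `deviation` (proportion)
#' @export
pacing_check <- function(cs, fifty_delta) {
  stopifnot_scalar(cs, "cs", positive = TRUE)
  stopifnot_scalar(fifty_delta, "fifty_delta", positive = TRUE)
  deviation <- abs(cs - fifty_delta) / fifty_delta
  list(pass = deviation < 0.035, deviation = deviation)
}

#' Verification screen for cohort bookkeeping
#'
#' Mirrors the acceptance decision of [process_verification()] (relative
#' difference within 3%, inclusive), exposed so cohort-level QC and the
#' per-test processing share one rule.
#'
#' @param result list with `relative_difference` (and optionally `accepted`)
#'   as returned by [process_verification()]
#' @return list with `pass` and `deviation`
#' @export
vp_check <- function(result) {
  if (!is.list(result) || is.null(result$relative_difference))
    stop("result must be a verification result with 'relative_difference'",
         call. = FALSE)
  dev <- result$relative_difference
  list(pass = dev <= 0.03, deviation = dev)
}

#' Apply both quality-control screens to a cohort
#'
#' Each athlete needs a CS, a 50%-delta and a ramp/verification VO2max pair.
#' Athletes failing either screen are excluded; an athlete failing both is
#' excluded once with reason `"both"`. Ordering is preserved and the valid
#' and excluded sets partition the input.
#'
#' @param cohort data frame with columns `id`, `cs`, `fifty_delta`,
#'   `vo2max_ramp`, `vo2max_vp` (additional columns are carried through)
#' @return list with `valid` and `excluded` data frames (each augmented with
#'   `pacing_pass`, `pacing_deviation`, `vp_pass`, `vp_deviation`,
#'   `excluded`, `reason`) and a `summary` list of counts by reason
#' @export
apply_qc <- function(cohort) {
  need <- c("id", "cs", "fifty_delta", "vo2max_ramp", "vo2max_vp")
  miss_col <- setdiff(need, names(cohort))
  if (length(miss_col))
    stop("cohort is missing columns: ", paste(miss_col, collapse = ", "),
         call. = FALSE)
  incomplete <- cohort$id[!stats::complete.cases(cohort[need])]
  if (length(incomplete))
    stop("incomplete records for ids: ", paste(incomplete, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(cohort$id))
    stop("cohort ids must be unique", call. = FALSE)

  n <- nrow(cohort)
  pacing_pass <- logical(n); pacing_dev <- numeric(n)
  vp_pass <- logical(n); vp_dev <- numeric(n)
  for (i in seq_len(n)) {
    pc <- pacing_check(cohort$cs[i], cohort$fifty_delta[i])
    vc <- vp_check(list(relative_difference =
      abs(cohort$vo2max_ramp[i] - cohort$vo2max_vp[i]) / cohort$vo2max_ramp[i]))
    pacing_pass[i] <- pc$pass; pacing_dev[i] <- pc$deviation
    vp_pass[i] <- vc$pass; vp_dev[i] <- vc$deviation
  }
  excluded <- !(pacing_pass & vp_pass)
  reason <- rep("none", n)
  reason[!pacing_pass & vp_pass] <- "pacing"
  reason[pacing_pass & !vp_pass] <- "verification"
  reason[!pacing_pass & !vp_pass] <- "both"

  out <- cohort
  out$pacing_pass <- pacing_pass
  out$pacing_deviation <- pacing_dev
  out$vp_pass <- vp_pass
  out$vp_deviation <- vp_dev
  out$excluded <- excluded
  out$reason <- reason

  summary <- list(
    n_input = n,
    n_valid = sum(!excluded),
    n_excluded = sum(excluded),
    n_pacing = sum(reason == "pacing"),
    n_verification = sum(reason == "verification"),
    n_both = sum(reason == "both"))

  list(valid = out[!excluded, , drop = FALSE],
       excluded = out[excluded, , drop = FALSE],
       summary = summary)
}
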