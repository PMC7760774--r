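# internal constants and small helpers shared across modules

# 1 mph in m/s and m/min
MPH_TO_MS <- 0.44704
MPH_TO_MMIN <- 26.8224

# resting component of the running metabolic-demand equation, mL/kg/min
DEMAND_REST <- 3.5
# standard demand slope per flat speed, (mL/kg/min)/(m/min)
DEMAND_SLOPE <- 0.2
# vertical demand coefficient, (mL/kg/min)/(m/min of vertical-equivalent)
DEMAND_VERT <- 0.9

#' Running metabolic demand of a treadmill speed and grade
#'
#' Demand (mL/kg/min) = 3.5 + slope * S + 0.9 * S * G with S in m/min and G a
#' fraction. The `slope` argument allows an individual running-economy slope;
#' the default 0.2 is the standard value for level running.
#'
#' @param speed_mmin speed in m/min
#' @param grade fractional incline (0.03 = 3%)
#' @param slope demand per flat speed, (mL/kg/min)/(m/min)
#' @return demand in mL/kg/min
#' @keywords internal
running_demand <- function(speed_mmin, grade = 0, slope = DEMAND_SLOPE) {
  DEMAND_REST + slope * speed_mmin + DEMAND_VERT * speed_mmin * grade
}

# inverse of running_demand for the flat-equivalent speed (m/min)
speed_for_demand <- function(demand, slope = DEMAND_SLOPE) {
  (demand - DEMAND_REST) / slope
}

stopifnot_scalar <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a finite numeric scalar", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("'%s' must be > 0", name), call. = FALSE)
  invisible(x)
}

# deterministic child seed from a base seed and a stream index (kept < 2^31)
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(index) * 16807) %% 2147483647)
}
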