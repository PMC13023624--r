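#' Normalize a gas volume to standard temperature and pressure
#'
#' Ideal-gas conversion of a volume logged at meter conditions to standard
#' conditions (273.15 K, 101.325 kPa), as conventional for reporting biogas
#' volumes from batch digesters.
#'
#' @param volume Volume in mL at meter conditions (>= 0). Vectorised.
#' @param temperature Meter temperature in K (> 0).
#' @param pressure Meter pressure in kPa (> 0).
#' @return Volume in mL at 273.15 K / 101.325 kPa.
#' @examples
#' normalize_to_stp(100, 308.15, 101.325)  # mesophilic headspace -> 88.64 mL
#' @export
normalize_to_stp <- function(volume, temperature, pressure) {
  if (any(!is.finite(temperature)) || any(temperature <= 0)) {
    stop("temperature must be positive (K)", call. = FALSE)
  }
  if (any(!is.finite(pressure)) || any(pressure <= 0)) {
    stop("pressure must be positive (kPa)", call. = FALSE)
  }
  if (any(volume < 0)) stop("volume must be non-negative", call. = FALSE)
  volume * (273.15 / temperature) * (pressure / 101.325)
}

#' Validate a gas-log table
#'
#' Checks the invariants of a raw per-channel gas log: strictly increasing
#' time within each channel, non-negative volume increments, positive
#' temperature and pressure, CH4 fraction inside [0, 1] when present.
#'
#' @param records Data frame with columns `channel_id`, `time` (elapsed
#'   hours), `volume_increment` (mL at meter conditions), `temperature` (K),
#'   `pressure` (kPa) and optionally `ch4_fraction`.
#' @return `records`, invisibly, after validation.
#' @export
validate_gas_log <- function(records) {
  needed <- c("channel_id", "time", "volume_increment", "temperature", "pressure")
  missing <- setdiff(needed, names(records))
  if (length(missing)) {
    stop("gas log missing columns: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  for (ch in unique(records$channel_id)) {
    tt <- records$time[records$channel_id == ch]
    if (any(diff(tt) <= 0)) {
      stop("time not strictly increasing in channel ", ch, call. = FALSE)
    }
  }
  if (any(records$volume_increment < 0)) stop("negative volume increment", call. = FALSE)
  if (any(records$temperature <= 0)) stop("non-positive temperature", call. = FALSE)
  if (any(records$pressure <= 0)) stop("non-positive pressure", call. = FALSE)
  if ("ch4_fraction" %in% names(records)) {
    f <- records$ch4_fraction[!is.na(records$ch4_fraction)]
    if (any(f < 0 | f > 1)) stop("ch4_fraction outside [0, 1]", call. = FALSE)
  }
  invisible(records)
}

# Cumulative STP methane (or total gas) for one channel's records, in mL.
channel_cumulative <- function(records, basis = "methane") {
  stp <- normalize_to_stp(records$volume_increment, records$temperature,
                          records$pressure)
  if (basis == "methane") {
    if (!"ch4_fraction" %in% names(records) || anyNA(records$ch4_fraction)) {
      stop("basis = \"methane\" requires a complete ch4_fraction column",
           call. = FALSE)
    }
    stp <- stp * records$ch4_fraction
  }
  data.frame(times = records$time / 24, cumulative = cumsum(stp))
}

#' Blank-corrected specific methane yield curve for one channel
#'
#' Converts a test channel's raw log to cumulative methane at STP, subtracts
#' the endogenous production of the inoculum (the blank curve, expressed per
#' gram of inoculum-VS, scaled by the test channel's inoculum-VS load), and
#' divides by the substrate-VS load. Negative blank-corrected values are
#' clamped so the output is non-negative and non-decreasing; specific yield is
#' physically non-negative, so dips below zero are meter noise.
#'
#' @param records Gas-log data frame for a single channel (see
#'   [validate_gas_log()]).
#' @param meta One-row data frame or list with `substrate_vs` (g, > 0) and
#'   `inoculum_vs` (g).
#' @param blank_curve A [yield_curve()] of the inoculum blank per g
#'   inoculum-VS, or `NULL` for no correction.
#' @param basis `"methane"` (requires `ch4_fraction` in the log) or
#'   `"total_gas"`.
#' @return A [yield_curve()] per g substrate-VS. The curve is flagged (with a
#'   warning) when the scaled blank exceeds the test channel at the final
#'   time point.
#' @export
specific_methane_curve <- function(records, meta, blank_curve = NULL,
                                   basis = c("methane", "total_gas")) {
  basis <- match.arg(basis)
  validate_gas_log(records)
  if (length(unique(records$channel_id)) != 1L) {
    stop("records must belong to a single channel", call. = FALSE)
  }
  if (is.null(meta$substrate_vs) || meta$substrate_vs <= 0) {
    stop("meta$substrate_vs must be positive for a test channel", call. = FALSE)
  }
  test <- channel_cumulative(records, basis)
  corrected <- test$cumulative
  flagged <- FALSE
  if (!is.null(blank_curve)) {
    if (is.null(meta$inoculum_vs) || meta$inoculum_vs < 0) {
      stop("meta$inoculum_vs required to scale the blank", call. = FALSE)
    }
    blank_abs <- curve_at(blank_curve, test$times) * meta$inoculum_vs
    corrected <- test$cumulative - blank_abs
    n <- length(corrected)
    if (corrected[n] < 0) {
      warning("blank production exceeds test channel at final time; ",
              "curve flagged", call. = FALSE)
      flagged <- TRUE
    }
    corrected <- cummax(pmax(corrected, 0))
  }
  specific <- corrected / meta$substrate_vs
  # anchor at t = 0: a batch starts with zero accumulated methane
  if (test$times[1L] > 0) {
    tt <- c(0, test$times)
    specific <- c(0, specific)
  } else {
    tt <- test$times
  }
  yield_curve(tt, specific, basis = basis, flagged = flagged)
}

#' Average replicate yield curves within a group
#'
#' Point-wise mean (and sd) of per-channel specific curves on the union time
#' grid. Channels are blank-corrected individually before averaging.
#'
#' @param curves List of [yield_curve()] objects.
#' @return A list with `mean` (a [yield_curve()]) and `sd` (numeric vector on
#'   the same grid).
#' @export
average_curves <- function(curves) {
  stopifnot(length(curves) >= 1L)
  grid <- sort(unique(unlist(lapply(curves, function(cv) cv$times))))
  mat <- vapply(curves, function(cv) curve_at(cv, grid), numeric(length(grid)))
  mat <- matrix(mat, nrow = length(grid))
  m <- rowMeans(mat)
  s <- apply(mat, 1L, stats::sd)
  list(mean = yield_curve(grid, cummax(m), basis = attr(curves[[1L]], "basis")),
       sd = s)
}

#' Daily and native-interval production from a cumulative curve
#'
#' Daily production is the first difference of the cumulative curve over 24 h
#' bins anchored at t = 0: day d covers elapsed time (d - 1, d] days, so a
#' start-up burst lands in day 1. Interval ("hourly") production is the first
#' difference over the native log intervals. Both series sum exactly to the
#' final cumulative value.
#'
#' @param curve A [yield_curve()].
#' @return List with `daily` (data frame: `day`, `production`) and `interval`
#'   (data frame: `time_start`, `time_end`, `production`, days).
#' @export
daily_and_hourly_production <- function(curve) {
  stopifnot(inherits(curve, "yield_curve"))
  n_days <- max(1L, ceiling(max(curve$times)))
  bounds <- curve_at(curve, 0:n_days)
  bounds[1L] <- 0  # nothing has accumulated before the assay starts
  daily <- data.frame(day = seq_len(n_days), production = diff(bounds))
  nt <- nrow(curve)
  interval <- if (nt >= 2L) {
    data.frame(time_start = curve$times[-nt], time_end = curve$times[-1L],
               production = diff(curve$cumulative))
  } else {
    data.frame(time_start = numeric(0), time_end = numeric(0),
               production = numeric(0))
  }
  list(daily = daily, interval = interval)
}

#' Timing statistics of a yield curve
#'
#' For each fraction f, the smallest whole day d at which the cumulative
#' curve reaches f times its final value (T50, T90, T95 for the default
#' fractions). Fraction 1.0 returns the last whole day. Computed on the
#' measured curve relative to its own final value and reported at whole-day
#' resolution.
#'
#' @param curve A [yield_curve()] with positive final value.
#' @param fractions Numeric vector in (0, 1].
#' @param termination If `TRUE`, also run [detect_termination()] on the daily
#'   series and report `end_day`.
#' @return A one-row data frame with one column per fraction (`t50`, `t90`,
#'   ... named from the fraction) plus `end_day`.
#' @export
timing_stats <- function(curve, fractions = c(0.5, 0.9, 0.95),
                         termination = TRUE) {
  stopifnot(inherits(curve, "yield_curve"))
  final <- curve$cumulative[nrow(curve)]
  if (final <= 0) stop("timing undefined for an all-zero curve", call. = FALSE)
  if (any(fractions <= 0 | fractions > 1)) {
    stop("fractions must lie in (0, 1]", call. = FALSE)
  }
  last_day <- max(1L, ceiling(max(curve$times)))
  days <- seq_len(last_day)
  cum_at_day <- curve_at(curve, days)
  t_at <- vapply(fractions, function(f) {
    if (f == 1) return(as.numeric(last_day))
    hit <- which(cum_at_day >= f * final - 1e-12 * max(final, 1))
    as.numeric(days[hit[1L]])
  }, numeric(1))
  out <- as.data.frame(as.list(t_at))
  names(out) <- paste0("t", sub("\\.?0+$", "", formatC(100 * fractions, format = "f", digits = 2)))
  out$end_day <- if (termination) {
    dp <- daily_and_hourly_production(curve)$daily
    end <- detect_termination(dp$production)
    if (is.null(end)) NA_real_ else as.numeric(end)
  } else {
    NA_real_
  }
  out
}

#' Fermentation termination day
#'
#' A run is considered finished on the first day ending a window of
#' consecutive days whose production is each below a fraction of the running
#' cumulative total (the instrument's stop rule: production below 1% of total
#' gas for three consecutive days).
#'
#' @param daily Non-negative numeric vector of per-day production (day 1
#'   first).
#' @param window Number of consecutive quiet days required (default 3).
#' @param threshold Fraction of the running cumulative total (default 0.01).
#' @return The terminating day (integer), or `NULL` if the rule never fires.
#' @export
detect_termination <- function(daily, window = 3L, threshold = 0.01) {
  if (any(daily < 0)) stop("daily production must be non-negative", call. = FALSE)
  n <- length(daily)
  if (n < window) return(NULL)
  running <- cumsum(daily)
  quiet <- daily < threshold * running & running > 0
  run <- 0L
  for (d in seq_len(n)) {
    run <- if (quiet[d]) run + 1L else 0L
    if (run >= window) return(d)
  }
  NULL
}
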