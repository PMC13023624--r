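#' Specific methane yield curve
#'
#' Container for a cumulative methane production curve expressed per gram of
#' substrate volatile solids (VS). Times are elapsed days from the start of
#' incubation; the curve must start at or after t = 0 and be non-decreasing.
#'
#' @param times Numeric vector of elapsed days, strictly increasing, first
#'   value >= 0.
#' @param cumulative Numeric vector, same length as `times`: cumulative methane
#'   at standard temperature and pressure (mL CH4 per g substrate-VS for test
#'   channels; per g inoculum-VS for blank curves), non-decreasing and
#'   non-negative.
#' @param basis `"methane"` (CH4-fraction weighted volumes) or `"total_gas"`.
#' @param flagged Logical; set by [specific_methane_curve()] when the blank
#'   exceeded the test channel at the final time point.
#' @return A data frame of class `"yield_curve"` with columns `times` and
#'   `cumulative` and attributes `basis` and `flagged`.
#' @examples
#' yield_curve(0:5, c(0, 120, 250, 310, 330, 335))
#' @export
yield_curve <- function(times, cumulative, basis = c("methane", "total_gas"),
                        flagged = FALSE) {
  basis <- match.arg(basis)
  times <- as.numeric(times)
  cumulative <- as.numeric(cumulative)
  if (length(times) != length(cumulative)) {
    stop("`times` and `cumulative` must have the same length", call. = FALSE)
  }
  if (length(times) < 1L) stop("empty curve", call. = FALSE)
  if (anyNA(times) || anyNA(cumulative)) stop("NA in curve", call. = FALSE)
  if (times[1L] < 0) stop("times must start at or after 0", call. = FALSE)
  if (any(diff(times) <= 0)) stop("times must be strictly increasing", call. = FALSE)
  if (cumulative[1L] < 0) stop("cumulative must be non-negative", call. = FALSE)
  # tolerate representation-level jitter when checking monotonicity
  if (any(diff(cumulative) < -1e-9 * max(abs(cumulative), 1))) {
    stop("cumulative must be non-decreasing", call. = FALSE)
  }
  out <- data.frame(times = times, cumulative = cumulative)
  class(out) <- c("yield_curve", "data.frame")
  attr(out, "basis") <- basis
  attr(out, "flagged") <- isTRUE(flagged)
  out
}

#' @export
print.yield_curve <- function(x, ...) {
  cat(sprintf(
    "<yield_curve> %d points, %.2f-%.2f d, final %.2f mL/g VS (basis: %s%s)\n",
    nrow(x), x$times[1L], x$times[nrow(x)], x$cumulative[nrow(x)],
    attr(x, "basis"), if (isTRUE(attr(x, "flagged"))) ", FLAGGED" else ""
  ))
  invisible(x)
}

#' Evaluate a yield curve at arbitrary times
#'
#' Linear interpolation between logged points; constant extrapolation beyond
#' the ends (a batch digester produces nothing before the first log entry and
#' the cumulative value is frozen after the last).
#'
#' @param curve A [yield_curve()].
#' @param at Numeric vector of days.
#' @return Numeric vector of cumulative values at `at`.
#' @export
curve_at <- function(curve, at) {
  stopifnot(inherits(curve, "yield_curve"))
  if (nrow(curve) == 1L) return(rep(curve$cumulative, length(at)))
  stats::approx(curve$times, curve$cumulative, xout = at, rule = 2)$y
}
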