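#' Closed-form cumulative methane production models
#'
#' The four models conventionally fitted to BMP cumulative methane curves
#' B(t) (mL CH4 per g VS):
#'
#' * Modified Gompertz: `B = B0 * exp(-exp(Rmax * e / B0 * (lambda - t) + 1))`
#' * Logistic: `B = B0 / (1 + exp(4 * Rmax / B0 * (lambda - t) + 2))`
#' * Cone: `B = B0 / (1 + (k * t)^(-n))`, defined as 0 at t = 0 by
#'   continuous extension
#' * First-order: `B = B0 * (1 - exp(-k * t))`
#'
#' with `B0` the ultimate methane potential (mL/g VS), `Rmax` the maximum
#' production rate (mL/g VS/d), `lambda` the lag phase (d), `k` a rate
#' constant (1/d) and `n` the Cone shape factor.
#'
#' @param model One of `"modified_gompertz"`, `"logistic"`, `"cone"`,
#'   `"first_order"`.
#' @param params Named list/vector with the model's parameters: `B0`, plus
#'   `Rmax` and `lambda` (Gompertz/Logistic), `k` (first-order), or `k` and
#'   `n` (Cone).
#' @param times Numeric vector of days (>= 0).
#' @return Predicted cumulative methane (mL/g VS) at `times`.
#' @examples
#' model_curve("first_order", list(B0 = 374.72, k = 0.64), 0:25)
#' @export
model_curve <- function(model = c("modified_gompertz", "logistic", "cone",
                                  "first_order"),
                        params, times) {
  model <- match.arg(model)
  p <- as.list(params)
  if (is.null(p$B0) || !is.finite(p$B0) || p$B0 <= 0) {
    stop("B0 must be positive", call. = FALSE)
  }
  if (any(times < 0)) stop("times must be non-negative", call. = FALSE)
  need <- kinetic_model_params(model)
  missing <- setdiff(need, names(p))
  if (length(missing)) {
    stop(model, " requires parameters: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  switch(model,
    modified_gompertz =
      p$B0 * exp(-exp(p$Rmax * exp(1) / p$B0 * (p$lambda - times) + 1)),
    logistic =
      p$B0 / (1 + exp(4 * p$Rmax / p$B0 * (p$lambda - times) + 2)),
    cone = {
      out <- ifelse(times > 0, p$B0 / (1 + (p$k * times)^(-p$n)), 0)
      out
    },
    first_order = p$B0 * (1 - exp(-p$k * times))
  )
}

#' Parameter names of each kinetic model
#' @param model Model name.
#' @return Character vector of required parameter names.
#' @export
kinetic_model_params <- function(model) {
  switch(model,
    modified_gompertz = c("B0", "Rmax", "lambda"),
    logistic          = c("B0", "Rmax", "lambda"),
    cone              = c("B0", "k", "n"),
    first_order       = c("B0", "k"),
    stop("unknown model: ", model, call. = FALSE)
  )
}

#' All kinetic model names
#' @return Character vector of the four supported model names.
#' @export
kinetic_models <- function() {
  c("modified_gompertz", "logistic", "cone", "first_order")
}

# Data-driven starting values for a model, following the usual BMP heuristics:
# B0 from the observed plateau, Rmax from the steepest daily increment,
# lambda from the first day with appreciable production.
kinetic_start <- function(model, times, cumulative) {
  final <- max(cumulative)
  incr <- diff(cumulative) / pmax(diff(times), 1e-9)
  rmax0 <- max(incr, final / max(times[length(times)], 1))
  lam0 <- times[which(cumulative > 0.01 * final)[1L]]
  if (!is.finite(lam0)) lam0 <- 0
  base <- switch(model,
    modified_gompertz = c(B0 = final, Rmax = rmax0, lambda = max(lam0, 0.01)),
    logistic          = c(B0 = final, Rmax = rmax0, lambda = max(lam0, 0.01)),
    cone              = c(B0 = final, k = 0.5, n = 2),
    first_order       = c(B0 = final, k = 0.5)
  )
  base
}

kinetic_bounds <- function(model, times, cumulative) {
  final <- max(cumulative)
  dur <- max(times)
  lower <- switch(model,
    modified_gompertz = c(B0 = 1e-6, Rmax = 1e-6, lambda = 0),
    logistic          = c(B0 = 1e-6, Rmax = 1e-6, lambda = 0),
    cone              = c(B0 = 1e-6, k = 1e-6, n = 1e-3),
    first_order       = c(B0 = 1e-6, k = 1e-6)
  )
  upper <- switch(model,
    modified_gompertz = c(B0 = 3 * final, Rmax = Inf, lambda = dur),
    logistic          = c(B0 = 3 * final, Rmax = Inf, lambda = dur),
    cone              = c(B0 = 3 * final, k = Inf, n = 50),
    first_order       = c(B0 = 3 * final, k = Inf)
  )
  list(lower = lower, upper = upper)
}

#' Fit one kinetic model to a yield curve
#'
#' Nonlinear least squares (Levenberg-Marquardt, bounded) on the cumulative
#' curve, with multi-start initialization: the data-driven starting point is
#' perturbed by factors 0.5/1/2 on every parameter and the best converged fit
#' by residual sum of squares is kept. R-squared is the plain
#' `1 - SS_res/SS_tot`.
#'
#' @param curve A [yield_curve()], or a data frame with `times` and
#'   `cumulative` columns.
#' @param model Model name (see [kinetic_models()]).
#' @return A list of class `"kinetic_fit"`: `model`, `params` (named vector),
#'   `r_squared` in \[0, 1\], `residuals`, `converged`, `n_points`, `ss_res`.
#' @export
fit_kinetic <- function(curve, model = c("modified_gompertz", "logistic",
                                         "cone", "first_order")) {
  model <- match.arg(model)
  times <- curve$times
  y <- curve$cumulative
  pnames <- kinetic_model_params(model)
  if (length(times) < 2L + length(pnames)) {
    stop("need at least ", 2L + length(pnames), " points to fit ", model,
         call. = FALSE)
  }
  if (max(y) <= 0) stop("no fittable signal: curve is all zero", call. = FALSE)

  start0 <- kinetic_start(model, times, y)
  bb <- kinetic_bounds(model, times, y)
  factors <- c(0.5, 1, 2)
  grid <- expand.grid(rep(list(factors), length(start0)))

  best <- NULL
  for (i in seq_len(nrow(grid))) {
    st <- pmin(pmax(start0 * unlist(grid[i, ]), bb$lower + 1e-9),
               ifelse(is.finite(bb$upper), bb$upper, start0 * unlist(grid[i, ])))
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = st,
        lower = bb$lower, upper = bb$upper,
        fn = function(p) y - model_curve(model, as.list(p), times),
        control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-14,
                                             ptol = 1e-14)
      ),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    ss <- sum(fit$fvec^2)
    if (is.null(best) || ss < best$ss) {
      best <- list(par = stats::coef(fit), ss = ss,
                   converged = fit$info %in% 1:4)
    }
  }

  if (is.null(best)) {
    return(structure(
      list(model = model,
           params = stats::setNames(rep(NA_real_, length(pnames)), pnames),
           r_squared = NA_real_, residuals = rep(NA_real_, length(y)),
           converged = FALSE, n_points = length(y), ss_res = NA_real_),
      class = "kinetic_fit"
    ))
  }

  pred <- model_curve(model, as.list(best$par), times)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - best$ss / ss_tot else NA_real_
  structure(
    list(model = model, params = best$par,
         r_squared = max(0, min(1, r2)),
         residuals = y - pred, converged = best$converged,
         n_points = length(y), ss_res = best$ss),
    class = "kinetic_fit"
  )
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat(sprintf("<kinetic_fit> %s: %s; R^2 = %.4f%s\n", x$model,
              paste(sprintf("%s = %.4g", names(x$params), x$params),
                    collapse = ", "),
              x$r_squared, if (!x$converged) " (NOT converged)" else ""))
  invisible(x)
}

#' Fit all four kinetic models and tabulate
#'
#' One row per model with the fitted parameters and R-squared in percent, in
#' the layout conventional for BMP kinetics tables. Parameters a model does
#' not define are `NA`. A model that fails to fit is reported with
#' `converged = FALSE` without aborting the others.
#'
#' @param curve A [yield_curve()].
#' @param group Optional group label carried into the table.
#' @return Data frame with columns `model`, `group`, `B0`, `Rmax`, `lambda`,
#'   `k`, `n`, `r_squared_pct`, `converged`.
#' @export
fit_all_models <- function(curve, group = NA_character_) {
  rows <- lapply(kinetic_models(), function(m) {
    fit <- tryCatch(fit_kinetic(curve, m), error = function(e) NULL)
    row <- data.frame(model = m, group = group, B0 = NA_real_,
                      Rmax = NA_real_, lambda = NA_real_, k = NA_real_,
                      n = NA_real_, r_squared_pct = NA_real_,
                      converged = FALSE)
    if (!is.null(fit)) {
      for (pn in names(fit$params)) row[[pn]] <- unname(fit$params[[pn]])
      row$r_squared_pct <- round(100 * fit$r_squared, 2)
      row$converged <- fit$converged
    }
    row
  })
  do.call(rbind, rows)
}

#' First-order hydrolysis rate constant from a single removal measurement
#'
#' Inverts the first-order decay `S_t = S0 * exp(-k_deg * t)`: given the
#' fraction of substrate removed by time t, `k_deg = -ln(1 - removal) / t`.
#'
#' @param removal_fraction Fraction of initial substrate removed, in \[0, 1).
#' @param t Elapsed time in days (> 0).
#' @return First-order hydrolysis rate constant k_deg (1/d).
#' @examples
#' hydrolysis_k_single_point(0.9796, 4)  # ~0.97 / d
#' @export
hydrolysis_k_single_point <- function(removal_fraction, t) {
  if (any(t <= 0)) stop("t must be positive", call. = FALSE)
  if (any(removal_fraction < 0)) stop("removal_fraction must be >= 0", call. = FALSE)
  if (any(removal_fraction >= 1)) {
    stop("complete removal implies an infinite rate constant", call. = FALSE)
  }
  -log(1 - removal_fraction) / t
}

#' Fit first-order hydrolysis to a substrate concentration series
#'
#' Least-squares fit of `S_t = S0 * exp(-k_deg * t)`. The default fits on the
#' original concentration scale by nonlinear least squares (log-linear
#' regression distorts the noise structure near complete removal); a
#' log-linear fit is available via `method = "log_linear"`. Non-positive
#' concentrations are excluded with a warning (the log-linear route cannot
#' use them; the nonlinear route excludes them for comparability).
#'
#' @param times Days.
#' @param concentration Substrate concentration (g/L or any consistent unit).
#' @param method `"nls"` (default) or `"log_linear"`.
#' @return List of class `"hydrolysis_fit"`: `s0`, `k_deg`, `r_squared`,
#'   `method`, `n_points`.
#' @export
fit_hydrolysis <- function(times, concentration,
                           method = c("nls", "log_linear")) {
  method <- match.arg(method)
  keep <- concentration > 0
  if (!all(keep)) {
    warning(sum(!keep), " non-positive concentration value(s) excluded",
            call. = FALSE)
    times <- times[keep]
    concentration <- concentration[keep]
  }
  if (length(times) < 3L) stop("need at least 3 positive points", call. = FALSE)
  if (concentration[1L] <= 0) stop("initial concentration must be positive",
                                   call. = FALSE)
  # log-linear solution; exact when noiseless, start value otherwise
  ll <- stats::lm(log(concentration) ~ times)
  s0_ll <- exp(unname(stats::coef(ll)[1L]))
  k_ll <- max(0, -unname(stats::coef(ll)[2L]))
  if (method == "log_linear") {
    s0 <- s0_ll
    k <- k_ll
  } else {
    fit <- minpack.lm::nls.lm(
      par = c(s0 = s0_ll, k = k_ll),
      lower = c(s0 = 1e-12, k = 0),
      fn = function(p) concentration - p[["s0"]] * exp(-p[["k"]] * times),
      control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-14,
                                           ptol = 1e-14)
    )
    s0 <- stats::coef(fit)[["s0"]]
    k <- stats::coef(fit)[["k"]]
  }
  pred <- s0 * exp(-k * times)
  ss_res <- sum((concentration - pred)^2)
  ss_tot <- sum((concentration - mean(concentration))^2)
  structure(
    list(s0 = s0, k_deg = k,
         r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_,
         method = method, n_points = length(times)),
    class = "hydrolysis_fit"
  )
}

#' @export
print.hydrolysis_fit <- function(x, ...) {
  cat(sprintf("<hydrolysis_fit> S0 = %.4g, k_deg = %.4g /d, R^2 = %.4f (%s)\n",
              x$s0, x$k_deg, x$r_squared, x$method))
  invisible(x)
}
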