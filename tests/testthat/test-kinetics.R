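test_that("model curves match their closed forms at anchor points", {
  B0 <- 374.72
  # first-order asymptote is B0
  expect_equal(model_curve("first_order", list(B0 = B0, k = 0.64), 1e6), B0)
  # Modified Gompertz at t = lambda equals B0 * exp(-e)
  expect_equal(
    model_curve("modified_gompertz",
                list(B0 = 200, Rmax = 50, lambda = 1.3), 1.3),
    200 * exp(-exp(1)), tolerance = 1e-12
  )
  # Logistic at t = lambda equals B0 / (1 + e^2)
  expect_equal(
    model_curve("logistic", list(B0 = 200, Rmax = 50, lambda = 1.3), 1.3),
    200 / (1 + exp(2)), tolerance = 1e-12
  )
  # Cone is 0 at t = 0 by continuous extension
  expect_equal(model_curve("cone", list(B0 = 300, k = 0.9, n = 2), 0), 0)
  expect_error(model_curve("first_order", list(B0 = -1, k = 0.5), 0:3), "B0")
  expect_error(model_curve("cone", list(B0 = 300, k = 0.9), 0:3), "requires")
})

test_that("model curves are non-decreasing and bounded by B0 (property)", {
  set.seed(11)
  tt <- seq(0, 40, by = 0.25)
  for (i in 1:20) {
    m <- sample(kinetic_models(), 1)
    pars <- switch(m,
      modified_gompertz = list(B0 = runif(1, 50, 500), Rmax = runif(1, 10, 300),
                               lambda = runif(1, 0, 3)),
      logistic = list(B0 = runif(1, 50, 500), Rmax = runif(1, 10, 300),
                      lambda = runif(1, 0, 3)),
      cone = list(B0 = runif(1, 50, 500), k = runif(1, 0.1, 2),
                  n = runif(1, 0.5, 4)),
      first_order = list(B0 = runif(1, 50, 500), k = runif(1, 0.1, 2)))
    y <- model_curve(m, pars, tt)
    expect_true(all(diff(y) >= -1e-12))
    expect_true(all(y <= pars$B0 + 1e-9))
    if (m %in% c("cone", "first_order")) expect_equal(y[1], 0)
  }
})

test_that("noiseless self-fit recovers parameters to 1e-6 relative", {
  days <- 0:25
  cases <- list(
    modified_gompertz = list(B0 = 300, Rmax = 150, lambda = 0.2),
    logistic = list(B0 = 340, Rmax = 170, lambda = 0.2),
    cone = list(B0 = 373.58, k = 0.85, n = 1.6),
    first_order = list(B0 = 374.72, k = 0.64)
  )
  for (m in names(cases)) {
    truth <- cases[[m]]
    cv <- yield_curve(days, model_curve(m, truth, days))
    fit <- fit_kinetic(cv, m)
    expect_true(fit$converged)
    rel <- abs(fit$params - unlist(truth)) / unlist(truth)
    expect_lt(max(rel), 1e-6)
    expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  }
})

test_that("degenerate inputs are rejected", {
  expect_error(fit_kinetic(yield_curve(0:25, rep(0, 26)), "first_order"),
               "all zero")
  expect_error(fit_kinetic(yield_curve(0:2, c(0, 1, 2)), "cone"), "at least")
})

test_that("fit_all_models tabulates all four models with R^2 in percent", {
  cv <- fixture_curve(B0 = 360, k = 0.6)
  tab <- fit_all_models(cv, group = "HC3")
  expect_equal(nrow(tab), 4)
  expect_setequal(tab$model, kinetic_models())
  expect_true(all(tab$r_squared_pct >= 0 & tab$r_squared_pct <= 100))
  expect_true(all(is.na(tab$k[tab$model == "modified_gompertz"])))
  expect_true(all(is.na(tab$lambda[tab$model == "cone"])))
  # noiseless Cone-generated data: Cone row fits perfectly
  cone_cv <- yield_curve(0:25, model_curve("cone",
                                           list(B0 = 350, k = 0.9, n = 1.8),
                                           0:25))
  cone_tab <- fit_all_models(cone_cv)
  expect_equal(cone_tab$r_squared_pct[cone_tab$model == "cone"], 100)
})

test_that("Cone R^2 is at least first-order R^2 on a lagged noisy fixture", {
  # real cumulative curves show a lag phase; the Cone shape parameter can
  # bend into that sigmoid while the first-order model cannot
  cfg <- default_bmp_config(seed = 99)
  cfg$true_model$HC3 <- list(model = "modified_gompertz",
                             params = list(B0 = 373.66, Rmax = 167.01,
                                           lambda = 0.5))
  ds <- generate_bmp_dataset(cfg)
  pre <- preprocess_bmp(ds$logs, ds$meta)
  cv <- pre$group_curves$HC3
  daily <- yield_curve(0:25, cummax(curve_at(cv, 0:25)))
  tab <- fit_all_models(daily)
  expect_gte(tab$r_squared_pct[tab$model == "cone"],
             tab$r_squared_pct[tab$model == "first_order"])
})

test_that("single-point hydrolysis inversion matches the closed form", {
  expect_equal(hydrolysis_k_single_point(0, 3), 0)
  expect_equal(hydrolysis_k_single_point(1 - exp(-2), 1), 2, tolerance = 1e-12)
  expect_equal(hydrolysis_k_single_point(0.8647, 1), 2.00, tolerance = 1e-3)
  expect_error(hydrolysis_k_single_point(1, 4), "infinite")
  expect_error(hydrolysis_k_single_point(-0.1, 4), ">= 0")
  expect_error(hydrolysis_k_single_point(0.5, 0), "positive")
})

test_that("hydrolysis fitting recovers the decay and handles edge cases", {
  tt <- c(0, 0.5, 1, 2, 4, 7, 10)
  s <- 10 * exp(-0.97 * tt)
  fit <- fit_hydrolysis(tt, s)
  expect_lt(abs(fit$s0 - 10) / 10, 1e-8)
  expect_lt(abs(fit$k_deg - 0.97) / 0.97, 1e-8)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)

  # log-linear route agrees on noiseless data
  fit_ll <- fit_hydrolysis(tt, s, method = "log_linear")
  expect_equal(fit_ll$k_deg, 0.97, tolerance = 1e-10)

  # constant series -> zero rate
  expect_equal(fit_hydrolysis(tt, rep(5, length(tt)))$k_deg, 0)

  # non-positive concentrations excluded with a warning
  expect_warning(fit_hydrolysis(c(tt, 30), c(s, 0)), "excluded")
})

test_that("two-point fit agrees exactly with the single-point inversion", {
  # (plus a third interpolating point so the fit is determined)
  k_true <- 0.7
  tt <- c(0, 2, 4)
  s <- 8 * exp(-k_true * tt)
  fit <- fit_hydrolysis(tt, s)
  k_single <- hydrolysis_k_single_point(1 - s[3] / s[1], 4)
  expect_equal(fit$k_deg, k_single, tolerance = 1e-9)
})

test_that("mean hydrolysis estimate is within 5% of truth at 2% noise", {
  k_hat <- vapply(1:50, function(i) {
    ser <- generate_substrate_series(10, 0.97, c(0, 0.5, 1, 2, 3, 4, 7, 10),
                                     noise_cv = 0.02, seed = 5000 + i)
    fit_hydrolysis(ser$times, ser$concentration)$k_deg
  }, numeric(1))
  expect_lt(abs(mean(k_hat) - 0.97) / 0.97, 0.05)
})
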