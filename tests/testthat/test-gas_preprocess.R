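test_that("STP normalization follows the ideal-gas ratio", {
  expect_equal(normalize_to_stp(100, 273.15, 101.325), 100)
  expect_equal(normalize_to_stp(100, 308.15, 101.325),
               100 * 273.15 / 308.15, tolerance = 1e-12)
  expect_equal(normalize_to_stp(100, 308.15, 101.325), 88.64, tolerance = 1e-4)
  expect_equal(normalize_to_stp(100, 273.15, 202.65), 200)
  expect_error(normalize_to_stp(100, 0, 101.325), "temperature")
  expect_error(normalize_to_stp(100, 308.15, -1), "pressure")
  expect_error(normalize_to_stp(-5, 308.15, 101.325), "volume")
})

make_log <- function(id, hours, inc, temp = 273.15, pres = 101.325, ch4 = 1) {
  data.frame(channel_id = id, time = hours, volume_increment = inc,
             temperature = temp, pressure = pres, ch4_fraction = ch4)
}

test_that("blank subtraction and VS scaling give the specific curve", {
  hours <- c(24, 48, 72)
  blank <- yield_curve(c(0, hours / 24), c(0, 10, 15, 18))  # per g inoc-VS
  # test channel producing exactly 2x the scaled blank, 1 g substrate-VS
  meta <- list(substrate_vs = 1, inoculum_vs = 2)
  test_inc <- diff(c(0, 2 * c(10, 15, 18) * meta$inoculum_vs))
  cv <- specific_methane_curve(make_log("a", hours, test_inc), meta, blank)
  expect_equal(curve_at(cv, c(1, 2, 3)), c(20, 30, 36), tolerance = 1e-12)

  # test equal to blank (equal inoculum) -> all-zero curve
  meta5 <- list(substrate_vs = 5, inoculum_vs = 2)
  same_inc <- diff(c(0, c(10, 15, 18) * meta5$inoculum_vs))
  cv0 <- specific_methane_curve(make_log("b", hours, same_inc), meta5, blank)
  expect_true(all(cv0$cumulative == 0))
})

test_that("blank exceeding the test channel flags the curve and clamps", {
  hours <- c(24, 48)
  blank <- yield_curve(c(0, 1, 2), c(0, 50, 100))
  meta <- list(substrate_vs = 1, inoculum_vs = 1)
  expect_warning(
    cv <- specific_methane_curve(make_log("a", hours, c(30, 20)), meta, blank),
    "flagged"
  )
  expect_true(attr(cv, "flagged"))
  expect_true(all(diff(cv$cumulative) >= 0))
  expect_true(all(cv$cumulative >= 0))
})

test_that("methane basis requires a CH4 fraction and weights by it", {
  hours <- c(24, 48)
  lg <- make_log("a", hours, c(100, 100), ch4 = 0.5)
  meta <- list(substrate_vs = 1, inoculum_vs = 0)
  cv <- specific_methane_curve(lg, meta, NULL, basis = "methane")
  expect_equal(cv$cumulative[nrow(cv)], 100)
  lg$ch4_fraction <- NULL
  expect_error(specific_methane_curve(lg, meta, NULL, basis = "methane"),
               "ch4_fraction")
  cv2 <- specific_methane_curve(lg, meta, NULL, basis = "total_gas")
  expect_equal(cv2$cumulative[nrow(cv2)], 200)
})

test_that("daily production is the first difference over 24 h bins", {
  cv <- yield_curve(c(0, 1, 2, 3), c(0, 100, 150, 160))
  dp <- daily_and_hourly_production(cv)
  expect_equal(dp$daily$production, c(100, 50, 10))
  expect_equal(sum(dp$daily$production), 160)
  expect_equal(sum(dp$interval$production), 160)

  # constant-slope curve -> equal daily values
  lin <- yield_curve(0:10, 25 * (0:10))
  expect_equal(daily_and_hourly_production(lin)$daily$production, rep(25, 10))

  # sub-daily grid: the start-up burst lands in day 1 (bin (0, 24 h])
  sub <- yield_curve(c(0, 0.25, 0.5, 1, 2), c(0, 80, 120, 150, 160))
  dsub <- daily_and_hourly_production(sub)$daily
  expect_equal(dsub$production, c(150, 10))
})

test_that("daily peak of a sigmoidal curve matches brute-force argmax", {
  days <- 0:25
  cv <- yield_curve(days, model_curve("modified_gompertz",
                                      list(B0 = 300, Rmax = 80, lambda = 1.5),
                                      days))
  dp <- daily_and_hourly_production(cv)$daily
  expect_equal(which.max(dp$production), which.max(diff(cv$cumulative)))
})

test_that("timing stats find the smallest whole day reaching each fraction", {
  # 50% of the final value is reached during day 1
  cv <- fixture_curve(B0 = 350, k = 0.8)
  ts <- timing_stats(cv)
  expect_equal(ts$t50, 1)

  # linearly increasing cumulative over 25 days -> T50 on day 13
  lin <- yield_curve(0:25, 10 * (0:25))
  expect_equal(timing_stats(lin, termination = FALSE)$t50, 13)

  # fraction 1.0 returns the final day
  expect_equal(timing_stats(lin, fractions = 1, termination = FALSE)$t100, 25)

  expect_error(timing_stats(yield_curve(0:3, rep(0, 4))), "all-zero")
  expect_error(timing_stats(lin, fractions = c(0.5, 1.5)), "fractions")
})

test_that("T50 <= T90 <= T95 and monotone in the fraction (property)", {
  set.seed(42)
  for (i in 1:25) {
    B0 <- runif(1, 100, 500)
    k <- runif(1, 0.1, 1.5)
    lam <- runif(1, 0, 2)
    m <- sample(kinetic_models(), 1)
    pars <- switch(m,
      modified_gompertz = list(B0 = B0, Rmax = B0 * k, lambda = lam),
      logistic = list(B0 = B0, Rmax = B0 * k, lambda = lam),
      cone = list(B0 = B0, k = k, n = runif(1, 1, 3)),
      first_order = list(B0 = B0, k = k))
    cv <- yield_curve(0:30, model_curve(m, pars, 0:30))
    ts <- timing_stats(cv, termination = FALSE)
    expect_true(ts$t50 <= ts$t90 && ts$t90 <= ts$t95)
    fr <- sort(runif(3, 0.05, 1))
    tt <- unlist(timing_stats(cv, fractions = fr, termination = FALSE)[1, 1:3])
    expect_true(all(diff(tt) >= 0))
  }
})

test_that("termination rule matches spec examples and the brute-force scan", {
  expect_equal(detect_termination(c(500, 300, 100, 5, 4, 3)), 6)
  expect_null(detect_termination(rep(50, 30)))
  # final three zero days after positive production terminate at the last day
  expect_equal(detect_termination(c(100, 50, 0, 0, 0)), 5)

  set.seed(7)
  for (i in 1:100) {
    n <- sample(5:40, 1)
    daily <- rexp(n, rate = 1 / 50) * exp(-0.3 * seq_len(n))
    got <- detect_termination(daily)
    want <- oracle_termination(daily)
    expect_identical(got, want)
  }
})

test_that("gas-log validation enforces the record invariants", {
  lg <- make_log("a", c(1, 2, 3), c(1, 1, 1))
  expect_silent(validate_gas_log(lg))
  bad <- lg; bad$time <- c(1, 1, 2)
  expect_error(validate_gas_log(bad), "increasing")
  bad <- lg; bad$volume_increment[2] <- -1
  expect_error(validate_gas_log(bad), "negative")
  bad <- lg; bad$ch4_fraction[1] <- 1.2
  expect_error(validate_gas_log(bad), "ch4_fraction")
})
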