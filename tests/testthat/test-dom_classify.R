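test_that("H/C and O/C ratios are exact rational ratios", {
  f <- data.frame(c = c(6, 10, 5), h = c(12, 12, 8), o = c(6, 5, 4))
  r <- hc_oc(f)
  expect_equal(r$hc, c(2.0, 1.2, 1.6))
  expect_equal(r$oc, c(1.0, 0.5, 0.8))
  expect_error(hc_oc(data.frame(c = 0, h = 4, o = 1)), "carbon")
})

test_that("classification follows the class boxes with first-match ties", {
  # interior points of each box
  expect_equal(classify_vk(data.frame(c = 10, h = 10, o = 4)), "lignin_cram")
  expect_equal(classify_vk(data.frame(c = 10, h = 18, o = 1)), "lipids")
  expect_equal(classify_vk(data.frame(c = 10, h = 18, o = 5)),
               "aliphatic_proteins")
  expect_equal(classify_vk(data.frame(c = 10, h = 20, o = 10)),
               "carbohydrates")
  expect_equal(classify_vk(data.frame(c = 20, h = 20, o = 1)),
               "unsaturated_hc")
  expect_equal(classify_vk(data.frame(c = 10, h = 5, o = 3)), "aromatic")
  expect_equal(classify_vk(data.frame(c = 10, h = 10, o = 8)), "tannin")
  # far outside every box
  expect_equal(classify_vk(data.frame(c = 1, h = 3, o = 2)), "unassigned")
  # shared edges resolve to the first-listed class:
  # O/C = 0.3 belongs to aliphatic/proteins' [0.3, 0.67), not lipids' [0, 0.3)
  expect_equal(classify_vk(data.frame(c = 10, h = 18, o = 3)),
               "aliphatic_proteins")
  # H/C = 1.5 at low O/C belongs to lipids' [1.5, 2.0), not lignin/CRAM
  expect_equal(classify_vk(data.frame(c = 10, h = 15, o = 2)), "lipids")
  # tannin's upper edge (O/C = 1) is inclusive
  expect_equal(classify_vk(data.frame(c = 10, h = 10, o = 10)), "tannin")
})

test_that("every formula gets exactly one label; partition sums to 100", {
  set.seed(202)
  n <- 10000
  f <- data.frame(
    c = sample(1:40, n, replace = TRUE),
    h = sample(0:80, n, replace = TRUE),
    o = sample(0:48, n, replace = TRUE),
    n = sample(0:3, n, replace = TRUE),
    s = sample(0:2, n, replace = TRUE),
    relative_intensity = rexp(n)
  )
  cls <- classify_vk(f)
  expect_length(cls, n)
  expect_true(all(cls %in% vk_classes()))
  sm <- suppressMessages(vk_summary(f))
  expect_equal(sum(sm$class_share), 100, tolerance = 1e-6)
  expect_equal(sum(sm$group_share), 100, tolerance = 1e-6)
})

test_that("element groups follow N/S presence; oxygen-free goes to other", {
  f <- data.frame(c = c(6, 5, 5, 5, 8), h = c(10, 9, 9, 9, 18),
                  o = c(5, 3, 3, 3, 0),
                  n = c(0, 1, 0, 1, 0), s = c(0, 0, 1, 1, 0))
  expect_message(g <- element_group(f), "other")
  expect_equal(g, c("CHO", "CHON", "CHOS", "CHONS", "other"))
})

test_that("formula strings parse to atom counts", {
  p <- parse_formula(c("C6H12O6", "C5H9O3N1S1", "CH4", "C10H12O5N2"))
  expect_equal(p$c, c(6, 5, 1, 10))
  expect_equal(p$h, c(12, 9, 4, 12))
  expect_equal(p$o, c(6, 3, 0, 5))
  expect_equal(p$n, c(0, 1, 0, 2))
  expect_equal(p$s, c(0, 1, 0, 0))
  expect_error(parse_formula("C6H12O6X2"), "cannot parse")
})

test_that("shares follow the weights and their invariances", {
  one <- data.frame(c = 10, h = 10, o = 4, relative_intensity = 3)
  expect_equal(vk_summary(one)$class_share[["lignin_cram"]], 100)
  two <- data.frame(c = c(10, 10), h = c(10, 18), o = c(4, 1),
                    relative_intensity = c(5, 5))
  sm <- vk_summary(two)
  expect_equal(sm$class_share[["lignin_cram"]], 50)
  expect_equal(sm$class_share[["lipids"]], 50)
  # intensity rescaling leaves shares unchanged
  two_scaled <- two
  two_scaled$relative_intensity <- two$relative_intensity * 1e6
  expect_equal(vk_summary(two_scaled)$class_share, sm$class_share)
  # permutation invariance
  expect_equal(vk_summary(two[2:1, ])$class_share, sm$class_share)
  # equal intensities make count- and intensity-weighting coincide
  expect_equal(vk_summary(two, "count")$class_share, sm$class_share)
  expect_error(vk_summary(two[0, ]), "empty")
  zero_w <- two
  zero_w$relative_intensity <- 0
  expect_error(vk_summary(zero_w), "zero total weight")
})

test_that("generated tables recover their target shares", {
  cfg <- default_dom_config(n_formulas = 5000, seed = 314)
  ft <- generate_formula_table(cfg)
  expect_true(all(classify_vk(ft) == ft$class_intended))
  sm <- vk_summary(ft, weighting = "count")
  targets <- c(lignin_cram = 62.57, aliphatic_proteins = 22.97,
               lipids = 11.00)
  for (nm in names(targets)) {
    p <- targets[[nm]] / 100
    half <- 100 * stats::qnorm(0.995) * sqrt(p * (1 - p) / cfg$n_formulas)
    expect_lt(abs(sm$class_share[[nm]] - targets[[nm]]), half)
  }
  # element-group mixture recovered within a binomial 99% CI
  cfg2 <- default_dom_config(n_formulas = 3000,
                             group_probs = c(CHO = 0.7, CHON = 0.3),
                             seed = 2718)
  ft2 <- generate_formula_table(cfg2)
  grp <- element_group(ft2)
  half <- 100 * stats::qnorm(0.995) * sqrt(0.7 * 0.3 / cfg2$n_formulas)
  expect_lt(abs(100 * mean(grp == "CHO") - 70), half)
})
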