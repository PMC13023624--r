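#' Default BMP simulation configuration
#'
#' The study conditions emulated by the generator: three substrate groups at
#' inoculum-to-substrate ratios 2:1, 3:1 and 4:1 (VS basis) with three
#' replicates each plus an inoculum-only blank group, hourly logging of a
#' mesophilic (308.15 K) meter for 25 days, and first-order true kinetics
#' with the ultimate yields and rate constants typical of a rapidly degraded
#' hemicellulose (HC2 343.76 mL/g VS at 0.62 /d, HC3 374.72 at 0.64, HC4
#' 364.76 at 0.55). The inoculum's endogenous background is first-order with
#' a small specific yield (10 mL per g inoculum-VS at 0.1 /d). Measurement
#' noise is additive Gaussian on the per-tick meter increments, truncated at
#' zero; when `noise_sd` is `NA` the standard deviation is `noise_pct` times
#' the channel's mean noiseless increment (default 2%).
#'
#' @param seed RNG seed recorded in the outputs (default 20260302).
#' @param noise_sd Absolute noise sd in mL per tick, or `NA` to derive it
#'   from `noise_pct`.
#' @param noise_pct Relative noise level used when `noise_sd` is `NA`.
#' @param duration_days,dt_hours Logging span and tick size.
#' @param substrate_vs Substrate VS load per test channel, g.
#' @return Configuration list for [generate_bmp_dataset()].
#' @export
default_bmp_config <- function(seed = 20260302, noise_sd = NA_real_,
                               noise_pct = 0.02, duration_days = 25,
                               dt_hours = 1, substrate_vs = 2) {
  groups <- data.frame(
    label = c("HC2", "HC3", "HC4"),
    isr = c(2, 3, 4),
    substrate_vs = substrate_vs,
    inoculum_vs = c(2, 3, 4) * substrate_vs,
    replicates = 3L
  )
  true_model <- list(
    HC2 = list(model = "first_order", params = list(B0 = 343.76, k = 0.62)),
    HC3 = list(model = "first_order", params = list(B0 = 374.72, k = 0.64)),
    HC4 = list(model = "first_order", params = list(B0 = 364.76, k = 0.55))
  )
  list(
    groups = groups,
    true_model = true_model,
    blank_model = list(B0 = 10, k = 0.1),  # per g inoculum-VS
    blank_inoculum_vs = 6,
    blank_replicates = 3L,
    noise_sd = noise_sd,
    noise_pct = noise_pct,
    duration_days = duration_days,
    dt_hours = dt_hours,
    meter_temperature = 308.15,
    meter_pressure = 101.325,
    ch4_fraction = 1,  # the meter logs methane after CO2 absorption
    seed = seed
  )
}

# True specific curve of a group at given days (starts at 0 by construction
# for the first-order and Cone models used as truths).
true_specific <- function(spec, days) {
  model_curve(spec$model, spec$params, days)
}

#' Generate a synthetic BMP gas-log dataset
#'
#' Simulates per-channel gas-flow-meter logs for the configured groups and
#' an inoculum-only blank group. Each test channel's cumulative methane at
#' STP is the group's true specific curve times its substrate-VS load plus
#' the blank curve times its inoculum-VS load; increments are back-converted
#' to meter conditions, divided by the CH4 fraction when below one, and
#' perturbed by truncated Gaussian noise. Ground truth (curves, parameters,
#' config) is returned alongside so recovery can be scored.
#'
#' @param config List from [default_bmp_config()] (fields may be
#'   overridden).
#' @return List with `logs` (gas-log data frame, see [validate_gas_log()]),
#'   `meta` (channel metadata: `channel_id`, `group_label`, `substrate_vs`,
#'   `inoculum_vs`, `is_blank`, `replicate_index`) and `truth` (`specific`
#'   per-group [yield_curve()]s, `blank` per g inoculum-VS, `config`).
#' @export
generate_bmp_dataset <- function(config = default_bmp_config()) {
  stopifnot(all(config$groups$replicates >= 1L), config$dt_hours > 0,
            config$duration_days > 0)
  set.seed(config$seed)
  hours <- seq(config$dt_hours, config$duration_days * 24, by = config$dt_hours)
  days <- hours / 24
  stp_to_meter <- 1 / ((273.15 / config$meter_temperature) *
                         (config$meter_pressure / 101.325))

  blank_cum <- model_curve("first_order", config$blank_model, days)
  truth_specific <- list()
  logs <- list()
  meta <- list()

  emit_channel <- function(id, group, substrate_vs, inoculum_vs, rep_i,
                           is_blank, spec_cum) {
    cum_stp <- spec_cum * substrate_vs + blank_cum * inoculum_vs
    inc_stp <- diff(c(0, cum_stp))
    inc_meter <- inc_stp * stp_to_meter / config$ch4_fraction
    sd_i <- if (is.na(config$noise_sd)) {
      config$noise_pct * mean(inc_meter)
    } else {
      config$noise_sd
    }
    if (sd_i > 0) {
      inc_meter <- pmax(0, inc_meter + stats::rnorm(length(inc_meter), 0, sd_i))
    }
    logs[[id]] <<- data.frame(
      channel_id = id, time = hours, volume_increment = inc_meter,
      temperature = config$meter_temperature,
      pressure = config$meter_pressure,
      ch4_fraction = config$ch4_fraction
    )
    meta[[id]] <<- data.frame(
      channel_id = id, group_label = group, substrate_vs = substrate_vs,
      inoculum_vs = inoculum_vs, is_blank = is_blank,
      replicate_index = rep_i
    )
  }

  for (g in seq_len(nrow(config$groups))) {
    row <- config$groups[g, ]
    spec <- config$true_model[[row$label]]
    spec_cum <- true_specific(spec, days)
    truth_specific[[row$label]] <- yield_curve(c(0, days), c(0, spec_cum))
    for (r in seq_len(row$replicates)) {
      emit_channel(sprintf("%s_r%d", row$label, r), row$label,
                   row$substrate_vs, row$inoculum_vs, r, FALSE, spec_cum)
    }
  }
  for (r in seq_len(config$blank_replicates)) {
    emit_channel(sprintf("blank_r%d", r), "blank", 0,
                 config$blank_inoculum_vs, r, TRUE, rep(0, length(days)))
  }

  list(
    logs = do.call(rbind, c(logs, make.row.names = FALSE)),
    meta = do.call(rbind, c(meta, make.row.names = FALSE)),
    truth = list(
      specific = truth_specific,
      blank = yield_curve(c(0, days), c(0, blank_cum)),
      config = config
    )
  )
}

#' Generate a substrate-concentration decay series
#'
#' First-order decay `S0 * exp(-k_deg * t)` with mean-one multiplicative
#' log-normal noise, emulating residual-substrate measurements over a batch
#' digestion.
#'
#' @param s0 Initial concentration (> 0).
#' @param k_deg First-order rate constant (1/d, >= 0).
#' @param times Days.
#' @param noise_cv Coefficient of variation of the multiplicative noise
#'   (0 for noiseless).
#' @param seed RNG seed.
#' @return Data frame with `times` and `concentration`.
#' @export
generate_substrate_series <- function(s0, k_deg, times, noise_cv = 0,
                                      seed = 20260302) {
  if (s0 <= 0) stop("s0 must be positive", call. = FALSE)
  if (k_deg < 0) stop("k_deg must be non-negative", call. = FALSE)
  set.seed(seed)
  s <- s0 * exp(-k_deg * times)
  if (noise_cv > 0) {
    sdlog <- sqrt(log(1 + noise_cv^2))
    s <- s * stats::rlnorm(length(times), meanlog = -sdlog^2 / 2, sdlog = sdlog)
  }
  data.frame(times = times, concentration = pmax(s, 0))
}

#' Default DOM formula-table simulation configuration
#'
#' Target class shares reflect the composition of the liquid phase of an
#' anaerobic granular sludge at the start of digestion: lignin/CRAM-like
#' 62.57%, aliphatic/proteins 22.97%, lipids 11.00%, the remaining 3.46%
#' spread evenly over carbohydrates, unsaturated hydrocarbons, aromatic
#' structures and tannins. Element groups default to a CHO/CHON-dominated
#' mixture; intensities are log-normal.
#'
#' @param n_formulas Number of formulas to draw (default 5000).
#' @param class_shares Named percent vector over the seven classes (sums to
#'   at most 100).
#' @param group_probs Named probability vector over CHO/CHON/CHOS/CHONS.
#' @param intensity_meanlog,intensity_sdlog Log-normal intensity parameters.
#' @param seed RNG seed.
#' @return Configuration list for [generate_formula_table()].
#' @export
default_dom_config <- function(n_formulas = 5000,
                               class_shares = c(
                                 lignin_cram = 62.57,
                                 aliphatic_proteins = 22.97,
                                 lipids = 11.00,
                                 carbohydrates = 0.865,
                                 unsaturated_hc = 0.865,
                                 aromatic = 0.865,
                                 tannin = 0.865
                               ),
                               group_probs = c(CHO = 0.70, CHON = 0.25,
                                               CHOS = 0.03, CHONS = 0.02),
                               intensity_meanlog = 10,
                               intensity_sdlog = 1,
                               seed = 20260302) {
  stopifnot(n_formulas >= 1, all(class_shares >= 0),
            sum(class_shares) <= 100 + 1e-9, all(group_probs >= 0))
  list(n_formulas = n_formulas, class_shares = class_shares,
       group_probs = group_probs, intensity_meanlog = intensity_meanlog,
       intensity_sdlog = intensity_sdlog, seed = seed)
}

# Draw one formula whose realized class under classify_vk() equals `cls`.
# Rejection sampling inside the class's H/C-O/C box with integer atom
# counts; documented retry limit.
sample_formula_in_class <- function(cls, boundaries, max_tries = 1000L) {
  b <- boundaries[boundaries$class == cls, ]
  if (nrow(b) != 1L) stop("unknown class: ", cls, call. = FALSE)
  for (i in seq_len(max_tries)) {
    cc <- sample(4:40, 1L)
    hh <- round(stats::runif(1L, b$hc_lo, b$hc_hi) * cc)
    oo <- round(stats::runif(1L, b$oc_lo, b$oc_hi) * cc)
    if (hh < 1L || oo < 1L) next
    f <- data.frame(c = cc, h = hh, o = oo)
    if (classify_vk(f, boundaries) == cls) return(c(c = cc, h = hh, o = oo))
  }
  stop("could not sample a formula in class ", cls, " after ", max_tries,
       " tries", call. = FALSE)
}

#' Generate a synthetic FT-ICR-MS formula table
#'
#' Draws formulas class-by-class (multinomial over the target shares, any
#' share shortfall below 100% left as classes drawn proportionally) so that
#' every emitted formula's realized Van Krevelen class equals its intended
#' class; assigns element groups by adding N and/or S atoms (which do not
#' move the H/C-O/C coordinates) and log-normal relative intensities.
#'
#' @param config List from [default_dom_config()].
#' @param sample_id Sample label stored on every row.
#' @param boundaries Class boxes, default [vk_boundaries()].
#' @return Data frame with columns `c`, `h`, `o`, `n`, `s`,
#'   `relative_intensity`, `sample_id`, `class_intended`.
#' @export
generate_formula_table <- function(config = default_dom_config(),
                                   sample_id = "synthetic",
                                   boundaries = vk_boundaries()) {
  set.seed(config$seed)
  shares <- config$class_shares / sum(config$class_shares)
  cls_draw <- sample(names(shares), config$n_formulas, replace = TRUE,
                     prob = shares)
  base <- t(vapply(cls_draw, sample_formula_in_class, numeric(3L),
                   boundaries = boundaries))
  grp <- sample(names(config$group_probs), config$n_formulas, replace = TRUE,
                prob = config$group_probs)
  n_atoms <- ifelse(grp %in% c("CHON", "CHONS"), sample(1:3, config$n_formulas,
                                                        replace = TRUE), 0L)
  s_atoms <- ifelse(grp %in% c("CHOS", "CHONS"), sample(1:2, config$n_formulas,
                                                        replace = TRUE), 0L)
  data.frame(
    c = as.integer(base[, "c"]), h = as.integer(base[, "h"]),
    o = as.integer(base[, "o"]), n = as.integer(n_atoms),
    s = as.integer(s_atoms),
    relative_intensity = stats::rlnorm(config$n_formulas,
                                       config$intensity_meanlog,
                                       config$intensity_sdlog),
    sample_id = sample_id,
    class_intended = cls_draw,
    row.names = NULL
  )
}
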