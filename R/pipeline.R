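#' Blank-correct and average all channels of a BMP dataset
#'
#' Builds the mean blank curve per gram of inoculum-VS from the blank
#' channels, blank-corrects every test channel individually, then averages
#' replicates within each group (per-channel correction before averaging).
#'
#' @param logs Gas-log data frame (see [validate_gas_log()]).
#' @param meta Channel metadata (see [read_channel_meta()]).
#' @param basis `"methane"` or `"total_gas"`.
#' @return List with `group_curves` (named list of mean [yield_curve()]s),
#'   `replicate_curves` (named list of per-channel curves by group),
#'   `blank_curve` (per g inoculum-VS) and `timing` (data frame of
#'   [timing_stats()] per group).
#' @export
preprocess_bmp <- function(logs, meta, basis = "methane") {
  validate_gas_log(logs)
  split_logs <- split(logs, logs$channel_id)

  blank_ids <- meta$channel_id[meta$is_blank]
  blank_curve <- NULL
  if (length(blank_ids)) {
    per_blank <- lapply(blank_ids, function(id) {
      cum <- channel_cumulative(split_logs[[id]], basis)
      ivs <- meta$inoculum_vs[meta$channel_id == id]
      yield_curve(c(0, cum$times), c(0, cum$cumulative / ivs), basis = basis)
    })
    blank_curve <- average_curves(per_blank)$mean
  }

  test_ids <- meta$channel_id[!meta$is_blank]
  replicate_curves <- list()
  for (id in test_ids) {
    m <- meta[meta$channel_id == id, ]
    cv <- specific_methane_curve(split_logs[[id]], m, blank_curve,
                                 basis = basis)
    replicate_curves[[m$group_label]] <-
      c(replicate_curves[[m$group_label]], list(cv))
  }

  group_curves <- lapply(replicate_curves, function(x) average_curves(x)$mean)
  timing <- do.call(rbind, lapply(names(group_curves), function(g) {
    cbind(group = g, timing_stats(group_curves[[g]]))
  }))
  list(group_curves = group_curves, replicate_curves = replicate_curves,
       blank_curve = blank_curve, timing = timing)
}

#' Run the full BMP analysis pipeline
#'
#' Orchestrates preprocessing, kinetic fitting, stoichiometry, DOM
#' classification and economics from a single configuration. Stages run
#' independently: a stage whose inputs are absent is skipped with a notice,
#' and a stage that fails is reported without aborting the others. Given the
#' same configuration and inputs the output is deterministic.
#'
#' @param config List with any of:
#'   * `gas`: list(`logs`, `meta`) data frames (e.g. from
#'     [generate_bmp_dataset()]), plus optional `basis`;
#'   * `composition`: list(`c_pct`, `h_pct`, `o_pct`, `n_pct`,
#'     `vs_fraction`) for the substrate;
#'   * `formulas`: formula data frame for [vk_summary()], plus optional
#'     `dom_weighting`;
#'   * `economics`: data frame of scenarios (`label`, `emp`,
#'     `digestion_time`) plus optional constants `energy_density`,
#'     `efficiency`, `tariff`, `reference_period`;
#'   * `output_dir`: if set, tab-separated report tables are written there.
#' @return List of class `"bmp_report"` with elements `curves`, `timing`,
#'   `kinetics`, `stoichiometry`, `dom`, `economics` (those whose inputs
#'   were missing are `NULL`) and `log` (character vector of stage notices).
#' @export
run_pipeline <- function(config) {
  report <- list(curves = NULL, timing = NULL, kinetics = NULL,
                 stoichiometry = NULL, dom = NULL, economics = NULL,
                 log = character())
  note <- function(msg) report$log <<- c(report$log, msg)
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      note(sprintf("stage %s FAILED: %s", name, conditionMessage(e)))
      NULL
    })
  }

  if (!is.null(config$gas)) {
    pre <- run_stage("preprocess", {
      preprocess_bmp(config$gas$logs, config$gas$meta,
                     basis = config$gas$basis %||% "methane")
    })
    if (!is.null(pre)) {
      report$curves <- pre
      report$timing <- pre$timing
      note("stage preprocess: ok")
      report$kinetics <- run_stage("kinetics", {
        do.call(rbind, lapply(names(pre$group_curves), function(g) {
          fit_all_models(pre$group_curves[[g]], group = g)
        }))
      })
      if (!is.null(report$kinetics)) note("stage kinetics: ok")
    }
  } else {
    note("stage preprocess: skipped (no gas inputs)")
    note("stage kinetics: skipped (no gas inputs)")
  }

  if (!is.null(config$composition)) {
    report$stoichiometry <- run_stage("stoichiometry", {
      cmp <- config$composition
      subs <- composition_to_subscripts(cmp$c_pct, cmp$h_pct, cmp$o_pct,
                                        cmp$n_pct %||% 0)
      res <- buswell(subs)
      out <- data.frame(tmp_per_g_dry = res$tmp,
                        ch4_coeff = res$ch4_coeff, co2_coeff = res$co2_coeff,
                        nh3_coeff = res$nh3_coeff)
      emp <- cmp$emp %||% if (!is.null(report$curves)) {
        max(vapply(report$curves$group_curves,
                   function(cv) cv$cumulative[nrow(cv)], numeric(1)))
      } else {
        NULL
      }
      if (!is.null(emp) && !is.null(cmp$vs_fraction)) {
        bd <- biodegradability(emp, res$tmp, "per_g_dry", cmp$vs_fraction)
        out$emp <- emp
        out$tmp_per_g_vs <- bd$tmp_per_g_vs
        out$bd_pct <- bd$bd
      }
      out
    })
    if (!is.null(report$stoichiometry)) note("stage stoichiometry: ok")
  } else {
    note("stage stoichiometry: skipped (no composition)")
  }

  if (!is.null(config$formulas)) {
    report$dom <- run_stage("dom", {
      vk_summary(config$formulas,
                 weighting = config$dom_weighting %||% "intensity")
    })
    if (!is.null(report$dom)) note("stage dom: ok")
  } else {
    note("stage dom: skipped (no formula table)")
  }

  if (!is.null(config$economics)) {
    report$economics <- run_stage("economics", {
      ec <- config$economics
      economics_table(
        ec,
        reference_period = config$reference_period %||% 100,
        energy_density = config$energy_density %||% 9.97,
        efficiency = config$efficiency %||% 0.6,
        tariff = config$tariff %||% 0.75
      )
    })
    if (!is.null(report$economics)) note("stage economics: ok")
  } else {
    note("stage economics: skipped (no scenarios)")
  }

  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
    wr <- function(x, f) {
      if (!is.null(x)) {
        utils::write.table(x, file.path(config$output_dir, f), sep = "\t",
                           row.names = FALSE, quote = FALSE)
      }
    }
    if (!is.null(report$curves)) {
      write_group_curves(report$curves$replicate_curves,
                         file.path(config$output_dir, "curves.tsv"))
    }
    wr(report$timing, "timing.tsv")
    wr(report$kinetics, "kinetics.tsv")
    wr(report$stoichiometry, "stoichiometry.tsv")
    if (!is.null(report$dom)) {
      wr(data.frame(class = names(report$dom$class_share),
                    share_pct = unname(report$dom$class_share)), "dom.tsv")
    }
    wr(report$economics, "economics.tsv")
    writeLines(report$log, file.path(config$output_dir, "run_log.txt"))
  }

  class(report) <- "bmp_report"
  report
}

#' @export
print.bmp_report <- function(x, ...) {
  cat("<bmp_report>\n")
  for (line in x$log) cat(" ", line, "\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
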