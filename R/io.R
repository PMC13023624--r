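#' Read a delimiter-separated gas log
#'
#' Reads an AMPTS-style gas log with a header row. Column names in the file
#' are mapped onto the canonical names via `columns`; timestamps may be
#' elapsed hours (numeric) or ISO datetimes, which are converted to elapsed
#' hours from the earliest timestamp in the file.
#'
#' @param path File path.
#' @param sep Field separator (default tab).
#' @param columns Named character vector mapping canonical names
#'   (`channel_id`, `time`, `volume_increment`, `temperature`, `pressure`,
#'   `ch4_fraction`) to the file's column names; identity by default.
#' @return Validated gas-log data frame (see [validate_gas_log()]).
#' @export
read_gas_log <- function(path, sep = "\t", columns = NULL) {
  raw <- utils::read.delim(path, sep = sep, header = TRUE,
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(columns)) {
    for (canon in names(columns)) {
      src <- columns[[canon]]
      if (!src %in% names(raw)) {
        stop("column ", src, " not found in ", path, call. = FALSE)
      }
      names(raw)[names(raw) == src] <- canon
    }
  }
  if (is.character(raw$time)) {
    ts <- as.POSIXct(raw$time, tz = "UTC")
    if (anyNA(ts)) stop("unparseable timestamps in ", path, call. = FALSE)
    raw$time <- as.numeric(difftime(ts, min(ts), units = "hours"))
  }
  validate_gas_log(raw)
  raw
}

#' Read a channel-metadata table
#'
#' @param path File path to a delimiter-separated table with columns
#'   `channel_id`, `group_label`, `substrate_vs`, `inoculum_vs`, `is_blank`,
#'   `replicate_index`.
#' @param sep Field separator.
#' @return Data frame of channel metadata.
#' @export
read_channel_meta <- function(path, sep = "\t") {
  meta <- utils::read.delim(path, sep = sep, header = TRUE,
                            stringsAsFactors = FALSE)
  needed <- c("channel_id", "group_label", "substrate_vs", "inoculum_vs",
              "is_blank")
  missing <- setdiff(needed, names(meta))
  if (length(missing)) {
    stop("metadata missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  meta$is_blank <- as.logical(meta$is_blank)
  if (any(meta$inoculum_vs <= 0)) stop("inoculum_vs must be positive", call. = FALSE)
  if (any(meta$substrate_vs[meta$is_blank] != 0)) {
    stop("blank channels must have substrate_vs = 0", call. = FALSE)
  }
  meta
}

#' Read an FT-ICR-MS formula-assignment table
#'
#' Accepts either per-element count columns (`c`, `h`, `o`, `n`, `s`) or a
#' `formula` column of strings like `"C10H12O5N1"` (parsed with
#' [parse_formula()]), plus `relative_intensity` and optionally `sample_id`.
#'
#' @param path File path.
#' @param sep Field separator.
#' @return Formula data frame ready for [vk_summary()].
#' @export
read_formula_table <- function(path, sep = "\t") {
  raw <- utils::read.delim(path, sep = sep, header = TRUE,
                           stringsAsFactors = FALSE)
  if (!all(c("c", "h", "o") %in% names(raw))) {
    if (!"formula" %in% names(raw)) {
      stop("need either c/h/o count columns or a formula column", call. = FALSE)
    }
    counts <- parse_formula(raw$formula)
    raw <- cbind(raw[setdiff(names(raw), names(counts))], counts)
  }
  if (!"relative_intensity" %in% names(raw)) {
    stop("missing relative_intensity column", call. = FALSE)
  }
  raw
}

#' Write a tidy per-group production table
#'
#' One row per group and time point with replicate mean and sd of the
#' cumulative specific yield.
#'
#' @param curves Named list (by group) of lists of [yield_curve()]s
#'   (replicates).
#' @param path Output path (tab-separated).
#' @return The written data frame, invisibly.
#' @export
write_group_curves <- function(curves, path) {
  rows <- lapply(names(curves), function(g) {
    avg <- average_curves(curves[[g]])
    data.frame(group = g, times = avg$mean$times,
               cumulative_mean = avg$mean$cumulative, cumulative_sd = avg$sd)
  })
  out <- do.call(rbind, rows)
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(out)
}
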