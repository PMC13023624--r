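#' Van Krevelen class boundaries
#'
#' The seven compound-class boxes in the H/C vs O/C plane conventionally used
#' to bin dissolved organic matter formulas, in precedence order: lipids,
#' aliphatic/proteins, lignin/CRAM-like, carbohydrates, unsaturated
#' hydrocarbons, aromatic structures, tannins. Boxes overlap on shared
#' edges; classification resolves ties by first match in this order with
#' half-open [low, high) intervals, the upper edges of the last-listed class
#' being inclusive so the listed ranges cover their stated extent.
#'
#' @return Data frame with columns `class`, `hc_lo`, `hc_hi`, `oc_lo`,
#'   `oc_hi`, `hi_inclusive`.
#' @export
vk_boundaries <- function() {
  b <- data.frame(
    class = c("lipids", "aliphatic_proteins", "lignin_cram", "carbohydrates",
              "unsaturated_hc", "aromatic", "tannin"),
    hc_lo = c(1.5, 1.5, 0.7, 1.5, 0.7, 0.2, 0.6),
    hc_hi = c(2.0, 2.2, 1.5, 2.4, 1.5, 0.7, 1.5),
    oc_lo = c(0.0, 0.3, 0.1, 0.67, 0.0, 0.0, 0.67),
    oc_hi = c(0.3, 0.67, 0.67, 1.2, 0.1, 0.67, 1.0),
    stringsAsFactors = FALSE
  )
  b$hi_inclusive <- c(rep(FALSE, nrow(b) - 1L), TRUE)
  b
}

#' All Van Krevelen class labels, including the unassigned bucket
#' @return Character vector of the eight class labels.
#' @export
vk_classes <- function() c(vk_boundaries()$class, "unassigned")

#' H/C and O/C atomic ratios of formulas
#'
#' @param formulas Data frame with integer atom-count columns `c`, `h`, `o`
#'   (and optionally `n`, `s`).
#' @return Data frame with columns `hc` and `oc`.
#' @export
hc_oc <- function(formulas) {
  if (any(formulas$c < 1)) stop("formulas must contain carbon (c >= 1)", call. = FALSE)
  data.frame(hc = formulas$h / formulas$c, oc = formulas$o / formulas$c)
}

#' Classify formulas into Van Krevelen compound classes
#'
#' Assigns each formula the first class (in `boundaries` order) whose H/C and
#' O/C box contains its atomic ratios; formulas outside every box are
#' `"unassigned"` and retained, so class shares always partition the sample.
#'
#' @param formulas Data frame with columns `c`, `h`, `o` (see [hc_oc()]).
#' @param boundaries Class boxes and precedence, default [vk_boundaries()].
#' @return Character vector of class labels, one per formula.
#' @examples
#' classify_vk(data.frame(c = 10, h = 12, o = 5))  # H/C 1.2, O/C 0.5
#' @export
classify_vk <- function(formulas, boundaries = vk_boundaries()) {
  r <- hc_oc(formulas)
  out <- rep("unassigned", nrow(r))
  unset <- rep(TRUE, nrow(r))
  for (i in seq_len(nrow(boundaries))) {
    b <- boundaries[i, ]
    hit <- r$hc >= b$hc_lo & r$oc >= b$oc_lo &
      (if (b$hi_inclusive) r$hc <= b$hc_hi & r$oc <= b$oc_hi
       else r$hc < b$hc_hi & r$oc < b$oc_hi)
    take <- hit & unset
    out[take] <- b$class
    unset <- unset & !hit
  }
  out
}

#' Element group of formulas (CHO / CHON / CHOS / CHONS)
#'
#' Grouped by the presence of nitrogen and sulfur. Formulas without oxygen do
#' not belong to any of the four DOM groups and land in an `"other"` bucket
#' (reported with a message rather than dropped).
#'
#' @param formulas Data frame with columns `c`, `h`, `o` and optionally `n`,
#'   `s` (missing columns are treated as zero).
#' @return Character vector of group labels.
#' @export
element_group <- function(formulas) {
  n <- if ("n" %in% names(formulas)) formulas$n else rep(0, nrow(formulas))
  s <- if ("s" %in% names(formulas)) formulas$s else rep(0, nrow(formulas))
  out <- ifelse(n > 0 & s > 0, "CHONS",
         ifelse(n > 0, "CHON",
         ifelse(s > 0, "CHOS", "CHO")))
  no_o <- formulas$o == 0
  if (any(no_o)) {
    message(sum(no_o), " formula(s) without oxygen assigned to group 'other'")
    out[no_o] <- "other"
  }
  out
}

#' Parse molecular formula strings
#'
#' Parses strings of the form `"C10H12O5"` / `"C5H9O3N1S1"` (element order
#' free, counts optional: `"CH4"` means C1H4) into atom-count columns.
#'
#' @param x Character vector of formula strings over the elements C, H, O,
#'   N, S.
#' @return Data frame with integer columns `c`, `h`, `o`, `n`, `s`.
#' @export
parse_formula <- function(x) {
  out <- matrix(0L, nrow = length(x), ncol = 5L,
                dimnames = list(NULL, c("c", "h", "o", "n", "s")))
  for (i in seq_along(x)) {
    m <- gregexpr("([CHONS])([0-9]*)", x[[i]])
    if (m[[1L]][1L] == -1L ||
        sum(attr(m[[1L]], "match.length")) != nchar(x[[i]])) {
      stop("cannot parse formula: ", x[[i]], call. = FALSE)
    }
    parts <- regmatches(x[[i]], m)[[1L]]
    for (p in parts) {
      el <- tolower(substr(p, 1L, 1L))
      cnt <- substr(p, 2L, nchar(p))
      out[i, el] <- out[i, el] + if (nchar(cnt)) as.integer(cnt) else 1L
    }
  }
  as.data.frame(out)
}

#' Intensity-weighted Van Krevelen composition summary
#'
#' Per-class and per-element-group shares of a formula table, weighted by
#' relative intensity (default) or by formula count. Each partition sums to
#' 100.
#'
#' @param formulas Data frame with atom-count columns `c`, `h`, `o`
#'   (optionally `n`, `s`) and, for intensity weighting, a
#'   `relative_intensity` column.
#' @param weighting `"intensity"` or `"count"`.
#' @param boundaries Class boxes, default [vk_boundaries()].
#' @return List of class `"vk_summary"`: `class_share` and `group_share`
#'   (named numeric vectors in percent), `weighting`, `n_formulas`.
#' @export
vk_summary <- function(formulas, weighting = c("intensity", "count"),
                       boundaries = vk_boundaries()) {
  weighting <- match.arg(weighting)
  if (nrow(formulas) == 0L) stop("empty formula table", call. = FALSE)
  w <- if (weighting == "intensity") {
    if (!"relative_intensity" %in% names(formulas)) {
      stop("intensity weighting requires a relative_intensity column",
           call. = FALSE)
    }
    formulas$relative_intensity
  } else {
    rep(1, nrow(formulas))
  }
  if (any(w < 0) || !all(is.finite(w))) stop("invalid weights", call. = FALSE)
  tot <- sum(w)
  if (tot <= 0) stop("zero total weight", call. = FALSE)

  cls <- factor(classify_vk(formulas, boundaries),
                levels = c(boundaries$class, "unassigned"))
  class_share <- 100 * tapply(w, cls, sum, default = 0) / tot

  grp <- suppressMessages(element_group(formulas))
  grp <- factor(grp, levels = c("CHO", "CHON", "CHOS", "CHONS", "other"))
  group_share <- 100 * tapply(w, grp, sum, default = 0) / tot
  if (group_share[["other"]] == 0) {
    group_share <- group_share[setdiff(names(group_share), "other")]
  }

  structure(
    list(class_share = c(class_share), group_share = c(group_share),
         weighting = weighting, n_formulas = nrow(formulas)),
    class = "vk_summary"
  )
}

#' @export
print.vk_summary <- function(x, ...) {
  cat(sprintf("<vk_summary> %d formulas, %s-weighted\n", x$n_formulas,
              x$weighting))
  for (nm in names(x$class_share)) {
    if (x$class_share[[nm]] > 0) {
      cat(sprintf("  %-20s %6.2f%%\n", nm, x$class_share[[nm]]))
    }
  }
  cat("  element groups: ",
      paste(sprintf("%s %.2f%%", names(x$group_share), x$group_share),
            collapse = ", "), "\n")
  invisible(x)
}

#' Van Krevelen scatter coordinates for plotting
#'
#' @param formulas Formula table (see [vk_summary()]).
#' @param boundaries Class boxes.
#' @return Data frame with `hc`, `oc`, `class` and, when present,
#'   `relative_intensity` — ready for a Van Krevelen diagram.
#' @export
vk_coordinates <- function(formulas, boundaries = vk_boundaries()) {
  out <- cbind(hc_oc(formulas),
               class = classify_vk(formulas, boundaries))
  if ("relative_intensity" %in% names(formulas)) {
    out$relative_intensity <- formulas$relative_intensity
  }
  out
}
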