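#' Molar subscripts from an elemental composition
#'
#' Converts dry-basis mass percentages of C, H, O and N into molar subscripts
#' (n, a, b, c) of the empirical formula CnHaObNc. Nominal integer atomic
#' masses (12, 1, 16, 14) are used so the result is consistent with the
#' Buswell methane-potential formula, whose denominator is `12n + a + 16b +
#' 14c`. The subscripts are only defined up to a common factor; the
#' theoretical methane potential is invariant to that scale.
#'
#' @param c_pct,h_pct,o_pct,n_pct Mass percent of each element on a dry
#'   basis (each >= 0; carbon > 0). Their sum may be below 100 (ash etc.).
#' @return Named numeric vector `c(n, a, b, c)` (subscripts per 100 g dry
#'   matter).
#' @examples
#' composition_to_subscripts(42.08, 6.60, 50.98, 0.01)  # xylan
#' @export
composition_to_subscripts <- function(c_pct, h_pct, o_pct, n_pct = 0) {
  vals <- c(c_pct, h_pct, o_pct, n_pct)
  if (any(vals < 0)) stop("mass percentages must be non-negative", call. = FALSE)
  if (c_pct <= 0) stop("carbon content must be positive", call. = FALSE)
  if (sum(vals) > 101) {
    stop("mass percentages sum above 100% (beyond 1% tolerance)", call. = FALSE)
  }
  c(n = c_pct / 12, a = h_pct / 1, b = o_pct / 16, c = n_pct / 14)
}

#' Buswell stoichiometry and theoretical methane potential
#'
#' Balances the total anaerobic-digestion reaction
#' \deqn{C_nH_aO_bN_c + (n - a/4 - b/2 + 3c/4) H_2O \rightarrow
#'   (n/2 + a/8 - b/4 - 3c/8) CH_4 + (n/2 - a/8 + b/4 + 3c/8) CO_2 + c NH_3}
#' and computes the theoretical methane potential
#' \deqn{TMP = 22.4 \times 1000 \times
#'   \frac{n/2 + a/8 - b/4 - 3c/8}{12n + a + 16b + 14c}}
#' in mL CH4 per g substrate, using the molar volume 22.4 L/mol and nominal
#' atomic masses 12/1/16/14 as conventional for this formula. Sulfur is not
#' part of the reaction.
#'
#' @param subs Named vector/list with subscripts `n`, `a`, `b`, `c` (see
#'   [composition_to_subscripts()]).
#' @param basis Label recorded in the result: `"per_g_dry"` (default, when
#'   subscripts come from dry-basis composition) or `"per_g_vs"`.
#' @return List of class `"stoich_result"`: `tmp` (mL/g), `ch4_coeff`,
#'   `co2_coeff`, `nh3_coeff`, `h2o_coeff`, `subs`, `basis`.
#' @examples
#' buswell(c(n = 5, a = 8, b = 4, c = 0))  # xylan repeating unit C5H8O4
#' @export
buswell <- function(subs, basis = c("per_g_dry", "per_g_vs")) {
  basis <- match.arg(basis)
  s <- as.list(subs)
  for (nm in c("n", "a", "b", "c")) {
    if (is.null(s[[nm]]) || !is.finite(s[[nm]]) || s[[nm]] < 0) {
      stop("subscript ", nm, " must be a non-negative number", call. = FALSE)
    }
  }
  if (s$n <= 0) stop("subscript n must be positive", call. = FALSE)
  ch4 <- s$n / 2 + s$a / 8 - s$b / 4 - 3 * s$c / 8
  if (ch4 <= 0) {
    stop("substrate is not methanogenic: CH4 coefficient <= 0", call. = FALSE)
  }
  co2 <- s$n / 2 - s$a / 8 + s$b / 4 + 3 * s$c / 8
  h2o <- s$n - s$a / 4 - s$b / 2 + 3 * s$c / 4
  mw <- 12 * s$n + s$a + 16 * s$b + 14 * s$c
  structure(
    list(tmp = 22.4 * 1000 * ch4 / mw,
         ch4_coeff = ch4, co2_coeff = co2, nh3_coeff = s$c, h2o_coeff = h2o,
         subs = c(n = s$n, a = s$a, b = s$b, c = s$c), basis = basis),
    class = "stoich_result"
  )
}

#' @export
print.stoich_result <- function(x, ...) {
  cat(sprintf(
    "<stoich_result> TMP = %.2f mL CH4/g (%s); CH4 %.4g, CO2 %.4g, NH3 %.4g, H2O %.4g\n",
    x$tmp, x$basis, x$ch4_coeff, x$co2_coeff, x$nh3_coeff, x$h2o_coeff))
  invisible(x)
}

#' Element balance check of a Buswell result
#'
#' Verifies that C, H, O and N each balance between the two sides of the
#' total reaction, to a relative tolerance.
#'
#' @param result A `"stoich_result"` from [buswell()] (possibly perturbed).
#' @param tol Relative tolerance (default 1e-9).
#' @return Data frame with one row per element: `element`, `lhs`, `rhs`,
#'   `rel_imbalance`, `pass`.
#' @export
element_balance_check <- function(result, tol = 1e-9) {
  s <- as.list(result$subs)
  lhs <- c(C = s$n,
           H = s$a + 2 * result$h2o_coeff,
           O = s$b + result$h2o_coeff,
           N = s$c)
  rhs <- c(C = result$ch4_coeff + result$co2_coeff,
           H = 4 * result$ch4_coeff + 3 * result$nh3_coeff,
           O = 2 * result$co2_coeff,
           N = result$nh3_coeff)
  scale <- pmax(abs(lhs), abs(rhs), 1)
  rel <- abs(lhs - rhs) / scale
  data.frame(element = names(lhs), lhs = unname(lhs), rhs = unname(rhs),
             rel_imbalance = unname(rel), pass = unname(rel <= tol))
}

#' Biodegradability from experimental and theoretical methane potential
#'
#' BD = 100 * EMP / TMP after aligning the bases. EMP from a BMP assay is
#' per gram of substrate-VS; TMP from a dry-basis elemental composition is
#' per gram of dry matter. When the bases differ, the VS fraction of dry
#' matter converts TMP to a per-g-VS value (`tmp / vs_fraction`); without it
#' a mismatch is an error rather than a silently biased ratio.
#'
#' @param emp Experimental methane production, mL CH4/g VS (>= 0).
#' @param tmp Theoretical methane potential, mL CH4/g (> 0).
#' @param tmp_basis Basis of `tmp`: `"per_g_dry"` or `"per_g_vs"`.
#' @param vs_fraction VS fraction of dry matter in (0, 1], required when
#'   `tmp_basis = "per_g_dry"`.
#' @return List of class `"bd_result"`: `emp`, `tmp` (as given),
#'   `tmp_per_g_vs`, `bd` (percent), `tmp_basis`.
#' @export
biodegradability <- function(emp, tmp, tmp_basis = c("per_g_dry", "per_g_vs"),
                             vs_fraction = NULL) {
  tmp_basis <- match.arg(tmp_basis)
  if (tmp <= 0) stop("tmp must be positive", call. = FALSE)
  if (emp < 0) stop("emp must be non-negative", call. = FALSE)
  tmp_vs <- if (tmp_basis == "per_g_vs") {
    tmp
  } else {
    if (is.null(vs_fraction)) {
      stop("vs_fraction required to convert per-g-dry TMP to the per-g-VS ",
           "basis of EMP", call. = FALSE)
    }
    if (vs_fraction <= 0 || vs_fraction > 1) {
      stop("vs_fraction must lie in (0, 1]", call. = FALSE)
    }
    tmp / vs_fraction
  }
  structure(
    list(emp = emp, tmp = tmp, tmp_per_g_vs = tmp_vs,
         bd = 100 * emp / tmp_vs, tmp_basis = tmp_basis),
    class = "bd_result"
  )
}

#' @export
print.bd_result <- function(x, ...) {
  cat(sprintf("<bd_result> BD = %.2f%% (EMP %.2f mL/g VS, TMP %.2f mL/g %s)\n",
              x$bd, x$emp, x$tmp, x$tmp_basis))
  invisible(x)
}
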