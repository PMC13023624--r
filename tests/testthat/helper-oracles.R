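# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: the stoichiometry oracle solves the reaction
# balance as a linear system instead of using the closed-form coefficients,
# and the termination oracle evaluates the stop rule by literal enumeration.

# Balance CnHaObNc + w H2O -> x CH4 + y CO2 + c NH3 by linear algebra:
#   C: x + y = n;  H: a + 2w = 4x + 3c;  O: b + w = 2y.
# Returns the methane volume per gram with nominal masses, as an independent
# route to the theoretical methane potential.
oracle_buswell <- function(n, a, b, c) {
  A <- rbind(
    c(0, 1, 1),   # C
    c(-2, 4, 0),  # H
    c(-1, 0, 2)   # O
  )
  rhs <- c(n, a - 3 * c, b)
  sol <- solve(A, rhs)  # (w, x, y)
  list(
    h2o = sol[1], ch4 = sol[2], co2 = sol[3], nh3 = c,
    tmp = 22.4 * 1000 * sol[2] / (12 * n + a + 16 * b + 14 * c)
  )
}

# Literal enumeration of the instrument stop rule: first day ending `window`
# consecutive days each below `threshold` of the running cumulative total.
oracle_termination <- function(daily, window = 3L, threshold = 0.01) {
  total <- cumsum(daily)
  for (d in seq_along(daily)) {
    if (d < window) next
    idx <- (d - window + 1L):d
    if (all(daily[idx] < threshold * total[idx] & total[idx] > 0)) return(d)
  }
  NULL
}

# Smallest whole day at which the running cumulative sum of a daily series
# reaches a fraction of its final value (brute-force scan).
oracle_t_fraction <- function(daily, fraction) {
  cum <- cumsum(daily)
  which(cum >= fraction * cum[length(cum)])[1L]
}

# A realistic noiseless test curve: first-order yield on a daily grid.
fixture_curve <- function(B0 = 350, k = 0.6, days = 0:25) {
  yield_curve(days, model_curve("first_order", list(B0 = B0, k = k), days))
}
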