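---
title: "Models and methods behind bmpkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind bmpkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bmpkit)
```

This vignette explains the models implemented in bmpkit, the assumptions
behind them, the numerical choices that matter, and what the synthetic-data
generator does and does not emulate.

## The assay and its preprocessing

A biochemical methane potential (BMP) assay incubates a substrate with
anaerobic inoculum in sealed, stirred, mesophilic (35 °C) batch reactors
and meters the gas produced, typically on an hourly tick. Three things
separate a raw log from a publishable curve:

1. **Volume normalization.** Meter volumes depend on headspace temperature
   and pressure; `normalize_to_stp()` applies the ideal-gas ratio to 273.15
   K / 101.325 kPa. We assume water-vapour-free headspace readings and
   apply no moisture correction; systems that need one should correct
   upstream. Volumes are weighted by the CH4 fraction when the basis is
   methane; a missing fraction under that basis is an error, not a silent
   assumption of pure methane.
2. **Blank correction.** The inoculum itself produces methane. Blank
   (inoculum-only) channels are normalized per gram of inoculum-VS,
   averaged, rescaled by each test channel's inoculum-VS load, and
   subtracted *per channel* before replicates are averaged. The convention
   of VS-proportional blank scaling is standard for BMP work; the order
   (correct, then average) keeps channel-level meter faults visible.
   Because subtraction can transiently dip below zero under noise, the
   corrected curve is clamped to be non-negative and non-decreasing;
   a blank that exceeds the test channel *at the final time* is a real
   anomaly and flags the curve with a warning instead of being hidden.
3. **Binning.** Day `d` covers elapsed hours `(24(d-1), 24d]`, so a
   start-up burst lands in day 1 — this matches how a "first-day peak" is
   reported for rapidly degraded substrates. Daily values are first
   differences of the cumulative curve at whole days and always sum to the
   final cumulative value exactly.

`timing_stats()` reports T50/T90/T95 as the earliest whole day reaching
the corresponding fraction of the curve's **own final value**, not of a
fitted asymptote: the statistic then exists for every measured curve and
matches the integer-day resolution these numbers are reported at.
`detect_termination()` implements the instrument's stop rule (production
below 1% of the running cumulative total for three consecutive days).

## Kinetic models

Four closed forms are fitted to the cumulative specific curve B(t):
Modified Gompertz and Logistic (sigmoids parameterized by the ultimate
yield B0, maximum rate Rmax and lag λ), Cone (B0, rate constant k, shape
n) and first-order (B0, k). All are non-decreasing and bounded by B0 for
valid parameters; Cone and first-order pass through the origin, and Cone's
value at t = 0 is taken as 0 by continuous extension of `B0/(1+(kt)^-n)`.

Fitting is bounded Levenberg–Marquardt nonlinear least squares
(`minpack.lm::nls.lm`) on the original scale. Because the original fits in
this problem domain are usually done in point-and-click software with
unreported settings, initialization is data-driven and deliberately dumb:
B0 starts at the observed maximum, Rmax at the steepest observed daily
increment, λ at the first day exceeding 1% of the final value, k at 0.5/d
and n at 2, with a 0.5/1/2 multi-start grid on every parameter and the
best residual sum of squares kept. Bounds keep all parameters
non-negative, λ within the assay duration and B0 below three times the
observed final value, which prevents divergent asymptotes on short series.
Convergence tolerances are tightened (`ftol = ptol = 1e-14`) so that
noiseless self-generated data are recovered to better than 1e-6 relative
error — the suite checks exactly that on 26-point daily grids. R² is the
plain (unadjusted) `1 - SS_res/SS_tot`, reported in percent to 2 decimals
in the comparison table; the t = 0 point enters the fit as measured.

Two deliberate reporting choices: the Cone shape parameter n is always
estimated freely and always reported, even though comparison tables in the
literature often omit it (omitting it makes published Cone fits
unrecoverable); and a model that fails all starts is reported with
`converged = FALSE` rather than dropped, so a four-model table always has
four rows.

A caution on model ordering: the Cone model's free shape lets it bend into
the lagged sigmoids real BMP curves show, so its R² typically beats the
first-order model's on real data. That ordering is *not* a mathematical
nesting — on data whose true generator is first-order, Cone can fit
marginally worse — so the package's ordering test uses a lagged
(Gompertz-generated) fixture, which is the regime the claim is about.

Substrate hydrolysis is first-order, `S_t = S0 exp(-k_deg t)`.
`fit_hydrolysis()` defaults to nonlinear least squares on the original
concentration scale because a log transform inflates the weight of
near-zero late-time points exactly where a rapidly hydrolysed substrate is
noisiest; the log-linear route is available as an option and agrees
exactly on noiseless data. `hydrolysis_k_single_point()` inverts the decay
from one removal fraction — with a removal of 97.96% at day 4 it returns
0.97/d — and agrees with the full fit on noiseless two-point data by
construction. Non-positive concentrations are excluded with a warning on
both routes.

## Buswell stoichiometry

The theoretical methane potential treats the substrate CnHaObNc as fully
converted to CH4, CO2 and NH3 with water closing the balance. The
implementation uses the closed-form coefficients; the test suite solves
the element balance as an independent linear system and requires agreement
to 1e-9 relative on 1000 random compositions. Two numerical conventions
are locked in deliberately: the molar volume 22.4 L/mol and nominal
integer atomic masses (12/1/16/14). CODATA values would change TMP by a
few tenths of a percent and break comparability with the standard printed
formula; bit-compatibility with that formula wins. Sulfur is ignored (the
total reaction carries no S term).

Biodegradability BD = 100·EMP/TMP is basis-sensitive: EMP is measured per
g VS, TMP per g dry matter when derived from a dry-basis elemental
analysis. The package refuses to divide mismatched bases without a VS
fraction and reports BD under both conventions in the analysis scripts —
for a nearly ash-free polysaccharide the repeating-unit basis
(TMP = 424.24 mL/g for C5H8O4) and the elemental basis (400.38 mL/g for
the measured composition) bracket plausible published values, and neither
is privileged.

## Van Krevelen classification

Formulas are classified by H/C and O/C into seven classes whose
conventional boxes overlap on shared edges (O/C = 0.3 between lipids and
aliphatic/proteins; H/C = 1.5 between lignin/CRAM-like and lipids;
O/C = 0.67 between lignin/CRAM-like and tannins). Published class lists
give no tie rule, so the package resolves ties deterministically:
first match in the listed precedence order with half-open `[low, high)`
intervals, the upper edges of the last-listed class (tannins) being
inclusive so its stated range keeps its full extent. The precedence table
is data (`vk_boundaries()`) and can be reordered or replaced by the user.
Formulas outside every box are kept as an explicit `unassigned` share so
the class partition always sums to 100; formulas without oxygen cannot
belong to any of the CHO/CHON/CHOS/CHONS element groups and land in a
reported `other` bucket. Whether published composition figures are
intensity- or count-weighted is often unstated; both weightings are
implemented, intensity being the default, and they coincide when all
intensities are equal. Isotopologues and adducts are out of scope — input
is assumed to be monoisotopic neutral assigned formulas.

## Economics

The chain is linear and transparent: SMY = EMP × reference/digestion-time
(reference period 100 d), power = SMY[m³] × energy density × efficiency,
benefit = power × tariff. The energy density of methane defaults to
9.97 kWh/m³ (≈35.9 MJ/m³): published benefit tables of this kind rarely
state the value, and 9.97 is the value back-consistent with a reference
scenario of 405.80 mL SMY yielding 2.43×10⁻³ kWh at 60% efficiency. It is
a configurable argument, and relative comparisons
(`benefit_increase_pct()`) are exactly invariant to it — and to efficiency
and tariff — whenever both scenarios share the constants, a property the
suite verifies over random constants.

## The synthetic-data generator

`generate_bmp_dataset()` emulates the study design end to end: three
substrate groups at ISR 2/3/4 (VS basis) with three replicate channels
each plus three inoculum-only blanks, hourly ticks for 25 days at 308.15 K
meter conditions, first-order true kinetics per group with ultimate yields
343.76/374.72/364.76 mL/g VS and rate constants 0.62/0.64/0.55 /d (the
HC2/HC3/HC4 regime of a rapidly degraded hemicellulose), and a small
first-order inoculum background (10 mL per g inoculum-VS at 0.1 /d —
published work subtracts a blank but never prints its curve, so this is
the package's own choice of a weak, slowly decaying endogenous signal).
Substrate loads are 2 g VS per channel, in the range a 400 mL mesophilic
reactor at ~8% TS implies. The default CH4 fraction is 1, matching meters
that log methane after external CO2 absorption; a constant fraction below
1 converts the logs to total-gas volumes with a composition column.

Noise is additive Gaussian on per-tick increments, truncated at zero
(flow meters cannot tick backwards), with sd equal to 2% of the channel's
mean noiseless increment by default — the "2% meter noise" condition used
throughout the tests; an absolute mL value can be given instead.
Truncation makes the noise slightly asymmetric on near-zero late-time
ticks, which is exactly what real tipping-bucket meters do, and is the
reason the noisy-recovery checks score the *rate constant*, which absorbs
that bias well below the 5% acceptance band.

The generator is a pure function of its configuration and seed (default
seed 20260302, recorded in the ground-truth record): identical reruns are
byte-identical, and with zero noise the preprocessing chain reproduces the
true specific curves to floating-point accuracy (≤1e-9 relative), which
is the package's strongest end-to-end correctness check.

`generate_formula_table()` draws formulas class-by-class inside each
class's H/C–O/C box by rejection over integer atom counts (C between 4 and
40, at least one O, retry limit 1000), so every emitted formula's realized
class equals its intended class by construction; element groups are
assigned by adding N/S atoms, which leaves the H/C–O/C coordinates
untouched; intensities are log-normal. Default target shares put
62.57/22.97/11.00% in lignin-CRAM/aliphatic-proteins/lipids — the
composition of a granular-sludge liquid phase at the start of digestion —
with the 3.46% remainder spread evenly over the other four classes.

**What the generator does not emulate**, and hence what green tests do not
demonstrate about real data: pH and VFA inhibition dynamics (the true
curves are time-invariant closed forms, so a transient acidification
plateau would violate the first-order truth), meter drift and
temperature excursions, replicate heterogeneity beyond iid noise,
correlated formula intensities, and any microbial community structure.
Parameter recovery on synthetic data bounds estimation error under the
stated noise model only.

## Problem sizes and determinism

The test suite and the acceptance script size their simulations to run on
a single CPU in well under the package's own CI budget: 26-point daily
grids for self-fits, 100-seed noisy-recovery studies on a single group
with three replicates plus blanks, 5000-formula DOM tables, 1000-draw
stoichiometry sweeps, 10 000-formula partition checks. All randomness
flows from explicit seeds; the acceptance script derives every per-run
seed from its `--seed` argument.

## Known limitations

* The kinetic fits summarize curve shape; they are not mechanistic
  (no ADM1-style multi-population model, no Bayesian uncertainty).
* T-statistics at whole-day resolution saturate for substrates that reach
  50% inside the first day — T50 = 1 is a floor, not an estimate.
* BD inherits the TMP basis ambiguity discussed above; comparisons of BD
  across publications that leave the basis unstated carry a few percent
  of irreducible slack.
* The economics module prices energy only; capital and operating costs,
  discounting and net-present-value analysis are out of scope.
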