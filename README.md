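# bmpkit

Analysis chain for biochemical methane potential (BMP) batch assays of
lignocellulosic substrates, built around the anaerobic digestion of xylan
(the model hemicellulose) at inoculum-to-substrate ratios (ISR) of 2:1, 3:1
and 4:1. It is aimed at anaerobic-digestion researchers who run automatic
methane potential test systems (AMPTS-style gas-flow meters) and want a
scripted, testable route from raw gas logs to kinetic parameters,
theoretical yields, dissolved-organic-matter composition and
methane-to-electricity economics.

## What it computes

**Gas preprocessing.** Per-tick meter volumes are converted to standard
conditions (273.15 K, 101.325 kPa) by the ideal-gas ratio, weighted by the
CH4 fraction, accumulated, blank-corrected by the inoculum-only channels
(scaled by inoculum-VS), and divided by substrate-VS to give the specific
yield curve B(t) in mL CH4 per g VS. Timing statistics T50/T90/T95 are the
earliest whole days reaching 50/90/95% of the final value; a run terminates
when production stays below 1% of the running total for three consecutive
days.

**Kinetics.** Four closed-form models are fitted to B(t) by bounded
Levenberg–Marquardt least squares with multi-start initialization:

- Modified Gompertz: `B = B0 exp(-exp(Rmax e / B0 (λ - t) + 1))`
- Logistic: `B = B0 / (1 + exp(4 Rmax / B0 (λ - t) + 2))`
- Cone: `B = B0 / (1 + (k t)^(-n))`
- First-order: `B = B0 (1 - exp(-k t))`

with B0 the ultimate yield (mL/g VS), Rmax the maximum rate (mL/g VS/d), λ
the lag (d) and k a rate constant (1/d). Substrate hydrolysis is modelled
as `S_t = S0 exp(-k_deg t)`, fitted to concentration series or inverted
from a single removal measurement.

**Stoichiometry.** The Buswell total reaction

```
CnHaObNc + (n - a/4 - b/2 + 3c/4) H2O ->
  (n/2 + a/8 - b/4 - 3c/8) CH4 + (n/2 - a/8 + b/4 + 3c/8) CO2 + c NH3
```

gives the theoretical methane potential
`TMP = 22.4 * 1000 * (n/2 + a/8 - b/4 - 3c/8) / (12n + a + 16b + 14c)`
(mL/g), and biodegradability is `BD = 100 * EMP / TMP` after aligning the
per-g-VS and per-g-dry bases.

**DOM classification.** FT-ICR-MS formulas are binned by their H/C and O/C
ratios into the seven Van Krevelen compound classes (lipids,
aliphatic/proteins, lignin/CRAM-like, carbohydrates, unsaturated
hydrocarbons, aromatics, tannins) plus an explicit unassigned bucket, and
into CHO/CHON/CHOS/CHONS element groups, with intensity- or count-weighted
shares.

**Economics.** Yields are normalized to a 100-day reference period
(`SMY = EMP * 100 / digestion time`), converted to electricity through a
combined-cycle gas turbine (9.97 kWh/m3 CH4, 60% efficiency) and priced at
a 0.75 CNY/kWh feed-in tariff.

A seeded synthetic-data generator emulates the whole study design (three
replicate channels per group plus blanks, hourly mesophilic metering, 2%
meter noise, target DOM class shares), so every stage is testable without
instrument data.

## Worked example

The numbered scripts under `analysis/` run the full chain on synthetic
data (seed 20260302). `Rscript analysis/01_simulate.R` then
`Rscript analysis/02_preprocess.R` prints:

```
HC2: final 344.2 mL CH4/g VS; T50 2 d, T90 4 d, T95 5 d, end day 10
HC3: final 375.0 mL CH4/g VS; T50 2 d, T90 4 d, T95 5 d, end day 10
HC4: final 364.5 mL CH4/g VS; T50 2 d, T90 5 d, T95 6 d, end day 10
peak daily production lands on day 1
```

i.e. the mid-ISR group yields the most methane, 90% of it within 4–5 days,
and the instrument stop rule would have ended the runs on day 10.
`Rscript analysis/03_kinetics.R` fits all four models per group — e.g. for
HC3 the first-order fit recovers B0 = 374.8 mL/g VS and k = 0.639 /d from
the noisy logs, and the residual-xylan series gives k_deg = 0.97 /d from
the day-4 removal of 97.9% — and `04`–`06` print the theoretical potential
(424.24 mL/g on the C5H8O4 repeating unit, 400.38 mL/g from the elemental
analysis), the DOM class shares (62.8% lignin/CRAM-like, 23.1%
aliphatic/proteins, 11.0% lipids) and the economics table (specific methane
yield 1499.8 mL over 100 days, 0.0090 kWh, 0.0067 CNY per g VS; 269.6%
more benefit than the lower-yield literature scenario).

In code, the same chain is three calls:

```r
library(bmpkit)
ds  <- generate_bmp_dataset(default_bmp_config())
pre <- preprocess_bmp(ds$logs, ds$meta)
fit_all_models(pre$group_curves$HC3, group = "HC3")
```

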