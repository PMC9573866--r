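# otolife

Otolith-based reconstruction of sardine early life histories: growth,
experienced temperature, field metabolism, metabolically optimal temperature,
and an early-survival index.

## What it does

Sardine otoliths accrete daily growth increments and record the chemistry of
the water the fish lived in. From per-fish otolith profiles (daily increment
widths plus δ13C/δ18O of sequentially micromilled age intervals), `otolife`
reconstructs:

- **Standard length at age** by the biological intercept method,
  `SL_n = (SL_catch − SL_first)·(OR_n − OR_first)/(OR_catch − OR_first) + SL_first`,
  with Monte Carlo uncertainty from the 3.8–6.5 mm initial-size range.
- **M_oto**, the proportion of metabolically derived carbon in otolith
  carbonate — a field-metabolic-rate proxy — from the mixing model
  `M_oto = (δ13C_oto − δ13C_DIC)/(δ13C_diet − δ13C_DIC) + ε`, with Monte
  Carlo propagation of the region-specific diet and DIC end-member ranges.
- **Experienced temperature** from otolith δ18O via
  `δ18O_oto = δ18O_sw − 0.18·T + 2.69`: direct inversion at fixed seawater
  δ18O (−0.32 ‰, California Current) or monthly quadratic thermometers
  fitted to hydrographic T/S observations (Kuroshio–Oyashio).
- **Optimal temperature** per life stage: 1 °C binning of (T, M_oto) pairs,
  quadratic fit to per-bin 95th percentiles, Gaussian log-link fit to 5th
  percentiles, and the argmax of the gap between the two envelopes — an
  aerobic-scope analogue.
- **LNRR**, log recruitment residuals of a Ricker stock-recruitment fit
  (`LNRR_t = ln(R_t/S_t) − (a + b·S_t)`), correlated against temperature
  anomaly series with exact two-sided p-values and Benjamini–Hochberg
  correction.

A synthetic-data generator (`cohort_params()`, `gen_fish_cohort()`,
`gen_hydro()`, `gen_stock_recruit()`) runs all forward models in the
generative direction with known ground truth, so every estimator has a
parameter-recovery test without any field data. `run_pipeline()` drives the
whole chain over a CSV bundle and writes per-stage outputs plus a manifest.

## Worked example

```r
library(otolife)

params <- cohort_params("JP", n_fish = 50, seed = 1)
cohort <- gen_fish_cohort(params)

d18o  <- acid_fractionation_adjust(cohort$isotopes$d18o_vpdb,
                                   cohort$isotopes$instrument)
temps <- invert_fixed_sw(d18o, cohort$truth$sw_d18o)
moto  <- mc_moto(cohort$isotopes$d13c_vpdb, isotope_context("JP"),
                 n_draws = 2000, seed = 1)

estimate_scope_envelope(temps, moto$moto_mean)
#> Aerobic-scope envelope over 6 temperature bins
#>   upper (p95): -1.787 +0.2855*T -0.008805*T^2
#>   lower (p5):  exp(-3.594 +0.1016*T)
#>   optimal temperature: 15.4 degC (range 13..19)

cohort$truth$t_opt_true
#> [1] 15.6
```

The fitted upper (95th percentile) and lower (5th percentile) M_oto
envelopes bracket the metabolic diversity at each temperature; their gap is
widest at 15.4 °C here, recovering the generator's true optimum of 15.6 °C
well within the 1 °C bin width.

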