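# rotimpact

Multi-function sustainability assessment of diversified crop rotation
systems, for agronomists and agroecosystem modellers evaluating
long-term rotation trials. The package quantifies each rotation along
the axes such trials measure and aggregates them into a single
comprehensive evaluation index:

* **Productivity** — wheat-equivalent yield
  `EY = yield · price / wheat_price`, CPI-deflated net income
  `EB = yield · price · CPI_j/CPI_base − cost`, protein yield
  `PC = yield · β`, and a min–max-normalized nutrition composite.
* **Greenhouse-gas balance** — static-chamber N2O/CH4 fluxes
  `f = (M/V0)(T0/T)(P/P0) H (dc/dt) · 60`, trapezoidal time
  integration, 100-year warming potential
  `GWP = N2O·273 + CH4·27` (species masses), life-cycle indirect
  emissions `CE = Σ D_k C_k`, soil organic carbon stocks by depth
  increment, sequestration `ΔC = (T2 − T1)·44/12/n`, and the budget
  identity `Net = CE + GWP − ΔC` (asserted exactly on every run).
* **Soil health** — Cornell-style 0–100 scoring of ten indicators
  against the pooled sample distribution, weighted by PCA loadings
  (Kaiser criterion, ≤ 3 components).
* **Microbial diversity** — seeded rarefaction of OTU tables and six
  alpha-diversity indices (Shannon, richness, Gini–Simpson, Pielou,
  Chao1, ACE).
* **Comprehensive evaluation index (CEI)** — entropy-weighted TOPSIS
  over seven criteria, `CEI_i = D_i⁻/(D_i⁺ + D_i⁻) ∈ [0, 1]`.

A seeded synthetic experiment generator reproduces the structure of a
six-rotation × three-replicate × six-year randomized complete block
trial (a wheat–maize control plus sweet potato, peanut, soybean, spring
maize, and ryegrass–sorghum diversified rotations), so the whole
pipeline is testable end-to-end with no field data. Every generated
quantity is recorded as ground truth and recovered by the pipeline in
the test suite.

## Worked example

```r
library(rotimpact)
cfg <- experiment_config(seed = 42)   # the default six-rotation trial
report <- run_pipeline(cfg)
print(report)
#> <rotation_report>
#>   config 3bfcd46c, seed 42
#>   CEI ranking:
#>     SpWM   CEI = 0.677 (rank 1)
#>     PWM    CEI = 0.651 (rank 2)
#>     SWM    CEI = 0.585 (rank 3)
#>     RSWM   CEI = 0.348 (rank 4)
#>     SmWM   CEI = 0.157 (rank 5)
#>     WM     CEI = 0.148 (rank 6)
```

The sweet-potato (SpWM), peanut (PWM) and soybean (SWM) rotations rank
far above the wheat–maize control (WM): they combine higher equivalent
yield or income with large cuts in net GHG emissions and better soil
health, while the cereal-only alternatives (SmWM, RSWM) gain little.
The decision matrix behind the index:

```r
round(report$decision_matrix, 2)
#>      equivalent_yield economic_benefit nutrition_yield soil_biodiversity
#> WM           13190.34         23453.69            0.25              4.18
#> SpWM         18159.77         37335.10            0.31              4.54
#> PWM          13641.15         27578.21            0.19              4.62
#> SWM          11908.24         26990.11            0.18              4.60
#> SmWM         10876.44         21930.47            0.11              4.22
#> RSWM         11856.48         24305.21            0.81              4.22
#>      soil_health c_sequestration net_ghg
#> WM         28.76            0.76 9816.85
#> SpWM       55.37            1.20 3160.04
#> PWM        65.54            2.21  322.98
#> SWM        62.20            1.63 1504.28
#> SmWM       49.50            0.33 7844.42
#> RSWM       53.87            0.57 7981.13
```

Units: kg/ha/yr (equivalent yield), Yuan/ha/yr deflated to 2008
(economic benefit), a 0–1 composite (nutrition), mean Shannon index
(biodiversity), a 0–100 score (soil health), t C/ha/yr (sequestration)
and kg CO2-eq/ha/yr (net GHG). Replicated metrics come with one-way
ANOVA and LSD letter groups, e.g. equivalent yield:

```r
report$stats$equivalent_yield$means
#>   group     mean        sd n letters
#> 1  SpWM 18159.77 514.48006 3       a
#> 2   PWM 13641.15 270.01090 3       b
#> 3    WM 13190.34 141.90836 3       b
#> 4   SWM 11908.24 405.54629 3       c
#> 5  RSWM 11856.48 106.69140 3       c
#> 6  SmWM 10876.44  61.88042 3       d
```

Individual stages are plain functions — for a single chamber
deployment:

```r
fit_flux(c(0, 12, 24, 36), c(0.320, 0.332, 0.344, 0.356),
         T_K = 298.15, P_kPa = 101.325, H_m = 0.3, gas = "n2o")$flux_ug_m2_h
#> [1] 32.3722
```

A thin command-line wrapper ships at `inst/cli/rotation-impact`
(`simulate` and `run` subcommands); all other stages are the exported
functions `equivalent_yield()`, `fit_flux()`, `cumulative_emission()`,
`indirect_emissions()`, `soc_stock()`, `delta_soc()`, `net_ghg()`,
`soil_health_assessment()`, `rarefy_table()`, `alpha_diversity()`,
`cei()`, `group_stats()` and friends.

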