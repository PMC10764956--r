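---
title: "Assessing diversified crop rotations: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing diversified crop rotations: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rotimpact)
```

rotimpact evaluates crop rotation systems the way a long-term agronomic
field trial is evaluated: productivity, greenhouse-gas balance, soil
health, soil microbial diversity, and a single comprehensive index that
aggregates them. This vignette documents the models, the tunable
parameters and their defaults, the numerical choices, and what the
synthetic experiment generator does and does not emulate.

## The assessment model

### Productivity

Crops as different as wheat grain, sweet-potato tubers and sorghum
silage are compared through three per-crop metrics:

* **Equivalent yield** $EY_{ij} = Yield_{ij} \cdot Price_{ij} / WheatPrice_j$
  re-expresses any crop in winter-wheat yield units via the price ratio
  in the harvest year $j$.
* **Economic benefit** $EB_{ij} = Yield_{ij} \cdot Price_{ij} \cdot
  CPI_j / CPI_{base} - Cost_{ij}$ is net income deflated to a base year
  (default 2008) by a consumer price index, so incomes across seasons
  are comparable in real terms.
* **Protein yield** $PC_i = Yield_i \cdot \beta_i$, with $\beta_i$ the
  protein mass fraction of the harvested product.

Cycle totals are divided by the cycle length in years
(`annualize_rotation()`), so one-year double-cropping controls and
two-year diversified rotations are compared per year. Yields are carried
at commercial moisture (13% grain, 14% peanut pods, 30% silage
moisture, fresh tubers); a per-crop moisture field supports conversion
to a dry-matter basis when needed.

The **nutrition composite** sums annual per-nutrient yields
(yield x concentration) over a rotation's crops, min--max normalizes
each nutrient across rotations, and averages with configurable weights
(equal by default). The per-nutrient aggregation is a design choice of
this package: normalized-then-averaged values match how multi-nutrient
comparisons are usually presented on radar charts, and the weights are
exposed rather than fixed because no single convention dominates the
literature. A nutrient constant across rotations is scored 0.5
everywhere (it carries no ranking information).

### Chamber fluxes and warming potential

Static-chamber N2O and CH4 fluxes come from the slope of headspace
concentration against closure time (default 0, 12, 24, 36 min):

$$f = \frac{M}{V_0}\,\frac{T_0}{T}\,\frac{P}{P_0}\,H\,\frac{dc}{dt}
  \times 60 \quad [\mu g\, m^{-2} h^{-1}]$$

with $M$ = 44 (N2O) or 16 (CH4) g/mol and the ideal-gas reference state
$V_0 = 0.022414\,m^3/mol$, $T_0 = 273.15\,K$, $P_0 = 101.325\,kPa$
(these reference values are a documented choice; the flux equation
names but does not fix them). Ordinary least squares is used with **no
goodness-of-fit rejection by default** -- an optional `min_r2` flag
implements the common chamber QC but stays off, reproducing the plain
linear-approach convention. Negative fluxes are valid and encode the
soil CH4 sink.

Cumulative emissions use trapezoidal integration of the piecewise-linear
interpolant, `F = sum((f_i + f_{i+1})/2 * (t_{i+1} - t_i)) * 24` with
flux in kg/ha/h and time in days; window boundaries are clipped onto the
interpolant. Warming potential uses the 100-year coefficients
`GWP = N2O x 273 + CH4 x 27` on **species masses**. Cumulative N2O is
carried internally on the nitrogen basis (kg N2O-N/ha, the customary
field-reporting unit) and converted by 44/28 only at the GWP step; CH4
is carried as species mass throughout. This is the only unit convention
that makes a control rotation emitting 8.9 kg N2O-N/ha/yr with a
-2.004 kg CH4/ha/yr sink come out at 3764 kg CO2-eq/ha/yr, which the
acceptance tests verify. Whether CH4 is reported as CH4 or CH4-C is a
genuine ambiguity in field conventions; species mass is assumed,
consistent with using M = 16 in the flux equation.

### Carbon budget

* **Indirect emissions** $CE = \sum_k D_k C_k$ over the input inventory
  (fertilizer N/P/K, diesel, electricity, pesticide, seed, labor), with
  cradle-to-farm-gate emission factors shipped as an editable CSV of
  placeholder literature-style values -- factors are data, not code.
* **SOC stocks** by fixed-depth layers (defaults 0--10, 10--20, 20--30,
  30--50, 50--70, 70--90 cm): concentration x bulk density x thickness
  x 0.1, in t C/ha. No equivalent-soil-mass correction is applied --
  fixed depths are the convention this assessment follows.
* **Sequestration** $\Delta C = (T_2 - T_1) \cdot \tfrac{44}{12} / n$
  (kg CO2-eq/ha/yr). The sign convention here is deliberate: positive
  $\Delta C$ means the soil is a carbon sink, consistent with
  subtracting it from the budget. (Writing the difference as
  $T_1 - T_2$ with $T_1$ the baseline would flip reported sequestration
  rates negative.)
* **Net budget** $Net = CE + GWP - \Delta C$, asserted exactly (not to
  tolerance) on every pipeline run, with the offset fraction
  $\Delta C / (CE + GWP)$ reported alongside.

### Soil health

Ten indicators (BD, SWC, pH, TN, SOC, DOC, NO3-N, AP, MBC, MBN) are
scored 0--100 with cumulative-normal scoring curves against the pooled
distribution of **all plots and both timepoints**, so baseline and
final-year scores are directly comparable. Direction flags: more-is-
better for all nutrients/biology and water content, less-is-better for
bulk density, and a symmetric optimum curve for pH (target 7.0,
configurable). The curve family is a design choice: published scoring
frameworks use fitted logistic curves per indicator; the cumulative
normal against the pooled sample is the standard distribution-based
variant and is fully testable without external calibration data.
Available P is scored more-is-better by default; in heavily fertilized
systems an optimum curve can be argued, and the direction vector is
user-replaceable for that reason.

Indicator weights come from PCA of the standardized indicator matrix:
components with eigenvalue > 1 (Kaiser) are retained, capped at three
(the scree-plot inflection typical of a 10-indicator soil dataset), and
each indicator's weight is the **sum of absolute loadings** across
retained components -- eigenvector signs are arbitrary, so absolute
values keep weights non-negative and deterministic. The overall score is
the weighted mean $\sum A_j w_j / \sum w_j$.

### Microbial alpha diversity

OTU tables are rarefied to the minimum sample depth without replacement
(seeded, via vegan's `rrarefy`), then six indices are computed per
sample: Shannon (natural log), richness, Simpson (reported as
Gini--Simpson $1 - \sum p_i^2$, with the raw concentration also emitted
so either convention is recoverable), Pielou $H / \ln S$ (missing when
$S = 1$), Chao1 (classic $S + F_1^2 / 2F_2$, bias-corrected
$S + F_1(F_1-1)/(2(F_2+1))$ only when doubletons are absent), and ACE
with the standard rare/abundant cutoff of 10 (configurable). Shannon,
Simpson and ACE are cross-checked against vegan in the test suite;
Chao1 deliberately differs from vegan's always-bias-corrected variant
and is tested against the formula directly.

### Entropy-TOPSIS comprehensive evaluation index

Seven rotation-level criteria (equivalent yield, economic benefit,
nutrition yield, soil biodiversity, soil health score, carbon
sequestration as positives; net GHG emissions as the negative) are
min--max normalized with direction, weighted by information entropy,
and ranked by TOPSIS closeness:

1. $b_{ij} = (x_{ij} - x_{min})/(x_{max} - x_{min})$ (positive) or
   $(x_{max} - x_{ij})/(x_{max} - x_{min})$ (negative);
2. $f_{ij} = b_{ij} / \sum_i b_{ij}$ per criterion, switching to
   $(1 + b_{ij}) / \sum_i (1 + b_{ij})$ for any column containing a
   zero (the shift applies to the whole column, preserving
   $\sum_i f_{ij} = 1$);
3. $H_j = -\frac{1}{\ln m} \sum_i f_{ij} \ln f_{ij}$ with
   $0 \ln 0 := 0$, and $W_j = (1 - H_j) / \sum_k (1 - H_k)$;
4. $z_{ij} = W_j b_{ij}$, ideals $z_j^\pm$ as column max/min, Euclidean
   distances $D_i^\pm$, and $CEI_i = D_i^- / (D_i^+ + D_i^-) \in [0, 1]$.

Two notational ambiguities in common write-ups of the method are
resolved the only way that yields per-criterion weights: entropy is
taken per criterion across alternatives and normalized by the log of
the number of alternatives; and the TOPSIS weighting multiplies the
normalized decision values $b_{ij}$ (not the proportions $f_{ij}$) --
the `topsis_cei(b, w)` surface accepts any matrix, so the alternative
reading is one call away. Criterion inputs are rotation-level means of
the upstream stages; the soil biodiversity criterion is the mean of the
bacterial and fungal rotation-mean Shannon indices at the final
timepoint (the aggregation is a documented choice). The whole chain is
verified to 1e-12 against an independent literal-loop evaluation in the
test suite.

### Group statistics

One-way ANOVA with least-significant-difference post-hoc comparisons at
$\alpha = 0.05$, rendered as a compact letter display by the standard
insert--absorb algorithm ('a' marks the highest mean). Pearson
correlations between rotation-level metrics round out the report;
constant columns are reported as missing.

## The synthetic experiment generator

`generate_dataset()` emulates the design of a six-year randomized
complete block rotation trial on the North China Plain: a winter
wheat--summer maize double-cropping control (1-year cycle) and five
diversified rotations (2-year cycles) that precede the wheat--maize
year with sweet potato, peanut, soybean, spring maize, or a
ryegrass--sorghum forage year; 6 rotations x 3 replicates = 18 plots.
Rotation-to-plot assignment is a seeded permutation within each block.

Default group-level parameters are calibrated once to the magnitudes
such a trial reports: control annual cumulative N2O-N of 8.9 kg/ha and
a CH4 sink of about -2 kg/ha (together 3764 kg CO2-eq/ha/yr), an
indirect-emission inventory summing to about 8800 kg CO2-eq/ha/yr for
the control, SOC accrual rates from 0.21 to 2.03 t C/ha/yr across
rotations, a 2016 soil profile holding 51% of its 0--90 cm carbon in
the top 20 cm, control equivalent yield near 13,200 kg/ha/yr with the
sweet-potato rotation about 38% higher, and soil-health indicator means
that rank the legume rotations highest and the control lowest.
Within-plot variance components are not published for such trials, so
noise SDs (yield CV 4--8%, flux noise 25 and 8 ug m^-2 h^-1, layer
concentration SDs 0.1--0.35 g/kg, indicator SDs at typical lab
repeatability) are free parameters chosen once at field-realistic
magnitudes and documented in `experiment_config()`.

Design choices worth knowing:

* **Flux model.** Weekly sampling with extra deployments 1 and 3 days
  after fertilization (and 1 day after rain events); the noise-free
  slope profile is baseline plus exponentially decaying fertilization
  pulses (half-life 5 days, pulse share 40% of the annual total). The
  profile is scaled so its trapezoidal integral over the sampled dates
  equals the configured annual target *exactly*; since slope noise is
  additive with zero mean and the trapezoid is linear, the cumulative
  emission recovered downstream is unbiased for the target by
  construction -- parameter-recovery tests need no bias allowance.
  Noise is truncated only where a negative slope would drive headspace
  concentration negative, which at realistic magnitudes never binds.
* **OTU model.** Relative abundances are evenly spaced quantiles of a
  log-normal distribution (a deterministic profile, so the population
  Shannon index is an exact function of the shape parameter), sampled
  into counts by multinomial draws at jittered depths. A rotation's
  diversity gain is a reduction of the log-normal shape in the final
  year. This is the standard null model for count tables; it does not
  emulate taxon co-occurrence, compositional correlation between
  samples, or a shared taxon pool across plots.
* **Soil model.** Two-timepoint layered profiles; the configured
  accrual is placed into layers along a depth-share vector (40% in the
  top 10 cm, declining below) as concentration increments computed
  against template bulk density, keeping the expected stock change
  equal to accrual x years.
* **Seeding.** One experiment seed expands into per-stream child seeds
  by a documented polynomial-hash scheme (`child_seed()`), so any
  single stream can be regenerated alone and equal seeds give
  bit-identical datasets.

What passing tests on this generator do **not** show: the generator has
no weather, no crop-growth feedback, no spatial autocorrelation beyond
a block effect, Gaussian noise everywhere, and independence between
streams (e.g. a wet year does not jointly shift yields and fluxes).
Recovery of configured parameters demonstrates that the pipeline's
estimators are unbiased and correctly plumbed -- not that they are
robust to the correlated, heavy-tailed structure of real field data.

## Numerical choices and degenerate inputs

* Chamber fits require >= 3 strictly increasing closure times; zero
  time span is an error. Flat series give flux 0 with $R^2$ reported
  as 1 (a perfect fit of a zero slope).
* Integration requires >= 2 points after window clipping; unordered
  dates are an error, never silently sorted.
* A constant criterion column in the decision matrix is an error naming
  the criterion (min--max normalization is undefined), as is a
  single-alternative matrix, an all-identical matrix in TOPSIS, and an
  all-uniform matrix in entropy weighting.
* CSHA scoring errors on zero pooled SD; PCA errors on zero-variance
  indicators rather than dropping them silently.
* Rarefaction refuses depths exceeding any retained sample and lists
  the offending samples. Ranking ties in the CEI share their minimum
  rank and are flagged.
* Problem sizes in the test suite are chosen for tight feedback:
  Monte-Carlo recovery uses 50 seeds (200 for the flux target, whose
  per-seed cost is small), and the ranking-recovery study runs 100
  seeded pipeline replicates of a trimmed three-rotation configuration.

## Known limitations

* Emission factors are placeholders pending a site-specific inventory;
  conclusions about indirect emissions inherit their uncertainty.
* The nutrition composite's per-nutrient table ships with seven
  components; a full food-composition table (17+ components) can be
  supplied by the user but is not bundled.
* The CSHA curve family and the AP direction are conventions, not
  calibrated scoring functions; both are configurable.
* No nonlinear (HMR-style) chamber models, no gap-filling beyond
  linear interpolation, no CO2 flux, no beta-diversity or ordination,
  and no price forecasting -- all out of scope by design.
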