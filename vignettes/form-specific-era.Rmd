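---
title: "Methods: form-specific probabilistic exposure, hazard and risk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: form-specific probabilistic exposure, hazard and risk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fsera)
```

This vignette documents the models implemented in `fsera`, the
assumptions behind them, the defaults of every tunable that matters, and
the numerical conventions that make results reproducible. It states no
empirical result beyond what the package's tests and acceptance script
compute themselves.

## 1. Form disaggregation

A material family (here graphene-based materials: pristine graphene pG,
graphene oxide GO, reduced graphene oxide rGO) is produced as distinct
forms whose environmental behaviour must be assessed separately, but
production statistics are only available as totals. The disaggregation
layer therefore works entirely with row-stochastic share matrices:

* `E` (years × categories): how each year's market splits across product
  categories;
* `F` (categories × forms): which forms each category uses;
* `G = E F` (years × forms): the induced form shares, with
  `g_mz = Σ_n e_mn f_nz`.

The category allocation specific to a form `z` is `e_mn f_nz / g_mz`,
which sums to one per year by construction. A year in which a form has
zero market share (`g_mz = 0`) has no meaningful allocation for that
form, so the operation raises an error naming the year rather than
emitting a zero row.

The shipped split table `gbm_form_splits()` stores **exact fractions**
(e.g. 1/3, 0.095) whose rows sum to one; the familiar whole-percent
renderings (33 %, 10 %) are produced by a separate report formatter,
`format_share_percent()`. Printed percent rows can sum to 99–101 because
of rounding; keeping the stored matrix exact avoids that artefact
contaminating computations. Where published sources give only rounded
percentages for a blended category we chose the exact fractions closest
to them that sum to one (composite 0.81/0.095/0.095, energy storage
0.57/0.215/0.215, automotive 0.77/0.115/0.115); categories with no
reported form usage receive an equal split, and oxide-only categories
halve the oxide share between GO and rGO, reflecting the assumption that
the two oxide forms share those markets evenly. `combine_market_matrices()`
is provided for users who have a form market-fraction vector `A` and a
form × application matrix `B` and wish to derive category splits
themselves. Whether a separately sourced research-and-development row
should enter `F` before or after normalising the other categories is not
determined by the available sources; we ship it as a direct exact row
(0.71/0.17/0.12), which keeps `F` row-stochastic without renormalising
other rows.

## 2. The flow engine

The dynamic probabilistic material-flow engine propagates yearly
form-specific production through a directed graph of technical and
environmental compartments.

**Transfer coefficients (TCs).** Each edge carries a prior (point,
uniform or triangular, all parameters in [0, 1]). Per Monte-Carlo run,
every outgoing coefficient of a compartment is drawn from its prior and
the vector renormalised to sum to exactly one — the standard
draw-then-renormalise construction of probabilistic MFA. A Dirichlet
sampler would also produce normalised vectors but cannot honour
independently specified per-edge priors, which is how scenario data
arrive. TCs are drawn **once per run and held fixed across years**:
the uncertainty being modelled is parameter uncertainty (we do not know
the true coefficient), not year-to-year process noise. Per-year
resampling can be emulated by passing a custom `tc` matrix to
`run_simulation()`.

**Within-year dynamics.** The model's time step is one year. Propagation
is a single topological pass over the non-sink compartments, so
multi-hop transport (production → air → soil) completes within the year;
a cycle among non-sink compartments is rejected at graph construction.
Air is a *transfer* compartment: mass flows through it but it ends every
year with zero stock, since airborne particles deposit back to the
surface well within the annual time step. Sinks and elimination have no
outgoing edges and accumulate over the horizon.

**Stocks and release schedules.** An in-use compartment may declare a
release schedule: fractions of each entering cohort's *original* mass
released at lag 0, 1, 2, … years (non-negative, cumulative sum ≤ 1).
Mass not yet released stays as stock and is counted in the mass balance.
Categories without a schedule release everything the year it arrives —
an explicit, conservative default chosen because product lifetime data
for these materials are generally unavailable.

**Conservation.** For every run and year, cumulative external inflow
equals accumulated sinks + elimination + stocks to numerical precision;
`mass_balance_report()` exposes the residuals, and the test suite checks
them at 1e-9 relative on a 10,000-run scenario as well as exact
agreement with a hand-rolled propagation on small point-TC graphs.

## 3. Exposure

`pec_freshwater()` converts the annual mass released to surface waters
(tonnes/year, sample-wise over the ensemble) into ng/L by dividing by the
freshwater compartment volume. Two conventions are exposed because the
regulatory literature uses both:

* `annual_dilution` (default): `PEC = M / V`;
* `residence_scaled`: `PEC = (M / V) · τ / 365` with hydraulic residence
  time τ (default 40 days, the value recommended for regional freshwater
  assessment; capped at 365).

`annual_dilution` is the default because summing form-specific
freshwater PECs under it reproduces the corresponding aggregate release
concentration of the European GBM assessment chain this package targets;
the residence-scaled variant remains one argument away. Soil PECs divide
an annual inflow or an accumulated sink inventory (caller's choice — the
two answer different questions, and published assessments are not
explicit about which is meant) by the receiving soil mass. The European
freshwater volume and soil masses are **inputs**, not baked-in
constants.

Summaries report mean, SD and the 5/25/75/95 % quantiles with linear
interpolation between order statistics (R's default type 7); the
convention is fixed for reproducibility and configurable only by editing
one call site. The report formatter `round_report()` rounds values below
100 to two significant figures and values at or above 100 to three —
the printing convention of the flow diagrams and concentration tables
this package's outputs are meant to be compared against.

## 4. Hazard

Endpoints arrive as NOEC, LOEC, HONEC, ECx or LCx from acute or chronic
tests (mg/L). They are converted to chronic NOECs by dividing by
`UF_t · UF_dd`. The shipped factors — acute→chronic 10; EC50/LC50-type
10, LOEC 2.5, HONEC 1, NOEC 1 — follow common extrapolation practice in
the probabilistic SSD lineage; because primary sources often do not
print their exact factors, the table is an explicit, editable argument
(`default_uf_table()`) rather than hidden truth, and every pipeline run
logs the table it used.

The probabilistic species sensitivity distribution treats each species
as a **discrete uniform distribution over its converted endpoints**,
embracing within-species variability without asserting a parametric
form. Each of the 10,000 Monte-Carlo iterations draws one value per
species and takes the 5th percentile (type 7) of the drawn community as
that iteration's HC5. The mean of the HC5 samples is reported as the
PNEC point value (the median is also returned; the mean is the
convention for the headline "mean of PNEC" statistic). An alternative
mode uses only each species' most sensitive endpoint, a construction
some SSD variants prefer; it is exposed but not the default because it
discards the within-species information the probabilistic approach
exists to keep.

When data cannot support an SSD — fewer than 8 species (default) or a
missing key trophic group among fish, daphnids and algae —
`choose_pnec_strategy()` selects the assessment-factor route:
`pnec_af()` divides the lowest raw endpoint by an assessment factor
(default 1000), recording which record was the minimum.

## 5. Risk

`rcr_distribution()` reconciles units (exact powers of ten within a
basis; cross-basis conversion is an error), then divides PEC by PNEC.
With a probabilistic PNEC the PEC and PNEC chains are **independently**
resampled with replacement to a common length — the two Monte-Carlo
chains share no randomness by design, so pairing them would fabricate
correlation. With a point PNEC the division is elementwise. Summaries
report the mean, interquartile range, exceedance probability at RCR = 1
and `orders_below_one()` = `floor(−log10(mean RCR))` (with a small
epsilon so that exact powers of ten land on the intended integer).

## 6. The synthetic-data generator

`make_scenario()` emulates the statistical shape of a real scenario:
Dirichlet(1, …, 1) rows for `E` and `F` (maximally uninformative but
valid share matrices), lognormal yearly production (median 100 t/yr,
CV 0.5 by default — a mid-range prospective-production uncertainty),
triangular TC priors of half-width 0.1 around realistic central routing
(80 % of use-phase mass to solid waste, 10 % to air, 10 % to water;
waste split 45/45/10 between landfill, incineration/elimination and
wastewater treatment), and a fixed toy graph whose expectations are
computable in closed form under point TCs. `make_hazard_dataset()`
emulates a curated hazard inventory: 26 species carrying 113 endpoints,
species sensitivities lognormal(μ = 0, σ = 0.5 natural-log units,
i.e. about a factor 2.7 between-species spread), endpoints scattered
lognormally (σ = 0.2) around each species' truth, and descriptors/
regimes assigned from a mix — with recorded values pre-multiplied by the
uncertainty factors so the chronic-NOEC conversion recovers the intended
values exactly. The analytic ground truth
`HC5 = exp(μ + σ·Φ⁻¹(0.05))` is a property of the law, not the seed.

The defaults are also the regime in which HC5 **parameter recovery** is
meaningful: the sample 5th percentile of 26 species is an order
statistic whose finite-sample bias and spread grow with σ. At σ = 0.5
the estimator recovers the analytic quantile to within a few percent on
average (the acceptance script reports the measured bias over 20
replicates); real inventories spanning four orders of magnitude
correspond to σ ≈ 2–3, where a 26-species HC5 carries substantially more
sampling error — a property of the estimator itself that users should
expect with data of that spread, not an artefact of this implementation.
Passing recovery tests on the synthetic law therefore validates the
machinery (sampling, quantile convention, UF round-trip, determinism),
not the field accuracy of any 26-species HC5.

What the generator deliberately does **not** emulate: the real European
parameterisation (compartment list, TC values, production forecasts),
correlated endpoint errors within studies, censored endpoints
("> highest tested"), or inter-laboratory variation. Conclusions about
real GBM risk require the real scenario and hazard inventories, supplied
as CSV/YAML inputs.

## 7. Orchestration and reproducibility

`run_era()` executes disaggregation → per-form simulation → PEC → PNEC →
RCR under a single root seed expanded into per-stage substreams, so a
stage can be re-run independently with stable randomness. TC
realisations are shared across forms, which makes form PECs add exactly
to the total PEC sample-wise — a conservation property the tests assert.
Every run logs the defaults it actually used (PEC mode, soil basis, UF
table, per-form PNEC strategy and whether pooled records were
substituted for a form with no records) into the result and the JSON
summary. Default problem sizes (1,000 flow runs, 10,000 SSD iterations)
keep a full synthetic assessment interactive on a laptop; the flow-engine
conservation checks use 10,000 runs.

## 8. Known limitations

* No environmental fate: PECs are release concentrations; dissolution,
  agglomeration and sedimentation would lower freshwater values.
* Regional averages only; local or accidental releases can exceed them
  by orders of magnitude.
* Soil hazard and soil RCRs are out of scope (soil PECs are computed,
  their risk characterisation is not).
* The within-year single-pass propagation cannot represent feedback
  loops among non-sink compartments.
* The HC5 order-statistic bias discussed in §6 applies to any SSD built
  on few species with wide scatter.
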