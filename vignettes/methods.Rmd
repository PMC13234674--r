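---
title: "Methods: stochastic techno-economic assessment with ML surrogates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stochastic techno-economic assessment with ML surrogates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`batchtea` implements a stochastic techno-economic assessment (TEA) of a
batch active-pharmaceutical-ingredient (API) plant — an API produced by the
condensation of quinaldine and hydroquinone — together with a
machine-learning surrogate layer that replaces repeated simulation when
propagating cost uncertainty.  This vignette documents the model, its
calibration, the numerical choices, and what the package's tests do and do
not demonstrate.

## The process model

The flowsheet is a fixed batch recipe (chlorination of quinaldine,
condensation, isolation by Nutsche filtration, re-dissolution and impurity
removal, neutralization, charcoal treatment, crystallization, drying).
Only two aspects of the recipe enter the economics:

* **Scheduling.**  The plant's design availability is 7,920 h/yr and the
  baseline executes 134 batches/yr.  The individual step durations span a
  scheduling cycle between 58.47 and 113.39 h, but the bottleneck recipe
  cycle that yields exactly 134 batches is not derivable from the step
  list alone (equipment is shared and re-used across steps).  We therefore
  *calibrate* the cycle time as 7920/134 = 59.104 h, which lies inside the
  reported scheduling range.  `batches_per_year()` floors the ratio of the
  sampled annual operation time (7,200–8,760 h) to this cycle.
* **Per-batch mass.**  The baseline annual output is 33,000 kg, so the
  per-batch API mass is fixed at 33,000/134 = 246.27 kg.  Step yields are
  tracked by `chain_yield()` (overall 0.724 for the baseline recipe) but
  the economics are anchored on the calibrated per-batch mass, not on a
  molar balance: feed masses per batch are not public.

### Calibrating the material balance

Per-batch material and waste quantities are likewise not public; what is
known is the baseline *cost* structure: raw materials 2,143,000 USD/yr and
waste treatment 884,000 USD/yr at baseline unit prices.  The package
back-solves per-batch coefficients from assumed cost shares:

* **Waste streams** share the bill uniformly (18 priced streams), for want
  of any stream-level information.
* **Raw materials** use shares calibrated from the reported sensitivity
  structure.  With independent uniform price sampling, the contribution of
  material $i$ to the unit production cost has standard deviation
  proportional to $s_i \cdot (\mathrm{hi}_i-\mathrm{lo}_i)/p_i^0$, where
  $s_i$ is its baseline cost share and $p_i^0$ its baseline price.  The
  published rank correlations against UPC (labor 0.73, quinaldine 0.50,
  isopropanol 0.30, process water 0.25, nitrogen 0.13) pin down the
  relative contribution of each printed material once the labor
  contribution (back-solved exactly, see below) fixes the overall scale.
  Solving that variance decomposition gives the default shares
  quinaldine 44.4%, isopropanol 21.0%, nitrogen 8.0%, chlorine 7.5%,
  sodium carbonate 5.5%, hydroquinone 4.0%, carbon tetrachloride 3.5%,
  sodium hydroxide 3.4%, process water 2.2%, wash water 0.5%.
  A naive allocation concentrated on quinaldine/water would make process
  water (whose price bounds span a factor 100) the dominant UPC driver
  and break the published ranking.  The shares are configurable through
  `tea_process(material_coef = ...)`.

## The operating-cost model

`compute_opex()` composes five categories, calibrated to reproduce the
baseline breakdown exactly (total 5,776,000 USD/yr, UPC 175 USD/kg):

* raw materials: annual demand × sampled prices;
* facility-dependent: (6% maintenance + 1% insurance + 2% local taxes +
  5% overhead) of direct fixed capital (DFC) plus 10-yr straight-line
  depreciation.  DFC is never public; the unique value consistent with the
  baseline facility cost and the stated factors is
  $1{,}325{,}000 = (0.14 + 0.10)\,\mathrm{DFC} \Rightarrow
  \mathrm{DFC} = 5{,}520{,}833$ USD.  The remaining capital
  (7,066,000 − DFC) is treated as non-depreciable (working capital and
  startup);
* labor-dependent: operator hours × wage × (1 + administration +
  supervision burden).  Hours are back-solved from the baseline:
  $1{,}238{,}000/(41.4 \times 1.3) = 23{,}003$ h at 7,920 h availability,
  scaled proportionally with the sampled operation time.  The burden
  ladder is 0.9/0.5/0.3/0.2/0.1 (administration) and 0.8/0.5/0.3/0.2/0.2
  (supervision) over the wage bands <5, 5–10, 10–15, 15–18, >18 USD/h;
  the 15–18 administration tier (0.2) bridges the published endpoints,
  and supervision mirrors them;
* laboratory/QC/QA: a fixed 15.02% of the labor-dependent cost
  (186/1238);
* waste treatment: stream masses × sampled unit costs.

UPC is the quotient of the OPEX total by the annual production
(`compute_upc()`), so UPC × production recovers OPEX exactly.

## Discounted cash flow, IRR and MPSP

`build_cash_flow()` lays out equity cash flows over years 0–15.  None of
the following conventions are public, so they are package choices, stated
once and fixed:

* capital is spent 40/40/20% over years 0–2 (a 30-month construction
  period); the first operating year (year 2) is a startup year at 50%
  throughput, scaling revenue and the variable cost categories (raw
  materials, waste) while fixed costs run in full;
* revenue and operating cost escalate with the sampled inflation rate
  from year 0 money; the MPSP is quoted in year-0 money;
* the OPEX total includes the depreciation charge inside the
  facility-dependent category; the cash-flow model removes this non-cash
  component from cash operating cost and applies depreciation only to the
  taxable base;
* 40% of the DFC is debt, drawn in year 0 and amortized with equal
  principal over the sampled loan period at the sampled interest rate
  (without some debt, the loan variables could not influence any output,
  contradicting the published feature-selection result);
* income tax applies to (revenue − cash opex − depreciation − interest),
  floored at zero — losses carry no refund.

`npv()` is the discounted sum of net flows; `irr()` brackets and bisects
the rate; `solve_mpsp()` bisects the selling price on [0, 10,000] USD/kg
to a relative tolerance of 1e-6 — NPV is strictly increasing in price, so
the zero-NPV price (the minimum product selling price, MPSP) is unique.
At the baseline these conventions give MPSP(30%) ≈ 242 USD/kg.

## The scenario generator

`tea_scenarios()` draws the 34 inputs independently and uniformly within
the bounds of `tea_bounds()` (the published sampling intervals:
e.g. quinaldine 16–48 USD/kg, labor 5–50 USD/h, inflation 1–6%, income tax
10–50%, operation time 7,200–8,760 h).  These defaults *are* the study
conditions; they are not tuning knobs.  A target internal rate of return
is sampled per scenario — the published account is ambiguous about whether
IRR is an input or an output, but the downstream analyses (SHAP, the
MPSP(IRR, UPC) heatmap) require MPSP to respond to IRR, so the default
mode samples a target IRR and solves the MPSP at it.  The sampling law of
the IRR is not public; the package uses Uniform(0.01, 0.50), configurable
via `irr_range`.  An alternative mode (`reference_price` in
`run_scenario()`) computes the realized IRR at a fixed price instead.
The default run produces 5,000 records of 37 columns (34 inputs + IRR +
UPC + MPSP), deterministic per seed, CSV round-trippable.

## Surrogate models

`tea_surrogate()` mirrors a standard supervised pipeline: an 80/20
hold-out split; 5-fold cross-validation inside the training part; min–max
scaling fitted inside each fold on the fold-training rows only (the
scaler test suite probes that refitting on a fold changes the parameters,
i.e. no leakage); two independent per-target regressors per technique
(multi-output wrapping); metrics $R^2$, RMSE and MAPE per target plus
their uniform average.  Rows with $|y| < 10^{-9}$ are excluded from MAPE.

The six techniques and their defaults mirror one reference library family
throughout: linear regression; k-nearest neighbors (k = 5); support
vector regression (RBF kernel, C = 1, ε = 0.1); degree-2 polynomial ridge
(penalty α = 1, closed form, intercept unpenalized — degree 2 keeps the
expansion tractable at 35 features); random forest (100 bagged trees, all
features tried per split); gradient boosting (100 rounds, learning rate
0.3, depth 6, exact per-target tree SHAP available).

**Feature selection** uses the multitask LASSO (`glmnet`,
`family = "mgaussian"`): one group-sparse linear model fitted jointly to
UPC and MPSP, so a feature is kept or dropped for both targets at once.
The penalty strength is the fixed library default (λ = 1 on raw targets,
min–max features).  A cross-validated penalty (`penalty = "cv"`) is also
available but degenerates on this data: because the simulator is
deterministic and noise-free, every input with *any* real effect —
including waste-stream prices worth a fraction of a percent of the
variance — measurably reduces CV error, and the one-standard-error rule
collapses (fold SEs are near zero), so CV retains essentially all 35
candidates.  The fixed default penalty retains 8 features on the default
dataset (labor rate, quinaldine, isopropanol, process water, operation
time, income tax, inflation, IRR), which matches the magnitude and
composition of the published 9-variable selection.

**Tuning** (`tune_surrogate()`) is a randomized search, 30 configurations
× 5-fold CV, uniform over the printed space (trees 50–300, depth 3–30,
learning rate 0.001–0.1, subsample and column-sample 0.3–1.0;
integer-uniform for counts).  Note the searched learning rates exclude
the default 0.3, so the search is not guaranteed to dominate the default
configuration.  `learning_curve()` reports train/validation $R^2$ over a
grid of training sizes.

## Uncertainty analyses

* `spearman_table()`: rank correlations (average-rank ties) between every
  input and each target; the classical rank-difference formula serves as
  the independent oracle in the tests.
* `kde_marginals()`: Gaussian-kernel densities, Scott's bandwidth rule.
* `shap_summary()`: exact tree-path SHAP for the boosted models
  (additivity to the prediction is asserted per sample); a Monte Carlo
  permutation explainer is the fallback for non-tree models.
* `interpolate_heatmap()`: the MPSP surface over (IRR, UPC).  Scattered
  cubic interpolation is performed with an exact thin-plate-spline
  interpolant; since MPSP at a given (IRR, UPC) still varies with the
  other financial inputs, large scatters are first aggregated to
  grid-cell means (~400 support nodes) so the interpolant passes through
  local averages rather than oscillating through noise.  Nodes outside
  the convex hull of the support are masked, never extrapolated.
  Localized interpolation artifacts (small non-monotone pockets) are
  expected and not smoothed away.
* `feasible_mpsp_range()`: the min/max of the surface over cells with
  IRR ≥ MARR (default 30%) and UPC inside a window (default 140–240
  USD/kg).

## Problem sizes and determinism

The acceptance analyses use the full study size (5,000 scenarios,
4,000 training rows, 5-fold CV for all six models); unit tests use small
generated datasets (120–500 rows) and synthetic toys.  One pipeline seed
fans out to per-stage seeds by fixed offsets, so the dataset, the split,
the fold assignment, the search and the tree learners are all reproducible
end to end; `reproduce()` writes the seed and configuration into a
provenance block next to every artifact.

## What the synthetic generator does and does not emulate

The generator reproduces the baseline cost structure exactly and the
published input-to-UPC sensitivity structure closely.  It does **not**
reproduce the proprietary simulator's full mass/energy balance: material
demands are calibrated coefficients, not stoichiometric solutions, and
the MPSP level away from the baseline depends on cash-flow conventions
that are not public.  Two consequences are visible in the acceptance
suite and are reported rather than hidden:

* the Monte Carlo MPSP span is narrower than the published 262–525 USD/kg
  feasibility interval — the published interval evidently includes
  scenarios with target returns above our sampling cap of 50% and/or a
  costlier cash-flow template;
* the surrogate's task is *easier* here: the published boosted-tree CV
  $R^2$ of 0.86 reflects residual structure in the richer simulator that
  a clean deterministic emulator does not have, so our cross-validated
  $R^2$ comes out higher (~0.96), and the weakest learners (KNN) sit
  below the published per-target UPC bar of 0.92 because the calibrated
  generator spreads real signal over more inputs than the 8 selected
  features retain.

Both limits are properties of the reconstruction, not of the method; the
tests assert the published values at their stated tolerances and fail
visibly where the reconstruction cannot reach them.
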