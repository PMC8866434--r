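---
title: "Methods: PM2.5 attributable mortality and co-benefit valuation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: PM2.5 attributable mortality and co-benefit valuation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pm25cobenefit)
```

This vignette is the package's account of its science: the models it
implements, the assumptions they carry, the parameters a user can turn,
and the numerical and design choices made where the method itself leaves
room.

## The exposure-response model

Long-term exposure to ambient fine particulate matter (PM2.5) raises
mortality from noncommunicable diseases and lower respiratory
infections. The package uses the Global Exposure Mortality Model (GEMM)
relative-risk function, fitted across cohort studies of outdoor
exposure:

$$RR(C) = \exp\left\{\frac{\theta \,\ln(z/\alpha + 1)}
  {1 + \exp(-(z-\mu)/\nu)}\right\},\qquad z = C - c_{min},$$

for $C > c_{min}$, and $RR = 1$ otherwise. The numerator is a
log-linear term in excess concentration scaled by $\alpha$; the
denominator is a logistic weight centered at $\mu$ with width $\nu$
that flattens the curve at low excess concentrations. All logarithms
are natural. The parameters are per disease and adult age group
(5-year bands from 25 to 85+, or an all-adult aggregate); people under
25 are assigned $RR = 1$ and contribute no attributable deaths.

Parameters and what they mean:

| parameter | units | meaning | source |
|---|---|---|---|
| $\theta$, $SE(\theta)$ | – | log-RR scale and its standard error | fit table |
| $\alpha$ | µg/m³ | log-term concentration scale | fit table |
| $\mu$, $\nu$ | µg/m³ | logistic center and width | fit table |
| $c_{min}$ | µg/m³ | minimum-risk concentration, default 2.4 | argument |

$c_{min}$ is an argument with default 2.4 µg/m³ rather than a constant,
so threshold sensitivity analyses need no code change. A published
all-adult NCD+LRI fit row ships in
`inst/extdata/gemm_ncd_lri_example.tsv` as a format example.

## From risk to deaths

For disease $i$, age group $j$, grid cells $g$ with population
$P_{g,j}$ and reported national incidence $I_{i,j}$ (deaths per
person-year):

$$\bar{RR} = \frac{\sum_g P_{g,j}\,RR(C_g)}{\sum_g P_{g,j}},\qquad
  \hat{I}_{i,j} = I_{i,j}/\bar{RR},\qquad
  M_{i,j} = \sum_g P_{g,j}\,\hat{I}_{i,j}\,(RR(C_g) - 1).$$

$\hat I$ is the hypothetical *underlying incidence* that would remain
at the minimum-risk concentration: the observed national rate already
contains the pollution effect, so it is deflated by the population
-weighted mean risk before excess risk is applied cell by cell. On a
uniform field the chain collapses to the population attributable
fraction identity $M = P\,I\,(RR-1)/RR$, which doubles as a closed-form
oracle in the tests (1e-12 relative tolerance).

Two reading notes on this chain as commonly printed. First, the
mean-risk sum runs over grid cells (the printed index occasionally
collides with the disease index); the implementation averages over
cells. Second, $\bar{RR}$ is computed with *national* (whole-grid)
population weights even when a region mask is applied afterwards —
the underlying incidence is a national quantity, and regional tables
reuse it. A province-level $\bar{RR}$ would be an alternative reading;
the national choice is deliberate and documented here.

Avoided deaths of a policy scenario against its same-year no-policy
reference are $\Delta M = M_{REF} - M_{policy}$ per stratum, with sign
preserved: a policy scenario can carry the larger burden, which
surfaces as negative avoided deaths and a negative monetized benefit.

## Uncertainty

The ~95% interval inserts the standard error of the exposure-response
fit into the function: bounds are the full chain (including $\bar{RR}$
and $\hat I$) re-run at $\theta \mp z_{crit}\,SE(\theta)$, with
$z_{crit} = 1.96$ by default. Two choices here were genuinely open:

* **Which parameters carry uncertainty.** Only $\theta$ is perturbed.
  The public fit tables report a standard error for $\theta$ alone, and
  $\theta$ is the scale of the log-risk, so this captures the dominant
  fit uncertainty. The multiplier is an argument (`zCrit`), so profile
  or wider-quantile variants are available to the user.
* **How bounds aggregate.** Because the $\theta$ shift is applied
  globally, per-stratum bounds are summed (differenced) across strata
  and scenarios — a perfect-dependence assumption. The result is a
  bound on the interval, not a propagated interval; every table carries
  a `ci_method` attribute saying so, and the serialized form records it
  in a comment line. Independent-error propagation would narrow the
  aggregate interval but contradict the single-parameter-shift
  interpretation.

Bounds are re-ordered with elementwise min/max after differencing, so
`deaths_low <= deaths_mean <= deaths_high` holds even where a
difference flips an interval.

## Exposure summaries

Per scenario the pipeline reports the population-weighted mean
concentration $\sum_g C_g P_g / \sum_g P_g$ and the population living
above an air-quality goal (default 35 µg/m³). The above-goal count uses
a *strict* inequality: the goal is "at most 35", so non-attainment is
$C > 35$. Both summaries are invariant to splitting a cell into parts
with the same concentration, which the property tests exercise.

Inputs must be co-registered: concentration and population grids must
share identical cell edges, elementwise within 1e-9 degrees, in the
same storage order. The pipeline refuses misregistered grids rather
than regridding, keeping the analysis core free of interpolation
choices. Region masks are boolean grids that zero population outside
the region — province-level reporting without a GIS dependency.

Grid I/O uses a plain delimited long-table format
(`lat_index, lon_index, value`, age-resolved for population) with the
grid edges and metadata in `#` header lines; it is human-readable,
diff-able, and round-trips bit-exactly at 17 significant digits.

## Valuation

Avoided deaths are monetized with a value of statistical life:

* **Local linear:** $VSL(inc) = VSL_0 + (inc - inc_0)\cdot MVSL$, with
  the default marginal VSL from a Chongqing contingent-valuation study
  (14,550 USD of VSL per 145.8 USD of annual per-capita income, about
  99.79 USD/USD). A negative extrapolation is floored at zero with a
  warning (or an error on request). The default baseline VSL
  (1.675 million USD) and baseline income (3,277 USD) are placeholders
  of a plausible magnitude for a mid-2010s China baseline — **not**
  study-derived values — and should be set explicitly for any real
  valuation.
* **International transfer:** $VSL_{ref}\,(inc/inc_{ref})^{\beta}$ with
  income elasticity $\beta \in [0,2]$ (typical sensitivity values 0.8
  and 0.4).

A single national VSL applies per scenario-year, driven by that year's
per-capita income; currency is constant (2017) USD with no discounting
or inflation adjustment inside the pipeline. Net benefit is benefit
minus mitigation cost (an input — the pipeline does not compute
mitigation costs), and the benefit-cost ratio is flagged undefined when
the cost is zero. GDP shares are emitted only when a GDP projection is
supplied in the config.

## The synthetic-data generator

`syntheticSpec()` describes desk-scale inputs with the statistical
structure the analysis assumes, so every stage runs and is testable
without downloads:

* **Concentration:** white noise smoothed with a separable
  moving-average kernel (width = correlation length, reflecting edges),
  standardized to the requested log-scale SD, exponentiated, and
  rescaled so the grid mean equals `concMean` exactly. The result is
  positive, smooth, and right-skewed like annual-mean surfaces from a
  chemical-transport model. The exact correlation model is not
  scientifically load-bearing — positivity and smoothness are.
  `concSigma = 0` produces an exactly uniform field, the degenerate
  case the closed-form recovery tests rely on. The policy member of a
  scenario pair is the reference scaled cell-wise by
  `1 - reductionFraction`.
* **Population:** a mixture of Gaussian clusters over a diffuse
  background. Counts are integers by largest-remainder apportionment,
  age groups first (so the age profile is honored exactly when shares
  are integral), then cells within each age group; the grand total is
  conserved exactly. Ties in the apportionment break by first index —
  deterministic, if arbitrary.
* **Incidence and fit parameters:** incidence rises roughly
  exponentially with adult age (3·10⁻⁴ per person-year at 25–29 with a
  9.5%/year slope, reaching ~0.1 at 85+), matching the shape of
  burden-of-disease tables; fit parameters are drawn uniformly from
  plausible ranges ($\theta \in [0.08, 0.18]$ with 10% relative SE,
  $\alpha \in [1,20]$, $\mu \in [5,30]$, $\nu \in [1,50]$ µg/m³). A
  null mode ($\theta = 0$) drives the downstream burden exactly to
  zero.

Defaults are the conditions the package treats as its reference
experiment: a 48×48 grid with mean 53 µg/m³ (the national
population-weighted level of the mid-2010s), moderate log-normal
variability (σ = 0.45), 50 million people in 6 clusters with a
China-like age structure, and a 10% policy reduction. All randomness
derives from the spec seed; every generator restores the caller's RNG
state.

What the generator does **not** emulate: atmospheric chemistry (the
nonlinear response of secondary PM2.5 to precursor reductions —
synthetic policy scenarios are uniform fractional reductions, real ones
are spatially heterogeneous), meteorological variability, satellite
calibration, migration or urbanization in the population pattern, and
correlated parameter uncertainty across age groups. Passing tests
therefore demonstrate the correctness of the accounting chain on
structurally realistic inputs, not the realism of any headline number.

## Numerical choices and degenerate inputs

* At $C \le c_{min}$ the risk is exactly 1 (branch, not clamp), and the
  curve is continuous at the threshold from above.
* Zero total (or zero age-group) population makes weighted means
  undefined and raises an error rather than returning NaN.
* `theta_se = 0` or `zCrit = 0` collapse intervals exactly onto the
  point estimate (`identical`, not merely close).
* Table serialization uses 17 significant digits, so write-then-read
  round trips are bit-exact; written tables re-verify their invariants
  (bound ordering, the net-benefit identity) and refuse to write
  otherwise.
* The pipeline is a pure function of (config, input files, seed):
  repeated runs are byte-identical, which a test asserts file by file.

Test problem sizes are deliberately small — oracle equivalence on
20×20 grids (five random draws), curve-oracle agreement on 100 random
parameter draws, end-to-end runs on 8×8 to 32×32 grids with 10⁵–10⁶
people — chosen so the whole suite documents the method's properties in
seconds while exercising every code path.

## Interfaces

The spec-level command-line surface is provided as package functions
(`readRunConfig()`, `runPipeline()`, `writeReport()`,
`simulateDataFiles()`) plus a thin Rscript front end
(`inst/cli/cobenefit.R`) with subcommands `simulate-data`, `exposure`,
`burden`, `cobenefit`, `valuate`, `run`, `report`; each subcommand is a
view over the same pure pipeline function, so stage-wise and one-shot
invocations agree by construction. Configuration is YAML; outputs are
deterministic TSVs plus a plain-text summary and a run log recording
package version, seed, and the config file's MD5.

## Known limitations

Baseline incidence is held at its input-year values for all projection
years; years are labels, not dynamics. Mortality endpoints only — no
years-of-life-lost, morbidity, cessation lag, or ozone effects. The
burden interval reflects exposure-response fit uncertainty only, not
concentration, population, or incidence uncertainty. Valuation ignores
distributional questions (one national VSL) and pollution-control cost
savings. NetCDF grid input is not implemented; the delimited long-table
format is the on-disk interface.
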