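---
title: "Modelling the seed germination thermal niche: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the seed germination thermal niche}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermoniche)
```

## The problem

Seeds of many winter annuals are shed with nondeep physiological dormancy:
at maturity they germinate only within a narrow band of temperatures, and
dry after-ripening progressively widens that band until the full,
nondormant thermal niche is reached. Quantifying *where* the band sits,
*how fast* it widens in storage, and *when* the field temperature first
re-enters it ties seed physiology to germination phenology: a narrow niche
at dispersal plus a summer's worth of after-ripening produces the classic
delayed, autumn-germination strategy.

`thermoniche` implements the full quantitative chain: a population-based
threshold (PBT) model of germination, nonlinear least-squares estimation of
its parameters from multi-temperature census data, a degree-hour model of
dormancy release in storage, a synchrony statistic, dormancy typology, and
a climate-overlap prediction of germination timing — plus a seeded
synthetic-data generator so that the whole chain is testable without any
field data.

## The population-based threshold model

Each seed has a lower and a higher limit temperature between which it can
germinate; both limits are normally distributed across the population. The
germinable fraction at temperature $T$ is

$$\mathrm{GF}(T) \;=\; \Phi\!\left(\frac{T - T_{l50}}{\sigma_{T_l}}\right)
 \;-\; \Phi\!\left(\frac{T - T_{h50}}{\sigma_{T_h}}\right),$$

clamped to $[0,1]$. The difference-of-CDFs form is algebraically identical
(via $\Phi(-z) = 1 - \Phi(z)$) to writing the upper tail as a
$1-\Phi(\cdot)$ term; the clamp guards heavy overlap of the two limit
distributions, a case the model's sources do not discuss.

Timing within the window follows thermal time: at sub-optimal temperatures
($T \le T_o$) degree-days accumulate at rate $T - T_b$; at supra-optimal
temperatures at rate $T_m - T$. The thermal-time requirement
$\theta$ is itself normally distributed ($\theta_{50}, \sigma_\theta$,
separately for the two ranges), so the expected cumulative germination
after $t$ days is

$$G(T, t) \;=\; \mathrm{GF}(T)\,
  \Phi\!\left(\frac{\theta_{\mathrm{acc}}(T,t) - \theta_{50}}
                   {\sigma_\theta}\right).$$

Three deliberate choices, each isolated behind one function so it can be
revisited:

* **Multiplicative composition.** The window layer and the timing layer are
  combined as a product (independence). The literature defines the two
  layers separately and never states their joint law; the product is the
  simplest composition with the right limits ($G \to \mathrm{GF}$ as
  $t \to \infty$, $G \approx 0$ at $t = 0$ for any realistic
  $\theta_{50}/\sigma_\theta$).
* **Tie-break at the optimum.** $T = T_o$ uses the sub-optimal branch.
* **Distributed supra-optimal thermal time.** A strict reading of the
  model's prose would make supra-optimal thermal time a constant per seed,
  yet published per-stage parameter tables report a positive
  $\sigma_{supra}$ for every stage. The tabulated parameters win:
  $\theta_{sup}$ is distributed exactly like $\theta_{sub}$.

Dormancy release is classified from the first-to-last change of the two
limits (`classify_dormancy_type()`): Type 1 raises $T_{h50}$ at constant
$T_{l50}$, Type 2 lowers $T_{l50}$ at constant $T_{h50}$, Type 3 does both.
The "constant" tolerance defaults to 1&nbsp;°C — smaller than any real
between-stage step in the after-ripening series the package ships as a
fixture (≥ 2.5 °C), large enough to absorb fitting noise.

## Parameter estimation

`fit_stage()` minimises the RMSE between observed and modelled cumulative
fractions pooled over every dish, day and temperature of one
population-by-stage cell. Eight parameters are free; the cardinal
temperatures are fixed configuration inputs (they describe nondormant
seeds and are conventionally estimated from a separate rate-based
experiment). Design choices:

* **Optimiser.** Bounded L-BFGS-B from `n_starts ≥ 8` seeded
  Latin-hypercube starts. The original analyses of this model family used
  a spreadsheet GRG solver; any bounded local method with multi-start
  matches that intent, and explicit seeds make the whole pipeline
  reproducible run-to-run.
* **Bounds.** $T_{l50} \in [0,15]$, $\sigma_{T_l} \in [0.05,15]$,
  $T_{h50} \in [10,40]$, $\sigma_{T_h} \in [0.05,25]$,
  $\theta_{50} \in [1,60]$, $\sigma_\theta \in [0.1,25]$ °C·day — spanning
  all tabulated estimates for this species with margin.
* **The 30 °C filter.** Treatments at 30 °C (where no seed of any
  population germinates) are removed before fitting, mirroring the source
  experiment's analysis; the synthetic generator still produces them so the
  filter is exercised.
* **Observation weighting.** Every daily census of every dish is one
  observation, unweighted; dishes in which nothing germinates stay in the
  objective as zero-fraction observations — they carry the information
  about the window edges.

`fit_rwtn()` is ordinary least squares of $T_{h50}$ (response, °C) on
storage hours (regressor), with `RWTN = 1/b` the hours of dry storage per
degree of niche widening, and an F-test (1, $n-2$ df) for significance.
Two notes. First, the published equation for this regression letters the
variables the other way around; the printed intercepts (20.6–26.0 °C,
i.e. $T_{h50}$ at zero storage) and the °C-per-hour scale of the printed
slopes identify $T_{h50}$ as the response, and that orientation reproduces
the published coefficients exactly. Second, the stage coding
M = 0, AR1 = 720, AR2 = 1440, AR5 = 3600 h (30-day months, immature stage
excluded) was verified against the published regression table before being
frozen as the default: it reproduces every printed slope, SE and p-value
to printed precision.

## Synchrony of germination

`sog()` is a root-mean-square dispersion over percentile-level data points:
for each replicate dish and each percentile 0.1–0.9, the day on which the
dish first reaches that percentile (linearly interpolated between daily
censuses, with a virtual day-0 census at zero) is the observed value
$X_O$; the model-predicted day to the same percentile is $X_S$. The
default statistic is $\sqrt{\sum_i (X_{S,i} - \mu_O)^2 / N}$ with $\mu_O$
the mean of the observed set. The defining formula in the source
literature is typographically ambiguous between this μ-centred reading and
a pairwise RMSE $\sqrt{\sum_i (X_{S,i} - X_{O,i})^2/N}$; the accompanying
step-by-step prose ("mean of the data set", "distance from each data point
to the mean") supports the μ-centred form, which is the default, while the
pairwise form is available as `mode = "paired"`. Points whose percentile
is never reached (percentile ≥ germinable fraction, or temperature outside
the accumulation range) are dropped pairwise. No published numeric value
of this statistic exists, so all synchrony tests are property-based:
SOG = 0 on zero-deviation input, scale- and permutation-equivariance, and
a strict decrease of stage-mean SOG across an after-ripening series whose
window and thermal-time spreads shrink.

## Thermal after-ripening time and germination timing

`thermal_afterripening_time()` is the degree-hour integral
$\max(0, T_s - T_{sl}) \times t$ with $T_{sl}$ the storage temperature
below which after-ripening stops (5 °C for the species the fixtures
describe); linear in duration and zero at or below $T_{sl}$.

`predict_timing()` implements the graphical niche-overlap method
numerically: monthly climate normals are interpolated piecewise-linearly,
the stage-appropriate envelope (D/M before 720 elapsed hours, then AR1,
AR2 from 1440 h, AR5 from 3600 h; 720 h per scanned month) is selected
piecewise-constantly and right-continuously, and the first entry of the
temperature curve into the closed band $[T_{l50}, T_{h50}]$ within 12
months is reported with its crossing temperature. The source describes
"nonlinear regression and interpolation" without a functional form, and
its site-specific predicted temperatures depend on weather-station series
that are not redistributable — so the *mechanism* is the tested contract
here, verified by translation-invariance, monotonicity in envelope width,
and analytic inversion of sinusoidal synthetic climates, not by
reproducing site numbers.

## The synthetic-data generator

`generate_timecourses()` emulates the source study design: 9 populations ×
5 dormancy stages × temperatures 5–30 °C in 5 °C steps × 3 dishes × 20
seeds, scored daily (default 30 days). Daily increments are drawn from the
conditional binomial
$\mathrm{Bin}\!\left(n - k_{d-1},\, \frac{p_d - p_{d-1}}{1 - p_{d-1}}\right)$,
so cumulative counts are monotone by construction — the real census is
cumulative because germinated seeds are removed. All randomness flows from
one integer seed; identical seeds give byte-identical output.

The generator's stated world: stage truths are the published per-stage
parameter table shipped as `table1.csv`; cardinal temperatures are the
synthetic configuration $T_b = 1$, $T_o = 22$, $T_m = 30$ °C
(`cardinals_synthetic.csv`). The cardinals are *not* the study's own
values (those sit in an unavailable supplement): $T_b < 5$ is forced by
observed germination at 5 °C, $T_o \approx 22$–23 °C is the reported
optimum for the species, and $T_m = 30$ °C reproduces the observed total
germination failure at 30 °C, because the supra-optimal accumulation rate
$T_m - T$ vanishes there. What the generator does **not** emulate:
dish-level overdispersion beyond binomial sampling, seed mortality and
fungal loss, diurnal temperature fluctuation, and light effects. A green
recovery test therefore establishes correctness of the estimation
machinery under the model's own assumptions, not robustness to real-data
pathologies.

## Known limitations

* **Upper-limit identifiability.** When the true $T_{h50}$ lies well above
  the warmest scored temperature (a fully after-ripened lot scored only to
  25 °C with $T_{h50} = 35$, $\sigma_{T_h} = 2$), the germinable fraction
  at every scored temperature is within $3 \times 10^{-7}$ of its limit
  and the RMSE surface is flat in $(T_{h50} - 25)/\sigma_{T_h}$ beyond
  ≈ 2.5. A multi-start fit then drifts within the flat region (typically
  to a bound), and *any* single-start solver simply stops near its
  starting value. Published estimates of far-above-range upper limits from
  such designs should be read as initialisation-dependent; the package's
  Monte-Carlo acceptance test documents this honestly rather than tuning
  around it.
* **Published-table inconsistencies.** One row of the published storage
  regression table (Semirom) prints an intercept and $R^2$ that are
  mathematically incompatible with the slope, SE and p-value printed
  beside them; the package reproduces the self-consistent eight rows
  exactly and reports the recomputed values for the ninth. The published
  $R^2$ values are truncated, not rounded, to two decimals — the
  reproduction tests match under that convention.
* **Climate input.** Only monthly normals are consumed; no soil-temperature
  translation or within-month variability, so predicted crossings are
  mean-field statements.

## Numerical conventions

Convergence uses `optim`'s L-BFGS-B defaults with `maxit = 500`; a fit is
flagged converged when the optimiser reports success or the objective is
below the configured tolerance (`1e-8`, relevant for noiseless data where
the line search terminates abnormally at an exact zero). Ties among
multi-start solutions resolve to the smallest objective; the
`Tl50 < Th50` ordering is enforced by a penalty rather than
reparameterisation so that reported parameters stay on their natural
scale. Percentile extraction treats day 0 as an implicit zero census.
Degenerate inputs (no germination anywhere, constant $T_{h50}$, zero
observed variance) return flagged results, not errors, wherever the
pipeline must keep running.
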