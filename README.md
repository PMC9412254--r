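# thermoniche

Population-based threshold modelling of the **seed germination thermal
niche** — for seed ecologists and ecophysiologists quantifying how
physiological dormancy restricts the temperatures at which a seed lot can
germinate, and how dry after-ripening relaxes that restriction.

## The model

A seed lot's permissive window is bounded by normally distributed lower and
higher limit temperatures. The germinable fraction at temperature *T* is

    GF(T) = Φ((T − Tl50)/σTl) − Φ((T − Th50)/σTh)

and timing within the window follows normally distributed thermal-time
requirements accumulated at rate `T − Tb` (sub-optimal range) or `Tm − T`
(supra-optimal range), so the expected cumulative germination after *t*
days is `G(T,t) = GF(T) · Φ((θacc(T,t) − θ50)/σθ)`.

On top of this core the package provides:

* **`fit_stage()`** — seeded multi-start bounded least squares estimating
  the eight window/timing parameters from multi-temperature census data
  (cardinal temperatures `Tb`, `To`, `Tm` are fixed configuration inputs;
  30 °C treatments are filtered before fitting).
* **`fit_rwtn()`** — OLS of `Th50` on storage hours; `RWTN = 1/b` is the
  storage time (h) per 1 °C of niche widening, with SE, R² and F-test p.
* **`thermal_afterripening_time()`** — degree-hours `max(0, Ts − Tsl)·t`
  of dormancy-breaking storage.
* **`sog()` / `sog_stage()`** — the synchrony-of-germination statistic
  (RMS dispersion of percentile-level germination times).
* **`classify_dormancy_type()`** — Type 1/2/3 nondeep physiological
  dormancy from the stage-wise movement of the two limits.
* **`build_envelope()` / `predict_timing()`** — the graphical method:
  intersect the stage-indexed `Tl50..Th50` band with monthly long-term
  mean temperatures to predict when field germination becomes possible.
* **`generate_timecourses()` and friends** — a seeded synthetic-data
  generator emulating a 9-population × 5-stage × 6-temperature × 3-dish ×
  20-seed daily-census trial (conditional-binomial increments, so counts
  are monotone).
* **`run_pipeline()` / `thermoniche_main()`** — the end-to-end pipeline
  and its command-line interface (`inst/exec/thermoniche`).

Fixtures under `inst/extdata/` include a transcribed per-stage parameter
table (`table1.csv`), the expected storage-regression coefficients
(`table2_expected.csv`), and a *synthetic* cardinal-temperature
configuration (`cardinals_synthetic.csv`; see the methods vignette for why
`Tb = 1, To = 22, Tm = 30` °C).

## Worked example

```r
library(thermoniche)
table1 <- read_params(thermoniche_example("table1.csv"))
arak   <- table1[table1$population == "Arak", ]

## germinable fraction of a fully after-ripened lot
w <- thermal_window(Tl50 = 6.6, sigma_Tl = 2, Th50 = 35, sigma_Th = 2)
germinable_fraction(c(5, 15, 25, 33), w)
#> [1] 0.2119 1.0000 1.0000 0.8413

## dormancy-release pattern across the five stages
classify_dormancy_type(arak)
#> [1] "Type1"

## rate of widening of the thermal niche (Zabol population)
th50 <- c(M = 25, AR1 = 28, AR2 = 30, AR5 = 33)   # published Th50 by stage
fit_rwtn(th50)
#> <rwtn_fit> a = 26.00 degC, b = 0.002083 degC/h (se 0.000415),
#>            RWTN = 480.0 h/degC, R2 = 0.926, p = 0.0375, n = 4

## degree-hours of after-ripening in 5 months at 20 degC storage
thermal_afterripening_time(Ts = 20, Tsl = 5, duration = 3600)
#> [1] 54000

## when does a sinusoidal climate re-enter the Arak niche after July?
env <- build_envelope(arak)
cl  <- generate_climate(amplitude = 12, mean = 18, phase_month = 7)
predict_timing(env, cl, maturity_month = 7)
#> $crossed               TRUE
#> $crossing_month        8.54      (mid-late August)
#> $months_after_maturity 1.54
#> $predicted_temp        26        (degC; the AR1-stage upper limit)
#> $stage                 "AR1"
```

Reading: mature Arak seeds cannot germinate in mid-summer (the mean
temperature sits above the niche); after one month of after-ripening the
upper limit has risen to 26 °C and the cooling climate curve meets it
about 1.5 months after maturity — a delayed, late-summer/autumn
germination strategy. The `fit_rwtn` line reproduces the published Zabol
regression exactly: 480 h of dry storage per 1 °C of niche widening.

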