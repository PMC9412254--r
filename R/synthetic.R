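# Seeded synthetic-data generators emulating a multi-population germination
# trial: daily-censused dishes under the PBT model with sequential-
# conditional binomial increments (cumulative counts are monotone by
# construction, mirroring a census in which germinated seeds are removed),
# Th50 storage trajectories for the niche-widening regression, and
# sinusoidal climate normals.

#' Design of a simulated germination trial
#'
#' Defaults emulate a common multi-population after-ripening study design:
#' a gradient of six temperatures from 5 to 30 degrees C in 5-degree steps,
#' three replicate dishes of 20 seeds per treatment, daily scoring for 30
#' days. 30 degrees C typically yields no germination under realistic
#' parameter sets and is filtered out again before fitting.
#'
#' @param temperatures Incubation temperatures, degrees C (distinct).
#' @param dishes Replicate dishes per treatment.
#' @param seeds_per_dish Seeds per dish (`>= 0`).
#' @param census_days Trial duration, days (daily scoring).
#' @param rng_seed Integer seed; all generator randomness flows from it.
#' @return An object of class `design_spec`.
#' @export
design_spec <- function(temperatures = c(5, 10, 15, 20, 25, 30),
                        dishes = 3L, seeds_per_dish = 20L,
                        census_days = 30L, rng_seed = 1L) {
  if (anyDuplicated(temperatures)) stopf("`temperatures` must be distinct")
  if (dishes < 1L || census_days < 1L)
    stopf("`dishes` and `census_days` must be positive")
  if (seeds_per_dish < 0L) stopf("`seeds_per_dish` must be >= 0")
  structure(list(temperatures = as.numeric(temperatures),
                 dishes = as.integer(dishes),
                 seeds_per_dish = as.integer(seeds_per_dish),
                 census_days = as.integer(census_days),
                 rng_seed = as.integer(rng_seed)),
            class = "design_spec")
}

#' Simulate germination time-courses for one population-by-stage cell
#'
#' For each dish, daily cumulative germinated counts follow the PBT model
#' expectation: the day-`d` increment is drawn from the conditional binomial
#' `Binomial(n - k_{d-1}, (p_d - p_{d-1}) / (1 - p_{d-1}))` where `p_d` is
#' the model cumulative fraction, so counts never decrease and never exceed
#' the dish size. Deterministic given `design$rng_seed`.
#'
#' @param truth A [stage_params()] generating the data.
#' @param design A [design_spec()].
#' @return List with `timecourses` (list of [germination_timecourse()]) and
#'   `truth` (the generating parameters, for recovery tests).
#' @export
generate_timecourses <- function(truth, design) {
  stopifnot(inherits(truth, "stage_params"), inherits(design, "design_spec"))
  days <- seq_len(design$census_days)
  n <- design$seeds_per_dish
  tcs <- list()
  with_seed(design$rng_seed, {
    for (T in design$temperatures) {
      p <- cumulative_germination(T, days, truth)
      for (dish in seq_len(design$dishes)) {
        counts <- integer(length(days))
        k <- 0L
        p_prev <- 0
        for (d in seq_along(days)) {
          denom <- 1 - p_prev
          q <- if (denom <= 0) 0 else min(1, max(0, (p[d] - p_prev) / denom))
          k <- k + (if (n - k > 0L) rbinom(1L, n - k, q) else 0L)
          counts[d] <- k
          p_prev <- p[d]
        }
        tcs[[length(tcs) + 1L]] <- germination_timecourse(
          temperature = T, days = days,
          cum_fraction = if (n > 0L) counts / n else counts * 0,
          n_seeds = n, replicate = dish,
          population = truth$population, stage = truth$stage)
      }
    }
  })
  list(timecourses = tcs, truth = truth)
}

#' Simulate a Th50 trajectory over dry storage
#'
#' `Th50(stage) = th0 + rate * hours(stage) + Normal(0, noise_sd)`; feeds
#' the niche-widening regression with data of known slope.
#'
#' @param th0 Higher-limit temperature at maturity, degrees C.
#' @param rate Widening rate, degrees C per storage hour (`>= 0`).
#' @param stage_hours Named storage-hours vector; default
#'   [default_stage_hours()].
#' @param noise_sd SD of additive Gaussian noise, degrees C.
#' @param rng_seed Integer seed.
#' @return Named numeric vector of Th50 per stage.
#' @export
generate_th50_trajectory <- function(th0, rate, stage_hours = default_stage_hours(),
                                     noise_sd = 0, rng_seed = 1L) {
  check_number(th0, "th0")
  if (rate < 0) stopf("`rate` must be >= 0")
  if (noise_sd < 0) stopf("`noise_sd` must be >= 0")
  with_seed(rng_seed, {
    th0 + rate * stage_hours + rnorm(length(stage_hours), 0, noise_sd)
  })
}

#' Simulate sinusoidal monthly climate normals
#'
#' Monthly means `mean + amplitude * cos(2*pi*(m - phase_month)/12)`: the
#' warmest month is `phase_month`, the coldest is six months away.
#'
#' @param amplitude Half peak-to-trough range, degrees C (`>= 0`).
#' @param mean Annual mean temperature, degrees C.
#' @param phase_month Warmest calendar month (1-12).
#' @param noise_sd Optional Gaussian jitter SD, degrees C.
#' @param rng_seed Integer seed (only used when `noise_sd > 0`).
#' @return A [climate_series()].
#' @export
generate_climate <- function(amplitude, mean = 18, phase_month = 7L,
                             noise_sd = 0, rng_seed = 1L) {
  if (amplitude < 0) stopf("`amplitude` must be >= 0")
  if (!phase_month %in% 1:12) stopf("`phase_month` must be in 1..12")
  m <- 1:12
  temps <- mean + amplitude * cos(2 * pi * (m - phase_month) / 12)
  if (noise_sd > 0)
    temps <- with_seed(rng_seed, temps + rnorm(12, 0, noise_sd))
  climate_series(temps, m)
}
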