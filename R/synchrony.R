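# Synchrony of germination (SOG): a root-mean-square dispersion statistic
# over percentile-level germination values. Data points are the times (days)
# at which each replicate dish first reaches the percentiles 0.1..0.9 of
# cumulative germination, extracted by linear interpolation between censuses;
# the simulated counterpart is the model-predicted time to each percentile.
# Smaller SOG = more synchronous germination.

#' Synchrony-of-germination statistic
#'
#' Default (`mode = "mu"`): `sqrt(sum((Xs_i - mu)^2) / N)` where `mu` is the
#' mean of the observed data set — the RMS distance of the simulated points
#' from the observed mean, a standard-deviation-like dispersion measure.
#' `mode = "paired"` instead computes the RMS of pairwise simulated-minus-
#' observed differences. Both readings of the dispersion formula are
#' provided because either can be defended; the mu-centred one is the
#' default (see the methods vignette).
#'
#' @param simulated,observed Equal-length numeric vectors of data points
#'   (percentile-by-replicate values).
#' @param mode `"mu"` (deviations from the observed mean) or `"paired"`
#'   (pairwise differences).
#' @return Non-negative scalar; 0 iff every simulated value equals the
#'   reference.
#' @examples
#' sog(c(0.2, 0.4), c(0.25, 0.35))  # 0.1
#' @export
sog <- function(simulated, observed, mode = c("mu", "paired")) {
  mode <- match.arg(mode)
  if (length(simulated) == 0L || length(observed) == 0L)
    stopf("`simulated` and `observed` must be non-empty")
  if (length(simulated) != length(observed))
    stopf("`simulated` and `observed` must have equal length")
  if (any(!is.finite(simulated)) || any(!is.finite(observed)))
    stopf("inputs must be finite")
  dev <- if (mode == "mu") simulated - mean(observed) else simulated - observed
  sqrt(sum(dev^2) / length(dev))
}

#' Days to reach germination percentiles, from a censused time-course
#'
#' The day at which cumulative germination first reaches each percentile,
#' linearly interpolated between census days (a virtual census at day 0 with
#' fraction 0 is assumed). Percentiles never reached are `NA`.
#'
#' @param timecourse A [germination_timecourse()].
#' @param percentiles Percentile grid in `(0, 1)`; default `0.1..0.9`.
#' @return Named numeric vector of days (NA where unreached).
#' @export
percentile_days <- function(timecourse, percentiles = seq(0.1, 0.9, 0.1)) {
  stopifnot(inherits(timecourse, "germination_timecourse"))
  if (any(percentiles <= 0) || any(percentiles >= 1))
    stopf("`percentiles` must lie strictly inside (0, 1)")
  d <- c(0, timecourse$days)
  f <- c(0, timecourse$cum_fraction)
  out <- vapply(percentiles, function(p) {
    i <- which(f >= p)[1L]
    if (is.na(i)) return(NA_real_)
    if (i == 1L) return(0)
    # interpolate within the census interval in which p was crossed
    d[i - 1L] + (p - f[i - 1L]) / (f[i] - f[i - 1L]) * (d[i] - d[i - 1L])
  }, 0)
  names(out) <- sprintf("p%02d", round(100 * percentiles))
  out
}

#' Model-predicted day to reach a germination percentile
#'
#' Inverts the PBT model at a constant incubation temperature: the fraction
#' `p` is reached when the accumulated thermal time equals
#' `theta50 + sigma_theta * qnorm(p / GF(T))`. `NA` when the percentile
#' exceeds the germinable fraction or the accumulation rate is zero.
#'
#' @param params A [stage_params()].
#' @param temperature Incubation temperature, degrees C.
#' @param percentiles Percentile grid in `(0, 1)`.
#' @return Named numeric vector of days (NA where unreachable).
#' @export
predicted_percentile_days <- function(params, temperature,
                                      percentiles = seq(0.1, 0.9, 0.1)) {
  stopifnot(inherits(params, "stage_params"))
  gf <- germinable_fraction(temperature, params$window)
  acc <- accumulate_thermal_time(temperature, 1, params$cardinals)
  rate <- acc$thermal_time  # degree-days per day at this temperature
  if (acc$range == "sub") {
    th50 <- params$timing$theta_sub50; sd <- params$timing$sigma_sub
  } else {
    th50 <- params$timing$theta_sup50; sd <- params$timing$sigma_sup
  }
  out <- vapply(percentiles, function(p) {
    if (rate <= 0 || p >= gf) return(NA_real_)
    theta_needed <- th50 + sd * qnorm(p / gf)
    max(0, theta_needed / rate)
  }, 0)
  names(out) <- sprintf("p%02d", round(100 * percentiles))
  out
}

#' SOG for one population-by-stage cell
#'
#' Builds the percentile-by-replicate data set from the observed
#' time-courses, predicts the matching values from the fitted (or true)
#' stage parameters, drops points where either side is undefined (percentile
#' unreached), and applies [sog()].
#'
#' @param timecourses List of [germination_timecourse()] for the cell.
#' @param params A [stage_params()] describing the same cell.
#' @param percentiles Percentile grid; default `0.1..0.9`.
#' @param mode Passed to [sog()].
#' @return List with `sog`, `n` (data points used) and `mu` (observed mean).
#' @export
sog_stage <- function(timecourses, params,
                      percentiles = seq(0.1, 0.9, 0.1),
                      mode = c("mu", "paired")) {
  mode <- match.arg(mode)
  obs <- sim <- numeric(0)
  for (tc in timecourses) {
    o <- percentile_days(tc, percentiles)
    s <- predicted_percentile_days(params, tc$temperature, percentiles)
    keep <- is.finite(o) & is.finite(s)
    obs <- c(obs, o[keep]); sim <- c(sim, s[keep])
  }
  if (length(obs) == 0L)
    return(list(sog = NA_real_, n = 0L, mu = NA_real_))
  list(sog = sog(sim, obs, mode = mode), n = length(obs), mu = mean(obs))
}
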