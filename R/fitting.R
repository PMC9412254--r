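# Stage-parameter estimation: bounded multi-start nonlinear least squares
# minimising the RMSE between simulated and observed cumulative germination
# fractions, pooled over all temperatures, dishes and census days of a stage.
# Cardinal temperatures (Tb, To, Tm) are held fixed during fitting.

#' Root-mean-square error between observed and simulated fractions
#'
#' @param observed,simulated Equal-length numeric vectors.
#' @return `sqrt(mean((observed - simulated)^2))`.
#' @examples
#' rmse(c(0, 0.5), c(0.3, 0.5))  # 0.2121
#' @export
rmse <- function(observed, simulated) {
  if (length(observed) != length(simulated))
    stopf("`observed` (%d) and `simulated` (%d) differ in length",
          length(observed), length(simulated))
  if (length(observed) < 1L) stopf("need at least one observation")
  sqrt(mean((observed - simulated)^2))
}

#' Coefficient of determination, pooled over a stage
#'
#' `1 - SSres/SStot` over all observations (temperatures, dishes and days
#' pooled); the convention used to report goodness of fit of a stage model.
#'
#' @param observed,simulated Equal-length numeric vectors, `length >= 2`.
#' @return `R^2` (can be negative for fits worse than the mean).
#' @export
r_squared <- function(observed, simulated) {
  if (length(observed) != length(simulated))
    stopf("`observed` and `simulated` differ in length")
  if (length(observed) < 2L) stopf("need at least two observations")
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot <= 0)
    stopf("undefined statistic: observed values have zero variance")
  1 - sum((observed - simulated)^2) / ss_tot
}

#' Configuration for stage fitting
#'
#' @param bounds Named list of `c(lower, upper)` box constraints for the
#'   eight free parameters (`Tl50`, `sigma_Tl`, `Th50`, `sigma_Th`,
#'   `theta_sub50`, `sigma_sub`, `theta_sup50`, `sigma_sup`). Defaults span
#'   the parameter ranges reported for annual-species after-ripening series
#'   with margin.
#' @param n_starts Number of Latin-hypercube multi-start initialisations
#'   (`>= 1`).
#' @param seed RNG seed controlling the starts (reproducibility contract).
#' @param tol Convergence tolerance on the RMSE objective.
#' @param maxit Maximum optimiser iterations per start.
#' @return An object of class `fit_config`.
#' @export
fit_config <- function(bounds = default_fit_bounds(), n_starts = 8L,
                       seed = 1L, tol = 1e-8, maxit = 500L) {
  if (n_starts < 1L) stopf("`n_starts` must be >= 1")
  check_positive(tol, "tol")
  req <- names(default_fit_bounds())
  if (!all(req %in% names(bounds)))
    stopf("`bounds` must name all of: %s", paste(req, collapse = ", "))
  for (nm in req) {
    b <- bounds[[nm]]
    if (length(b) != 2L || b[1L] >= b[2L])
      stopf("bound for `%s` must be c(lower, upper) with lower < upper", nm)
  }
  structure(list(bounds = bounds[req], n_starts = as.integer(n_starts),
                 seed = as.integer(seed), tol = tol,
                 maxit = as.integer(maxit)),
            class = "fit_config")
}

#' @rdname fit_config
#' @export
default_fit_bounds <- function() {
  list(Tl50       = c(0, 15),
       sigma_Tl   = c(0.05, 15),
       Th50       = c(10, 40),
       sigma_Th   = c(0.05, 25),
       theta_sub50 = c(1, 60),
       sigma_sub  = c(0.1, 25),
       theta_sup50 = c(1, 60),
       sigma_sup  = c(0.1, 25))
}

# Stack a list of time-courses into one observation table.
flatten_timecourses <- function(timecourses) {
  stopifnot(length(timecourses) > 0L)
  do.call(rbind, lapply(timecourses, function(tc) {
    stopifnot(inherits(tc, "germination_timecourse"))
    data.frame(temperature = tc$temperature, day = tc$days,
               observed = tc$cum_fraction)
  }))
}

# Model-predicted fractions for one parameter vector over an observation
# table; vectorised per temperature block.
predict_fractions <- function(par, obs, cardinals) {
  window <- thermal_window(par[["Tl50"]], par[["sigma_Tl"]],
                           par[["Th50"]], par[["sigma_Th"]])
  out <- numeric(nrow(obs))
  for (T in unique(obs$temperature)) {
    idx <- obs$temperature == T
    acc <- accumulate_thermal_time(T, obs$day[idx], cardinals)
    if (acc$range == "sub") {
      th50 <- par[["theta_sub50"]]; sd <- par[["sigma_sub"]]
    } else {
      th50 <- par[["theta_sup50"]]; sd <- par[["sigma_sup"]]
    }
    out[idx] <- germinable_fraction(T, window) *
      pnorm((acc$thermal_time - th50) / sd)
  }
  out
}

# Seeded Latin-hypercube starts over the box constraints.
lhs_starts <- function(bounds, n, seed) {
  k <- length(bounds)
  with_seed(seed, {
    pts <- vapply(seq_len(k), function(j) {
      (sample(n) - runif(n)) / n
    }, numeric(n))
  })
  pts <- matrix(pts, nrow = n, ncol = k)
  colnames(pts) <- names(bounds)
  for (j in seq_len(k)) {
    b <- bounds[[j]]
    pts[, j] <- b[1L] + pts[, j] * (b[2L] - b[1L])
  }
  pts
}

#' Fit stage parameters to multi-temperature germination time-courses
#'
#' Minimises the RMSE between observed and model cumulative germination
#' fractions over all census observations of one population-by-stage cell,
#' using bounded L-BFGS-B from seeded Latin-hypercube multi-starts. Eight
#' parameters are free (window and thermal-time means and SDs); the cardinal
#' temperatures are fixed inputs. An ordering penalty keeps `Tl50 < Th50`.
#'
#' Observations at or above `exclude_temps` (default 30 degrees C, the
#' temperature at which no germination occurs and which is removed from both
#' model and analysis) are dropped before fitting.
#'
#' @param timecourses List of [germination_timecourse()] spanning at least 3
#'   distinct temperatures (after exclusion).
#' @param cardinals A [cardinal_temps()], held fixed.
#' @param config A [fit_config()].
#' @param init Optional numeric vector (or matrix, one row per start) of
#'   additional starting points named like the free parameters.
#' @param exclude_temps Temperatures whose observations are filtered out.
#' @param population,stage Labels attached to the result.
#' @return An object of class `fit_result`: `params` ([stage_params()]),
#'   `rmse`, `r2`, `n_obs`, `converged`, `start_index`, `start_objectives`.
#' @export
fit_stage <- function(timecourses, cardinals, config = fit_config(),
                      init = NULL, exclude_temps = 30,
                      population = "pop", stage = "M") {
  stopifnot(inherits(cardinals, "cardinal_temps"),
            inherits(config, "fit_config"))
  obs <- flatten_timecourses(timecourses)
  if (length(exclude_temps))
    obs <- obs[!obs$temperature %in% exclude_temps, , drop = FALSE]
  n_temp <- length(unique(obs$temperature))
  if (n_temp < 3L)
    stopf("insufficient data: need >= 3 distinct temperatures, got %d", n_temp)

  bounds <- config$bounds
  lower <- vapply(bounds, `[`, 0, 1L)
  upper <- vapply(bounds, `[`, 0, 2L)
  par_names <- names(bounds)

  objective <- function(par) {
    names(par) <- par_names
    if (par[["Tl50"]] >= par[["Th50"]])          # ordering penalty
      return(10 + (par[["Tl50"]] - par[["Th50"]]))
    rmse(obs$observed, predict_fractions(par, obs, cardinals))
  }

  starts <- lhs_starts(bounds, config$n_starts, config$seed)
  if (!is.null(init)) {
    init <- rbind(init)
    if (is.null(colnames(init))) colnames(init) <- par_names
    starts <- rbind(starts, init[, par_names, drop = FALSE])
  }

  runs <- lapply(seq_len(nrow(starts)), function(i) {
    res <- tryCatch(
      optim(starts[i, ], objective, method = "L-BFGS-B",
            lower = lower, upper = upper,
            control = list(maxit = config$maxit)),
      error = function(e) list(par = starts[i, ], value = objective(starts[i, ]),
                               convergence = 99L))
    res
  })
  values <- vapply(runs, `[[`, 0, "value")
  best_i <- which.min(values)
  best <- runs[[best_i]]
  par <- best$par
  names(par) <- par_names

  sim <- predict_fractions(par, obs, cardinals)
  fit_rmse <- rmse(obs$observed, sim)
  degenerate <- var(obs$observed) <= 0
  r2 <- if (degenerate) NA_real_ else r_squared(obs$observed, sim)
  params <- stage_params(
    population, stage,
    window = thermal_window(par[["Tl50"]], par[["sigma_Tl"]],
                            par[["Th50"]], par[["sigma_Th"]]),
    timing = thermal_time_params(par[["theta_sub50"]], par[["sigma_sub"]],
                                 par[["theta_sup50"]], par[["sigma_sup"]]),
    cardinals = cardinals,
    r2 = if (!is.na(r2)) max(0, min(1, r2)) else NULL)
  structure(list(params = params, rmse = fit_rmse, r2 = r2,
                 n_obs = nrow(obs),
                 converged = !degenerate &&
                   (best$convergence == 0L || fit_rmse <= config$tol),
                 start_index = best_i, start_objectives = values),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> rmse = %.5f, R2 = %s, n_obs = %d, %s (start %d)\n",
              x$rmse, ifelse(is.na(x$r2), "NA", sprintf("%.3f", x$r2)),
              x$n_obs, if (x$converged) "converged" else "NOT converged",
              x$start_index))
  print(x$params)
  invisible(x)
}
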