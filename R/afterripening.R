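# Dormancy release in dry storage: thermal after-ripening time (degree-hours
# above a lower-limit storage temperature) and the rate of widening of the
# thermal niche (RWTN), from an OLS regression of Th50 on storage hours.

#' Thermal after-ripening time accumulated in dry storage
#'
#' Degree-hours driving dormancy loss: `max(0, Ts - Tsl) * duration`, where
#' `Tsl` is the lower-limit storage temperature below which after-ripening
#' does not occur (5 degrees C is a typical value for warm-season annuals
#' stored dry).
#'
#' @param Ts Storage temperature, degrees C.
#' @param Tsl Lower-limit storage temperature, degrees C.
#' @param duration Storage time, hours (`>= 0`); vectorised.
#' @return Thermal after-ripening time, degree C hour.
#' @examples
#' thermal_afterripening_time(20, 5, 720)  # 10800
#' @export
thermal_afterripening_time <- function(Ts, Tsl, duration) {
  check_number(Ts, "Ts"); check_number(Tsl, "Tsl")
  if (any(!is.finite(duration)) || any(duration < 0))
    stopf("`duration` must be non-negative and finite")
  max(0, Ts - Tsl) * duration
}

#' Rate of widening of the thermal niche (RWTN)
#'
#' Ordinary least squares of the higher-limit temperature `Th50` (response,
#' degrees C) on dry-storage time (regressor, hours). The slope `b` is the
#' niche-widening rate in degrees C per hour and `RWTN = 1/b` is the storage
#' time needed per one-degree increase of `Th50`. Significance is assessed by
#' the regression F test (1 and n-2 df).
#'
#' @param th50 Named numeric vector of `Th50` per stage, degrees C.
#' @param hours Storage hours per stage. Either a named vector matched to
#'   `names(th50)`, or `NULL` to use [default_stage_hours()] (the immature
#'   stage `D`, which has no storage-time coding, is dropped).
#' @return An object of class `rwtn_fit` with elements `a` (intercept,
#'   degrees C), `b` (slope, degrees C/hour), `se_b`, `r2`, `p_value`,
#'   `rwtn` (hours per degree C; `Inf` with `degenerate = TRUE` when the
#'   slope is indistinguishable from zero), and `n`.
#' @examples
#' fit_rwtn(c(M = 25, AR1 = 28, AR2 = 30, AR5 = 33))
#' @export
fit_rwtn <- function(th50, hours = NULL) {
  if (is.null(hours)) {
    hours <- default_stage_hours()
    if (!is.null(names(th50))) {
      keep <- intersect(names(th50), names(hours))
      th50 <- th50[keep]; hours <- hours[keep]
    }
  } else if (!is.null(names(hours)) && !is.null(names(th50))) {
    common <- intersect(names(th50), names(hours))
    th50 <- th50[common]; hours <- hours[common]
  }
  if (length(th50) != length(hours))
    stopf("`th50` and `hours` must match in length / names")
  if (length(th50) < 3L)
    stopf("insufficient data: need >= 3 stages for the storage regression")
  if (length(unique(hours)) < 2L)
    stopf("storage hours must not all be equal")

  fit <- lm(th50 ~ hours)
  # noiseless synthetic trajectories legitimately produce a perfect fit;
  # muffle only that advisory warning
  sm <- withCallingHandlers(summary(fit), warning = function(w) {
    if (grepl("essentially perfect fit", conditionMessage(w)))
      invokeRestart("muffleWarning")
  })
  b <- unname(coef(fit)[2L])
  se_b <- sm$coefficients[2L, 2L]
  fstat <- sm$fstatistic
  p <- if (is.null(fstat) || !all(is.finite(fstat))) NA_real_ else
    unname(pf(fstat[1L], fstat[2L], fstat[3L], lower.tail = FALSE))
  degenerate <- abs(b) < 1e-12
  r2 <- sm$r.squared
  if (!is.finite(r2)) r2 <- NA_real_   # constant response
  structure(list(a = unname(coef(fit)[1L]), b = b, se_b = se_b,
                 r2 = r2, p_value = p,
                 rwtn = if (degenerate) Inf else 1 / b,
                 degenerate = degenerate, n = length(th50),
                 residuals = unname(stats::residuals(fit)),
                 hours = unname(hours)),
            class = "rwtn_fit")
}

#' @export
print.rwtn_fit <- function(x, ...) {
  cat(sprintf(
    "<rwtn_fit> a = %.2f degC, b = %.6f degC/h (se %.6f), RWTN = %s h/degC, R2 = %.3f, p = %.4f, n = %d\n",
    x$a, x$b, x$se_b,
    if (is.finite(x$rwtn)) sprintf("%.1f", x$rwtn) else "Inf",
    x$r2, x$p_value, x$n))
  invisible(x)
}

#' Storage regressions for every population of a parameter table
#'
#' Applies [fit_rwtn()] population-wise to a Table-1-schema parameter table
#' (columns `population`, `stage`, `Th50`, ...), using the after-ripened
#' stage coding in `hours`.
#'
#' @param params Data frame in the parameter schema (see [read_params()]).
#' @param hours Named storage-hours vector; default [default_stage_hours()].
#' @return Data frame with one row per population: `a`, `b`, `se_b`, `rwtn`,
#'   `p_value`, `r2`, `n`.
#' @export
fit_rwtn_table <- function(params, hours = default_stage_hours()) {
  stopifnot(is.data.frame(params),
            all(c("population", "stage", "Th50") %in% names(params)))
  pops <- unique(params$population)
  rows <- lapply(pops, function(pop) {
    sub <- params[params$population == pop & params$stage %in% names(hours), ]
    th <- sub$Th50
    names(th) <- sub$stage
    f <- fit_rwtn(th, hours[names(th)])
    data.frame(population = pop, a = f$a, b = f$b, se_b = f$se_b,
               rwtn = f$rwtn, p_value = f$p_value, r2 = f$r2, n = f$n,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
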