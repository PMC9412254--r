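# Core population-based threshold (PBT) germination model.
#
# A seed lot's permissive temperature window is bounded by normally
# distributed lower and higher limit temperatures; within the window,
# germination timing follows normally distributed thermal-time requirements
# accumulated above Tb (sub-optimal) or below Tm (supra-optimal). The two
# layers are combined multiplicatively (independence of window membership and
# timing), a composition the window/timing literature leaves implicit; it is
# isolated in cumulative_germination() so the choice is replaceable.

#' Standard normal cumulative distribution function
#'
#' The normal probability integral used throughout the threshold model.
#'
#' @param z Numeric vector of quantiles; must be finite.
#' @return `P(Z <= z)` for `Z ~ N(0, 1)`.
#' @examples
#' std_normal_cdf(0)       # 0.5
#' std_normal_cdf(1)       # 0.8413447
#' @export
std_normal_cdf <- function(z) {
  if (!is.numeric(z) || length(z) == 0L || any(!is.finite(z)))
    stopf("`z` must be finite numeric")
  pnorm(z)
}

#' Germinable fraction of a seed lot at a temperature
#'
#' Fraction of the population whose permissive window contains `T`:
#' `GF(T) = Phi((T - Tl50)/sigma_Tl) - Phi((T - Th50)/sigma_Th)`, clamped to
#' `[0, 1]`. By the symmetry `Phi(-z) = 1 - Phi(z)` this difference-of-CDFs
#' form is algebraically identical to writing the upper tail as
#' `1 - Phi((T - Th50)/sigma_Th)` subtracted from 1. Clamping at zero guards
#' the (physically questionable) case where the two limit distributions
#' overlap heavily.
#'
#' @param temperature Incubation temperature(s), degrees C; finite.
#' @param window A [thermal_window()].
#' @return Germinable fraction(s) in `[0, 1]`.
#' @examples
#' germinable_fraction(20, thermal_window(10, 1, 30, 1))   # ~1
#' germinable_fraction(33, thermal_window(6.6, 2, 35, 2))  # ~0.84
#' @export
germinable_fraction <- function(temperature, window) {
  if (!inherits(window, "thermal_window"))
    stopf("`window` must be a thermal_window object")
  if (any(!is.finite(temperature)))
    stopf("`temperature` must be finite")
  gf <- pnorm((temperature - window$Tl50) / window$sigma_Tl) -
        pnorm((temperature - window$Th50) / window$sigma_Th)
  pmin(1, pmax(0, gf))
}

#' Thermal-time accumulation at a constant incubation temperature
#'
#' Degree-days accrued after `t` days at temperature `T`: above the base
#' temperature in the sub-optimal range (`T <= To`), below the ceiling
#' temperature in the supra-optimal range (`T > To`). The boundary `T == To`
#' is assigned to the sub-optimal branch.
#'
#' @param temperature Incubation temperature, degrees C.
#' @param t Elapsed time, days (vectorised); must be `>= 0`.
#' @param cardinals A [cardinal_temps()].
#' @return A list with `range` (`"sub"` or `"sup"`) and `thermal_time`
#'   (degree C day, same length as `t`).
#' @examples
#' accumulate_thermal_time(15, 3, cardinal_temps(5, 20, 35))  # sub, 30
#' @export
accumulate_thermal_time <- function(temperature, t, cardinals) {
  if (!inherits(cardinals, "cardinal_temps"))
    stopf("`cardinals` must be a cardinal_temps object")
  check_number(temperature, "temperature")
  if (any(!is.finite(t)) || any(t < 0))
    stopf("`t` must be non-negative and finite")
  if (temperature <= cardinals$To) {
    list(range = "sub",
         thermal_time = pmax(0, temperature - cardinals$Tb) * t)
  } else {
    list(range = "sup",
         thermal_time = pmax(0, cardinals$Tm - temperature) * t)
  }
}

#' Cumulative germination fraction under the PBT model
#'
#' Expected cumulative germinated fraction after `t` days of incubation at
#' `temperature`: the germinable fraction of the window multiplied by the
#' fraction of seeds whose thermal-time requirement has been met,
#' `GF(T) * Phi((theta_acc(T, t) - theta50) / sigma_theta)`, with the sub- or
#' supra-optimal `theta50`/`sigma_theta` pair selected by the temperature
#' range. Non-decreasing in `t` and bounded above by `germinable_fraction()`.
#'
#' @param temperature Incubation temperature, degrees C (scalar).
#' @param t Elapsed time, days (vectorised, `>= 0`).
#' @param params A [stage_params()].
#' @return Cumulative germinated fraction(s).
#' @examples
#' p <- stage_params("Arak", "AR5",
#'        thermal_window(6.6, 2, 35, 2),
#'        thermal_time_params(15, 4.4, 16, 4),
#'        cardinal_temps(1, 22, 30))
#' cumulative_germination(15, 0:5, p)
#' @export
cumulative_germination <- function(temperature, t, params) {
  if (!inherits(params, "stage_params"))
    stopf("`params` must be a stage_params object")
  acc <- accumulate_thermal_time(temperature, t, params$cardinals)
  gf <- germinable_fraction(temperature, params$window)
  if (acc$range == "sub") {
    th50 <- params$timing$theta_sub50; sd <- params$timing$sigma_sub
  } else {
    th50 <- params$timing$theta_sup50; sd <- params$timing$sigma_sup
  }
  # At zero accumulation rate (T at/below Tb, or at/above Tm) this stays at
  # the negligible floor gf * Phi(-theta50/sigma) for all t.
  gf * pnorm((acc$thermal_time - th50) / sd)
}

#' Classify the pattern of nondeep physiological dormancy release
#'
#' Compares the thermal window of the first and last dormancy stage of one
#' population. Type 1: the higher limit `Th50` rises while the lower limit
#' `Tl50` stays put (dormant seeds germinate only at low temperature, and
#' dormancy loss shifts the permissive range upward). Type 2: `Tl50` falls
#' while `Th50` stays put. Type 3: the window widens at both ends. `"none"`:
#' no change beyond tolerance.
#'
#' @param stages Either a list of [stage_params()] in developmental order, or
#'   a data frame with columns `Tl50` and `Th50` (rows in developmental
#'   order).
#' @param tol Tolerance in degrees C for calling a limit "constant"; default
#'   1, smaller than any real between-stage step in a typical after-ripening
#'   series.
#' @return One of `"Type1"`, `"Type2"`, `"Type3"`, `"none"`.
#' @export
classify_dormancy_type <- function(stages, tol = 1) {
  check_positive(tol, "tol")
  if (is.data.frame(stages)) {
    if (!all(c("Tl50", "Th50") %in% names(stages)))
      stopf("data-frame input needs `Tl50` and `Th50` columns")
    tl <- stages$Tl50; th <- stages$Th50
  } else if (is.list(stages) && all(vapply(stages, inherits, TRUE, "stage_params"))) {
    pops <- unique(vapply(stages, `[[`, "", "population"))
    if (length(pops) > 1L)
      stopf("stages mix populations: %s", paste(pops, collapse = ", "))
    tl <- vapply(stages, function(s) s$window$Tl50, 0)
    th <- vapply(stages, function(s) s$window$Th50, 0)
  } else {
    stopf("`stages` must be a list of stage_params or a data frame")
  }
  if (length(tl) < 2L)
    stopf("insufficient data: need at least 2 stages to classify")
  d_tl <- tl[length(tl)] - tl[1L]
  d_th <- th[length(th)] - th[1L]
  th_up <- d_th > tol
  tl_down <- d_tl < -tol
  if (th_up && !tl_down && abs(d_tl) <= tol) "Type1"
  else if (tl_down && !th_up && abs(d_th) <= tol) "Type2"
  else if (th_up && tl_down) "Type3"
  else "none"
}
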