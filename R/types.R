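# Domain containers for the population-based threshold (PBT) model.
#
# Lightweight S3 records with validating constructors: the model layer assumes
# its invariants hold, so every user-facing entry point builds these.

#' Dormancy stage labels and default storage-hour coding
#'
#' Stages follow the sampling design of a common-garden after-ripening trial:
#' immature (`D`, two weeks before maturity), mature (`M`), and 1, 2 and 5
#' months of dry after-ripening (`AR1`, `AR2`, `AR5`). Storage hours use
#' 30-day months (720 h): `M = 0`, `AR1 = 720`, `AR2 = 1440`, `AR5 = 3600`.
#' The immature stage has no storage-time coding and is excluded from
#' storage-time regressions.
#'
#' @return `stage_levels()`: character vector of the five labels, in
#'   developmental order. `default_stage_hours()`: named numeric vector of
#'   storage hours for the stages that have one.
#' @export
stage_levels <- function() c("D", "M", "AR1", "AR2", "AR5")

#' @rdname stage_levels
#' @export
default_stage_hours <- function() {
  c(M = 0, AR1 = 720, AR2 = 1440, AR5 = 3600)
}

#' Thermal window of a seed lot
#'
#' The dormancy-state envelope: lower- and higher-limit temperatures below or
#' above which half of the seed population cannot germinate, each normally
#' distributed over seeds.
#'
#' @param Tl50 Mean lower-limit temperature, degrees C.
#' @param sigma_Tl Standard deviation of the lower limit, degrees C (> 0).
#' @param Th50 Mean higher-limit temperature, degrees C (> `Tl50`).
#' @param sigma_Th Standard deviation of the higher limit, degrees C (> 0).
#' @return An object of class `thermal_window`.
#' @examples
#' thermal_window(6.6, 2, 35, 2)
#' @export
thermal_window <- function(Tl50, sigma_Tl, Th50, sigma_Th) {
  check_number(Tl50, "Tl50"); check_number(Th50, "Th50")
  check_positive(sigma_Tl, "sigma_Tl"); check_positive(sigma_Th, "sigma_Th")
  if (Tl50 >= Th50) stopf("Tl50 (%g) must be below Th50 (%g)", Tl50, Th50)
  structure(list(Tl50 = Tl50, sigma_Tl = sigma_Tl,
                 Th50 = Th50, sigma_Th = sigma_Th),
            class = "thermal_window")
}

#' Cardinal temperatures for germination rate
#'
#' Base, optimum and maximum (ceiling) temperatures, assumed constant for the
#' whole seed population. Thermal time accumulates above `Tb` in the
#' sub-optimal range and below `Tm` in the supra-optimal range.
#'
#' @param Tb Base temperature, degrees C.
#' @param To Optimum temperature, degrees C.
#' @param Tm Maximum (ceiling) temperature, degrees C.
#' @return An object of class `cardinal_temps`.
#' @export
cardinal_temps <- function(Tb, To, Tm) {
  check_number(Tb, "Tb"); check_number(To, "To"); check_number(Tm, "Tm")
  if (!(Tb < To && To < Tm))
    stopf("cardinal temperatures must satisfy Tb < To < Tm (got %g, %g, %g)",
          Tb, To, Tm)
  structure(list(Tb = Tb, To = To, Tm = Tm), class = "cardinal_temps")
}

#' Thermal-time parameters of germination timing
#'
#' Mean and standard deviation of the thermal time (degree-days) required to
#' complete germination, separately for the sub-optimal and supra-optimal
#' temperature ranges; both distributions are normal over seeds.
#'
#' @param theta_sub50,sigma_sub Mean and SD of sub-optimal thermal time,
#'   degree C day (> 0).
#' @param theta_sup50,sigma_sup Mean and SD of supra-optimal thermal time,
#'   degree C day (> 0).
#' @return An object of class `thermal_time_params`.
#' @export
thermal_time_params <- function(theta_sub50, sigma_sub,
                                theta_sup50, sigma_sup) {
  check_positive(theta_sub50, "theta_sub50")
  check_positive(sigma_sub, "sigma_sub")
  check_positive(theta_sup50, "theta_sup50")
  check_positive(sigma_sup, "sigma_sup")
  structure(list(theta_sub50 = theta_sub50, sigma_sub = sigma_sub,
                 theta_sup50 = theta_sup50, sigma_sup = sigma_sup),
            class = "thermal_time_params")
}

#' Full parameter set of one population at one dormancy stage
#'
#' @param population Population identifier (character scalar).
#' @param stage Stage label, one of [stage_levels()].
#' @param window A [thermal_window()].
#' @param timing A [thermal_time_params()].
#' @param cardinals A [cardinal_temps()].
#' @param r2 Optional goodness-of-fit in `[0, 1]`.
#' @return An object of class `stage_params`.
#' @export
stage_params <- function(population, stage, window, timing, cardinals,
                         r2 = NULL) {
  if (!is.character(population) || length(population) != 1L)
    stopf("`population` must be a single character identifier")
  stage <- match.arg(stage, stage_levels())
  stopifnot(inherits(window, "thermal_window"),
            inherits(timing, "thermal_time_params"),
            inherits(cardinals, "cardinal_temps"))
  if (!is.null(r2)) {
    check_number(r2, "r2")
    if (r2 < 0 || r2 > 1) stopf("`r2` must lie in [0, 1]")
  }
  structure(list(population = population, stage = stage, window = window,
                 timing = timing, cardinals = cardinals, r2 = r2),
            class = "stage_params")
}

#' Observed or simulated germination time-course at one temperature
#'
#' @param temperature Incubation temperature, degrees C.
#' @param days Strictly increasing census days.
#' @param cum_fraction Cumulative germinated fraction at each census day;
#'   non-decreasing, in `[0, 1]`.
#' @param n_seeds Seeds per dish.
#' @param replicate Dish identifier.
#' @param population,stage Optional provenance labels.
#' @return An object of class `germination_timecourse`.
#' @export
germination_timecourse <- function(temperature, days, cum_fraction,
                                   n_seeds, replicate = 1L,
                                   population = NA_character_,
                                   stage = NA_character_) {
  check_number(temperature, "temperature")
  if (length(days) == 0L || any(!is.finite(days)))
    stopf("`days` must be non-empty and finite")
  if (any(diff(days) <= 0)) stopf("`days` must be strictly increasing")
  if (length(days) != length(cum_fraction))
    stopf("`days` and `cum_fraction` must have equal length")
  if (any(!is.finite(cum_fraction)) ||
      any(cum_fraction < 0) || any(cum_fraction > 1))
    stopf("`cum_fraction` must lie in [0, 1]")
  if (any(diff(cum_fraction) < -1e-12))
    stopf("`cum_fraction` must be non-decreasing over days")
  if (!is.numeric(n_seeds) || n_seeds < 0)
    stopf("`n_seeds` must be a non-negative count")
  structure(list(temperature = as.numeric(temperature),
                 days = as.numeric(days),
                 cum_fraction = as.numeric(cum_fraction),
                 n_seeds = as.integer(n_seeds), replicate = replicate,
                 population = population, stage = stage),
            class = "germination_timecourse")
}

#' @export
print.thermal_window <- function(x, ...) {
  cat(sprintf("<thermal_window> Tl50 = %.2f (sd %.2f), Th50 = %.2f (sd %.2f) degC\n",
              x$Tl50, x$sigma_Tl, x$Th50, x$sigma_Th))
  invisible(x)
}

#' @export
print.stage_params <- function(x, ...) {
  cat(sprintf("<stage_params> %s / %s\n", x$population, x$stage))
  print(x$window)
  cat(sprintf("  theta_sub50 = %.2f (sd %.2f), theta_sup50 = %.2f (sd %.2f) degC day\n",
              x$timing$theta_sub50, x$timing$sigma_sub,
              x$timing$theta_sup50, x$timing$sigma_sup))
  cat(sprintf("  cardinals: Tb = %.2f, To = %.2f, Tm = %.2f degC%s\n",
              x$cardinals$Tb, x$cardinals$To, x$cardinals$Tm,
              if (!is.null(x$r2)) sprintf("; R2 = %.3f", x$r2) else ""))
  invisible(x)
}

#' Convert between stage parameters and the tabular parameter schema
#'
#' `stage_params_row()` turns a [stage_params()] into one row of the
#' parameter-table schema used by [read_params()]/[write_params()];
#' `stage_params_from_row()` rebuilds the object from such a row plus the
#' cardinal temperatures (which the table does not carry).
#'
#' @param p A [stage_params()].
#' @param storage_month Months of dry storage recorded in the row.
#' @return A one-row data frame, or a [stage_params()].
#' @export
stage_params_row <- function(p, storage_month = NA_real_) {
  data.frame(population = p$population, storage_month = storage_month,
             stage = p$stage,
             Tl50 = p$window$Tl50, sigma_Tl = p$window$sigma_Tl,
             Th50 = p$window$Th50, sigma_Th = p$window$sigma_Th,
             theta_sub50 = p$timing$theta_sub50,
             sigma_sub = p$timing$sigma_sub,
             theta_sup50 = p$timing$theta_sup50,
             sigma_sup = p$timing$sigma_sup,
             R2 = if (is.null(p$r2)) NA_real_ else p$r2,
             stringsAsFactors = FALSE)
}

#' @rdname stage_params_row
#' @param row One row of the parameter schema.
#' @param cardinals A [cardinal_temps()].
#' @export
stage_params_from_row <- function(row, cardinals) {
  stage_params(
    population = as.character(row$population),
    stage = as.character(row$stage),
    window = thermal_window(row$Tl50, row$sigma_Tl, row$Th50, row$sigma_Th),
    timing = thermal_time_params(row$theta_sub50, row$sigma_sub,
                                 row$theta_sup50, row$sigma_sup),
    cardinals = cardinals,
    r2 = if (!is.null(row$R2) && is.finite(row$R2)) row$R2 else NULL)
}
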