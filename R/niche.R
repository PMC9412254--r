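# Thermal-niche envelopes and germination-timing prediction: the graphical
# method of plotting the stage-indexed permissive band (Tl50..Th50) against
# long-term monthly mean temperatures, and the forward scan that finds when
# the climate curve first enters the stage-appropriate band.

#' Stage-indexed thermal-niche envelope of one population
#'
#' @param fits List of [stage_params()] (or a parameter-schema data frame
#'   restricted to one population) covering at least two stages.
#' @param stage_hours Named storage-hours vector ordering the stages; stages
#'   without a coding (e.g. immature `D`) are placed first at `-Inf`... they
#'   are kept for plotting but the timing scan uses coded stages only.
#' @return An object of class `niche_envelope`: `population`, `stages`,
#'   `hours`, `lower` (Tl50), `upper` (Th50).
#' @export
build_envelope <- function(fits, stage_hours = default_stage_hours()) {
  if (is.data.frame(fits)) {
    pops <- unique(fits$population)
    if (length(pops) > 1L)
      stopf("`fits` mixes populations: %s", paste(pops, collapse = ", "))
    stages <- as.character(fits$stage)
    lower <- fits$Tl50; upper <- fits$Th50; population <- pops
  } else {
    stopifnot(all(vapply(fits, inherits, TRUE, "stage_params")))
    pops <- unique(vapply(fits, `[[`, "", "population"))
    if (length(pops) > 1L)
      stopf("`fits` mixes populations: %s", paste(pops, collapse = ", "))
    stages <- vapply(fits, `[[`, "", "stage")
    lower <- vapply(fits, function(f) f$window$Tl50, 0)
    upper <- vapply(fits, function(f) f$window$Th50, 0)
    population <- pops
  }
  if (length(stages) < 2L)
    stopf("insufficient data: need >= 2 stages to build an envelope")
  if (anyDuplicated(stages)) stopf("duplicated stage labels")
  hours <- unname(stage_hours[stages])
  hours[is.na(hours)] <- -Inf      # uncoded (immature) stages sort first
  o <- order(hours)
  stages <- stages[o]; hours <- hours[o]
  lower <- lower[o]; upper <- upper[o]
  if (any(lower >= upper))
    stopf("envelope invalid: lower limit must be below upper at every stage")
  structure(list(population = population, stages = stages, hours = hours,
                 lower = lower, upper = upper),
            class = "niche_envelope")
}

#' Does a mean temperature fall inside a stage's thermal niche?
#'
#' The envelope is treated as a closed interval.
#'
#' @param envelope A [niche_envelope()].
#' @param stage Stage label present in the envelope.
#' @param mean_temp Mean temperature, degrees C.
#' @return `TRUE` iff `lower(stage) <= mean_temp <= upper(stage)`.
#' @export
overlaps <- function(envelope, stage, mean_temp) {
  stopifnot(inherits(envelope, "niche_envelope"))
  i <- match(stage, envelope$stages)
  if (is.na(i)) stopf("unknown stage `%s`", stage)
  check_number(mean_temp, "mean_temp")
  mean_temp >= envelope$lower[i] && mean_temp <= envelope$upper[i]
}

#' Climate normals container
#'
#' @param mean_temp Long-term (e.g. 20-year) mean temperature per calendar
#'   month, degrees C; length 1-12, finite.
#' @param months Integer month labels (default `1:length(mean_temp)`).
#' @return An object of class `climate_series`.
#' @export
climate_series <- function(mean_temp, months = seq_along(mean_temp)) {
  if (length(mean_temp) < 1L || length(mean_temp) > 12L ||
      any(!is.finite(mean_temp)))
    stopf("`mean_temp` must be 1-12 finite monthly means")
  if (length(months) != length(mean_temp) || anyDuplicated(months))
    stopf("`months` must be distinct and match `mean_temp`")
  o <- order(months)
  structure(list(months = as.integer(months)[o],
                 mean_temp = as.numeric(mean_temp)[o]),
            class = "climate_series")
}

# Stage in force after `h` storage hours since maturity: piecewise constant,
# right-continuous, switching at each coded stage's hours.
stage_for_elapsed_hours <- function(envelope, h) {
  coded <- is.finite(envelope$hours)
  stages <- envelope$stages[coded]; hours <- envelope$hours[coded]
  if (!length(stages)) stopf("envelope has no storage-coded stages")
  i <- findInterval(h, hours)
  stages[pmax(1L, i)]
}

#' Predict field germination timing from climate normals
#'
#' Scans forward from the month of seed maturity over a cyclic year. The
#' monthly mean-temperature curve is interpolated piecewise-linearly between
#' consecutive months; at each point the stage-appropriate envelope (chosen
#' by elapsed storage hours, 720 h per scanned month) is compared with the
#' interpolated temperature, and the first entry of the curve into the
#' closed band `[Tl50, Th50]` is returned.
#'
#' @param envelope A [niche_envelope()].
#' @param climate A [climate_series()] covering all 12 months.
#' @param maturity_month Calendar month (1-12) at which seeds mature and dry
#'   storage begins.
#' @return List with `crossed` (logical), `crossing_month` (calendar month,
#'   possibly fractional), `months_after_maturity`, `predicted_temp`
#'   (degrees C at the crossing) and `stage` (envelope stage in force).
#'   `crossed = FALSE` with `NA` fields when the curve never enters the band
#'   within 12 months.
#' @export
predict_timing <- function(envelope, climate, maturity_month) {
  stopifnot(inherits(envelope, "niche_envelope"),
            inherits(climate, "climate_series"))
  if (length(climate$mean_temp) != 12L)
    stopf("timing prediction needs all 12 monthly means")
  if (!maturity_month %in% 1:12) stopf("`maturity_month` must be in 1..12")

  month_at <- function(tau) ((maturity_month - 1 + tau) %% 12) + 1
  temp_at_offset <- function(tau) {        # tau in months since maturity
    m0 <- floor(tau); frac <- tau - m0
    i <- as.integer(((maturity_month - 1 + m0) %% 12)) + 1L
    j <- as.integer((i %% 12)) + 1L
    climate$mean_temp[i] * (1 - frac) + climate$mean_temp[j] * frac
  }

  for (k in 0:11) {                        # scan month segments forward
    stage <- stage_for_elapsed_hours(envelope, 720 * k)
    si <- match(stage, envelope$stages)
    lo <- envelope$lower[si]; hi <- envelope$upper[si]
    t0 <- temp_at_offset(k); t1 <- temp_at_offset(k + 1)
    inside0 <- t0 >= lo && t0 <= hi
    if (inside0) {
      return(list(crossed = TRUE, crossing_month = month_at(k),
                  months_after_maturity = k, predicted_temp = t0,
                  stage = stage))
    }
    # linear segment: first tau in (k, k+1] where the curve meets the band
    target <- if (t0 > hi && t1 < t0) hi
              else if (t0 < lo && t1 > t0) lo
              else NA_real_
    if (!is.na(target)) {
      frac <- (target - t0) / (t1 - t0)
      if (frac >= 0 && frac <= 1) {
        tau <- k + frac
        return(list(crossed = TRUE, crossing_month = month_at(tau),
                    months_after_maturity = tau, predicted_temp = target,
                    stage = stage))
      }
    }
  }
  list(crossed = FALSE, crossing_month = NA_real_,
       months_after_maturity = NA_real_, predicted_temp = NA_real_,
       stage = NA_character_)
}

#' Plot a population's thermal niche against climate normals
#'
#' Envelope bands (Tl50..Th50 per stage, ordered by storage hours) with the
#' monthly long-term means overplotted as solid squares.
#'
#' @param envelope A [niche_envelope()].
#' @param climate Optional [climate_series()].
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, the envelope.
#' @export
plot_niche <- function(envelope, climate = NULL, ...) {
  stopifnot(inherits(envelope, "niche_envelope"))
  n <- length(envelope$stages)
  x <- seq_len(n)
  ylim <- range(envelope$lower, envelope$upper,
                if (!is.null(climate)) climate$mean_temp)
  graphics::plot(NA, xlim = c(0.5, n + 0.5), ylim = ylim + c(-1, 1),
                 xaxt = "n", xlab = "dormancy stage (storage time order)",
                 ylab = "temperature (degC)",
                 main = envelope$population, ...)
  axis(1, at = x, labels = envelope$stages)
  polygon(c(x, rev(x)), c(envelope$lower, rev(envelope$upper)),
          col = "#a6cee380", border = "#1f78b4")
  lines(x, envelope$lower, col = "#1f78b4", lwd = 2)
  lines(x, envelope$upper, col = "#1f78b4", lwd = 2)
  if (!is.null(climate)) {
    xx <- seq(0.75, n + 0.25, length.out = length(climate$mean_temp))
    points(xx, climate$mean_temp, pch = 15, col = "black")
    legend("topleft", bty = "n", pch = c(15, NA), lty = c(NA, 1),
           col = c("black", "#1f78b4"),
           legend = c("monthly long-term mean", "Tl50..Th50 envelope"))
  }
  invisible(envelope)
}
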