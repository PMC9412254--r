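# Readers and writers for the pipeline's plain-text schemas.
#
# counts.csv    long census format: population,stage,temp_c,replicate,day,
#               germinated,total
# params.csv    Table-1-style parameter schema: population,storage_month,
#               stage,Tl50,sigma_Tl,Th50,sigma_Th,theta_sub50,sigma_sub,
#               theta_sup50,sigma_sup,R2
# cardinals.csv population,Tb,To,Tm
# climate.csv   month,mean_temp_c

counts_columns <- c("population", "stage", "temp_c", "replicate", "day",
                    "germinated", "total")

#' Read a long-format germination census table
#'
#' Validates the schema row by row: counts must be integers within the dish
#' size and cumulative counts must be non-decreasing over days within each
#' dish. Violations raise an error naming the offending row.
#'
#' @param path CSV file with columns `population, stage, temp_c, replicate,
#'   day, germinated, total`.
#' @return A list of [germination_timecourse()], one per
#'   population-stage-temperature-dish combination.
#' @export
read_counts <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stopf("counts file `%s` is empty", path)
  missing_cols <- setdiff(counts_columns, names(df))
  if (length(missing_cols))
    stopf("counts file lacks columns: %s", paste(missing_cols, collapse = ", "))
  bad <- which(!is.finite(df$germinated) | !is.finite(df$total) |
               df$germinated < 0 | df$germinated > df$total)
  if (length(bad))
    stopf("counts file row %d: germinated must lie in [0, total]", bad[1L] + 1L)
  counts_to_timecourses(df)
}

#' Convert a counts data frame to time-course objects (and back)
#'
#' @param df Data frame in the counts schema.
#' @return `counts_to_timecourses()`: list of [germination_timecourse()];
#'   `timecourses_to_counts()`: data frame in the counts schema.
#' @export
counts_to_timecourses <- function(df) {
  key <- interaction(df$population, df$stage, df$temp_c, df$replicate,
                     drop = TRUE)
  lapply(split(df, key), function(g) {
    g <- g[order(g$day), ]
    if (any(diff(g$germinated) < 0))
      stopf("non-monotone cumulative counts for %s/%s at %g degC dish %s",
            g$population[1L], g$stage[1L], g$temp_c[1L], g$replicate[1L])
    germination_timecourse(
      temperature = g$temp_c[1L], days = g$day,
      cum_fraction = if (g$total[1L] > 0) g$germinated / g$total else
        g$germinated * 0,
      n_seeds = g$total[1L], replicate = g$replicate[1L],
      population = as.character(g$population[1L]),
      stage = as.character(g$stage[1L]))
  })
}

#' @rdname counts_to_timecourses
#' @param timecourses List of [germination_timecourse()].
#' @export
timecourses_to_counts <- function(timecourses) {
  do.call(rbind, lapply(timecourses, function(tc) {
    data.frame(population = tc$population, stage = tc$stage,
               temp_c = tc$temperature, replicate = tc$replicate,
               day = tc$days,
               germinated = as.integer(round(tc$cum_fraction * tc$n_seeds)),
               total = tc$n_seeds, stringsAsFactors = FALSE)
  }))
}

#' @rdname read_counts
#' @param timecourses List of [germination_timecourse()].
#' @export
write_counts <- function(timecourses, path) {
  write.csv(timecourses_to_counts(timecourses), path, row.names = FALSE)
  invisible(path)
}

#' Read / write the Table-1-style parameter schema
#'
#' @param path CSV path.
#' @return `read_params()`: data frame with the parameter columns.
#' @export
read_params <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("population", "stage", "Tl50", "sigma_Tl", "Th50", "sigma_Th",
            "theta_sub50", "sigma_sub", "theta_sup50", "sigma_sup")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stopf("parameter file lacks columns: %s",
          paste(missing_cols, collapse = ", "))
  bad <- which(df$Tl50 >= df$Th50)
  if (length(bad))
    stopf("parameter file row %d: Tl50 must be below Th50", bad[1L] + 1L)
  df
}

#' @rdname read_params
#' @param params Data frame in the parameter schema.
#' @export
write_params <- function(params, path) {
  write.csv(params, path, row.names = FALSE)
  invisible(path)
}

#' Read a per-population cardinal-temperature table
#'
#' @param path CSV with columns `population, Tb, To, Tm`.
#' @return Named list of [cardinal_temps()] keyed by population.
#' @export
read_cardinals <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("population", "Tb", "To", "Tm")
  if (!all(need %in% names(df)))
    stopf("cardinals file needs columns: %s", paste(need, collapse = ", "))
  out <- lapply(seq_len(nrow(df)),
                function(i) cardinal_temps(df$Tb[i], df$To[i], df$Tm[i]))
  names(out) <- df$population
  out
}

#' Read / write monthly climate normals
#'
#' @param path CSV with columns `month` (1-12) and `mean_temp_c`.
#' @return `read_climate()`: a [climate_series()].
#' @export
read_climate <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("month", "mean_temp_c") %in% names(df)))
    stopf("climate file needs columns `month` and `mean_temp_c`")
  climate_series(df$mean_temp_c, df$month)
}

#' @rdname read_climate
#' @param climate A [climate_series()].
#' @export
write_climate <- function(climate, path) {
  stopifnot(inherits(climate, "climate_series"))
  write.csv(data.frame(month = climate$months,
                       mean_temp_c = climate$mean_temp),
            path, row.names = FALSE)
  invisible(path)
}
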