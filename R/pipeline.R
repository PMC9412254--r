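# End-to-end analysis pipeline: census counts -> stage fits -> dormancy
# typology -> niche-widening regression -> synchrony -> envelopes -> timing.

#' Pipeline configuration
#'
#' @param counts Counts file path or a list of [germination_timecourse()].
#' @param cardinals Cardinals file path or a named list of
#'   [cardinal_temps()] keyed by population (a single unnamed
#'   `cardinal_temps` is recycled for all populations).
#' @param climate Optional climate file path or [climate_series()].
#' @param stage_hours Named storage-hours vector; default
#'   [default_stage_hours()].
#' @param maturity_month Calendar month when storage begins (used for
#'   timing prediction); default 7 (mid-summer seed maturity).
#' @param sog_mode `"mu"` or `"paired"` (see [sog()]).
#' @param seed Master RNG seed for the whole run.
#' @param n_starts Multi-start count for each stage fit.
#' @param exclude_temps Temperatures filtered before fitting (default 30).
#' @param outdir Output directory for the CSV reports (created if needed);
#'   `NULL` to skip writing.
#' @param figures Also write per-population niche figures (PNG).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(counts, cardinals, climate = NULL,
                            stage_hours = default_stage_hours(),
                            maturity_month = 7L, sog_mode = "mu",
                            seed = 1L, n_starts = 8L, exclude_temps = 30,
                            outdir = NULL, figures = FALSE) {
  if (is.unsorted(stage_hours, strictly = TRUE))
    stopf("`stage_hours` must be strictly increasing")
  structure(list(counts = counts, cardinals = cardinals, climate = climate,
                 stage_hours = stage_hours,
                 maturity_month = as.integer(maturity_month),
                 sog_mode = match.arg(sog_mode, c("mu", "paired")),
                 seed = as.integer(seed), n_starts = as.integer(n_starts),
                 exclude_temps = exclude_temps, outdir = outdir,
                 figures = isTRUE(figures)),
            class = "pipeline_config")
}

resolve_counts <- function(x) {
  if (is.character(x)) read_counts(x) else x
}

resolve_cardinals <- function(x) {
  if (is.character(x)) read_cardinals(x)
  else if (inherits(x, "cardinal_temps")) list(.default = x)
  else x
}

resolve_climate <- function(x) {
  if (is.null(x)) NULL
  else if (is.character(x)) read_climate(x)
  else x
}

cardinals_for <- function(cardinals, population) {
  if (!is.null(cardinals[[population]])) cardinals[[population]]
  else if (!is.null(cardinals$.default)) cardinals$.default
  else stopf("no cardinal temperatures configured for population `%s`",
             population)
}

#' Run the full thermal-niche analysis pipeline
#'
#' Fits stage parameters for every population-by-stage cell of the census,
#' classifies the dormancy-release pattern, regresses Th50 on storage hours
#' (RWTN), computes the synchrony statistic, builds niche envelopes and —
#' when a climate series is configured — predicts germination timing. All
#' randomness flows from the single configured seed, so two runs with equal
#' configuration are identical.
#'
#' @param config A [pipeline_config()].
#' @return A report list with data frames `params`, `dormancy`, `rwtn`,
#'   `sog`, `timing`, plus `envelopes` and `fits`. When `config$outdir` is
#'   set, the data frames are also written as `params.csv`, `dormancy.csv`,
#'   `rwtn.csv`, `sog.csv`, `timing.csv`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  tcs <- resolve_counts(config$counts)
  if (length(tcs) == 0L) stopf("no time-courses in input")
  cardinals <- resolve_cardinals(config$cardinals)
  climate <- resolve_climate(config$climate)

  pops <- unique(vapply(tcs, `[[`, "", "population"))
  stage_of <- vapply(tcs, `[[`, "", "stage")
  pop_of <- vapply(tcs, `[[`, "", "population")

  params_rows <- list(); fits <- list(); sog_rows <- list()
  for (pop in pops) {
    card <- cardinals_for(cardinals, pop)
    stages_here <- intersect(stage_levels(), unique(stage_of[pop_of == pop]))
    for (st in stages_here) {
      cell <- tcs[pop_of == pop & stage_of == st]
      fit <- tryCatch(
        fit_stage(cell, card,
                  config = fit_config(n_starts = config$n_starts,
                                      seed = derive_seed(config$seed,
                                                         length(fits))),
                  exclude_temps = config$exclude_temps,
                  population = pop, stage = st),
        error = function(e) stopf("stage fit failed for %s/%s: %s",
                                  pop, st, conditionMessage(e)))
      fits[[paste(pop, st, sep = ".")]] <- fit
      row <- stage_params_row(fit$params,
                              storage_month = unname(config$stage_hours[st] / 720))
      row$rmse <- fit$rmse
      row$converged <- fit$converged
      params_rows[[length(params_rows) + 1L]] <- row
      s <- sog_stage(cell, fit$params, mode = config$sog_mode)
      sog_rows[[length(sog_rows) + 1L]] <-
        data.frame(population = pop, stage = st, sog = s$sog, n = s$n,
                   stringsAsFactors = FALSE)
    }
  }
  params <- do.call(rbind, params_rows)
  sog_df <- do.call(rbind, sog_rows)

  dormancy <- do.call(rbind, lapply(pops, function(pop) {
    sub <- params[params$population == pop, ]
    sub <- sub[order(match(sub$stage, stage_levels())), ]
    data.frame(population = pop,
               type = classify_dormancy_type(sub),
               stringsAsFactors = FALSE)
  }))

  rwtn <- fit_rwtn_table(params, hours = config$stage_hours)

  envelopes <- lapply(pops, function(pop)
    build_envelope(params[params$population == pop, ],
                   stage_hours = config$stage_hours))
  names(envelopes) <- pops

  timing <- NULL
  if (!is.null(climate)) {
    timing <- do.call(rbind, lapply(pops, function(pop) {
      tm <- predict_timing(envelopes[[pop]], climate, config$maturity_month)
      data.frame(population = pop, crossed = tm$crossed,
                 crossing_month = tm$crossing_month,
                 months_after_maturity = tm$months_after_maturity,
                 predicted_temp_c = tm$predicted_temp,
                 stage = tm$stage, stringsAsFactors = FALSE)
    }))
  }

  report <- list(params = params, dormancy = dormancy, rwtn = rwtn,
                 sog = sog_df, timing = timing, envelopes = envelopes,
                 fits = fits)

  if (!is.null(config$outdir)) {
    dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
    write_params(params, file.path(config$outdir, "params.csv"))
    write.csv(dormancy, file.path(config$outdir, "dormancy.csv"),
              row.names = FALSE)
    write.csv(rwtn, file.path(config$outdir, "rwtn.csv"), row.names = FALSE)
    write.csv(sog_df, file.path(config$outdir, "sog.csv"), row.names = FALSE)
    if (!is.null(timing))
      write.csv(timing, file.path(config$outdir, "timing.csv"),
                row.names = FALSE)
    if (config$figures) {
      for (pop in pops) {
        f <- file.path(config$outdir, sprintf("niche_%s.png", pop))
        tryCatch({
          png(f, width = 800, height = 600)
          plot_niche(envelopes[[pop]], climate)
          dev.off()
        }, error = function(e) {
          try(dev.off(), silent = TRUE)
          warning("could not render figure for ", pop, ": ",
                  conditionMessage(e))
        })
      }
    }
  }
  report
}
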