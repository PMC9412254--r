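# Shared fixtures: the transcribed parameter table, synthetic-world cardinal
# temperatures, and small helper constructors used across test files.

table1 <- read_params(thermoniche_example("table1.csv"))
table2_expected <- read.csv(thermoniche_example("table2_expected.csv"),
                            stringsAsFactors = FALSE)

# Synthetic-world cardinal temperatures (see cardinals_synthetic.csv).
synthetic_cardinals <- cardinal_temps(Tb = 1, To = 22, Tm = 30)

table1_params <- function(pop, st, cardinals = synthetic_cardinals) {
  stage_params_from_row(table1[table1$population == pop &
                               table1$stage == st, ], cardinals)
}

# A small, fully identifiable truth (window inside the tested temperature
# range) for fitting tests.
identifiable_truth <- function(population = "testpop", stage = "M") {
  stage_params(population, stage,
               window = thermal_window(8, 2, 20, 3),
               timing = thermal_time_params(15, 4, 12, 4),
               cardinals = cardinal_temps(2, 18, 32))
}

# Noiseless time-courses straight from the model expectation.
noiseless_timecourses <- function(truth, temperatures = c(5, 10, 15, 20, 25),
                                  days = 1:15) {
  lapply(temperatures, function(T) {
    germination_timecourse(
      temperature = T, days = days,
      cum_fraction = cumulative_germination(T, days, truth),
      n_seeds = 20, replicate = 1L,
      population = truth$population, stage = truth$stage)
  })
}

# Free-parameter vector of a truth, named like the fit bounds.
truth_par <- function(truth) {
  c(Tl50 = truth$window$Tl50, sigma_Tl = truth$window$sigma_Tl,
    Th50 = truth$window$Th50, sigma_Th = truth$window$sigma_Th,
    theta_sub50 = truth$timing$theta_sub50,
    sigma_sub = truth$timing$sigma_sub,
    theta_sup50 = truth$timing$theta_sup50,
    sigma_sup = truth$timing$sigma_sup)
}
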