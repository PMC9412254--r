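# Niche envelopes, overlap tests and germination-timing prediction.

test_that("build_envelope orders stages by storage hours", {
  arak <- build_envelope(table1[table1$population == "Arak", ])
  expect_identical(arak$stages, c("D", "M", "AR1", "AR2", "AR5"))
  expect_identical(arak$lower, rep(6.6, 5))
  expect_identical(arak$upper, c(19.3, 23, 26, 32, 35))
  expect_error(build_envelope(table1[table1$population == "Arak" &
                                     table1$stage == "M", ]),
               "insufficient")
  expect_error(build_envelope(table1[table1$stage == "M", ]), "mix")
})

test_that("envelope width is non-decreasing across stages for every
           transcribed population", {
  for (pop in unique(table1$population)) {
    env <- build_envelope(table1[table1$population == pop, ])
    expect_true(all(diff(env$upper - env$lower) >= 0), label = pop)
  }
})

test_that("overlaps uses a closed interval", {
  arak <- build_envelope(table1[table1$population == "Arak", ])
  expect_true(overlaps(arak, "M", 6.6))     # exactly the lower bound
  expect_true(overlaps(arak, "M", 23))      # exactly the upper bound
  expect_false(overlaps(arak, "M", 28))
  expect_false(overlaps(arak, "D", 19.31))
  expect_error(overlaps(arak, "AR9", 20), "unknown stage")
  # widening the envelope never flips true -> false
  set.seed(13)
  for (i in 1:50) {
    lo <- runif(1, 0, 10); hi <- lo + runif(1, 2, 20)
    env <- build_envelope(data.frame(population = "p",
                                     stage = c("M", "AR1"),
                                     Tl50 = c(lo, lo - 1),
                                     Th50 = c(hi, hi + 3)))
    temp <- runif(1, -5, 40)
    if (overlaps(env, "M", temp)) expect_true(overlaps(env, "AR1", temp))
  }
})

test_that("stage selection by elapsed hours is right-continuous", {
  env <- build_envelope(table1[table1$population == "Zabol", ])
  sfe <- thermoniche:::stage_for_elapsed_hours
  expect_identical(sfe(env, 0), "M")
  expect_identical(sfe(env, 719.9), "M")
  expect_identical(sfe(env, 720), "AR1")     # switches exactly at the knot
  expect_identical(sfe(env, 1440), "AR2")
  expect_identical(sfe(env, 3599), "AR2")
  expect_identical(sfe(env, 3600), "AR5")
  expect_identical(sfe(env, 1e5), "AR5")
})

test_that("predict_timing finds the first entry into the permissive band", {
  env <- build_envelope(data.frame(population = "p",
                                   stage = c("M", "AR1", "AR2", "AR5"),
                                   Tl50 = 5, Th50 = 25))
  # climate inside the band at maturity
  mild <- climate_series(rep(15, 12))
  tm <- predict_timing(env, mild, 7)
  expect_true(tm$crossed)
  expect_identical(tm$crossing_month, 7)
  expect_identical(tm$predicted_temp, 15)
  # Sep = 28, Oct = 22: the interpolated curve hits the 25-degree limit
  temps <- rep(10, 12); temps[9] <- 28; temps[10] <- 22
  tm2 <- predict_timing(env, climate_series(temps), 9)
  expect_true(tm2$crossed)
  expect_equal(tm2$predicted_temp, 25)
  expect_equal(tm2$crossing_month, 9.5)
  # no crossing inside 12 months: flagged, not an error
  hot <- climate_series(rep(40, 12))
  tm3 <- predict_timing(env, hot, 7)
  expect_false(tm3$crossed)
  expect_true(is.na(tm3$predicted_temp))
})

test_that("predict_timing is translation-consistent and monotone in
           envelope width", {
  set.seed(21)
  for (i in 1:20) {
    amp <- runif(1, 6, 14); base <- runif(1, 12, 22)
    climate <- generate_climate(amp, base, 7)
    narrow <- build_envelope(data.frame(population = "p",
                                        stage = c("M", "AR1", "AR2", "AR5"),
                                        Tl50 = 6, Th50 = c(16, 18, 21, 24)))
    wide <- build_envelope(data.frame(population = "p",
                                      stage = c("M", "AR1", "AR2", "AR5"),
                                      Tl50 = 4, Th50 = c(20, 23, 26, 29)))
    tn <- predict_timing(narrow, climate, 7)
    tw <- predict_timing(wide, climate, 7)
    if (tn$crossed) {
      expect_true(tw$crossed)
      expect_lte(tw$months_after_maturity, tn$months_after_maturity)
    }
    # translation consistency
    shift <- 3.7
    shifted_climate <- climate_series(climate$mean_temp + shift)
    shifted_env <- build_envelope(data.frame(population = "p",
      stage = c("M", "AR1", "AR2", "AR5"),
      Tl50 = 6 + shift, Th50 = c(16, 18, 21, 24) + shift))
    ts <- predict_timing(shifted_env, shifted_climate, 7)
    expect_equal(ts$months_after_maturity, tn$months_after_maturity,
                 tolerance = 1e-9)
  }
})
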