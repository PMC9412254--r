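# Core PBT model: normal integral, germinable fraction, thermal time,
# cumulative germination, dormancy typology.

test_that("std_normal_cdf matches its contract", {
  expect_identical(std_normal_cdf(0), 0.5)
  expect_lt(abs(std_normal_cdf(10) - 1), 1e-12)
  # frozen from a high-precision erf oracle: Phi(1) = (1 + erf(1/sqrt(2)))/2
  expect_equal(std_normal_cdf(1), 0.841344746068543, tolerance = 1e-6)
  z <- seq(-4, 4, length.out = 50)
  expect_true(all(diff(std_normal_cdf(z)) > 0))
  expect_error(std_normal_cdf(Inf), "finite")
  expect_error(std_normal_cdf(NA_real_), "finite")
})

test_that("germinable_fraction reproduces anchor values", {
  expect_lt(abs(germinable_fraction(20, thermal_window(10, 1, 30, 1)) - 1),
            1e-9)
  expect_lt(abs(germinable_fraction(10, thermal_window(10, 2, 60, 2)) - 0.5),
            1e-9)
  # Arak AR5 window at 33 degC: Phi(13.2) - Phi(-1)
  expect_equal(germinable_fraction(33, thermal_window(6.6, 2, 35, 2)),
               0.8413, tolerance = 1e-3)
  expect_error(germinable_fraction(20, list(Tl50 = 1)), "thermal_window")
  expect_error(thermal_window(10, 1, 5, 1), "below")
  expect_error(thermal_window(10, -1, 30, 1), "positive")
})

test_that("germinable_fraction stays in [0,1], vanishes in both tails, and is
           monotone in the window limits", {
  set.seed(42)
  for (i in 1:200) {
    Tl <- runif(1, 0, 15); Th <- Tl + runif(1, 1, 30)
    w <- thermal_window(Tl, runif(1, 0.1, 10), Th, runif(1, 0.1, 10))
    T <- runif(1, -20, 50)
    g <- germinable_fraction(T, w)
    expect_gte(g, 0); expect_lte(g, 1)
    # tails
    expect_lt(germinable_fraction(w$Tl50 - 10 * w$sigma_Tl, w), 1e-9)
    expect_lt(germinable_fraction(w$Th50 + 10 * w$sigma_Th, w), 1e-9)
    # monotone in Th50 (wider upper) and in Tl50 (lower bound moves down)
    w_up <- thermal_window(Tl, w$sigma_Tl, Th + 1, w$sigma_Th)
    w_dn <- thermal_window(Tl - 1, w$sigma_Tl, Th, w$sigma_Th)
    expect_gte(germinable_fraction(T, w_up) - g, -1e-12)
    expect_gte(germinable_fraction(T, w_dn) - g, -1e-12)
  }
})

test_that("difference-of-CDFs form equals the literal 1-minus-upper-tail form", {
  set.seed(7)
  worst <- 0
  for (i in 1:1000) {
    Tl <- runif(1, -5, 15); Th <- Tl + runif(1, 0.5, 30)
    sTl <- runif(1, 0.05, 10); sTh <- runif(1, 0.05, 10)
    T <- runif(1, -20, 50)
    w <- thermal_window(Tl, sTl, Th, sTh)
    literal <- pnorm((T - Tl) / sTl) - (1 - pnorm(-(T - Th) / sTh))
    worst <- max(worst, abs(germinable_fraction(T, w) -
                              min(1, max(0, literal))))
  }
  expect_lt(worst, 1e-12)
})

test_that("thermal-time accumulation follows the sub/supra split", {
  card <- cardinal_temps(5, 20, 35)
  at_base <- accumulate_thermal_time(5, c(0, 3, 10), card)
  expect_identical(at_base$range, "sub")
  expect_identical(at_base$thermal_time, c(0, 0, 0))
  sub <- accumulate_thermal_time(15, 3, card)
  expect_identical(sub$range, "sub")
  expect_identical(sub$thermal_time, 30)
  sup <- accumulate_thermal_time(30, 2, card)
  expect_identical(sup$range, "sup")
  expect_identical(sup$thermal_time, 10)
  # tie-break: exactly To uses the sub-optimal branch
  expect_identical(accumulate_thermal_time(20, 1, card)$range, "sub")
  expect_error(accumulate_thermal_time(15, -1, card), "non-negative")
})

test_that("cumulative_germination composes window and timing", {
  p <- table1_params("Arak", "AR5",
                     cardinals = cardinal_temps(6.6, 20, 35))
  # worked example: T = 15, t = 3, Tb = 6.6 from config
  gf <- pnorm((15 - 6.6) / 2) - pnorm((15 - 35) / 2)
  expected <- gf * pnorm(((15 - 6.6) * 3 - 15) / 4.4)
  expect_equal(cumulative_germination(15, 3, p), expected, tolerance = 1e-12)
  # no thermal time accumulated at t = 0
  expect_lt(cumulative_germination(15, 0, p), 0.01)
  # saturation at the germinable fraction
  expect_lt(abs(cumulative_germination(15, 1e6, p) -
                  germinable_fraction(15, p$window)), 1e-9)
})

test_that("cumulative_germination is non-decreasing in t and bounded by the
           germinable fraction (random draws)", {
  set.seed(11)
  for (i in 1:100) {
    Tl <- runif(1, 0, 10); Th <- Tl + runif(1, 5, 30)
    p <- stage_params("x", "M",
      thermal_window(Tl, runif(1, 0.5, 8), Th, runif(1, 0.5, 8)),
      thermal_time_params(runif(1, 2, 40), runif(1, 0.5, 10),
                          runif(1, 2, 40), runif(1, 0.5, 10)),
      cardinal_temps(0, 20, 36))
    T <- runif(1, 2, 34)
    t <- sort(runif(10, 0, 40))
    f <- cumulative_germination(T, t, p)
    expect_true(all(diff(f) >= -1e-12))
    expect_true(all(f <= germinable_fraction(T, p$window) + 1e-12))
  }
})

test_that("dormancy typology distinguishes the three release patterns", {
  arak <- table1[table1$population == "Arak", ]
  expect_identical(classify_dormancy_type(arak), "Type1")
  same <- data.frame(Tl50 = c(5, 5, 5), Th50 = c(25, 25, 25))
  expect_identical(classify_dormancy_type(same), "none")
  type2 <- data.frame(Tl50 = c(12, 9, 6), Th50 = c(30, 30, 30))
  expect_identical(classify_dormancy_type(type2), "Type2")
  type3 <- data.frame(Tl50 = c(12, 6), Th50 = c(25, 32))
  expect_identical(classify_dormancy_type(type3), "Type3")
  expect_error(classify_dormancy_type(data.frame(Tl50 = 5, Th50 = 20)),
               "insufficient")
  # list-of-stage_params interface refuses mixed populations
  a <- table1_params("Arak", "M"); z <- table1_params("Zabol", "M")
  expect_error(classify_dormancy_type(list(a, z)), "mix")
})
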