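times_fine <- c(0, 0.25, 0.5, 1, 2, 3, 5, 7, 7.5, 8, 10, 14, 21)

test_that("kinetic heterogeneity solution matches its analytic form", {
  pu <- glucose_pulse(0.2, 7)
  p <- 0.1; ds <- 0.3; b <- 0.65
  t_lab <- c(0, 1, 3, 7)
  expect_equal(predict_kinetic_het(t_lab, pu, p, ds, b),
               (p * b * 0.2 / ds) * (1 - exp(-ds * t_lab)))
  # zero proliferation means no labeling
  expect_equal(predict_kinetic_het(times_fine, pu, 0, 0.3, b),
               rep(0, length(times_fine)))
  # fixed point: d* = p, b*u = 1 saturates at 1
  expect_equal(predict_kinetic_het(500, glucose_pulse(1, 1000), 0.2, 0.2, 1),
               1, tolerance = 1e-9)
  expect_error(predict_kinetic_het(c(2, 1), pu, p, ds), "sorted")
})

test_that("multi-exponential model reduces, sums and validates", {
  pu <- glucose_pulse(0.2, 7)
  # N = 1 equals kinetic het with d* = p at machine precision
  expect_identical(predict_multi_exp(times_fine, pu, 1, 0.07, 0.65),
                   predict_kinetic_het(times_fine, pu, 0.07, 0.07, 0.65))
  # two components, square pulse: analytic sum of saturating exponentials
  t_lab <- c(0.5, 2, 5)
  got <- predict_multi_exp(t_lab, pu, c(0.3, 0.7), c(1, 0.02), 0.5)
  want <- 0.3 * 0.5 * 0.2 * (1 - exp(-1 * t_lab)) +
          0.7 * 0.5 * 0.2 * (1 - exp(-0.02 * t_lab))
  expect_equal(got, want)
  expect_equal(predict_multi_exp(times_fine, pu, c(0.4, 0.6), c(0, 0)),
               rep(0, length(times_fine)))
  expect_error(predict_multi_exp(1, pu, c(0.5, 0.4), c(1, 0.1)), "sum to 1")
})

test_that("growing-culture model plateaus at b*U and matches the raw pools", {
  pu <- glucose_pulse(0.2, 200)
  expect_equal(predict_growing_culture(150, pu, p = 0.5, b = 0.65),
               0.65 * 0.2, tolerance = 1e-9)
  expect_equal(predict_growing_culture(times_fine, glucose_pulse(0, 7), 0.5, 0.65),
               rep(0, length(times_fine)))
  pu7 <- glucose_pulse(0.2, 7)
  expect_equal(predict_growing_culture(times_fine, pu7, 0.52, 0.65),
               oracle_integrate("growing_culture", list(p = 0.52, b = 0.65),
                                pu7, times_fine),
               tolerance = 1e-8)
  expect_error(predict_growing_culture(1, pu7, p = 0), "p > 0")
})

test_that("bone-marrow model: lag, plateau and fast-equilibration limit", {
  pu <- glucose_pulse(1, 7)
  # no labeled cells reach blood before the maturation delay
  expect_equal(predict_bone_marrow(c(0, 1, 2.9), pu, 0.1, 0.5,
                                   delta_lag = 3, psi = 1.2), rep(0, 3))
  # marrow plateau psi passes into blood under long labeling
  expect_equal(predict_bone_marrow(400, glucose_pulse(1, 1000), 0.3, 0.5,
                                   2, psi = 1.2), 1.2, tolerance = 1e-8)
  # d >> p with no lag collapses blood onto the marrow curve
  p <- 0.05
  fm <- psi_fm <- function(t) 1.3 * (1 - exp(-p * t))
  fb <- predict_bone_marrow(c(2, 5, 7), pu, p, d = 1000 * p, 0, 1.3)
  expect_equal(fb, fm(c(2, 5, 7)), tolerance = 1e-2)
})

test_that("delayed-observation model is a lagged, damped kinetic-het pool", {
  # delta = 0, psi = 1 reduces to kinetic het with unit square pulse
  t <- c(0, 1, 3, 7, 9, 14)
  expect_equal(predict_delayed_obs(t, 7, 0.05, 0.3, 0, 1),
               predict_kinetic_het(t, glucose_pulse(1, 7), 0.05, 0.3, 1))
  # marrow plateau psi p / d*
  expect_equal(predict_delayed_obs(4000, 5000, 0.04, 0.2, 0, 1.5),
               1.5 * 0.04 / 0.2, tolerance = 1e-9)
  # blood is the marrow curve shifted right and damped by exp(-d* delta)
  lag <- 2.5; ds <- 0.3
  fb <- predict_delayed_obs(t + lag, 7, 0.05, ds, lag, 1.2)
  fm <- predict_delayed_obs(t, 7, 0.05, ds, 0, 1.2)
  expect_equal(fb, fm * exp(-ds * lag))
})

test_that("water-forced granulocyte model has the right plateau and nulls", {
  crv0 <- water_curve(0, 0.3, 0, 63)
  expect_equal(predict_granulocyte_water(c(0, 10, 70), crv0, 0.1, 0.3, 5, 4),
               rep(0, 3))
  # constant availability f: marrow (and blood) plateau at b_w * f
  flat <- water_curve(0.015, 0.5, 0.015, 5000)
  expect_equal(predict_granulocyte_water(3000, flat, 0.1, 0.3, 5, 4),
               4 * 0.015, tolerance = 1e-8)
  # coincident marrow and body-water rates stay finite (nudged limit)
  crv <- water_curve(0.015, 0.1, 0.002, 63)
  v <- predict_granulocyte_water(c(10, 63, 100), crv, 0.1, 0.25, 5, 4)
  expect_true(all(is.finite(v) & v >= 0))
})

test_that("predictions are non-negative and monotone during labeling", {
  t_lab <- seq(0, 7, by = 0.5)
  pu <- glucose_pulse(0.3, 7)
  curves <- list(
    predict_kinetic_het(t_lab, pu, 0.2, 0.4, 0.65),
    predict_multi_exp(t_lab, pu, c(0.2, 0.8), c(1, 0.05), 0.65),
    predict_growing_culture(t_lab, pu, 0.5, 0.65),
    predict_bone_marrow(t_lab, glucose_pulse(1, 7), 0.2, 0.5, 1, 1.2),
    predict_delayed_obs(t_lab, 7, 0.2, 0.4, 1, 1.2),
    predict_granulocyte_water(t_lab, water_curve(0.05, 0.3, 0, 7),
                              0.2, 0.5, 1, 3.5))
  for (f in curves) {
    expect_true(all(f >= 0))
    expect_true(all(diff(f) >= -1e-12))
  }
})

test_that("numeric-schedule fallback agrees with the closed form", {
  # an empirical interpolant tracing the square pulse reproduces the pulse
  emp <- empirical_schedule(c(0, 6.999, 7.001, 21), c(0.2, 0.2, 0, 0), tau = 7)
  pu <- glucose_pulse(0.2, 7)
  t <- c(0, 1, 3, 6.5)
  expect_equal(predict_kinetic_het(t, emp, 0.1, 0.3, 0.65),
               predict_kinetic_het(t, pu, 0.1, 0.3, 0.65), tolerance = 1e-5)
})
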