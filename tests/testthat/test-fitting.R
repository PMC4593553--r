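unit_pulse <- glucose_pulse(1, 7)

test_that("AICc follows the small-sample Gaussian least-squares form", {
  expect_equal(aicc(1, 10, 2), 10 * log(0.1) + 4 + 12 / 7)
  # doubling the RSS at fixed n, k raises AICc by n log 2
  expect_equal(aicc(2, 10, 2) - aicc(1, 10, 2), 10 * log(2))
  expect_equal(aicc(0.5, 8, 0), 8 * log(0.5 / 8))
  expect_true(is.na(aicc(0, 10, 2)))      # zero RSS: undefined marker
  expect_true(is.na(aicc(1, 3, 2)))       # n <= k + 1: undefined marker
})

test_that("multi-start least squares recovers noiseless kinetic-het data", {
  s <- kh_series(0.05, 0.08, unit_pulse, population = "PBMC")
  fit <- fit_kinetics(kinetic_het_model(), s, unit_pulse,
                      fit_config(n_starts = 25, seed = 1))
  expect_true(fit$converged)
  expect_lt(abs(coef(fit)[["p"]] / 0.05 - 1), 1e-6)
  expect_lt(abs(coef(fit)[["d_star"]] / 0.08 - 1), 1e-6)
  # deterministic given the seed
  fit2 <- fit_kinetics(kinetic_het_model(), s, unit_pulse,
                       fit_config(n_starts = 25, seed = 1))
  expect_identical(coef(fit), coef(fit2))
  # a different seed reaches the same optimum
  fit3 <- fit_kinetics(kinetic_het_model(), s, unit_pulse,
                       fit_config(n_starts = 25, seed = 99))
  expect_equal(coef(fit), coef(fit3), tolerance = 1e-6)
})

test_that("degenerate designs return a fit with undefined AICc", {
  s <- enrichment_series(3, 0.02, population = "PBMC")
  fit <- fit_kinetics(kinetic_het_model(), s, unit_pulse,
                      fit_config(n_starts = 5, seed = 1))
  expect_s3_class(fit, "kinfit")
  expect_true(is.na(fit$aicc))
})

test_that("proliferation estimates are nearly unbiased at realistic noise", {
  mu <- predict_kinetic_het(mouse_days, unit_pulse, 0.05, 0.05)
  est <- replicate(200, {
    y <- pmin(pmax(mu + rnorm(length(mu), 0, 0.002), 0), 1)
    f <- fit_kinetics(kinetic_het_model(), enrichment_series(mouse_days, y),
                      unit_pulse, fit_config(n_starts = 3, seed = 1))
    coef(f)[["p"]]
  })
  expect_lt(abs(mean(est) / 0.05 - 1), 0.05)
})

test_that("pooled fits share population parameters and split individual ones", {
  pu <- glucose_pulse(1, 7)
  t <- c(1, 2, 3, 4, 5, 7, 10, 14, 21, 28)
  psi <- c(s1 = 0.9, s2 = 1.2, s3 = 1.5)
  subs <- lapply(psi, function(ps)
    enrichment_series(t, predict_bone_marrow(t, pu, 0.05, 0.4, 5, ps),
                      population = "monocytes"))
  fit <- fit_pooled(bone_marrow_model(), subs, pu,
                    population = c("p", "d", "delta_lag"),
                    individual = "psi",
                    config = fit_config(n_starts = 40, seed = 1))
  expect_equal(fit$k_params, 6L)  # 3 shared + 3 per-subject
  expect_equal(unname(coef(fit)[c("p", "d", "delta_lag")]),
               c(0.05, 0.4, 5), tolerance = 1e-5)
  expect_equal(unname(coef(fit)[paste0("psi.", names(psi))]), unname(psi),
               tolerance = 1e-5)
  # a single subject reduces to the plain fit
  single <- fit_pooled(bone_marrow_model(), subs[1], pu,
                       population = c("p", "d", "delta_lag"),
                       individual = "psi",
                       config = fit_config(n_starts = 40, seed = 1))
  plain <- fit_kinetics(bone_marrow_model(), subs[[1]], pu,
                        fit_config(n_starts = 40, seed = 1))
  expect_equal(unname(coef(single)[c("p", "d", "delta_lag")]),
               unname(coef(plain)[c("p", "d", "delta_lag")]),
               tolerance = 1e-4)
  expect_error(fit_pooled(bone_marrow_model(), subs, pu,
                          population = c("p", "d", "delta_lag", "psi"),
                          individual = "psi"), "both")
})

test_that("AICc order selection finds the generating number of components", {
  pu <- glucose_pulse(1, 2)
  t <- c(0.25, 0.5, 1, 1.5, 2, 2.5, 3, 4, 6, 8, 10, 14, 21, 28)
  # noiseless single-component data: the perfect N = 1 fit dominates
  s1 <- enrichment_series(t, predict_multi_exp(t, pu, 1, 0.05))
  sel1 <- select_multiexp_order(s1, pu, 2, fit_config(n_starts = 30, seed = 2))
  expect_equal(sel1$N, 1L)

  y2 <- predict_multi_exp(t, pu, c(0.1, 0.9), c(1, 0.01))
  sel2 <- select_multiexp_order(enrichment_series(t, y2), pu, 3,
                                fit_config(n_starts = 40, seed = 2))
  expect_equal(sel2$N, 2L)
  expect_equal(unname(sel2$report[c("p1", "p2")]), c(1, 0.01),
               tolerance = 1e-4)
  expect_equal(unname(sel2$report[["alpha1"]]), 0.1, tolerance = 1e-4)
  expect_false(is.na(sel2$aicc))

  # on noisy data the selected order always has a defined AICc
  set.seed(41)
  yn <- pmax(y2 + rnorm(length(t), 0, 0.002), 0)
  seln <- select_multiexp_order(enrichment_series(t, yn), pu, 3,
                                fit_config(n_starts = 25, seed = 2))
  expect_false(is.na(seln$aicc))
})

test_that("without saturation the aggregate turnover matches the kinetic-het p", {
  # short labeling, mild rates: no subpopulation approaches its plateau
  pu <- glucose_pulse(1, 1)
  t <- c(0.25, 0.5, 1, 1.5, 2, 3, 4, 5, 7)
  y <- predict_multi_exp(t, pu, c(0.3, 0.7), c(0.1, 0.02))
  me <- fit_kinetics(multi_exp_model(2), enrichment_series(t, y), pu,
                     fit_config(n_starts = 40, seed = 2))
  kh <- fit_kinetics(kinetic_het_model(), enrichment_series(t, y), pu,
                     fit_config(n_starts = 30, seed = 3))
  expect_equal(unname(me$report[["p_avg"]]), coef(kh)[["p"]],
               tolerance = 0.02)
})

test_that("Akaike weights average parameters across models", {
  mk <- function(est, aicc_val, sdv = 0) {
    structure(list(estimates = c(p = est), aicc = aicc_val,
                   sd = c(p = sdv)), class = "kinfit")
  }
  eq <- akaike_weighted(list(mk(1, -10), mk(3, -10)), "p")
  expect_equal(unname(eq[["mean"]]), 2)
  expect_equal(sum(eq[c("w1", "w2")]), 1)

  dom <- akaike_weighted(list(mk(1, -60), mk(3, -10)), "p")
  expect_lt(abs(dom[["mean"]] - 1), 1e-9)

  two <- akaike_weighted(list(mk(100, 5), mk(200, 5)), "p")
  expect_equal(unname(two[["mean"]]), 150)
  expect_equal(unname(two[["sd"]]), 50)

  expect_error(akaike_weighted(list(mk(1, NA), mk(2, 0)), "p"), "undefined")
})

test_that("bootstrap intervals are degenerate without noise and contain the estimate", {
  s <- kh_series(0.05, 0.05, unit_pulse)
  fit <- fit_kinetics(kinetic_het_model(), s, unit_pulse,
                      fit_config(n_starts = 5, seed = 1))
  ci0 <- bootstrap_ci(fit, n_boot = 30)
  expect_lt(ci0["p", "hi"] - ci0["p", "lo"], 1e-8)

  set.seed(21)
  y <- pmax(predict_kinetic_het(mouse_days, unit_pulse, 0.05, 0.05) +
              rnorm(length(mouse_days), 0, 0.002), 0)
  fn <- fit_kinetics(kinetic_het_model(), enrichment_series(mouse_days, y),
                     unit_pulse, fit_config(n_starts = 5, seed = 1))
  ci <- bootstrap_ci(fn, n_boot = 99)
  expect_lte(ci["p", "lo"], coef(fn)[["p"]])
  expect_gte(ci["p", "hi"], coef(fn)[["p"]])
})

test_that("bootstrap interval coverage is close to nominal", {
  mu <- predict_kinetic_het(mouse_days, unit_pulse, 0.05, 0.05)
  set.seed(31)
  seeds <- sample.int(1e6, 200)
  covered <- vapply(seeds, function(sd_i) {
    set.seed(sd_i)
    y <- pmin(pmax(mu + rnorm(length(mu), 0, 0.002), 0), 1)
    f <- fit_kinetics(kinetic_het_model(), enrichment_series(mouse_days, y),
                      unit_pulse, fit_config(n_starts = 6, seed = 1))
    ci <- bootstrap_ci(f, n_boot = 99, seed = sd_i + 1)
    ci["p", "lo"] <= 0.05 && 0.05 <= ci["p", "hi"]
  }, logical(1))
  expect_gte(mean(covered), 0.90)
  expect_lte(mean(covered), 0.99)
})

test_that("rank tests match exact enumeration and are symmetric", {
  a <- c(1, 2, 3); b <- c(4, 5, 6)
  expect_equal(mann_whitney(a, b), 0.1)
  expect_equal(mann_whitney(a, b), mw_enumerate(a, b))
  # enumeration oracle also agrees on an interleaved configuration
  a2 <- c(1.2, 3.4, 5.1, 7.3); b2 <- c(2.2, 4.9, 6.8)
  expect_equal(mann_whitney(a2, b2), mw_enumerate(a2, b2))
  expect_equal(mann_whitney(a2, b2), mann_whitney(b2, a2))
  expect_equal(mann_whitney(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_error(mann_whitney(numeric(0), 1), "at least one")
  # paired signed-rank analogue
  x <- c(1.1, 2.4, 3.1, 4.9, 5.5, 6.2)
  y <- x + c(0.4, 0.6, 0.5, 0.7, 0.3, 0.55)
  expect_equal(mann_whitney(x, y, paired = TRUE),
               stats::wilcox.test(x, y, paired = TRUE, exact = TRUE)$p.value)
  expect_error(mann_whitney(x, y[-1], paired = TRUE), "equal")
})
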