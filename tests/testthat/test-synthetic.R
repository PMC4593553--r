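test_that("generators are pure functions of their arguments and seed", {
  expect_identical(gen_invitro(seed = 5)$series, gen_invitro(seed = 5)$series)
  expect_false(identical(gen_invitro(seed = 5)$series,
                         gen_invitro(seed = 6)$series))
  expect_identical(gen_mouse("glucose", seed = 2)$series,
                   gen_mouse("glucose", seed = 2)$series)
  expect_identical(gen_human_monocyte("1d", seed = 3)$series,
                   gen_human_monocyte("1d", seed = 3)$series)
  expect_identical(gen_human_granulocyte(seed = 4)$series,
                   gen_human_granulocyte(seed = 4)$series)
})

test_that("noiseless output lies exactly on the generating model curve", {
  st <- gen_invitro(p = 0.5, noise_sd = 0)
  sg <- st$series[st$series$population == "jurkat_glucose", ]
  expect_equal(sg$enrichment,
               predict_growing_culture(sg$time_days, glucose_pulse(0.2, 7),
                                       0.5, 0.65))
  # glucose-arm plateau approaches b_g * media enrichment
  expect_equal(max(sg$enrichment), 0.65 * 0.20 * (1 - exp(-0.5 * 7)),
               tolerance = 1e-6)
})

test_that("noise is truncated to [0, 1] and truncation is reported", {
  st <- gen_invitro(noise_sd = 0.3, seed = 9)
  expect_true(all(st$series$enrichment >= 0 & st$series$enrichment <= 1))
  expect_gt(st$truncated, 0)
  expect_equal(gen_invitro(noise_sd = 0, seed = 9)$truncated, 0L)
})

test_that("matched estimators round-trip every design's noiseless truth", {
  # in vitro, both labels
  iv <- gen_invitro(p = 0.5, b_w = 3.46, noise_sd = 0)
  gl <- iv$series[iv$series$population == "jurkat_glucose", ]
  f_gl <- fit_kinetics(growing_culture_model("glucose"), gl,
                       glucose_pulse(0.2, 7), fit_config(seed = 1))
  expect_lt(abs(coef(f_gl)[["p"]] / 0.5 - 1), 1e-6)
  wa <- iv$series[iv$series$population == "jurkat_water", ]
  f_wa <- fit_kinetics(growing_culture_model("water"), wa,
                       glucose_pulse(0.02, 7), fit_config(seed = 1))
  expect_lt(abs(coef(f_wa)[["p"]] / 0.5 - 1), 1e-6)
  expect_lt(abs(coef(f_wa)[["b"]] / 3.46 - 1), 1e-6)

  # mouse, both arms, through the plateau-normalization route
  for (arm in c("glucose", "water")) {
    st <- gen_mouse(arm, p_pbmc = 0.05, noise_sd = 0)
    sched <- if (arm == "glucose") glucose_pulse(1, 7)
             else water_curve(1, st$truth$delta, st$truth$beta / st$truth$f, 7)
    thy <- st$series[st$series$population == "thymocytes", ]
    pl <- estimate_reference_plateau(thy, sched)
    expect_lt(abs(pl$plateau / st$truth$label_ceiling - 1), 1e-6)
    pb <- st$series[st$series$population == "PBMC", ]
    nb <- suppressWarnings(normalize_to_plateau(pb, pl$plateau))
    f <- fit_kinetics(kinetic_het_model(), nb, sched, fit_config(seed = 1))
    expect_lt(abs(coef(f)[["p"]] / 0.05 - 1), 1e-6)
  }

  # human monocytes: pooled fit recovers a common psi exactly
  mono <- gen_human_monocyte("7d", psi_true = 1, psi_cv = 0, noise_sd = 0)
  subs <- lapply(split(as.data.frame(mono$series), mono$series$subject_id),
                 identity)
  pf <- fit_pooled(bone_marrow_model(), subs, glucose_pulse(1, 7),
                   population = c("p", "d", "delta_lag"), individual = "psi",
                   config = fit_config(n_starts = 40, seed = 1))
  for (nm in grep("^psi", names(coef(pf)), value = TRUE))
    expect_lt(abs(coef(pf)[[nm]] - 1), 1e-5)

  # human granulocytes: full four-parameter water model
  gr <- gen_human_granulocyte(b_w_true = 4, noise_sd = 0)
  f_gr <- fit_kinetics(granulocyte_water_model(),
                       gr$series, water_curve(0.015, 0.08, 0.002, 63),
                       fit_config(n_starts = 60, seed = 1))
  expect_lt(abs(coef(f_gr)[["b_w"]] / 4 - 1), 1e-6)
  expect_lt(abs(coef(f_gr)[["p"]] / 0.1 - 1), 1e-5)
})

test_that("mis-normalized one-day monocyte data yield plateaus above 100%", {
  st <- gen_human_monocyte("1d", psi_true = 1.8, psi_cv = 0.1,
                           noise_sd = 0.002, seed = 12)
  subs <- lapply(split(as.data.frame(st$series), st$series$subject_id),
                 identity)
  pf <- fit_pooled(bone_marrow_model(), subs, glucose_pulse(1, 1),
                   population = c("p", "d", "delta_lag"), individual = "psi",
                   config = fit_config(n_starts = 40, seed = 1))
  psis <- coef(pf)[grep("^psi", names(coef(pf)))]
  expect_true(all(psis > 1))
})

test_that("diurnal plasma glucose has its minimum at mid-scotophase", {
  st <- gen_mouse("glucose", plasma_times = seq(0, 7, by = 1 / 24),
                  noise_sd = 0, seed = 8)
  plasma <- st$series[st$series$compartment == "plasma", ]
  prof <- diurnal_profile(plasma)
  prof <- prof[!prof$duplicate, ]
  expect_equal(prof$hour[which.min(prof$median)], 18)
  # zero amplitude collapses to a noisy square pulse
  flat <- gen_mouse("glucose", diurnal_amplitude = 0, noise_sd = 0,
                    plasma_times = seq(0, 6.9, by = 0.25), seed = 8)
  pf <- flat$series[flat$series$compartment == "plasma", ]
  expect_equal(pf$enrichment, rep(flat$truth$u_bar, nrow(pf)))
})

test_that("thymocyte series plateau matches the configured ceiling", {
  st <- gen_mouse("glucose", noise_sd = 0.002, seed = 13)
  thy <- st$series[st$series$population == "thymocytes", ]
  late <- thy$enrichment[thy$time_days == 7]
  # within 3 standard errors of the noise on the per-day mean
  expect_lt(abs(mean(late) - st$truth$label_ceiling),
            3 * st$truth$noise_sd / sqrt(length(late)))
})

test_that("only the product b_w * U is identified from trajectories", {
  crv <- water_curve(0.015, 0.08, 0.002, 63)
  crv2 <- water_curve(0.015 * 2, 0.08, 0.002 * 2, 63)   # U scaled by 2
  t <- seq(7, 126, by = 7)
  expect_equal(predict_granulocyte_water(t, crv, 0.1, 0.25, 5, 4),
               predict_granulocyte_water(t, crv2, 0.1, 0.25, 5, 2),
               tolerance = 1e-12)
})

test_that("noise level widens the bootstrap interval of b_w", {
  widths <- vapply(c(5e-4, 5e-3), function(sdv) {
    st <- gen_human_granulocyte(b_w_true = 4, noise_sd = sdv, seed = 17)
    f <- fit_kinetics(granulocyte_water_model(), st$series,
                      water_curve(0.015, 0.08, 0.002, 63),
                      fit_config(n_starts = 40, seed = 1))
    ci <- bootstrap_ci(f, n_boot = 60)
    ci["b_w", "hi"] - ci["b_w", "lo"]
  }, numeric(1))
  expect_lt(widths[1], widths[2])
})
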