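# Seeded synthetic-study generators. Each generator is a pure function of
# its arguments (including the seed) and stores the generating truth next to
# the data, so every estimator can be exercised as a round trip. The noise
# model is additive Gaussian on the fraction scale truncated to [0, 1];
# truncation events are counted and reported.

.add_noise <- function(x, sd) {
  if (sd == 0) return(list(y = x, truncated = 0L))
  y <- x + rnorm(length(x), 0, sd)
  trunc_n <- sum(y < 0 | y > 1)
  list(y = pmin(pmax(y, 0), 1), truncated = trunc_n)
}

.study <- function(design, truth, series, seed, truncated) {
  structure(list(design = design, truth = truth, series = series,
                 seed = seed, truncated = truncated),
            class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat("<synthetic_study>", x$design, " seed =", x$seed, "\n")
  cat("  series:", nrow(x$series), "records,",
      length(unique(x$series$subject_id)), "subject(s)\n")
  cat("  truth:", paste(names(x$truth),
                        vapply(x$truth, function(v)
                          paste(signif(unlist(v), 4), collapse = "/"),
                          character(1)),
                        sep = " = ", collapse = ", "), "\n")
  if (x$truncated > 0)
    cat("  noise truncation events:", x$truncated, "\n")
  invisible(x)
}

# Sampling days of the in vitro cultures: 0 and 8 h, then days 1, 2, 4, 5,
# 7, 8, 9, 11, 12, 14 (7-day label + 7-day washout).
.invitro_times <- c(0, 8 / 24, 1, 2, 4, 5, 7, 8, 9, 11, 12, 14)

#' Synthetic dual-label in vitro culture study
#'
#' Emulates seven-day dual (deuterated glucose + deuterated water) labeling
#' of an exponentially growing T-cell culture with a seven-day washout,
#' sampled at 0 and 8 h and days 1, 2, 4, 5, 7, 8, 9, 11, 12 and 14.
#' Trajectories come from the growing-culture model with constant media
#' forcing (glucose 20%, water 2%).
#'
#' @param p Culture proliferation rate, per day.
#' @param b_g Glucose intracellular dilution factor.
#' @param b_w Water scaling factor.
#' @param media_glucose,media_water Media label enrichments (fractions).
#' @param noise_sd Additive Gaussian noise sd on the fraction scale.
#' @param seed Integer seed.
#' @param tau Labeling duration in days.
#' @param times Sampling times in days.
#' @return A `"synthetic_study"`; populations `"jurkat_glucose"` and
#'   `"jurkat_water"`.
#' @export
gen_invitro <- function(p = 0.5, b_g = 0.65, b_w = 3.46,
                        media_glucose = 0.20, media_water = 0.02,
                        noise_sd = 0.002, seed = 1, tau = 7,
                        times = .invitro_times) {
  stopifnot(noise_sd >= 0)
  sched_g <- glucose_pulse(media_glucose, tau)
  sched_w <- glucose_pulse(media_water, tau)
  mu_g <- predict_growing_culture(times, sched_g, p, b_g)
  mu_w <- predict_growing_culture(times, sched_w, p, b_w)
  .with_seed(seed, {
    ng <- .add_noise(mu_g, noise_sd)
    nw <- .add_noise(mu_w, noise_sd)
  })
  series <- rbind(
    enrichment_series(times, ng$y, "culture1", "dna", "jurkat_glucose"),
    enrichment_series(times, nw$y, "culture1", "dna", "jurkat_water"))
  .study("invitro_dual",
         list(p = p, b_g = b_g, b_w = b_w, media_glucose = media_glucose,
              media_water = media_water, tau = tau, noise_sd = noise_sd),
         .as_series(series), seed, ng$truncated + nw$truncated)
}

# Sacrifice days of the murine cross-sectional design (mice killed at 8 am).
.mouse_days <- c(0, 1, 2, 3, 4, 7, 8, 10, 15, 21)

#' Synthetic cross-sectional mouse labeling study
#'
#' Emulates seven-day oral labeling of mice with sacrifice at 8 am on days
#' 0, 1, 2, 3, 4, 7, 8, 10, 15 and 21; each synthetic mouse contributes one
#' time point (no repeated measures). The water arm's plasma follows the
#' body-water curve; the glucose arm's plasma follows a square pulse
#' modulated by a 24 h sinusoid with its minimum at mid-scotophase. DNA
#' series (near-saturating thymocytes, PBMC, splenocytes) come from the
#' kinetic heterogeneity model, driven by the arm's mean availability, with
#' maximal attainable raw enrichment `label_ceiling`.
#'
#' In the glucose arm the default plasma level (`u_bar` about 3.3%) is
#' deliberately below `label_ceiling / b_g` (ceiling about 4.9%): measured
#' plasma enrichment under-reports the label available to dividing cells,
#' so conventional normalization inflates proliferation estimates while
#' thymocyte-plateau normalization does not. Pass
#' `u_bar = label_ceiling / b_g` for an unbiased-plasma scenario.
#'
#' @param arm `"water"` or `"glucose"`.
#' @param p_pbmc,p_spleen Proliferation rates, per day.
#' @param d_star_factor Ratio `d_star / p` for PBMC and splenocytes.
#' @param p_thymus Thymocyte turnover rate, per day (near-saturating).
#' @param label_ceiling Maximal attainable raw DNA enrichment (the true
#'   thymocyte plateau). Defaults: 0.049 (glucose), 0.28 (water).
#' @param f,delta,beta Body-water curve parameters (water arm).
#' @param u_bar Mean plasma glucose enrichment (glucose arm).
#' @param diurnal_amplitude,diurnal_min_hour Diurnal modulation of plasma
#'   glucose; the minimum sits at mid-scotophase (hour 18 after an 8 am
#'   start under a standard 8 am-8 pm light phase).
#' @param tau Labeling duration, days.
#' @param n_per_day Mice sacrificed per time point.
#' @param days Sacrifice days.
#' @param plasma_times Optional plasma sampling times (days, fractional for
#'   within-day sampling); defaults to the sacrifice times.
#' @param noise_sd Additive Gaussian noise sd.
#' @param seed Integer seed.
#' @return A `"synthetic_study"` with plasma and DNA series (populations
#'   `"thymocytes"`, `"PBMC"`, `"splenocytes"`).
#' @export
gen_mouse <- function(arm = c("water", "glucose"), p_pbmc = 0.05,
                      p_spleen = 0.06, d_star_factor = 1, p_thymus = 1.5,
                      label_ceiling = NULL, f = 0.08, delta = 0.3,
                      beta = 0.02, u_bar = 0.033, diurnal_amplitude = 0.3,
                      diurnal_min_hour = 18, tau = 7, n_per_day = 3,
                      days = .mouse_days, plasma_times = NULL,
                      noise_sd = 0.002, seed = 1) {
  arm <- match.arg(arm)
  if (is.null(label_ceiling))
    label_ceiling <- if (arm == "glucose") 0.049 else 0.28
  curve <- water_curve(f, delta, beta, tau)
  plasma_sched <- if (arm == "water") curve else
    diurnal_pulse(u_bar, tau, diurnal_amplitude, diurnal_min_hour)
  # DNA responds to the arm's true mean availability; raw enrichment is the
  # unit-forcing kinetic-het solution scaled by the attainable ceiling.
  dna_sched <- if (arm == "water")
    water_curve(1, delta, beta / f, tau)   # unit-asymptote relative curve
  else glucose_pulse(1, tau)
  dna_mu <- function(t, p, d_star)
    predict_kinetic_het(t, dna_sched, p, d_star, b = label_ceiling)
  t_dna <- rep(days, each = n_per_day)
  mouse_id <- paste0("m", sprintf("%02d", seq_along(t_dna)))
  if (is.null(plasma_times)) plasma_times <- days
  mu_plasma <- schedule_value(plasma_sched, plasma_times)
  mu_thy <- dna_mu(t_dna, p_thymus, p_thymus)
  mu_pbmc <- dna_mu(t_dna, p_pbmc, p_pbmc * d_star_factor)
  mu_spl <- dna_mu(t_dna, p_spleen, p_spleen * d_star_factor)
  .with_seed(seed, {
    npl <- .add_noise(mu_plasma, noise_sd)
    nthy <- .add_noise(mu_thy, noise_sd)
    npb <- .add_noise(mu_pbmc, noise_sd)
    nsp <- .add_noise(mu_spl, noise_sd)
  })
  plasma_id <- paste0("pl", sprintf("%02d", seq_along(plasma_times)))
  series <- rbind(
    data.frame(subject_id = plasma_id, compartment = "plasma",
               population = "", time_days = plasma_times,
               enrichment = npl$y, stringsAsFactors = FALSE),
    data.frame(subject_id = mouse_id, compartment = "dna",
               population = "thymocytes", time_days = t_dna,
               enrichment = nthy$y, stringsAsFactors = FALSE),
    data.frame(subject_id = mouse_id, compartment = "dna",
               population = "PBMC", time_days = t_dna,
               enrichment = npb$y, stringsAsFactors = FALSE),
    data.frame(subject_id = mouse_id, compartment = "dna",
               population = "splenocytes", time_days = t_dna,
               enrichment = nsp$y, stringsAsFactors = FALSE))
  .study(paste0("mouse_", arm),
         list(arm = arm, p_pbmc = p_pbmc, p_spleen = p_spleen,
              p_thymus = p_thymus, d_star_factor = d_star_factor,
              label_ceiling = label_ceiling, f = f, delta = delta,
              beta = beta, u_bar = u_bar, tau = tau,
              diurnal_amplitude = diurnal_amplitude,
              diurnal_min_hour = diurnal_min_hour, noise_sd = noise_sd),
         .as_series(series), seed,
         npl$truncated + nthy$truncated + npb$truncated + nsp$truncated)
}

#' Synthetic human monocyte labeling study
#'
#' Emulates the one-day and seven-day deuterated-glucose monocyte designs.
#' Per-subject blood-monocyte trajectories come from the bone-marrow model
#' with a subject-specific maximal enrichment `psi` drawn lognormally
#' around `psi_true` (coefficient of variation `psi_cv`). The series are in
#' conventionally normalized units, so `psi != 1` encodes
#' mis-normalization (the plateau the fit should recover).
#'
#' @param design `"1d"` or `"7d"` (fixes `tau` and the sampling times).
#' @param psi_true Central maximal enrichment (1 = correct normalization).
#' @param p Progenitor proliferation rate, per day.
#' @param d Blood disappearance rate, per day.
#' @param delta_lag Maturation delay, days.
#' @param psi_cv Between-subject lognormal coefficient of variation of psi.
#' @param n_subjects Number of subjects (defaults: 8 for 1d, 3 for 7d).
#' @param noise_sd Additive Gaussian noise sd.
#' @param seed Integer seed.
#' @return A `"synthetic_study"`; one series per subject, population
#'   `"monocytes"`.
#' @export
gen_human_monocyte <- function(design = c("1d", "7d"), psi_true = 1,
                               p = 0.05, d = 0.4, delta_lag = 5,
                               psi_cv = 0.15, n_subjects = NULL,
                               noise_sd = 0.002, seed = 1) {
  design <- match.arg(design)
  tau <- if (design == "1d") 1 else 7
  times <- if (design == "1d") c(0.5, 1, 2, 3, 4, 5, 7, 10, 14, 21)
           else c(1, 2, 3, 4, 5, 7, 10, 14, 21, 28)
  if (is.null(n_subjects)) n_subjects <- if (design == "1d") 8L else 3L
  pulse <- glucose_pulse(1, tau)
  sdlog <- sqrt(log(1 + psi_cv^2))
  .with_seed(seed, {
    psi_i <- rlnorm(n_subjects, log(psi_true) - sdlog^2 / 2, sdlog)
    rows <- vector("list", n_subjects)
    trunc_n <- 0L
    for (i in seq_len(n_subjects)) {
      mu <- predict_bone_marrow(times, pulse, p, d, delta_lag, psi_i[i])
      nz <- .add_noise(mu, noise_sd)
      trunc_n <- trunc_n + nz$truncated
      rows[[i]] <- data.frame(subject_id = sprintf("C%02d", i),
                              compartment = "dna",
                              population = "monocytes",
                              time_days = times, enrichment = nz$y,
                              stringsAsFactors = FALSE)
    }
  })
  .study(paste0("human_glucose_", design),
         list(design = design, psi_true = psi_true, psi = psi_i, p = p,
              d = d, delta_lag = delta_lag, tau = tau, noise_sd = noise_sd),
         .as_series(do.call(rbind, rows)), seed, trunc_n)
}

#' Synthetic human granulocyte water-labeling study
#'
#' Emulates a nine-week deuterated-water study: granulocyte blood
#' enrichment follows the water-forced bone-marrow model with scaling
#' factor `b_w_true`; used for scaling-factor recovery experiments.
#'
#' @param curve Body-water [water_curve()] (default: 9-week labeling with
#'   asymptote 1.5%).
#' @param b_w_true Water scaling factor generating the data.
#' @param p Marrow precursor proliferation rate, per day.
#' @param d Blood disappearance rate, per day.
#' @param delta_lag Marrow-to-blood lag, days.
#' @param times Sampling times in days.
#' @param noise_sd Additive Gaussian noise sd.
#' @param seed Integer seed.
#' @return A `"synthetic_study"`; population `"granulocytes"`. The DNA
#'   series is raw (un-normalized model units).
#' @export
gen_human_granulocyte <- function(curve = water_curve(0.015, 0.08, 0.002, 63),
                                  b_w_true = 4, p = 0.1, d = 0.25,
                                  delta_lag = 5,
                                  times = seq(7, 126, by = 7),
                                  noise_sd = 0.002, seed = 1) {
  mu <- predict_granulocyte_water(times, curve, p, d, delta_lag, b_w_true)
  .with_seed(seed, nz <- .add_noise(mu, noise_sd))
  series <- data.frame(subject_id = "A", compartment = "dna",
                       population = "granulocytes", time_days = times,
                       enrichment = nz$y, stringsAsFactors = FALSE)
  .study("human_water_9w",
         list(curve = unclass(curve), b_w = b_w_true, p = p, d = d,
              delta_lag = delta_lag, noise_sd = noise_sd),
         .as_series(series), seed, nz$truncated)
}
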