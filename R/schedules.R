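# Precursor label-availability forcing functions U(t) and their summaries.

#' Body-water enrichment curve
#'
#' Label availability in body water during and after deuterated-water
#' administration. During labeling (`t <= tau`) the enrichment relaxes from
#' the post-boost level `beta` towards the asymptote `f` at the body-water
#' turnover rate `delta`; after labeling it decays exponentially at the same
#' rate:
#' \deqn{U(t) = f(1 - e^{-\delta t}) + \beta e^{-\delta t}, \quad t \le \tau}
#' \deqn{U(t) = U(\tau) e^{-\delta (t - \tau)}, \quad t > \tau}
#'
#' @param f Asymptotic precursor fraction in body water, in \[0, 1).
#' @param delta Body-water turnover rate, per day (> 0).
#' @param beta Enrichment attained by the end of day 0 after the boost,
#'   in \[0, 1).
#' @param tau Labeling duration in days (> 0).
#' @return An object of class `c("water_curve", "label_schedule")`.
#' @examples
#' u <- water_curve(f = 0.08, delta = 0.3, beta = 0.02, tau = 7)
#' water_enrichment(u, c(0, 1, 7, 10))
#' @export
water_curve <- function(f, delta, beta = 0, tau) {
  stopifnot(f >= 0, f < 1 || isTRUE(all.equal(f, 1)), delta > 0,
            beta >= 0, beta < 1 || isTRUE(all.equal(beta, 1)), tau > 0)
  structure(list(f = f, delta = delta, beta = beta, tau = tau),
            class = c("water_curve", "label_schedule"))
}

#' Square glucose pulse
#'
#' Constant label availability `u_bar` during the labeling period, zero
#' afterwards. This is the conventional approximation for plasma glucose
#' enrichment, which is rapidly turned over.
#'
#' @param u_bar Mean plasma enrichment fraction in \[0, 1\].
#' @param tau Labeling duration in days (> 0).
#' @return An object of class `c("glucose_pulse", "label_schedule")`.
#' @export
glucose_pulse <- function(u_bar, tau) {
  stopifnot(u_bar >= 0, u_bar <= 1, tau > 0)
  structure(list(u_bar = u_bar, tau = tau),
            class = c("glucose_pulse", "label_schedule"))
}

#' Diurnally modulated glucose pulse
#'
#' A square pulse whose height is modulated by a 24-hour sinusoid with its
#' minimum at `min_hour` (hours after the start of labeling):
#' `u(t) = u_bar * (1 - amplitude * cos(2*pi*(t - min_hour/24)))` for
#' `t <= tau`, zero afterwards. The 24-hour mean equals `u_bar`.
#'
#' @param u_bar Mean plasma enrichment fraction.
#' @param tau Labeling duration in days.
#' @param amplitude Relative modulation amplitude in \[0, 1\].
#' @param min_hour Hour of the diurnal minimum, in \[0, 24).
#' @return An object of class `c("diurnal_pulse", "label_schedule")`.
#' @export
diurnal_pulse <- function(u_bar, tau, amplitude = 0.3, min_hour = 18) {
  stopifnot(u_bar >= 0, tau > 0, amplitude >= 0, amplitude <= 1,
            min_hour >= 0, min_hour < 24)
  structure(list(u_bar = u_bar, tau = tau, amplitude = amplitude,
                 min_hour = min_hour),
            class = c("diurnal_pulse", "label_schedule"))
}

#' Empirical schedule from measured availability
#'
#' Linear interpolation through measured (time, enrichment) points, held
#' constant outside the observed range.
#'
#' @param time_days,value Observation times (days) and availabilities.
#' @param tau Labeling duration in days (metadata used by fitting helpers).
#' @return An object of class `c("empirical_schedule", "label_schedule")`.
#' @export
empirical_schedule <- function(time_days, value, tau = max(time_days)) {
  stopifnot(length(time_days) >= 1L, length(time_days) == length(value))
  ord <- order(time_days)
  structure(list(time_days = time_days[ord], value = value[ord], tau = tau),
            class = c("empirical_schedule", "label_schedule"))
}

#' Evaluate a label schedule
#'
#' @param schedule A `label_schedule` object.
#' @param t Times in days (>= 0).
#' @return Label availability fractions at `t`.
#' @export
schedule_value <- function(schedule, t) UseMethod("schedule_value")

#' @export
schedule_value.water_curve <- function(schedule, t) {
  water_enrichment(schedule, t)
}

#' @export
schedule_value.glucose_pulse <- function(schedule, t) {
  if (any(t < 0)) stop("negative time in schedule evaluation")
  ifelse(t <= schedule$tau, schedule$u_bar, 0)
}

#' @export
schedule_value.diurnal_pulse <- function(schedule, t) {
  if (any(t < 0)) stop("negative time in schedule evaluation")
  u <- schedule$u_bar *
    (1 - schedule$amplitude * cos(2 * pi * (t - schedule$min_hour / 24)))
  ifelse(t <= schedule$tau, u, 0)
}

#' @export
schedule_value.empirical_schedule <- function(schedule, t) {
  if (any(t < 0)) stop("negative time in schedule evaluation")
  stats::approx(schedule$time_days, schedule$value, xout = t, rule = 2)$y
}

#' Evaluate the body-water enrichment curve
#'
#' @param curve A [water_curve()].
#' @param t Times in days (>= 0).
#' @return Enrichment fractions at `t`.
#' @export
water_enrichment <- function(curve, t) {
  if (any(t < 0)) stop("negative time in water_enrichment")
  with(curve, {
    lab <- f * (1 - exp(-delta * t)) + beta * exp(-delta * t)
    utau <- f * (1 - exp(-delta * tau)) + beta * exp(-delta * tau)
    ifelse(t <= tau, lab, utau * exp(-delta * (t - tau)))
  })
}

# Labeling duration and asymptotic labeling-phase availability of a schedule.
.sched_tau <- function(schedule) schedule$tau
.sched_asymptote <- function(schedule) {
  switch(class(schedule)[1],
         water_curve = schedule$f,
         glucose_pulse = schedule$u_bar,
         diurnal_pulse = schedule$u_bar,
         empirical_schedule = max(schedule$value),
         stop("unknown schedule class"))
}

#' Mean availability from a measured enrichment series
#'
#' Trapezoid-rule area under the observed enrichment-time curve restricted to
#' `[0, tau]`, divided by `tau`. The first observed value is held constant
#' back to `t = 0` and the last value forward to `tau` (no extrapolation).
#' A single record returns that record's value.
#'
#' @param series An enrichment series (plasma or urine).
#' @param tau Labeling duration in days.
#' @return The mean enrichment fraction over `[0, tau]`.
#' @examples
#' s <- enrichment_series(c(0, 7), c(0, 0.14), compartment = "plasma")
#' mean_enrichment(s, tau = 7)  # 0.07
#' @export
mean_enrichment <- function(series, tau) {
  t <- series$time_days
  y <- series$enrichment
  keep <- t <= tau
  if (!any(keep))
    stop("no records with time in [0, ", tau, "]")
  t <- t[keep]; y <- y[keep]
  if (length(t) == 1L) return(y)
  if (t[1] > 0) { t <- c(0, t); y <- c(y[1], y) }
  if (t[length(t)] < tau) { t <- c(t, tau); y <- c(y, y[length(y)]) }
  auc <- sum(diff(t) * (head2(y) + tail2(y)) / 2)
  auc / tau
}

head2 <- function(x) x[-length(x)]
tail2 <- function(x) x[-1]

#' Fit a body-water enrichment curve to plasma data
#'
#' Least-squares estimation of `f`, `delta` and `beta` of the body-water
#' curve with the labeling duration `tau` fixed by the study design.
#' Non-convergence is flagged in the result, not raised as an error.
#'
#' @param series A plasma or urine enrichment series covering labeling and
#'   delabeling phases (>= 4 records recommended).
#' @param tau Labeling duration in days (fixed).
#' @param config A [fit_config()]; the defaults use 30 random starts.
#' @return A `"kinfit"` object whose `$curve` element is the fitted
#'   [water_curve()]. `coef()` returns `f`, `delta`, `beta`.
#' @export
fit_water_curve <- function(series, tau, config = fit_config(n_starts = 30)) {
  obs <- series$enrichment
  times <- series$time_days
  if (all(obs == 0)) {
    curve <- water_curve(0, 1, 0, tau)
    fit <- .kinfit_shell(estimates = c(f = 0, delta = 1, beta = 0),
                         free = c("f", "delta", "beta"),
                         rss = 0, n_obs = length(obs),
                         data = series, config = config,
                         fitted = rep(0, length(obs)),
                         residuals = obs, converged = TRUE)
    fit$curve <- curve
    fit$degenerate <- TRUE
    return(fit)
  }
  resid_fn <- function(par) {
    crv <- list(f = par[["f"]], delta = par[["delta"]], beta = par[["beta"]],
                tau = tau)
    class(crv) <- c("water_curve", "label_schedule")
    water_enrichment(crv, times) - obs
  }
  lower <- c(f = 0, delta = 1e-5, beta = 0)
  upper <- c(f = 0.999, delta = 20, beta = 0.999)
  ms <- .multistart_lsq(resid_fn, lower, upper, config)
  est <- ms$par
  if (est[["beta"]] > est[["f"]])
    warning("fitted beta exceeds f: boost enrichment above the asymptote")
  fit <- .kinfit_shell(estimates = est, free = names(est), rss = ms$rss,
                       n_obs = length(obs), data = series, config = config,
                       fitted = obs + ms$resid, residuals = -ms$resid,
                       converged = ms$converged, vcov = ms$vcov)
  fit$curve <- water_curve(est[["f"]], est[["delta"]], est[["beta"]], tau)
  fit
}

#' Diurnal profile of an enrichment series
#'
#' Maps sampling times onto the hour of a 24-hour cycle (after an optional
#' phase offset, used to translate animals housed under a reversed light
#' cycle onto a common clock) and returns the per-hour median enrichment.
#' The 0-hour bin is duplicated at 24 h for circular plotting and flagged.
#'
#' @param series An enrichment series with times in days.
#' @param phase_offset Offset in hours added before the modulo-24 mapping.
#' @return A data frame with columns `hour`, `median`, `n`, `duplicate`.
#' @export
diurnal_profile <- function(series, phase_offset = 0) {
  hour <- round((series$time_days * 24 + phase_offset) %% 24, 9)
  agg <- aggregate(series$enrichment, by = list(hour = hour),
                   FUN = function(v) c(median = median(v), n = length(v)))
  out <- data.frame(hour = agg$hour,
                    median = agg$x[, "median"],
                    n = as.integer(agg$x[, "n"]),
                    duplicate = FALSE)
  out <- out[order(out$hour), ]
  if (any(out$hour == 0)) {
    dup <- out[out$hour == 0, , drop = FALSE]
    dup$hour <- 24
    dup$duplicate <- TRUE
    out <- rbind(out, dup)
  }
  rownames(out) <- NULL
  out
}
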