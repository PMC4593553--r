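# Closed-form solutions of the labeling models. All models are expressed as
# normalized-fraction linear systems driven by a label schedule U(t); the
# reduced forms assume the (sub)populations are independently at equilibrium,
# which eliminates the absolute pool sizes and the marrow exit rate. The raw
# pool equations live in oracle_integrate() and are used for verification.

# (exp(-b t) - exp(-a t)) / (a - b), with the a -> b limit t exp(-a t).
# Written via expm1 so coincident and near-coincident rates are exact.
.difexp <- function(a, b, t) {
  d <- a - b
  scale <- max(abs(a), abs(b), 1)
  if (abs(d) < 1e-13 * scale) return(t * exp(-a * t))
  if (d > 0) -exp(-b * t) * expm1(-d * t) / d
  else        exp(-a * t) * expm1( d * t) / d
}

# (1 - exp(-a t)) / a with the a -> 0 limit t.
.exprel <- function(a, t) .difexp(a, 0, t)

.check_times <- function(times) {
  if (is.unsorted(times)) stop("times must be sorted non-decreasing")
  if (any(times < 0)) stop("times must be non-negative")
  times
}

#' Kinetic heterogeneity model
#'
#' Solves the labeled-fraction equation of the kinetic heterogeneity model,
#' \deqn{dF/dt = p\, b\, U(t) - d^{*} F, \qquad F(0) = 0,}
#' in which the average proliferation rate of the population (`p`) need not
#' equal the disappearance rate of labeled cells (`d_star`). Closed forms are
#' used for square-pulse and body-water forcing; other schedules are handled
#' by adaptive numeric integration.
#'
#' @param times Sorted times in days (duplicates allowed).
#' @param schedule A [label_schedule][glucose_pulse] forcing `U(t)`.
#' @param p Average proliferation rate of the whole population, per day.
#' @param d_star Disappearance rate of labeled cells, per day.
#' @param b Precursor scaling factor (`b_g` for glucose, `b_w` for water).
#' @return Predicted enrichment fractions at `times`.
#' @examples
#' predict_kinetic_het(0:10, glucose_pulse(0.2, 7), p = 0.1, d_star = 0.1,
#'                     b = 0.65)
#' @export
predict_kinetic_het <- function(times, schedule, p, d_star, b = 1) {
  .check_times(times)
  stopifnot(p >= 0, d_star >= 0, b > 0)
  if (inherits(schedule, "glucose_pulse")) {
    tau <- schedule$tau
    ftau <- p * b * schedule$u_bar * .exprel(d_star, tau)
    ifelse(times <= tau,
           p * b * schedule$u_bar * .exprel(d_star, times),
           ftau * exp(-d_star * (times - tau)))
  } else if (inherits(schedule, "water_curve")) {
    f <- schedule$f; delta <- schedule$delta; beta <- schedule$beta
    tau <- schedule$tau
    lab <- function(t) {
      p * b * (f * .exprel(d_star, t) + (beta - f) * .difexp(d_star, delta, t))
    }
    utau <- water_enrichment(schedule, tau)
    ftau <- lab(tau)
    ifelse(times <= tau,
           lab(times),
           ftau * exp(-d_star * (times - tau)) +
             p * b * utau * .difexp(d_star, delta, pmax(times - tau, 0)))
  } else {
    .ode_fraction(times, function(t) schedule_value(schedule, t),
                  gain = p * b, decay = d_star)
  }
}

# Numeric fallback: dF/dt = gain * u(t) - decay * F, F(0) = 0.
.ode_fraction <- function(times, u, gain, decay) {
  grid <- sort(unique(c(0, times)))
  sol <- deSolve::ode(y = c(F = 0), times = grid,
                      func = function(t, y, parms)
                        list(gain * u(t) - decay * y[1]),
                      rtol = 1e-10, atol = 1e-12, method = "lsoda",
                      maxsteps = 50000)
  vals <- stats::setNames(sol[, "F"], as.character(sol[, "time"]))
  unname(vals[as.character(times)])
}

#' Multi-exponential labeling model
#'
#' A mixture of `N` kinetically homogeneous subpopulations, each
#' independently at equilibrium with turnover rate `p[i]` and relative size
#' `alpha[i]`:
#' \deqn{F(t) = \sum_i \alpha_i F_i(t), \qquad
#'   dF_i/dt = p_i\, b\, U(t) - p_i F_i.}
#'
#' @inheritParams predict_kinetic_het
#' @param alpha Relative subpopulation sizes; must sum to 1 (tolerance 1e-9).
#' @param p Per-subpopulation proliferation rates, per day.
#' @return Predicted enrichment fractions at `times`.
#' @export
predict_multi_exp <- function(times, schedule, alpha, p, b = 1) {
  .check_times(times)
  if (length(alpha) != length(p)) stop("alpha and p must have equal length")
  if (abs(sum(alpha) - 1) > 1e-9) stop("alpha must sum to 1")
  out <- numeric(length(times))
  for (i in seq_along(alpha))
    out <- out + alpha[i] * predict_kinetic_het(times, schedule, p[i], p[i], b)
  out
}

#' Growing-culture labeling model
#'
#' Labeled fraction of cells `L = A*/(A* + R)` in an exponentially growing
#' culture with negligible death, governed by
#' `dL/dt = b U(t) p - p L` during labeling and `dL/dt = -p L` afterwards
#' (label production ceases when the labeled medium is replaced).
#'
#' @inheritParams predict_kinetic_het
#' @param p Culture proliferation rate, per day (> 0).
#' @return Predicted labeled fractions at `times`.
#' @export
predict_growing_culture <- function(times, schedule, p, b = 1) {
  if (p <= 0) stop("growing-culture model requires p > 0")
  .check_times(times)
  tau <- .sched_tau(schedule)
  lab <- predict_kinetic_het(pmin(times, tau), schedule, p, p, b)
  ftau <- predict_kinetic_het(tau, schedule, p, p, b)
  ifelse(times <= tau, lab, ftau * exp(-p * (times - tau)))
}

#' Bone-marrow (delayed precursor) model
#'
#' Progenitors proliferate in the marrow at rate `p` and reach a maximal
#' fractional enrichment `psi` (1 under correct normalization); after a fixed
#' maturation delay `delta_lag` labeled cells appear in blood, which turns
#' over at rate `d`:
#' \deqn{F_M(t) = \psi \bar u (1 - e^{-pt}) \text{ for } t \le \tau,
#'   \text{ decaying as } e^{-p(t-\tau)} \text{ after};}
#' \deqn{dF_B/dt = d\, F_M(t - \Delta) - d\, F_B, \qquad F_M(s) = 0, s < 0.}
#' The solution is piecewise analytic across the breakpoints
#' `delta_lag`, `tau + delta_lag`.
#'
#' @inheritParams predict_kinetic_het
#' @param pulse A [glucose_pulse()], conventionally normalized to height 1;
#'   a height `u_bar != 1` scales the plateau by `u_bar`.
#' @param p Progenitor proliferation rate, per day.
#' @param d Blood-compartment disappearance rate, per day (> 0).
#' @param delta_lag Maturation delay in days (>= 0).
#' @param psi Maximal enrichment (1 under correct normalization).
#' @return Blood-compartment enrichment fractions `F_B` at `times`.
#' @export
predict_bone_marrow <- function(times, pulse, p, d, delta_lag, psi) {
  .check_times(times)
  stopifnot(p >= 0, d > 0, delta_lag >= 0, psi > 0)
  tau <- pulse$tau
  amp <- psi * pulse$u_bar
  fm_tau <- amp * (1 - exp(-p * tau))
  fb <- numeric(length(times))
  s <- times - delta_lag                     # time since labeled inflow began
  ph1 <- s > 0 & s <= tau
  ph2 <- s > tau
  fb[ph1] <- d * (amp * .difexp(d, 0, s[ph1]) - amp * .difexp(d, p, s[ph1]))
  if (any(ph2)) {
    fb_tau <- d * (amp * .difexp(d, 0, tau) - amp * .difexp(d, p, tau))
    r <- s[ph2] - tau
    fb[ph2] <- fb_tau * exp(-d * r) + d * fm_tau * .difexp(d, p, r)
  }
  fb
}

#' Delayed-observation model
#'
#' A kinetic-heterogeneity pool representing marrow monocytes, observed in
#' blood after a fixed lag:
#' \deqn{dF_M/dt = \psi p - d^{*} F_M \ (t \le \tau), \quad
#'   dF_M/dt = -d^{*} F_M \ (t > \tau),}
#' \deqn{F_B(t) = F_M(t - \Delta)\, e^{-d^{*} \Delta}, \quad F_B = 0
#'   \text{ for } t < \Delta.}
#'
#' @inheritParams predict_bone_marrow
#' @param tau Labeling duration in days.
#' @param d_star Disappearance rate of labeled cells, per day.
#' @return Blood-compartment enrichment fractions `F_B` at `times`.
#' @export
predict_delayed_obs <- function(times, tau, p, d_star, delta_lag, psi) {
  .check_times(times)
  stopifnot(p >= 0, d_star >= 0, delta_lag >= 0, psi > 0, tau > 0)
  fm <- function(t) {
    ftau <- psi * p * .exprel(d_star, tau)
    ifelse(t <= tau, psi * p * .exprel(d_star, t),
           ftau * exp(-d_star * (t - tau)))
  }
  s <- times - delta_lag
  ifelse(s < 0, 0, fm(pmax(s, 0)) * exp(-d_star * delta_lag))
}

#' Water-forced granulocyte (bone-marrow) model
#'
#' The bone-marrow model adjusted for deuterated-water labeling: marrow
#' precursors are forced by the body-water curve scaled by `b_w`,
#' \deqn{dF_M/dt = b_w U(t) p - p F_M, \qquad
#'   dF_B/dt = d F_M(t - \Delta) - d F_B.}
#' Solved piecewise analytically; `F_M` is represented as an exponential sum,
#' so when `p` coincides with the body-water turnover rate `delta` the latter
#' is nudged by 1e-8 to keep the representation non-degenerate.
#'
#' @inheritParams predict_bone_marrow
#' @param curve A [water_curve()] forcing.
#' @param b_w Water scaling factor (> 0; typically >= 1).
#' @return Blood-compartment enrichment fractions `F_B` at `times`.
#' @export
predict_granulocyte_water <- function(times, curve, p, d, delta_lag, b_w) {
  .check_times(times)
  stopifnot(p >= 0, d > 0, delta_lag >= 0, b_w > 0)
  f <- curve$f; delta <- curve$delta; beta <- curve$beta; tau <- curve$tau
  if (abs(p - delta) < 1e-8) delta <- delta + 1e-8
  # F_M on [0, tau]: c0 + cp e^{-pt} + cd e^{-delta t}
  k <- b_w * p * (beta - f) / (p - delta)
  c0 <- b_w * f
  cd <- k
  cp <- -(b_w * f + k)
  fm_tau <- c0 + cp * exp(-p * tau) + cd * exp(-delta * tau)
  utau <- water_enrichment(curve, tau)
  # F_M on (tau, Inf), s = t - tau: c1p e^{-ps} + c1d e^{-delta s}
  c1d <- b_w * p * utau / (p - delta)
  c1p <- fm_tau - c1d
  fb <- numeric(length(times))
  s <- times - delta_lag
  ph1 <- s > 0 & s <= tau
  ph2 <- s > tau
  if (any(ph1)) {
    sv <- s[ph1]
    fb[ph1] <- d * (c0 * .difexp(d, 0, sv) + cp * .difexp(d, p, sv) +
                      cd * .difexp(d, delta, sv))
  }
  if (any(ph2)) {
    fb_tau <- d * (c0 * .difexp(d, 0, tau) + cp * .difexp(d, p, tau) +
                     cd * .difexp(d, delta, tau))
    r <- s[ph2] - tau
    fb[ph2] <- fb_tau * exp(-d * r) +
      d * (c1p * .difexp(d, p, r) + c1d * .difexp(d, delta, r))
  }
  fb
}

# ---------------------------------------------------------------------------
# Model specification objects used by the fitting machinery. A kin_model
# bundles the parameter names, default box bounds, default fixed values and
# the prediction function mapping a full named parameter vector to fractions.

kin_model <- function(name, params, predict, lower, upper,
                      fixed = numeric(0), report = NULL) {
  structure(list(name = name, params = params, predict = predict,
                 lower = lower, upper = upper, fixed = fixed,
                 report = report),
            class = "kin_model")
}

#' @export
print.kin_model <- function(x, ...) {
  cat("<kin_model>", x$name, "\n  parameters:",
      paste(x$params, collapse = ", "), "\n")
  if (length(x$fixed))
    cat("  fixed by default:",
        paste(names(x$fixed), signif(x$fixed, 4), sep = " = ",
              collapse = ", "), "\n")
  invisible(x)
}

# Default bounds chosen to cover all values reported for these systems with
# margin: rates in [1e-5, 10]/day, lags up to 30 days, plateaus in [0.1, 5],
# water scaling in [1, 10].
.rate_lo <- 1e-5
.rate_hi <- 10

#' Model specification constructors
#'
#' Build a model specification for use with [fit_kinetics()]. Each model
#' carries its parameter names, default box bounds and default fixed
#' parameters; bounds and the fixed set can be overridden through
#' [fit_config()] or the `fixed` argument of [fit_kinetics()].
#'
#' * `kinetic_het_model()`: parameters `p`, `d_star`, with the scaling `b`
#'   fixed by default.
#' * `multi_exp_model(N)`: rates `p1..pN` plus `N - 1` simplex logits
#'   `a1..a(N-1)` (softmax with the last component as reference), `2N - 1`
#'   free parameters; `b` fixed by default.
#' * `growing_culture_model(label)`: `p` free; for `"glucose"` the scaling
#'   `b` is fixed at `b_g` (default 0.65), for `"water"` `b` is free in
#'   `[1, 10]`.
#' * `bone_marrow_model()`: `p`, `d`, `delta_lag`, `psi`.
#' * `delayed_obs_model()`: `p`, `d_star`, `delta_lag`, `psi`.
#' * `granulocyte_water_model()`: `p`, `d`, `delta_lag`, `b_w`.
#'
#' @param b Scaling factor value used when `b` is fixed.
#' @param N Number of subpopulations (>= 1).
#' @param label `"glucose"` or `"water"` (growing culture).
#' @param b_g Glucose intracellular dilution factor (default 0.65).
#' @return A `"kin_model"` object.
#' @name kin_models
NULL

#' @rdname kin_models
#' @export
kinetic_het_model <- function(b = 1) {
  kin_model("kinetic_het", c("p", "d_star", "b"),
            function(pars, schedule, times)
              predict_kinetic_het(times, schedule, pars[["p"]],
                                  pars[["d_star"]], pars[["b"]]),
            lower = c(p = .rate_lo, d_star = .rate_lo, b = 1e-3),
            upper = c(p = .rate_hi, d_star = .rate_hi, b = 10),
            fixed = c(b = b))
}

# softmax with the last component as reference logit 0
.alpha_from_logits <- function(a) {
  e <- exp(c(a, 0))
  e / sum(e)
}

#' @rdname kin_models
#' @export
multi_exp_model <- function(N, b = 1) {
  stopifnot(N >= 1)
  pn <- paste0("p", seq_len(N))
  an <- if (N > 1) paste0("a", seq_len(N - 1)) else character(0)
  params <- c(pn, an, "b")
  lower <- c(setNames(rep(.rate_lo, N), pn), setNames(rep(-10, N - 1), an),
             b = 1e-3)
  upper <- c(setNames(rep(.rate_hi, N), pn), setNames(rep(10, N - 1), an),
             b = 10)
  kin_model(paste0("multi_exp_", N), params,
            function(pars, schedule, times) {
              alpha <- .alpha_from_logits(unname(pars[an]))
              predict_multi_exp(times, schedule, alpha, unname(pars[pn]),
                                pars[["b"]])
            },
            lower = lower, upper = upper, fixed = c(b = b),
            report = function(pars) {
              alpha <- .alpha_from_logits(unname(pars[an]))
              p <- unname(pars[pn])
              ord <- order(p, decreasing = TRUE)   # canonical order
              c(setNames(p[ord], pn),
                setNames(alpha[ord], paste0("alpha", seq_len(N))),
                b = unname(pars[["b"]]),
                p_avg = sum(alpha * p))
            })
}

#' @rdname kin_models
#' @export
growing_culture_model <- function(label = c("glucose", "water"), b_g = 0.65) {
  label <- match.arg(label)
  fixed <- if (label == "glucose") c(b = b_g) else numeric(0)
  lower <- c(p = .rate_lo, b = if (label == "water") 1 else 1e-3)
  upper <- c(p = .rate_hi, b = 10)
  kin_model(paste0("growing_culture_", label), c("p", "b"),
            function(pars, schedule, times)
              predict_growing_culture(times, schedule, pars[["p"]],
                                      pars[["b"]]),
            lower = lower, upper = upper, fixed = fixed)
}

#' @rdname kin_models
#' @export
bone_marrow_model <- function() {
  kin_model("bone_marrow", c("p", "d", "delta_lag", "psi"),
            function(pars, schedule, times)
              predict_bone_marrow(times, schedule, pars[["p"]], pars[["d"]],
                                  pars[["delta_lag"]], pars[["psi"]]),
            lower = c(p = .rate_lo, d = .rate_lo, delta_lag = 0, psi = 0.1),
            upper = c(p = .rate_hi, d = .rate_hi, delta_lag = 30, psi = 5))
}

#' @rdname kin_models
#' @export
delayed_obs_model <- function() {
  kin_model("delayed_obs", c("p", "d_star", "delta_lag", "psi"),
            function(pars, schedule, times)
              predict_delayed_obs(times, .sched_tau(schedule), pars[["p"]],
                                  pars[["d_star"]], pars[["delta_lag"]],
                                  pars[["psi"]]),
            lower = c(p = .rate_lo, d_star = .rate_lo, delta_lag = 0,
                      psi = 0.1),
            upper = c(p = .rate_hi, d_star = .rate_hi, delta_lag = 30,
                      psi = 5))
}

#' @rdname kin_models
#' @export
granulocyte_water_model <- function() {
  kin_model("granulocyte_water", c("p", "d", "delta_lag", "b_w"),
            function(pars, schedule, times)
              predict_granulocyte_water(times, schedule, pars[["p"]],
                                        pars[["d"]], pars[["delta_lag"]],
                                        pars[["b_w"]]),
            lower = c(p = .rate_lo, d = .rate_lo, delta_lag = 0, b_w = 1),
            upper = c(p = .rate_hi, d = .rate_hi, delta_lag = 30, b_w = 10))
}
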