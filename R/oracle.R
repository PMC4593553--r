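# Raw-pool numerical oracle. Integrates the unreduced labeled-adenosine pool
# equations (including absolute pool sizes and the marrow exit rate, which
# the reduced closed forms eliminate via the equilibrium assumptions) with a
# high-accuracy adaptive stepper, then forms the normalized fraction. The
# integration is restarted at every forcing breakpoint (end of labeling,
# maturation delay) so discontinuous right-hand sides never degrade the
# step-size control; delayed terms use dense output interpolated piecewise.
# Used for verification; never called by the fitting path.

# Integrate y' = func(t, y) from 0, restarting at `breaks`; returns the
# state matrix at the sorted unique query times (plus a lookup helper).
.seg_ode <- function(y0, query, func, breaks = numeric(0), rtol = 1e-10,
                     atol = 1e-12) {
  qs <- sort(unique(c(0, query)))
  tmax <- max(qs)
  bks <- sort(unique(breaks))
  bks <- bks[bks > 0 & bks < tmax]
  pts <- sort(unique(c(qs, bks)))
  res <- matrix(NA_real_, length(pts), length(y0))
  res[1, ] <- y0
  cuts <- c(0, bks, tmax)
  y <- y0
  for (k in seq_len(length(cuts) - 1)) {
    if (cuts[k] == cuts[k + 1]) next
    tt <- pts[pts >= cuts[k] & pts <= cuts[k + 1]]
    sol <- deSolve::ode(y, tt, function(t, yy, parms) list(func(t, yy)),
                        NULL, rtol = rtol, atol = atol, maxsteps = 100000)
    if (anyNA(sol[, -1]))
      stop("oracle integration failed between t = ", cuts[k], " and ",
           cuts[k + 1])
    res[match(tt, pts), ] <- sol[, 1 + seq_along(y0), drop = FALSE]
    y <- res[match(cuts[k + 1], pts), ]
  }
  list(at = function(t) res[match(t, pts), , drop = FALSE], times = pts)
}

# Piecewise cubic-spline interpolant through (x, y) split at `breaks`
# (dense-output history for the delayed terms).
.pw_spline <- function(x, y, breaks) {
  bks <- sort(unique(breaks))
  bks <- bks[bks > min(x) & bks < max(x)]
  edges <- c(min(x), bks, max(x))
  funs <- lapply(seq_len(length(edges) - 1), function(k) {
    keep <- x >= edges[k] & x <= edges[k + 1]
    stats::splinefun(x[keep], y[keep], method = "natural")
  })
  function(t) {
    piece <- pmin(pmax(findInterval(t, edges, rightmost.closed = TRUE), 1),
                  length(funs))
    out <- numeric(length(t))
    for (k in unique(piece)) out[piece == k] <- funs[[k]](t[piece == k])
    out
  }
}

#' Integrate the raw pool equations of a labeling model
#'
#' High-accuracy numerical solution of the unreduced labeled/unlabeled pool
#' system for any of the six labeling models, returning the normalized
#' enrichment fraction at `times`. The marrow/blood models are integrated
#' as delay systems using dense-output history; the equilibrium relations
#' (`epsilon = p`, `epsilon * M = d * B`) that the reduced forms assume are
#' imposed on the raw pools. Absolute pool sizes are arbitrary (`A0`) and
#' must cancel from the returned fraction.
#'
#' @param model Model name: one of `"kinetic_het"`, `"multi_exp"`,
#'   `"growing_culture"`, `"bone_marrow"`, `"delayed_obs"`,
#'   `"granulocyte_water"`; or a `"kin_model"` object, whose name prefix is
#'   used.
#' @param pars Named list/vector of parameters. `kinetic_het`: `p`, `d_star`,
#'   `b`; `multi_exp`: vectors `alpha`, `p` and scalar `b`;
#'   `growing_culture`: `p`, `b`; `bone_marrow`: `p`, `d`, `delta_lag`,
#'   `psi`; `delayed_obs`: `p`, `d_star`, `delta_lag`, `psi`;
#'   `granulocyte_water`: `p`, `d`, `delta_lag`, `b_w`.
#' @param schedule The forcing [label_schedule][glucose_pulse].
#' @param times Sorted output times in days.
#' @param A0 Arbitrary absolute pool size used for the raw system.
#' @param rtol,atol Solver tolerances.
#' @param history_step Grid step (days) of the dense-output history used
#'   for the delayed terms.
#' @return Enrichment fractions at `times`.
#' @export
oracle_integrate <- function(model, pars, schedule, times, A0 = 3.7,
                             rtol = 1e-10, atol = 1e-12,
                             history_step = 0.01) {
  if (inherits(model, "kin_model")) model <- sub("_[0-9]+$", "", model$name)
  model <- sub("^growing_culture.*", "growing_culture", model)
  .check_times(times)
  pars <- as.list(pars)
  u <- function(t) schedule_value(schedule, t)
  tau <- .sched_tau(schedule)
  tq <- sort(unique(c(0, times)))
  take <- function(sol, col) sol$at(times)[, col]

  # marrow/blood delay system: integrate the marrow pool on a dense grid,
  # spline it piecewise, and feed the lagged values into the blood pool.
  delay_blood <- function(marrow_rhs, marrow_breaks) {
    lag <- pars$delta_lag
    tmax <- max(tq)
    hist_t <- sort(unique(c(seq(0, max(tmax, marrow_breaks, 1),
                                by = history_step),
                            tmax, marrow_breaks)))
    m <- .seg_ode(0, hist_t, marrow_rhs, breaks = marrow_breaks,
                  rtol = rtol, atol = atol)
    am <- .pw_spline(m$times, m$at(m$times)[, 1], marrow_breaks)
    am_lag <- function(t) ifelse(t < lag, 0, am(pmax(t - lag, 0)))
    B <- pars$p * A0 / pars$d
    blood <- .seg_ode(0, tq, function(t, y)
      pars$p * am_lag(t) - pars$d * y[1],
      breaks = c(lag, marrow_breaks + lag), rtol = rtol, atol = atol)
    blood$at(times)[, 1] / B
  }

  switch(model,
    kinetic_het = {
      sol <- .seg_ode(0, tq, function(t, y)
        pars$p * pars$b * u(t) * A0 - pars$d_star * y[1],
        breaks = tau, rtol = rtol, atol = atol)
      take(sol, 1) / A0
    },
    multi_exp = {
      N <- length(pars$p)
      sol <- .seg_ode(rep(0, N), tq, function(t, y)
        pars$p * pars$b * u(t) * pars$alpha * A0 - pars$p * y,
        breaks = tau, rtol = rtol, atol = atol)
      rowSums(sol$at(times)) / A0
    },
    growing_culture = {
      sol <- .seg_ode(c(A0, 0), tq, function(t, y) {
        ue <- if (t <= tau) u(t) else 0   # label production ends at tau
        tot <- y[1] + y[2]
        c((1 - pars$b * ue) * pars$p * tot, pars$b * ue * pars$p * tot)
      }, breaks = tau, rtol = rtol, atol = atol)
      take(sol, 2) / (take(sol, 1) + take(sol, 2))
    },
    bone_marrow = {
      # raw labeled adenosine; epsilon = p, B = p M / d
      delay_blood(function(t, y) {
        if (t <= tau) pars$psi * pars$p * u(t) * A0 - pars$p * y[1]
        else -pars$p * y[1]
      }, marrow_breaks = tau)
    },
    delayed_obs = {
      shifted <- sort(unique(c(0, pmax(times - pars$delta_lag, 0))))
      sol <- .seg_ode(0, shifted, function(t, y) {
        if (t <= tau) pars$psi * pars$p - pars$d_star * y[1]
        else -pars$d_star * y[1]
      }, breaks = tau, rtol = rtol, atol = atol)
      s <- pmax(times - pars$delta_lag, 0)
      out <- sol$at(s)[, 1] * exp(-pars$d_star * pars$delta_lag)
      out[times < pars$delta_lag] <- 0
      out
    },
    granulocyte_water = {
      delay_blood(function(t, y)
        pars$b_w * u(t) * pars$p * A0 - pars$p * y[1],
        marrow_breaks = tau)
    },
    stop("unknown model '", model, "'")
  )
}
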