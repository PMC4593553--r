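# Shared fixtures: everything is generated in code, no stored data.

mouse_days <- c(0, 1, 2, 3, 4, 7, 8, 10, 15, 21)

# Noiseless kinetic-het series on the murine sacrifice grid.
kh_series <- function(p, d_star, schedule, b = 1, times = mouse_days, ...) {
  enrichment_series(times,
                    predict_kinetic_het(times, schedule, p, d_star, b), ...)
}

# Exact two-tailed Mann-Whitney p-value by enumeration of all group
# assignments (independent oracle for mann_whitney; no ties assumed).
mw_enumerate <- function(a, b) {
  pooled <- c(a, b)
  n_a <- length(a)
  idx <- utils::combn(length(pooled), n_a)
  u_of <- function(av, bv) sum(outer(av, bv, ">")) + 0.5 * sum(outer(av, bv, "=="))
  u_obs <- u_of(a, b)
  all_u <- apply(idx, 2, function(i) u_of(pooled[i], pooled[-i]))
  min(1, 2 * min(mean(all_u <= u_obs), mean(all_u >= u_obs)))
}

# Draw one uniform value (convenience for seeded parameter sweeps).
runif1 <- function(lo, hi) stats::runif(1, lo, hi)
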