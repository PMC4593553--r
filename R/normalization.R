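# The three normalization routes from raw DNA enrichment to model-ready
# fractions. Normalization never clips or discards data: values exceeding 1
# after scaling are the diagnostic of mis-normalization and are flagged.

.flag_over_unity <- function(series, soft_margin = 0.05) {
  v <- series$enrichment
  over <- which(v > 1)
  attr(series, "over_unity") <- over
  if (length(over)) {
    if (max(v[over]) <= 1 + soft_margin)
      warning("normalized enrichment slightly exceeds 1 (", length(over),
              " value(s)); possible mis-normalization", call. = FALSE)
    else
      warning("normalized enrichment exceeds 1 by more than ",
              soft_margin, " (max ", signif(max(v), 4),
              "); precursor availability is likely underestimated",
              call. = FALSE)
  }
  series
}

#' Conventional glucose normalization
#'
#' Divides each DNA enrichment by `b_g * u_bar`, the intracellular glucose
#' dilution factor times the mean plasma enrichment over the labeling
#' period. Output may exceed 1 when the plasma measurements underestimate
#' the label actually available to dividing cells; such values are flagged
#' (attribute `"over_unity"`), never clipped.
#'
#' @param series A DNA enrichment series (fractions).
#' @param u_bar Mean plasma enrichment over the labeling period (> 0);
#'   see [mean_enrichment()].
#' @param b_g Intracellular dilution factor, in (0, 1\]; default 0.65
#'   (supported range roughly 0.6-0.75).
#' @param soft_margin Width of the band above 1 treated as a soft warning.
#' @return The normalized series (same class), with attribute
#'   `"over_unity"` giving the indices of values above 1.
#' @export
normalize_conventional_glucose <- function(series, u_bar, b_g = 0.65,
                                           soft_margin = 0.05) {
  if (u_bar <= 0) stop("u_bar must be positive")
  if (b_g <= 0 || b_g > 1) stop("b_g must lie in (0, 1]")
  out <- series
  out$enrichment <- series$enrichment / (b_g * u_bar)
  .flag_over_unity(.as_series(out), soft_margin)
}

#' Normalization to a reference-population plateau
#'
#' Divides each DNA enrichment by the maximal attainable enrichment
#' estimated from a rapidly turning-over reference population (thymocytes,
#' granulocytes, monocytes). Over-unity values are flagged, never clipped.
#'
#' @param series A DNA enrichment series.
#' @param plateau Reference maximal enrichment fraction (> 0).
#' @inheritParams normalize_conventional_glucose
#' @return The normalized series with attribute `"over_unity"`.
#' @export
normalize_to_plateau <- function(series, plateau, soft_margin = 0.05) {
  if (plateau <= 0) stop("plateau must be positive")
  out <- series
  out$enrichment <- series$enrichment / plateau
  .flag_over_unity(.as_series(out), soft_margin)
}

#' Estimate the maximal attainable enrichment from a reference population
#'
#' Fits the kinetic heterogeneity model with a free amplitude to the raw
#' reference series and returns the asymptote of the labeling-phase
#' solution. Because the equation is linear, the proliferation rate and the
#' amplitude scale enter only through their product, so the fit uses the
#' identifiable parameterization `dF/dt = gain * U(t) - d_star * F`
#' (`gain = scale * p`); the returned plateau is
#' `gain * U_max / d_star`, where `U_max` is the asymptotic labeling-phase
#' availability of the schedule. This is the model used to anchor the 100%
#' level of DNA labeling; it is swappable by fitting any other model and
#' passing its plateau to [normalize_to_plateau()].
#'
#' @param reference Raw enrichment series of the reference population,
#'   covering labeling and delabeling phases.
#' @param schedule The forcing schedule (a unit-height pulse makes the
#'   scale directly interpretable).
#' @param config A [fit_config()].
#' @return A list with `plateau` (fraction), `fit` (a `"kinfit"`) and
#'   `degenerate` (flag; `TRUE` for constant-zero references or
#'   non-convergence).
#' @export
estimate_reference_plateau <- function(reference, schedule,
                                       config = fit_config(n_starts = 30)) {
  if (all(reference$enrichment == 0)) {
    return(list(plateau = 0, fit = NULL, degenerate = TRUE))
  }
  model <- kin_model(
    "reference_plateau", c("gain", "d_star"),
    function(pars, schedule, times)
      predict_kinetic_het(times, schedule, p = 1, pars[["d_star"]],
                          b = pars[["gain"]]),
    lower = c(gain = 1e-6, d_star = 1e-5),
    upper = c(gain = 10, d_star = 10))
  fit <- fit_kinetics(model, reference, schedule, config)
  u_max <- .sched_asymptote(schedule)
  plateau <- unname(fit$estimates[["gain"]] * u_max /
                      fit$estimates[["d_star"]])
  list(plateau = plateau, fit = fit,
       degenerate = !isTRUE(fit$converged) || plateau < 1e-8)
}

#' Water scaling factor from a reference plateau
#'
#' Returns the factor `b_w` that makes the reference population's maximal
#' enrichment correspond to 100%: the plateau divided by the asymptotic
#' labeling-phase availability implied by the body-water curve.
#'
#' @param plateau Reference maximal DNA enrichment fraction (> 0).
#' @param curve A [water_curve()]; its asymptote `f` is the availability.
#' @return The scaling factor `b_w = plateau / f`.
#' @examples
#' choose_bw(0.28, water_curve(f = 0.08, delta = 0.3, beta = 0.02, tau = 7))
#' @export
choose_bw <- function(plateau, curve) {
  if (plateau <= 0) stop("plateau must be positive")
  avail <- .sched_asymptote(curve)
  if (avail <= 0) stop("schedule has zero asymptotic availability")
  plateau / avail
}
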