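# S3 methods for "kinfit" objects.

#' @export
print.kinfit <- function(x, digits = 4, ...) {
  cat("Labeling-kinetics fit",
      if (!is.null(x$model)) paste0("(", x$model$name, ")"), "\n")
  est <- if (!is.null(x$report)) x$report else x$estimates
  cat("  estimates: ",
      paste(names(est), signif(est, digits), sep = " = ", collapse = ", "),
      "\n", sep = "")
  cat("  n = ", x$n_obs, ", free parameters = ", x$k_params,
      ", RSS = ", signif(x$rss, digits),
      ", AICc = ", if (is.na(x$aicc)) "undefined" else signif(x$aicc, digits),
      "\n", sep = "")
  if (!isTRUE(x$converged)) cat("  WARNING: fit did not converge\n")
  invisible(x)
}

#' @export
summary.kinfit <- function(object, ...) {
  est <- object$estimates
  tab <- data.frame(estimate = est,
                    sd = object$sd[names(est)],
                    lo95 = object$ci95[names(est), 1],
                    hi95 = object$ci95[names(est), 2],
                    free = names(est) %in% object$free)
  out <- list(table = tab, rss = object$rss, n_obs = object$n_obs,
              k_params = object$k_params, aicc = object$aicc,
              converged = object$converged, seed_used = object$seed_used,
              model = if (!is.null(object$model)) object$model$name,
              report = object$report)
  class(out) <- "summary.kinfit"
  out
}

#' @export
print.summary.kinfit <- function(x, digits = 4, ...) {
  cat("Labeling-kinetics fit", if (!is.null(x$model)) paste0("(", x$model, ")"),
      "\n\n")
  print(signif_df(x$table, digits))
  cat("\nRSS = ", signif(x$rss, digits), ", n = ", x$n_obs,
      ", k = ", x$k_params, ", AICc = ",
      if (is.na(x$aicc)) "undefined" else signif(x$aicc, digits),
      ", seed = ", x$seed_used, "\n", sep = "")
  if (!is.null(x$report)) {
    cat("\nDerived (canonical) parameters:\n")
    print(signif(x$report, digits))
  }
  if (!isTRUE(x$converged)) cat("\nWARNING: fit did not converge\n")
  invisible(x)
}

signif_df <- function(df, digits) {
  for (j in seq_along(df)) if (is.numeric(df[[j]]))
    df[[j]] <- signif(df[[j]], digits)
  df
}

#' @export
coef.kinfit <- function(object, ...) {
  object$estimates
}

#' @export
vcov.kinfit <- function(object, ...) object$vcov

#' @export
fitted.kinfit <- function(object, ...) object$fitted

#' @export
residuals.kinfit <- function(object, ...) object$residuals

#' @export
predict.kinfit <- function(object, times = NULL, schedule = NULL, ...) {
  if (is.null(object$model)) stop("fit carries no model specification")
  if (is.null(schedule)) {
    schedule <- object$schedule
    if (is.list(schedule) && !inherits(schedule, "label_schedule"))
      schedule <- schedule[[1]]
  }
  if (is.null(times)) {
    d <- if (is.data.frame(object$data)) object$data else object$data[[1]]
    times <- d$time_days
  }
  object$model$predict(object$estimates, schedule, times)
}

#' @export
plot.kinfit <- function(x, n_grid = 200, xlab = "time (days)",
                        ylab = "enrichment (fraction)", ...) {
  d <- if (is.data.frame(x$data)) x$data else do.call(rbind, x$data)
  tmax <- max(d$time_days)
  grid <- seq(0, tmax, length.out = n_grid)
  pred <- predict(x, times = grid)
  plot(d$time_days, d$enrichment, xlab = xlab, ylab = ylab,
       ylim = range(0, d$enrichment, pred), ...)
  lines(grid, pred)
  sched <- if (inherits(x$schedule, "label_schedule")) x$schedule else
    if (is.list(x$schedule)) x$schedule[[1]] else NULL
  if (!is.null(sched) && !is.null(sched$tau))
    abline(v = sched$tau, lty = 2, col = "grey50")
  invisible(x)
}

#' @export
simulate.kinfit <- function(object, nsim = 1, seed = NULL, ...) {
  if (is.null(seed)) seed <- object$seed_used + 100L
  sigma <- sqrt(max(object$rss, 0) /
                  max(object$n_obs - object$k_params, 1))
  d <- if (is.data.frame(object$data)) object$data else object$data[[1]]
  mu <- predict(object, times = d$time_days)
  .with_seed(seed, {
    out <- replicate(nsim, pmin(pmax(mu + rnorm(length(mu), 0, sigma), 0), 1),
                     simplify = FALSE)
  })
  lapply(out, function(y) {
    s <- d
    s$enrichment <- y
    .as_series(s)
  })
}
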