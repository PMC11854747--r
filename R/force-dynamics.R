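#' Fit a force-decay model to one elastomeric-chain force series
#'
#' Elastomeric chains lose force monotonically over an activation cycle.
#' Two models are available:
#'
#' * `exponential`: \eqn{u(t) = u_0 e^{-k (t-1)}} with \eqn{k \ge 0} and day 1
#'   the application day. With exactly two measurements the curve passes
#'   through both; with more, it is the least-squares fit on log-force.
#'   The asymptote is zero — two points per cycle cannot constrain a nonzero
#'   residual force, so the remanent force is reported as the day-28
#'   prediction rather than fitted.
#' * `piecewise_linear`: linear interpolation between measurements, flat
#'   extrapolation beyond the first and last.
#'
#' A later measurement exceeding an earlier one is rejected as a non-physical
#' force increase (equal forces are allowed; they fit `k = 0`).
#'
#' @param series A [force_series()] with at least two measurements.
#' @param model `"exponential"` (default) or `"piecewise_linear"`.
#' @return An object of class `decay_fit`: `u0` (fitted day-1 force, gf),
#'   `rate_k` (per-day decay constant; `NA` for the piecewise model),
#'   `model`, `cycle_length`, and the measurement `day`/`force` vectors.
#' @examples
#' fs <- force_series("CA1", c(1, 14), c(220, 100))
#' fit <- fit_decay(fs)
#' predict_force(fit, 28)  # remanent force at cycle end, ~42.8 gf
#' @export
fit_decay <- function(series, model = c("exponential", "piecewise_linear")) {
  model <- match.arg(model)
  if (!inherits(series, "force_series")) stop("series must be a force_series", call. = FALSE)
  if (length(series$day) < 2) stop("at least two measurements are required", call. = FALSE)
  if (any(diff(series$force) > 0)) {
    stop("non-physical force increase: a later measurement exceeds an earlier one",
         call. = FALSE)
  }
  if (model == "exponential") {
    if (length(series$day) == 2) {
      k <- log(series$force[1] / series$force[2]) / diff(series$day)
      u0 <- series$force[1] * exp(k * (series$day[1] - 1))
    } else {
      co <- stats::coef(stats::lm(log(series$force) ~ I(series$day - 1)))
      k <- max(0, -co[[2]])
      u0 <- exp(co[[1]])
    }
  } else {
    k <- NA_real_
    u0 <- series$force[1]
  }
  structure(list(u0 = u0, rate_k = k, model = model,
                 cycle_length = series$cycle_length,
                 day = series$day, force = series$force,
                 cycle_id = series$cycle_id),
            class = "decay_fit")
}

#' Predicted chain force at a given day of the cycle
#'
#' @param fit A [fit_decay()] result.
#' @param day Day (or vector of days) within `[1, cycle_length]`.
#' @return Predicted force(s), grams-force. Exact at the measurement days
#'   for the piecewise model and for two-point exponential fits.
#' @export
predict_force <- function(fit, day) {
  if (!inherits(fit, "decay_fit")) stop("fit must be a decay_fit", call. = FALSE)
  if (any(day < 1) || any(day > fit$cycle_length)) {
    stop(sprintf("day must lie within [1, %g]", fit$cycle_length), call. = FALSE)
  }
  if (fit$model == "exponential") {
    fit$u0 * exp(-fit$rate_k * (day - 1))
  } else {
    stats::approx(fit$day, fit$force, xout = day, rule = 2)$y
  }
}

#' @export
print.decay_fit <- function(x, ...) {
  if (x$model == "exponential") {
    cat(sprintf("<decay_fit> %s exponential: u0 = %.4g gf, k = %.4g /day, day-%g force %.4g gf\n",
                x$cycle_id, x$u0, x$rate_k, x$cycle_length,
                predict_force(x, x$cycle_length)))
  } else {
    cat(sprintf("<decay_fit> %s piecewise linear through %d measurements\n",
                x$cycle_id, length(x$day)))
  }
  invisible(x)
}

#' @export
plot.decay_fit <- function(x, ..., n = 200) {
  t <- seq(1, x$cycle_length, length.out = n)
  plot(t, predict_force(x, t), type = "l", xlab = "day",
       ylab = "force [gf]", main = sprintf("Chain force decay (%s)", x$cycle_id), ...)
  graphics::points(x$day, x$force, pch = 19)
  invisible(x)
}

#' Cohort-level force summary per activation cycle
#'
#' For each cycle label present in the cohort: the mean initial (first
#' measurement) force, the mean day-14 force (or last measurement when no
#' day-14 reading exists), and the mean retention fraction (day-14 force /
#' day-1 force), averaged across teeth.
#'
#' @param cohort List of [tooth_record()] objects.
#' @return Data frame with columns `cycle_id`, `n_teeth`,
#'   `mean_initial_gf`, `mean_day14_gf`, `mean_retention`.
#' @export
force_summary <- function(cohort) {
  validate_cohort(cohort)
  rows <- do.call(rbind, lapply(cohort, function(r) {
    do.call(rbind, lapply(r$cycles, function(cy) {
      fs <- cy$force
      f14 <- if (any(fs$day == 14)) fs$force[fs$day == 14][1] else fs$force[length(fs$force)]
      data.frame(cycle_id = fs$cycle_id, initial = fs$force[1], day14 = f14,
                 stringsAsFactors = FALSE)
    }))
  }))
  out <- do.call(rbind, lapply(split(rows, rows$cycle_id), function(g) {
    data.frame(cycle_id = g$cycle_id[1], n_teeth = nrow(g),
               mean_initial_gf = mean(g$initial), mean_day14_gf = mean(g$day14),
               mean_retention = mean(g$day14 / g$initial),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out[order(out$cycle_id), , drop = FALSE]
}

#' In-vitro mean initial force of memory elastomeric chains
#'
#' Reference constant: the mean initial force the same memory elastomeric
#' chains deliver in vitro (gf). Clinically applied initial forces are
#' substantially lower (mean around 220 gf in vivo) because high forces risk
#' pain and damage to periodontal and dental structures.
#' @export
in_vitro_initial_force_gf <- 347
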