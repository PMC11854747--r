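#' Weights of the tissue-resistance denominator polynomial
#'
#' The denominator of the tissue-resistance coefficient is a cubic polynomial
#' in the root length sf and slot-to-gingiva distance s~ with three
#' non-negative weights. Their tissue-level meaning is not specified by the
#' underlying model; they are opaque, calibratable parameters.
#'
#' @param delta0 Weight of the linear (per-mm) term.
#' @param delta1 Weight of the quadratic (per-mm squared) term.
#' @param delta2 Weight of the cubic (per-mm cubed) term.
#' @return An object of class `delta_coefficients`.
#' @export
delta_coefficients <- function(delta0 = 1, delta1 = 1, delta2 = 1) {
  d <- c(delta0 = delta0, delta1 = delta1, delta2 = delta2)
  if (!all(is.finite(d)) || any(d < 0)) {
    stop("delta coefficients must be finite and non-negative", call. = FALSE)
  }
  if (all(d == 0)) stop("delta coefficients must not all be zero", call. = FALSE)
  structure(as.list(d), class = "delta_coefficients")
}

#' @export
print.delta_coefficients <- function(x, ...) {
  cat(sprintf("<delta_coefficients> delta0 = %.6g, delta1 = %.6g, delta2 = %.6g\n",
              x$delta0, x$delta1, x$delta2))
  invisible(x)
}

as_deltas <- function(x) {
  if (inherits(x, "delta_coefficients")) return(x)
  if (is.numeric(x) && length(x) == 3) return(delta_coefficients(x[1], x[2], x[3]))
  stop("deltas must be a delta_coefficients object or a numeric vector of length 3",
       call. = FALSE)
}

# Basis terms of the denominator as a function of sf (gingiva->apex) and
# s~ (slot->gingiva); the denominator is their dot product with (d0, d1, d2).
denominator_basis <- function(sf, s_tilde) {
  cbind(sf,
        (sf^2 + 2 * sf * s_tilde) / 2,
        (sf^3 + 3 * sf^2 * s_tilde + 3 * sf * s_tilde^2) / 3)
}

#' Denominator of the tissue-resistance coefficient
#'
#' Evaluates
#' \deqn{D = \delta_0 s_f + \frac{\delta_1}{2}(s_f^2 + 2 s_f \tilde{s})
#'       + \frac{\delta_2}{3}(s_f^3 + 3 s_f^2 \tilde{s} + 3 s_f \tilde{s}^2)}
#' which depends on the geometry only through the root length \eqn{s_f} and
#' the slot-to-gingiva distance \eqn{\tilde{s}}. Strictly positive for valid
#' geometry and admissible weights.
#'
#' @param geometry A [tooth_geometry()].
#' @param deltas A [delta_coefficients()] (or numeric length-3 vector).
#' @return The denominator (mm-weighted scalar).
#' @export
sigma_denominator <- function(geometry, deltas = delta_coefficients()) {
  deltas <- as_deltas(deltas)
  d <- c(deltas$delta0, deltas$delta1, deltas$delta2)
  if (all(d == 0)) stop("degenerate denominator: all delta coefficients are zero",
                        call. = FALSE)
  drop(denominator_basis(geometry$gingiva_to_apex, geometry$slot_to_gingiva) %*% d)
}

#' Tissue-resistance weighting coefficient of one tooth-cycle
#'
#' The coefficient
#' \deqn{\sigma = \frac{u_0\, s_c}{D(s_f, \tilde{s}; \delta)}}
#' (grams-force per square millimetre) summarizes the plastic resistance of
#' the periodontal ligament plus alveolar bone to the applied moment: it is
#' *inversely* related to the actual tissue resistance. Values above the
#' threshold (default 2 gf/mm2) read as reduced tissue resistance, below as
#' increased; a value exactly at the threshold is classed `"threshold"`.
#'
#' @param force Applied force (grams-force), typically the day-1 chain force.
#' @param sc A [rotation_center()] or finite positive numeric sc (mm).
#' @param geometry A [tooth_geometry()].
#' @param deltas A [delta_coefficients()].
#' @param threshold Classification threshold (gf/mm2), default 2.
#' @return An object of class `sigma_result` with components `sigma`,
#'   `resistance_class` (`reduced`, `increased` or `threshold`) and
#'   `threshold`.
#' @examples
#' g <- tooth_geometry(31, 5, 4.5, 21.5)
#' compute_sigma(220, 243, g, delta_coefficients(1, 1, 1))
#' @export
compute_sigma <- function(force, sc, geometry, deltas = delta_coefficients(),
                          threshold = 2) {
  sc <- as_sc(sc)
  if (sc$is_infinite) {
    stop("sigma undefined for pure translation (rotation center at infinity)",
         call. = FALSE)
  }
  if (!is.finite(force) || force <= 0) {
    stop("force must be finite and strictly positive", call. = FALSE)
  }
  if (sc$sc <= 0) {
    stop("sigma requires a rotation center strictly apical of the bracket slot (sc > 0)",
         call. = FALSE)
  }
  sigma <- force * sc$sc / sigma_denominator(geometry, deltas)
  cls <- if (sigma > threshold) "reduced"
         else if (sigma < threshold) "increased"
         else "threshold"
  structure(list(sigma = sigma, resistance_class = cls, threshold = threshold),
            class = "sigma_result")
}

#' @export
print.sigma_result <- function(x, ...) {
  cat(sprintf("<sigma_result> sigma = %.4f gf/mm2 (%s tissue resistance at threshold %g)\n",
              x$sigma, x$resistance_class, x$threshold))
  invisible(x)
}

#' Implied denominator of one observed coefficient value
#'
#' Algebraic inverse of the coefficient relation: given an observed sigma,
#' the force and the rotation center, returns the denominator value
#' `force * sc / sigma` that observation implies. Comparing implied
#' denominators across teeth with identical root geometry is the diagnostic
#' for whether any single static delta-set can explain a set of observed
#' coefficients.
#'
#' @param sigma Observed coefficient (gf/mm2), strictly positive.
#' @param force Applied force (grams-force).
#' @param sc Rotation center (mm).
#' @return Implied denominator (mm-weighted scalar).
#' @export
invert_denominator <- function(sigma, force, sc) {
  if (any(!is.finite(sigma)) || any(sigma <= 0)) {
    stop("sigma must be finite and strictly positive", call. = FALSE)
  }
  force * sc / sigma
}

# Exact non-negative least squares for <= 3 free parameters by enumerating
# active sets: solve the unconstrained LS problem on every subset of free
# columns, keep feasible candidates, return the feasible minimizer.
nnls_small <- function(A, b) {
  p <- ncol(A)
  best <- NULL
  best_sse <- Inf
  for (mask in 0:(2^p - 1)) {
    free <- which(bitwAnd(mask, 2^(seq_len(p) - 1)) > 0)
    x <- numeric(p)
    if (length(free) > 0) {
      fit <- tryCatch(stats::lsfit(A[, free, drop = FALSE], b, intercept = FALSE),
                      error = function(e) NULL)
      if (is.null(fit)) next
      x[free] <- fit$coefficients
    }
    if (any(x < 0)) next
    sse <- sum((b - A %*% x)^2)
    if (!is.finite(sse)) next
    if (is.infinite(best_sse) || sse < best_sse - 1e-12 * max(1, best_sse)) {
      best <- x
      best_sse <- sse
    }
  }
  best
}

#' Calibrate the denominator weights from observed coefficient values
#'
#' Recovers the three denominator weights from observations of the
#' tissue-resistance coefficient by non-negative least squares on the
#' coefficient scale: minimizes the sum of squared differences between
#' predicted and observed sigma subject to all weights being non-negative.
#' A unique solution needs at least three observations with distinct root
#' geometries (`sf`, `s_tilde`); a rank-deficient design triggers a warning
#' and returns the minimum-norm solution (clamped to non-negative).
#'
#' The solver first solves the linearized problem exactly — each observation
#' implies a denominator `force * sc / sigma`, linear in the weights — by
#' active-set non-negative least squares, then refines the weights against
#' the coefficient-scale objective with bounded quasi-Newton iterations.
#' Noise-free observations are recovered exactly by the linear stage.
#'
#' @param observations Data frame with one row per observation and columns
#'   `force` (gf), `sc` (mm), `sf` and `s_tilde` (mm, the root length and
#'   slot-to-gingiva distance), and `sigma_observed` (gf/mm2).
#' @param fixed Optional named numeric vector pinning weights at known
#'   values, e.g. `c(delta1 = 0, delta2 = 0)` to calibrate `delta0` alone
#'   from a single observation.
#' @param refine Refine against the coefficient-scale objective (default
#'   `TRUE`); `FALSE` keeps the linearized denominator-space solution.
#' @return An object of class `delta_calibration`: `deltas` (a
#'   [delta_coefficients()]), `fitted` (predicted sigma per observation),
#'   `residuals` (observed minus fitted), `rmse`, and `rank_deficient`.
#' @examples
#' g <- list(tooth_geometry(31, 5, 4.5, 21.5),
#'           tooth_geometry(30, 5, 4.5, 20.5),
#'           tooth_geometry(24, 4, 4, 16))
#' truth <- delta_coefficients(0.5, 0.2, 0.1)
#' obs <- do.call(rbind, lapply(g, function(gi) {
#'   s <- compute_sigma(220, 150, gi, truth)
#'   data.frame(force = 220, sc = 150, sf = gi$gingiva_to_apex,
#'              s_tilde = gi$slot_to_gingiva, sigma_observed = s$sigma)
#' }))
#' calibrate_deltas(obs)$deltas
#' @export
calibrate_deltas <- function(observations, fixed = NULL, refine = TRUE) {
  need <- c("force", "sc", "sf", "s_tilde", "sigma_observed")
  if (!is.data.frame(observations) || nrow(observations) < 1 ||
      !all(need %in% names(observations))) {
    stop(sprintf("observations must be a data frame with columns %s",
                 paste(need, collapse = ", ")), call. = FALSE)
  }
  if (any(observations$sigma_observed <= 0) || any(observations$force <= 0) ||
      any(observations$sc <= 0)) {
    stop("observations need strictly positive force, sc and sigma_observed",
         call. = FALSE)
  }
  A <- denominator_basis(observations$sf, observations$s_tilde)
  colnames(A) <- c("delta0", "delta1", "delta2")
  b <- invert_denominator(observations$sigma_observed, observations$force,
                          observations$sc)

  par <- c(delta0 = 0, delta1 = 0, delta2 = 0)
  free <- setdiff(names(par), names(fixed))
  if (!is.null(fixed)) {
    if (!all(names(fixed) %in% names(par))) {
      stop("fixed must name a subset of delta0, delta1, delta2", call. = FALSE)
    }
    par[names(fixed)] <- fixed
    b <- drop(b - A[, names(fixed), drop = FALSE] %*% fixed)
  }
  if (length(free) == 0) stop("no free delta coefficients to calibrate", call. = FALSE)
  Af <- A[, free, drop = FALSE]

  rank_deficient <- qr(Af)$rank < length(free)
  if (rank_deficient) {
    warning("rank-deficient calibration design (fewer distinct root geometries than free weights); returning the minimum-norm non-negative solution",
            call. = FALSE)
    par[free] <- pmax(0, drop(MASS::ginv(Af) %*% b))
  } else {
    par[free] <- nnls_small(Af, b)
  }

  sigma_of <- function(p) {
    drop(observations$force * observations$sc / (A %*% p))
  }
  if (refine && !rank_deficient) {
    obj <- function(pf) {
      p <- par
      p[free] <- pf
      den <- drop(A %*% p)
      # large finite penalty (not Inf): keeps box-constrained quasi-Newton happy
      if (any(den <= 0)) return(1e6 * (1 + sum(observations$sigma_observed^2)))
      sum((observations$sigma_observed - observations$force * observations$sc / den)^2)
    }
    start_obj <- obj(par[free])
    if (is.finite(start_obj) && start_obj > 0) {
      opt <- stats::optim(par[free], obj, method = "L-BFGS-B",
                          lower = rep(0, length(free)),
                          control = list(factr = 1e4, maxit = 500))
      if (opt$value <= start_obj) par[free] <- opt$par
    }
  }

  fitted <- sigma_of(par)
  res <- observations$sigma_observed - fitted
  structure(list(
    deltas = delta_coefficients(unname(par["delta0"]), unname(par["delta1"]),
                                unname(par["delta2"])),
    fitted = fitted, residuals = res,
    rmse = sqrt(mean(res^2)), rank_deficient = rank_deficient,
    n_obs = nrow(observations)),
    class = "delta_calibration")
}

#' @export
print.delta_calibration <- function(x, ...) {
  cat(sprintf("<delta_calibration> %d observation(s), RMSE %.4g gf/mm2%s\n",
              x$n_obs, x$rmse, if (x$rank_deficient) " [rank-deficient]" else ""))
  print(x$deltas)
  invisible(x)
}
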