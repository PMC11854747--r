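#' Specification of a synthetic clinical cohort
#'
#' Defines the sampling distributions for a cohort of synthetic tooth
#' records with known ground truth. Defaults emulate the three-canine
#' distal-retraction study conditions: geometry ranges bracketing the
#' observed canines, rotation centers well beyond the apex (roto-translation
#' regime), crown moves of 0.6-1.0 mm per 28-day cycle, day-1 chain forces
#' of 200-230 gf, per-day decay constants spanning the observed two-point
#' fits, and 0.05 mm Gaussian displacement noise.
#'
#' @param n_teeth Number of teeth (default 3).
#' @param n_cycles Activation cycles per tooth (default 2).
#' @param slot_to_cusp_range,slot_to_gingiva_range,gingiva_to_apex_range
#'   Uniform sampling ranges (mm) for the three partial lengths; the total
#'   length is their exact sum.
#' @param sc_range True rotation-center range (mm from the bracket slot).
#' @param crown_move_range True crown displacement range (mm per cycle).
#' @param delta_truth Ground-truth denominator weights
#'   (a [delta_coefficients()]).
#' @param force_range Day-1 chain force range (gf).
#' @param decay_k_range Exponential decay-constant range (per day).
#' @param noise_sd_move Gaussian SD of displacement measurement noise (mm).
#' @param noise_sd_force Gaussian SD of force measurement noise (gf).
#' @param clinical_resolution Round displacements to 0.1 mm, the resolution
#'   of clinical measurement (default `FALSE`).
#' @param cycle_length Cycle length (days).
#' @param seed Integer seed; generation is a pure function of the spec.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_teeth = 3, n_cycles = 2,
                        slot_to_cusp_range = c(4.5, 5),
                        slot_to_gingiva_range = c(4, 5),
                        gingiva_to_apex_range = c(20, 22),
                        sc_range = c(80, 250),
                        crown_move_range = c(0.6, 1),
                        delta_truth = delta_coefficients(1, 1, 1),
                        force_range = c(200, 230),
                        decay_k_range = c(0.055, 0.07),
                        noise_sd_move = 0.05,
                        noise_sd_force = 5,
                        clinical_resolution = FALSE,
                        cycle_length = 28,
                        seed = 1L) {
  rngs <- list(slot_to_cusp_range = slot_to_cusp_range,
               slot_to_gingiva_range = slot_to_gingiva_range,
               gingiva_to_apex_range = gingiva_to_apex_range,
               sc_range = sc_range, crown_move_range = crown_move_range,
               force_range = force_range, decay_k_range = decay_k_range)
  for (nm in names(rngs)) {
    r <- rngs[[nm]]
    if (length(r) != 2 || !all(is.finite(r)) || r[1] > r[2]) {
      stop(sprintf("%s must be an ordered (min, max) pair", nm), call. = FALSE)
    }
  }
  geom_rngs <- rngs[c("slot_to_cusp_range", "slot_to_gingiva_range",
                      "gingiva_to_apex_range")]
  if (any(vapply(geom_rngs, function(r) r[1] <= 0, logical(1)))) {
    stop("geometry ranges must produce strictly positive lengths", call. = FALSE)
  }
  if (rngs$force_range[1] <= 0 || rngs$decay_k_range[1] < 0 ||
      rngs$crown_move_range[1] <= 0) {
    stop("forces and crown moves must be positive, decay constants non-negative",
         call. = FALSE)
  }
  stopifnot(n_teeth >= 1, n_cycles >= 1, noise_sd_move >= 0, noise_sd_force >= 0,
            cycle_length > 14)
  structure(c(list(n_teeth = as.integer(n_teeth), n_cycles = as.integer(n_cycles)),
              rngs,
              list(delta_truth = as_deltas(delta_truth),
                   noise_sd_move = noise_sd_move, noise_sd_force = noise_sd_force,
                   clinical_resolution = isTRUE(clinical_resolution),
                   cycle_length = cycle_length, seed = as.integer(seed))),
            class = "cohort_spec")
}

runif1 <- function(r) stats::runif(1, r[1], r[2])

#' Generate a synthetic cohort with known ground truth
#'
#' Forward model per tooth-cycle: a true rotation center and crown
#' displacement are drawn uniformly; the true apex displacement follows from
#' the forward kinematic relation ([predict_apex_movement()]); independent
#' Gaussian noise is added to both recorded displacements (optionally
#' rounded to 0.1 mm). Chain forces follow the exponential decay model with
#' a drawn day-1 force and decay constant, measured at day 1 and day 14 with
#' Gaussian noise, floored at 0.1 gf and capped so the day-14 reading never
#' exceeds the day-1 reading. Ground truth records the true center, the true
#' tissue-resistance coefficient (from the true day-1 force and
#' `delta_truth`) and the true movement class.
#'
#' Generation is a pure function of the spec: the same spec (including seed)
#' reproduces the cohort bit for bit, and the caller's RNG state is left
#' untouched.
#'
#' @param spec A [cohort_spec()].
#' @return List with `cohort` (list of [tooth_record()]) and `truth`
#'   (data.frame: `tooth_id`, `cycle_id`, `sc_true_mm`, `crown_true_mm`,
#'   `apex_true_mm`, `u0_true_gf`, `decay_k_true`, `sigma_true_gf_mm2`,
#'   `class_true`).
#' @examples
#' g <- generate_cohort(cohort_spec(n_teeth = 2, seed = 42))
#' run_analysis(g$cohort)
#' @export
generate_cohort <- function(spec) {
  if (!inherits(spec, "cohort_spec")) stop("spec must be a cohort_spec", call. = FALSE)
  old_seed <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(spec$seed)

  cohort <- vector("list", spec$n_teeth)
  truth <- vector("list", spec$n_teeth)
  for (i in seq_len(spec$n_teeth)) {
    stc <- runif1(spec$slot_to_cusp_range)
    stg <- runif1(spec$slot_to_gingiva_range)
    gta <- runif1(spec$gingiva_to_apex_range)
    geom <- tooth_geometry(stc + stg + gta, stc, stg, gta, tol = 0)

    cycles <- vector("list", spec$n_cycles)
    trows <- vector("list", spec$n_cycles)
    for (k in seq_len(spec$n_cycles)) {
      cid <- paste0("CA", k)
      sc_true <- runif1(spec$sc_range)
      crown_true <- runif1(spec$crown_move_range)
      apex_true <- predict_apex_movement(crown_true, sc_true, geom)
      crown_obs <- crown_true + stats::rnorm(1, 0, spec$noise_sd_move)
      apex_obs <- apex_true + stats::rnorm(1, 0, spec$noise_sd_move)
      if (spec$clinical_resolution) {
        crown_obs <- round(crown_obs, 1)
        apex_obs <- round(apex_obs, 1)
      }
      u0_true <- runif1(spec$force_range)
      k_true <- runif1(spec$decay_k_range)
      f1 <- max(0.1, u0_true + stats::rnorm(1, 0, spec$noise_sd_force))
      f14 <- u0_true * exp(-k_true * 13) + stats::rnorm(1, 0, spec$noise_sd_force)
      f14 <- min(max(0.1, f14), f1)
      cycles[[k]] <- list(
        force = force_series(cid, c(1, 14), c(f1, f14),
                             cycle_length = spec$cycle_length),
        movement = cycle_movement(crown_obs, apex_obs, cid))
      cls_true <- classify_movement(crown_true, apex_true, geom)
      trows[[k]] <- data.frame(
        tooth_id = sprintf("S%03d", i), cycle_id = cid,
        sc_true_mm = sc_true, crown_true_mm = crown_true,
        apex_true_mm = apex_true, u0_true_gf = u0_true, decay_k_true = k_true,
        sigma_true_gf_mm2 = compute_sigma(u0_true, sc_true, geom,
                                          spec$delta_truth)$sigma,
        class_true = cls_true$kind, stringsAsFactors = FALSE)
    }
    cohort[[i]] <- tooth_record(sprintf("S%03d", i), geom, cycles)
    truth[[i]] <- do.call(rbind, trows)
  }
  truth <- do.call(rbind, truth)
  rownames(truth) <- NULL
  list(cohort = cohort, truth = truth)
}
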