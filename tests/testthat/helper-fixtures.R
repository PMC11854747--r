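# Shared fixtures, built in code.

# Geometries of the three observed canines.
geom_c1 <- function() tooth_geometry(31, 5, 4.5, 21.5)
geom_c2 <- function() tooth_geometry(30, 5, 4.5, 20.5)
geom_c3 <- function() tooth_geometry(29.5, 4.5, 4.5, 20.5)

# The example cohort rebuilt programmatically (independent of the shipped CSV).
build_example_cohort <- function() {
  mk <- function(id, sex, geom, f, mv) {
    cycles <- lapply(1:2, function(k) list(
      force = force_series(paste0("CA", k), c(1, 14), f[[k]]),
      movement = cycle_movement(mv[[k]][1], mv[[k]][2], paste0("CA", k))))
    tooth_record(id, geom, cycles, patient_sex = sex)
  }
  list(
    mk("C1", "male", geom_c1(), list(c(220, 100), c(210, 90)),
       list(c(0.8, 0.7), c(0.8, 0.6))),
    mk("C2", "male", geom_c2(), list(c(230, 110), c(210, 85)),
       list(c(0.8, 0.7), c(0.9, 0.6))),
    mk("C3", "female", geom_c3(), list(c(210, 90), c(200, 80)),
       list(c(0.9, 0.7), c(0.9, 0.6))))
}

# Synthetic delta-calibration observations from known truth weights.
make_sigma_obs <- function(geometries, forces, scs, deltas) {
  do.call(rbind, Map(function(g, u, sc) {
    data.frame(force = u, sc = sc, sf = g$gingiva_to_apex,
               s_tilde = g$slot_to_gingiva,
               sigma_observed = compute_sigma(u, sc, g, deltas)$sigma)
  }, geometries, forces, scs))
}

expect_rel_equal <- function(actual, expected, rel_tol) {
  expect_true(all(abs(actual - expected) <= rel_tol * abs(expected)),
              label = sprintf("max rel err %.3g vs tol %.3g",
                              max(abs(actual - expected) / abs(expected)), rel_tol))
}
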