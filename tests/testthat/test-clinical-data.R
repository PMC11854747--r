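test_that("tooth geometry enforces positivity and length decomposition", {
  g <- tooth_geometry(31, 5, 4.5, 21.5)
  expect_s3_class(g, "tooth_geometry")
  # all three observed canines decompose exactly
  expect_equal(with(geom_c1(), slot_to_cusp + slot_to_gingiva + gingiva_to_apex), 31)
  expect_equal(with(geom_c2(), slot_to_cusp + slot_to_gingiva + gingiva_to_apex), 30)
  expect_equal(with(geom_c3(), slot_to_cusp + slot_to_gingiva + gingiva_to_apex), 29.5)

  expect_error(tooth_geometry(31, -5, 4.5, 21.5), "positive")
  expect_error(tooth_geometry(31, 5, 4.5, 10), "decomposition")
  # tolerance is configurable
  expect_silent(tooth_geometry(31, 5, 4.5, 21.2, tol = 0.5))
  expect_error(tooth_geometry(31, 5, 4.5, 21.2, tol = 0.1), "decomposition")
})

test_that("force series enforces day ordering, range and positivity", {
  fs <- force_series("CA1", c(1, 14), c(220, 100))
  expect_equal(fs$cycle_length, 28)
  expect_error(force_series("CA1", c(14, 1), c(100, 220)), "increasing")
  expect_error(force_series("CA1", c(1, 30), c(220, 100)), "within")
  expect_error(force_series("CA1", c(1, 14), c(220, -5)), "positive")
  expect_error(force_series("CA1", c(0.5, 14), c(220, 100)), "within")
})

test_that("cycle movement and tooth record validate their parts", {
  expect_error(cycle_movement(NA, 0.7, "CA1"), "finite")
  g <- geom_c1()
  cyc <- list(list(force = force_series("CA1", c(1, 14), c(220, 100)),
                   movement = cycle_movement(0.8, 0.7, "CA1")))
  expect_s3_class(tooth_record("C1", g, cyc, "male"), "tooth_record")
  expect_error(tooth_record("C1", g, list()), "at least one")
  expect_error(tooth_record("C1", g, list(list(force = 1, movement = 2))),
               "force_series")
})

test_that("reading the bundled CSV reproduces the example records", {
  cohort <- read_cohort(canine_cohort_path())
  expect_length(cohort, 3)
  c1 <- cohort[[1]]
  expect_equal(c1$tooth_id, "C1")
  expect_equal(c1$patient_sex, "male")
  expect_equal(unclass(c1$geometry),
               list(total_length = 31, slot_to_cusp = 5,
                    slot_to_gingiva = 4.5, gingiva_to_apex = 21.5))
  expect_length(c1$cycles, 2)
  expect_equal(c1$cycles[[1]]$force$force, c(220, 100))
  expect_equal(c1$cycles[[1]]$movement$crown_move, 0.8)
  expect_equal(c1$cycles[[2]]$movement$apex_move, 0.6)
})

test_that("cohort CSV reader reports schema and validation problems by name", {
  bad <- tempfile(fileext = ".csv")
  on.exit(unlink(bad))

  writeLines("tooth_id,total_length,slot_to_cusp,slot_to_gingiva", bad)
  expect_error(read_cohort(bad), "no records")

  write.csv(data.frame(tooth_id = "T1", total_length = 31, slot_to_cusp = 5,
                       slot_to_gingiva = 4.5, fi1 = 220), bad, row.names = FALSE)
  expect_error(read_cohort(bad), "gingiva_to_apex")

  write.csv(data.frame(tooth_id = "T1", total_length = 31, slot_to_cusp = 5,
                       slot_to_gingiva = 4.5, gingiva_to_apex = 21.5),
            bad, row.names = FALSE)
  expect_error(read_cohort(bad), "fi1")

  # invariant violation names the tooth and the rule
  write.csv(data.frame(tooth_id = "T9", total_length = 31, slot_to_cusp = 5,
                       slot_to_gingiva = 4.5, gingiva_to_apex = 10,
                       fi1 = 220, fint1 = 100, y_crown_ca1 = 0.8,
                       y_apex_ca1 = 0.7), bad, row.names = FALSE)
  expect_error(read_cohort(bad), "T9.*decomposition")

  # duplicated tooth ids rejected at cohort level
  write.csv(data.frame(tooth_id = c("T1", "T1"), total_length = 31,
                       slot_to_cusp = 5, slot_to_gingiva = 4.5,
                       gingiva_to_apex = 21.5, fi1 = 220, fint1 = 100,
                       y_crown_ca1 = 0.8, y_apex_ca1 = 0.7),
            bad, row.names = FALSE)
  expect_error(read_cohort(bad), "duplicate")
})

test_that("cohort round-trips through CSV and JSON identically", {
  cohort <- build_example_cohort()
  for (ext in c(".csv", ".json")) {
    p <- tempfile(fileext = ext)
    write_cohort(cohort, p)
    back <- read_cohort(p)
    expect_equal(back, cohort, ignore_attr = FALSE)
    unlink(p)
  }
})

test_that("JSON cohort format carries force series beyond two measurements", {
  rec <- tooth_record("X1", geom_c1(), list(list(
    force = force_series("CA1", c(1, 7, 14, 21), c(220, 150, 100, 80)),
    movement = cycle_movement(0.8, 0.7, "CA1"))))
  p <- tempfile(fileext = ".json")
  on.exit(unlink(p))
  write_cohort(list(rec), p)
  back <- read_cohort(p)
  expect_equal(back[[1]]$cycles[[1]]$force$day, c(1, 7, 14, 21))
  # the wide CSV schema cannot hold it
  expect_error(write_cohort(list(rec), tempfile(fileext = ".csv")), "day-1 and day-14")
})

test_that("analysis tables round-trip at their printed precision", {
  res <- run_analysis(build_example_cohort())
  for (ext in c(".csv", ".json")) {
    p <- tempfile(fileext = ext)
    write_analysis(res, p)
    back <- read_analysis(p)
    expect_equal(back$sc_mm, round(res$sc_mm, 2))
    expect_equal(back$sigma_gf_mm2, round(res$sigma_gf_mm2, 4))
    expect_equal(back$movement_class, res$movement_class)
    expect_equal(back$resistance_class, res$resistance_class)
    unlink(p)
  }
  expect_error(write_analysis(res[0, ], tempfile(fileext = ".csv")), "non-empty")
})

test_that("analysis round trip holds for a synthetic cohort", {
  g <- generate_cohort(cohort_spec(n_teeth = 8, seed = 21))
  res <- suppressWarnings(run_analysis(g$cohort))
  p <- tempfile(fileext = ".csv")
  on.exit(unlink(p))
  write_analysis(res, p)
  back <- read_analysis(p)
  expect_equal(back$sc_mm, round(res$sc_mm, 2))
  expect_equal(back$sigma_gf_mm2, round(res$sigma_gf_mm2, 4))
})
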