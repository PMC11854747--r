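#' Tooth geometry: the four axial lengths of one tooth
#'
#' The tooth long axis is parameterized from the bracket slot, positive
#' toward the apex: the cusp tip sits at `-slot_to_cusp` and the apex at
#' `gingiva_to_apex + slot_to_gingiva`. The three partial lengths must sum to
#' the total crown-tip-to-apex length within `tol`.
#'
#' @param total_length Total tooth length, cusp tip to apex (mm).
#' @param slot_to_cusp Bracket slot to cusp tip (mm).
#' @param slot_to_gingiva Bracket slot to gingival margin (mm).
#' @param gingiva_to_apex Gingival margin to apex (mm).
#' @param tol Allowed absolute mismatch between `total_length` and the sum of
#'   the three partial lengths (mm). Default 0.5, the scale of clinical
#'   caliper error.
#' @return An object of class `tooth_geometry`.
#' @examples
#' tooth_geometry(31, 5, 4.5, 21.5)
#' @export
tooth_geometry <- function(total_length, slot_to_cusp, slot_to_gingiva,
                           gingiva_to_apex, tol = 0.5) {
  lens <- c(total_length = total_length, slot_to_cusp = slot_to_cusp,
            slot_to_gingiva = slot_to_gingiva, gingiva_to_apex = gingiva_to_apex)
  if (!all(is.finite(lens)) || any(lens <= 0)) {
    stop("all four tooth lengths must be finite and strictly positive", call. = FALSE)
  }
  mismatch <- abs(slot_to_cusp + slot_to_gingiva + gingiva_to_apex - total_length)
  if (mismatch > tol) {
    stop(sprintf(
      "length decomposition violated: slot_to_cusp + slot_to_gingiva + gingiva_to_apex differs from total_length by %.4g mm (tolerance %.4g mm)",
      mismatch, tol), call. = FALSE)
  }
  structure(
    list(total_length = total_length, slot_to_cusp = slot_to_cusp,
         slot_to_gingiva = slot_to_gingiva, gingiva_to_apex = gingiva_to_apex),
    class = "tooth_geometry")
}

#' @export
print.tooth_geometry <- function(x, ...) {
  cat(sprintf(
    "<tooth_geometry> total %.4g mm (slot->cusp %.4g, slot->gingiva %.4g, gingiva->apex %.4g)\n",
    x$total_length, x$slot_to_cusp, x$slot_to_gingiva, x$gingiva_to_apex))
  invisible(x)
}

# Signed position of the apex along the long axis, measured from the slot.
apex_position <- function(geometry) {
  geometry$gingiva_to_apex + geometry$slot_to_gingiva
}

#' Timed force measurements of one elastomeric chain over one activation cycle
#'
#' @param cycle_id Cycle label, e.g. `"CA1"`.
#' @param day Measurement days since cycle start, strictly increasing, within
#'   `[1, cycle_length]`. Day 1 is the chain-application day.
#' @param force Measured forces (grams-force), strictly positive, one per day.
#' @param cycle_length Cycle length in days (default 28, one activation
#'   cycle between chain replacements).
#' @return An object of class `force_series`.
#' @examples
#' force_series("CA1", day = c(1, 14), force = c(220, 100))
#' @export
force_series <- function(cycle_id, day, force, cycle_length = 28) {
  if (length(day) != length(force) || length(day) < 1) {
    stop("day and force must be equal-length, non-empty vectors", call. = FALSE)
  }
  if (!all(is.finite(day)) || any(diff(day) <= 0)) {
    stop("measurement days must be finite and strictly increasing", call. = FALSE)
  }
  if (any(day < 1) || any(day > cycle_length)) {
    stop(sprintf("measurement days must lie within [1, %g]", cycle_length), call. = FALSE)
  }
  if (!all(is.finite(force)) || any(force <= 0)) {
    stop("forces must be finite and strictly positive", call. = FALSE)
  }
  structure(list(cycle_id = as.character(cycle_id), day = as.numeric(day),
                 force = as.numeric(force), cycle_length = cycle_length),
            class = "force_series")
}

#' @export
print.force_series <- function(x, ...) {
  cat(sprintf("<force_series> %s (%g-day cycle): %s\n", x$cycle_id, x$cycle_length,
              paste(sprintf("day %g: %g gf", x$day, x$force), collapse = ", ")))
  invisible(x)
}

#' Crown-tip and apex displacements of one tooth over one activation cycle
#'
#' Sign convention: positive = distal, i.e. the direction of the applied
#' retraction force.
#'
#' @param crown_move Cusp-tip displacement over the cycle (mm).
#' @param apex_move Apex displacement over the cycle (mm).
#' @param cycle_id Cycle label.
#' @return An object of class `cycle_movement`.
#' @export
cycle_movement <- function(crown_move, apex_move, cycle_id) {
  if (!is.finite(crown_move) || !is.finite(apex_move)) {
    stop("crown and apex displacements must be finite", call. = FALSE)
  }
  structure(list(crown_move = crown_move, apex_move = apex_move,
                 cycle_id = as.character(cycle_id)),
            class = "cycle_movement")
}

#' One tooth's clinical record: geometry plus per-cycle forces and movements
#'
#' @param tooth_id Tooth label, unique within a cohort.
#' @param geometry A [tooth_geometry()].
#' @param cycles List of cycles; each element a list with components `force`
#'   (a [force_series()]) and `movement` (a [cycle_movement()]).
#' @param patient_sex `"male"`, `"female"` or `"unknown"`.
#' @return An object of class `tooth_record`.
#' @export
tooth_record <- function(tooth_id, geometry, cycles, patient_sex = "unknown") {
  patient_sex <- match.arg(patient_sex, c("male", "female", "unknown"))
  if (!inherits(geometry, "tooth_geometry")) {
    stop("geometry must be a tooth_geometry", call. = FALSE)
  }
  if (!is.list(cycles) || length(cycles) < 1) {
    stop(sprintf("tooth %s: at least one activation cycle is required", tooth_id),
         call. = FALSE)
  }
  for (cy in cycles) {
    if (!inherits(cy$force, "force_series") || !inherits(cy$movement, "cycle_movement")) {
      stop(sprintf("tooth %s: each cycle needs a force_series and a cycle_movement",
                   tooth_id), call. = FALSE)
    }
  }
  structure(list(tooth_id = as.character(tooth_id), patient_sex = patient_sex,
                 geometry = geometry, cycles = cycles),
            class = "tooth_record")
}

#' @export
print.tooth_record <- function(x, ...) {
  cat(sprintf("<tooth_record> %s (%s), %d cycle(s), total length %.4g mm\n",
              x$tooth_id, x$patient_sex, length(x$cycles), x$geometry$total_length))
  invisible(x)
}

validate_cohort <- function(records) {
  if (length(records) == 0) stop("no records", call. = FALSE)
  ids <- vapply(records, function(r) r$tooth_id, character(1))
  if (anyDuplicated(ids)) {
    stop(sprintf("duplicate tooth_id in cohort: %s",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")), call. = FALSE)
  }
  invisible(records)
}

# Fixed wide-CSV schema: one row per tooth; per-cycle column quadruples
# fi<k>, fint<k>, y_crown_ca<k>, y_apex_ca<k> hold the day-1 force, day-14
# force and the two displacements of activation cycle k.
.geom_cols <- c("total_length", "slot_to_cusp", "slot_to_gingiva", "gingiva_to_apex")

#' Read a clinical cohort file
#'
#' CSV files use a wide schema (one row per tooth): `tooth_id`, optionally
#' `patient_sex`, the geometry columns `total_length`, `slot_to_cusp`,
#' `slot_to_gingiva`, `gingiva_to_apex`, and per activation cycle k the
#' columns `fi<k>` (day-1 force, gf), `fint<k>` (day-14 force, gf),
#' `y_crown_ca<k>` and `y_apex_ca<k>` (displacements, mm). JSON files hold an
#' array of records with nested `geometry` and `cycles` (each cycle with
#' `cycle_id`, `measurements` of `{day, force}`, `crown_move`, `apex_move`),
#' which permits force series with more than two measurement days.
#'
#' @param path File path.
#' @param format `"csv"` or `"json"`; default guessed from the extension.
#' @param length_tol Geometry decomposition tolerance in mm, see
#'   [tooth_geometry()].
#' @return List of [tooth_record()] objects, in file order.
#' @export
read_cohort <- function(path, format = c("auto", "csv", "json"), length_tol = 0.5) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  if (!file.exists(path)) stop(sprintf("cohort file not found: %s", path), call. = FALSE)
  records <- switch(format,
    csv = read_cohort_csv(path, length_tol),
    json = read_cohort_json(path, length_tol))
  validate_cohort(records)
}

read_cohort_csv <- function(path, length_tol) {
  df <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE),
    error = function(e) stop("no records (empty or unreadable cohort file)", call. = FALSE))
  if (nrow(df) == 0) stop("no records", call. = FALSE)

  need <- c("tooth_id", .geom_cols)
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop(sprintf("cohort schema error: missing column(s) %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  cyc_idx <- sort(as.integer(sub("^fi", "", grep("^fi[0-9]+$", names(df), value = TRUE))))
  if (length(cyc_idx) == 0) {
    stop("cohort schema error: missing column(s) fi1 (no activation-cycle columns found)",
         call. = FALSE)
  }
  for (k in cyc_idx) {
    kneed <- c(paste0("fint", k), paste0("y_crown_ca", k), paste0("y_apex_ca", k))
    kmiss <- setdiff(kneed, names(df))
    if (length(kmiss)) {
      stop(sprintf("cohort schema error: missing column(s) %s",
                   paste(kmiss, collapse = ", ")), call. = FALSE)
    }
  }

  lapply(seq_len(nrow(df)), function(i) {
    row <- df[i, ]
    id <- as.character(row$tooth_id)
    geom <- tryCatch(
      tooth_geometry(row$total_length, row$slot_to_cusp, row$slot_to_gingiva,
                     row$gingiva_to_apex, tol = length_tol),
      error = function(e) stop(sprintf("tooth %s: %s", id, conditionMessage(e)),
                               call. = FALSE))
    cycles <- lapply(cyc_idx, function(k) {
      cid <- paste0("CA", k)
      fs <- tryCatch(
        force_series(cid, day = c(1, 14),
                     force = c(row[[paste0("fi", k)]], row[[paste0("fint", k)]])),
        error = function(e) stop(sprintf("tooth %s, cycle %s: %s", id, cid,
                                         conditionMessage(e)), call. = FALSE))
      mv <- tryCatch(
        cycle_movement(row[[paste0("y_crown_ca", k)]], row[[paste0("y_apex_ca", k)]], cid),
        error = function(e) stop(sprintf("tooth %s, cycle %s: %s", id, cid,
                                         conditionMessage(e)), call. = FALSE))
      list(force = fs, movement = mv)
    })
    sex <- if ("patient_sex" %in% names(df)) as.character(row$patient_sex) else "unknown"
    tooth_record(id, geom, cycles, patient_sex = sex)
  })
}

read_cohort_json <- function(path, length_tol) {
  recs <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (length(recs) == 0) stop("no records", call. = FALSE)
  lapply(recs, function(r) {
    g <- r$geometry
    geom <- tooth_geometry(g$total_length, g$slot_to_cusp, g$slot_to_gingiva,
                           g$gingiva_to_apex, tol = length_tol)
    cycles <- lapply(r$cycles, function(cy) {
      days <- vapply(cy$measurements, function(m) m$day, numeric(1))
      forces <- vapply(cy$measurements, function(m) m$force, numeric(1))
      cl <- if (is.null(cy$cycle_length)) 28 else cy$cycle_length
      list(force = force_series(cy$cycle_id, days, forces, cycle_length = cl),
           movement = cycle_movement(cy$crown_move, cy$apex_move, cy$cycle_id))
    })
    sex <- if (is.null(r$patient_sex)) "unknown" else r$patient_sex
    tooth_record(r$tooth_id, geom, cycles, patient_sex = sex)
  })
}

#' Write a clinical cohort file
#'
#' Inverse of [read_cohort()]: `read_cohort(write_cohort(x, p), p)` returns
#' the cohort unchanged. CSV output requires every cycle to carry exactly the
#' day-1/day-14 measurement pair of the wide schema; JSON handles arbitrary
#' force series.
#'
#' @param records List of [tooth_record()] objects.
#' @param path Output path.
#' @param format `"csv"` or `"json"`; default guessed from the extension.
#' @export
write_cohort <- function(records, path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  validate_cohort(records)
  if (format == "json") {
    out <- lapply(records, function(r) {
      list(tooth_id = r$tooth_id, patient_sex = r$patient_sex,
           geometry = unclass(r$geometry),
           cycles = lapply(r$cycles, function(cy) list(
             cycle_id = cy$force$cycle_id,
             cycle_length = cy$force$cycle_length,
             measurements = Map(function(d, f) list(day = d, force = f),
                                cy$force$day, cy$force$force),
             crown_move = cy$movement$crown_move,
             apex_move = cy$movement$apex_move)))
    })
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
    return(invisible(path))
  }
  n_cyc <- vapply(records, function(r) length(r$cycles), integer(1))
  rows <- lapply(records, function(r) {
    base <- data.frame(tooth_id = r$tooth_id, patient_sex = r$patient_sex,
                       total_length = r$geometry$total_length,
                       slot_to_cusp = r$geometry$slot_to_cusp,
                       slot_to_gingiva = r$geometry$slot_to_gingiva,
                       gingiva_to_apex = r$geometry$gingiva_to_apex,
                       stringsAsFactors = FALSE)
    for (k in seq_along(r$cycles)) {
      cy <- r$cycles[[k]]
      if (!identical(cy$force$day, c(1, 14))) {
        stop("CSV cohort output needs exactly day-1 and day-14 force measurements per cycle; use format = \"json\"",
             call. = FALSE)
      }
      base[[paste0("fi", k)]] <- cy$force$force[1]
      base[[paste0("fint", k)]] <- cy$force$force[2]
      base[[paste0("y_crown_ca", k)]] <- cy$movement$crown_move
      base[[paste0("y_apex_ca", k)]] <- cy$movement$apex_move
    }
    base
  })
  if (length(unique(n_cyc)) > 1) {
    stop("CSV cohort output needs the same number of cycles for every tooth; use format = \"json\"",
         call. = FALSE)
  }
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write an analysis results table
#'
#' Emits one row per tooth-cycle with the rotation center printed to 2
#' decimals and the tissue-resistance coefficient to 4 decimals (the
#' precision the quantities are clinically reported at). [read_analysis()]
#' reads the file back.
#'
#' @param results A `retraction_analysis` data.frame from [run_analysis()].
#' @param path Output path.
#' @param format `"csv"` or `"json"`; default guessed from the extension.
#' @export
write_analysis <- function(results, path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  if (!is.data.frame(results) || nrow(results) == 0) {
    stop("results must be a non-empty analysis table", call. = FALSE)
  }
  out <- data.frame(
    tooth_id = results$tooth_id,
    cycle_id = results$cycle_id,
    sc_mm = ifelse(results$is_infinite, NA_character_, sprintf("%.2f", results$sc_mm)),
    sigma_gf_mm2 = ifelse(is.na(results$sigma_gf_mm2), NA_character_,
                          sprintf("%.4f", results$sigma_gf_mm2)),
    movement_class = results$movement_class,
    resistance_class = results$resistance_class,
    stringsAsFactors = FALSE)
  if (format == "json") {
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, na = "null")
  } else {
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  }
  invisible(path)
}

#' Read back an analysis results table written by [write_analysis()]
#'
#' @param path File path.
#' @param format `"csv"` or `"json"`; default guessed from the extension.
#' @return Data frame with numeric `sc_mm` and `sigma_gf_mm2` columns.
#' @export
read_analysis <- function(path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  df <- if (format == "json") {
    as.data.frame(jsonlite::fromJSON(path))
  } else {
    utils::read.csv(path, stringsAsFactors = FALSE)
  }
  df$sc_mm <- as.numeric(df$sc_mm)
  df$sigma_gf_mm2 <- as.numeric(df$sigma_gf_mm2)
  df
}

#' The three-canine distal-retraction example dataset
#'
#' Clinical measurements from the distal retraction of three maxillary
#' canines (two patients) over two 28-day activation cycles: tooth geometry
#' from intraoral and radiographic measurement, elastomeric-chain forces at
#' day 1 and day 14 of each cycle, and crown-tip/apex displacements per cycle
#' measured against temporary anchorage devices.
#'
#' @return List of three [tooth_record()] objects (C1, C2, C3).
#' @examples
#' cohort <- canine_cohort()
#' cohort[[1]]
#' @export
canine_cohort <- function() {
  read_cohort(canine_cohort_path(), format = "csv")
}

#' @rdname canine_cohort
#' @export
canine_cohort_path <- function() {
  system.file("extdata", "canine_retraction.csv", package = "orthoretract",
              mustWork = TRUE)
}
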