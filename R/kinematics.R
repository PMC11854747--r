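#' Center of rotation of a planar tooth movement
#'
#' Position of the instantaneous rotation center along the tooth long axis,
#' measured from the bracket slot and positive toward (and beyond) the apex.
#' Pure translation is represented by an explicit `is_infinite` flag rather
#' than a sentinel value.
#'
#' @param sc Signed distance from the bracket slot (mm); `NA` when infinite.
#' @param is_infinite `TRUE` for pure translation (center at infinity).
#' @return An object of class `rotation_center`.
#' @export
rotation_center <- function(sc, is_infinite = FALSE) {
  if (is_infinite) {
    sc <- NA_real_
  } else if (!is.finite(sc)) {
    stop("a finite rotation center needs a finite sc", call. = FALSE)
  }
  structure(list(sc = sc, is_infinite = is_infinite), class = "rotation_center")
}

#' @export
print.rotation_center <- function(x, ...) {
  if (x$is_infinite) cat("<rotation_center> at infinity (pure translation)\n")
  else cat(sprintf("<rotation_center> sc = %.4g mm from bracket slot\n", x$sc))
  invisible(x)
}

as_sc <- function(sc) {
  if (inherits(sc, "rotation_center")) return(sc)
  rotation_center(sc)
}

#' Estimate the rotation center from crown and apex displacements
#'
#' For a rigid planar movement of the tooth, the rotation center sc along the
#' long axis satisfies
#' \deqn{s_c = \frac{y_\beta \tilde{s}' + (s_f + \tilde{s})\, y_\alpha'}{y_\alpha' - y_\beta}}
#' where \eqn{y_\alpha'} is the crown-tip displacement, \eqn{y_\beta} the apex
#' displacement, \eqn{\tilde{s}'} the slot-to-cusp distance and
#' \eqn{s_f + \tilde{s}} the slot-to-apex distance. Equal displacements mean
#' the center is at infinity (pure translation).
#'
#' @param crown_move Cusp-tip displacement (mm), positive distal.
#' @param apex_move Apex displacement (mm), positive distal.
#' @param geometry A [tooth_geometry()].
#' @param epsilon Displacement difference (mm) below which the movement is
#'   treated as pure translation. Default 1e-9; raise it toward the
#'   measurement resolution (0.1 mm) to guard against absurd centers from
#'   near-equal clinical readings.
#' @return A [rotation_center()].
#' @examples
#' g <- tooth_geometry(31, 5, 4.5, 21.5)
#' compute_rotation_center(0.8, 0.7, g)  # 243 mm, far beyond the apex
#' @export
compute_rotation_center <- function(crown_move, apex_move, geometry,
                                    epsilon = 1e-9) {
  if (crown_move == 0 && apex_move == 0) stop("no movement", call. = FALSE)
  if (abs(crown_move - apex_move) < epsilon) {
    return(rotation_center(NA_real_, is_infinite = TRUE))
  }
  sc <- (apex_move * geometry$slot_to_cusp +
           apex_position(geometry) * crown_move) / (crown_move - apex_move)
  rotation_center(sc)
}

#' Predict apex displacement from crown displacement and a rotation center
#'
#' The forward kinematic relation
#' \deqn{y_\beta = \frac{s_c - (s_f + \tilde{s})}{s_c + \tilde{s}'}\, y_\alpha'}
#' i.e. the similar-triangles ratio of the apex and cusp lever arms about the
#' rotation center. A center at infinity gives \eqn{y_\beta = y_\alpha'}
#' (translation); a center at the apex gives \eqn{y_\beta = 0}; a center at
#' the cusp tip (\eqn{s_c = -\tilde{s}'}) is singular.
#'
#' @param crown_move Cusp-tip displacement (mm).
#' @param sc A [rotation_center()] or a finite numeric sc (mm).
#' @param geometry A [tooth_geometry()].
#' @return Apex displacement (mm).
#' @examples
#' g <- tooth_geometry(31, 5, 4.5, 21.5)
#' predict_apex_movement(0.8, 243, g)  # 0.7 mm
#' @export
predict_apex_movement <- function(crown_move, sc, geometry) {
  sc <- as_sc(sc)
  if (sc$is_infinite) return(crown_move)
  if (sc$sc == -geometry$slot_to_cusp) {
    stop("rotation center at the cusp tip: apex movement is singular there",
         call. = FALSE)
  }
  (sc$sc - apex_position(geometry)) / (sc$sc + geometry$slot_to_cusp) * crown_move
}

#' Classify a tooth movement from its crown and apex displacements
#'
#' Movement taxonomy: *rotation* (crown and apex move in opposite
#' directions; center within the tooth span), *roto-translation* (same
#' direction, apex lagging; center beyond the apex), *pure translation*
#' (equal displacements; center at infinity) and *apex pivot* (apex
#' stationary; center exactly at the apex). Same-direction movement with the
#' apex leading the crown lies outside the clinically expected regime
#' (center beyond the cusp tip) and is reported as roto-translation with
#' `improper = TRUE` and a warning.
#'
#' @inheritParams compute_rotation_center
#' @return An object of class `movement_class` with components `kind`
#'   (`rotation`, `roto_translation`, `pure_translation` or `apex_pivot`),
#'   `center_location` (`inside_tooth`, `outside_tooth` or `at_infinity`),
#'   `center` (the [rotation_center()]) and `improper`.
#' @examples
#' g <- tooth_geometry(31, 5, 4.5, 21.5)
#' classify_movement(0.8, 0.7, g)   # roto-translation, center outside
#' classify_movement(0.8, -0.2, g)  # rotation, center inside
#' @export
classify_movement <- function(crown_move, apex_move, geometry, epsilon = 1e-9) {
  if (crown_move == 0 && apex_move == 0) stop("no movement", call. = FALSE)
  center <- compute_rotation_center(crown_move, apex_move, geometry, epsilon)
  improper <- FALSE
  if (center$is_infinite) {
    kind <- "pure_translation"
    loc <- "at_infinity"
  } else {
    if (apex_move == 0) {
      kind <- "apex_pivot"
    } else if (crown_move == 0 || sign(crown_move) != sign(apex_move)) {
      kind <- "rotation"
    } else {
      kind <- "roto_translation"
      if (abs(apex_move) > abs(crown_move)) {
        improper <- TRUE
        warning("apex displacement exceeds crown displacement: rotation center lies beyond the cusp tip, outside the clinically expected regime",
                call. = FALSE)
      }
    }
    loc <- if (center$sc > 0 && center$sc < apex_position(geometry))
      "inside_tooth" else "outside_tooth"
  }
  structure(list(kind = kind, center_location = loc, center = center,
                 improper = improper),
            class = "movement_class")
}

#' @export
print.movement_class <- function(x, ...) {
  cat(sprintf("<movement_class> %s (center %s)%s\n", x$kind, x$center_location,
              if (x$improper) " [improper: apex leads crown]" else ""))
  invisible(x)
}
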