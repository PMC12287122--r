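#' Construct a patient-specific PICS coordinate frame
#'
#' Builds the rigid transform from scanner space to the 3D Pelvic Inclination
#' Correction System (PICS) from four bony landmarks: the inferior pubic
#' point and the sacrococcygeal articulation (midsagittal plane) and the two
#' ischial spines (axial plane). PICS axes: +x anterior-to-posterior, +y
#' superior-to-inferior, +z left-to-right, right-handed, with the origin
#' (0/0/0) at the inferior pubic point.
#'
#' The construction: the z axis is the unit vector from the left to the right
#' ischial spine; the pubis-to-sacrococcygeal direction is orthogonalized
#' against z (Gram-Schmidt) and then tilted by `inclination_deg` about z,
#' down toward the horizontal, to give the x axis; y completes the
#' right-handed triad. The sacrococcygeal articulation therefore maps onto
#' the midsagittal plane (z = 0), posterior and superior to the pubis
#' (x > 0, y < 0), with the pubis-to-sacrococcygeal line making an angle of
#' `inclination_deg` with the PICS horizontal.
#'
#' @param bones Named list with finite 3-vectors (scanner mm):
#'   `inferior_pubic_point`, `sacrococcygeal_articulation`,
#'   `ischial_spine_left`, `ischial_spine_right`.
#' @param inclination_deg Pelvic inclination angle in degrees, strictly
#'   between 0 and 90. Default 34: the population-average tilt of the
#'   pubis-to-sacrococcygeal line below the horizontal (the packaged
#'   left-side coccyx mean (91.7, -61.8, 0) mm subtends atan2(61.8, 91.7)
#'   which is approximately 34 degrees).
#' @return A `pics_frame` object: list with `origin` (scanner position of the
#'   inferior pubic point), `rotation` (3x3 proper orthonormal matrix whose
#'   rows are the PICS axes in scanner coordinates), `inclination_deg`.
#' @export
#' @examples
#' bones <- list(
#'   inferior_pubic_point = c(0, 0, 0),
#'   sacrococcygeal_articulation = 110 * c(cos(34 * pi / 180), -sin(34 * pi / 180), 0),
#'   ischial_spine_left = c(55, -48, -57),
#'   ischial_spine_right = c(55, -48, 57))
#' frame <- build_frame(bones)
#' to_pics(frame, bones$inferior_pubic_point)  # (0, 0, 0)
build_frame <- function(bones, inclination_deg = 34) {
  needed <- c("inferior_pubic_point", "sacrococcygeal_articulation",
              "ischial_spine_left", "ischial_spine_right")
  if (!all(needed %in% names(bones))) {
    rlang::abort(sprintf("bones must contain: %s",
                         paste(setdiff(needed, names(bones)), collapse = ", ")))
  }
  pub <- vec3(bones$inferior_pubic_point, "inferior_pubic_point")
  sac <- vec3(bones$sacrococcygeal_articulation, "sacrococcygeal_articulation")
  isl <- vec3(bones$ischial_spine_left, "ischial_spine_left")
  isr <- vec3(bones$ischial_spine_right, "ischial_spine_right")
  if (!is.numeric(inclination_deg) || length(inclination_deg) != 1 ||
      !is.finite(inclination_deg) ||
      inclination_deg <= 0 || inclination_deg >= 90) {
    rlang::abort("inclination_deg must lie strictly between 0 and 90 degrees")
  }

  z <- unit(isr - isl, "inter-spine line (ischial spines coincident?)", tol = 1e-6)
  w <- sac - pub
  if (sqrt(sum(w^2)) < 1e-6) {
    rlang::abort("degenerate geometry: sacrococcygeal articulation coincides with the pubic point")
  }
  w_perp <- w - sum(w * z) * z
  x0 <- unit(w_perp,
             "pubis-to-sacrococcygeal line (parallel to the inter-spine line?)",
             tol = 1e-6)
  # pubis on the inter-spine line <=> spine-to-pubis vector parallel to z
  u <- pub - isl
  if (sqrt(sum(cross3(u, z)^2)) < 1e-6) {
    rlang::abort("degenerate geometry: pubic point lies on the inter-spine line")
  }
  y0 <- cross3(z, x0)
  th <- deg2rad(inclination_deg)
  x <- cos(th) * x0 + sin(th) * y0
  y <- cross3(z, x)
  rotation <- rbind(x, y, z, deparse.level = 0)
  dimnames(rotation) <- list(c("x", "y", "z"), NULL)
  structure(list(origin = pub, rotation = rotation,
                 inclination_deg = inclination_deg),
            class = "pics_frame")
}

#' @export
print.pics_frame <- function(x, ...) {
  cat("<pics_frame>\n")
  cat(sprintf("  origin (scanner mm): %.3f %.3f %.3f\n",
              x$origin[1], x$origin[2], x$origin[3]))
  cat(sprintf("  inclination: %g deg\n", x$inclination_deg))
  cat("  rotation (rows = PICS axes in scanner coords):\n")
  print(round(x$rotation, 6))
  invisible(x)
}

assert_frame <- function(frame, tol = 1e-9) {
  if (!inherits(frame, "pics_frame")) rlang::abort("not a pics_frame")
  R <- frame$rotation
  if (max(abs(crossprod(R) - diag(3))) > tol || abs(det(R) - 1) > tol) {
    rlang::abort("pics_frame rotation is not a proper orthonormal matrix")
  }
  invisible(frame)
}

#' Map points between scanner and PICS space
#'
#' `to_pics()` applies the rigid map p -> R (p - origin); `from_pics()` is its
#' exact inverse. Both accept a single 3-vector or an n x 3 matrix.
#'
#' @param frame A [build_frame()] result.
#' @param points A numeric 3-vector or n x 3 matrix of coordinates (mm).
#' @return Coordinates in the target space, same shape as the input.
#' @export
to_pics <- function(frame, points) {
  assert_frame(frame)
  if (is.null(dim(points))) {
    drop(frame$rotation %*% (vec3(points) - frame$origin))
  } else {
    t(frame$rotation %*% (t(points) - frame$origin))
  }
}

#' @rdname to_pics
#' @export
from_pics <- function(frame, points) {
  assert_frame(frame)
  if (is.null(dim(points))) {
    drop(crossprod(frame$rotation, vec3(points))) + frame$origin
  } else {
    t(crossprod(frame$rotation, t(points)) + frame$origin)
  }
}

# Extract the four frame-defining bony landmarks of one (subject, rater) set.
bony_landmark_set <- function(points) {
  pick <- function(structure, side) {
    row <- points[points$structure == structure & points$side == side, ]
    if (nrow(row) != 1) {
      rlang::abort(sprintf("expected exactly one '%s' (%s) point, found %d",
                           structure, side, nrow(row)))
    }
    c(row$x_mm, row$y_mm, row$z_mm)
  }
  list(inferior_pubic_point = pick("symphysis", "midline"),
       sacrococcygeal_articulation = pick("sacrococcygeal_articulation", "midline"),
       ischial_spine_left = pick("ischial_spine", "left"),
       ischial_spine_right = pick("ischial_spine", "right"))
}

#' Transform annotation sets from scanner to PICS space
#'
#' For every (subject, rater) set, builds the patient-specific frame from its
#' own bony landmarks and maps all points into PICS space. Strictly midline
#' structures (coccyx tip, sacrococcygeal articulation) are asserted to land
#' within `midline_tolerance_mm` of the midsagittal plane; a violation raises
#' a warning (annotation noise should be visible, not silently projected
#' away).
#'
#' @param points Landmark tibble with `space == "scanner"`.
#' @param inclination_deg Pelvic inclination passed to [build_frame()].
#' @param midline_tolerance_mm Tolerance for |z| of strictly midline
#'   structures after transformation. Default 1e-6 (synthetic data); a
#'   real-data profile would use about 2 mm.
#' @return The landmark tibble in PICS space (`space == "pics"`).
#' @export
transform_set <- function(points, inclination_deg = 34,
                          midline_tolerance_mm = 1e-6) {
  assert_landmarks(points)
  if (any(points$space == "pics")) {
    rlang::abort("annotation set is already in PICS space")
  }
  strict <- structure_schema()
  strict <- strict$structure[strict$strictly_midline]

  out <- dplyr::group_modify(
    dplyr::group_by(points, .data$subject_id, .data$rater),
    function(set, key) {
      bones <- bony_landmark_set(set)
      frame <- build_frame(bones, inclination_deg = inclination_deg)
      set <- set_coords(set, to_pics(frame, coord_matrix(set)))
      mid <- set$structure %in% strict
      if (any(abs(set$z_mm[mid]) > midline_tolerance_mm)) {
        worst <- max(abs(set$z_mm[mid]))
        rlang::warn(sprintf(
          "subject '%s' (rater '%s'): midline structure %.3g mm off the midsagittal plane (tolerance %g mm)",
          key$subject_id, key$rater, worst, midline_tolerance_mm))
      }
      set
    })
  out <- dplyr::ungroup(out)
  out$space <- "pics"
  out[, landmark_columns()]
}
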