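#' Specify a synthetic cohort
#'
#' Bundles and validates everything the generator needs: the group label,
#' the number of subjects, the per-point coordinate model (means and SDs per
#' axis, left side; right-side means are mirrored by negating z), an
#' optional exchangeable within-point axis correlation, the pose model for
#' scanner positioning, the second-rater noise level, and the master seed.
#'
#' Defaults emulate the study cohorts: 22 subjects per group, the packaged
#' left-side point model of [table2_point_model()], independent axes,
#' +/-15 degree rotations and +/-50 mm translations of scanner pose, and
#' 2 mm per-axis second-rater noise.
#'
#' @param group `"control"` or `"case"`.
#' @param n_subjects Number of subjects (default 22).
#' @param point_model Point model tibble (columns as in
#'   [table2_point_model()]); defaults to the packaged model for `group`.
#' @param correlation Exchangeable correlation between the three axes of one
#'   point, in [0, 1); default 0 (independent axes).
#' @param rotation_range_deg,translation_range_mm Uniform half-ranges of the
#'   per-subject scanner pose.
#' @param rater_noise_sd_mm Per-axis SD of second-rater annotation noise.
#' @param seed Master seed (integer); all draws derive deterministic
#'   sub-streams from it.
#' @param inclination_deg Pelvic inclination used to synthesize the
#'   sacrococcygeal articulation consistently with [build_frame()].
#' @param sc_distance_mm Distance from the pubis at which the sacrococcygeal
#'   articulation is placed on the midsagittal line (default 110 mm).
#' @param subject_prefix Prefix for subject ids (default from `group`).
#' @return A validated `cohort_spec` list.
#' @export
cohort_spec <- function(group = c("control", "case"), n_subjects = 22,
                        point_model = NULL, correlation = 0,
                        rotation_range_deg = 15, translation_range_mm = 50,
                        rater_noise_sd_mm = 2, seed = 1,
                        inclination_deg = 34, sc_distance_mm = 110,
                        subject_prefix = NULL) {
  group <- match.arg(group)
  if (is.null(point_model)) point_model <- table2_point_model(group)
  if ("group" %in% names(point_model)) {
    point_model <- point_model[point_model$group == group,
                               setdiff(names(point_model), "group")]
  }
  stopifnot(n_subjects >= 1, correlation >= 0, correlation < 1,
            rater_noise_sd_mm >= 0, sc_distance_mm > 0,
            inclination_deg > 0, inclination_deg < 90)
  sds <- as.matrix(point_model[, c("sd_x", "sd_y", "sd_z")])
  if (any(sds < 0)) rlang::abort("point model SDs must be non-negative")
  strict <- structure_schema()
  strict <- strict$structure[strict$strictly_midline]
  bad <- point_model$structure %in% strict &
    (point_model$mean_z != 0 | point_model$sd_z != 0)
  if (any(bad)) {
    rlang::abort(sprintf(
      "strictly midline structure '%s' must have z mean 0 and z SD 0",
      point_model$structure[which(bad)[1]]))
  }
  structure(list(group = group, n_subjects = as.integer(n_subjects),
                 point_model = point_model, correlation = correlation,
                 rotation_range_deg = rotation_range_deg,
                 translation_range_mm = translation_range_mm,
                 rater_noise_sd_mm = rater_noise_sd_mm,
                 seed = as.integer(seed),
                 inclination_deg = inclination_deg,
                 sc_distance_mm = sc_distance_mm,
                 subject_prefix = subject_prefix %||%
                   if (group == "control") "ctrl" else "case"),
            class = "cohort_spec")
}

# Cholesky factor of the exchangeable 3x3 correlation matrix.
axis_chol <- function(rho) {
  if (rho == 0) return(diag(3))
  chol((1 - rho) * diag(3) + rho)
}

#' Generate a synthetic cohort of landmark annotations
#'
#' Draws each annotated point of each subject from an independent Gaussian
#' per axis (mean and SD from the spec's point model; optional exchangeable
#' within-point axis correlation), directly in PICS space. The generated
#' subject is exactly in its own PICS frame:
#' \itemize{
#'   \item the symphysis (inferior pubic point) is fixed at (0, 0, 0);
#'   \item the sacrococcygeal articulation is synthesized deterministically
#'     on the midsagittal plane at `sc_distance_mm` from the pubis along the
#'     direction making `inclination_deg` with the PICS horizontal;
#'   \item the right ischial spine mirrors the left one exactly (same x and
#'     y draw, negated z), keeping the inter-spine line parallel to the z
#'     axis.
#' }
#' All other bilateral structures are drawn independently per side with
#' mirrored means. Strictly midline z coordinates (coccyx) are exactly 0.
#' Draws are deterministic given the spec's seed, with per-subject
#' sub-streams.
#'
#' @param spec A [cohort_spec()].
#' @param rater Rater id stamped on the generated sets (default `"R1"`).
#' @return Landmark tibble in PICS space.
#' @export
generate_cohort <- function(spec, rater = "R1") {
  stopifnot(inherits(spec, "cohort_spec"))
  model <- spec$point_model
  th <- deg2rad(spec$inclination_deg)
  sc <- spec$sc_distance_mm * c(cos(th), -sin(th), 0)
  L <- axis_chol(spec$correlation)

  draw_point <- function(mean, sd) {
    mean + sd * drop(crossprod(L, stats::rnorm(3)))
  }

  old_rng <- save_rng()
  on.exit(restore_rng(old_rng))
  streams <- make_streams(spec$seed, spec$n_subjects)

  subjects <- purrr::map_dfr(seq_len(spec$n_subjects), function(i) {
    use_stream(streams[[i]])
    rows <- purrr::pmap_dfr(model, function(structure, role, index, side,
                                            mean_x, mean_y, mean_z,
                                            sd_x, sd_y, sd_z) {
      mu <- c(mean_x, mean_y, mean_z)
      sd <- c(sd_x, sd_y, sd_z)
      if (side == "midline") {
        p <- draw_point(mu, sd)
        tibble::tibble(structure = structure, role = role, index = index,
                       side = side, x_mm = p[1], y_mm = p[2], z_mm = p[3])
      } else if (structure == "ischial_spine") {
        p <- draw_point(mu, sd)
        tibble::tibble(structure = structure, role = role, index = index,
                       side = c("left", "right"),
                       x_mm = p[1], y_mm = p[2], z_mm = c(p[3], -p[3]))
      } else {
        pl <- draw_point(mu, sd)
        pr <- draw_point(mu * c(1, 1, -1), sd)
        tibble::tibble(structure = structure, role = role, index = index,
                       side = c("left", "right"),
                       x_mm = c(pl[1], pr[1]), y_mm = c(pl[2], pr[2]),
                       z_mm = c(pl[3], pr[3]))
      }
    })
    rows <- dplyr::bind_rows(rows, tibble::tibble(
      structure = "sacrococcygeal_articulation", role = "bone", index = 1L,
      side = "midline", x_mm = sc[1], y_mm = sc[2], z_mm = sc[3]))
    rows$subject_id <- sprintf("%s%03d", spec$subject_prefix, i)
    rows
  })
  subjects$group <- spec$group
  subjects$rater <- rater
  subjects$space <- "pics"
  subjects <- subjects[, landmark_columns()]
  assert_landmarks(subjects, "generated cohort")
  subjects
}

# Rotation matrix from intrinsic z-y-x Euler angles (degrees).
euler_rotation <- function(angles_deg) {
  a <- deg2rad(angles_deg)
  cz <- cos(a[1]); sz <- sin(a[1])
  cy <- cos(a[2]); sy <- sin(a[2])
  cx <- cos(a[3]); sx <- sin(a[3])
  Rz <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, byrow = TRUE)
  Ry <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, byrow = TRUE)
  Rx <- matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, byrow = TRUE)
  Rz %*% Ry %*% Rx
}

#' Apply a random rigid scanner pose to PICS-space annotation sets
#'
#' Each subject receives one proper rigid transform (rotation drawn
#' uniformly within `+/-rotation_range_deg` per Euler axis, translation
#' within `+/-translation_range_mm` per axis), shared across that subject's
#' raters, mapping its PICS coordinates into a synthetic scanner space.
#' [build_frame()] applied to the posed bony landmarks recovers the pose, so
#' [transform_set()] restores the original coordinates.
#'
#' @param points Landmark tibble with `space == "pics"`.
#' @param rotation_range_deg,translation_range_mm Pose ranges (defaults 15
#'   degrees, 50 mm).
#' @param seed Master seed for the per-subject pose sub-streams.
#' @return The tibble in scanner space (`space == "scanner"`).
#' @export
apply_pose <- function(points, rotation_range_deg = 15,
                       translation_range_mm = 50, seed = 1) {
  assert_landmarks(points)
  if (any(points$space != "pics")) {
    rlang::abort("apply_pose expects PICS-space input")
  }
  subjects <- sort(unique(points$subject_id))
  old_rng <- save_rng()
  on.exit(restore_rng(old_rng))
  streams <- make_streams(seed, length(subjects))
  out <- points
  for (i in seq_along(subjects)) {
    use_stream(streams[[i]])
    Q <- euler_rotation(stats::runif(3, -rotation_range_deg, rotation_range_deg))
    tr <- stats::runif(3, -translation_range_mm, translation_range_mm)
    idx <- out$subject_id == subjects[i]
    # scanner = Q' p + t: the synthetic frame has rotation Q and origin t
    m <- coord_matrix(out[idx, ])
    out[idx, c("x_mm", "y_mm", "z_mm")] <- t(crossprod(Q, t(m)) + tr)
  }
  out$space <- "scanner"
  out
}

#' Add a second rater with annotation noise
#'
#' Returns a copy of the input sets under a new rater id with independent
#' zero-mean Gaussian offsets per point and axis. Coordinates that are 0 by
#' definition are left untouched: the symphysis point entirely, and the z
#' coordinate of the coccyx tip (midsagittal by definition).
#'
#' @param points Landmark tibble (any space).
#' @param rater_noise_sd_mm Per-axis noise SD in mm (>= 0).
#' @param rater New rater id (default `"R2"`).
#' @param seed Master seed for per-subject noise sub-streams.
#' @return A landmark tibble for the new rater only (bind with the input to
#'   get the two-rater collection).
#' @export
add_rater_noise <- function(points, rater_noise_sd_mm = 2, rater = "R2",
                            seed = 1) {
  assert_landmarks(points)
  stopifnot(rater_noise_sd_mm >= 0)
  subjects <- sort(unique(points$subject_id))
  old_rng <- save_rng()
  on.exit(restore_rng(old_rng))
  streams <- make_streams(sub_seed(seed, 104729L), length(subjects))
  out <- points
  for (i in seq_along(subjects)) {
    use_stream(streams[[i]])
    idx <- which(out$subject_id == subjects[i])
    noise <- matrix(stats::rnorm(3 * length(idx), 0, rater_noise_sd_mm),
                    ncol = 3)
    fixed <- out$structure[idx] == "symphysis"
    noise[fixed, ] <- 0
    noise[out$structure[idx] == "coccyx", 3] <- 0
    m <- coord_matrix(out[idx, ]) + noise
    out[idx, c("x_mm", "y_mm", "z_mm")] <- m
  }
  out$rater <- rater
  out
}
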