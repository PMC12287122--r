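#' Annotation schema for pelvic landmark tables
#'
#' The pipeline works on tidy landmark tables: one annotated 3D point per row
#' with columns `subject_id`, `group` (`control`/`case`), `rater`, `structure`,
#' `role` (`origin`/`insertion`/`organ`/`bone`), `index`, `side`
#' (`left`/`right`/`midline`), `x_mm`, `y_mm`, `z_mm`, `space`
#' (`scanner`/`pics`). All coordinates are millimetres.
#'
#' `structure_schema()` returns the allowed (structure, role) combinations,
#' their index ranges, laterality, and which indices a complete annotation must
#' carry. Bilateral entries exist once per side; midline entries once per
#' subject. Structures flagged `strictly_midline` are defined to lie exactly on
#' the midsagittal plane (z = 0 in PICS space): the pubic symphysis point (the
#' frame origin), the coccyx tip, and the sacrococcygeal articulation. Organ
#' points are annotated as single midline-side points but their z coordinate is
#' free.
#'
#' @return A tibble with columns `structure`, `role`, `laterality`
#'   (`bilateral`/`midline`), `index_min`, `index_max`, `required_indices`
#'   (comma-separated string, empty if the structure is optional),
#'   `strictly_midline` (logical).
#' @export
#' @examples
#' structure_schema()
structure_schema <- function() {
  tibble::tribble(
    ~structure,                    ~role,        ~laterality, ~index_min, ~index_max, ~required_indices, ~strictly_midline,
    "bladder",                     "organ",      "midline",   1L,         1L,         "1",               FALSE,
    "cervix",                      "organ",      "midline",   1L,         1L,         "1",               FALSE,
    "anorectum",                   "organ",      "midline",   1L,         1L,         "1",               FALSE,
    "symphysis",                   "bone",       "midline",   1L,         1L,         "1",               TRUE,
    "sacrococcygeal_articulation", "bone",       "midline",   1L,         1L,         "1",               TRUE,
    "coccyx",                      "bone",       "midline",   1L,         1L,         "",                TRUE,
    "ischial_spine",               "bone",       "bilateral", 1L,         1L,         "1",               FALSE,
    "pvm",                         "origin",     "bilateral", 1L,         3L,         "1,3",             FALSE,
    "pvam",                        "insertion",  "bilateral", 1L,         2L,         "1,2",             FALSE,
    "ppm",                         "insertion",  "bilateral", 1L,         1L,         "1",               FALSE,
    "pam",                         "insertion",  "bilateral", 1L,         3L,         "2",               FALSE,
    "prm",                         "origin",     "bilateral", 1L,         2L,         "1,2",             FALSE,
    "prm",                         "insertion",  "bilateral", 1L,         2L,         "1",               FALSE,
    "icm",                         "origin",     "bilateral", 1L,         4L,         "1,4",             FALSE,
    "icm",                         "insertion",  "bilateral", 1L,         2L,         "1,2",             FALSE,
    "coc",                         "insertion",  "bilateral", 1L,         2L,         "1,2",             FALSE
  )
}

landmark_columns <- function() {
  c("subject_id", "group", "rater", "structure", "role", "index", "side",
    "x_mm", "y_mm", "z_mm", "space")
}

# Structural (row-level) checks shared by readers and writers. Returns a
# character vector of problems, empty when clean.
check_landmark_rows <- function(points) {
  problems <- character()
  missing_cols <- setdiff(landmark_columns(), names(points))
  if (length(missing_cols)) {
    return(sprintf("missing column(s): %s", paste(missing_cols, collapse = ", ")))
  }
  if (!nrow(points)) return(problems)

  bad_group <- !points$group %in% c("control", "case")
  if (any(bad_group)) {
    problems <- c(problems, sprintf("row %d: unknown group '%s'",
                                    which(bad_group)[1], points$group[which(bad_group)[1]]))
  }
  bad_space <- !points$space %in% c("scanner", "pics")
  if (any(bad_space)) {
    problems <- c(problems, sprintf("row %d: unknown space '%s'",
                                    which(bad_space)[1], points$space[which(bad_space)[1]]))
  }
  bad_side <- !points$side %in% c("left", "right", "midline")
  if (any(bad_side)) {
    problems <- c(problems, sprintf("row %d: unknown side '%s'",
                                    which(bad_side)[1], points$side[which(bad_side)[1]]))
  }
  if (!all(is.finite(points$x_mm)) || !all(is.finite(points$y_mm)) ||
      !all(is.finite(points$z_mm))) {
    bad <- which(!(is.finite(points$x_mm) & is.finite(points$y_mm) &
                     is.finite(points$z_mm)))[1]
    problems <- c(problems, sprintf("row %d: non-finite coordinate", bad))
  }

  schema <- structure_schema()
  key <- paste(points$structure, points$role)
  known <- paste(schema$structure, schema$role)
  bad_struct <- !key %in% known
  if (any(bad_struct)) {
    i <- which(bad_struct)[1]
    problems <- c(problems, sprintf("row %d: unknown structure/role '%s %s'",
                                    i, points$structure[i], points$role[i]))
  }

  ok <- !bad_struct & !bad_side
  if (any(ok)) {
    m <- match(key[ok], known)
    idx <- points$index[ok]
    out_of_range <- idx < schema$index_min[m] | idx > schema$index_max[m]
    if (any(out_of_range)) {
      i <- which(ok)[which(out_of_range)[1]]
      problems <- c(problems, sprintf(
        "row %d: index %d out of schema range for '%s %s'",
        i, points$index[i], points$structure[i], points$role[i]))
    }
    lat <- schema$laterality[m]
    side <- points$side[ok]
    side_bad <- (lat == "midline" & side != "midline") |
      (lat == "bilateral" & !side %in% c("left", "right"))
    if (any(side_bad)) {
      i <- which(ok)[which(side_bad)[1]]
      problems <- c(problems, sprintf(
        "row %d: side '%s' invalid for '%s' (%s structure)",
        i, points$side[i], points$structure[i], lat[which(side_bad)[1]]))
    }
  }

  dup <- duplicated(points[, c("subject_id", "rater", "structure", "role",
                               "index", "side")])
  if (any(dup)) {
    i <- which(dup)[1]
    problems <- c(problems, sprintf(
      "row %d: duplicate point '%s %s %d %s' for subject '%s', rater '%s'",
      i, points$structure[i], points$role[i], points$index[i], points$side[i],
      points$subject_id[i], points$rater[i]))
  }

  mixed <- dplyr::summarise(
    dplyr::group_by(points, .data$subject_id, .data$rater),
    n_spaces = dplyr::n_distinct(.data$space), .groups = "drop")
  if (any(mixed$n_spaces > 1)) {
    bad <- mixed[mixed$n_spaces > 1, ][1, ]
    problems <- c(problems, sprintf(
      "subject '%s', rater '%s': mixed coordinate spaces within one annotation set",
      bad$subject_id, bad$rater))
  }
  problems
}

assert_landmarks <- function(points, what = "landmark table") {
  problems <- check_landmark_rows(points)
  if (length(problems)) {
    rlang::abort(c(sprintf("invalid %s", what), problems))
  }
  invisible(points)
}

#' Packaged left-side point model (group means and SDs)
#'
#' Per-point coordinate means and standard deviations (millimetres, PICS
#' space, left side / midline) for the control and prolapse-case groups, as
#' shipped in `inst/extdata/point_model_left.csv`. These drive the synthetic
#' cohort generator and the fixture-based group-difference checks. Right-side
#' means are obtained downstream by negating z.
#'
#' @param group `"control"`, `"case"`, or `"both"` (default) to keep the
#'   `group` column.
#' @return A tibble with columns `group`, `structure`, `role`, `index`,
#'   `side`, `mean_x`, `mean_y`, `mean_z`, `sd_x`, `sd_y`, `sd_z`.
#' @export
#' @examples
#' table2_point_model("control")
table2_point_model <- function(group = c("both", "control", "case")) {
  group <- match.arg(group)
  path <- system.file("extdata", "point_model_left.csv", package = "picsmorph",
                      mustWork = TRUE)
  model <- readr::read_csv(path, show_col_types = FALSE,
                           col_types = readr::cols(
                             group = "c", structure = "c", role = "c",
                             index = "i", side = "c",
                             .default = readr::col_double()))
  if (group != "both") model <- model[model$group == group, ]
  model
}
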