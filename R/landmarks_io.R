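#' Read landmark annotation tables
#'
#' Reads one or more per-subject, per-rater annotation sets from a CSV or
#' JSON file. The CSV schema is one point per row with columns (exact order)
#' `subject_id, group, rater, structure, role, index, side, x_mm, y_mm, z_mm,
#' space`; the JSON mirror is a list of objects with the same keys.
#' Coordinates are millimetres; `space` is `"scanner"` or `"pics"`.
#'
#' Structural validity (known structure names, index within the annotation
#' schema, no duplicate points, a single coordinate space per subject/rater
#' set) is enforced on read; completeness against a profile is checked
#' separately by [validate_schema()].
#'
#' @param path Path to the annotation file.
#' @param format `"csv"` or `"json"`; default guessed from the file extension.
#' @return A landmark tibble (see [structure_schema()] for the data model).
#' @seealso [write_annotations()], [validate_schema()]
#' @export
read_annotations <- function(path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (!file.exists(path)) rlang::abort(sprintf("file not found: %s", path))
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  if (format == "csv") {
    points <- readr::read_csv(
      path, show_col_types = FALSE,
      col_types = readr::cols(
        subject_id = "c", group = "c", rater = "c", structure = "c",
        role = "c", index = "i", side = "c",
        x_mm = "d", y_mm = "d", z_mm = "d", space = "c"))
    probs <- readr::problems(points)
    if (nrow(probs)) {
      rlang::abort(sprintf("parse error in %s at line %d: %s",
                           path, probs$row[1] + 1L, probs$expected[1]))
    }
  } else {
    raw <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
    if (length(raw) == 0) {
      points <- tibble::as_tibble(
        stats::setNames(rep(list(character()), 11), landmark_columns()))
      points$index <- integer()
      points$x_mm <- points$y_mm <- points$z_mm <- double()
    } else {
      points <- tibble::as_tibble(raw)
      points$index <- as.integer(points$index)
    }
  }
  points <- points[, landmark_columns()]
  assert_landmarks(points, what = sprintf("annotation file '%s'", path))
  points
}

#' Write landmark annotation tables
#'
#' Serializes a landmark tibble to CSV or JSON in the documented column
#' schema. The round trip through [read_annotations()] is lossless to well
#' below 1e-6 mm. All sets in one call must share a coordinate space.
#'
#' @param points Landmark tibble.
#' @param path Output file path.
#' @param format `"csv"` or `"json"`; default guessed from the extension.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(points, path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (!nrow(points)) rlang::abort("refusing to write an empty annotation table")
  assert_landmarks(points)
  if (length(unique(points$space)) > 1) {
    rlang::abort("mixed coordinate spaces across sets in one write call")
  }
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  points <- points[, landmark_columns()]
  if (format == "csv") {
    readr::write_csv(points, path)
  } else {
    jsonlite::write_json(points, path, digits = NA, auto_unbox = TRUE)
  }
  invisible(path)
}

#' Validate annotation completeness against a profile
#'
#' Checks each (subject, rater) set for the points a given analysis profile
#' needs. The `full` profile requires all organs, the bony landmarks
#' (symphysis, sacrococcygeal articulation, both ischial spines; the coccyx
#' tip is optional), and the required indices of every muscle subdivision on
#' both sides. The `bony_only` profile requires just the four landmarks that
#' anchor the PICS frame.
#'
#' @param points Landmark tibble.
#' @param profile `"full"` or `"bony_only"`.
#' @return A tibble of failures (zero rows = pass) with columns `subject_id`,
#'   `rater`, `problem`, `structure`, `role`, `index`, `side`.
#' @export
validate_schema <- function(points, profile = c("full", "bony_only")) {
  profile <- match.arg(profile)
  assert_landmarks(points)
  schema <- structure_schema()

  required <- schema[schema$required_indices != "", ]
  if (profile == "bony_only") {
    required <- required[required$structure %in%
                           c("symphysis", "sacrococcygeal_articulation",
                             "ischial_spine"), ]
  }
  req_rows <- purrr::pmap_dfr(required, function(structure, role, laterality,
                                                 index_min, index_max,
                                                 required_indices, strictly_midline) {
    idx <- as.integer(strsplit(required_indices, ",")[[1]])
    sides <- if (laterality == "bilateral") c("left", "right") else "midline"
    tidyr::expand_grid(structure = structure, role = role, index = idx,
                       side = sides)
  })

  sets <- dplyr::distinct(points[, c("subject_id", "rater")])
  failures <- purrr::pmap_dfr(sets, function(subject_id, rater) {
    have <- points[points$subject_id == subject_id & points$rater == rater, ]
    missing <- dplyr::anti_join(
      req_rows, have, by = c("structure", "role", "index", "side"))
    if (!nrow(missing)) return(tibble::tibble())
    tibble::tibble(subject_id = subject_id, rater = rater,
                   problem = "missing required point",
                   structure = missing$structure, role = missing$role,
                   index = missing$index, side = missing$side)
  })
  if (!nrow(failures)) {
    failures <- tibble::tibble(subject_id = character(), rater = character(),
                               problem = character(), structure = character(),
                               role = character(), index = integer(),
                               side = character())
  }
  failures
}
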