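#' Auxiliary equidistant points along the pubovisceral origin
#'
#' Returns the first, second, and third equidistant points between the first
#' and last origin points of the pubovisceral muscle (parameters 1/4, 1/2,
#' 3/4 along the segment), so that the five points -- the two border origins
#' plus the three auxiliaries -- are equally spaced. These auxiliary points
#' serve as effective origins for the fan-like PVM subdivisions.
#'
#' @param first_origin,last_origin Finite 3-vectors (mm).
#' @return A 3 x 3 matrix, one auxiliary point per row.
#' @export
#' @examples
#' auxiliary_points(c(0, 0, 0), c(4, 0, 0))
auxiliary_points <- function(first_origin, last_origin) {
  a <- vec3(first_origin, "first_origin")
  b <- vec3(last_origin, "last_origin")
  t(sapply(c(1, 2, 3) / 4, function(s) a + s * (b - a)))
}

#' Straight-line muscle length
#'
#' Euclidean distance in millimetres between an effective origin and
#' insertion point.
#'
#' @param origin,insertion Finite 3-vectors (mm).
#' @return Length in mm (non-negative scalar).
#' @export
muscle_length <- function(origin, insertion) {
  sqrt(sum((vec3(insertion, "insertion") - vec3(origin, "origin"))^2))
}

#' Signed angles between a muscle and the PICS reference planes
#'
#' The muscle's directional vector v = insertion - origin is compared with
#' the coronal, transverse, and sagittal PICS planes. For a plane with unit
#' normal n (posterior (1,0,0) for coronal, inferior (0,1,0) for transverse,
#' right (0,0,1) for sagittal), the angle is asin(v . n / |v|) in degrees,
#' in [-90, 90]: muscles directed posterior, inferior, or toward the
#' subject's right get positive angles; the opposite directions get negative
#' angles. The asin argument is clamped to [-1, 1] to absorb rounding at
#' axis-aligned vectors.
#'
#' @param origin,insertion Finite, distinct 3-vectors in PICS mm.
#' @return Named numeric vector `c(coronal, transverse, sagittal)` (degrees).
#' @export
#' @examples
#' plane_angles(c(0, 0, 0), c(1, 1, 0))  # coronal 45, transverse 45, sagittal 0
plane_angles <- function(origin, insertion) {
  v <- vec3(insertion, "insertion") - vec3(origin, "origin")
  n <- sqrt(sum(v^2))
  if (n < 1e-12) {
    rlang::abort("zero-length directional vector: origin and insertion coincide")
  }
  ang <- rad2deg(asin(clamp(v / n, -1, 1)))
  names(ang) <- c("coronal", "transverse", "sagittal")
  ang
}

endpoint_ref <- function(structure, role, index) {
  list(type = "point", structure = structure, role = role,
       index = as.integer(index))
}

#' Default muscle measurement graph
#'
#' The declarative pairing of effective origin and insertion points for every
#' measured levator ani segment, per side. Point-selection rules follow the
#' annotation protocol: the puboanal (PAM) insertion uses only the middle of
#' its three marked points (index 2), and the pubovisceral (PVM) and
#' iliococcygeus (ICM) origins use only their two border points (indices 1/3
#' and 1/4). Effective origins of the PVM subdivisions are the auxiliary
#' points of [auxiliary_points()] interpolated between the PVM border
#' origins.
#'
#' The exact origin-to-insertion pairing per subdivision is configuration,
#' not code, so alternative interpretations can be tested: pass a modified
#' graph (or one loaded with [read_muscle_graph()]) to
#' [compute_morphometry()]. Defaults: PVaM = auxiliary 1 to the midpoint of
#' its two insertions; PPM = auxiliary 2 to its insertion; PAM = auxiliary 3
#' to the middle insertion; PVM = border origin 1 to the PAM middle insertion
#' (the longest fan path); PRM = origin 2 to insertion 1; ICM = two segments
#' (origin 1 to insertion 1, origin 4 to insertion 2); COC = two segments
#' from the ischial spine to each coccygeus insertion.
#'
#' @return A `muscle_graph` object: list of segment specifications.
#' @seealso [read_muscle_graph()], [write_muscle_graph()]
#' @export
default_muscle_graph <- function() {
  segs <- list(
    list(muscle = "pvm", segment = "pvm",
         origin = endpoint_ref("pvm", "origin", 1),
         insertion = endpoint_ref("pam", "insertion", 2)),
    list(muscle = "pvam", segment = "pvam",
         origin = list(type = "auxiliary", index = 1L),
         insertion = list(type = "midpoint",
                          points = list(endpoint_ref("pvam", "insertion", 1),
                                        endpoint_ref("pvam", "insertion", 2)))),
    list(muscle = "ppm", segment = "ppm",
         origin = list(type = "auxiliary", index = 2L),
         insertion = endpoint_ref("ppm", "insertion", 1)),
    list(muscle = "pam", segment = "pam",
         origin = list(type = "auxiliary", index = 3L),
         insertion = endpoint_ref("pam", "insertion", 2)),
    list(muscle = "prm", segment = "prm",
         origin = endpoint_ref("prm", "origin", 2),
         insertion = endpoint_ref("prm", "insertion", 1)),
    list(muscle = "icm", segment = "icm_1",
         origin = endpoint_ref("icm", "origin", 1),
         insertion = endpoint_ref("icm", "insertion", 1)),
    list(muscle = "icm", segment = "icm_2",
         origin = endpoint_ref("icm", "origin", 4),
         insertion = endpoint_ref("icm", "insertion", 2)),
    list(muscle = "coc", segment = "coc_1",
         origin = endpoint_ref("ischial_spine", "bone", 1),
         insertion = endpoint_ref("coc", "insertion", 1)),
    list(muscle = "coc", segment = "coc_2",
         origin = endpoint_ref("ischial_spine", "bone", 1),
         insertion = endpoint_ref("coc", "insertion", 2)))
  structure(list(segments = segs), class = "muscle_graph")
}

#' Read or write a muscle graph configuration
#'
#' Muscle graphs serialize to YAML so the measurement pairing can be edited
#' without touching code. The packaged default ships at
#' `system.file("extdata", "muscle_graph.yaml", package = "picsmorph")`.
#'
#' @param path YAML file path.
#' @param graph A `muscle_graph` object.
#' @return `read_muscle_graph()`: a `muscle_graph`; `write_muscle_graph()`:
#'   `path`, invisibly.
#' @export
read_muscle_graph <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw$segments)) rlang::abort("muscle graph file lacks 'segments'")
  fix_endpoint <- function(e) {
    if (!is.null(e$index)) e$index <- as.integer(e$index)
    if (!is.null(e$points)) e$points <- lapply(e$points, fix_endpoint)
    e
  }
  raw$segments <- lapply(raw$segments, function(s) {
    s$origin <- fix_endpoint(s$origin)
    s$insertion <- fix_endpoint(s$insertion)
    s
  })
  structure(list(segments = raw$segments), class = "muscle_graph")
}

#' @rdname read_muscle_graph
#' @export
write_muscle_graph <- function(graph, path) {
  stopifnot(inherits(graph, "muscle_graph"))
  yaml::write_yaml(list(segments = graph$segments), path)
  invisible(path)
}

# Resolve one endpoint specification against one (subject, rater, side)
# point set. `side_points` holds the points available to that side
# (side-matched bilateral points plus midline points).
resolve_endpoint <- function(side_points, spec, side) {
  get_point <- function(structure, role, index) {
    row <- side_points[side_points$structure == structure &
                         side_points$role == role &
                         side_points$index == index, ]
    if (nrow(row) != 1) {
      rlang::abort(sprintf(
        "cannot resolve segment: missing point '%s %s %d' (%s side)",
        structure, role, index, side))
    }
    c(row$x_mm, row$y_mm, row$z_mm)
  }
  switch(
    spec$type,
    point = get_point(spec$structure, spec$role, spec$index),
    midpoint = {
      pts <- lapply(spec$points, function(p) get_point(p$structure, p$role, p$index))
      colMeans(do.call(rbind, pts))
    },
    auxiliary = {
      aux <- auxiliary_points(get_point("pvm", "origin", 1),
                              get_point("pvm", "origin", 3))
      aux[spec$index, ]
    },
    rlang::abort(sprintf("unknown endpoint spec type '%s'", spec$type)))
}

#' Resolve the effective origin/insertion pair of one muscle segment
#'
#' Applies the point-selection rules of the measurement graph (middle point
#' for the PAM insertion, border points and auxiliary interpolation for the
#' PVM fan, graph defaults for PRM/ICM/COC) to one subject's PICS-space
#' annotation set.
#'
#' @param points Landmark tibble for a single subject and rater, PICS space.
#' @param graph A `muscle_graph`.
#' @param muscle Muscle name (e.g. `"prm"`).
#' @param side `"left"` or `"right"`.
#' @param segment Segment label, required when a muscle has several segments
#'   (e.g. `"icm_1"`).
#' @return List with `origin` and `insertion` 3-vectors (mm).
#' @export
resolve_segment <- function(points, graph, muscle, side, segment = NULL) {
  stopifnot(inherits(graph, "muscle_graph"))
  segs <- Filter(function(s) s$muscle == muscle, graph$segments)
  if (!is.null(segment)) segs <- Filter(function(s) s$segment == segment, segs)
  if (length(segs) != 1) {
    rlang::abort(sprintf(
      "muscle '%s' resolves to %d segments; use the 'segment' argument",
      muscle, length(segs)))
  }
  side_points <- points[points$side %in% c(side, "midline"), ]
  list(origin = resolve_endpoint(side_points, segs[[1]]$origin, side),
       insertion = resolve_endpoint(side_points, segs[[1]]$insertion, side))
}

#' Per-subject muscle morphometry
#'
#' Computes one record per configured muscle segment and side: the straight
#' Euclidean length and the three signed plane angles, all in PICS space.
#'
#' @param points Landmark tibble in PICS space; each (subject, rater) set
#'   must pass `validate_schema(points, "full")`.
#' @param graph Measurement graph; default [default_muscle_graph()].
#' @return Tibble with columns `subject_id`, `group`, `rater`, `side`,
#'   `muscle`, `segment`, `length_mm`, `angle_coronal_deg`,
#'   `angle_sagittal_deg`, `angle_transverse_deg`.
#' @export
compute_morphometry <- function(points, graph = default_muscle_graph()) {
  assert_landmarks(points)
  if (any(points$space != "pics")) {
    rlang::abort("morphometry requires PICS-space coordinates; run transform_set() first")
  }
  failures <- validate_schema(points, "full")
  if (nrow(failures)) {
    rlang::abort(c("annotation sets are incomplete for morphometry",
                   sprintf("%s (rater %s): missing %s %s %d (%s)",
                           failures$subject_id, failures$rater,
                           failures$structure, failures$role,
                           failures$index, failures$side)[seq_len(min(5, nrow(failures)))]))
  }

  sets <- dplyr::distinct(points[, c("subject_id", "group", "rater")])
  purrr::pmap_dfr(sets, function(subject_id, group, rater) {
    set <- points[points$subject_id == subject_id & points$rater == rater, ]
    purrr::map_dfr(c("left", "right"), function(side) {
      purrr::map_dfr(graph$segments, function(seg) {
        ends <- withCallingHandlers(
          resolve_segment(set, graph, seg$muscle, side, seg$segment),
          error = function(e) {
            rlang::abort(sprintf("subject '%s', segment '%s' (%s): %s",
                                 subject_id, seg$segment, side,
                                 conditionMessage(e)))
          })
        ang <- plane_angles(ends$origin, ends$insertion)
        tibble::tibble(
          subject_id = subject_id, group = group, rater = rater, side = side,
          muscle = seg$muscle, segment = seg$segment,
          length_mm = muscle_length(ends$origin, ends$insertion),
          angle_coronal_deg = ang[["coronal"]],
          angle_sagittal_deg = ang[["sagittal"]],
          angle_transverse_deg = ang[["transverse"]])
      })
    })
  })
}
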