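#' Group summaries of point coordinates
#'
#' Per (group, structure, role, index, side, axis): sample mean, SD (n - 1
#' denominator), and n over subjects. Internal math is full precision;
#' rounding happens only at export.
#'
#' @param points Landmark tibble in PICS space, single rater per subject (use
#'   `rater` to select one when several are present).
#' @param rater Optional rater id to filter on.
#' @return Tibble with columns `group`, `structure`, `role`, `index`, `side`,
#'   `axis`, `mean_mm`, `sd_mm`, `n`.
#' @export
summarize_points <- function(points, rater = NULL) {
  assert_landmarks(points)
  if (!is.null(rater)) points <- points[points$rater == rater, ]
  if (!nrow(points)) rlang::abort("no points to summarize (empty group?)")
  if (dplyr::n_distinct(points$rater) > 1) {
    rlang::abort("several raters present; pass `rater` to pick one")
  }
  long <- tidyr::pivot_longer(points, cols = c("x_mm", "y_mm", "z_mm"),
                              names_to = "axis", values_to = "value")
  long$axis <- sub("_mm$", "", long$axis)
  out <- dplyr::summarise(
    dplyr::group_by(long, .data$group, .data$structure, .data$role,
                    .data$index, .data$side, .data$axis),
    mean_mm = mean(.data$value),
    sd_mm = stats::sd(.data$value),
    n = dplyr::n(), .groups = "drop")
  out$sd_mm[is.na(out$sd_mm)] <- 0  # single-subject group
  out
}

#' Group summaries of morphometry records
#'
#' Per (group, side, muscle, segment) and per measure (length and the three
#' plane angles): mean, SD, median, and first/third quartiles. Quartiles use
#' linear interpolation between order statistics (the inclusive convention,
#' `stats::quantile` type 7).
#'
#' @param records Output of [compute_morphometry()].
#' @return Tibble with columns `group`, `side`, `muscle`, `segment`,
#'   `measure`, `mean`, `sd`, `median`, `q1`, `q3`, `n`.
#' @export
summarize_morphometry <- function(records) {
  if (!nrow(records)) rlang::abort("no morphometry records to summarize")
  long <- tidyr::pivot_longer(
    records,
    cols = c("length_mm", "angle_coronal_deg", "angle_sagittal_deg",
             "angle_transverse_deg"),
    names_to = "measure", values_to = "value")
  out <- dplyr::summarise(
    dplyr::group_by(long, .data$group, .data$side, .data$muscle,
                    .data$segment, .data$measure),
    mean = mean(.data$value),
    sd = ifelse(dplyr::n() > 1, stats::sd(.data$value), 0),
    median = stats::median(.data$value),
    q1 = stats::quantile(.data$value, 0.25, type = 7, names = FALSE),
    q3 = stats::quantile(.data$value, 0.75, type = 7, names = FALSE),
    n = dplyr::n(), .groups = "drop")
  out
}

#' Summarize a cohort (points and morphometry together)
#'
#' Convenience wrapper bundling [summarize_points()] and
#' [summarize_morphometry()].
#'
#' @param points Landmark tibble in PICS space.
#' @param records Optional morphometry records (computed from `points` with
#'   the default graph when omitted).
#' @param rater Optional rater filter passed to [summarize_points()].
#' @return List with elements `points` and `morphometry`.
#' @export
summarize_cohort <- function(points, records = NULL, rater = NULL) {
  if (is.null(records)) records <- compute_morphometry(points)
  list(points = summarize_points(points, rater = rater),
       morphometry = summarize_morphometry(records))
}

#' Between-group difference of point coordinate means
#'
#' `group_differences()` joins the control and case rows of a point summary
#' and reports, per (structure, role, index, side, axis), the case-minus-
#' control difference of means and its absolute value, at full precision.
#' `group_difference()` looks up a single entry from two per-group summaries.
#'
#' @param summary_control,summary_case Point summaries (from
#'   [summarize_points()]) containing the respective group's rows.
#' @param structure,role,index,side,axis Identification of the point and axis.
#' @return A one-row tibble (or, for `group_differences()`, one row per
#'   common point/axis) with `mean_control`, `mean_case`, `difference`
#'   (case - control), `abs_difference` (mm).
#' @export
group_difference <- function(summary_control, summary_case, structure,
                             role, index, side, axis) {
  pick <- function(s, grp) {
    s <- s[s$group == grp & s$structure == structure & s$role == role &
             s$index == index & s$side == side & s$axis == axis, ]
    if (nrow(s) != 1) {
      rlang::abort(sprintf("point '%s %s %d' (%s, axis %s) not found in the %s summary",
                           structure, role, index, side, axis, grp))
    }
    s$mean_mm
  }
  mc <- pick(summary_control, "control")
  mx <- pick(summary_case, "case")
  tibble::tibble(structure = structure, role = role, index = as.integer(index),
                 side = side, axis = axis,
                 mean_control = mc, mean_case = mx,
                 difference = mx - mc, abs_difference = abs(mx - mc))
}

#' @rdname group_difference
#' @param point_summary A point summary holding both groups.
#' @export
group_differences <- function(point_summary) {
  ctrl <- point_summary[point_summary$group == "control", ]
  case <- point_summary[point_summary$group == "case", ]
  joined <- dplyr::inner_join(
    ctrl, case, by = c("structure", "role", "index", "side", "axis"),
    suffix = c("_control", "_case"))
  tibble::tibble(
    structure = joined$structure, role = joined$role, index = joined$index,
    side = joined$side, axis = joined$axis,
    mean_control = joined$mean_mm_control, mean_case = joined$mean_mm_case,
    difference = joined$mean_mm_case - joined$mean_mm_control,
    abs_difference = abs(joined$mean_mm_case - joined$mean_mm_control))
}

# Round-half-even to one decimal, then format with a fixed decimal; -0.0 is
# normalized to 0.0.
format_mm <- function(x) {
  v <- round(x, 1)
  v[v == 0] <- 0
  sprintf("%.1f", v)
}

#' Export a left-sided point summary table
#'
#' Lays out per-point coordinate summaries in the conventional left-sided
#' report shape: one row per structure point, per-axis columns holding
#' "mean +/- SD" for each group, values rounded half-even to one decimal at
#' export only.
#'
#' @param point_summary Point summary containing both groups (see
#'   [summarize_points()]; bind the two groups' rows when summarized
#'   separately).
#' @param path Optional CSV output path.
#' @param side Side to tabulate; default `"left"` (midline structures are
#'   always included).
#' @return The formatted tibble, invisibly if `path` is given.
#' @export
export_summary_table <- function(point_summary, path = NULL, side = "left") {
  s <- point_summary[point_summary$side %in% c(side, "midline"), ]
  if (!nrow(s)) rlang::abort("empty summary: nothing to export")
  s$cell <- paste0(format_mm(s$mean_mm), " ± ", format_mm(s$sd_mm))
  wide <- tidyr::pivot_wider(
    s[, c("group", "structure", "role", "index", "axis", "cell")],
    names_from = c("group", "axis"), values_from = "cell",
    names_glue = "{group}_{axis}")
  # stable anatomical ordering: organs, bones, then muscles as annotated
  order_key <- c("bladder", "cervix", "anorectum", "symphysis",
                 "sacrococcygeal_articulation", "ischial_spine", "coccyx",
                 "pvm", "pvam", "ppm", "pam", "prm", "icm", "coc")
  wide <- wide[order(match(wide$structure, order_key), wide$role, wide$index), ]
  wanted <- intersect(c("structure", "role", "index",
                        "control_x", "control_y", "control_z",
                        "case_x", "case_y", "case_z"), names(wide))
  wide <- wide[, wanted]
  if (!is.null(path)) {
    readr::write_csv(wide, path)
    return(invisible(wide))
  }
  wide
}
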