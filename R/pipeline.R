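#' Default color scheme for 3D cohort renderings
#'
#' Point colors keyed by `structure_role`: pubovisceral origin bright red,
#' pubovaginal insertion dark red, puboperineal insertion orange, puboanal
#' insertion yellow, puborectal origin and insertion green, iliococcygeus
#' origin and insertion blue, coccygeus insertion gray; organs and bones in
#' muted grays/black.
#'
#' @return Named character vector of colors.
#' @export
pics_palette <- function() {
  c(pvm_origin = "red", pvam_insertion = "darkred", ppm_insertion = "orange",
    pam_insertion = "yellow3", prm_origin = "green4", prm_insertion = "green4",
    icm_origin = "blue", icm_insertion = "blue", coc_insertion = "gray50",
    bladder_organ = "black", cervix_organ = "black", anorectum_organ = "black",
    symphysis_bone = "gray30", ischial_spine_bone = "gray30",
    coccyx_bone = "gray30", sacrococcygeal_articulation_bone = "gray30")
}

#' Render a 3D scatter of a PICS-space cohort
#'
#' Writes a PNG with one marker per annotated point, colored by structure
#' and role (default [pics_palette()]), axes labeled x/y/z in mm with the
#' PICS orientation (+x posterior, +y inferior, +z right).
#'
#' @param points Landmark tibble in PICS space.
#' @param path Output PNG path.
#' @param colors Color overrides, a named vector merged over
#'   [pics_palette()] by `structure_role` key.
#' @param width,height Device size in pixels.
#' @return `path`, invisibly.
#' @export
render_cohort_3d <- function(points, path, colors = NULL,
                             width = 900, height = 700) {
  assert_landmarks(points)
  if (!nrow(points)) rlang::abort("empty point set: nothing to render")
  if (any(points$space != "pics")) {
    rlang::abort("render_cohort_3d expects PICS-space input")
  }
  pal <- pics_palette()
  if (!is.null(colors)) pal[names(colors)] <- colors
  key <- paste(points$structure, points$role, sep = "_")
  col <- unname(pal[key])
  col[is.na(col)] <- "black"
  grDevices::png(path, width = width, height = height)
  on.exit(grDevices::dev.off(), add = TRUE)
  print(lattice::cloud(
    -y_mm ~ x_mm * z_mm, data = points, col = col, pch = 19, cex = 0.5,
    xlab = "x (posterior, mm)", ylab = "z (right, mm)",
    zlab = "-y (superior, mm)",
    main = "Landmark cloud in PICS space"))
  invisible(path)
}

#' Assemble and validate a pipeline configuration
#'
#' Exactly one input source must be configured: either `input` (path of an
#' annotation file to analyze) or `simulate = TRUE` (generate the two
#' synthetic study cohorts).
#'
#' @param out_dir Output directory (created if needed).
#' @param simulate Generate synthetic control/case cohorts (default `TRUE`).
#' @param input Optional path to an existing scanner-space annotation file.
#' @param n_control,n_case Cohort sizes when simulating (default 22 each).
#' @param seed Master seed for all randomness.
#' @param inclination_deg Pelvic inclination for frame construction and the
#'   generator.
#' @param midline_tolerance_mm Midline assertion tolerance of
#'   [transform_set()].
#' @param rater_noise_sd_mm Second-rater noise for the reliability arm.
#' @param n_reliability_per_group Subjects per group re-annotated by the
#'   second rater (default 5, mirroring a 5 + 5 reliability subset).
#' @param make_figure Write the 3D cohort rendering.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir, simulate = TRUE, input = NULL,
                            n_control = 22, n_case = 22, seed = 1,
                            inclination_deg = 34, midline_tolerance_mm = 1e-6,
                            rater_noise_sd_mm = 2,
                            n_reliability_per_group = 5, make_figure = TRUE) {
  if (isTRUE(simulate) && !is.null(input)) {
    rlang::abort("configure exactly one input source: simulation or an input file, not both")
  }
  if (!isTRUE(simulate) && is.null(input)) {
    rlang::abort("configure an input source: simulation or an input file")
  }
  structure(list(out_dir = out_dir, simulate = isTRUE(simulate), input = input,
                 n_control = n_control, n_case = n_case, seed = as.integer(seed),
                 inclination_deg = inclination_deg,
                 midline_tolerance_mm = midline_tolerance_mm,
                 rater_noise_sd_mm = rater_noise_sd_mm,
                 n_reliability_per_group = n_reliability_per_group,
                 make_figure = isTRUE(make_figure)),
            class = "pipeline_config")
}

#' Run the full morphometry pipeline
#'
#' Orchestrates simulate (or load) -> frame transform -> morphometry ->
#' group summaries and differences -> two-rater reliability -> figure, and
#' writes the documented CSV interfaces plus a manifest with MD5 content
#' hashes. Deterministic: identical configuration and seed give identical
#' numeric outputs.
#'
#' Outputs under `config$out_dir`: `annotations_scanner.csv`,
#' `annotations_pics.csv`, `morphometry.csv`, `point_summary.csv`,
#' `morphometry_summary.csv`, `group_differences.csv`,
#' `point_summary_table.csv`, `icc_report.csv`, optionally
#' `figures/cohort_3d.png`, and `manifest.csv`.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the in-memory results and output paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(config$out_dir, ...)
  written <- character()

  if (config$simulate) {
    ctrl <- generate_cohort(cohort_spec(
      "control", n_subjects = config$n_control, seed = sub_seed(config$seed, 1),
      inclination_deg = config$inclination_deg))
    case <- generate_cohort(cohort_spec(
      "case", n_subjects = config$n_case, seed = sub_seed(config$seed, 2),
      inclination_deg = config$inclination_deg))
    pics_truth <- dplyr::bind_rows(ctrl, case)
    scanner <- apply_pose(pics_truth, seed = sub_seed(config$seed, 3))
  } else {
    scanner <- read_annotations(config$input)
  }
  write_annotations(scanner, out("annotations_scanner.csv"))
  written <- c(written, "annotations_scanner.csv")

  pics <- transform_set(scanner, inclination_deg = config$inclination_deg,
                        midline_tolerance_mm = config$midline_tolerance_mm)
  write_annotations(pics, out("annotations_pics.csv"))
  written <- c(written, "annotations_pics.csv")

  records <- compute_morphometry(pics)
  readr::write_csv(records[, c("subject_id", "group", "side", "muscle",
                               "segment", "length_mm", "angle_coronal_deg",
                               "angle_sagittal_deg", "angle_transverse_deg")],
                   out("morphometry.csv"))
  written <- c(written, "morphometry.csv")

  point_summary <- summarize_points(pics)
  morph_summary <- summarize_morphometry(records)
  differences <- group_differences(point_summary)
  readr::write_csv(point_summary, out("point_summary.csv"))
  readr::write_csv(morph_summary, out("morphometry_summary.csv"))
  readr::write_csv(differences, out("group_differences.csv"))
  export_summary_table(point_summary, out("point_summary_table.csv"))
  written <- c(written, "point_summary.csv", "morphometry_summary.csv",
               "group_differences.csv", "point_summary_table.csv")

  set.seed(sub_seed(config$seed, 4))
  chosen <- unlist(lapply(split(unique(pics$subject_id),
                                sub("[0-9]+$", "", unique(pics$subject_id))),
                          function(s) sample(s, min(config$n_reliability_per_group,
                                                    length(s)))))
  subset <- pics[pics$subject_id %in% chosen, ]
  second <- add_rater_noise(subset, config$rater_noise_sd_mm, rater = "R2",
                            seed = sub_seed(config$seed, 5))
  icc_report <- reliability_report(dplyr::bind_rows(subset, second))
  readr::write_csv(icc_report, out("icc_report.csv"))
  written <- c(written, "icc_report.csv")

  if (config$make_figure) {
    dir.create(out("figures"), showWarnings = FALSE)
    render_cohort_3d(pics, out("figures", "cohort_3d.png"))
    written <- c(written, file.path("figures", "cohort_3d.png"))
  }

  manifest <- tibble::tibble(
    file = written,
    md5 = unname(tools::md5sum(file.path(config$out_dir, written))),
    bytes = file.size(file.path(config$out_dir, written)))
  readr::write_csv(manifest, out("manifest.csv"))

  invisible(list(points = pics, records = records,
                 point_summary = point_summary,
                 morphometry_summary = morph_summary,
                 differences = differences, icc_report = icc_report,
                 manifest = manifest, out_dir = config$out_dir))
}
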