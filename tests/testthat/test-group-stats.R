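two_subject_points <- function(ys = c(-10, -14)) {
  tibble::tibble(
    subject_id = c("a", "b"), group = "control", rater = "R1",
    structure = "bladder", role = "organ", index = 1L, side = "midline",
    x_mm = c(1, 3), y_mm = ys, z_mm = 0, space = "pics")
}

test_that("point summaries use the sample mean and n-1 SD", {
  s <- summarize_points(two_subject_points())
  y <- s[s$axis == "y", ]
  expect_equal(y$mean_mm, -12)
  expect_equal(y$sd_mm, sqrt(8))
  expect_equal(y$n, 2L)

  one <- summarize_points(two_subject_points()[1, ])
  expect_equal(one$sd_mm, rep(0, 3))
  expect_equal(one$mean_mm[one$axis == "x"], 1)
})

test_that("summaries are permutation-invariant and mean-stable", {
  pts <- generate_cohort(cohort_spec("control", n_subjects = 6, seed = 14))
  s1 <- summarize_points(pts)
  s2 <- summarize_points(pts[rev(seq_len(nrow(pts))), ])
  expect_equal(dplyr::arrange(s1, structure, role, index, side, axis),
               dplyr::arrange(s2, structure, role, index, side, axis))

  # adding a subject exactly at the mean keeps the mean, shrinks the SD
  p <- two_subject_points()
  at_mean <- p[1, ]
  at_mean$subject_id <- "c"; at_mean$x_mm <- 2; at_mean$y_mm <- -12
  s3 <- summarize_points(dplyr::bind_rows(p, at_mean))
  y2 <- s3[s3$axis == "y", ]
  expect_equal(y2$mean_mm, -12)
  expect_lte(y2$sd_mm, sqrt(8))
})

test_that("morphometry summaries report inclusive-convention quartiles", {
  pts <- generate_cohort(cohort_spec("case", n_subjects = 5, seed = 6))
  rec <- compute_morphometry(pts)
  s <- summarize_morphometry(rec)
  row <- s[s$segment == "prm" & s$side == "left" & s$measure == "length_mm", ]
  vals <- rec$length_mm[rec$segment == "prm" & rec$side == "left"]
  expect_equal(row$median, stats::median(vals))
  expect_equal(row$q1, stats::quantile(vals, 0.25, type = 7, names = FALSE))
  expect_equal(row$q3, stats::quantile(vals, 0.75, type = 7, names = FALSE))
  expect_true(all(s$q1 <= s$median & s$median <= s$q3))
  expect_true(all(s$sd >= 0))
})

test_that("group differences reproduce the fixture insertion displacements", {
  ctrl <- summarize_points(zero_noise_cohort("control", n = 2))
  case <- summarize_points(zero_noise_cohort("case", n = 2))

  d <- group_difference(ctrl, case, "pvam", "insertion", 1, "left", "y")
  expect_equal(d$abs_difference, 7.7)
  expect_equal(d$difference, 7.7)  # cases sit lower (less negative y)

  expect_equal(group_difference(ctrl, case, "ppm", "insertion", 1, "left",
                                "y")$abs_difference, 8.8)
  expect_equal(group_difference(ctrl, case, "pam", "insertion", 2, "left",
                                "y")$abs_difference, 8.2)
  expect_equal(group_difference(ctrl, case, "prm", "insertion", 1, "left",
                                "y")$abs_difference, 1.8)
  expect_equal(group_difference(ctrl, case, "ppm", "insertion", 1, "left",
                                "x")$abs_difference, 14.6)

  expect_error(group_difference(ctrl, case, "pvm", "origin", 2, "left", "y"),
               "not found")
})

test_that("group_differences is antisymmetric and zero on identical groups", {
  ctrl <- summarize_points(zero_noise_cohort("control", n = 2))
  case <- summarize_points(zero_noise_cohort("case", n = 2))
  both <- dplyr::bind_rows(ctrl, case)
  d <- group_differences(both)
  swapped <- both
  swapped$group <- c(control = "case", case = "control")[swapped$group]
  d2 <- group_differences(swapped)
  j <- dplyr::inner_join(d, d2, by = c("structure", "role", "index", "side", "axis"))
  expect_equal(j$difference.x, -j$difference.y)

  same <- ctrl
  same$group <- "case"
  d0 <- group_differences(dplyr::bind_rows(ctrl, same))
  expect_true(all(d0$difference == 0))
})

test_that("export table mirrors the left-sided layout with one-decimal cells", {
  ctrl <- summarize_points(zero_noise_cohort("control", n = 3))
  case <- summarize_points(zero_noise_cohort("case", n = 3))
  path <- withr::local_tempfile(fileext = ".csv")
  export_summary_table(dplyr::bind_rows(ctrl, case), path)
  tab <- readr::read_csv(path, show_col_types = FALSE)
  expect_true(all(c("control_x", "control_y", "control_z",
                    "case_x", "case_y", "case_z") %in% names(tab)))
  ppm <- tab[tab$structure == "ppm", ]
  expect_equal(ppm$control_x, "22.0 ± 0.0")
  expect_equal(ppm$case_x, "36.6 ± 0.0")
  coccyx <- tab[tab$structure == "coccyx", ]
  expect_equal(coccyx$control_z, "0.0 ± 0.0")

  expect_error(export_summary_table(ctrl[0, ]), "empty")
})

test_that("export rounding is half-even at one decimal, applied at export only", {
  expect_equal(picsmorph:::format_mm(36.449), "36.4")
  expect_equal(picsmorph:::format_mm(2.25), "2.2")
  expect_equal(picsmorph:::format_mm(2.35), "2.4")
  expect_equal(picsmorph:::format_mm(-0.04), "0.0")
})

test_that("summarize_cohort bundles point and morphometry summaries", {
  pts <- generate_cohort(cohort_spec("control", n_subjects = 3, seed = 21))
  s <- summarize_cohort(pts)
  expect_named(s, c("points", "morphometry"))
  expect_equal(unique(s$points$group), "control")
  expect_equal(nrow(s$morphometry), 9 * 2 * 4)  # segments x sides x measures
})
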