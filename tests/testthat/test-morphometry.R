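test_that("auxiliary points are the three equidistant interior points", {
  aux <- auxiliary_points(c(0, 0, 0), c(4, 0, 0))
  expect_equal(aux, rbind(c(1, 0, 0), c(2, 0, 0), c(3, 0, 0)))

  p <- c(2.5, -1, 7)
  expect_equal(auxiliary_points(p, p), matrix(rep(p, 3), nrow = 3, byrow = TRUE))

  # fixture means: control left PVM border origins
  aux <- auxiliary_points(c(9.3, -34.5, -30.3), c(-4.3, -14.0, -16.6))
  expect_equal(unname(aux[2, ]), c(2.5, -24.25, -23.45))

  # five points (borders + auxiliaries) are equally spaced
  a <- c(1, 2, 3); b <- c(-5, 8, 0.5)
  five <- rbind(a, auxiliary_points(a, b), b)
  gaps <- sqrt(rowSums(diff(five)^2))
  expect_lt(max(abs(gaps - gaps[1])), 1e-12)
})

test_that("auxiliary points are rigid-transform equivariant", {
  set.seed(17)
  for (rep in 1:10) {
    pose <- random_pose()
    a <- stats::rnorm(3, 0, 30); b <- stats::rnorm(3, 0, 30)
    lhs <- auxiliary_points(drop(pose_points(rbind(a), pose)),
                            drop(pose_points(rbind(b), pose)))
    rhs <- pose_points(auxiliary_points(a, b), pose)
    expect_lt(max(abs(lhs - rhs)), 1e-9)
  }
})

test_that("muscle_length is the Euclidean distance", {
  expect_equal(muscle_length(c(0, 0, 0), c(0, 0, 0)), 0)
  expect_equal(muscle_length(c(0, 0, 0), c(3, 4, 0)), 5)
  expect_equal(muscle_length(c(1, 2, 2), c(3, 4, 5)), sqrt(17))
})

test_that("plane angles follow the posterior/inferior/right sign rule", {
  expect_equal(plane_angles(c(0, 0, 0), c(1, 0, 0)),
               c(coronal = 90, transverse = 0, sagittal = 0))
  expect_equal(plane_angles(c(0, 0, 0), c(0, -1, 0)),
               c(coronal = 0, transverse = -90, sagittal = 0))
  expect_equal(plane_angles(c(0, 0, 0), c(0, 0, 1)),
               c(coronal = 0, transverse = 0, sagittal = 90))
  expect_equal(plane_angles(c(0, 0, 0), c(1, 1, 0)),
               c(coronal = 45, transverse = 45, sagittal = 0))
  expect_error(plane_angles(c(1, 1, 1), c(1, 1, 1)), "zero-length")
})

test_that("squared sines of the three plane angles sum to one", {
  set.seed(23)
  for (rep in 1:25) {
    v <- stats::rnorm(3)
    ang <- plane_angles(c(0, 0, 0), v) * pi / 180
    expect_equal(sum(sin(ang)^2), 1, tolerance = 1e-12)
    expect_true(all(ang * 180 / pi >= -90 & ang * 180 / pi <= 90))
  }
})

test_that("segment resolution applies the point-selection rules", {
  pts <- noisy_subject(seed = 4)
  graph <- default_muscle_graph()

  # PAM effective insertion is the middle marked point (index 2)
  seg <- resolve_segment(pts, graph, "pam", "left")
  mid <- pts[pts$structure == "pam" & pts$index == 2 & pts$side == "left", ]
  expect_equal(unname(seg$insertion), c(mid$x_mm, mid$y_mm, mid$z_mm))

  # PVM border origins (1, 3) feed the auxiliary construction
  o1 <- pts[pts$structure == "pvm" & pts$index == 1 & pts$side == "left", ]
  o3 <- pts[pts$structure == "pvm" & pts$index == 3 & pts$side == "left", ]
  aux <- auxiliary_points(c(o1$x_mm, o1$y_mm, o1$z_mm),
                          c(o3$x_mm, o3$y_mm, o3$z_mm))
  expect_equal(unname(resolve_segment(pts, graph, "ppm", "left")$origin),
               unname(aux[2, ]))
  expect_equal(unname(resolve_segment(pts, graph, "pvam", "left")$origin),
               unname(aux[1, ]))

  # a missing required point is named in the error
  no_pam <- pts[!(pts$structure == "pam" & pts$side == "left"), ]
  expect_error(resolve_segment(no_pam, graph, "pam", "left"),
               "pam insertion 2")

  # multi-segment muscles need the segment label
  expect_error(resolve_segment(pts, graph, "icm", "left"), "segment")
  seg1 <- resolve_segment(pts, graph, "icm", "left", "icm_1")
  o <- pts[pts$structure == "icm" & pts$role == "origin" &
             pts$index == 1 & pts$side == "left", ]
  expect_equal(unname(seg1$origin), c(o$x_mm, o$y_mm, o$z_mm))
})

test_that("morphometry at the fixture means matches hand arithmetic", {
  pts <- zero_noise_cohort("control", n = 1)
  rec <- compute_morphometry(pts)
  expect_equal(nrow(rec), 2 * 9)  # 9 segments per side

  # PRM left: origin 2 (2.5, -2.8, -17.0) to insertion 1 (40.3, -6.5, -1.4)
  v <- c(40.3, -6.5, -1.4) - c(2.5, -2.8, -17.0)
  prm <- rec[rec$segment == "prm" & rec$side == "left", ]
  expect_equal(prm$length_mm, sqrt(sum(v^2)))
  expect_equal(prm$angle_coronal_deg, asin(v[1] / sqrt(sum(v^2))) * 180 / pi)

  # PVaM left: auxiliary 1 to the midpoint of its two insertions
  aux1 <- c(9.3, -34.5, -30.3) + 0.25 * (c(-4.3, -14.0, -16.6) - c(9.3, -34.5, -30.3))
  ins <- (c(5.3, -12.3, -16.2) + c(17.4, -11.6, -12.5)) / 2
  pvam <- rec[rec$segment == "pvam" & rec$side == "left", ]
  expect_equal(pvam$length_mm, sqrt(sum((ins - aux1)^2)))

  # COC left segment 1: ischial spine to COC insertion 1
  v <- c(82.4, -59.5, -5.0) - c(55.5, -47.9, -57.5)
  expect_equal(rec$length_mm[rec$segment == "coc_1" & rec$side == "left"],
               sqrt(sum(v^2)))
})

test_that("mirroring across the midsagittal plane negates only sagittal angles", {
  pts <- noisy_subject(seed = 12)
  mirrored <- pts
  mirrored$z_mm <- -mirrored$z_mm
  mirrored$side <- c(left = "right", right = "left",
                     midline = "midline")[mirrored$side]
  a <- compute_morphometry(pts)
  b <- compute_morphometry(mirrored)
  b$side <- c(left = "right", right = "left")[b$side]
  key <- c("side", "muscle", "segment")
  j <- dplyr::inner_join(a, b, by = key, suffix = c("", ".m"))
  expect_equal(nrow(j), nrow(a))
  expect_equal(j$length_mm, j$length_mm.m, tolerance = 1e-9)
  expect_equal(j$angle_coronal_deg, j$angle_coronal_deg.m, tolerance = 1e-9)
  expect_equal(j$angle_transverse_deg, j$angle_transverse_deg.m, tolerance = 1e-9)
  expect_equal(j$angle_sagittal_deg, -j$angle_sagittal_deg.m, tolerance = 1e-9)
})

test_that("morphometry is invariant under rigid scanner pose", {
  pts <- noisy_subject(seed = 19)
  base <- compute_morphometry(pts)
  for (s in 1:5) {
    posed <- apply_pose(pts, seed = s)
    rec <- transform_set(posed) |> compute_morphometry()
    expect_lt(max(abs(rec$length_mm - base$length_mm)), 1e-6)
    expect_lt(max(abs(rec$angle_coronal_deg - base$angle_coronal_deg)), 1e-6)
    expect_lt(max(abs(rec$angle_sagittal_deg - base$angle_sagittal_deg)), 1e-6)
    expect_lt(max(abs(rec$angle_transverse_deg - base$angle_transverse_deg)), 1e-6)
  }
})

test_that("morphometry requires PICS space and complete annotation", {
  pts <- noisy_subject(seed = 2)
  posed <- apply_pose(pts, seed = 2)
  expect_error(compute_morphometry(posed), "PICS-space")
  incomplete <- pts[!(pts$structure == "prm" & pts$index == 2 &
                        pts$side == "left"), ]
  expect_error(compute_morphometry(incomplete), "incomplete")
})

test_that("the packaged muscle graph file equals the in-code default", {
  path <- system.file("extdata", "muscle_graph.yaml", package = "picsmorph")
  expect_identical(unclass(read_muscle_graph(path)),
                   unclass(default_muscle_graph()))
  tmp <- withr::local_tempfile(fileext = ".yaml")
  write_muscle_graph(default_muscle_graph(), tmp)
  expect_identical(unclass(read_muscle_graph(tmp)),
                   unclass(default_muscle_graph()))
})
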