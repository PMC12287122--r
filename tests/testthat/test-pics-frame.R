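canonical_bones <- function(theta_deg = 34) {
  th <- theta_deg * pi / 180
  list(inferior_pubic_point = c(0, 0, 0),
       sacrococcygeal_articulation = 110 * c(cos(th), -sin(th), 0),
       ischial_spine_left = c(55.5, -47.9, -57.5),
       ischial_spine_right = c(55.5, -47.9, 57.5))
}

test_that("canonical bones give the identity frame", {
  f <- build_frame(canonical_bones(34), inclination_deg = 34)
  expect_lt(max(abs(f$rotation - diag(3))), 1e-12)
  expect_equal(unname(f$origin), c(0, 0, 0))
  expect_equal(unname(to_pics(f, c(0, 0, 0))), c(0, 0, 0))
})

test_that("build_frame recovers a known rigid pose to 1e-9", {
  set.seed(11)
  bones <- canonical_bones(34)
  for (rep in 1:10) {
    pose <- random_pose()
    posed <- lapply(bones, function(p) drop(crossprod(pose$Q, p)) + pose$t)
    f <- build_frame(posed, inclination_deg = 34)
    expect_lt(max(abs(f$rotation %*% t(pose$Q) - diag(3))), 1e-9)
    expect_lt(max(abs(f$origin - pose_points(rbind(c(0, 0, 0)), pose))), 1e-9)
    # sacrococcygeal point maps onto the midsagittal plane, posterior-superior
    sc <- to_pics(f, posed$sacrococcygeal_articulation)
    expect_lt(abs(sc[3]), 1e-9)
    expect_gt(sc[1], 0)
    expect_lt(sc[2], 0)
  }
})

test_that("the pubis-to-sacrococcygeal line subtends the inclination angle", {
  for (theta in c(20, 34, 55)) {
    f <- build_frame(canonical_bones(40), inclination_deg = theta)
    sc <- to_pics(f, canonical_bones(40)$sacrococcygeal_articulation)
    expect_equal(unname(atan2(-sc[2], sc[1]) * 180 / pi), theta,
                 tolerance = 1e-9)
  }
})

test_that("degenerate landmark configurations raise geometry errors", {
  b <- canonical_bones()
  bad <- b; bad$ischial_spine_right <- bad$ischial_spine_left
  expect_error(build_frame(bad), "spines")
  bad <- b; bad$sacrococcygeal_articulation <- b$inferior_pubic_point
  expect_error(build_frame(bad), "coincides")
  bad <- b
  bad$inferior_pubic_point <- (b$ischial_spine_left + b$ischial_spine_right) / 2
  bad$sacrococcygeal_articulation <- bad$inferior_pubic_point + c(0, 0, 10)
  expect_error(build_frame(bad), "degenerate")
  expect_error(build_frame(b, inclination_deg = 0), "strictly between")
  expect_error(build_frame(b, inclination_deg = 95), "strictly between")
})

test_that("frames are rigid: distances and angles preserved to 1e-9", {
  set.seed(21)
  for (rep in 1:20) {
    pose <- random_pose()
    bones <- lapply(canonical_bones(), function(p)
      drop(crossprod(pose$Q, p)) + pose$t)
    f <- build_frame(bones)
    pts <- matrix(stats::rnorm(30, 0, 50), ncol = 3)
    mapped <- to_pics(f, pts)
    expect_lt(max(abs(stats::dist(pts) - stats::dist(mapped))), 1e-9)
    # triple angle preservation via one representative triangle
    ang <- function(m) {
      u <- m[1, ] - m[2, ]; v <- m[3, ] - m[2, ]
      acos(sum(u * v) / sqrt(sum(u^2) * sum(v^2)))
    }
    expect_equal(ang(pts[1:3, ]), ang(mapped[1:3, ]), tolerance = 1e-9)
    # handedness: x cross y = z
    R <- f$rotation
    expect_lt(max(abs(picsmorph:::cross3(R[1, ], R[2, ]) - R[3, ])), 1e-9)
    expect_equal(det(R), 1, tolerance = 1e-9)
  }
})

test_that("from_pics inverts to_pics on the fixture means", {
  set.seed(31)
  pose <- random_pose()
  bones <- lapply(canonical_bones(), function(p)
    drop(crossprod(pose$Q, p)) + pose$t)
  f <- build_frame(bones)
  m <- as.matrix(table2_point_model("control")[, c("mean_x", "mean_y", "mean_z")])
  expect_lt(max(abs(from_pics(f, to_pics(f, m)) - m)), 1e-9)
  expect_equal(unname(from_pics(f, c(0, 0, 0))), unname(f$origin))
})

test_that("transform_set restores generated coordinates and guards its input", {
  pts <- noisy_subject(seed = 8)
  sc <- apply_pose(pts, seed = 9)
  back <- transform_set(sc)
  expect_lt(max(abs(coords(sort_points(pts)) - coords(sort_points(back)))), 1e-6)
  expect_setequal(unique(back$space), "pics")
  expect_error(transform_set(back), "already in PICS space")

  # an already-canonical subject passes through unchanged
  relabeled <- pts; relabeled$space <- "scanner"
  same <- transform_set(relabeled)
  expect_lt(max(abs(coords(sort_points(pts)) - coords(sort_points(same)))), 1e-9)

  # midline annotation noise is surfaced, not hidden
  shifted <- relabeled
  i <- which(shifted$structure == "coccyx")
  shifted$z_mm[i] <- shifted$z_mm[i] + 0.5
  expect_warning(transform_set(shifted), "midline")
})
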