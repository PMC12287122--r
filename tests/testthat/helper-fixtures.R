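# Shared fixtures, built in code.

# Point model with all SDs zeroed: every generated subject sits exactly at
# the group means.
zero_noise_model <- function(group) {
  m <- table2_point_model(group)
  m$sd_x <- m$sd_y <- m$sd_z <- 0
  m
}

zero_noise_cohort <- function(group, n = 2, seed = 1) {
  generate_cohort(cohort_spec(group, n_subjects = n,
                              point_model = zero_noise_model(group),
                              seed = seed))
}

# One noisy synthetic subject in PICS space.
noisy_subject <- function(group = "control", seed = 42) {
  generate_cohort(cohort_spec(group, n_subjects = 1, seed = seed))
}

# A random proper rigid pose applied directly to a coordinate matrix.
random_pose <- function() {
  ang <- stats::runif(3, -180, 180)
  list(Q = picsmorph:::euler_rotation(ang),
       t = stats::runif(3, -100, 100))
}

pose_points <- function(m, pose) {
  t(crossprod(pose$Q, t(m)) + pose$t)
}

coords <- function(points) as.matrix(points[, c("x_mm", "y_mm", "z_mm")])

sort_points <- function(points) {
  points[order(points$subject_id, points$rater, points$structure,
               points$role, points$index, points$side), ]
}
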