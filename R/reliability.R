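#' Intraclass correlation from a subjects-by-raters grid
#'
#' Two-way ANOVA-based intraclass correlation for inter-rater agreement.
#' The default model is ICC(2,1) -- two-way random effects, absolute
#' agreement, single rater: raters are treated as a random sample and
#' single-rater scores are the unit of analysis. The consistency form
#' ICC(3,1) (two-way mixed, rater offsets ignored) is also available.
#' Confidence intervals use the classical F-distribution construction
#' (Shrout-Fleiss).
#'
#' Mean squares come from the two-way decomposition value ~ subject + rater
#' fitted with `stats::aov`. With n subjects, k raters, MSR/MSC/MSE the
#' subject, rater, and residual mean squares:
#' ICC(2,1) = (MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n),
#' ICC(3,1) = (MSR - MSE) / (MSR + (k-1) MSE).
#'
#' A grid with (numerically) zero total variance is flagged undefined: the
#' ratio has no information (this is the situation of coordinates that are 0
#' by definition, e.g. the coccyx z coordinate on the midsagittal plane).
#'
#' @param values n x k numeric matrix: rows subjects, columns raters; no
#'   missing cells, n >= 3, k >= 2.
#' @param model `"ICC2"` (absolute agreement, default) or `"ICC3"`
#'   (consistency); single-rater forms.
#' @param conf_level Confidence level for the interval (default 0.95).
#' @return One-row tibble: `model`, `icc`, `ci_low`, `ci_high`, `label`
#'   (Landis-Koch), `defined`, `n_subjects`, `n_raters`.
#' @export
#' @examples
#' m <- cbind(r1 = c(9, 6, 8, 7, 10, 6), r2 = c(2, 1, 4, 1, 5, 2))
#' icc(m, model = "ICC2")
icc <- function(values, model = c("ICC2", "ICC3"), conf_level = 0.95) {
  model <- match.arg(model)
  values <- as.matrix(values)
  if (!is.numeric(values) || anyNA(values)) {
    rlang::abort("rating grid must be numeric with no missing cells")
  }
  n <- nrow(values)
  k <- ncol(values)
  if (n < 3 || k < 2) rlang::abort("need at least 3 subjects and 2 raters")
  model_label <- if (model == "ICC2") "ICC(2,1)" else "ICC(3,1)"

  scale <- max(abs(values - mean(values)))
  if (scale < 1e-12 * max(1, abs(mean(values)))) {
    return(tibble::tibble(model = model_label, icc = NA_real_,
                          ci_low = NA_real_, ci_high = NA_real_,
                          label = "undefined", defined = FALSE,
                          n_subjects = n, n_raters = k))
  }

  d <- data.frame(value = as.vector(values),
                  subject = factor(rep(seq_len(n), times = k)),
                  rater = factor(rep(seq_len(k), each = n)))
  # perfect-agreement grids trip aov's F-test warning; degenerate cases are
  # handled explicitly above and below, so the warning carries no information
  ms <- suppressWarnings(
    stats::anova(stats::aov(value ~ subject + rater, data = d))$`Mean Sq`)
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  alpha <- 1 - conf_level

  if (model == "ICC3") {
    est <- (msr - mse) / (msr + (k - 1) * mse)
    if (mse <= 0) {
      lo <- hi <- 1
    } else {
      f <- msr / mse
      df2 <- (n - 1) * (k - 1)
      fl <- f / stats::qf(1 - alpha / 2, n - 1, df2)
      fu <- f * stats::qf(1 - alpha / 2, df2, n - 1)
      lo <- (fl - 1) / (fl + k - 1)
      hi <- (fu - 1) / (fu + k - 1)
    }
  } else {
    est <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
    # floor MSE for the interval only, so perfect-agreement grids stay finite
    mse_ci <- max(mse, 1e-12 * max(msr, msc, 1))
    r <- est
    fj <- msc / mse_ci
    vn <- (k - 1) * (n - 1) *
      (k * r * fj + n * (1 + (k - 1) * r) - k * r)^2
    vd <- (n - 1) * k^2 * r^2 * fj^2 +
      (n * (1 + (k - 1) * r) - k * r)^2
    v <- vn / vd
    f3u <- stats::qf(1 - alpha / 2, n - 1, v)
    f3l <- stats::qf(1 - alpha / 2, v, n - 1)
    lo <- n * (msr - f3u * mse_ci) /
      (f3u * (k * msc + (k * n - k - n) * mse_ci) + n * msr)
    hi <- n * (f3l * msr - mse_ci) /
      (k * msc + (k * n - k - n) * mse_ci + n * f3l * msr)
  }
  lo <- min(max(lo, -1), est)
  hi <- max(min(hi, 1), est)
  tibble::tibble(model = model_label, icc = est, ci_low = lo, ci_high = hi,
                 label = landis_koch_label(est), defined = TRUE,
                 n_subjects = n, n_raters = k)
}

#' Landis-Koch qualitative agreement label
#'
#' Maps an agreement coefficient to the conventional qualitative bands,
#' resolved as contiguous half-open intervals: poor [-1, 0.2), fair
#' [0.2, 0.4], moderate (0.4, 0.7], substantial (0.7, 0.8], almost perfect
#' (0.8, 1]. `NA` maps to `"undefined"`.
#'
#' @param estimate Numeric vector of coefficients in [-1, 1] (or `NA`).
#' @return Character vector of labels.
#' @export
#' @examples
#' landis_koch_label(c(0.1, 0.2, 0.55, 0.75, 0.95))
landis_koch_label <- function(estimate) {
  vapply(estimate, function(x) {
    if (is.na(x)) return("undefined")
    if (x < 0.2) "poor"
    else if (x <= 0.4) "fair"
    else if (x <= 0.7) "moderate"
    else if (x <= 0.8) "substantial"
    else "almost_perfect"
  }, character(1))
}

#' Two-rater reliability report per point, axis, and side
#'
#' Builds the subjects-by-raters grid for every (structure, role, index,
#' side, axis) present in a two-rater annotation collection and computes the
#' intraclass correlation with its confidence interval and Landis-Koch
#' label. The symphysis point is excluded (all its coordinates are 0 by
#' definition); any other grid with zero variance -- notably the coccyx z
#' coordinate, defined as 0 on the midsagittal plane -- is reported with
#' `defined = FALSE`.
#'
#' @param points Landmark tibble (PICS space) containing the same subjects
#'   annotated by exactly two (or more) raters.
#' @param model,conf_level Passed to [icc()].
#' @return Tibble: `structure`, `role`, `index`, `side`, `axis`, `icc`,
#'   `ci_low`, `ci_high`, `model`, `label`, `defined`, `n_subjects`,
#'   `n_raters`.
#' @export
reliability_report <- function(points, model = "ICC2", conf_level = 0.95) {
  assert_landmarks(points)
  raters <- sort(unique(points$rater))
  if (length(raters) < 2) rlang::abort("reliability needs at least two raters")
  by_rater <- split(points$subject_id, points$rater)
  subj_sets <- lapply(by_rater, function(s) sort(unique(s)))
  if (length(unique(subj_sets)) != 1) {
    rlang::abort("all raters must annotate the same subjects")
  }
  subjects <- subj_sets[[1]]

  pts <- points[points$structure != "symphysis", ]
  long <- tidyr::pivot_longer(pts, cols = c("x_mm", "y_mm", "z_mm"),
                              names_to = "axis", values_to = "value")
  long$axis <- sub("_mm$", "", long$axis)

  keys <- dplyr::distinct(long[, c("structure", "role", "index", "side", "axis")])
  purrr::pmap_dfr(keys, function(structure, role, index, side, axis) {
    cell <- long[long$structure == structure & long$role == role &
                   long$index == index & long$side == side & long$axis == axis, ]
    grid <- matrix(NA_real_, nrow = length(subjects), ncol = length(raters),
                   dimnames = list(subjects, raters))
    grid[cbind(match(cell$subject_id, subjects), match(cell$rater, raters))] <-
      cell$value
    if (anyNA(grid)) {
      rlang::abort(sprintf("missing cells for '%s %s %d' (%s, axis %s)",
                           structure, role, index, side, axis))
    }
    res <- icc(grid, model = model, conf_level = conf_level)
    tibble::tibble(structure = structure, role = role, index = index,
                   side = side, axis = axis,
                   icc = res$icc, ci_low = res$ci_low, ci_high = res$ci_high,
                   model = res$model, label = res$label, defined = res$defined,
                   n_subjects = res$n_subjects, n_raters = res$n_raters)
  })
}
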