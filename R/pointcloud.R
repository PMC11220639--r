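#' Simulate two-arm 3D point clouds of ligase--DNA complexes
#'
#' Each cloud emulates the segmented DNA density of one negatively
#' stained complex: two straight arms of equal length meeting at the
#' origin, with the conformer class drawn from `proportions`, the true
#' bend angle jittered by Gaussian noise (reflected at 0), a uniformly
#' random 3D orientation, points sampled uniformly along each arm, and
#' isotropic positional noise.
#'
#' @param n number of clouds.
#' @param angle_set conformer bend angles in degrees (defaults
#'   0, 20, 60, 100).
#' @param proportions class proportions over `angle_set` (defaults to
#'   the ligase--AMP--DNA particle percentages 0.54, 0.30, 0.10, 0.06).
#' @param points_per_arm points sampled per arm (default 200).
#' @param arm_length arm length in nm (default 8.5, a 25-bp arm).
#' @param angle_noise_sd Gaussian jitter of the true angle in degrees
#'   (default 5).
#' @param positional_noise_sd isotropic point noise in nm (default 0.3).
#' @param seed master integer seed.
#' @return A list of class `point_cloud_set`: `clouds` (each a
#'   data.frame `x`, `y`, `z`, `arm` with both arm labels),
#'   `true_angle` (jittered, degrees), `true_class` (index into
#'   `angle_set`), and the generation parameters.
#' @export
simulate_complex_pointclouds <- function(n,
                                         angle_set = c(0, 20, 60, 100),
                                         proportions =
                                           c(0.54, 0.30, 0.10, 0.06),
                                         points_per_arm = 200L,
                                         arm_length = 8.5,
                                         angle_noise_sd = 5,
                                         positional_noise_sd = 0.3,
                                         seed = 1L) {
  if (any(angle_set < 0 | angle_set >= 180)) {
    stop("`angle_set` must lie in [0, 180)", call. = FALSE)
  }
  check_simplex(proportions, length(angle_set), "proportions")
  if (arm_length <= 0) stop("`arm_length` must be > 0", call. = FALSE)
  with_seed(seed, {
    classes <- sample(seq_along(angle_set), n, replace = TRUE,
                      prob = proportions)
    true_angle <- abs(angle_set[classes] +
                        stats::rnorm(n, sd = angle_noise_sd))
    true_angle <- pmin(true_angle, 180 - 1e-9)
    clouds <- lapply(seq_len(n), function(i) {
      # random orthonormal frame
      u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
      v <- stats::rnorm(3); v <- v - sum(v * u) * u
      v <- v / sqrt(sum(v^2))
      w2 <- c(u[2] * v[3] - u[3] * v[2],
              u[3] * v[1] - u[1] * v[3],
              u[1] * v[2] - u[2] * v[1])
      psi <- stats::runif(1, 0, 2 * pi)
      inter <- deg2rad(180 - true_angle[i])   # inter-arm angle
      dir2 <- cos(inter) * u +
        sin(inter) * (cos(psi) * v + sin(psi) * w2)
      t1 <- stats::runif(points_per_arm, 0, arm_length)
      t2 <- stats::runif(points_per_arm, 0, arm_length)
      pts <- rbind(outer(t1, u), outer(t2, dir2)) +
        matrix(stats::rnorm(2 * points_per_arm * 3,
                            sd = positional_noise_sd),
               ncol = 3)
      data.frame(x = pts[, 1], y = pts[, 2], z = pts[, 3],
                 arm = rep(c("arm1", "arm2"), each = points_per_arm),
                 stringsAsFactors = FALSE)
    })
    structure(list(clouds = clouds, true_angle = true_angle,
                   true_class = classes, angle_set = angle_set,
                   proportions = proportions,
                   points_per_arm = as.integer(points_per_arm),
                   arm_length = arm_length,
                   angle_noise_sd = angle_noise_sd,
                   positional_noise_sd = positional_noise_sd,
                   seed = as.integer(seed)),
              class = "point_cloud_set")
  })
}

#' Measure the DNA bend angle of a two-arm point cloud
#'
#' Fits a total-least-squares (principal-axis) line through each
#' labelled arm, orients both directions to point away from the shared
#' junction (the arm ends nearest the overall centroid), and returns
#' the bend angle: 180 degrees minus the inter-arm angle, so collinear
#' arms measure 0.
#'
#' @param cloud a data.frame with columns `x`, `y`, `z`, `arm` (two
#'   labels), or one element of
#'   [simulate_complex_pointclouds()]`$clouds`.
#' @return Bend angle in degrees, in `[0, 180)`.
#' @export
measure_bend_angle <- function(cloud) {
  need <- c("x", "y", "z", "arm")
  if (!is.data.frame(cloud) || !all(need %in% names(cloud))) {
    stop("`cloud` must be a data.frame with columns x, y, z, arm",
         call. = FALSE)
  }
  arms <- split(cloud[, c("x", "y", "z")], cloud$arm)
  if (length(arms) != 2L) stop("cloud must contain exactly two arm labels",
                               call. = FALSE)
  if (any(vapply(arms, nrow, integer(1)) < 3L)) {
    stop("each arm needs at least 3 points", call. = FALSE)
  }
  centroid <- colMeans(cloud[, c("x", "y", "z")])
  fit_arm <- function(m) {
    m <- as.matrix(m)
    cen <- colMeans(m)
    mc <- sweep(m, 2, cen)
    sv <- svd(mc, nu = 0, nv = 1)
    if (sv$d[1] < 1e-12) {
      stop("degenerate arm: all points coincide", call. = FALSE)
    }
    dir <- sv$v[, 1]
    proj <- mc %*% dir
    ends <- rbind(cen + min(proj) * dir, cen + max(proj) * dir)
    # junction end = the end closer to the overall centroid
    d_ends <- rowSums(sweep(ends, 2, centroid)^2)
    if (d_ends[1] <= d_ends[2]) dir else -dir
  }
  d1 <- fit_arm(arms[[1]])
  d2 <- fit_arm(arms[[2]])
  cosang <- max(-1, min(1, sum(d1 * d2)))
  180 - rad2deg(acos(cosang))
}

#' Assign a measured bend angle to a conformer class
#'
#' Nearest conformer angle wins; midpoint ties break toward the
#' smaller class index (the straighter conformer).
#'
#' @param angle measured bend angle(s) in degrees, `[0, 180)`.
#' @param geom a [conformer_geometry()] (its `angles` define the
#'   classes).
#' @return Integer class indices (1 = class I) with levels attribute
#'   `c("I","II","III","IV")` truncated to the number of classes.
#' @export
classify_complex <- function(angle, geom = conformer_geometry()) {
  if (any(angle < 0 | angle >= 180)) {
    stop("`angle` must be in [0, 180)", call. = FALSE)
  }
  vapply(angle, function(a) {
    d <- abs(geom$angles - a)
    which(d == min(d))[1]   # ties -> smaller index
  }, integer(1))
}
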