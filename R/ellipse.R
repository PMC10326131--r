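#' Polar radius of an origin-centered ellipse
#'
#' Radius of the ellipse with semi-axes `a >= b` and semi-major tilt
#' `tilt_deg` along the direction `angle_deg`:
#' `r = a b / sqrt(b^2 cos^2(psi) + a^2 sin^2(psi))` with
#' `psi = angle - tilt`. This is the generator geometry for noiseless
#' angular profiles.
#'
#' @param a,b Semi-major and semi-minor axis lengths (RRT units), `a >= b > 0`.
#' @param tilt_deg Tilt of the semi-major axis, degrees counter-clockwise from
#'   the positive x-axis.
#' @param angle_deg Direction(s) along which to evaluate the radius (degrees).
#' @return Radii in the same units as `a` and `b` (vectorized over
#'   `angle_deg`).
#' @export
ellipse_polar_radius <- function(a, b, tilt_deg, angle_deg) {
  stopifnot(a >= b, b > 0)
  psi <- (angle_deg - tilt_deg) * pi / 180
  a * b / sqrt(b^2 * cos(psi)^2 + a^2 * sin(psi)^2)
}

#' Convert an angular profile to a Cartesian point cloud
#'
#' Each reading becomes the point whose Euclidean distance from the origin is
#' the arrival time and whose direction is the measurement angle
#' (counter-clockwise from the positive x-axis).
#'
#' @param profile An [angular_profile()] or data frame with `angle_deg`, `rrt`.
#' @return A tibble with columns `x` and `y` (RRT units).
#' @export
polar_to_cartesian <- function(profile) {
  th <- profile$angle_deg * pi / 180
  tibble::tibble(x = profile$rrt * cos(th), y = profile$rrt * sin(th))
}

# Direct least-squares conic fit with the ellipse-specificity constraint
# (4ac - b^2 = 1), solved with the numerically stable block decomposition of
# the scatter matrix. Input is centered and scaled before solving; the conic
# is mapped back to the original frame afterwards. Returns the conic
# coefficient 6-vector (A, B, C, D, E, F) for
# A x^2 + B xy + C y^2 + D x + E y + F = 0, unit-normalized.
fit_conic_direct <- function(x, y) {
  n <- length(x)
  cx <- mean(x); cy <- mean(y)
  s <- sqrt(mean((x - cx)^2 + (y - cy)^2))
  if (!is.finite(s) || s <= 0) stop("degenerate point cloud.", call. = FALSE)
  xs <- (x - cx) / s
  ys <- (y - cy) / s

  d1 <- cbind(xs^2, xs * ys, ys^2)        # quadratic part
  d2 <- cbind(xs, ys, rep(1, n))          # linear part
  s1 <- crossprod(d1)
  s2 <- crossprod(d1, d2)
  s3 <- crossprod(d2)
  t_mat <- tryCatch(-solve(s3, t(s2)), error = function(e) {
    stop("degenerate-fit error: collinear or deficient point cloud.",
         call. = FALSE)
  })
  m <- s1 + s2 %*% t_mat
  # premultiply by inv(C1), C1 the ellipse-constraint matrix
  m_red <- rbind(m[3, ] / 2, -m[2, ], m[1, ] / 2)
  ev <- eigen(m_red)
  vecs <- Re(ev$vectors)
  # the ellipse solution is the eigenvector with 4ac - b^2 > 0
  cond <- 4 * vecs[1, ] * vecs[3, ] - vecs[2, ]^2
  ok <- which(cond > 1e-12)
  if (length(ok) == 0L) {
    stop("degenerate-fit error: no ellipse satisfies the constraint ",
         "(collinear or near-degenerate data).", call. = FALSE)
  }
  a1 <- vecs[, ok[1]]
  conic_s <- c(a1, t_mat %*% a1)   # (A,B,C,D,E,F) in scaled frame

  # map conic back: x_s = (X - cx)/s, y_s = (Y - cy)/s
  a_ <- conic_s[1]; b_ <- conic_s[2]; c_ <- conic_s[3]
  d_ <- conic_s[4]; e_ <- conic_s[5]; f_ <- conic_s[6]
  conic <- c(
    a_ / s^2,
    b_ / s^2,
    c_ / s^2,
    (-2 * a_ * cx - b_ * cy) / s^2 + d_ / s,
    (-b_ * cx - 2 * c_ * cy) / s^2 + e_ / s,
    (a_ * cx^2 + b_ * cx * cy + c_ * cy^2) / s^2 - (d_ * cx + e_ * cy) / s + f_
  )
  conic / sqrt(sum(conic^2))
}

# Geometric ellipse parameters from conic coefficients.
conic_to_geometry <- function(conic) {
  A <- conic[1]; B <- conic[2]; C <- conic[3]
  D <- conic[4]; E <- conic[5]; F <- conic[6]
  disc <- B^2 - 4 * A * C
  if (!is.finite(disc) || disc >= 0) {
    stop("degenerate-fit error: conic is not an ellipse (B^2 - 4AC >= 0).",
         call. = FALSE)
  }
  center <- solve(matrix(c(2 * A, B, B, 2 * C), 2, 2), c(-D, -E))
  m0 <- matrix(c(F, D / 2, E / 2,
                 D / 2, A, B / 2,
                 E / 2, B / 2, C), 3, 3)
  m <- matrix(c(A, B / 2, B / 2, C), 2, 2)
  em <- eigen(m, symmetric = TRUE)
  ax2 <- -det(m0) / (det(m) * em$values)
  if (any(!is.finite(ax2)) || any(ax2 <= 0)) {
    stop("degenerate-fit error: non-positive axis lengths.", call. = FALSE)
  }
  axes <- sqrt(ax2)
  major <- which.max(axes)
  a <- axes[major]
  b <- axes[-major]
  v <- em$vectors[, major]          # direction of the semi-major axis
  tilt <- (atan2(v[2], v[1]) * 180 / pi) %% 180
  list(center = center, a = a, b = b, tilt_deg = tilt)
}

#' Fit an ellipse to a point cloud by direct least squares
#'
#' Fits the conic that minimizes the algebraic distance to the points under
#' the ellipse-specificity constraint (`4AC - B^2 = 1`), using the stable
#' block decomposition of the scatter matrix with prior centering and
#' rescaling of the data. The geometric parameters (center, semi-axes, tilt)
#' are extracted from the conic coefficients; if the extracted "semi-major"
#' axis is the shorter one, axes are swapped and the tilt rotated by 90
#' degrees so that `a >= b` always holds. The fit is deterministic.
#'
#' @param points A data frame or matrix with columns/x-y pairs `x`, `y`, e.g.
#'   from [polar_to_cartesian()].
#' @return An object of class `"ellipse_fit"`: a list with `center` (x, y),
#'   `a`, `b` (semi-major/minor, RRT units), `tilt_deg` in `[0, 180)`,
#'   `conic` (unit-normalized coefficient 6-vector) and `rms_residual`
#'   (root-mean-square gradient-normalized algebraic distance, an
#'   approximate geometric misfit in RRT units; diagnostics only).
#' @export
#' @examples
#' ang <- seq(0, 350, by = 10)
#' pts <- polar_to_cartesian(
#'   angular_profile(ang, ellipse_polar_radius(224.044, 160, 30, ang)))
#' fit_ellipse_direct(pts)
fit_ellipse_direct <- function(points) {
  if (is.matrix(points)) points <- data.frame(x = points[, 1], y = points[, 2])
  x <- points$x; y <- points$y
  if (length(x) < 6L) {
    stop("insufficient data: at least 6 points are required to fit a conic.",
         call. = FALSE)
  }
  conic <- fit_conic_direct(x, y)
  geom <- conic_to_geometry(conic)
  alg <- conic[1] * x^2 + conic[2] * x * y + conic[3] * y^2 +
    conic[4] * x + conic[5] * y + conic[6]
  # gradient-normalized (Sampson) distance: first-order approximation to the
  # geometric point-to-ellipse distance, in RRT units
  gx <- 2 * conic[1] * x + conic[2] * y + conic[4]
  gy <- conic[2] * x + 2 * conic[3] * y + conic[5]
  structure(
    list(center = geom$center, a = geom$a, b = geom$b,
         tilt_deg = geom$tilt_deg, conic = conic,
         rms_residual = sqrt(mean((alg / sqrt(gx^2 + gy^2))^2)),
         n_points = length(x)),
    class = "ellipse_fit"
  )
}

#' @export
print.ellipse_fit <- function(x, ...) {
  cat("Direct least-squares ellipse fit (", x$n_points, " points)\n", sep = "")
  cat(sprintf("  center: (%.3f, %.3f) RRT\n", x$center[1], x$center[2]))
  cat(sprintf("  semi-major a: %.3f  semi-minor b: %.3f RRT\n", x$a, x$b))
  cat(sprintf("  tilt: %.2f deg   eccentricity: %.4f\n",
              x$tilt_deg, sqrt(1 - (x$b / x$a)^2)))
  cat(sprintf("  rms algebraic residual: %.4g\n", x$rms_residual))
  invisible(x)
}

#' Anisotropy metrics from an ellipse fit
#'
#' Computes the ellipse-based skin metrics: eccentricity
#' `e = sqrt(1 - b^2 / a^2)` (0 for isotropic skin, approaching 1 for
#' transversely isotropic), area `A = pi a b` (an inverse measure of average
#' stiffness across all directions), and the Langer-line direction. The tilt
#' of the semi-major axis marks the slowest travelling wave; the fastest
#' wave — the Langer-line direction — is perpendicular to it, so
#' `langer_angle = (tilt + 90) mod 180`.
#'
#' @param fit An `"ellipse_fit"` object.
#' @return A tibble with one row: `a`, `b`, `tilt_deg`, `eccentricity`,
#'   `area`, `langer_angle_deg`, `rms_residual`.
#' @export
metrics_from_fit <- function(fit) {
  stopifnot(inherits(fit, "ellipse_fit"))
  tibble::tibble(
    a = fit$a, b = fit$b, tilt_deg = fit$tilt_deg,
    eccentricity = sqrt(1 - (fit$b / fit$a)^2),
    area = pi * fit$a * fit$b,
    langer_angle_deg = (fit$tilt_deg + 90) %% 180,
    rms_residual = fit$rms_residual
  )
}

#' Anisotropic ratio of an angular profile
#'
#' The classic anisotropy measure: the maximum arrival time divided by the
#' minimum arrival time across all measured angles
#' (`AR = RRT_max / RRT_min`). It uses only the two extreme readings, which
#' makes it sensitive to outliers — the motivation for the ellipse
#' eccentricity alternative.
#'
#' @param profile An [angular_profile()] or data frame with an `rrt` column.
#' @return The dimensionless ratio, `>= 1`.
#' @export
anisotropic_ratio <- function(profile) {
  r <- profile[["rrt"]]
  if (is.null(r) || length(r) == 0L) stop("empty profile.", call. = FALSE)
  if (any(r <= 0)) stop("all arrival times must be > 0.", call. = FALSE)
  max(r) / min(r)
}

#' Full per-profile anisotropy metrics
#'
#' Convenience wrapper: fits the ellipse to a profile and returns the fit
#' metrics together with the anisotropic ratio and the raw-data Langer
#' direction.
#'
#' @param profile An [angular_profile()].
#' @return One-row tibble of metrics.
#' @export
profile_metrics <- function(profile) {
  fit <- fit_ellipse_direct(polar_to_cartesian(profile))
  m <- metrics_from_fit(fit)
  m$ar <- anisotropic_ratio(profile)
  m$langer_raw_deg <- langer_direction_raw(profile)
  m
}

#' Fit ellipses to every averaged profile of a cohort
#'
#' Averages repeats (if not already averaged) and fits one ellipse per
#' subject and configuration.
#'
#' @param cohort A validated long-format cohort tibble.
#' @return A tibble with one row per subject x configuration:
#'   `subject_id, age_years, gender, configuration, a, b, tilt_deg,
#'   eccentricity, area, ar, langer_angle_deg, langer_raw_deg, rms_residual`,
#'   plus the model outcome columns `log_ecc`, `area_scaled`, `semi_minor`.
#' @export
fit_cohort_ellipses <- function(cohort) {
  if (!all(cohort[["repeat"]] == "avg")) cohort <- average_repeats(cohort)
  keys <- dplyr::distinct(cohort, .data$subject_id, .data$age_years,
                          .data$gender, .data$configuration)
  res <- vector("list", nrow(keys))
  for (i in seq_len(nrow(keys))) {
    prof <- cohort_profile(cohort, keys$subject_id[i], keys$configuration[i])
    res[[i]] <- profile_metrics(prof)
  }
  out <- dplyr::bind_cols(keys, dplyr::bind_rows(res))
  out$log_ecc <- log(out$eccentricity)
  out$area_scaled <- out$area / 1000
  out$semi_minor <- out$b
  out
}
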