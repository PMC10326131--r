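test_that("polar to Cartesian places readings on the measurement rays", {
  p <- angular_profile(c(0, 90, 180), c(160, 200, 123))
  pts <- polar_to_cartesian(p)
  expect_equal(pts$x, c(160, 0, -123), tolerance = 1e-12)
  expect_equal(pts$y, c(0, 200, 0), tolerance = 1e-12)
})

test_that("direct fit recovers a circle and rejects degenerate inputs", {
  pts <- polar_to_cartesian(ellipse_profile(160, 160))
  fit <- fit_ellipse_direct(pts)
  expect_equal(fit$a, 160, tolerance = 1e-6)
  expect_equal(fit$b, 160, tolerance = 1e-6)
  expect_equal(unname(fit$center), c(0, 0), tolerance = 1e-6)

  expect_error(fit_ellipse_direct(data.frame(x = 1:5, y = 1:5)),
               "insufficient data")
  line <- data.frame(x = seq_len(36), y = 2 * seq_len(36) + 1)
  expect_error(fit_ellipse_direct(line), "degenerate")
})

test_that("direct fit recovers noiseless ellipse parameters exactly", {
  fit <- fit_ellipse_direct(polar_to_cartesian(
    ellipse_profile(224.044, 160, 30)))
  expect_equal(fit$a, 224.044, tolerance = 1e-6)
  expect_equal(fit$b, 160, tolerance = 1e-6)
  expect_equal(fit$tilt_deg, 30, tolerance = 1e-6)
  expect_equal(unname(fit$center), c(0, 0), tolerance = 1e-4)
  expect_lt(fit$rms_residual, 1e-6)
})

test_that("noiseless recovery holds across random ellipses with a/b <= 10", {
  set.seed(42)
  for (i in 1:25) {
    b <- runif(1, 50, 300)
    a <- b * runif(1, 1.01, 10)
    tilt <- runif(1, 0, 180)
    fit <- fit_ellipse_direct(polar_to_cartesian(ellipse_profile(a, b, tilt)))
    expect_equal(fit$a, a, tolerance = 1e-6)
    expect_equal(fit$b, b, tolerance = 1e-6)
    # axial distance on [0, 180)
    d <- abs(fit$tilt_deg - tilt) %% 180
    expect_lt(min(d, 180 - d), 1e-5)
    expect_gt(fit$a, fit$b)                      # axis ordering restored
    expect_true(fit$tilt_deg >= 0 && fit$tilt_deg < 180)
    # conic is a real ellipse
    expect_lt(fit$conic[2]^2 - 4 * fit$conic[1] * fit$conic[3], 0)
  }
})

test_that("fit is equivariant under rotation and scaling", {
  set.seed(7)
  base <- polar_to_cartesian(ellipse_profile(260, 160, 20))
  ref <- fit_ellipse_direct(base)
  for (phi in c(33, 90, 147.5)) {
    th <- phi * pi / 180
    rot <- data.frame(x = base$x * cos(th) - base$y * sin(th),
                      y = base$x * sin(th) + base$y * cos(th))
    fit <- fit_ellipse_direct(rot)
    expect_equal(fit$a, ref$a, tolerance = 1e-8)
    expect_equal(fit$b, ref$b, tolerance = 1e-8)
    d <- abs(fit$tilt_deg - (ref$tilt_deg + phi)) %% 180
    expect_lt(min(d, 180 - d), 1e-6)
  }
  for (k in c(0.25, 3)) {
    fit <- fit_ellipse_direct(data.frame(x = k * base$x, y = k * base$y))
    expect_equal(fit$a, k * ref$a, tolerance = 1e-8)
    mk <- metrics_from_fit(fit); m0 <- metrics_from_fit(ref)
    expect_equal(mk$eccentricity, m0$eccentricity, tolerance = 1e-8)
    expect_equal(mk$area, k^2 * m0$area, tolerance = 1e-8)
  }
})

test_that("metrics follow the closed forms e = sqrt(1 - b^2/a^2), A = pi a b", {
  unit <- structure(list(center = c(0, 0), a = 1, b = 1, tilt_deg = 0,
                         conic = rep(0, 6), rms_residual = 0, n_points = 36),
                    class = "ellipse_fit")
  m <- metrics_from_fit(unit)
  expect_equal(m$eccentricity, 0)
  expect_equal(m$area, pi)

  fit <- fit_ellipse_direct(polar_to_cartesian(ellipse_profile(224.044, 160)))
  expect_equal(metrics_from_fit(fit)$eccentricity, 0.7, tolerance = 1e-5)

  fit9 <- fit_ellipse_direct(polar_to_cartesian(ellipse_profile(367.065, 160)))
  m9 <- metrics_from_fit(fit9)
  expect_equal(m9$eccentricity, 0.9, tolerance = 1e-5)
  expect_equal(m9$area, pi * 367.065 * 160, tolerance = 1e-6)
})

test_that("Langer angle is perpendicular to the tilt, reduced to [0, 180)", {
  fit <- fit_ellipse_direct(polar_to_cartesian(
    ellipse_profile(224.044, 160, 135)))
  expect_equal(metrics_from_fit(fit)$langer_angle_deg, 45, tolerance = 1e-5)
})

test_that("anisotropic ratio is max over min arrival time", {
  expect_equal(anisotropic_ratio(angular_profile(grid_angles(), rep(3, 36))), 1)
  # noiseless e = 0.7 ellipse: the grid includes both axes, AR = a/b = 1.40
  expect_equal(anisotropic_ratio(ellipse_profile(224.044, 160)), 1.4,
               tolerance = 5e-4)
  expect_equal(anisotropic_ratio(ellipse_profile(367.065, 160)),
               1 / sqrt(1 - 0.81), tolerance = 5e-4)
  expect_error(anisotropic_ratio(tibble::tibble(rrt = c(1, -2))), "> 0")
})

test_that("AR equals 1/sqrt(1-e^2) on noiseless grids within 0.5%", {
  set.seed(13)
  # arbitrary tilt: grid discretization keeps the identity within 0.5% up to
  # the study's typical anisotropy (e <= 0.7)
  for (i in 1:10) {
    e <- runif(1, 0.1, 0.7)
    tilt <- runif(1, 0, 180)
    prof <- ellipse_profile(major_from_e(e), 160, tilt)
    expect_equal(anisotropic_ratio(prof), 1 / sqrt(1 - e^2),
                 tolerance = 5e-3)
  }
  # grid-aligned axes: exact for any eccentricity
  for (e in c(0.5, 0.7, 0.9, 0.95)) {
    prof <- ellipse_profile(major_from_e(e), 160, 40)
    expect_equal(anisotropic_ratio(prof), 1 / sqrt(1 - e^2),
                 tolerance = 1e-9)
  }
})

test_that("cohort ellipse fitting returns one metrics row per profile", {
  res <- fit_cohort_ellipses(tiny_cohort())
  expect_equal(nrow(res), 6L)
  expect_true(all(res$eccentricity > 0 & res$eccentricity < 1))
  expect_equal(res$log_ecc, log(res$eccentricity))
  expect_equal(res$area_scaled, res$area / 1000)
  expect_equal(res$semi_minor, res$b)
  # tiny_cohort ellipses: a = 200+10s, b = 150, noise sd 1
  expect_equal(res$b, rep(150, 6), tolerance = 0.05)
})
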