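test_that("profile construction enforces the angular-grid invariants", {
  expect_s3_class(angular_profile(c(0, 10, 20, 30, 40, 50), rep(100, 6)),
                  "angular_profile")
  expect_error(angular_profile(numeric(0), numeric(0)), "at least one")
  expect_error(angular_profile(c(0, 15), c(1, 1)), "grid")
  expect_error(angular_profile(c(10, 10), c(1, 1)), "increasing")
  expect_error(angular_profile(c(0, 10), c(1, -1)), "> 0")
  expect_error(angular_profile(c(0, 360), c(1, 1)), "\\[0, 360\\)")
  expect_error(angular_profile(grid_angles()[-1], rep(1, 35),
                               require_full = TRUE), "exactly 36")
})

test_that("cohort CSV round-trips through write and read", {
  cohort <- tiny_cohort()
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(cohort, path)
  back <- read_cohort(path, grid_step = 30, age_range = c(0, 120))
  expect_equal(as.data.frame(back), as.data.frame(cohort), tolerance = 1e-12)
})

test_that("read_cohort reports schema, parse and duplication errors precisely", {
  path <- withr::local_tempfile(fileext = ".csv")
  cohort <- tiny_cohort()

  writeLines("subject_id,age_years,gender,configuration,angle_deg,rrt", path)
  expect_error(read_cohort(path), "repeat")

  # header only, full schema: empty collection
  writeLines(paste(c("subject_id", "age_years", "gender", "configuration",
                     "repeat", "angle_deg", "rrt"), collapse = ","), path)
  expect_equal(nrow(read_cohort(path)), 0L)

  bad <- cohort
  bad$rrt[5] <- NA
  bad$rrt <- as.character(bad$rrt)
  bad$rrt[5] <- "oops"
  readr::write_csv(bad, path)
  expect_error(read_cohort(path), "non-numeric rrt at data row 5")

  dup <- dplyr::bind_rows(cohort, cohort[1, ])
  readr::write_csv(dup, path)
  expect_error(read_cohort(path, grid_step = 30), "duplicate")
})

test_that("one full-protocol subject yields a 36-reading profile", {
  prof <- ellipse_profile(224.044, 160, 30)
  df <- tibble::tibble(subject_id = "S1", age_years = 26, gender = "M",
                       configuration = "natural", "repeat" = "1",
                       angle_deg = prof$angle_deg, rrt = prof$rrt)
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(df, path)
  got <- read_cohort(path)
  expect_equal(nrow(got), 36L)
  p <- cohort_profile(got, "S1", "natural", which_repeat = "1")
  expect_equal(nrow(p), 36L)
})

test_that("average_repeats takes the per-angle mean and ignores input order", {
  ang <- grid_angles()
  base <- ellipse_polar_radius(224.044, 160, 40, ang)
  p1 <- angular_profile(ang, base)
  p2 <- angular_profile(ang, base + 3)
  p3 <- angular_profile(ang, base - 3)

  expect_equal(average_repeats(list(p1, p1, p1))$rrt, p1$rrt)
  expect_equal(average_repeats(list(
    angular_profile(ang, rep(100, 36)),
    angular_profile(ang, rep(200, 36))))$rrt, rep(150, 36))
  expect_equal(average_repeats(list(p1, p2, p3))$rrt, base)
  # permutation invariance
  expect_equal(average_repeats(list(p3, p1, p2))$rrt,
               average_repeats(list(p1, p2, p3))$rrt)

  expect_error(average_repeats(list(p1, angular_profile(ang[-5], base[-5]))),
               "mismatched angle grids")
})

test_that("cohort-level averaging produces one avg profile per configuration", {
  avg <- average_repeats(tiny_cohort())
  expect_true(all(avg[["repeat"]] == "avg"))
  expect_equal(nrow(avg), 3 * 2 * 12)   # subjects x configs x angles
  # averaging is idempotent
  expect_equal(average_repeats(avg)$rrt, avg$rrt)
})

test_that("raw Langer direction is the axial argmin with smallest-angle ties", {
  ang <- grid_angles()
  r <- rep(200, 36); r[ang == 240] <- 150
  expect_equal(langer_direction_raw(angular_profile(ang, r)), 60)
  expect_equal(langer_direction_raw(angular_profile(ang, rep(7, 36))), 0)
  # noiseless ellipse, semi-major tilt 30: fastest direction is 120
  expect_equal(langer_direction_raw(ellipse_profile(224.044, 160, 30)), 120)
  expect_error(langer_direction_raw(tibble::tibble()), "empty")
})

test_that("Langer direction is invariant to adding a constant arrival time", {
  set.seed(11)
  for (i in 1:5) {
    tilt <- runif(1, 0, 180)
    ang <- grid_angles()
    r <- ellipse_polar_radius(300, 160, tilt, ang) + rnorm(36, 0, 5)
    p0 <- angular_profile(ang, r)
    p1 <- angular_profile(ang, r + 57)
    expect_equal(langer_direction_raw(p1), langer_direction_raw(p0))
  }
})
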