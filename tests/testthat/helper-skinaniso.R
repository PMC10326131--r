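# Shared fixtures: all built in code at test time.

grid_angles <- function(step = 10) seq(0, 360 - step, by = step)

# Noiseless profile sampled on the angular grid of an origin-centered ellipse.
ellipse_profile <- function(a, b, tilt_deg = 0, step = 10) {
  ang <- grid_angles(step)
  angular_profile(ang, ellipse_polar_radius(a, b, tilt_deg, ang),
                  grid_step = step)
}

# semi-major axis implied by eccentricity at fixed semi-minor axis
major_from_e <- function(e, b = 160) b / sqrt(1 - e^2)

# Small long-format cohort table built directly (3 subjects, 2 configs,
# 2 repeats, coarse 30-degree grid) for IO tests.
tiny_cohort <- function() {
  rows <- list()
  set.seed(99)
  for (s in 1:3) {
    for (cf in c("natural", "stretched")) {
      tilt <- 10 * s
      a <- 200 + 10 * s; b <- 150
      for (rp in 1:2) {
        ang <- grid_angles(30)
        rows[[length(rows) + 1]] <- tibble::tibble(
          subject_id = paste0("S", s), age_years = 20 + s,
          gender = c("F", "M")[1 + s %% 2], configuration = cf,
          "repeat" = as.character(rp), angle_deg = ang,
          rrt = ellipse_polar_radius(a, b, tilt, ang) + rnorm(length(ang)))
      }
    }
  }
  validate_cohort(dplyr::bind_rows(rows), grid_step = 30)
}

# A fast cohort configuration for MCMC tests.
fast_config <- function(...) cohort_config(...)
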