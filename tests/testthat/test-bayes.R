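test_that("hpdi matches known intervals and an independent implementation", {
  set.seed(1)
  z <- rnorm(50000)
  int <- hpdi(z, 0.95)
  expect_equal(unname(int), c(-1.96, 1.96), tolerance = 0.05)

  expect_equal(unname(hpdi(rep(3.5, 200))), c(3.5, 3.5))
  expect_error(hpdi(rnorm(50)), "at least 100")

  # right-skewed: HPDI is shorter than the equal-tailed interval
  x <- rexp(20000)
  int_h <- hpdi(x, 0.9)
  int_q <- quantile(x, c(0.05, 0.95))
  expect_lt(diff(int_h), diff(int_q))

  skip_if_not_installed("coda")
  # independent implementation agrees up to its off-by-one window convention
  for (draws in list(z[1:5000], x[1:5000], rgamma(5000, 2))) {
    got <- hpdi(draws, 0.9)
    ref <- coda::HPDinterval(coda::as.mcmc(draws), prob = 0.9)
    expect_equal(unname(got), unname(c(ref[1, "lower"], ref[1, "upper"])),
                 tolerance = 0.02)
  }
})

test_that("hpdi is order-invariant and monotone in level", {
  set.seed(2)
  x <- rgamma(2000, 3)
  expect_identical(hpdi(x), hpdi(sample(x)))
  w <- sapply(c(0.5, 0.8, 0.9, 0.95, 0.99), function(l) diff(hpdi(x, l)))
  expect_true(all(diff(w) > 0))
})

test_that("interval overlap works linearly and on the circle", {
  expect_true(hpdi_overlap(c(10, 30), c(20, 40)))
  expect_false(hpdi_overlap(c(10, 30), c(40, 60)))
  expect_true(hpdi_overlap(c(350, 10), c(5, 20), circular = TRUE))
  expect_false(hpdi_overlap(c(350, 10), c(30, 60), circular = TRUE))
  expect_true(hpdi_overlap(c(170, 10), c(5, 30), circular = TRUE,
                           period = 180))
})

test_that("Gibbs coefficient conditional matches the closed form with fixed Sigma", {
  cfg <- cohort_config()
  out <- generate_outcomes(cfg, seed = 30)
  X <- cbind(1, out$age, out$gender, out$configuration)
  Y <- as.matrix(out[c("log_ecc", "area_scaled", "semi_minor")])
  tau <- 100
  M <- solve(crossprod(X) + diag(4) / tau^2, crossprod(X, Y))

  post <- fit_mvreg(out, chains = 1, iter = 11000, warmup = 1000, seed = 31,
                    fix_Sigma = diag(3) * 1e-8)
  got <- colMeans(post$draws)
  expect_equal(unname(got["alpha[log_ecc]"]), unname(M[1, 1]),
               tolerance = 1e-3)
  expect_equal(unname(got["B[log_ecc,age]"]), unname(M[2, 1]),
               tolerance = 1e-3)
  expect_equal(unname(got["B[semi_minor,configuration]"]), unname(M[4, 3]),
               tolerance = 1e-3)
  expect_equal(unname(got["B[area_scaled,gender]"]), unname(M[3, 2]),
               tolerance = 1e-3)
})

test_that("with diffuse priors the posterior mean approaches OLS", {
  cfg <- cohort_config(Sigma = default_outcome_covariance() * 0.01)
  out <- generate_outcomes(cfg, seed = 32)
  fitlm <- lm(cbind(log_ecc, area_scaled, semi_minor) ~ age + gender +
                configuration, data = out)
  post <- fit_mvreg(out, chains = 2, iter = 1500, seed = 33)
  tab <- significance_table(post)
  cf <- coef(fitlm)                  # terms x outcomes
  ols <- unname(c(cf[1, ], as.vector(cf[-1, ])))   # covariate-fastest order
  expect_equal(tab$mean, ols, tolerance = 0.02)
})

test_that("posterior recovers known coefficients within 3 posterior SDs", {
  cfg <- cohort_config()
  out <- generate_outcomes(cfg, seed = 34)
  post <- fit_mvreg(out, chains = 2, iter = 1500, seed = 35)
  expect_true(post$converged)
  expect_gt(min(post$ess, na.rm = TRUE), 400)

  truth <- c(cfg$alpha, as.vector(t(cfg$B)))
  tab <- significance_table(post)
  sds <- apply(post$draws[, tab$coefficient], 2, sd)
  expect_true(all(abs(tab$mean - truth) <= 3 * sds))
})

test_that("posterior summaries are insensitive to a 10x wider prior scale", {
  out <- generate_outcomes(cohort_config(), seed = 36)
  p1 <- fit_mvreg(out, chains = 2, iter = 1500, seed = 37, prior_scale = 100)
  p2 <- fit_mvreg(out, chains = 2, iter = 1500, seed = 37, prior_scale = 1000)
  t1 <- significance_table(p1); t2 <- significance_table(p2)
  scale <- pmax(abs(t1$mean), 0.01)
  expect_lt(max(abs(t1$mean - t2$mean) / scale), 0.05)
  expect_identical(t1$significant, t2$significant)
})

test_that("row order does not change posterior summaries under one seed", {
  out <- generate_outcomes(cohort_config(n_subjects = 40), seed = 38)
  perm <- out[sample(nrow(out)), ]
  t1 <- significance_table(fit_mvreg(out, chains = 2, iter = 800, seed = 39))
  t2 <- significance_table(fit_mvreg(perm, chains = 2, iter = 800, seed = 39))
  expect_equal(t1$mean, t2$mean, tolerance = 1e-10)
})

test_that("rank-deficient designs fail naming the collinear column", {
  out <- generate_outcomes(cohort_config(), seed = 40)
  out$dup <- out$age
  expect_error(fit_mvreg(out, covariates = c("age", "gender", "dup")),
               "collinear.*dup")
})

test_that("significance flags follow the zero-in-HPDI rule", {
  # intervals of the shapes reported for age/gender effects
  post <- fit_mvreg(generate_outcomes(cohort_config(), seed = 41),
                    chains = 2, iter = 1000, seed = 42)
  tab <- significance_table(post)
  expect_identical(tab$significant,
                   tab$hpdi_low > 0 | tab$hpdi_high < 0)
  expect_equal(nrow(tab), 12L)   # 3 intercepts + 3 covariates x 3 outcomes
  expect_true(all(tab$hpdi_low <= tab$mean & tab$mean <= tab$hpdi_high))
})

test_that("circular regression recovers a large configuration shift", {
  set.seed(50)
  circ0 <- list(baseline_deg = 80, shift_deg = 0, concentration = 8)
  circ1 <- list(baseline_deg = 80, shift_deg = 120, concentration = 8)
  ang <- c(generate_angles(200, 0, circ0), generate_angles(200, 1, circ1)) / 2
  cfgv <- rep(c(0, 1), each = 200)
  fit <- fit_circular(ang, cfgv, axial = TRUE, chains = 2, iter = 1000,
                      seed = 51)
  expect_equal(unname(fit$circ_mean["natural"]), 40, tolerance = 2)
  expect_equal(unname(fit$circ_mean["stretched"]), 100, tolerance = 2)
  expect_false(fit$overlap)
})

test_that("no configuration shift gives overlapping circular HPDIs", {
  set.seed(52)
  circ <- list(baseline_deg = 60, shift_deg = 0, concentration = 6)
  ang <- generate_angles(160, rep(c(0, 1), each = 80), circ) / 2
  fit <- fit_circular(ang, rep(c(0, 1), each = 80), chains = 2, iter = 1000,
                      seed = 53)
  expect_true(fit$overlap)
})

test_that("single-configuration circular fits return only a baseline mean", {
  set.seed(54)
  ang <- generate_angles(60, 0, list(baseline_deg = 30, shift_deg = 0,
                                     concentration = 10)) / 2
  fit <- fit_circular(ang, rep(0, 60), chains = 2, iter = 800, seed = 55)
  expect_named(fit$hpdi, "natural")
  expect_true(is.na(fit$overlap))
  expect_equal(unname(fit$circ_mean), 15, tolerance = 3)

  expect_warning(fit_circular(rep(42, 30), rep(c(0, 1), each = 15),
                              chains = 2, iter = 500, seed = 56),
                 "identical")
})
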