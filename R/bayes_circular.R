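#' Bayesian projected-normal circular regression
#'
#' Fits the circular regression `angle = alpha + beta * configuration + eps`
#' used to test whether stretching the skin rotates the fitted ellipse (i.e.
#' moves the Langer-line direction). The angle is modelled with a projected
#' normal distribution: each observed direction is the radial projection of a
#' latent bivariate normal with identity covariance whose mean is linear in
#' the configuration indicator. Sampling is by Gibbs with the latent lengths
#' as auxiliary variables: given the lengths the latent coordinates are
#' ordinary normal regressions with conjugate normal priors; given the
#' coefficients each length has density proportional to
#' `r * phi(r - m)` on `r > 0` and is updated by an exact two-step slice
#' move (`v ~ U(0, r)`, then `r` from a normal truncated to `(v, Inf)`).
#'
#' Ellipse tilt is axial (period 180 degrees); with `axial = TRUE` (the
#' default) angles are doubled onto the full circle before fitting and all
#' reported directions are halved back to `[0, 180)`.
#'
#' @param angles_deg Observed directions in degrees.
#' @param configuration 0/1 covariate (0 = natural, 1 = stretched), same
#'   length as `angles_deg`; may be all one level, in which case only the
#'   baseline mean is estimated.
#' @param axial Treat the data as axial (period 180) and double before
#'   fitting.
#' @param chains,iter,warmup,seed MCMC settings.
#' @param prior_scale Prior SD of the latent regression coefficients.
#' @param level Probability mass for the reported HPDIs.
#' @return An object of class `"circular_post"`: list with `mean_draws`
#'   (matrix of per-draw posterior circular mean directions per
#'   configuration, degrees on the reporting scale), `circ_mean` (posterior
#'   circular means), `hpdi` (list of circular HPDIs), `overlap` (do the two
#'   configurations' HPDIs overlap; `NA` with one configuration),
#'   `coef_draws`, and the settings used.
#' @export
fit_circular <- function(angles_deg, configuration = NULL, axial = TRUE,
                         chains = 2, iter = 2000, warmup = floor(iter / 2),
                         seed = 1, prior_scale = 100, level = 0.95) {
  n <- length(angles_deg)
  stopifnot(n >= 10, iter > warmup)
  if (is.null(configuration)) configuration <- rep(0, n)
  stopifnot(length(configuration) == n, all(configuration %in% c(0, 1)))
  two_groups <- length(unique(configuration)) == 2
  if (two_groups && any(table(configuration) < 10)) {
    stop("at least 10 angles per configuration are required.", call. = FALSE)
  }
  if (length(unique(angles_deg %% 360)) == 1L) {
    warning("all angles identical; posterior is degenerate around that value.")
  }

  period <- if (axial) 180 else 360
  work <- if (axial) (2 * angles_deg) %% 360 else angles_deg %% 360
  th <- work * pi / 180
  U <- cbind(cos(th), sin(th))
  X <- if (two_groups) cbind(1, configuration) else
    matrix(1, n, 1)
  k <- ncol(X)
  xtx <- crossprod(X)
  V <- solve(xtx + diag(k) / prior_scale^2)
  L_V <- t(chol(V))

  n_keep <- iter - warmup
  mean_draws <- matrix(NA_real_, n_keep * chains, if (two_groups) 2 else 1)
  colnames(mean_draws) <- c("natural", "stretched")[seq_len(ncol(mean_draws))]
  coef_draws <- matrix(NA_real_, n_keep * chains, 2 * k)
  colnames(coef_draws) <- as.vector(outer(
    if (two_groups) c("intercept", "shift") else "intercept", c("I", "II"),
    paste, sep = "."))

  for (ch in seq_len(chains)) {
    set.seed(seed + 1000L * ch)
    r <- rep(1, n)
    B <- matrix(0, k, 2)
    for (it in seq_len(iter)) {
      Yl <- U * r                       # latent bivariate observations
      for (j in 1:2) {
        m_j <- V %*% crossprod(X, Yl[, j])
        B[, j] <- m_j + L_V %*% rnorm(k)
      }
      mu <- X %*% B                     # n x 2 latent means
      m <- rowSums(U * mu)              # projection onto each unit vector
      v <- runif(n, 0, r)
      lo <- pnorm(v - m)
      r <- m + qnorm(lo + runif(n) * (1 - lo))
      # guard against qnorm(1) overflow at extreme m
      r[!is.finite(r)] <- m[!is.finite(r)] + 6
      if (it > warmup) {
        row <- (ch - 1) * n_keep + (it - warmup)
        ang_nat <- (atan2(B[1, 2], B[1, 1]) * 180 / pi) %% 360
        if (two_groups) {
          mu_str <- B[1, ] + B[2, ]
          ang_str <- (atan2(mu_str[2], mu_str[1]) * 180 / pi) %% 360
          mean_draws[row, ] <- c(ang_nat, ang_str)
        } else {
          mean_draws[row, 1] <- ang_nat
        }
        coef_draws[row, ] <- as.vector(B)
      }
    }
  }
  if (axial) mean_draws <- mean_draws / 2   # back to [0, 180)

  circ_mean <- apply(mean_draws, 2, circular_mean_deg, period = period)
  hp <- lapply(seq_len(ncol(mean_draws)), function(j) {
    circular_hpdi(mean_draws[, j], level = level, period = period)
  })
  names(hp) <- colnames(mean_draws)
  overlap <- if (two_groups) {
    hpdi_overlap(hp[[1]], hp[[2]], circular = TRUE, period = period)
  } else NA
  structure(list(mean_draws = mean_draws, circ_mean = circ_mean, hpdi = hp,
                 overlap = overlap, coef_draws = coef_draws, axial = axial,
                 period = period, level = level, two_groups = two_groups,
                 n = n, chains = chains, n_keep = n_keep),
            class = "circular_post")
}

#' @export
print.circular_post <- function(x, ...) {
  cat(sprintf(
    "Projected-normal circular regression (%s, n = %d, %d draws)\n",
    if (x$axial) "axial, period 180" else "period 360",
    x$n, nrow(x$mean_draws)))
  for (nm in names(x$hpdi)) {
    cat(sprintf("  %s: posterior circular mean %.1f deg, %.0f%% HPDI [%.1f, %.1f]\n",
                nm, x$circ_mean[nm], 100 * x$level,
                x$hpdi[[nm]][1], x$hpdi[[nm]][2]))
  }
  if (x$two_groups) {
    cat(sprintf("  HPDIs %s -> %s\n",
                if (x$overlap) "overlap" else "are disjoint",
                if (x$overlap) "no significant configuration effect on angle"
                else "significant configuration effect on angle"))
  }
  invisible(x)
}

#' Circular mean of angles
#'
#' @param x Angles in degrees.
#' @param period Period of the data (360 for directions, 180 for axes; axial
#'   data are doubled internally).
#' @return Mean direction in degrees, in `[0, period)`.
#' @export
circular_mean_deg <- function(x, period = 360) {
  scale <- 360 / period
  th <- x * scale * pi / 180
  (atan2(mean(sin(th)), mean(cos(th))) * 180 / pi / scale) %% period
}

# Shortest interval containing `level` mass of circular draws: recenter the
# draws around their circular mean so the sample is effectively linear, then
# take the ordinary HPDI and map back.
circular_hpdi <- function(x, level = 0.95, period = 360) {
  ctr <- circular_mean_deg(x, period = period)
  centered <- ((x - ctr + period / 2) %% period) - period / 2
  int <- hpdi(centered, level)
  (int + ctr) %% period
}
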