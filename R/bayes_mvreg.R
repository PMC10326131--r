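#' Highest posterior density interval
#'
#' The shortest contiguous interval containing `ceiling(level * n)` of the
#' sorted draws. For a unimodal posterior this is the narrowest interval with
#' the stated probability mass, the interval used throughout for covariate
#' significance: an effect is declared significant when 0 lies outside its
#' 0.95 HPDI.
#'
#' @param draws Numeric vector of posterior draws (at least 100).
#' @param level Probability mass, in (0, 1).
#' @return Named numeric vector `c(lower, upper)`.
#' @export
hpdi <- function(draws, level = 0.95) {
  stopifnot(level > 0, level < 1)
  n <- length(draws)
  if (n < 100) stop("at least 100 draws are required for an HPDI.",
                    call. = FALSE)
  x <- sort(draws)
  k <- ceiling(level * n)
  widths <- x[k:n] - x[seq_len(n - k + 1)]
  i <- which.min(widths)
  c(lower = x[i], upper = x[i + k - 1])
}

#' Does 0 lie outside an interval?
#' @noRd
excludes_zero <- function(int) int[1] > 0 || int[2] < 0

#' Overlap of two (possibly circular) intervals
#'
#' Used to compare posterior HPDIs of circular means between the natural and
#' stretched configurations: overlapping 0.95 HPDIs indicate no significant
#' configuration effect on the angle.
#'
#' @param a,b Intervals `c(lower, upper)`. For `circular = TRUE` an interval
#'   with `lower > upper` wraps around the origin.
#' @param circular Compare on the circle of the given `period`.
#' @param period Circle period (360 for degrees).
#' @return `TRUE` if the intervals intersect.
#' @export
hpdi_overlap <- function(a, b, circular = FALSE, period = 360) {
  if (!circular) return(max(a[1], b[1]) <= min(a[2], b[2]))
  inside <- function(x, int) {
    ((x - int[1]) %% period) <= ((int[2] - int[1]) %% period)
  }
  inside(a[1], b) || inside(a[2], b) || inside(b[1], a) || inside(b[2], a)
}

# Split potential-scale-reduction factor on a draws matrix
# (iterations x chains).
split_rhat <- function(mat) {
  half <- floor(nrow(mat) / 2)
  split_mat <- cbind(mat[seq_len(half), , drop = FALSE],
                     mat[(nrow(mat) - half + 1):nrow(mat), , drop = FALSE])
  m <- ncol(split_mat); n <- nrow(split_mat)
  means <- colMeans(split_mat)
  vars <- apply(split_mat, 2, var)
  w <- mean(vars)
  b <- n * var(means)
  if (w <= 0) return(1)
  sqrt(((n - 1) / n * w + b / n) / w)
}

# Effective sample size via Geyer's initial monotone positive sequence,
# averaged chain autocovariances (simplified split-chain version).
ess_basic <- function(mat) {
  m <- ncol(mat); n <- nrow(mat)
  if (n < 4) return(m * n)
  max_lag <- min(n - 1, 200)
  acov <- sapply(seq_len(m), function(j) {
    x <- mat[, j] - mean(mat[, j])
    sapply(0:max_lag, function(l) sum(x[1:(n - l)] * x[(1 + l):n]) / n)
  })
  acov <- rowMeans(acov)
  if (acov[1] <= 0) return(m * n)
  rho <- acov / acov[1]
  # sum consecutive pairs until a pair sum goes non-positive
  tau <- 1
  lag <- 1
  while (lag + 1 <= max_lag) {
    pair <- rho[lag + 1] + rho[lag + 2]
    if (is.na(pair) || pair <= 0) break
    tau <- tau + 2 * pair
    lag <- lag + 2
  }
  max(m * n / tau, 1)
}

#' Bayesian trivariate-outcome regression via conjugate Gibbs sampling
#'
#' Fits the multivariate normal linear model
#' `[log(eccentricity), area/1000, semi-minor] = alpha + B [age, gender,
#' configuration] + E`, `E ~ N(0, Sigma)`, the model used to study how age,
#' gender and skin tension affect skin anisotropy and stiffness. Priors are
#' weakly informative and conjugate: matrix-normal `Gamma | Sigma ~
#' MN(0, prior_scale^2 I, Sigma)` on the stacked coefficients
#' (intercept row plus covariate rows) and inverse-Wishart
#' `IW(prior_df, prior_scale_matrix)` on `Sigma`, so both full conditionals
#' are exact and the sampler is an ordinary Gibbs scheme.
#'
#' @param data Data frame containing the outcome and covariate columns.
#' @param outcomes Names of the three outcome columns.
#' @param covariates Names of the covariate columns (gender and
#'   configuration numerically coded 0/1).
#' @param chains Number of chains (>= 2 for diagnostics).
#' @param iter Iterations per chain (first `warmup` discarded).
#' @param warmup Warm-up iterations per chain.
#' @param seed Integer seed.
#' @param prior_scale Prior SD of the coefficients (diffuse default 100).
#' @param prior_df,prior_scale_matrix Inverse-Wishart prior on `Sigma`.
#' @param fix_Sigma Optional known error covariance; when supplied, `Sigma`
#'   is held fixed and only the coefficients are sampled (used for
#'   closed-form validation of the Gibbs conditionals).
#' @return An object of class `"mvreg_post"`: list with `draws` (matrix,
#'   one column per scalar parameter), `chain` (chain index per draw),
#'   `rhat`, `ess`, `converged`, and bookkeeping (`outcomes`, `covariates`,
#'   dimensions).
#' @export
fit_mvreg <- function(data,
                      outcomes = c("log_ecc", "area_scaled", "semi_minor"),
                      covariates = c("age", "gender", "configuration"),
                      chains = 4, iter = 2000, warmup = floor(iter / 2),
                      seed = 1, prior_scale = 100, prior_df = 4,
                      prior_scale_matrix = diag(3), fix_Sigma = NULL) {
  stopifnot(nrow(data) >= 10, chains >= 1, iter > warmup)
  Y <- as.matrix(data[outcomes])
  if (any(!is.finite(Y))) stop("non-finite outcome values.", call. = FALSE)
  X <- cbind(intercept = 1, as.matrix(data[covariates]))
  k <- ncol(X); q <- ncol(Y); n <- nrow(X)
  qrX <- qr(X)
  if (qrX$rank < k) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):k]]
    stop("rank-deficient design; collinear column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }

  xtx <- crossprod(X)
  xty <- crossprod(X, Y)
  prec0 <- diag(k) / prior_scale^2
  V <- solve(xtx + prec0)
  M <- V %*% xty                       # conditional posterior mean of Gamma
  L_V <- t(chol(V))

  n_keep <- iter - warmup
  par_names <- c(
    paste0("alpha[", outcomes, "]"),
    as.vector(outer(covariates, outcomes,
                    function(cv, oc) paste0("B[", oc, ",", cv, "]"))),
    as.vector(outer(seq_len(q), seq_len(q),
                    function(i, j) paste0("Sigma[", i, ",", j, "]")))
  )
  draws <- matrix(NA_real_, n_keep * chains, length(par_names),
                  dimnames = list(NULL, par_names))
  chain_id <- rep(seq_len(chains), each = n_keep)

  for (ch in seq_len(chains)) {
    set.seed(seed + 1000L * ch)
    # start Sigma at the residual covariance of the least-squares fit
    Sigma <- if (is.null(fix_Sigma)) {
      res <- Y - X %*% qr.coef(qrX, Y)
      crossprod(res) / max(n - k, 1) + diag(q) * 1e-8
    } else fix_Sigma
    for (it in seq_len(iter)) {
      L_S <- t(chol(Sigma))
      Gamma <- M + L_V %*% matrix(rnorm(k * q), k, q) %*% t(L_S)
      if (is.null(fix_Sigma)) {
        res <- Y - X %*% Gamma
        scale_post <- prior_scale_matrix + crossprod(res) +
          crossprod(Gamma) / prior_scale^2
        df_post <- prior_df + n + k
        W <- rWishart(1, df_post, solve(scale_post))[, , 1]
        Sigma <- solve(W)
        Sigma <- (Sigma + t(Sigma)) / 2
      }
      if (it > warmup) {
        row <- (ch - 1) * n_keep + (it - warmup)
        draws[row, ] <- c(Gamma[1, ], as.vector(Gamma[-1, , drop = FALSE]),
                          as.vector(Sigma))
      }
    }
  }

  rhat <- ess <- setNames(rep(NA_real_, length(par_names)), par_names)
  if (chains >= 2) {
    for (p in seq_along(par_names)) {
      mat <- matrix(draws[, p], n_keep, chains)
      if (sd(draws[, p]) == 0) { rhat[p] <- 1; ess[p] <- n_keep * chains }
      else { rhat[p] <- split_rhat(mat); ess[p] <- ess_basic(mat) }
    }
  }
  converged <- all(is.na(rhat) | rhat < 1.01)
  if (chains >= 2 && !converged) {
    warning("possible non-convergence: max split-Rhat = ",
            round(max(rhat, na.rm = TRUE), 4))
  }
  structure(list(draws = draws, chain = chain_id, rhat = rhat, ess = ess,
                 converged = converged, outcomes = outcomes,
                 covariates = covariates, n = n, chains = chains,
                 n_keep = n_keep),
            class = "mvreg_post")
}

#' @export
print.mvreg_post <- function(x, ...) {
  cat(sprintf(
    "Bayesian trivariate regression posterior: %d draws (%d chains x %d), n = %d\n",
    nrow(x$draws), x$chains, x$n_keep, x$n))
  cat(sprintf("  max split-Rhat: %.4f   min ESS: %.0f   converged: %s\n",
              max(x$rhat, na.rm = TRUE), min(x$ess, na.rm = TRUE),
              x$converged))
  print(significance_table(x))
  invisible(x)
}

#' Posterior summary and significance table
#'
#' Summarises every intercept and coefficient of a fitted trivariate
#' regression with its posterior mean and HPDI, flagging as significant the
#' coefficients whose interval excludes 0.
#'
#' @param posterior An `"mvreg_post"` object.
#' @param level HPDI probability mass.
#' @return A tibble: `coefficient`, `outcome`, `covariate` (`"(intercept)"`
#'   for intercepts), `mean`, `hpdi_low`, `hpdi_high`, `significant`.
#' @export
significance_table <- function(posterior, level = 0.95) {
  stopifnot(inherits(posterior, "mvreg_post"))
  keep <- c(paste0("alpha[", posterior$outcomes, "]"),
            as.vector(outer(posterior$covariates, posterior$outcomes,
                            function(cv, oc) paste0("B[", oc, ",", cv, "]"))))
  rows <- lapply(keep, function(nm) {
    d <- posterior$draws[, nm]
    int <- hpdi(d, level)
    is_int <- startsWith(nm, "alpha")
    oc <- if (is_int) sub("^alpha\\[(.*)\\]$", "\\1", nm) else
      sub("^B\\[(.*),(.*)\\]$", "\\1", nm)
    cv <- if (is_int) "(intercept)" else sub("^B\\[(.*),(.*)\\]$", "\\2", nm)
    tibble::tibble(coefficient = nm, outcome = oc, covariate = cv,
                   mean = mean(d), hpdi_low = unname(int[1]),
                   hpdi_high = unname(int[2]),
                   significant = excludes_zero(int))
  })
  dplyr::bind_rows(rows)
}
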