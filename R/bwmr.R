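# Bayesian weighted MR: a hierarchical errors-in-variables model with a
# pleiotropy variance component and per-SNP robustness weights, fit by
# Metropolis-within-Gibbs.
#
# Model, per SNP j with observed (bx_j, sx_j, by_j, sy_j):
#   bx_j | gamma_j            ~ N(gamma_j, sx_j^2)
#   by_j | gamma_j, alpha_j   ~ N(theta * gamma_j + alpha_j, sy_j^2)
#   alpha_j                   ~ N(0, tau^2)          (horizontal pleiotropy)
#   gamma_j ~ N(0, 1);  theta ~ N(0, 10^2);  tau ~ half-N(0, 1)
#
# Robustness: each sweep recomputes weights w_j = min(1, (3 / |e_j|)^2) from
# the standardized marginal residual e_j = (by_j - theta*gamma_j) /
# sqrt(sy_j^2 + tau^2); w_j multiplies the outcome-likelihood precision, so
# grossly discrepant SNPs are progressively down-weighted rather than
# dropped.

#' Bayesian weighted MR estimator
#'
#' Fits the hierarchical summary-data model above by Gibbs sampling (normal
#' conditionals for the per-SNP true effects, pleiotropy terms and the causal
#' slope) with a random-walk Metropolis step on `log(tau)`. The causal effect
#' is reported as the posterior mean and SD of the slope; the p-value is a
#' two-sided normal approximation on mean/SD. A split-chain Rhat on the
#' slope above 1.1 flags (but does not suppress) the result.
#'
#' @param h A `harmonized_set` with at least 3 kept SNPs.
#' @param n_iter Total MCMC iterations (first third discarded as burn-in).
#'   Default 6000.
#' @param seed RNG seed; the sampler is deterministic given it.
#' @return An `mr_result` with method `"BWMR"`; `extra` carries `tau`
#'   (posterior mean), `rhat`, `converged`, and the final robustness
#'   `weights`.
#' @export
mr_bwmr <- function(h, n_iter = 6000, seed = NULL) {
  k <- kept_entries(h)
  if (nrow(k) < 3L) stop("BWMR requires >=3 instruments")
  bx <- k$beta_exposure; sx <- k$se_exposure
  by <- k$beta_outcome; sy <- k$se_outcome
  J <- nrow(k)
  burn <- floor(n_iter / 3)

  with_seed(seed, {
    gamma <- bx
    alpha <- rep(0, J)
    theta <- mr_ivw(h, "fixed")$beta
    tau <- 0.05
    wts <- rep(1, J)
    prop_sd <- 0.3
    theta_draws <- numeric(n_iter)
    tau_draws <- numeric(n_iter)

    log_post_tau <- function(tau, alpha) {
      sum(stats::dnorm(alpha, 0, tau, log = TRUE)) +
        stats::dnorm(tau, 0, 1, log = TRUE)
    }

    for (it in seq_len(n_iter)) {
      # robustness weights from marginal residuals
      e <- (by - theta * gamma) / sqrt(sy^2 + tau^2)
      wts <- pmin(1, (3 / pmax(abs(e), 1e-12))^2)
      wy <- wts / sy^2

      # gamma_j | rest
      prec_g <- 1 / sx^2 + theta^2 * wy + 1
      mean_g <- (bx / sx^2 + theta * (by - alpha) * wy) / prec_g
      gamma <- stats::rnorm(J, mean_g, sqrt(1 / prec_g))

      # alpha_j | rest
      prec_a <- wy + 1 / tau^2
      mean_a <- (by - theta * gamma) * wy / prec_a
      alpha <- stats::rnorm(J, mean_a, sqrt(1 / prec_a))

      # theta | rest
      prec_t <- sum(gamma^2 * wy) + 1 / 100
      mean_t <- sum(gamma * (by - alpha) * wy) / prec_t
      theta <- stats::rnorm(1, mean_t, sqrt(1 / prec_t))

      # tau | alpha (random-walk Metropolis on log tau)
      tau_prop <- tau * exp(stats::rnorm(1, 0, prop_sd))
      lr <- log_post_tau(tau_prop, alpha) - log_post_tau(tau, alpha) +
        log(tau_prop) - log(tau)  # Jacobian of the log transform
      if (is.finite(lr) && log(stats::runif(1)) < lr) tau <- tau_prop

      theta_draws[it] <- theta
      tau_draws[it] <- tau
    }

    post <- theta_draws[(burn + 1):n_iter]
    rhat <- split_chain_rhat(post)
    est <- mean(post); se <- stats::sd(post)
    res <- new_mr_result("BWMR", est, se, two_sided_normal_p(est / se), J,
                         extra = list(tau = mean(tau_draws[(burn + 1):n_iter]),
                                      rhat = rhat,
                                      converged = is.finite(rhat) && rhat <= 1.1,
                                      weights = wts, n_iter = n_iter))
    if (!isTRUE(res$extra$converged))
      warning(sprintf("BWMR split-chain Rhat = %.3f > 1.1: chain may not have converged",
                      rhat))
    res
  })
}

# Split-half potential scale reduction factor on a single chain.
split_chain_rhat <- function(x) {
  m <- length(x) %/% 2
  if (m < 2) return(NA_real_)
  halves <- list(x[1:m], x[(m + 1):(2 * m)])
  means <- vapply(halves, mean, numeric(1))
  vars <- vapply(halves, stats::var, numeric(1))
  W <- mean(vars)
  B <- m * stats::var(means)
  if (W == 0) return(1)
  sqrt(((m - 1) / m * W + B / m) / W)
}
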