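# MR estimators operating on a harmonized set: Wald ratio, IVW (fixed and
# multiplicative random effects), MR-Egger, weighted median, simple and
# weighted mode. The Bayesian weighted estimator lives in bwmr.R.

new_mr_result <- function(method, beta, se, pval, n_snp, extra = list()) {
  stopifnot(n_snp >= 1)
  structure(list(method = method, beta = beta, se = se, pval = pval,
                 n_snp = n_snp, or_point = exp(beta),
                 ci_low = exp(beta - 1.96 * se),
                 ci_high = exp(beta + 1.96 * se),
                 extra = extra),
            class = "mr_result")
}

#' @export
print.mr_result <- function(x, ...) {
  cat(sprintf("%s (%d SNPs): beta = %.4g, se = %.4g, p = %.3g, OR = %.3f [%.3f, %.3f]\n",
              x$method, x$n_snp, x$beta, x$se, x$pval, x$or_point,
              x$ci_low, x$ci_high))
  invisible(x)
}

#' @export
as.data.frame.mr_result <- function(x, ...) {
  df <- data.frame(method = x$method, nsnp = x$n_snp, beta = x$beta,
                   se = x$se, pval = x$pval, or = x$or_point,
                   ci_low = x$ci_low, ci_high = x$ci_high,
                   stringsAsFactors = FALSE)
  for (nm in names(x$extra))
    if (is.numeric(x$extra[[nm]]) && length(x$extra[[nm]]) == 1L)
      df[[nm]] <- x$extra[[nm]]
  df
}

# Per-SNP Wald ratios and their standard errors.
wald_ratios <- function(h, wald_se = c("first", "second")) {
  wald_se <- match.arg(wald_se)
  k <- kept_entries(h)
  if (any(k$beta_exposure == 0)) stop("beta_exposure = 0: Wald ratio undefined")
  r <- k$beta_outcome / k$beta_exposure
  se <- switch(wald_se,
               first = k$se_outcome / abs(k$beta_exposure),
               second = sqrt(k$se_outcome^2 / k$beta_exposure^2 +
                               k$beta_outcome^2 * k$se_exposure^2 /
                               k$beta_exposure^4))
  data.frame(rsid = k$rsid, ratio = r, se = se, stringsAsFactors = FALSE)
}

#' Single-SNP Wald ratio estimate
#'
#' The base case of all summary-data MR estimators: the outcome effect
#' divided by the exposure effect, with a first-order standard error
#' `se_outcome / |beta_exposure|` (second-order optionally adds the exposure
#' uncertainty term).
#'
#' @param h A `harmonized_set` with exactly one kept SNP (or more; the first
#'   is used with a warning).
#' @param wald_se `"first"` (default) or `"second"` order standard error.
#' @return An `mr_result` with method `"WaldRatio"`.
#' @export
mr_wald_ratio <- function(h, wald_se = "first") {
  w <- wald_ratios(h, wald_se)
  if (nrow(w) == 0L) stop("no kept SNPs")
  if (nrow(w) > 1L) warning("multiple SNPs supplied; using the first")
  new_mr_result("WaldRatio", w$ratio[1], w$se[1],
                two_sided_normal_p(w$ratio[1] / w$se[1]), 1L)
}

#' Inverse-variance weighted estimator
#'
#' Weighted least squares of the outcome betas on the exposure betas through
#' the origin with weights `1/se_outcome^2` — algebraically the
#' inverse-variance weighted mean of the per-SNP Wald ratios under
#' first-order ratio SEs. Under the default multiplicative random-effects
#' model the standard error is scaled by `max(1, sqrt(Q/(k-1)))` where Q is
#' Cochran's heterogeneity statistic; p-values use the normal reference.
#' With fewer than 2 kept SNPs the estimate downgrades to the single-SNP
#' Wald ratio (logged).
#'
#' @param h A `harmonized_set`.
#' @param model `"random"` (default) or `"fixed"`.
#' @return An `mr_result` with method `"IVW"`; `extra` carries `q`, `q_df`,
#'   `q_pval` and the `se_scale` applied.
#' @export
mr_ivw <- function(h, model = c("random", "fixed")) {
  model <- match.arg(model)
  k <- kept_entries(h)
  if (nrow(k) < 2L) {
    message("mr_ivw: < 2 SNPs, downgrading to Wald ratio")
    return(mr_wald_ratio(h))
  }
  bx <- k$beta_exposure; by <- k$beta_outcome; w <- 1 / k$se_outcome^2
  beta <- sum(w * bx * by) / sum(w * bx^2)
  se_fixed <- sqrt(1 / sum(w * bx^2))
  q <- sum(w * (by - beta * bx)^2)
  df <- nrow(k) - 1L
  scale <- if (model == "random") max(1, sqrt(q / df)) else 1
  se <- se_fixed * scale
  new_mr_result("IVW", beta, se, two_sided_normal_p(beta / se), nrow(k),
                extra = list(model = model, q = q, q_df = df,
                             q_pval = stats::pchisq(q, df, lower.tail = FALSE),
                             se_scale = scale))
}

#' MR-Egger regression
#'
#' Weighted least squares of outcome betas on exposure betas with an
#' intercept (weights `1/se_outcome^2`), after re-orienting every SNP so its
#' exposure beta is non-negative (both betas flipped together), which makes
#' the intercept — the average directional pleiotropy — identifiable. The
#' slope is the causal estimate. Standard errors use the multiplicative
#' random-effects convention (residual scale bounded below by 1); p-values
#' use the t distribution with k - 2 degrees of freedom.
#'
#' @param h A `harmonized_set` with at least 3 kept SNPs.
#' @return An `mr_result` with method `"Egger"`; `extra` carries
#'   `intercept`, `intercept_se`, `intercept_pval`.
#' @export
mr_egger <- function(h) {
  k <- kept_entries(h)
  if (nrow(k) < 3L) stop("Egger requires >=3 instruments")
  flip <- sign(k$beta_exposure)
  flip[flip == 0] <- 1
  bx <- k$beta_exposure * flip; by <- k$beta_outcome * flip
  if (stats::sd(bx) == 0)
    stop("degenerate design: all exposure betas equal (collinear with intercept)")
  w <- 1 / k$se_outcome^2
  fit <- stats::lm(by ~ bx, weights = w)
  sm <- summary(fit)
  co <- sm$coefficients
  infl <- 1 / min(1, sm$sigma)  # forbid under-dispersion credit
  b <- co["bx", "Estimate"]; b_se <- co["bx", "Std. Error"] * infl
  a <- co["(Intercept)", "Estimate"]
  a_se <- co["(Intercept)", "Std. Error"] * infl
  df <- nrow(k) - 2L
  pt2 <- function(z) 2 * stats::pt(-abs(z), df)
  new_mr_result("Egger", b, b_se, pt2(b / b_se), nrow(k),
                extra = list(intercept = a, intercept_se = a_se,
                             intercept_pval = pt2(a / a_se), df = df))
}

# Weighted median of values x with weights w: the point where the
# standardized cumulative weight crosses 0.5, linearly interpolated.
weighted_median_point <- function(x, w) {
  ord <- order(x)
  x <- x[ord]; w <- w[ord] / sum(w)
  s <- cumsum(w) - w / 2
  if (s[1] >= 0.5) return(x[1])
  if (s[length(s)] <= 0.5) return(x[length(x)])
  stats::approx(s, x, xout = 0.5, ties = "ordered")$y
}

#' Weighted median estimator
#'
#' The inverse-variance weighted median of the per-SNP Wald ratios:
#' consistent when SNPs carrying at least half of the total weight are valid
#' instruments. The standard error comes from a parametric bootstrap
#' (per-SNP betas resampled from normals at their observed values and SEs).
#'
#' @param h A `harmonized_set` with at least 3 kept SNPs.
#' @param n_boot Bootstrap replicates. Default 1000.
#' @param seed Seed for the bootstrap stream.
#' @param wald_se Ratio-SE order for the weights.
#' @return An `mr_result` with method `"WeightedMedian"`.
#' @export
mr_weighted_median <- function(h, n_boot = 1000, seed = NULL,
                               wald_se = "first") {
  k <- kept_entries(h)
  if (nrow(k) < 3L) stop("weighted median requires >=3 instruments")
  wr <- wald_ratios(h, wald_se)
  w <- 1 / wr$se^2
  est <- weighted_median_point(wr$ratio, w)
  se <- boot_se_ratio(k, n_boot, seed, wald_se,
                      function(r, s) weighted_median_point(r, 1 / s^2))
  new_mr_result("WeightedMedian", est, se, two_sided_normal_p(est / se),
                nrow(k))
}

# Parametric bootstrap SE for a statistic of (ratios, ratio SEs).
boot_se_ratio <- function(k, n_boot, seed, wald_se, statistic) {
  with_seed(seed, {
    ests <- vapply(seq_len(n_boot), function(i) {
      bx <- stats::rnorm(nrow(k), k$beta_exposure, k$se_exposure)
      by <- stats::rnorm(nrow(k), k$beta_outcome, k$se_outcome)
      bx[bx == 0] <- .Machine$double.eps
      r <- by / bx
      s <- switch(wald_se,
                  first = k$se_outcome / abs(bx),
                  second = sqrt(k$se_outcome^2 / bx^2 +
                                  by^2 * k$se_exposure^2 / bx^4))
      statistic(r, s)
    }, numeric(1))
    stats::sd(ests)
  })
}

# Modified Silverman bandwidth on the ratios (mode-based estimation rule).
mbe_bandwidth <- function(r) {
  s <- stats::sd(r); m <- stats::mad(r)
  core <- if (m > 0) min(s, m) else s
  if (core == 0) return(0)
  0.9 * core * length(r)^(-1 / 5)
}

mode_point <- function(r, w, bw) {
  if (bw == 0) {
    # degenerate: all ratios (essentially) equal
    ur <- unique(r)
    if (length(ur) == 1L) return(ur)
    bw <- max(stats::sd(r), .Machine$double.eps) * length(r)^(-1 / 5)
  }
  d <- stats::density(r, weights = w / sum(w), bw = bw, n = 1024,
                      from = min(r) - 3 * bw, to = max(r) + 3 * bw)
  d$x[which.max(d$y)]
}

#' Mode-based estimators (simple and weighted)
#'
#' The argmax of a normal-kernel smoothed density of the per-SNP Wald
#' ratios. The bandwidth is `bandwidth_factor` times a modified Silverman
#' rule (`0.9 min(sd, mad) k^(-1/5)`). The simple mode weighs every ratio
#' equally; the weighted mode uses inverse-variance weights. Consistent when
#' the largest group of SNPs sharing a causal estimate is valid (zero modal
#' pleiotropy). SE via parametric bootstrap.
#'
#' @param h A `harmonized_set` with at least 3 kept SNPs.
#' @param weighted Use inverse-variance weights (`TRUE` = weighted mode).
#' @param bandwidth_factor Multiplier on the Silverman bandwidth. Default 1.
#' @param n_boot,seed Bootstrap replicates and seed.
#' @param wald_se Ratio-SE order.
#' @return An `mr_result` with method `"WeightedMode"` or `"SimpleMode"`.
#' @export
mr_mode <- function(h, weighted = TRUE, bandwidth_factor = 1, n_boot = 1000,
                    seed = NULL, wald_se = "first") {
  k <- kept_entries(h)
  if (nrow(k) < 3L) stop("mode estimator requires >=3 instruments")
  wr <- wald_ratios(h, wald_se)
  bw <- bandwidth_factor * mbe_bandwidth(wr$ratio)
  wts <- if (weighted) 1 / wr$se^2 else rep(1, nrow(wr))
  est <- mode_point(wr$ratio, wts, bw)
  se <- boot_se_ratio(k, n_boot, seed, wald_se, function(r, s) {
    mode_point(r, if (weighted) 1 / s^2 else rep(1, length(r)),
               bandwidth_factor * mbe_bandwidth(r))
  })
  new_mr_result(if (weighted) "WeightedMode" else "SimpleMode", est, se,
                two_sided_normal_p(est / se), nrow(k),
                extra = list(bandwidth = bw))
}

#' Run the full MR method battery
#'
#' IVW, MR-Egger, weighted median, weighted mode and simple mode (plus BWMR
#' when enabled in the config), with a direction-concordance flag: `TRUE`
#' iff all five core point estimates share one sign. Methods whose
#' preconditions fail are reported absent with a reason, and the flag is
#' then `FALSE` with reason `"incomplete battery"`.
#'
#' @param h A `harmonized_set`.
#' @param config An [mr_config()].
#' @return An `mr_battery`: list with `results` (named list of `mr_result`),
#'   `failures` (named reasons), `direction_concordant`, `concordance_reason`.
#' @export
run_all_methods <- function(h, config = mr_config()) {
  seed <- config$seed
  tasks <- list(
    IVW = function() mr_ivw(h, config$ivw_model),
    Egger = function() mr_egger(h),
    WeightedMedian = function() mr_weighted_median(
      h, config$n_boot, derive_seed(seed, 1L), config$wald_se),
    WeightedMode = function() mr_mode(
      h, TRUE, 1, config$n_boot, derive_seed(seed, 2L), config$wald_se),
    SimpleMode = function() mr_mode(
      h, FALSE, 1, config$n_boot, derive_seed(seed, 3L), config$wald_se)
  )
  if (isTRUE(config$run_bwmr))
    tasks$BWMR <- function() mr_bwmr(h, n_iter = config$bwmr_iter,
                                     seed = derive_seed(seed, 4L))
  results <- list(); failures <- character(0)
  for (nm in names(tasks)) {
    res <- tryCatch(tasks[[nm]](), error = function(e) conditionMessage(e))
    if (inherits(res, "mr_result")) results[[nm]] <- res
    else failures[nm] <- res
  }
  core <- c("IVW", "Egger", "WeightedMedian", "WeightedMode", "SimpleMode")
  if (all(core %in% names(results))) {
    signs <- sign(vapply(results[core], `[[`, numeric(1), "beta"))
    concordant <- length(unique(signs[signs != 0])) <= 1L
    reason <- if (concordant) NA_character_ else "discordant directions"
  } else {
    concordant <- FALSE
    reason <- "incomplete battery"
  }
  structure(list(results = results, failures = failures,
                 direction_concordant = concordant,
                 concordance_reason = reason),
            class = "mr_battery")
}

#' @export
print.mr_battery <- function(x, ...) {
  print(as.data.frame(x))
  cat("direction_concordant:", x$direction_concordant,
      if (!is.na(x$concordance_reason)) paste0("(", x$concordance_reason, ")")
      else "", "\n")
  if (length(x$failures))
    cat("absent:", paste(names(x$failures), x$failures, sep = ": ",
                         collapse = "; "), "\n")
  invisible(x)
}

#' @export
as.data.frame.mr_battery <- function(x, ...) {
  dfs <- lapply(x$results, as.data.frame)
  cols <- unique(unlist(lapply(dfs, names)))
  dfs <- lapply(dfs, function(d) {
    d[setdiff(cols, names(d))] <- NA
    d[cols]
  })
  do.call(rbind, c(dfs, make.row.names = FALSE))
}

#' Serialize a method battery as TSV and/or JSON
#'
#' @param battery An `mr_battery`.
#' @param tsv,json Optional output paths.
#' @return The battery's data.frame, invisibly.
#' @export
write_mr_results <- function(battery, tsv = NULL, json = NULL) {
  df <- as.data.frame(battery)
  if (!is.null(tsv))
    utils::write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(json))
    jsonlite::write_json(
      list(results = df, direction_concordant = battery$direction_concordant,
           failures = as.list(battery$failures)),
      json, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(df)
}
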