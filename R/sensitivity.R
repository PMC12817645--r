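# Heterogeneity, pleiotropy, outlier and influence diagnostics.

#' Cochran's Q heterogeneity statistic
#'
#' `Q = sum_j w_j (r_j - theta)^2` over the per-SNP Wald ratios `r_j` with
#' inverse-variance weights `w_j = 1/se_ratio_j^2`, referred to a chi-square
#' with `k - 1` degrees of freedom. `theta` defaults to the fixed-effects
#' IVW estimate, at which Q over theta is minimized.
#'
#' @param h A `harmonized_set` with at least 2 kept SNPs.
#' @param theta Causal estimate at which to evaluate Q; default fixed-effects
#'   IVW.
#' @param wald_se Ratio-SE order.
#' @return List with `q`, `df`, `pval`.
#' @export
cochran_q <- function(h, theta = NULL, wald_se = "first") {
  wr <- wald_ratios(h, wald_se)
  if (nrow(wr) < 2L) stop("Cochran's Q requires >=2 SNPs")
  if (is.null(theta)) theta <- mr_ivw(h, "fixed")$beta
  w <- 1 / wr$se^2
  q <- sum(w * (wr$ratio - theta)^2)
  df <- nrow(wr) - 1L
  list(q = q, df = df, pval = stats::pchisq(q, df, lower.tail = FALSE))
}

# Leave-one-out fixed-effects IVW estimates via sum updates (vectorized).
loo_ivw_beta <- function(bx, by, w) {
  s1 <- sum(w * bx * by); s2 <- sum(w * bx^2)
  (s1 - w * bx * by) / (s2 - w * bx^2)
}

#' MR-PRESSO style global, outlier and distortion tests
#'
#' Residual-sum-of-squares test for horizontal-pleiotropy outliers.
#' The observed statistic is `RSS = sum_j w_j (by_j - theta_(-j) bx_j)^2`
#' with `theta_(-j)` the leave-one-out IVW estimate and weights
#' `w_j = 1/se_outcome_j^2`. Its null distribution is built by simulating
#' `n_sim` datasets with per-SNP betas drawn from normals centered on the
#' leave-one-out fitted values with the observed SEs, recomputing RSS the
#' same way. Per-SNP observed residual contributions are compared with their
#' simulated distributions for the outlier test (Bonferroni over SNPs), and
#' when outliers are flagged a distortion test compares the outlier-free IVW
#' estimate against estimates from removing equally many random SNPs.
#' Empirical p-values use the add-one rule `(1 + #exceed)/(n_sim + 1)`.
#'
#' @param h A `harmonized_set` with at least 4 kept SNPs.
#' @param n_sim Null-distribution draws (default 1000; below 100 a warning
#'   is logged).
#' @param sig Outlier significance level after Bonferroni correction.
#'   Default 0.05.
#' @param seed RNG seed.
#' @return List with `global_rss_obs`, `global_pval`, `outlier_indices`,
#'   `outlier_rsids`, `outlier_pvals` (Bonferroni-corrected, all SNPs),
#'   `distortion_pval`, `corrected_estimate` (IVW on non-outliers, or `NULL`
#'   when no outliers), `n_sim`, `seed`.
#' @export
mr_presso <- function(h, n_sim = 1000, sig = 0.05, seed = NULL) {
  k <- kept_entries(h)
  J <- nrow(k)
  if (J < 4L) stop("MR-PRESSO requires >=4 instruments")
  if (n_sim < 100) warning("mr_presso: n_sim < 100 gives a coarse null")
  bx <- k$beta_exposure; by <- k$beta_outcome
  sx <- k$se_exposure; sy <- k$se_outcome
  w <- 1 / sy^2

  theta_loo <- loo_ivw_beta(bx, by, w)
  res_obs <- w * (by - theta_loo * bx)^2
  rss_obs <- sum(res_obs)

  with_seed(seed, {
    # simulated datasets: k x n_sim matrices
    bx_sim <- matrix(stats::rnorm(J * n_sim, bx, sx), J, n_sim)
    by_sim <- matrix(stats::rnorm(J * n_sim, theta_loo * bx, sy), J, n_sim)
    s1 <- colSums(w * bx_sim * by_sim)
    s2 <- colSums(w * bx_sim^2)
    th_loo_sim <- (matrix(s1, J, n_sim, byrow = TRUE) - w * bx_sim * by_sim) /
      (matrix(s2, J, n_sim, byrow = TRUE) - w * bx_sim^2)
    res_sim <- w * (by_sim - th_loo_sim * bx_sim)^2
    rss_sim <- colSums(res_sim)
    global_pval <- (1 + sum(rss_sim >= rss_obs)) / (n_sim + 1)

    p_snp <- (1 + rowSums(res_sim >= res_obs)) / (n_sim + 1)
    p_adj <- pmin(1, p_snp * J)
    outliers <- which(p_adj < sig)

    distortion_pval <- NA_real_
    corrected <- NULL
    if (length(outliers) > 0 && length(outliers) < J - 1) {
      keep <- setdiff(seq_len(J), outliers)
      hk <- h_subset(h, k$rsid[keep])
      corrected <- mr_ivw(hk)
      draws <- vapply(seq_len(n_sim), function(i) {
        drop <- sample.int(J, length(outliers))
        kp <- setdiff(seq_len(J), drop)
        sum(w[kp] * bx[kp] * by[kp]) / sum(w[kp] * bx[kp]^2)
      }, numeric(1))
      lo <- (1 + sum(draws <= corrected$beta)) / (n_sim + 1)
      hi <- (1 + sum(draws >= corrected$beta)) / (n_sim + 1)
      distortion_pval <- min(1, 2 * min(lo, hi))
    }
    list(global_rss_obs = rss_obs, global_pval = global_pval,
         outlier_indices = outliers, outlier_rsids = k$rsid[outliers],
         outlier_pvals = p_adj, distortion_pval = distortion_pval,
         corrected_estimate = corrected, n_sim = n_sim, seed = seed)
  })
}

# Restrict a harmonized set to the given rsids (kept rows only).
h_subset <- function(h, rsids) {
  out <- h[h$rsid %in% rsids & h$action %in% c("kept", "flipped"), ,
           drop = FALSE]
  rownames(out) <- NULL
  attributes(out)[c("class", "exposure", "outcome")] <-
    attributes(h)[c("class", "exposure", "outcome")]
  out
}

#' Leave-one-out influence analysis
#'
#' Re-estimates the random-effects IVW effect k times, each time excluding
#' one SNP.
#'
#' @param h A `harmonized_set` with at least 3 kept SNPs.
#' @return Data.frame with columns `excluded_rsid`, `beta`, `se`, `pval`,
#'   one row per kept SNP.
#' @export
leave_one_out <- function(h) {
  k <- kept_entries(h)
  if (nrow(k) < 3L) stop("leave-one-out requires >=3 instruments")
  rows <- lapply(seq_len(nrow(k)), function(j) {
    fit <- mr_ivw(h_subset(h, k$rsid[-j]))
    data.frame(excluded_rsid = k$rsid[j], beta = fit$beta, se = fit$se,
               pval = fit$pval, stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, make.row.names = FALSE))
}

#' Full sensitivity report
#'
#' Bundles Cochran's Q (at the fixed-effects IVW estimate), the Egger
#' intercept test, MR-PRESSO and the leave-one-out table.
#'
#' @param h A `harmonized_set`.
#' @param config An [mr_config()]; `n_sim`, `presso_sig` and the seed stream
#'   are used.
#' @return A `sensitivity_report` list with components `q`, `egger`,
#'   `presso`, `loo` (unavailable components are `NULL` with the reason in
#'   `failures`).
#' @export
sensitivity_report <- function(h, config = mr_config()) {
  comp <- list(); failures <- character(0)
  run <- function(nm, f) {
    res <- tryCatch(f(), error = function(e) conditionMessage(e))
    if (is.character(res) && length(res) == 1L && !is.list(res))
      failures[[nm]] <<- res
    else comp[[nm]] <<- res
  }
  run("q", function() cochran_q(h))
  run("egger", function() {
    e <- mr_egger(h)
    list(intercept = e$extra$intercept, intercept_se = e$extra$intercept_se,
         intercept_pval = e$extra$intercept_pval)
  })
  run("presso", function() mr_presso(h, config$n_sim, config$presso_sig,
                                     derive_seed(config$seed, 11L)))
  run("loo", function() leave_one_out(h))
  structure(c(comp, list(failures = failures)),
            class = "sensitivity_report")
}

#' Serialize a sensitivity report as JSON
#' @param report A `sensitivity_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sensitivity_report <- function(report, path) {
  out <- unclass(report)
  if (!is.null(out$presso$corrected_estimate))
    out$presso$corrected_estimate <-
      as.data.frame(out$presso$corrected_estimate)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Deterministic plot-data exports
#'
#' Builds the data behind the standard MR diagnostic figures: per-SNP
#' scatter points with per-method regression lines, funnel points (Wald
#' ratio vs precision) with vertical method lines, a forest table (per-SNP
#' ratios with CIs plus combined method rows), and the leave-one-out table.
#' Rendering (see [mr_scatter_plot()] and friends) is a thin layer over
#' these tables.
#'
#' @param h A `harmonized_set`.
#' @param battery An `mr_battery` from [run_all_methods()] (optional; built
#'   with defaults when absent).
#' @param report A `sensitivity_report` (optional; its `loo` table is reused
#'   when present).
#' @return List of data.frames: `scatter_points`, `scatter_lines`,
#'   `funnel_points`, `funnel_lines`, `forest`, `loo`.
#' @export
plot_exports <- function(h, battery = NULL, report = NULL) {
  k <- kept_entries(h)
  if (is.null(battery)) battery <- run_all_methods(h)
  wr <- wald_ratios(h)
  scatter_points <- data.frame(
    rsid = k$rsid, beta_exposure = k$beta_exposure,
    se_exposure = k$se_exposure, beta_outcome = k$beta_outcome,
    se_outcome = k$se_outcome, stringsAsFactors = FALSE)
  scatter_lines <- do.call(rbind, lapply(names(battery$results), function(m) {
    r <- battery$results[[m]]
    data.frame(method = m, slope = r$beta,
               intercept = r$extra$intercept %||% 0,
               stringsAsFactors = FALSE)
  }))
  funnel_points <- data.frame(rsid = wr$rsid, ratio = wr$ratio,
                              precision = 1 / wr$se, stringsAsFactors = FALSE)
  funnel_lines <- data.frame(
    method = names(battery$results),
    beta = vapply(battery$results, `[[`, numeric(1), "beta"),
    stringsAsFactors = FALSE)
  rownames(funnel_lines) <- NULL
  forest_snp <- data.frame(
    label = wr$rsid, beta = wr$ratio, se = wr$se,
    ci_low = wr$ratio - 1.96 * wr$se, ci_high = wr$ratio + 1.96 * wr$se,
    type = "snp", stringsAsFactors = FALSE)
  forest_comb <- do.call(rbind, lapply(names(battery$results), function(m) {
    r <- battery$results[[m]]
    data.frame(label = m, beta = r$beta, se = r$se,
               ci_low = r$beta - 1.96 * r$se, ci_high = r$beta + 1.96 * r$se,
               type = "combined", stringsAsFactors = FALSE)
  }))
  loo <- report$loo %||% tryCatch(leave_one_out(h), error = function(e) NULL)
  list(scatter_points = scatter_points, scatter_lines = scatter_lines,
       funnel_points = funnel_points, funnel_lines = funnel_lines,
       forest = rbind(forest_snp, forest_comb), loo = loo)
}

#' Write plot-data tables as TSVs
#'
#' @param exports Output of [plot_exports()].
#' @param dir Output directory (created if needed); one `<name>.tsv` per
#'   table.
#' @return Vector of written paths, invisibly.
#' @export
write_plot_exports <- function(exports, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (nm in names(exports)) {
    if (is.null(exports[[nm]])) next
    p <- file.path(dir, paste0(nm, ".tsv"))
    utils::write.table(exports[[nm]], p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}
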