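test_that("Cochran's Q matches hand arithmetic and degenerates correctly", {
  h <- make_h(c(1, 1), c(0.4, 0.6), c(0.1, 0.2))
  q <- cochran_q(h, theta = 0.44)
  expect_equal(q$q, 100 * 0.04^2 + 25 * 0.16^2)  # 0.8
  expect_equal(q$df, 1L)
  # homogeneity: identical ratios
  q0 <- cochran_q(make_h(c(1, 1, 1), c(0.5, 0.5, 0.5), rep(0.1, 3)))
  expect_equal(q0$q, 0)
  expect_equal(q0$pval, 1)
  expect_error(cochran_q(make_h(1, 0.5, 0.1)), ">=2")
})

test_that("Q is minimized at the fixed-effects IVW estimate", {
  set.seed(17)
  bx <- runif(8, 0.1, 0.4); by <- 0.3 * bx + rnorm(8, 0, 0.02)
  h <- make_h(bx, by, sy = 0.02)
  theta_hat <- mr_ivw(h, "fixed")$beta
  q_hat <- cochran_q(h, theta_hat)$q
  for (d in c(-0.05, -0.01, 0.01, 0.05))
    expect_gt(cochran_q(h, theta_hat + d)$q, q_hat)
})

test_that("Q detects planted heterogeneity with high power", {
  ok <- vapply(1:100, function(s) {
    cfg <- simulation_config(
      n_snps = 40, n_snps_mediator = 0,
      pleiotropy = list(mode = "balanced", sd = 0.05, fraction_invalid = 0.5),
      seed = s)
    h <- sim_xy_harmonized(cfg)
    cochran_q(h)$pval < 0.05
  }, logical(1))
  expect_gte(mean(ok), 0.8)
})

test_that("MR-PRESSO flags a grossly displaced SNP and corrects the estimate", {
  st <- simulate_study(scenario_presets(seed = 3)$outliers)
  h <- harmonize(st$exposure, st$outcome)
  p <- mr_presso(h, n_sim = 1000, seed = 3)
  expect_true(st$truth$outlier_snp_ids %in% p$outlier_rsids)
  expect_lt(p$global_pval, 0.05)
  expect_s3_class(p$corrected_estimate, "mr_result")
  # the corrected estimate drops the outlier
  expect_equal(p$corrected_estimate$n_snp,
               nrow(kept_entries(h)) - length(p$outlier_indices))
  expect_false(is.na(p$distortion_pval))
  # removing the flagged outlier strictly decreases the observed RSS
  k <- kept_entries(h)
  h2 <- harmonize(st$exposure[st$exposure$rsid != st$truth$outlier_snp_ids, ],
                  st$outcome)
  p2 <- mr_presso(h2, n_sim = 200, seed = 3)
  expect_lt(p2$global_rss_obs, p$global_rss_obs)
})

test_that("MR-PRESSO is calibrated on clean data and degenerate inputs", {
  st <- simulate_study(simulation_config(n_snps = 21, n_snps_mediator = 0,
                                         seed = 9))
  h <- harmonize(st$exposure, st$outcome)
  p <- mr_presso(h, n_sim = 500, seed = 9)
  expect_gt(p$global_pval, 0.05)
  expect_length(p$outlier_indices, 0)
  # identical ratios with tiny SEs: RSS ~ 0, p ~ 1
  hd <- make_h(c(0.2, 0.25, 0.3, 0.35), 0.5 * c(0.2, 0.25, 0.3, 0.35),
               rep(1e-5, 4), sx = 1e-5)
  pd <- mr_presso(hd, n_sim = 200, seed = 1)
  expect_lt(pd$global_rss_obs, 1e-6)
  expect_gt(pd$global_pval, 0.9)
  expect_error(mr_presso(make_h(c(1, 1, 1), c(1, 1, 1), rep(0.1, 3))), ">=4")
  expect_warning(mr_presso(hd, n_sim = 50, seed = 1), "coarse")
})

test_that("MR-PRESSO global p is invariant to SNP order at a fixed seed", {
  set.seed(23)
  bx <- runif(10, 0.1, 0.4); by <- 0.3 * bx + rnorm(10, 0, 0.02)
  h <- make_h(bx, by, sy = 0.02)
  p1 <- mr_presso(h, n_sim = 500, seed = 5)
  perm <- sample(10)
  hp <- make_h(bx[perm], by[perm], sy = rep(0.02, 10))
  p2 <- mr_presso(hp, n_sim = 500, seed = 5)
  expect_lt(abs(p1$global_pval - p2$global_pval), 0.05)
})

test_that("leave-one-out produces one calibrated row per SNP", {
  # exchangeable SNPs: all rows identical
  h <- make_h(rep(0.2, 4), rep(0.1, 4), rep(0.02, 4))
  loo <- leave_one_out(h)
  expect_equal(nrow(loo), 4L)
  expect_equal(length(unique(round(loo$beta, 12))), 1L)
  # k = 3: each row is a 2-SNP IVW
  h3 <- make_h(c(0.2, 0.3, 0.25), c(0.06, 0.09, 0.08), rep(0.01, 3))
  expect_equal(nrow(leave_one_out(h3)), 3L)
  # a dominant outlier moves the estimate most when excluded
  set.seed(4)
  bx <- runif(8, 0.2, 0.4); by <- 0.3 * bx + rnorm(8, 0, 0.002)
  by[5] <- by[5] + 0.3
  ho <- make_h(bx, by, sy = 0.01)
  full <- mr_ivw(ho)$beta
  lo <- leave_one_out(ho)
  expect_equal(which.max(abs(lo$beta - full)), 5L)
})

test_that("plot exports carry points, method lines and a consistent forest", {
  h <- make_h(c(0.2, 0.3, 0.25, 0.35, 0.28),
              c(0.06, 0.09, 0.07, 0.11, 0.08), rep(0.01, 5))
  bat <- run_all_methods(h, mr_config(n_boot = 20, seed = 1))
  pe <- plot_exports(h, bat)
  expect_equal(nrow(pe$scatter_points), 5L)
  expect_gte(nrow(pe$scatter_lines), 2L)
  expect_equal(nrow(pe$funnel_points), 5L)
  # the combined forest row equals the IVW result exactly
  comb <- pe$forest[pe$forest$type == "combined" & pe$forest$label == "IVW", ]
  expect_equal(comb$beta, bat$results$IVW$beta)
  expect_equal(comb$se, bat$results$IVW$se)
  # Egger's scatter line carries its intercept, others zero
  sl <- pe$scatter_lines
  expect_equal(sl$intercept[sl$method == "IVW"], 0)
  expect_equal(sl$intercept[sl$method == "Egger"],
               bat$results$Egger$extra$intercept)
  # tables serialize deterministically
  d1 <- tempfile(); d2 <- tempfile()
  write_plot_exports(pe, d1); write_plot_exports(pe, d2)
  f1 <- list.files(d1, full.names = TRUE)
  f2 <- list.files(d2, full.names = TRUE)
  expect_equal(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
})

test_that("funnel plots are symmetric in the absence of pleiotropy", {
  ok <- vapply(1:60, function(s) {
    h <- sim_xy_harmonized(simulation_config(n_snps = 40,
                                             n_snps_mediator = 0, seed = s))
    wrr <- kept_entries(h)
    r <- wrr$beta_outcome / wrr$beta_exposure
    theta <- mr_ivw(h, "fixed")$beta
    stats::binom.test(sum(r > theta), length(r))$p.value > 0.05
  }, logical(1))
  expect_gte(mean(ok), 0.85)
})

test_that("the bundled sensitivity report serializes to JSON", {
  st <- simulate_study(simulation_config(n_snps = 15, n_snps_mediator = 0,
                                         seed = 6))
  h <- sim_xy_harmonized(simulation_config(n_snps = 15, n_snps_mediator = 0,
                                           seed = 6))
  rep <- sensitivity_report(h, mr_config(n_sim = 200, seed = 6))
  expect_named(rep, c("q", "egger", "presso", "loo", "failures"),
               ignore.order = TRUE)
  expect_equal(nrow(rep$loo), nrow(kept_entries(h)))
  js <- tempfile(fileext = ".json")
  write_sensitivity_report(rep, js)
  parsed <- jsonlite::read_json(js)
  expect_equal(parsed$q$df, rep$q$df)
})
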