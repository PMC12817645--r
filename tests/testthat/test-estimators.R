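test_that("Wald ratio is the direct outcome/exposure quotient", {
  expect_equal(mr_wald_ratio(make_h(0.1, 0.05, 0.02))$beta, 0.5)
  expect_equal(mr_wald_ratio(make_h(0.1, 0, 0.02))$beta, 0)
  expect_equal(mr_wald_ratio(make_h(0.1, 0.05, 0.02))$se, 0.2)
  # second-order SE adds the exposure uncertainty term
  r2 <- mr_wald_ratio(make_h(0.1, 0.05, 0.02, sx = 0.01), wald_se = "second")
  expect_equal(r2$se, sqrt(0.02^2 / 0.1^2 + 0.05^2 * 0.01^2 / 0.1^4))
  expect_error(mr_wald_ratio(make_h(0, 0.05, 0.02)), "undefined")
})

test_that("IVW reproduces the closed-form inverse-variance weighted mean", {
  # two SNPs with unit exposure betas: ratios 0.4 (se 0.1) and 0.6 (se 0.2)
  h <- make_h(c(1, 1), c(0.4, 0.6), c(0.1, 0.2))
  fit <- mr_ivw(h, "fixed")
  expect_equal(fit$beta, (0.4 * 100 + 0.6 * 25) / 125)  # 0.44
  # consensus: identical ratios
  expect_equal(mr_ivw(make_h(c(1, 1), c(0.5, 0.5), c(0.1, 0.1)))$beta, 0.5)
  # MRResult invariants
  expect_equal(fit$or_point, exp(fit$beta))
  expect_lt(fit$ci_low, fit$or_point)
  expect_gt(fit$ci_high, fit$or_point)
})

test_that("IVW equals the weighted mean of Wald ratios on small instances", {
  set.seed(8)
  for (k in 2:5) {
    bx <- rnorm(k, 0.2, 0.05); by <- rnorm(k, 0.06, 0.02)
    sy <- runif(k, 0.005, 0.05)
    h <- make_h(bx, by, sy)
    # independent oracle: weighted mean of ratios with 1/se_ratio^2 weights
    r <- by / bx; w <- (bx / sy)^2
    expect_equal(mr_ivw(h, "fixed")$beta, sum(w * r) / sum(w))
  }
})

test_that("IVW downgrades to the Wald ratio below 2 SNPs", {
  h <- make_h(0.1, 0.05, 0.02)
  fit <- suppressMessages(mr_ivw(h))
  expect_equal(fit$method, "WaldRatio")
  expect_equal(fit$beta, 0.5)
})

test_that("Egger recovers slope and intercept of a constructed line", {
  set.seed(21)
  bx <- seq(0.05, 0.5, length.out = 10)
  by <- 0.01 + 0.5 * bx + rnorm(10, 0, 1e-6)
  fit <- mr_egger(make_h(bx, by, sy = 0.01))
  expect_equal(fit$beta, 0.5, tolerance = 1e-3)
  expect_equal(fit$extra$intercept, 0.01, tolerance = 1e-3)
  expect_error(mr_egger(make_h(c(1, 1), c(0.4, 0.6), c(0.1, 0.2))), ">=3")
  expect_error(mr_egger(make_h(rep(0.2, 5), rnorm(5), 0.01)), "degenerate")
})

test_that("Egger with the intercept constrained to zero is IVW", {
  set.seed(9)
  bx <- runif(6, 0.05, 0.4); by <- 0.3 * bx + rnorm(6, 0, 0.01)
  h <- make_h(bx, by, sy = 0.01)
  refit <- lm(by ~ bx - 1, weights = rep(1 / 0.01^2, 6))
  expect_equal(mr_ivw(h, "fixed")$beta, unname(coef(refit)["bx"]))
})

test_that("Egger intercept test holds its size without pleiotropy", {
  ok <- vapply(1:300, function(s) {
    st <- simulate_study(simulation_config(n_snps = 50, n_snps_mediator = 0,
                                           seed = s))
    iv <- suppressMessages(select_instruments(st$exposure, st$ld))
    h <- harmonize(iv, st$outcome)
    mr_egger(h)$extra$intercept_pval > 0.05
  }, logical(1))
  expect_gte(mean(ok), 0.9)
})

test_that("weighted median matches hand cases and the plain median", {
  h <- make_h(c(1, 1, 1), c(0.1, 0.5, 0.9), c(0.1, 0.1, 0.1))
  fit <- mr_weighted_median(h, n_boot = 50, seed = 1)
  expect_equal(fit$beta, 0.5)
  # consensus with shrinking SEs: estimate exact, bootstrap SE shrinks
  h2 <- make_h(c(1, 1, 1), c(0.3, 0.3, 0.3), c(1e-4, 1e-4, 1e-4),
               sx = 1e-4)
  fit2 <- mr_weighted_median(h2, n_boot = 100, seed = 1)
  expect_equal(fit2$beta, 0.3)
  expect_lt(fit2$se, 1e-3)
  # equal weights reduce to the ordinary median of ratios
  set.seed(5)
  for (k in c(3, 5, 8)) {
    r <- rnorm(k, 0.3, 0.2)
    h3 <- make_h(rep(1, k), r, rep(0.05, k))
    fit3 <- mr_weighted_median(h3, n_boot = 10, seed = 1)
    expect_equal(fit3$beta, median(r))
  }
})

test_that("weighted median resists a minority of invalid instruments", {
  # 10 valid SNPs at theta 0.3 plus 4 with +0.5 pleiotropy; valid SNPs
  # carry the majority of the weight
  set.seed(14)
  bx <- runif(14, 0.15, 0.4)
  by <- 0.3 * bx + rnorm(14, 0, 0.004)
  by[11:14] <- by[11:14] + 0.5
  h <- make_h(bx, by, sy = 0.01)
  fit <- mr_weighted_median(h, n_boot = 500, seed = 2)
  expect_lt(abs(fit$beta - 0.3), 2 * fit$se)
  # while IVW is dragged far off by the same contamination
  expect_gt(abs(mr_ivw(h)$beta - 0.3), abs(fit$beta - 0.3))
})

test_that("mode estimators find the dominant ratio cluster", {
  h <- make_h(rep(1, 4), c(0.5, 0.5, 0.5, 2.0), rep(0.05, 4))
  fit <- mr_mode(h, weighted = FALSE, n_boot = 50, seed = 1)
  expect_equal(fit$beta, 0.5, tolerance = 0.05)
  # equal weights: weighted and simple modes agree exactly
  w <- mr_mode(h, weighted = TRUE, n_boot = 10, seed = 1)
  s <- mr_mode(h, weighted = FALSE, n_boot = 10, seed = 1)
  expect_equal(w$beta, s$beta)
  # bimodal ratios: argmax lands within half a bandwidth of the big cluster
  set.seed(3)
  r <- c(rnorm(12, 0.2, 0.01), rnorm(5, 0.8, 0.01))
  hb <- make_h(rep(1, 17), r, rep(0.03, 17))
  fb <- mr_mode(hb, weighted = FALSE, n_boot = 10, seed = 1)
  expect_lt(abs(fb$beta - 0.2), fb$extra$bandwidth / 2 + 0.02)
})

test_that("estimators are equivariant under exposure rescaling", {
  set.seed(31)
  bx <- runif(8, 0.1, 0.4); by <- 0.3 * bx + rnorm(8, 0, 0.01)
  h1 <- make_h(bx, by, sy = 0.01, sx = 0.02)
  c0 <- 2.5
  h2 <- make_h(c0 * bx, by, sy = 0.01, sx = c0 * 0.02)
  expect_equal(mr_ivw(h2)$beta, mr_ivw(h1)$beta / c0)
  expect_equal(mr_egger(h2)$beta, mr_egger(h1)$beta / c0)
  expect_equal(mr_weighted_median(h2, 10, 1)$beta,
               mr_weighted_median(h1, 10, 1)$beta / c0)
  expect_equal(mr_mode(h2, n_boot = 10, seed = 1)$beta,
               mr_mode(h1, n_boot = 10, seed = 1)$beta / c0)
})

test_that("BWMR recovers the causal effect and agrees with IVW when clean", {
  st <- simulate_study(simulation_config(theta_direct = 0.1, seed = 7))
  iv <- suppressMessages(select_instruments(st$exposure, st$ld))
  h <- harmonize(iv, st$outcome)
  fit <- mr_bwmr(h, n_iter = 6000, seed = 7)
  expect_lt(abs(fit$beta - 0.1), 2 * fit$se)
  # pleiotropy variance concentrates near zero on clean data
  expect_lt(fit$extra$tau, 0.02)
  expect_true(fit$extra$converged)
  # concordance with IVW under no pleiotropy and strong instruments
  ivw <- mr_ivw(h)
  expect_lt(abs(fit$beta - ivw$beta), 0.5 * ivw$se)
  # deterministic given the seed
  expect_identical(fit$beta, mr_bwmr(h, n_iter = 6000, seed = 7)$beta)
  expect_error(mr_bwmr(make_h(c(1, 1), c(0.4, 0.6), c(0.1, 0.2))), ">=3")
})

test_that("the method battery reports concordance and per-method failures", {
  st <- simulate_study(simulation_config(seed = 12))
  iv <- suppressMessages(select_instruments(st$exposure, st$ld))
  h <- harmonize(iv, st$outcome)
  bat <- run_all_methods(h, mr_config(seed = 12, n_boot = 100))
  expect_setequal(names(bat$results),
                  c("IVW", "Egger", "WeightedMedian", "WeightedMode",
                    "SimpleMode"))
  expect_true(bat$direction_concordant)
  df <- as.data.frame(bat)
  expect_equal(nrow(df), 5L)
  expect_true(all(c("method", "nsnp", "beta", "se", "pval", "or",
                    "ci_low", "ci_high") %in% names(df)))

  # a 2-SNP set cannot complete the battery: flag false with the reason
  h2 <- make_h(c(0.2, 0.3), c(0.06, 0.09), c(0.01, 0.01))
  bat2 <- suppressMessages(run_all_methods(h2, mr_config(n_boot = 10)))
  expect_false("Egger" %in% names(bat2$results))
  expect_false(bat2$direction_concordant)
  expect_equal(bat2$concordance_reason, "incomplete battery")
})

test_that("battery results serialize to TSV and JSON", {
  h <- make_h(c(0.2, 0.3, 0.25, 0.35), c(0.06, 0.09, 0.07, 0.11),
              rep(0.01, 4))
  bat <- run_all_methods(h, mr_config(n_boot = 20, seed = 1))
  tsv <- tempfile(fileext = ".tsv"); js <- tempfile(fileext = ".json")
  write_mr_results(bat, tsv = tsv, json = js)
  re <- utils::read.table(tsv, header = TRUE, sep = "\t")
  expect_equal(nrow(re), nrow(as.data.frame(bat)))
  parsed <- jsonlite::read_json(js)
  expect_true(is.logical(parsed$direction_concordant))
})
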