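test_that("reading a well-formed table returns all rows unchanged", {
  path <- write_tsv_fixture(canonical_table())
  ss <- read_sumstats(path)
  expect_s3_class(ss, "sumstats")
  expect_equal(nrow(ss), 3L)
  expect_equal(attr(ss, "n_dropped"), 0L)
  expect_equal(ss$rsid, c("rs1", "rs2", "rs3"))
  expect_equal(ss$beta, c(0.10, -0.05, 0.02))

  # comma-delimited variant reads identically
  path_csv <- write_tsv_fixture(canonical_table(),
                                tempfile(fileext = ".csv"), sep = ",")
  csv <- read_sumstats(path_csv, trait = "t")
  expect_equal(data.frame(csv), data.frame(ss))
})

test_that("invalid rows are dropped and counted, not fatal", {
  tab <- canonical_table()
  tab$SE[2] <- 0
  path <- write_tsv_fixture(tab)
  ss <- suppressMessages(read_sumstats(path))
  expect_equal(nrow(ss), 2L)
  expect_equal(attr(ss, "n_dropped"), 1L)
  expect_equal(unname(attr(ss, "drop_reasons")["bad_se"]), 1L)

  # multi-allelic and duplicate rows are likewise dropped with a count
  tab2 <- rbind(canonical_table(), canonical_table()[1, ])
  tab2$EA[2] <- "AT"
  path2 <- write_tsv_fixture(tab2)
  ss2 <- suppressMessages(read_sumstats(path2))
  expect_equal(nrow(ss2), 2L)
  expect_equal(attr(ss2, "n_dropped"), 2L)
})

test_that("column order is irrelevant given a column map", {
  tab <- canonical_table()
  shuffled <- tab[, c("P", "N", "SNP", "BETA", "SE", "CHR", "POS", "EA",
                      "OA", "EAF")]
  names(shuffled) <- c("pvalue", "nsamp", "marker", "b", "stderr", "chr",
                       "bp", "a1", "a2", "freq")
  path <- write_tsv_fixture(shuffled)
  ss <- read_sumstats(path, column_map = c(
    rsid = "marker", chrom = "chr", pos = "bp", effect_allele = "a1",
    other_allele = "a2", eaf = "freq", beta = "b", se = "stderr",
    pval = "pvalue", n = "nsamp"), trait = "t")
  ref <- read_sumstats(write_tsv_fixture(tab), trait = "t")
  expect_equal(data.frame(ss), data.frame(ref))
})

test_that("missing columns and empty files are hard errors", {
  tab <- canonical_table()
  tab$BETA <- NULL
  expect_error(read_sumstats(write_tsv_fixture(tab)), "BETA")
  empty <- tempfile()
  file.create(empty)
  expect_error(read_sumstats(empty), "empty")
  expect_error(read_sumstats(tempfile()), "not found")
})

test_that("harmonization aligns, flips, and excludes as specified", {
  ex <- make_ss(c("rs1", "rs2", "rs3", "rs4"), beta = c(0.10, 0.2, 0.1, 0.1),
                se = 0.01, ea = c("A", "A", "A", "A"),
                oa = c("G", "T", "C", "G"), eaf = c(0.2, 0.5, 0.3, 0.3))
  ou <- sumstats(c("rs1", "rs2", "rs3", "rs4"), "1", 1:4 * 1000L,
                 effect_allele = c("G", "A", "A", "A"),
                 other_allele = c("A", "T", "C", "C"),
                 eaf = c(0.8, 0.5, 0.3, 0.3),
                 beta = c(-0.05, 0.1, 0.1, 0.1), se = 0.02, pval = 0.01,
                 n = 10000, trait = "Y")
  h <- harmonize(ex, ou)
  expect_equal(h$action,
               c("flipped", "excluded_palindromic", "kept",
                 "excluded_mismatch"))
  # allele swap flips the outcome beta sign and complements its frequency
  expect_equal(h$beta_outcome[1], 0.05)
  expect_equal(h$eaf_outcome[1], 0.2)
  # only kept/flipped rows feed the estimators
  expect_equal(kept_entries(h)$rsid, c("rs1", "rs3"))
})

test_that("palindromes are kept only with concordant informative frequencies", {
  mk <- function(eaf_x, eaf_y, w = 0.08) {
    ex <- make_ss("rs1", 0.1, 0.01, ea = "A", oa = "T", eaf = eaf_x)
    ou <- make_ss("rs1", 0.05, 0.02, ea = "A", oa = "T", eaf = eaf_y)
    harmonize(ex, ou, palindrome_eaf_window = w)$action
  }
  expect_equal(mk(0.2, 0.25), "kept")
  expect_equal(mk(0.50, 0.50), "excluded_palindromic")  # uninformative
  expect_equal(mk(0.45, 0.45), "excluded_palindromic")  # inside the window
  expect_equal(mk(0.2, 0.8), "excluded_palindromic")    # opposite sides
  expect_equal(mk(NA, 0.2), "excluded_palindromic")     # missing frequency
  expect_equal(mk(0.2, 0.25, w = 0.5), "excluded_palindromic")  # w >= 0.5
})

test_that("allele-frequency discrepancies beyond the tolerance are excluded", {
  ex <- make_ss(c("rs1", "rs2"), c(0.1, 0.1), 0.01, eaf = c(0.10, 0.10))
  ou <- make_ss(c("rs1", "rs2"), c(0.05, 0.05), 0.02, eaf = c(0.35, 0.25))
  h <- harmonize(ex, ou, eaf_tol = 0.2)
  expect_equal(h$action, c("excluded_eaf", "kept"))
  expect_error(harmonize(make_ss("rs1", 0.1, 0.01),
                         make_ss("rsX", 0.1, 0.01)), "no overlapping")
})

test_that("harmonization count identity, idempotence and swap invariance hold", {
  set.seed(11)
  st <- simulate_study(simulation_config(n_snps = 40, n_snps_mediator = 0,
                                         seed = 5))
  h <- harmonize(st$exposure, st$outcome)
  # count identity over the rsid intersection
  expect_equal(nrow(h),
               length(intersect(st$exposure$rsid, st$outcome$rsid)))
  expect_equal(sum(table(h$action)), nrow(h))

  # idempotence: re-harmonizing the aligned kept entries changes nothing
  k <- kept_entries(h)
  ex2 <- sumstats(k$rsid, k$chrom, k$pos, k$effect_allele, k$other_allele,
                  k$eaf_exposure, k$beta_exposure, k$se_exposure,
                  k$pval_exposure, k$n_exposure, trait = "X")
  ou2 <- sumstats(k$rsid, k$chrom, k$pos, k$effect_allele, k$other_allele,
                  k$eaf_outcome, k$beta_outcome, k$se_outcome,
                  k$pval_outcome, k$n_outcome, trait = "Y")
  h2 <- harmonize(ex2, ou2)
  expect_true(all(h2$action == "kept"))
  expect_equal(h2$beta_outcome, k$beta_outcome)
  expect_equal(h2$beta_exposure, k$beta_exposure)

  # swapping every outcome row's alleles (and negating beta) is undone
  ou_sw <- st$outcome
  tmp <- ou_sw$effect_allele
  ou_sw$effect_allele <- ou_sw$other_allele
  ou_sw$other_allele <- tmp
  ou_sw$beta <- -ou_sw$beta
  ou_sw$eaf <- 1 - ou_sw$eaf
  h3 <- harmonize(st$exposure, ou_sw)
  k3 <- kept_entries(h3)
  expect_equal(k3$rsid, k$rsid)
  expect_equal(k3$beta_outcome, k$beta_outcome)
})

test_that("harmonized sets round-trip through TSV bit-stably", {
  st <- simulate_study(simulation_config(n_snps = 10, n_snps_mediator = 0,
                                         seed = 2))
  h <- harmonize(st$exposure, st$outcome)
  f1 <- tempfile(); f2 <- tempfile()
  write_harmonized(h, f1)
  write_harmonized(h, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_equal(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
})
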