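#' @keywords internal
"_PACKAGE"

# Run code with a temporary RNG state; restores the caller's .Random.seed.
# seed = NULL means "use the current stream" (no isolation).
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a child seed from a root seed; keeps results < 2^31.
derive_seed <- function(seed, offset) {
  if (is.null(seed)) return(NULL)
  (as.integer(seed) + as.integer(offset) * 7919L) %% 2147483629L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

two_sided_normal_p <- function(z) 2 * stats::pnorm(-abs(z))

#' Analysis configuration for the MR pipeline
#'
#' Bundles every tunable threshold of the instrument-selection, harmonization,
#' estimation and sensitivity stages into one list, so a whole analysis is
#' reproducible from (config, seed, input tables).
#'
#' @param p_threshold Instrument significance threshold (SNPs with
#'   `pval < p_threshold` are candidates). Default `1e-5`, the relaxed
#'   threshold used when genome-wide significant instruments are scarce.
#' @param clump_r2 LD clumping r-squared bound; SNPs within `clump_kb` of a
#'   retained index SNP with r-squared at or above this are removed.
#'   Default `0.001`.
#' @param clump_kb Clumping window in kilobases (center-to-center, same
#'   chromosome). Default `10000`.
#' @param f_min Weak-instrument cutoff: SNPs with F-statistic `> f_min` are
#'   kept. Default `10`.
#' @param palindrome_window Half-width `w` of the allele-frequency ambiguity
#'   zone for palindromic (A/T, C/G) SNPs: a palindrome is kept only when both
#'   effect-allele frequencies lie outside `[0.5 - w, 0.5 + w]` and on the same
#'   side of 0.5. `w >= 0.5` excludes all palindromes. Default `0.08`.
#' @param eaf_tol Maximum tolerated absolute effect-allele-frequency
#'   discrepancy between datasets after alignment. Default `0.2`.
#' @param ivw_model `"random"` (multiplicative random effects, default) or
#'   `"fixed"`.
#' @param wald_se `"first"` (default) or `"second"` order Wald-ratio standard
#'   error.
#' @param n_boot Parametric bootstrap replicates for median/mode estimators.
#' @param n_sim Simulated null datasets for the MR-PRESSO global/outlier tests.
#' @param presso_sig Outlier significance level (Bonferroni-corrected) for
#'   MR-PRESSO. Default `0.05`.
#' @param run_bwmr Include Bayesian weighted MR in the method battery.
#' @param bwmr_iter MCMC iterations for BWMR.
#' @param seed Root seed; all stochastic stages derive their own streams
#'   from it.
#' @return A list of class `"mr_config"`.
#' @export
mr_config <- function(p_threshold = 1e-5, clump_r2 = 0.001, clump_kb = 10000,
                      f_min = 10, palindrome_window = 0.08, eaf_tol = 0.2,
                      ivw_model = c("random", "fixed"),
                      wald_se = c("first", "second"),
                      n_boot = 1000, n_sim = 1000, presso_sig = 0.05,
                      run_bwmr = FALSE, bwmr_iter = 6000, seed = NULL) {
  stopifnot(p_threshold > 0, p_threshold <= 1, clump_r2 >= 0, clump_kb > 0,
            f_min >= 0, palindrome_window >= 0, eaf_tol >= 0,
            n_boot >= 1, n_sim >= 1)
  cfg <- list(p_threshold = p_threshold, clump_r2 = clump_r2,
              clump_kb = clump_kb, f_min = f_min,
              palindrome_window = palindrome_window, eaf_tol = eaf_tol,
              ivw_model = match.arg(ivw_model), wald_se = match.arg(wald_se),
              n_boot = n_boot, n_sim = n_sim, presso_sig = presso_sig,
              run_bwmr = run_bwmr, bwmr_iter = bwmr_iter, seed = seed)
  class(cfg) <- "mr_config"
  cfg
}
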