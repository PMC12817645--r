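# Simulated two-sample GWAS summary statistics with known causal and
# mediation structure (exposure -> mediator -> outcome), the offline
# stand-in for real lipidome / immune-phenotype / disease GWAS sources.
#
# Sampling model (standardized traits): per SNP j and trait with sample
# size N, the observed beta is Normal(true effect, se^2) with
# se = 1/sqrt(2 N maf (1 - maf)); the binary outcome keeps the same Gaussian
# model with its SEs inflated by `outcome_se_scale` (log-odds-scale
# approximation for a case/control GWAS).

#' Simulation configuration
#'
#' Defines a simulated two-sample MR mediation study. SNPs come in two
#' panels: `n_snps` exposure instruments with true exposure effects
#' `gamma_j ~ N(0, gamma_sd^2)` that propagate to the mediator
#' (`alpha_xm * gamma_j`) and outcome
#' (`theta_direct * gamma_j + beta_my * mediator effect`), and
#' `n_snps_mediator` mediator-specific instruments with their own effects
#' `delta_j ~ N(0, delta_sd^2)` on the mediator only (propagating to the
#' outcome as `beta_my * delta_j`) — without such variants a mediator trait
#' would have no instruments of its own and the mediator -> outcome MR leg
#' would be unidentifiable.
#'
#' @param n_snps Exposure-instrument SNPs. Default 50.
#' @param n_snps_mediator Mediator-specific SNPs (0 allowed). Default 30,
#'   matching the instrument counts specialized cell-phenotype GWAS yield
#'   at a relaxed threshold.
#' @param n_exposure,n_mediator,n_outcome GWAS sample sizes. Defaults 7174
#'   (lipidome-scale cohort), 400 (a specialized flow-cytometry
#'   immunophenotype cohort: small N, so only the mediator's own large
#'   cell-intrinsic QTLs — not exposure-transmitted signals — reach the
#'   instrument threshold) and 254618 (case/control outcome cohort).
#' @param maf_range Uniform range for minor-allele frequencies.
#'   Default `c(0.05, 0.45)`.
#' @param gamma_sd SD of true exposure-instrument effects (per-allele, SD
#'   units of the trait). Default 0.3.
#' @param delta_sd SD of mediator-specific instrument effects. Default 0.6:
#'   flow-cytometry cell phenotypes carry far larger per-variant effects
#'   than metabolite traits, which both strengthens their instruments and
#'   keeps selection clear of winner's-curse attenuation at small N.
#' @param theta_direct Direct exposure -> outcome effect. Default 0.3.
#' @param alpha_xm Exposure -> mediator effect. Default 0.
#' @param beta_my Mediator -> outcome effect. Default 0.
#' @param pleiotropy List `mode` (`"none"`, `"balanced"`, `"directional"`),
#'   `sd`, `fraction_invalid`, and `mu` (mean pleiotropic effect; 0 when
#'   balanced). Invalid exposure SNPs receive direct outcome effects
#'   `~ N(mu, sd^2)` and independent mediator-path effects of the same law.
#' @param n_outliers Gross outliers: SNPs whose observed outcome beta is
#'   displaced by `outlier_shift` outcome SEs.
#' @param outlier_shift Displacement in outcome-SE units.
#' @param palindrome_fraction Fraction of SNPs with A/T or C/G allele pairs.
#'   Default 0.2.
#' @param flip_fraction Fraction of mediator/outcome rows emitted with
#'   swapped alleles, negated beta and complemented frequency (harmonization
#'   must undo this). Default 0.3.
#' @param ld_blocks `NULL` (all SNPs independent) or list `size` (SNPs per
#'   LD block, placed within 100 kb of one another) and `r2` (within-block
#'   r-squared).
#' @param outcome_se_scale Outcome SE inflation factor approximating the
#'   log-odds scale of a case/control GWAS (2.8 corresponds to a case
#'   fraction near 0.15). Default 2.8.
#' @param seed RNG seed; generation is fully deterministic given it.
#' @return A `sim_config` list.
#' @export
simulation_config <- function(n_snps = 50, n_snps_mediator = 30,
                              n_exposure = 7174, n_mediator = 400,
                              n_outcome = 254618,
                              maf_range = c(0.05, 0.45), gamma_sd = 0.3,
                              delta_sd = 0.6,
                              theta_direct = 0.3, alpha_xm = 0, beta_my = 0,
                              pleiotropy = list(mode = "none", sd = 0,
                                                fraction_invalid = 0, mu = 0),
                              n_outliers = 0, outlier_shift = 0,
                              palindrome_fraction = 0.2, flip_fraction = 0.3,
                              ld_blocks = NULL, outcome_se_scale = 2.8,
                              seed = 1) {
  pleiotropy <- utils::modifyList(
    list(mode = "none", sd = 0, fraction_invalid = 0, mu = 0), pleiotropy)
  cfg <- list(n_snps = n_snps, n_snps_mediator = n_snps_mediator,
              n_exposure = n_exposure, n_mediator = n_mediator,
              n_outcome = n_outcome, maf_range = maf_range,
              gamma_sd = gamma_sd, delta_sd = delta_sd,
              theta_direct = theta_direct,
              alpha_xm = alpha_xm, beta_my = beta_my,
              pleiotropy = pleiotropy, n_outliers = n_outliers,
              outlier_shift = outlier_shift,
              palindrome_fraction = palindrome_fraction,
              flip_fraction = flip_fraction, ld_blocks = ld_blocks,
              outcome_se_scale = outcome_se_scale, seed = seed)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    if (n_snps < 2) stop("n_snps must be >= 2")
    if (n_snps_mediator < 0) stop("n_snps_mediator must be >= 0")
    if (any(c(n_exposure, n_mediator, n_outcome) < 2))
      stop("sample sizes must be >= 2")
    if (length(maf_range) != 2 || maf_range[1] <= 0 || maf_range[2] >= 1 ||
        maf_range[1] > maf_range[2]) stop("invalid maf_range")
    if (gamma_sd < 0 || delta_sd < 0) stop("effect SDs must be >= 0")
    frac <- c(pleiotropy$fraction_invalid, palindrome_fraction, flip_fraction)
    if (any(frac < 0 | frac > 1)) stop("fractions must lie in [0, 1]")
    if (!pleiotropy$mode %in% c("none", "balanced", "directional"))
      stop("pleiotropy mode must be none/balanced/directional")
    if (pleiotropy$sd < 0) stop("pleiotropy sd must be >= 0")
    if (n_outliers < 0 || n_outliers > n_snps) stop("invalid n_outliers")
    if (outcome_se_scale <= 0) stop("outcome_se_scale must be > 0")
    if (!is.null(ld_blocks) &&
        (is.null(ld_blocks$size) || ld_blocks$size < 1 ||
         is.null(ld_blocks$r2) || ld_blocks$r2 < 0 || ld_blocks$r2 > 1))
      stop("ld_blocks needs size >= 1 and r2 in [0, 1]")
  })
  invisible(cfg)
}

.nonpal_pairs <- rbind(c("A", "C"), c("A", "G"), c("C", "A"), c("C", "T"),
                       c("G", "A"), c("G", "T"), c("T", "C"), c("T", "G"))
.pal_pairs <- rbind(c("A", "T"), c("T", "A"), c("C", "G"), c("G", "C"))

#' Simulate a two-sample MR mediation study
#'
#' Generates exposure, mediator and outcome summary-statistic tables over a
#' shared SNP panel, a matching (block-diagonal) LD matrix, and the ground
#' truth, following the model described in [simulation_config()]. The
#' outputs are byte-identical for identical configurations (including the
#' seed); the flip/palindrome stages consume RNG draws even when their
#' fractions are zero, so runs differing only in those fractions share all
#' other draws.
#'
#' @param config A [simulation_config()].
#' @return A `sim_study` list: `exposure`, `mediator`, `outcome`
#'   (`sumstats`), `ld` (`ld_matrix`), `truth` (list with `theta_total`,
#'   `theta_direct`, `alpha_xm`, `beta_my`, `invalid_snp_ids`,
#'   `outlier_snp_ids`, `exposure_snp_ids`, `mediator_snp_ids`), and
#'   `config`.
#' @export
simulate_study <- function(config = simulation_config()) {
  validate_sim_config(config)
  cf <- config
  with_seed(cf$seed, {
    kx <- cf$n_snps; km <- cf$n_snps_mediator; k <- kx + km
    rsid <- c(sprintf("rs%04d", seq_len(kx)),
              if (km > 0) sprintf("rsm%04d", seq_len(km)))
    maf <- stats::runif(k, cf$maf_range[1], cf$maf_range[2])
    gamma <- stats::rnorm(kx, 0, cf$gamma_sd)           # exposure effects
    delta <- if (km > 0) stats::rnorm(km, 0, cf$delta_sd) else numeric(0)
    # physical bound: a single variant cannot explain more than ~30% of a
    # standardized trait's variance (2 maf (1-maf) beta^2 <= 0.3); winsorize
    cap <- sqrt(0.3 / (2 * maf * (1 - maf)))
    gamma <- sign(gamma) * pmin(abs(gamma), cap[seq_len(kx)])
    if (km > 0) delta <- sign(delta) * pmin(abs(delta), cap[kx + seq_len(km)])

    # allele pairs
    pal <- stats::runif(k) < cf$palindrome_fraction
    pick_pal <- sample.int(nrow(.pal_pairs), k, replace = TRUE)
    pick_non <- sample.int(nrow(.nonpal_pairs), k, replace = TRUE)
    ea <- ifelse(pal, .pal_pairs[pick_pal, 1], .nonpal_pairs[pick_non, 1])
    oa <- ifelse(pal, .pal_pairs[pick_pal, 2], .nonpal_pairs[pick_non, 2])

    # pleiotropy: invalid exposure SNPs get direct outcome effects and
    # independent mediator-path effects
    pl <- cf$pleiotropy
    n_invalid <- round(pl$fraction_invalid * kx)
    invalid <- sort(sample.int(kx, n_invalid))
    mu <- if (pl$mode == "directional") pl$mu else 0
    alpha_out <- numeric(kx)
    alpha_med <- numeric(kx)
    if (pl$mode != "none" && n_invalid > 0) {
      # directional pleiotropy acts in a fixed direction relative to the
      # exposure-increasing allele; under an allele-coding-symmetric draw it
      # would cancel on re-orientation and be undetectable by construction
      orient <- sign(gamma[invalid])
      orient[orient == 0] <- 1
      alpha_out[invalid] <- orient * stats::rnorm(n_invalid, mu, pl$sd)
      alpha_med[invalid] <- orient * stats::rnorm(n_invalid, mu, pl$sd)
    }

    # true per-SNP effects
    true_x <- c(gamma, numeric(km))
    true_m <- c(cf$alpha_xm * gamma + alpha_med, delta)
    true_y <- cf$theta_direct * true_x + cf$beta_my * true_m +
      c(alpha_out, numeric(km))

    pq <- maf * (1 - maf)
    se_x <- 1 / sqrt(2 * cf$n_exposure * pq)
    se_m <- 1 / sqrt(2 * cf$n_mediator * pq)
    se_y <- cf$outcome_se_scale / sqrt(2 * cf$n_outcome * pq)

    bx <- stats::rnorm(k, true_x, se_x)
    bm <- stats::rnorm(k, true_m, se_m)
    by <- stats::rnorm(k, true_y, se_y)

    # gross outliers: displace observed outcome betas (exposure panel only)
    outlier_idx <- if (cf$n_outliers > 0)
      sort(sample.int(kx, cf$n_outliers)) else integer(0)
    by[outlier_idx] <- by[outlier_idx] + cf$outlier_shift * se_y[outlier_idx]

    # genomic layout: LD blocks within 100 kb, blocks 30,000 kb apart or on
    # different chromosomes
    block_size <- if (is.null(cf$ld_blocks)) 1L else as.integer(cf$ld_blocks$size)
    block <- (seq_len(k) - 1L) %/% block_size
    n_block <- max(block) + 1L
    chrom <- as.character((block %% 22L) + 1L)
    within <- (seq_len(k) - 1L) %% block_size
    pos <- 1e6 + (block %/% 22L) * 3e7 + within * 1e4

    ld <- diag(1, k)
    if (block_size > 1L) {
      same <- outer(block, block, "==") & !diag(TRUE, k)
      ld[same] <- cf$ld_blocks$r2
    }
    dimnames(ld) <- list(rsid, rsid)

    mk_table <- function(beta, se, n, trait, flip_u) {
      flip <- flip_u < cf$flip_fraction
      sumstats(rsid, chrom, pos,
               effect_allele = ifelse(flip, oa, ea),
               other_allele = ifelse(flip, ea, oa),
               eaf = ifelse(flip, 1 - maf, maf),
               beta = ifelse(flip, -beta, beta), se = se,
               # clamp away from 0 so extreme associations stay valid rows
               pval = pmax(2 * stats::pnorm(-abs(beta / se)),
                           .Machine$double.xmin),
               n = n, trait = trait)
    }
    exposure <- mk_table(bx, se_x, cf$n_exposure, "exposure",
                         rep(1, k))  # exposure frame is the reference
    mediator <- mk_table(bm, se_m, cf$n_mediator, "mediator", stats::runif(k))
    outcome <- mk_table(by, se_y, cf$n_outcome, "outcome", stats::runif(k))

    structure(list(
      exposure = exposure, mediator = mediator, outcome = outcome,
      ld = ld_matrix(ld),
      truth = list(theta_total = cf$theta_direct + cf$alpha_xm * cf$beta_my,
                   theta_direct = cf$theta_direct, alpha_xm = cf$alpha_xm,
                   beta_my = cf$beta_my,
                   invalid_snp_ids = rsid[invalid],
                   outlier_snp_ids = rsid[outlier_idx],
                   exposure_snp_ids = rsid[seq_len(kx)],
                   mediator_snp_ids = if (km > 0) rsid[kx + seq_len(km)]
                                      else character(0),
                   gamma = gamma, delta = delta),
      config = cf), class = "sim_study")
  })
}

#' Named scenario presets
#'
#' Seeded configurations covering the study conditions exercised by the
#' validation suite:
#' \describe{
#'   \item{clean}{No pleiotropy, direct effect 0.3.}
#'   \item{balanced_pleiotropy}{30\% invalid SNPs, zero-mean pleiotropy
#'     (sd 0.05).}
#'   \item{directional_pleiotropy}{50\% invalid SNPs with mean pleiotropic
#'     effect 0.25 (sd 0.05), independent of instrument strength
#'     (InSIDE-satisfying).}
#'   \item{outliers}{21 SNPs, one with its outcome beta displaced by 10
#'     outcome SEs.}
#'   \item{mediation}{alpha_xm = 0.4, beta_my = 0.5, theta_direct = 0.1
#'     (total effect 0.30, indirect 0.20).}
#'   \item{null_mediation}{As mediation but alpha_xm = 0 (no
#'     exposure -> mediator path).}
#' }
#'
#' @param seed Root seed applied to every preset.
#' @return Named list of `sim_config` objects.
#' @export
scenario_presets <- function(seed = 1) {
  list(
    clean = simulation_config(seed = seed),
    balanced_pleiotropy = simulation_config(
      pleiotropy = list(mode = "balanced", sd = 0.05, fraction_invalid = 0.3),
      seed = seed),
    directional_pleiotropy = simulation_config(
      n_snps_mediator = 0, gamma_sd = 0.5,
      pleiotropy = list(mode = "directional", sd = 0.05,
                        fraction_invalid = 0.5, mu = 0.25),
      seed = seed),
    outliers = simulation_config(n_snps = 21, n_snps_mediator = 0,
                                 n_outliers = 1, outlier_shift = 10,
                                 seed = seed),
    mediation = simulation_config(theta_direct = 0.1, alpha_xm = 0.4,
                                  beta_my = 0.5, seed = seed),
    null_mediation = simulation_config(theta_direct = 0.1, alpha_xm = 0,
                                       beta_my = 0.5, seed = seed)
  )
}

#' Write a simulated study to disk
#'
#' Emits `exposure.tsv`, `mediator.tsv`, `outcome.tsv`, `ld.tsv` and
#' `truth.json` under `dir`.
#'
#' @param study A `sim_study`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulated_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_sumstats(study$exposure, file.path(dir, "exposure.tsv"))
  write_sumstats(study$mediator, file.path(dir, "mediator.tsv"))
  write_sumstats(study$outcome, file.path(dir, "outcome.tsv"))
  write_ld_matrix(study$ld, file.path(dir, "ld.tsv"))
  truth <- study$truth
  truth$gamma <- NULL; truth$delta <- NULL
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
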