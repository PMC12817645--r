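# Two-step MR mediation: product-of-coefficients indirect effect with
# first-order delta-method inference.

#' Product-of-coefficients mediation arithmetic
#'
#' For an exposure -> mediator effect `beta1` and a mediator -> outcome
#' effect `beta2`, the indirect (mediated) effect is `beta1 * beta2` with
#' first-order delta-method standard error
#' `sqrt(beta1^2 se2^2 + beta2^2 se1^2)` (the two legs come from
#' non-overlapping two-sample estimations, so their cross-covariance is
#' taken as zero). The direct effect is `beta_all - indirect` and the
#' proportion mediated `indirect / beta_all` is reported signed and
#' unclipped, with a `sign_consistent` flag marking whether the indirect and
#' total effects agree in direction.
#'
#' @param beta1,se1 Exposure -> mediator effect and SE (`se1 > 0`).
#' @param beta2,se2 Mediator -> outcome effect and SE (`se2 > 0`).
#' @param beta_all Total exposure -> outcome effect; when 0 (or `NA`) the
#'   proportion is reported absent.
#' @param exposure,mediator,outcome Optional labels.
#' @return A `mediation_result` list: `beta_all`, `beta1`, `se1`, `beta2`,
#'   `se2`, `indirect`, `indirect_se`, `indirect_pval`, `direct`,
#'   `proportion` (NA with `proportion_reason` when `beta_all` is 0),
#'   `sign_consistent`.
#' @export
mediation_effect <- function(beta1, se1, beta2, se2, beta_all = NA_real_,
                             exposure = NA_character_,
                             mediator = NA_character_,
                             outcome = NA_character_) {
  stopifnot(se1 > 0, se2 > 0)
  indirect <- beta1 * beta2
  indirect_se <- sqrt(beta1^2 * se2^2 + beta2^2 * se1^2)
  indirect_pval <- if (indirect_se > 0)
    two_sided_normal_p(indirect / indirect_se) else NA_real_
  if (!is.na(beta_all) && beta_all != 0) {
    proportion <- indirect / beta_all
    proportion_reason <- NA_character_
  } else {
    proportion <- NA_real_
    proportion_reason <- if (is.na(beta_all)) "total effect unavailable"
      else "total effect is zero"
  }
  structure(list(
    exposure = exposure, mediator = mediator, outcome = outcome,
    beta_all = beta_all, beta1 = beta1, se1 = se1, beta2 = beta2, se2 = se2,
    indirect = indirect, indirect_se = indirect_se,
    indirect_pval = indirect_pval,
    direct = if (is.na(beta_all)) NA_real_ else beta_all - indirect,
    proportion = proportion, proportion_reason = proportion_reason,
    sign_consistent = !is.na(beta_all) &&
      sign(indirect) == sign(beta_all) && indirect != 0),
    class = "mediation_result")
}

#' @export
print.mediation_result <- function(x, ...) {
  cat(sprintf(
    "mediation %s -> %s -> %s\n  total = %.4g, indirect = %.4g (se %.4g, p %.3g), direct = %.4g\n  proportion mediated = %s%s\n",
    x$exposure, x$mediator, x$outcome, x$beta_all, x$indirect, x$indirect_se,
    x$indirect_pval, x$direct,
    if (is.na(x$proportion)) paste0("NA (", x$proportion_reason, ")")
    else sprintf("%.3f", x$proportion),
    if (isTRUE(x$sign_consistent)) "" else " [sign-inconsistent]"))
  invisible(x)
}

#' @export
as.data.frame.mediation_result <- function(x, ...) {
  data.frame(exposure = x$exposure, mediator = x$mediator,
             outcome = x$outcome, beta_all = x$beta_all,
             mediation_effect = x$indirect, beta1 = x$beta1, beta2 = x$beta2,
             indirect_se = x$indirect_se, indirect_pval = x$indirect_pval,
             proportion = x$proportion, sign_consistent = x$sign_consistent,
             stringsAsFactors = FALSE)
}

#' Two-step MR mediation from three summary-statistic tables
#'
#' Runs the full instrument-selection + harmonization + IVW chain on three
#' legs — exposure -> outcome (total effect), exposure -> mediator (`beta1`)
#' and mediator -> outcome (`beta2`) — and combines them with
#' [mediation_effect()]. Each leg's method battery and sensitivity report
#' are attached for auditing.
#'
#' @param exposure,mediator,outcome `sumstats` objects.
#' @param ld An `ld_matrix` covering the candidate instruments of all three
#'   traits.
#' @param config An [mr_config()].
#' @param full_battery Also run the complete MR method battery on each leg
#'   (bootstrap estimators included); the default runs the IVW chain only,
#'   which is what the mediation arithmetic consumes.
#' @param sensitivity Also compute per-leg sensitivity reports (slower).
#' @return A `mediation_result` with attribute `legs`: per-leg list of
#'   `harmonized`, `ivw`, and optional `battery` / `sensitivity`.
#' @export
two_step_mediation <- function(exposure, mediator, outcome, ld,
                               config = mr_config(), full_battery = FALSE,
                               sensitivity = FALSE) {
  if (identical(exposure$rsid, mediator$rsid) &&
      isTRUE(all.equal(exposure$beta, mediator$beta)) &&
      isTRUE(all.equal(exposure$se, mediator$se)))
    stop("exposure and mediator tables are identical (self-mediation)")
  run_leg <- function(from, to, name) {
    iv <- select_instruments(from, ld, config)
    if (nrow(iv) < 2L)
      stop(sprintf("leg '%s': fewer than 2 instruments survive selection",
                   name))
    h <- harmonize(iv, to, config$palindrome_window, config$eaf_tol)
    if (nrow(kept_entries(h)) < 2L)
      stop(sprintf("leg '%s': fewer than 2 SNPs survive harmonization", name))
    battery <- if (full_battery) run_all_methods(h, config)
    ivw <- if (full_battery) battery$results$IVW
           else mr_ivw(h, config$ivw_model)
    if (is.null(ivw)) stop(sprintf("leg '%s': IVW unavailable", name))
    list(harmonized = h, battery = battery, ivw = ivw,
         sensitivity = if (sensitivity) sensitivity_report(h, config))
  }
  leg_total <- run_leg(exposure, outcome, "exposure->outcome")
  leg1 <- run_leg(exposure, mediator, "exposure->mediator")
  leg2 <- run_leg(mediator, outcome, "mediator->outcome")
  res <- mediation_effect(
    beta1 = leg1$ivw$beta, se1 = leg1$ivw$se,
    beta2 = leg2$ivw$beta, se2 = leg2$ivw$se,
    beta_all = leg_total$ivw$beta,
    exposure = attr(exposure, "trait"), mediator = attr(mediator, "trait"),
    outcome = attr(outcome, "trait"))
  attr(res, "legs") <- list(total = leg_total, exposure_mediator = leg1,
                            mediator_outcome = leg2)
  res
}

#' Write mediation results as a Table-1-shaped TSV
#'
#' Columns: Exposure, Mediator, Outcome, beta_all, Mediation_effect, Beta1,
#' Beta2, indirect_se, indirect_pval, proportion, sign_consistent.
#'
#' @param results A `mediation_result` or list of them.
#' @param path Output path.
#' @return The written data.frame, invisibly.
#' @export
write_mediation_table <- function(results, path) {
  if (inherits(results, "mediation_result")) results <- list(results)
  df <- do.call(rbind, c(lapply(results, as.data.frame),
                         make.row.names = FALSE))
  names(df) <- c("Exposure", "Mediator", "Outcome", "beta_all",
                 "Mediation_effect", "Beta1", "Beta2", "indirect_se",
                 "indirect_pval", "proportion", "sign_consistent")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
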