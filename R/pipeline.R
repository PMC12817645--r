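# Workflow orchestration: forward screening of exposure-outcome pairs,
# reverse MR, mediator screening, and the final mediation table.

#' Screen one exposure-outcome pair
#'
#' Runs the full chain — instrument selection, harmonization, the MR method
#' battery, the sensitivity suite and (optionally) reverse MR with the same
#' instrument rules applied to the outcome trait — and applies the screening
#' rule: a pair passes when the IVW p-value is below 0.05, all five core
#' methods agree in direction, the Egger intercept shows no pleiotropy
#' (p > 0.05) and the MR-PRESSO global test shows no outliers (p > 0.05).
#' The reverse-direction IVW p-value is recorded but only gates the
#' "no reverse causality" claim, not `passed`. Cochran's Q is reported, not
#' gated on.
#'
#' @param exposure,outcome `sumstats` objects.
#' @param ld An `ld_matrix`.
#' @param config An [mr_config()].
#' @param reverse Also run the reverse-direction leg. Default `TRUE`.
#' @return A `screening_decision`: list with `exposure`, `outcome`, `n_snp`,
#'   `ivw`, `battery`, `sensitivity`, `harmonized`, `reverse_ivw_pval`,
#'   `passed`, `reasons` (character vector of failed criteria).
#' @export
screen_pair <- function(exposure, outcome, ld, config = mr_config(),
                        reverse = TRUE) {
  iv <- select_instruments(exposure, ld, config)
  if (nrow(iv) < 2L) stop("fewer than 2 instruments survive selection")
  h <- harmonize(iv, outcome, config$palindrome_window, config$eaf_tol)
  if (nrow(kept_entries(h)) < 2L)
    stop("fewer than 2 SNPs survive harmonization")
  battery <- run_all_methods(h, config)
  ivw <- battery$results$IVW
  if (is.null(ivw)) stop("IVW unavailable: ", battery$failures["IVW"])
  sens <- sensitivity_report(h, config)

  reverse_pval <- NA_real_
  if (reverse) {
    reverse_pval <- tryCatch({
      iv_r <- select_instruments(outcome, ld, config)
      if (nrow(iv_r) < 1L) stop("no reverse instruments")
      h_r <- harmonize(iv_r, exposure, config$palindrome_window,
                       config$eaf_tol)
      mr_ivw(h_r, config$ivw_model)$pval
    }, error = function(e) {
      message("reverse MR unavailable: ", conditionMessage(e))
      NA_real_
    })
  }

  egger_p <- sens$egger$intercept_pval %||% NA_real_
  presso_p <- sens$presso$global_pval %||% NA_real_
  reasons <- character(0)
  if (!(ivw$pval < 0.05)) reasons <- c(reasons, "ivw_pval")
  if (!isTRUE(battery$direction_concordant))
    reasons <- c(reasons, "direction")
  if (is.na(egger_p)) reasons <- c(reasons, "egger_unavailable")
  else if (!(egger_p > 0.05)) reasons <- c(reasons, "egger_intercept")
  if (is.na(presso_p)) reasons <- c(reasons, "presso_unavailable")
  else if (!(presso_p > 0.05)) reasons <- c(reasons, "presso_global")

  structure(list(
    exposure = attr(exposure, "trait"), outcome = attr(outcome, "trait"),
    n_snp = ivw$n_snp, ivw = ivw, battery = battery, sensitivity = sens,
    harmonized = h, reverse_ivw_pval = reverse_pval,
    no_reverse_causality = if (is.na(reverse_pval)) NA else reverse_pval > 0.05,
    passed = length(reasons) == 0L, reasons = reasons),
    class = "screening_decision")
}

#' @export
print.screening_decision <- function(x, ...) {
  cat(sprintf("screen %s -> %s: %s (IVW beta %.4g, p %.3g, %d SNPs)\n",
              x$exposure, x$outcome, if (x$passed) "PASS" else "fail",
              x$ivw$beta, x$ivw$pval, x$n_snp))
  if (length(x$reasons)) cat("  failed:", paste(x$reasons, collapse = ", "), "\n")
  invisible(x)
}

decision_row <- function(d) {
  data.frame(exposure = d$exposure, outcome = d$outcome, n_snp = d$n_snp,
             ivw_beta = d$ivw$beta, ivw_se = d$ivw$se, ivw_pval = d$ivw$pval,
             direction_concordant = isTRUE(d$battery$direction_concordant),
             egger_intercept_pval = d$sensitivity$egger$intercept_pval %||% NA_real_,
             presso_global_pval = d$sensitivity$presso$global_pval %||% NA_real_,
             q_pval = d$sensitivity$q$pval %||% NA_real_,
             reverse_ivw_pval = d$reverse_ivw_pval,
             passed = d$passed,
             reasons = paste(d$reasons, collapse = ";"),
             stringsAsFactors = FALSE)
}

screen_many <- function(traits, target, ld, config, reverse, label) {
  decisions <- list()
  for (nm in names(traits)) {
    decisions[[nm]] <- tryCatch(
      screen_pair(traits[[nm]], target, ld, config, reverse = reverse),
      error = function(e) {
        message(sprintf("%s: %s -> %s failed: %s", label, nm,
                        attr(target, "trait"), conditionMessage(e)))
        NULL
      })
  }
  rows <- lapply(Filter(Negate(is.null), decisions), decision_row)
  tab <- NULL
  if (length(rows) > 0) {
    tab <- do.call(rbind, c(rows, make.row.names = FALSE))
    tab$ivw_fdr <- stats::p.adjust(tab$ivw_pval, method = "BH")
  }
  message(sprintf("%s: %d/%d pair(s) screened, %d passed", label,
                  sum(!vapply(decisions, is.null, logical(1))),
                  length(traits),
                  sum(vapply(decisions, function(d) isTRUE(d$passed),
                             logical(1)))))
  list(decisions = decisions, table = tab)
}

#' Run the full two-step mediation workflow
#'
#' (1) screens every exposure against the outcome; (2) screens every
#' mediator against the outcome; (3) for surviving exposures crossed with
#' surviving mediators, screens the exposure -> mediator leg; (4) for
#' triples passing all legs, computes the product-of-coefficients mediation
#' effect with delta-method inference. Per-triple failures are logged and
#' skipped, never fatal. No multiple-testing correction is applied across
#' pairs (nominal p < 0.05 gates, mirroring common screening practice); a
#' Benjamini-Hochberg `ivw_fdr` column is emitted alongside for users who
#' want it.
#'
#' @param exposures,mediators Named lists of `sumstats` objects (a single
#'   `sumstats` is promoted to a one-element list).
#' @param outcome A `sumstats` object.
#' @param ld An `ld_matrix` covering all candidate instruments.
#' @param config An [mr_config()].
#' @param out_dir Optional directory; when given, writes `mediation.tsv`,
#'   the three screening tables, and `manifest.json` (config + seed +
#'   package version). Outputs are byte-identical given identical inputs,
#'   config and seed.
#' @return A `mediation_pipeline` list: `mediation_table` (Table-1-shaped
#'   data.frame, sorted by exposure then mediator), `mediations` (the
#'   `mediation_result` objects), `screens` (the three screening stages,
#'   each with `decisions` and `table`).
#' @export
run_mediation_pipeline <- function(exposures, mediators, outcome, ld,
                                   config = mr_config(), out_dir = NULL) {
  as_named_list <- function(x, prefix) {
    if (inherits(x, "sumstats")) {
      nm <- attr(x, "trait")
      x <- stats::setNames(list(x), if (is.na(nm)) prefix else nm)
    }
    if (length(x) > 0 && (is.null(names(x)) || any(!nzchar(names(x)))))
      names(x) <- paste0(prefix, seq_along(x))
    x
  }
  exposures <- as_named_list(exposures, "exposure")
  mediators <- as_named_list(mediators, "mediator")
  for (nm in names(exposures)) attr(exposures[[nm]], "trait") <- nm
  for (nm in names(mediators)) attr(mediators[[nm]], "trait") <- nm

  s_xy <- screen_many(exposures, outcome, ld, config, reverse = TRUE,
                      label = "exposure->outcome")
  s_my <- screen_many(mediators, outcome, ld, config, reverse = FALSE,
                      label = "mediator->outcome")
  surv_x <- names(Filter(function(d) isTRUE(d$passed), s_xy$decisions))
  surv_m <- names(Filter(function(d) isTRUE(d$passed), s_my$decisions))

  xm_decisions <- list(); xm_rows <- list()
  mediations <- list()
  for (ex in surv_x) {
    for (me in surv_m) {
      key <- paste(ex, me, sep = " | ")
      d_xm <- tryCatch(
        screen_pair(exposures[[ex]], mediators[[me]], ld, config,
                    reverse = FALSE),
        error = function(e) {
          message(sprintf("exposure->mediator: %s failed: %s", key,
                          conditionMessage(e)))
          NULL
        })
      if (is.null(d_xm)) next
      xm_decisions[[key]] <- d_xm
      xm_rows[[key]] <- decision_row(d_xm)
      if (!isTRUE(d_xm$passed)) next
      d_xy <- s_xy$decisions[[ex]]; d_my <- s_my$decisions[[me]]
      mediations[[key]] <- mediation_effect(
        beta1 = d_xm$ivw$beta, se1 = d_xm$ivw$se,
        beta2 = d_my$ivw$beta, se2 = d_my$ivw$se,
        beta_all = d_xy$ivw$beta,
        exposure = ex, mediator = me, outcome = attr(outcome, "trait"))
    }
  }
  xm_table <- NULL
  if (length(xm_rows) > 0) {
    xm_table <- do.call(rbind, c(xm_rows, make.row.names = FALSE))
    xm_table$ivw_fdr <- stats::p.adjust(xm_table$ivw_pval, method = "BH")
  }

  med_table <- if (length(mediations) > 0) {
    tb <- do.call(rbind, c(lapply(mediations, as.data.frame),
                           make.row.names = FALSE))
    tb[order(tb$exposure, tb$mediator), , drop = FALSE]
  } else {
    data.frame(exposure = character(0), mediator = character(0),
               outcome = character(0), beta_all = numeric(0),
               mediation_effect = numeric(0), beta1 = numeric(0),
               beta2 = numeric(0), indirect_se = numeric(0),
               indirect_pval = numeric(0), proportion = numeric(0),
               sign_consistent = logical(0), stringsAsFactors = FALSE)
  }
  rownames(med_table) <- NULL
  message(sprintf("mediation: %d triple(s) in the final table",
                  nrow(med_table)))

  out <- structure(list(
    mediation_table = med_table, mediations = mediations,
    screens = list(exposure_outcome = s_xy, mediator_outcome = s_my,
                   exposure_mediator = list(decisions = xm_decisions,
                                            table = xm_table)),
    config = config), class = "mediation_pipeline")
  if (!is.null(out_dir)) write_pipeline_outputs(out, out_dir)
  out
}

write_pipeline_outputs <- function(pipeline, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, name) {
    if (is.null(df)) df <- data.frame()
    utils::write.table(df, file.path(dir, name), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  wt(pipeline$mediation_table, "mediation.tsv")
  wt(pipeline$screens$exposure_outcome$table,
     "screening_exposure_outcome.tsv")
  wt(pipeline$screens$mediator_outcome$table,
     "screening_mediator_outcome.tsv")
  wt(pipeline$screens$exposure_mediator$table,
     "screening_exposure_mediator.tsv")
  manifest <- list(
    package = "mrmediate",
    version = as.character(utils::packageVersion("mrmediate")),
    config = unclass(pipeline$config))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(dir)
}
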