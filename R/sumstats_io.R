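# GWAS summary-statistic tables: reading, validation, harmonization.
#
# Internal canonical columns: rsid, chrom, pos, effect_allele, other_allele,
# eaf, beta, se, pval, n. File-level canonical headers: SNP, CHR, POS, EA,
# OA, EAF, BETA, SE, P, N (overridable via column_map).

.canonical_cols <- c(rsid = "SNP", chrom = "CHR", pos = "POS",
                     effect_allele = "EA", other_allele = "OA", eaf = "EAF",
                     beta = "BETA", se = "SE", pval = "P", n = "N")

.valid_alleles <- c("A", "C", "G", "T")

new_sumstats <- function(df, trait = NA_character_, n_dropped = 0L,
                         drop_reasons = integer(0)) {
  rownames(df) <- NULL
  structure(df, class = c("sumstats", "data.frame"),
            trait = trait, n_dropped = n_dropped, drop_reasons = drop_reasons)
}

#' Build a summary-statistics object from vectors
#'
#' Constructor used by the simulator and by tests; applies the same row
#' validation as [read_sumstats()].
#'
#' @param rsid,chrom,pos,effect_allele,other_allele,eaf,beta,se,pval,n
#'   Per-SNP fields. `eaf` may contain `NA`.
#' @param trait Trait label carried through downstream reports.
#' @return Object of class `sumstats` (a validated data.frame) with attributes
#'   `trait`, `n_dropped`, `drop_reasons`.
#' @export
sumstats <- function(rsid, chrom, pos, effect_allele, other_allele, eaf,
                     beta, se, pval, n, trait = NA_character_) {
  df <- data.frame(rsid = as.character(rsid), chrom = as.character(chrom),
                   pos = as.integer(pos),
                   effect_allele = toupper(as.character(effect_allele)),
                   other_allele = toupper(as.character(other_allele)),
                   eaf = as.numeric(eaf), beta = as.numeric(beta),
                   se = as.numeric(se), pval = as.numeric(pval),
                   n = as.numeric(n), stringsAsFactors = FALSE)
  validate_sumstats(df, trait = trait)
}

# Drops invalid rows, counting reasons; hard-errors only on structural issues.
validate_sumstats <- function(df, trait = NA_character_) {
  reasons <- c(bad_allele = 0L, same_alleles = 0L, bad_se = 0L, bad_eaf = 0L,
               bad_pos = 0L, bad_pval = 0L, bad_n = 0L, missing_core = 0L,
               duplicate_rsid = 0L)
  ok_core <- !is.na(df$rsid) & !is.na(df$beta) & !is.na(df$se) &
    !is.na(df$pval) & !is.na(df$n) & !is.na(df$pos) &
    !is.na(df$effect_allele) & !is.na(df$other_allele)
  reasons["missing_core"] <- sum(!ok_core)
  df <- df[ok_core, , drop = FALSE]

  keep <- rep(TRUE, nrow(df))
  bad <- !(df$effect_allele %in% .valid_alleles) |
    !(df$other_allele %in% .valid_alleles)
  reasons["bad_allele"] <- sum(bad & keep); keep <- keep & !bad
  bad <- df$effect_allele == df$other_allele
  reasons["same_alleles"] <- sum(bad & keep); keep <- keep & !bad
  bad <- df$se <= 0
  reasons["bad_se"] <- sum(bad & keep); keep <- keep & !bad
  bad <- !is.na(df$eaf) & (df$eaf < 0 | df$eaf > 1)
  reasons["bad_eaf"] <- sum(bad & keep); keep <- keep & !bad
  bad <- df$pos < 1
  reasons["bad_pos"] <- sum(bad & keep); keep <- keep & !bad
  bad <- df$pval <= 0 | df$pval > 1
  reasons["bad_pval"] <- sum(bad & keep); keep <- keep & !bad
  bad <- df$n < 2
  reasons["bad_n"] <- sum(bad & keep); keep <- keep & !bad
  df <- df[keep, , drop = FALSE]

  dup <- duplicated(df$rsid)
  reasons["duplicate_rsid"] <- sum(dup)
  df <- df[!dup, , drop = FALSE]

  n_dropped <- sum(reasons)
  if (n_dropped > 0)
    message(sprintf("sumstats '%s': dropped %d invalid row(s) [%s]",
                    trait, n_dropped,
                    paste(sprintf("%s=%d", names(reasons)[reasons > 0],
                                  reasons[reasons > 0]), collapse = ", ")))
  new_sumstats(df, trait = trait, n_dropped = n_dropped,
               drop_reasons = reasons)
}

#' Read a GWAS summary-statistics table
#'
#' Reads a tab- or comma-delimited text file with header (delimiter sniffed
#' from the header line), maps columns to the canonical schema, validates each
#' row, and drops (with a logged count) rows violating the invariants:
#' alleles in A/C/G/T and distinct, `se > 0`, `eaf` in `[0, 1]` (may be
#' missing), `pos >= 1`, `pval` in `(0, 1]`, `n >= 2`. Duplicate rsids beyond
#' the first and multi-allelic rows (allele strings outside A/C/G/T) are also
#' dropped and counted.
#'
#' @param path Path to the file.
#' @param column_map Named character vector mapping canonical names
#'   (`rsid, chrom, pos, effect_allele, other_allele, eaf, beta, se, pval, n`)
#'   to the file's header names; defaults to
#'   `SNP, CHR, POS, EA, OA, EAF, BETA, SE, P, N`.
#' @param trait Optional trait label; defaults to the file name.
#' @return A `sumstats` object; `attr(, "n_dropped")` holds the drop count and
#'   `attr(, "drop_reasons")` its breakdown.
#' @export
read_sumstats <- function(path, column_map = NULL, trait = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  header <- readLines(path, n = 1L)
  if (length(header) == 0L || !nzchar(header)) stop("empty file: ", path)
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           na.strings = c("NA", ""), comment.char = "")
  cmap <- .canonical_cols
  if (!is.null(column_map)) {
    bad <- setdiff(names(column_map), names(cmap))
    if (length(bad)) stop("unknown column_map keys: ", paste(bad, collapse = ", "))
    cmap[names(column_map)] <- column_map
  }
  missing <- cmap[!(cmap %in% names(raw))]
  if (length(missing))
    stop("missing mandatory column(s): ", paste(missing, collapse = ", "))
  df <- raw[, cmap]
  names(df) <- names(cmap)
  sumstats(df$rsid, df$chrom, df$pos, df$effect_allele, df$other_allele,
           df$eaf, df$beta, df$se, df$pval, df$n,
           trait = trait %||% basename(path))
}

#' Write a summary-statistics table as TSV
#'
#' @param x A `sumstats` object.
#' @param path Output path; canonical headers are used.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(x, path) {
  out <- as.data.frame(x)[, names(.canonical_cols)]
  names(out) <- unname(.canonical_cols)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

is_palindromic <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
    (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

#' Harmonize exposure and outcome summary statistics
#'
#' Aligns two summary-statistic tables onto the exposure's effect-allele
#' frame, SNP by SNP over the rsid intersection:
#' \itemize{
#'   \item identical allele pairs are kept as-is;
#'   \item swapped pairs (outcome effect allele = exposure other allele and
#'     vice versa) have the outcome beta sign flipped and
#'     `eaf <- 1 - eaf` (`action = "flipped"`);
#'   \item palindromic SNPs (A/T or C/G) are kept only when, after any flip,
#'     both effect-allele frequencies lie outside
#'     `[0.5 - w, 0.5 + w]` and fall on the same side of 0.5; otherwise
#'     `excluded_palindromic`. Palindromes with a missing frequency on either
#'     side are excluded. `w >= 0.5` excludes all palindromes outright;
#'   \item irreconcilable allele pairs give `excluded_mismatch`;
#'   \item aligned frequency discrepancies `|eaf_exposure - eaf_outcome| >
#'     eaf_tol` give `excluded_eaf` (skipped when either frequency is
#'     missing).
#' }
#' Only `kept`/`flipped` entries feed the estimators.
#'
#' @param exposure,outcome `sumstats` objects (or data.frames with the
#'   canonical internal columns).
#' @param palindrome_eaf_window Half-width `w` of the palindrome ambiguity
#'   zone around 0.5. Default 0.08 (keep only frequencies outside
#'   `[0.42, 0.58]`).
#' @param eaf_tol Maximum tolerated aligned frequency discrepancy.
#'   Default 0.2.
#' @return A `harmonized_set`: a data.frame with columns `rsid`,
#'   `effect_allele`, `other_allele` (exposure frame), `beta_exposure`,
#'   `se_exposure`, `beta_outcome`, `se_outcome`, `eaf_exposure`,
#'   `eaf_outcome`, `action`; attributes `exposure`/`outcome` carry trait
#'   names. Use [kept_entries()] for the analysis-ready subset.
#' @export
harmonize <- function(exposure, outcome, palindrome_eaf_window = 0.08,
                      eaf_tol = 0.2) {
  shared <- intersect(exposure$rsid, outcome$rsid)
  if (length(shared) == 0L) stop("no overlapping SNPs")
  ex <- as.data.frame(exposure); ou <- as.data.frame(outcome)
  ex <- ex[match(shared, ex$rsid), ]
  ou <- ou[match(shared, ou$rsid), ]
  w <- palindrome_eaf_window

  n <- length(shared)
  action <- character(n)
  beta_out <- ou$beta; eaf_out <- ou$eaf; se_out <- ou$se

  same <- ex$effect_allele == ou$effect_allele &
    ex$other_allele == ou$other_allele
  swapped <- ex$effect_allele == ou$other_allele &
    ex$other_allele == ou$effect_allele
  pal <- is_palindromic(ex$effect_allele, ex$other_allele)
  # palindromes match both ways; "swapped" there means the labels differ
  swapped <- swapped & !same

  action[same] <- "kept"
  action[swapped] <- "flipped"
  beta_out[swapped] <- -beta_out[swapped]
  eaf_out[swapped] <- 1 - eaf_out[swapped]
  action[!same & !swapped] <- "excluded_mismatch"

  aligned <- action %in% c("kept", "flipped")
  if (any(pal & aligned)) {
    idx <- which(pal & aligned)
    fx <- ex$eaf[idx]; fy <- eaf_out[idx]
    informative <- !is.na(fx) & !is.na(fy) &
      abs(fx - 0.5) > w & abs(fy - 0.5) > w &
      sign(fx - 0.5) == sign(fy - 0.5)
    action[idx[!informative]] <- "excluded_palindromic"
  }

  aligned <- action %in% c("kept", "flipped")
  if (any(aligned)) {
    idx <- which(aligned)
    d <- abs(ex$eaf[idx] - eaf_out[idx])
    bad <- !is.na(d) & d > eaf_tol
    action[idx[bad]] <- "excluded_eaf"
  }

  h <- data.frame(rsid = shared,
                  chrom = ex$chrom, pos = ex$pos,
                  effect_allele = ex$effect_allele,
                  other_allele = ex$other_allele,
                  beta_exposure = ex$beta, se_exposure = ex$se,
                  beta_outcome = beta_out, se_outcome = se_out,
                  eaf_exposure = ex$eaf, eaf_outcome = eaf_out,
                  pval_exposure = ex$pval, pval_outcome = ou$pval,
                  n_exposure = ex$n, n_outcome = ou$n,
                  action = action, stringsAsFactors = FALSE)
  rownames(h) <- NULL
  structure(h, class = c("harmonized_set", "data.frame"),
            exposure = attr(exposure, "trait") %||% NA_character_,
            outcome = attr(outcome, "trait") %||% NA_character_,
            palindrome_eaf_window = w, eaf_tol = eaf_tol)
}

#' Analysis-ready subset of a harmonized set
#'
#' @param h A `harmonized_set`.
#' @return The rows with `action` in `kept`/`flipped`, class preserved.
#' @export
kept_entries <- function(h) {
  out <- h[h$action %in% c("kept", "flipped"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a harmonized set as TSV (including the action column)
#'
#' Output is bit-stable given identical input and configuration.
#'
#' @param h A `harmonized_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_harmonized <- function(h, path) {
  utils::write.table(as.data.frame(h), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
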