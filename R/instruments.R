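# Instrument selection: p-value thresholding, greedy LD clumping,
# per-SNP variance explained (R^2) and F-statistic.

#' LD matrix constructor
#'
#' @param mat Square numeric matrix of pairwise r-squared values with rsids as
#'   dimnames; must be symmetric, have unit diagonal, and entries in `[0, 1]`.
#' @return An `ld_matrix` (the validated matrix).
#' @export
ld_matrix <- function(mat) {
  if (!is.matrix(mat) || nrow(mat) != ncol(mat))
    stop("LD matrix must be square")
  if (is.null(rownames(mat)) || is.null(colnames(mat)))
    stop("LD matrix must carry rsids as dimnames")
  if (!identical(rownames(mat), colnames(mat)))
    stop("LD matrix row/column rsids disagree")
  if (any(is.na(mat)) || any(mat < 0) || any(mat > 1))
    stop("LD r-squared entries must lie in [0, 1]")
  if (max(abs(mat - t(mat))) > 1e-8) stop("LD matrix must be symmetric")
  if (max(abs(diag(mat) - 1)) > 1e-8) stop("LD matrix diagonal must be 1")
  structure(mat, class = c("ld_matrix", "matrix", "array"))
}

#' Read an LD matrix from text
#'
#' Accepts either a square TSV whose first row and first column are rsids, or
#' a 3-column long format `rsid_a rsid_b r2` (missing pairs are taken as
#' r-squared 0; the diagonal is filled with 1).
#'
#' @param path Path to the file.
#' @return An `ld_matrix`.
#' @export
read_ld_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(tab) == 3L && is.character(tab[[2]])) {
    # long format: rsid_a, rsid_b, r2
    ids <- sort(unique(c(as.character(tab[[1]]), as.character(tab[[2]]))))
    m <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
    ia <- match(as.character(tab[[1]]), ids)
    ib <- match(as.character(tab[[2]]), ids)
    m[cbind(ia, ib)] <- tab[[3]]
    m[cbind(ib, ia)] <- tab[[3]]
    diag(m) <- 1
    return(ld_matrix(m))
  }
  ids <- as.character(tab[[1]])
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- ids
  storage.mode(m) <- "double"
  ld_matrix(m)
}

#' Write an LD matrix as square TSV
#' @param ld An `ld_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ld_matrix <- function(ld, path) {
  out <- data.frame(rsid = rownames(ld), as.data.frame(unclass(ld)),
                    check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Filter summary statistics by association p-value
#'
#' Retains records with `pval` strictly below the threshold (a SNP at exactly
#' the threshold is excluded), preserving input order.
#'
#' @param records A `sumstats` object.
#' @param p_threshold Significance threshold in `(0, 1]`. Default `1e-5`.
#' @return The retained subset.
#' @export
select_by_pvalue <- function(records, p_threshold = 1e-5) {
  stopifnot(p_threshold > 0, p_threshold <= 1)
  out <- records[records$pval < p_threshold, , drop = FALSE]
  if (nrow(out) == 0L)
    message("select_by_pvalue: no SNPs pass p < ", format(p_threshold))
  rownames(out) <- NULL
  out
}

#' Greedy LD clumping
#'
#' Sorts candidates by ascending p-value (ties broken by rsid), repeatedly
#' takes the most significant unclaimed SNP as an index, and removes every
#' unclaimed SNP on the same chromosome within `window_kb` kilobases
#' (center-to-center) whose r-squared with the index is at or above
#' `r2_threshold`. SNP pairs absent from the LD matrix are treated as
#' r-squared 0; cross-chromosome pairs never clump. The retained indices are
#' returned in their original input order, so the result is invariant to
#' input row order.
#'
#' @param records A `sumstats` object.
#' @param ld An `ld_matrix` (may cover a superset of the records).
#' @param r2_threshold Removal bound on r-squared. Default `0.001`.
#' @param window_kb Window in kilobases. Default `10000`.
#' @return The retained subset of `records`.
#' @export
ld_clump <- function(records, ld, r2_threshold = 0.001, window_kb = 10000) {
  if (nrow(records) == 0L) return(records)
  ld <- ld_matrix(unclass(ld))  # revalidate
  ord <- order(records$pval, records$rsid)
  df <- as.data.frame(records)[ord, ]
  in_ld <- match(df$rsid, rownames(ld))
  claimed <- rep(FALSE, nrow(df))
  index <- logical(nrow(df))
  for (i in seq_len(nrow(df))) {
    if (claimed[i]) next
    index[i] <- TRUE
    claimed[i] <- TRUE
    near <- !claimed & df$chrom == df$chrom[i] &
      abs(df$pos - df$pos[i]) <= window_kb * 1000
    if (!any(near)) next
    j <- which(near)
    r2 <- rep(0, length(j))
    if (!is.na(in_ld[i])) {
      has <- !is.na(in_ld[j])
      r2[has] <- ld[in_ld[i], in_ld[j][has]]
    }
    claimed[j[r2 >= r2_threshold]] <- TRUE
  }
  keep_ids <- df$rsid[index]
  out <- records[records$rsid %in% keep_ids, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-SNP variance explained and F-statistic
#'
#' Variance explained is computed as
#' \deqn{R^2 = \frac{2\beta^2\,EAF(1-EAF)}{2N\,EAF(1-EAF)\,SE^2}}
#' whose frequency terms cancel algebraically to \eqn{\beta^2/(N\,SE^2)}; the
#' frequency form is evaluated when `eaf` is available and the cancellation
#' form is the fallback for missing `eaf` (the two are identical for any
#' frequency strictly inside (0, 1)). The instrument-strength statistic is
#' \eqn{F = R^2 (N - 2) / (1 - R^2)}.
#'
#' @param beta,se,n,eaf Effect size, its standard error (`> 0`), sample size
#'   (`> 2`), and effect-allele frequency (optional, may be `NA`).
#' @return A list with `r2` and `f` (vectorized over the inputs).
#' @export
instrument_strength <- function(beta, se, n, eaf = NA_real_) {
  stopifnot(all(se > 0), all(n > 2))
  k <- max(length(beta), length(se), length(n), length(eaf))
  beta <- rep_len(beta, k); se <- rep_len(se, k)
  n <- rep_len(n, k); eaf <- rep_len(eaf, k)
  usable <- !is.na(eaf) & eaf > 0 & eaf < 1
  r2 <- numeric(k)
  pq <- eaf[usable] * (1 - eaf[usable])
  r2[usable] <- (2 * beta[usable]^2 * pq) / (2 * n[usable] * pq * se[usable]^2)
  r2[!usable] <- beta[!usable]^2 / (n[!usable] * se[!usable]^2)
  if (any(r2 >= 1)) stop("inconsistent summary statistics: R^2 >= 1")
  f <- r2 * (n - 2) / (1 - r2)
  list(r2 = r2, f = f)
}

#' Remove weak instruments
#'
#' @param records A `sumstats` object (or instrument set with `f_stat`).
#' @param f_min Weak-instrument cutoff; SNPs with `f_stat > f_min` are kept.
#'   Default 10.
#' @return The retained subset; removal count is logged.
#' @export
filter_weak <- function(records, f_min = 10) {
  stopifnot(f_min >= 0)
  if (nrow(records) == 0L) return(records)
  f <- records$f_stat
  if (is.null(f))
    f <- instrument_strength(records$beta, records$se, records$n, records$eaf)$f
  keep <- f > f_min
  if (any(!keep))
    message(sprintf("filter_weak: removed %d weak instrument(s) (F <= %g)",
                    sum(!keep), f_min))
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Full instrument-selection chain
#'
#' p-value thresholding, LD clumping, strength computation and
#' weak-instrument filtering, in that order; attaches per-SNP `r2_trait` and
#' `f_stat` columns plus provenance counts.
#'
#' @param records A `sumstats` object for the exposure trait.
#' @param ld An `ld_matrix` covering the candidates (pairs absent are
#'   independent).
#' @param config An [mr_config()]; its `p_threshold`, `clump_r2`, `clump_kb`
#'   and `f_min` fields are used.
#' @return An `instrument_set`: the retained `sumstats` rows with `r2_trait`
#'   and `f_stat`; attribute `selection_counts` traces the chain.
#' @export
select_instruments <- function(records, ld, config = mr_config()) {
  p_pass <- select_by_pvalue(records, config$p_threshold)
  clumped <- ld_clump(p_pass, ld, config$clump_r2, config$clump_kb)
  if (nrow(clumped) > 0L) {
    st <- instrument_strength(clumped$beta, clumped$se, clumped$n, clumped$eaf)
    clumped$r2_trait <- st$r2
    clumped$f_stat <- st$f
  } else {
    clumped$r2_trait <- numeric(0); clumped$f_stat <- numeric(0)
  }
  strong <- filter_weak(clumped, config$f_min)
  structure(strong,
            class = c("instrument_set", class(strong)),
            selection_counts = c(candidates = nrow(records),
                                 passed_p = nrow(p_pass),
                                 passed_clump = nrow(clumped),
                                 passed_f = nrow(strong)))
}
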