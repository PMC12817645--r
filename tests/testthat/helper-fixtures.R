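# Small in-code fixtures shared across test files.

# Harmonized set built directly from effect vectors (all entries kept).
make_h <- function(bx, by, sy, sx = rep(0.01, length(bx))) {
  k <- length(bx)
  sx <- rep_len(sx, k); sy <- rep_len(sy, k)
  h <- data.frame(
    rsid = sprintf("s%03d", seq_len(k)), chrom = "1",
    pos = seq_len(k) * 1000L, effect_allele = "A", other_allele = "G",
    beta_exposure = bx, se_exposure = sx, beta_outcome = by,
    se_outcome = sy, eaf_exposure = 0.3, eaf_outcome = 0.3,
    pval_exposure = 2 * pnorm(-abs(bx / sx)),
    pval_outcome = 2 * pnorm(-abs(by / sy)),
    n_exposure = 10000, n_outcome = 10000,
    action = "kept", stringsAsFactors = FALSE)
  structure(h, class = c("harmonized_set", "data.frame"),
            exposure = "X", outcome = "Y")
}

# Quick sumstats builder with sensible defaults.
make_ss <- function(rsid, beta, se, pval = 2 * pnorm(-abs(beta / se)),
                    ea = "A", oa = "G", eaf = 0.3, chrom = "1",
                    pos = seq_along(rsid) * 1000L, n = 10000,
                    trait = "trait") {
  sumstats(rsid, chrom, pos, rep_len(ea, length(rsid)),
           rep_len(oa, length(rsid)), rep_len(eaf, length(rsid)),
           beta, se, pval, n, trait = trait)
}

# Selection + harmonization chain on a simulated study (exposure -> outcome).
sim_xy_harmonized <- function(config) {
  st <- simulate_study(config)
  iv <- suppressMessages(select_instruments(st$exposure, st$ld))
  harmonize(iv, st$outcome)
}

write_tsv_fixture <- function(df, path = tempfile(fileext = ".tsv"),
                              sep = "\t") {
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  path
}

# Canonical 3-row well-formed summary-stat table (file-level schema).
canonical_table <- function() {
  data.frame(SNP = c("rs1", "rs2", "rs3"), CHR = c("1", "1", "2"),
             POS = c(1000L, 2000L, 3000L), EA = c("A", "C", "G"),
             OA = c("G", "T", "A"), EAF = c(0.2, 0.3, 0.4),
             BETA = c(0.10, -0.05, 0.02), SE = c(0.01, 0.02, 0.015),
             P = c(1e-8, 0.01, 0.2), N = c(5000, 5000, 5000),
             stringsAsFactors = FALSE)
}
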