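---
title: "Two-step MR mediation: models, design choices and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-step MR mediation: models, design choices and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrmediate)
```

`mrmediate` estimates causal effects of an exposure on an outcome from GWAS
summary statistics, and decomposes that effect into a direct path and a
path transmitted through a mediator. This vignette documents the models the
package fits, the assumptions behind them, every tunable that matters, what
the built-in simulator does and does not emulate, and the design decisions
that were genuinely open.

## 1. The estimation framework

### Instrumental-variable assumptions

A SNP serves as an instrument for exposure X when it is (1) robustly
associated with X, (2) independent of X–Y confounders, and (3) associated
with the outcome Y only through X. Assumption (1) is enforced empirically
(p-value threshold, LD clumping, F-statistic filter); (2) is supplied by
Mendelian inheritance; (3) — no horizontal pleiotropy — is untestable per
SNP and is instead probed by the sensitivity suite.

### Harmonization

Exposure and outcome tables are aligned on the exposure's effect allele.
Swapped allele labels flip the sign of the outcome beta and complement its
frequency. Palindromic SNPs (A/T, C/G) cannot be strand-resolved from
alleles alone; they are kept only when both effect-allele frequencies fall
outside `0.5 ± w` *and* on the same side of 0.5, with `w = 0.08` by default
(`w ≥ 0.5` excludes every palindrome, for analysts who prefer the blunt
rule — both behaviors are in circulation and the choice is exposed rather
than hidden). Aligned frequency discrepancies above 0.2 are excluded; the
threshold quantifies "significant allele frequency discrepancy", for which
no standard number exists. Palindromes with a missing frequency are
excluded; non-palindromic SNPs tolerate missing frequencies (frequency is
only needed for palindrome resolution, the discrepancy check, and the
frequency form of R²).

### Instrument selection

* `p_threshold = 1e-5` — the relaxed threshold used when genome-wide
  significant instruments are too few; strict `<` at the boundary.
* LD clumping: greedy, ascending p (ties broken by rsid so the result is
  independent of row order); an index SNP claims every SNP on the same
  chromosome within `clump_kb = 10000` kilobases with r² ≥
  `clump_r2 = 0.001`. LD comes from an explicit matrix file (square or
  long format); pairs absent from it are treated as independent. The
  package does not estimate LD from genotypes.
* Per-SNP variance explained uses the frequency form
  R² = 2β²·EAF(1−EAF) / (2N·EAF(1−EAF)·SE²), whose frequency terms cancel
  algebraically to β²/(N·SE²). The cancellation is deliberate and
  documented rather than "fixed": the frequency form is evaluated when EAF
  is present, the reduced form when it is missing, and the two agree
  identically. R² ≥ 1 is a hard error (impossible summary statistics).
  F = R²(N−2)/(1−R²), with `f_min = 10` as the conventional
  weak-instrument cutoff (strict `>`).

### Estimators

All estimators consume the kept rows of a harmonized set. Per-SNP Wald
ratios use the first-order standard error `se_Y/|β_X|` by default; the
second-order form (adding the exposure-noise term) is a config switch —
published analyses rarely state which they used, so both are available.

* **IVW** — weighted regression of outcome betas on exposure betas through
  the origin, weights 1/se²_Y; identical to the inverse-variance-weighted
  mean of Wald ratios. Default is multiplicative random effects (SE scaled
  by max(1, √(Q/(k−1)))), which penalizes heterogeneity but never rewards
  under-dispersion; fixed effects is a switch. Normal reference for p.
  Below two SNPs the estimate downgrades to the single Wald ratio, logged.
* **MR-Egger** — the same regression with an intercept, after re-orienting
  every SNP so its exposure beta is non-negative (the intercept — average
  directional pleiotropy — is only interpretable in that frame). Slope and
  intercept SEs use the residual scale floored at 1; p-values use
  t with k−2 df. A design with all exposure betas equal is rank-deficient
  and errors.
* **Weighted median** — inverse-variance-weighted median of the ratios
  (cumulative-weight crossing of 0.5 with linear interpolation); consistent
  while valid instruments carry over half the weight. SE by parametric
  bootstrap (1000 reps by default, seeded).
* **Simple/weighted mode** — argmax of a normal-kernel density of the
  ratios with the modified Silverman bandwidth 0.9·min(sd, mad)·k^(−1/5)
  scaled by a bandwidth factor (default 1); consistent when the largest
  group of SNPs sharing an estimate is valid. Bootstrap SE.
* **BWMR** — a hierarchical Bayesian model: observed exposure betas are
  noisy measurements of latent effects γ_j; outcome betas are
  θγ_j + α_j with pleiotropy α_j ~ N(0, τ²); priors θ ~ N(0, 10²),
  γ_j ~ N(0, 1), τ half-normal(0, 1). Per-sweep robustness weights
  `min(1, (3/|e_j|)²)` on standardized marginal residuals down-weight
  grossly discrepant SNPs. Inference is Metropolis-within-Gibbs (normal
  conditionals for γ, α, θ; random-walk step on log τ), 6000 iterations
  with the first third discarded, split-chain R̂ > 1.1 flagged but never
  suppressed. This is the package's own concrete formulation of the
  Bayesian-weighted-MR idea; published uses of the name typically rely on a
  variational fit, so posterior summaries are approximations to that
  method, not reproductions of it.

The battery reports a direction-concordance flag: `TRUE` only when all five
core estimators (IVW, Egger, weighted median, weighted mode, simple mode)
agree in sign. If any method is unavailable the flag is `FALSE` with reason
"incomplete battery" — a two-SNP dataset cannot claim five-method
concordance. Near a true null the flag carries no validity claim: signs of
unbiased estimators of zero are coin flips.

### Sensitivity suite

* **Cochran's Q** at the fixed-effects IVW estimate (its minimizer), χ²
  with k−1 df. Reported, not gated on.
* **MR-PRESSO-style tests** — observed RSS with leave-one-out IVW fitted
  values; the null distribution is rebuilt by simulating datasets from the
  leave-one-out fits with the observed SEs (1000 draws by default).
  Per-SNP residual contributions against their simulated distributions
  give the outlier test (Bonferroni); when outliers are flagged, the
  outlier-free IVW is compared against estimates from dropping equally
  many random SNPs (distortion test, two-sided empirical p). Empirical
  p-values use the add-one rule (1 + #exceed)/(n + 1), so none is exactly
  zero.
* **Leave-one-out** — k random-effects IVW refits.
* **Plot data** — scatter (with per-method lines), funnel (ratio vs
  precision), forest (per-SNP + combined rows), and leave-one-out tables
  are deterministic data frames; ggplot2 rendering is a thin optional
  layer.

### Two-step mediation

The total effect is the exposure→outcome IVW estimate; β₁ and β₂ come from
the exposure→mediator and mediator→outcome legs, each with its own
instruments. The indirect effect β₁β₂ takes the first-order delta-method SE
√(β₁²se₂² + β₂²se₁²): the legs come from non-overlapping two-sample
estimations, so the cross-covariance is taken as zero, and the second-order
term is omitted (it matters only when both legs are weak, where the product
test is unreliable anyway — the validation checks 5% agreement with Monte
Carlo when both |β|/se > 2). The proportion mediated is reported signed and
unclipped with a `sign_consistent` flag, because real screening tables
contain sign-inconsistent rows and silently clipping them to [0, 1] would
hide a qualitative disagreement. `direct + indirect = total` holds exactly
by construction.

### The screening pipeline

A pair passes when IVW p < 0.05, all five methods agree in direction, the
Egger intercept shows no pleiotropy (p > 0.05) and the PRESSO global test
is clean (p > 0.05). Reverse-direction MR (same instrument rules applied to
the outcome trait) is recorded and gates only the "no reverse causality"
claim. Q is reported without gating. No multiple-testing correction is
applied across exposures or mediators — the screening tradition this
mirrors uses nominal thresholds — but a Benjamini–Hochberg column is
emitted alongside for users who want it. Note a structural property worth
stating plainly: the rule demands several simultaneous 5%-level tests all
be non-significant, so even a perfectly clean true pathway clears every
gate in only ~75% of replicates; the package's tests assert exactly that
operating characteristic rather than pretending the gates are free.

## 2. The simulator: what it emulates, and what it does not

`simulate_study()` generates summary statistics directly — no
individual-level genotypes — under the standard sampling model for
standardized traits: observed betas are normal around the true effects with
se = 1/√(2N·maf(1−maf)), p-values two-sided normal. That is exactly the
regime the estimators consume, which is the point: every pipeline stage is
testable offline against known truth.

Two SNP panels are generated. Exposure instruments carry effects
γ_j ~ N(0, gamma_sd²) that propagate to the mediator (α·γ_j) and outcome
(θ_direct·γ_j + b·mediator effect). Mediator-specific instruments carry
their own effects δ_j on the mediator only. The second panel is not
optional decoration: if every variant affected the mediator solely through
the exposure, the mediator→outcome leg would identify b + θ_direct/α
rather than b, and two-step mediation would be impossible by construction —
the mediator must have instruments of its own, as real mediator traits do.

Default study conditions and the reasoning behind them:

* `n_exposure = 7174`, `n_outcome = 254618` with outcome SEs inflated by
  2.8 — a lipidomics-scale exposure cohort and a biobank case/control
  outcome (the inflation approximates the log-odds scale at a case
  fraction near 0.15). The binary outcome is otherwise modeled by the same
  Gaussian machinery; case/control finite-sample effects (rare-variant
  separation, non-collapsibility) are *not* emulated.
* `n_mediator = 400`, `n_snps_mediator = 30`, `delta_sd = 0.6` — a small
  specialized cohort (flow-cytometry immunophenotypes are measured in
  hundreds, not hundreds of thousands of people) whose traits carry large
  cell-intrinsic per-variant effects. This corner is load-bearing: with a
  large mediator GWAS, exposure-transmitted signals (αγ_j) would cross the
  instrument threshold and enter the mediator→outcome leg as genuine
  pleiotropy that Egger and PRESSO rightly reject; with a small cohort and
  large mediator effects, the mediator's instruments are its own, which is
  precisely the two-step assumption. The small panel (~15 selected
  instruments) also matches what such GWAS actually yield, and keeps the
  regression-dilution signature of small-N instrument noise below the
  Egger intercept test's detection limit — at a 150-SNP panel the same
  dilution produces 20%+ intercept false positives.
* `gamma_sd = 0.3` — sizeable standardized per-allele effects, as lipid
  species loci show; per-SNP true effects are winsorized so no variant
  explains more than 30% of a trait's variance (2·maf(1−maf)·β² ≤ 0.3),
  the physical bound that keeps simulated rows consistent
  (R² < 1 always).
* `maf_range = (0.05, 0.45)`, `palindrome_fraction = 0.2`,
  `flip_fraction = 0.3` — common variants, a realistic share of
  palindromes, and a third of mediator/outcome rows emitted on the
  opposite allele frame so harmonization is always exercised.
* Pleiotropy: invalid exposure SNPs receive outcome effects
  N(µ, sd²) — and independent mediator-path effects of the same law —
  with µ = 0 for balanced and µ > 0 for directional pleiotropy.
  Directional effects are assigned relative to the exposure-increasing
  allele: under an allele-coding-symmetric draw, Egger's standard
  re-orientation would cancel the mean exactly and "directional"
  pleiotropy would be undetectable by any method, which is a statement
  about allele bookkeeping, not biology. Pleiotropy is drawn independently
  of instrument strength (InSIDE holds); InSIDE-violating correlated
  pleiotropy is *not* simulated.
* LD: block-diagonal by configuration (members within 100 kb, blocks
  30,000 kb apart or on different chromosomes); the matrix feeds clumping
  only. Observed betas are drawn independently even within a block — the
  simulator does not propagate LD into the sampling correlation of
  betas — and no reference-panel noise, winner's-curse correction, or
  sample-overlap bias is emulated. Tests passing on these data therefore
  certify the estimators and the pipeline logic, not robustness to
  correlated instruments or overlapping cohorts.

The named presets freeze the study conditions used throughout validation:
`clean` (θ = 0.3, nothing else), `balanced_pleiotropy` (30% invalid,
sd 0.05), `directional_pleiotropy` (50% invalid, sd 0.05, µ = 0.25,
`gamma_sd = 0.5`, no mediator panel), `outliers` (21 SNPs, one displaced
10 outcome-SEs), `mediation` (α = 0.4, b = 0.5, θ_direct = 0.1; total
0.30, indirect 0.20) and `null_mediation` (α = 0). The
directional-pleiotropy preset deserves a note: with 50% invalid
instruments and a 50-SNP panel, the Egger intercept test's power has a
structural ceiling near 85% regardless of the pleiotropy mean (the
non-centrality saturates at √(k_selected/c) for the design factor c), so
the preset is calibrated — larger instrument spread, µ at five times the
pleiotropy sd — to sit at that ceiling, and validation measures power
against an 80% floor with 400 replicates to keep Monte Carlo noise small.

## 3. Numerical choices and degenerate inputs

* Empirical p-values are never zero (add-one rule); simulated GWAS
  p-values are clamped at the smallest positive double rather than
  underflowing to an invalid 0.
* Weighted-median interpolation uses the (cum − w/2) convention, which
  reduces to the ordinary median under equal weights.
* Mode bandwidth falls back from mad to sd when the mad is 0, and returns
  the common ratio outright when all ratios coincide.
* Tie-breaks: clumping sorts by (p, rsid); all estimators are invariant to
  row order, and MR-PRESSO's global p is order-invariant at a fixed seed.
* Seeds: every stochastic routine takes an explicit seed and restores the
  caller's RNG state; the pipeline derives per-stage streams from one root
  seed, and identical (input, config, seed) triples give byte-identical
  output files.
* Degenerate designs error loudly: Wald ratio at β_X = 0, Egger with all
  exposure betas equal, mediation of a table against itself
  (self-mediation guard), empty rsid intersections, asymmetric or
  out-of-range LD matrices, R² ≥ 1.

## 4. Validation problem sizes

The test suite and `scripts/acceptance.R` run, per invocation: 200
replicates each for the IVW and mediation null calibrations, 100 for
mediation recovery, 400 for Egger power, 60 for weighted-median
robustness, 300 for the Egger null size, 20 full MR-PRESSO outlier fixtures
(1000 simulated nulls each), and 10⁵ Monte-Carlo draws for the delta-method
check — sizes chosen so each estimate's Monte Carlo error is small against
the band it is compared to, while a full run stays in the tens of seconds
on a single core.

## 5. Known limitations

* Two-sample, single-mediator, univariable MR only: no multivariable MR,
  no joint multiple-mediator decomposition, no MR-RAPS/contamination
  mixture/debiased IVW, no Steiger direction filtering.
* The weighted median's robustness claim concerns the *weight* of valid
  instruments, not immunity to one-directional contamination: at 40%
  invalid instruments with same-signed pleiotropy the estimator acquires a
  finite-sample bias of roughly one ratio-SD (the 50%-weight point slides
  up the valid cluster), and validation exercises the balanced
  (zero-mean) contamination where the breakdown property is actually
  informative.
* The Egger intercept inherits regression dilution from exposure-side
  noise; with many instruments and a small-N leg this produces genuine
  (correct, but easily misread) intercept signals. The simulator's default
  mediator design keeps this below the detection limit deliberately.
* BWMR is a concrete MCMC formulation of a method whose published form is
  variational; agreement is approximate by design.
* Harmonization resolves allele frames, not strands: complementary-strand
  records (A/G vs T/C) are treated as mismatches and excluded, and no
  multi-allelic handling, liftover, or rsid resolution is attempted.
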