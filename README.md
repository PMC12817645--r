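# mrmediate

Two-step Mendelian randomization (MR) mediation analysis from GWAS summary
statistics.

## The problem

Observational associations between molecular traits (say, a plasma lipid
species) and a disease (say, polycystic ovary syndrome) are confounded and
reverse-causation-prone. Two-sample MR sidesteps both by using genetic
variants as instrumental variables: per SNP *j*, the Wald ratio
β̂<sub>Yj</sub>/β̂<sub>Xj</sub> estimates the causal effect of exposure X on
outcome Y, and the inverse-variance-weighted (IVW) estimator pools them,

&nbsp;&nbsp;&nbsp;&nbsp;θ̂ = Σ w<sub>j</sub> β̂<sub>Xj</sub> β̂<sub>Yj</sub> / Σ w<sub>j</sub> β̂²<sub>Xj</sub>,&nbsp;&nbsp;w<sub>j</sub> = 1/se²<sub>Yj</sub>,

with MR-Egger, weighted median, and mode-based estimators (plus a Bayesian
weighted MR) as pleiotropy-robust companions. When a third trait M
(e.g. an immune-cell phenotype) may transmit part of the effect, two-step MR
estimates β₁ (X→M) and β₂ (M→Y) from separate instrument sets and reports
the indirect (mediated) effect as the product of coefficients,

&nbsp;&nbsp;&nbsp;&nbsp;indirect = β₁β₂,&nbsp;&nbsp;se = √(β₁²se₂² + β₂²se₁²)&nbsp;(delta method),&nbsp;&nbsp;proportion mediated = β₁β₂/θ̂<sub>total</sub>.

`mrmediate` implements the whole workflow for analysts working from
summary-statistic files: reading and harmonizing summary tables onto a
shared effect-allele frame (allele flips, palindromic-SNP resolution by
frequency, frequency-discrepancy exclusion), instrument selection
(p-value threshold, greedy LD clumping, per-SNP R²/F), the five-estimator
battery plus BWMR, the sensitivity suite (Cochran's Q, Egger intercept,
MR-PRESSO-style global/outlier/distortion tests, leave-one-out,
scatter/funnel/forest plot data), the product-of-coefficients mediation
arithmetic, and a config-driven screening pipeline. A summary-statistic
simulator with known causal and mediation structure makes every stage
testable offline.

## Worked example

Simulate a study in which the exposure raises the outcome directly
(θ<sub>direct</sub> = 0.1) and through a mediator (α = 0.4, b = 0.5, so the
total effect is 0.30 and the indirect effect 0.20), then run the forward MR
battery and the two-step mediation:

```r
library(mrmediate)

cfg   <- simulation_config(theta_direct = 0.1, alpha_xm = 0.4,
                           beta_my = 0.5, seed = 42)
study <- simulate_study(cfg)

iv      <- select_instruments(study$exposure, study$ld, mr_config())
h       <- harmonize(iv, study$outcome)
battery <- run_all_methods(h, mr_config(seed = 42))
battery
#>           method nsnp      beta          se          pval       or  ...
#> 1            IVW   35 0.2993338 0.005393817  0.000000e+00 1.348960
#> 2          Egger   35 0.3011322 0.011283049  6.466837e-24 1.351388
#> 3 WeightedMedian   35 0.2990531 0.008999510 3.979674e-242 1.348581
#> 4   WeightedMode   35 0.2991318 0.008584736 5.136705e-266 1.348687
#> 5     SimpleMode   35 0.2945001 0.014083939  4.310233e-97 1.342455
#> direction_concordant: TRUE

med <- two_step_mediation(study$exposure, study$mediator, study$outcome,
                          study$ld, mr_config(seed = 42))
med
#> mediation exposure -> mediator -> outcome
#>   total = 0.2993, indirect = 0.1812 (se 0.0218, p 9.39e-17), direct = 0.1181
#>   proportion mediated = 0.605
```

All five estimators agree on a positive effect near the true total of 0.30
(IVW 0.2993, OR 1.349 per SD of exposure), the Egger intercept shows no
directional pleiotropy (intercept −0.0006, p = 0.86), and the two-step
decomposition recovers an indirect effect of 0.181 ± 0.022 against a true
value of 0.20, with 60% of the total effect mediated (true 67%).

The full screening workflow — forward MR with the five-method direction
concordance check, Egger-intercept and MR-PRESSO gates, reverse-direction
MR, then mediation for the surviving triples — runs as

```r
pip <- run_mediation_pipeline(exposures = study$exposure,
                              mediators = study$mediator,
                              outcome   = study$outcome,
                              ld        = study$ld,
                              config    = mr_config(seed = 42),
                              out_dir   = "results/run1")
pip$mediation_table
```

writing the mediation table, per-stage screening tables and a run manifest;
identical inputs, config and seed give byte-identical outputs.

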