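---
title: "Methods: summary-data MR for lipoprotein risk-factor prioritization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: summary-data MR for lipoprotein risk-factor prioritization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the statistical models behind `lipidmr`, the
assumptions they make, the design decisions that were genuinely open, the
numerical choices, and what the synthetic-data generator does and does not
emulate. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## The setting

All methods operate on GWAS summary statistics: per-variant association
estimates `beta` with standard errors, for K exposures (lipoprotein-related
traits, in SD units) and one or more binary disease outcomes (log-odds).
Instrumental-variable logic applies throughout: a variant is a valid
instrument for an exposure if it is robustly associated with it, independent
of confounders, and affects the outcome only through the exposure. Direct
variant-to-outcome effects (pleiotropy) violate the last assumption; the
package addresses them through MR-Egger's intercept, multivariable
adjustment, model averaging over exposure subsets, and influence
diagnostics — not by assuming them away.

## Harmonization

Every trait's effect is re-expressed on the effect allele of the first
exposure. Swapped alleles flip the beta sign and replace eaf by 1 − eaf;
irreconcilable allele pairs are dropped. Strand-ambiguous (A/T, C/G)
variants are dropped by default: allele labels cannot distinguish strand
flips for them. The fallback mode (`drop_palindromic = FALSE`) keeps a
palindromic variant only when every dataset's eaf lies on the same side of
0.5 and all are farther than `eaf_threshold` (default 0.08) from 0.5; the
0.08 default is the conventional conservative band below which allele
frequencies no longer identify strand reliably. Indels and multi-allelic
records are rejected at load so allele logic stays exact. Every flip and
drop is written to an alignment log, and stage input/output counts
reconcile in the pipeline's run log.

Coordinates are 1-based inclusive everywhere; gene windows are closed
intervals `[max(1, start − flank), end + flank]` with a 200 kb default
flank, the conventional cis-window for drug-target proxies. Window
closure is tested at exact boundary positions.

## MR estimators

All estimators are generalized least squares of `bY` on `bX` through the
origin with weight matrix Ω⁻¹, Ω = diag(seY) · R · diag(seY), where R is
the LD correlation between instruments (identity when instruments were
pruned to independence). Solving by Cholesky whitening, the GLS with
identity R reproduces the classical closed-form IVW exactly; this is
enforced to 1e-10 in the tests against an independently coded oracle.

Choices a user can change, with defaults and reasoning:

* `effects = "random"` (default): the SE is inflated by
  max(1, sqrt(Q/df)), Q the GLS residual chi-square, df = J−1 for IVW,
  J−2 for Egger, J−K for MVMR. The inflation is bounded below at 1 so the
  random-effects SE can never undercut the fixed-effects SE — an ordering
  the tests assert. Q and J are always reported so heterogeneity is
  auditable.
* p-values use the normal distribution, not t: the summary-data MR
  convention at moderate instrument counts.
* MR-Egger first orients every variant so its exposure association is
  non-negative (flipping bX, bY and the corresponding LD rows jointly).
  The intercept — average directional pleiotropy — is only interpretable
  under this convention. A constant exposure column is a degenerate design
  (collinear with the intercept) and errors out rather than returning an
  arbitrary fit.
* MVMR treats an all-zero exposure column as estimable-but-empty: effect
  0 with infinite SE and a `zero_column` flag. Any other rank deficiency
  errors and names the collinear pairs (|r| > 0.999).

Drug-target results are reported per 1 SD *decrease* of the exposure
(protective targets give OR < 1), matching how lipid-lowering proxies are
conventionally presented; the sign convention is recorded in the estimate's
flags.

## MR-BMA

The outcome vector is inverse-variance standardized, ỹ = bY/seY (a z-score
scale on which the error covariance is the identity for independent
instruments), the exposure matrix likewise column-weighted,
X̃ = bX/seY, and each column scaled to unit Euclidean norm (scales retained
for back-transformation). Every non-empty exposure subset S up to
`max_model_size` is scored by the closed-form Gaussian marginal likelihood
of ỹ = X̃_S θ_S + ε, ε ~ N(0, I), θ_S ~ N(0, σ²I), computed stably via the
Woodbury and determinant identities on the K×K Gram matrix (so the
permutation loop costs O(2^K K³) per replicate, not O(J³)). Model priors
are independent-inclusion with `prior_inclusion = 0.1` (prior mean model
size K/10, mirroring the expectation that few of the correlated traits are
causal); the null model is excluded from enumeration since the method ranks
causal candidates — exclusion rescales all posteriors equally and cannot
change MIP ordering. Enumeration is exhaustive for K ≤ 20; larger K errors
(stochastic search is out of scope).

**Prior scale.** The one place this implementation deviates from a naive
fixed prior: `sigma_prior` (default 0.5) is interpreted *relative to the
norm of ỹ*, i.e. the effective prior SD is 0.5·‖ỹ‖. On the z-score scale a
single fully explanatory exposure has a standardized coefficient of about
‖ỹ‖ — at biobank-scale sample sizes, two orders of magnitude above 0.5. A
fixed absolute prior of 0.5 therefore shrinks the causal model so hard that
its residual carries most of the signal, and every correlated proxy
exposure is recruited to absorb it: in development runs all MIPs saturated
at 1 regardless of causality. The relative prior is scale-equivariant
(invariant to rescaling sample sizes), keeps shrinkage negligible for real
signals, and yields a BIC-like complexity penalty of about log(0.5·‖ỹ‖)
per added exposure. `model_log_evidence()` itself takes an absolute σ, so
its closed form can be (and is) verified against 1-D numerical quadrature
of the defining integral to 1e-6.

**Permutation p-values.** For each replicate the (bY, seY) *pairs* are
permuted jointly across variants: this breaks the exposure–outcome linkage
while preserving both the outcome SE structure and the exposure correlation
that the MIPs condition on (permuting exposure rows instead would destroy
the latter). p = (1 + #{perm MIP ≥ observed})/(n_perm + 1), guaranteeing
p ≥ 1/(n_perm+1); ties are counted as exceedances (an identity permutation
yields p = 1 by itself). Validity rests on exchangeability of the
(variant, outcome) pairs under the null, which holds for independent
variants with i.i.d.-drawn frequencies. The type-I test at the global null
(200 panels, 199 permutations) checks the rejection rate at 0.05 against
the exact binomial 95% interval. Note that under very strong signal the
observed MIP saturates at 1 and permuted MIPs occasionally saturate too, so
the permutation p is conservative there — a property of the statistic, not
a bug; the tests construct the saturation case explicitly.

**Multiplicity.** Two corrections are implemented and the report records
which was applied: Benjamini–Hochberg FDR over the K permutation p-values
(used for the major-trait analysis), and the Nyholt effective-tests
procedure (used for the strongly correlated subfraction set):
Meff = 1 + (K−1)(1 − Var(λ)/K) with λ the eigenvalues of the trait
correlation matrix and Var the *sample* variance. The sample-variance form
is the canonical one: it gives Meff = K for independent traits and Meff = 1
when all traits are perfectly correlated (rank-1), the procedure's defining
boundary properties (population variance would give 2 − 1/K in the rank-1
case). For K = 3 with constant off-diagonal 0.5 the eigenvalues are
{2, 0.5, 0.5} and Meff = 2.5. The corrected p is min(1, p·Meff) and is
floored at the uncorrected p in pipeline reports (a correction can never
make a p-value smaller).

**Diagnostics.** For the top model, per-variant Cook's distances from the
weighted least-squares fit and squared standardized residuals
(Q contributions) are reported; flags default to the conventional 4/J and
the chi-square(1) 95% point. The documented sensitivity mode is a refit
without flagged variants via `panel_subset()`.

## Bootstrap ratio of effects

The ratio of log-odds effects between two outcomes (e.g. CAD vs PAD per SD
of exposure decrease) is a ratio of two estimated quantities, so its CI is
obtained by a variant bootstrap: resample variant indices with replacement,
refit both IVW estimates, recompute the ratio; percentile 2.5/97.5 order
statistics (quantile type 1) give the CI and
p = 2·min(Pr*(r ≤ 1), Pr*(r ≥ 1)) with the +1 finite-sample correction.
Two open choices and how they were resolved:

* When both outcomes share the instrument set, *one* index vector per
  replicate is applied to both fits. Joint resampling preserves the
  cross-outcome dependence induced by shared instruments and is the
  conservative choice for the ratio's CI. (Parametric resampling of the
  effect estimates would be the alternative; variant resampling was chosen
  as the more assumption-light option.)
* Replicates with |denominator| < 1e-4 log-odds are excluded and counted
  rather than producing unbounded ratios; above 5% exclusions a warning is
  raised. The tolerance is configurable.

A single-variant panel has exactly one bootstrap resample, so the CI
degenerates to zero width — documented, tested behaviour rather than an
error. With LD-aware fits inside the bootstrap, duplicated indices make Ω
exactly singular; a 1e-6 ridge on the correlation keeps the per-replicate
GLS defined without measurably moving the point estimates.

## TWAS

The gene-level statistic imputes expression association from eQTL weights:
Z_g = Σ_l w_l σ_l Z_l / σ_g, σ_l = sqrt(2·eaf(1−eaf)) the Hardy–Weinberg
genotype SD (the standard summary-level substitute when reference genotypes
are unavailable), σ_g² = wᵀ S R S w with the LD reference R. Weighted
variants missing from the GWAS are dropped with a coverage report; below
50% coverage the result is flagged rather than suppressed. Z_g is invariant
to rescaling all weights by a positive constant and antisymmetric in their
sign; a single-variant gene reduces to Z_g = ±Z_l exactly.

The between-trait statistic Zdiff = (effect₁ − effect₂)/√(se₁²+se₂²) is
exposed in two modes — signed and magnitude (|effect₁| − |effect₂|) —
because both definitions are in circulation for comparing a gene's effects
on two traits; every report names the mode used, and no attempt is made to
privilege one. FDR is computed per trait *before* classification (a gene
is "shared" if it passes its own trait's FDR in both), not pooled across
traits.

## The synthetic-data generator

`simulate_panel()` draws minor-allele frequencies uniformly (default
0.05–0.5), gives each variant a loading on one of F latent genetic factors,
and builds true exposure effects B = ΛΓᵀ + E. The factor composition matrix
Γ induces the genetic correlation between exposures (e.g. an ApoB/LDL axis
and an HDL/TG axis for the five major traits; three overlapping axes for
the ten subfraction traits); the idiosyncratic component E (SD 0.3× the
loading scale) is what makes correlated exposures statistically
distinguishable at all. The outcome's true per-variant effect is
Σ_k θ_k B_jk + α_j with α the direct (pleiotropic) effects, zero for the
configured fraction of variants. Observed statistics add Gaussian noise at
the closed-form GWAS standard errors 1/sqrt(2·maf(1−maf)·n), with the
binary outcome using the effective sample size 4/(1/cases + 1/controls).

Default study conditions: J = 150 instruments, exposure GWAS n = 360,000
(biobank scale), outcome 31,307 cases / 211,753 controls, loading scale
0.08 SD per allele (typical lead lipid-variant effects), causal effect
θ = 0.25 log-odds per SD — between the PAD-like (|log 0.87| ≈ 0.14) and
CAD-like (|log 0.66| ≈ 0.42) per-SD effects a lipoprotein exposure
plausibly carries. The drug-target generator plants true per-SD-increase
effects of −log(0.87) and −log(0.66) for its two outcomes, so the true
per-SD-decrease ORs are 0.87 and 0.66 and the true CAD/PAD ratio of
effects is log(0.66)/log(0.87) ≈ 2.98. LD is block-diagonal AR(1);
independent-noise mode suits r²-pruned panels, while `noise_mode = "ld"`
draws estimation noise with covariance proportional to LD for gene-region
analyses whose instruments are deliberately correlated.

What the generator does *not* emulate — and hence what passing tests do
not show about real data: genotype-level LD (summary statistics are
simulated directly), ancestry structure and cross-ancestry LD mismatch,
winner's-curse in instrument selection, sample overlap between exposure
and outcome GWAS, non-Gaussian effect-size distributions, and binary-trait
non-collapsibility. Recovery rates measured on the presets are statements
about the presets' signal-to-noise regime, not guarantees for any real
dataset.

## Fixture and problem-size choices in the tests

* MR-BMA recovery is measured over 100 seeded replicates per preset
  (31 models at K = 5, 1023 at K = 10; the Gram-matrix evidence makes this
  cheap). Permutation type-I control uses 200 null panels at 199
  permutations — the smallest n_perm with resolution below 0.05 and an
  exact 10/200 null rejection probability at the 0.05 cut.
* The TWAS split-recovery fixture uses 10 genes in a designed
  5-unique/3-unique/2-shared configuration with gene-level |Z| centred at
  7, classified at q = 0.005. The stringent threshold is a design-time
  power decision, not a tuning: each "unique" gene is a standard-normal
  null in its other trait, and at the default q = 0.05 with 10 genes BH
  admits at least one cross-trait false positive with probability
  ≈ 1 − 0.97⁵·0.96³ ≈ 0.24 per run — exact recovery across seeds would be
  a coin flip for *any* correct implementation. At q = 0.005 the per-run
  exact-recovery probability is ≈ 0.97 while the designed effects
  (p ≈ 1e-12) remain detected with certainty, so the check exercises the
  classification logic rather than FDR boundary noise. The default
  q = 0.05 is unchanged everywhere else.
* Bootstrap checks use 200–5000 replicates: enough for order-statistic
  CIs at Monte-Carlo tolerance ~0.05 while keeping the suite fast.

## Numerical choices

* LD matrices are validated (symmetric, unit diagonal, entries in [−1,1])
  and made positive semi-definite at load: if the smallest eigenvalue is
  below 1e-8, a diagonal ridge starting at 1e-8 and doubling until PSD is
  applied and the matrix rescaled back to a correlation; the ridge is
  recorded. Sample LD matrices are routinely indefinite and GLS needs an
  invertible Ω.
* Greedy LD pruning iterates in ascending min-exposure-p order with
  lexicographic variant-id tie-breaks, making the survivor set
  deterministic for any input order.
* MIP ranking ties break by ascending permutation p, then name.
* Evidence computations subtract the running maximum before
  exponentiation (log-sum-exp); non-finite evidence is an error, not a
  silent NA.
* The pipeline derives per-stage seeds as (seed·10007 + stage index)
  mod 2³¹−1 so stages are independently reproducible, and its run log uses
  a deterministic step counter in place of wall-clock timestamps so reruns
  at the same seed are byte-identical — reproducibility was judged more
  valuable than timing metadata in the log file.

## Known limitations

* No weighted-median/mode estimators, Steiger filtering, or colocalization;
  MR-Egger is the only pleiotropy-robust sensitivity estimator included.
* MR-BMA assumes (approximately) independent instruments; there is no
  LD-aware model averaging, and K > 20 is unsupported by design.
* The TWAS component consumes pre-trained weight models; it does not train
  them, and single-tissue weights inherit that tissue's eQTL biases.
* Genetically proxied lifelong exposure differences need not match the
  magnitude of shorter-term pharmacological intervention; the drug-target
  ORs are prioritization devices, not dose-response predictions.
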