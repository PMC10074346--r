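---
title: "Methods: rare-variant collapsing burden analysis in rvburden"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rare-variant collapsing burden analysis in rvburden}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette records the statistical model, the defaults and the design
choices behind `rvburden`, in the spirit of a methods section: what is
computed, under which assumptions, and where the genuinely open decisions
were settled.

## 1. Qualifying variants and genetic scores

Each gene is screened with up to nine variant sets crossing three filters:

| sets | class rule | CADD rule | gnomAD AF ceiling |
|------|------------|-----------|-------------------|
| 1–3  | pLOF only  | none      | 10⁻², 10⁻³, 10⁻⁴ |
| 4–6  | pLOF + missense/in-frame | CADD ≥ MSC | 10⁻², 10⁻³, 10⁻⁴ |
| 7–9  | pLOF + missense/in-frame | none      | 10⁻², 10⁻³, 10⁻⁴ |

The CADD/MSC rule is applied to missense and in-frame variants only; pLOF
variants are exempt. This scoping is the natural reading of a filter
defined "for missense and in-frame variants": a truncating variant is not
discounted for a low deleteriousness score. A variant with no gnomAD entry
is treated as ultra-rare (AF 0); a missense variant with no CADD score
fails the CADD rule rather than passing by default. Branchpoint variants,
when enabled (`include_bp`), count as pLOF-class; their detection is an
upstream annotation, not re-implemented here.

Genotypes collapse into per-sample scores by zygosity: co-dominant
(2 = any biallelic qualifying genotype, 1 = any monoallelic, 0 otherwise),
heterozygous-only (1 = any monoallelic), recessive (1 = any biallelic) and
dominant (any carrier). A hemizygous male (ploidy 1 on X) is biallelic.
Compound heterozygotes — two monoallelic variants in one gene — are *not*
promoted to biallelic by default because phase is unknown; the
`compound_het` option enables the aggressive reading. Missing genotypes
score as non-carriers, so missingness can only dilute, never invent,
signal. Tests with fewer than 3 carriers across all samples are skipped.

## 2. The conditional-Firth burden test

The score is tested against status with a logistic likelihood-ratio test
adjusted for sex, age (years) and the top five PCs. If the ML p-value is
below 0.05 (or the ML fit diverges, as it does under separation), the model
is refit under Firth's Jeffreys-prior penalty
ℓ*(β) = ℓ(β) + ½·log det I(β), and the penalized LRT, odds ratio and
profile-penalized-likelihood CI are reported.

Two numerical decisions deserve a note:

* **Penalized LRT form.** The null model *fixes the score coefficient at
  zero inside the full design*, so the penalty (whose log-determinant
  scales with model dimension) cancels between full and null. Fitting the
  null with its own lower-dimensional penalty looks equivalent but is not:
  the penalty difference adds roughly log(information of the extra column)
  to the statistic, and in our null calibration it pushed 4.4% of null
  replicates below p = 0.01. The profile form — what `logistf`'s
  penalized-likelihood-ratio test computes — is calibrated (KS p ≈ 0.6
  over 2000 null replicates with active covariates).
* **Monotone ascent.** Firth iterations use modified-score Newton steps
  with step-halving, accepting only improving steps; when no halved step
  improves the penalized likelihood the current point is the optimum to
  machine precision. On every 2×2 table (margins ≤ 12 enumerated
  exhaustively, random tables to margin 50) the fitted slope matches the
  closed-form log cross-product ratio of the 0.5-added table to < 10⁻⁶.

Convergence: gradient norm ≤ 10⁻⁸, ≤ 50 iterations, ≤ 25 halvings.
P-values are clamped below at 10⁻³⁰⁰. CIs are profile penalized likelihood
(endpoints where the profile drops by ½χ²₁(0.95)); if bracketing fails the
Wald interval is returned flagged `wald = TRUE`. Whether published
intervals of this kind come from profile or Wald construction is usually
unstated; profile was chosen because it stays finite and asymmetric with
zero cells, matching the style of intervals like [1.5–528.7].

## 3. Scan, meta-analysis, consistency and multiple testing

`run_scan()` tests every gene × set × model with ≥ 3 carriers in a joint
analysis (global PCs), then within each ancestry stratum and each pipeline
stratum using stratum-specific PCs, combining strata with the
sample-size-weighted Z meta-analysis
Zᵢ = Φ⁻¹(1 − pᵢ/2)·sign(log ORᵢ), Z = Σ√nᵢZᵢ / √Σnᵢ. Strata where the gene
is untestable (or with one outcome class) are omitted. A stratum odds
ratio of exactly 1 contributes Zᵢ = 0. Note that k identical strata
amplify the common signal by √k — the weights cancel only in the
denominator — so a meta-analysis over one stratum is the identity, but a
meta of duplicated evidence is *stronger*, as sample-size weighting
intends.

Results with joint p < 10⁻³ but either meta p > 0.05 are flagged
`kept = FALSE` (inconsistent across analyses). Per model, the effective
number of variant sets is M_eff = 1 + (M−1)(1 − Var(λ)/M) with λ the
eigenvalues of the correlation matrix of per-gene signed Z statistics
across sets (sample variance, M−1 denominator), clipped to [1, M];
the Bonferroni threshold is 0.05/(n_genes × M_eff). M_eff is computed
per model from complete-case gene rows (a pairwise-complete option
exists): the published effective-test totals factor exactly as
6 × the analyzed-gene counts, which is what a shared per-model M_eff
produces. Signed statistics (not p-values) feed the correlation to retain
direction.

## 4. Enrichment, zygosity and reporting

A candidate gene set is pooled into one super-gene (default rule: pLOF at
gnomAD AF < 10⁻³; per-gene overrides allow a bLOF-only restriction or
added branchpoint variants) and tested with the same machinery; pooled
carriers are counted once. The empirical p-value compares the observed
test p with R = 1000 (default) matched null sets: each target gene is
replaced by a distinct gene with |ΔpLI| ≤ 0.1 and |ΔCoNeS| ≤ 0.5 —
"similar constraint" is qualitative, so the tolerances are configurable
and any monotone tightening is supported — and
p_emp = (1 + #{null ≤ obs})/(R + 1), never below 1/(R+1). Pooling uses the
identity that the score of a union of genes is the element-wise max of
per-gene scores, so per-gene scores are computed once across replicates.

The zygosity-differential test parametrizes carriers as any-carrier +
biallelic-increment and tests the increment (Firth, 1 df, profile-form
null), so "are biallelic odds higher than monoallelic odds?" is a single
fixed-at-zero restriction. Group mean ages are compared with Welch's
t-test (the unequal-variance flavor; the published flavor is unstated).
Carrier percentages round half-up to one decimal, matching printed
proportions such as 57/3269 → 1.7%.

## 5. The synthetic-cohort generator

`simulate_cohort()` draws a virtual population 20× the requested totals
(configurable; raise it when the case quota is large relative to
prevalence), assigns disease by a logistic model, and ascertains cases and
controls to quota — the case-control sampling design of a severe-disease
study. Its stated world:

* **Demographics.** Population age ~ Normal(43.8, 20.1²) years and sex
  balanced — the control marginals of a severe-infection cohort, controls
  approximating the infected general population. Case marginals (mean age
  55.7, SD 17.4; male:female 2.4 vs control male fraction 0.395) *emerge*
  from covariate effects: when not given explicitly, the age log-odds
  slope is the Gaussian discriminant (μ_case − μ_ctrl)/σ²_pooled
  ≈ 0.034/year and the sex effect is the log odds-ratio of the male
  fractions ≈ 1.31. This honors both the per-status moments and the
  logistic disease model with one construction.
* **Prevalence.** Baseline log-odds calibrated so the virtual-population
  prevalence of the severe outcome among the infected is 3% (configurable)
  — the approximate fraction of infections that turn critical.
* **Genetics.** Per gene and consequence class, a configured population
  carrier frequency (defaults: pLOF 2×10⁻³, missense 8×10⁻³) split across
  a small number of variants under Hardy–Weinberg; males are hemizygous on
  X. For genes planted with a recessive effect the configured frequency is
  that of *biallelic* carriers (allele frequency √(c/k) autosomal, c/k on
  X), since an autosomal recessive signal at allele frequency 5×10⁻³ would
  otherwise be unobservable at any realistic cohort size. Common
  background variants for PCA follow a Balding–Nichols model (ancestral
  frequency Uniform(0.1, 0.9), stratum frequencies Beta with divergence
  fst, default 0.05).
* **Determinism.** All draws run under per-component RNG streams derived
  from the root seed by a labeled hash, so adding a gene never perturbs
  another gene's genotypes, and identical configs give identical cohorts.

What the generator does **not** emulate: linkage disequilibrium among rare
variants, relatedness/pedigrees, sequencing or genotype-calling error,
batch effects correlated with pipeline, and annotation error (the gnomAD
AF column is generated near the simulation frequency rather than taken
from a real database — for planted recessive genes it is clipped below 1%
so the variants stay in scope of the rare filters). A green end-to-end
test therefore establishes that the statistics recover what was planted
under the stated model, not that the pipeline is robust to every artifact
of real sequencing data.

## 6. Calibration worlds and scaled-down checks

The test suite fixes its simulation worlds once:

* Null-calibration of the burden test: n = 500, 10% carrier frequency,
  active sex/age/PC covariates, 2000 replicates.
* Genomic-inflation check: 2100 testable genes at the study scale
  (3269/1373) with per-gene collapsed carrier frequencies spread
  0.5–5% (log-uniform). At much smaller carrier counts (≲ 20 carriers per
  gene) the ML-LRT's median chi-square runs ~10% hot, inflating λ even
  though tail calibration is fine — a known small-count limitation worth
  remembering when reading λ on sparse recessive scans.
* Empirical-p uniformity: 200 seeds × R = 99 (scaled from 500 × 199 for a
  single-CPU budget); the 2×2-oracle enumeration is exhaustive to margins
  of 12 with a 300-table random layer to margin 50 (full enumeration to 50
  would be ~4×10⁶ fits).
* Ground-truth recovery: an X-linked recessive gene (carrier frequency
  5×10⁻³, log-odds 2.5) planted in a 3269/1373 cohort must rank first
  under the recessive model in ≥ 9 of 10 seeds.

## 7. Known limitations

* No phasing: compound heterozygosity is off by default and, when enabled,
  is an upper bound, not an inference.
* The whole X is treated as non-pseudoautosomal for male ploidy.
* The weighted common+rare score uses the Madsen–Browning form
  w = 1/√(q(1−q)) with control-estimated q plus an add-one allele
  pseudocount; "weighting by frequency" admits other forms, so the weights
  are a parameter, and unit weights recover the plain allele count.
* The power simulation tests the covariate-free 2×2 design; covariates
  would only change power through confounding not modeled there.
* Meta-analysis is sample-size-weighted Z only (no inverse-variance
  option), matching the stated analysis.
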