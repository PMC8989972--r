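---
title: "Models and methods in lipidvc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in lipidvc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`lipidvc` analyzes lipidomic traits measured on members of a deep
founder-population pedigree: pedigree-expected relatedness, multi-component
variance decomposition, bivariate genetic correlation, mixed-model
association scans with conditional analysis, and a gene-dropping simulator
that makes the whole pipeline testable without access to restricted cohort
data. This vignette records the models, the defaults, and the design
decisions a maintainer would want to know.

## Relatedness from the pedigree

The kinship coefficient `phi(i,j)` — the probability that one allele drawn
from each of `i` and `j` is identical by descent — is computed by the
tabular recursion in topological (parents-first) order:
`phi(i,i) = (1 + phi(f_i, m_i))/2` and
`phi(i,j) = (phi(f_i,j) + phi(m_i,j))/2`, with founders at `1/2` on the
diagonal and unrelated to everyone else. The additive matrix is `A = 2 phi`
so that its variance component is the additive genetic variance and its
proportion of phenotypic variance is the narrow-sense heritability.

The dominance (fraternity) coefficient — the probability of sharing the
*genotype* identical by descent — uses the pair formula
`d(i,j) = phi(f_i,f_j) phi(m_i,m_j) + phi(f_i,m_j) phi(m_i,f_j)`, with
`d(i,i) = 1`. This formula is exact for non-inbred pairs only. We apply it
to all pairs and warn, listing the inbred individuals, whenever the
pedigree contains inbreeding: this matches common fraternity-matrix
practice, and the exact alternative (Jacquard's nine condensed identity
coefficients) is out of scope. The test suite consequently validates
dominance against gene-drop Monte Carlo on non-inbred pedigrees, where the
formula is provably exact, and kinship on arbitrary (including inbred)
pedigrees, where the recursion is always exact.

Parsing accepts PED-style files (`id father mother sex`, optional leading
family column ignored); `"0"` or an empty field is a missing parent, and a
parent referenced but not listed is auto-added as a founder with a warning.
One-parent records and cycles are structural errors; sex is validated
against parental roles but plays no role in the matrices.

## Variance decomposition

Each trait is modeled as `y ~ N(Xb, sum_k sigma2_k K_k + sigma2_e I)` over
any set of component matrices: additive, dominance, SNP GRMs, lipidome-class
covariance matrices. Estimation is average-information REML (ML optional):

* the trait is standardized internally, so convergence tolerances are
  scale-free; estimates are rescaled on output (REML is invariant to this);
* starting values split the phenotypic variance equally across components
  and residual (overridable via `vc_control(start = )`);
* AI steps are step-halved if they do not improve the restricted
  likelihood, proposals below zero are projected onto the boundary, and an
  expectation-maximization step is the fallback when no damped AI step
  helps;
* components parked at zero with a negative gradient are deactivated and
  flagged `boundary`; they re-enter if their gradient turns positive;
* convergence requires a relative log-likelihood change below `1e-8` *and*
  a gradient norm below `1e-6` (standardized scale), within 200 iterations;
  non-convergence is an error carrying the iteration trajectory;
* a component matrix numerically proportional to the identity is rejected
  up front (it cannot be separated from the residual). Other
  non-identifiable configurations — e.g. a dominance matrix that is a
  linear combination of the additive matrix and the identity, which happens
  exactly in full-sib-only designs — surface as non-convergence on a
  likelihood ridge.

Standard errors come from the inverse average-information matrix.
Likelihood-ratio tests default to the 50:50 mixture of a point mass at zero
and chi-square (the tested variance sits on the boundary of its space);
plain chi-square is selectable. ML must be used when fixed effects differ
between the models; REML comparisons require identical fixed effects and
the code enforces this. The greedy `sequential_component_selection()` adds,
at each step, the candidate with the smallest LRT p-value while it is below
`alpha` (default 0.05, the study's rule), breaking ties by candidate order
and recording a full audit trail including skipped candidates.

Data-derived class covariance matrices standardize each trait column to
mean zero and unit variance (denominator `n`), set missing entries to the
column mean, and form `S = XX'/m` over the `m` class members. The division
by `m` is our choice (the source procedure states only centering and
normalization): it gives `trace(S) = n`, so class components live on the
same proportion-of-variance scale as heritability and are comparable across
classes of different sizes. The SNP GRM follows the standard
per-variant-standardization convention, `G = WW'/m` with
`w = (g - 2p)/sqrt(2p(1-p))` and mean imputation of missing dosages;
frequencies come from the analyzed sample. Variant QC filters on call rate
(missingness > 2%), minor-allele frequency (< 0.01) and a plain 1-df
chi-square Hardy-Weinberg test (p < 1e-10); at that threshold a continuity
correction is irrelevant, and an exact test is not offered. HWE applies to
hard calls only; fractional dosages are exempt from it.

## Phenotype preparation

Each lipid species is residualized on age, age squared, sex and technical
batch factors (traditional lipids: the same minus batch terms), then
rank-based inverse-normal transformed with the Blom offset,
`z = qnorm((r - 3/8)/(n + 1/4))`. The offset is configurable; Blom is the
most common convention and which offset the original analyses used is not
stated. Ties receive average ranks — deterministic reproducibility is
preferred over exact normality — and missing values propagate. No
medication adjustment is applied. Aliased design columns are dropped with a
warning; a trait whose residual variance is numerically zero is a
degenerate-trait error.

## Bivariate genetic correlation

`fit_bivariate()` maximizes the ML likelihood of the stacked two-trait
model with genetic covariance `G0 (x) K` and residual `E0 (x) I`. The
covariance parameters are deliberately *unconstrained* (log variances, raw
covariances, no Cholesky), so the implied genetic correlation can leave
`[-1, 1]` — required to reproduce the masking rule: out-of-range estimates,
common when one or both traits have low heritability, are flagged and
reported missing in matrix output, with the reason kept. We extend the
masking symmetrically to out-of-range residual correlations. An
eigendecomposition of `K` reduces each likelihood evaluation to `n`
independent 2x2 problems; optimization is Nelder-Mead followed by a BFGS
polish, started from univariate fits and the phenotypic correlation.
Phenotypic correlations are pairwise-complete Pearson (the source is silent
on missing-data handling; this is documented as our choice).

## Association scans and thresholds

The scan is two-stage, as in population-scale LMM practice: REML fits the
null model (covariates plus any conditioning genotypes, additive component)
once; each variant then gets the GLS effect `beta = (x'Px)^-1 x'Py` with a
Wald t-test on `n - p - 1` degrees of freedom, re-estimating the residual
scale per variant. Because the scale re-estimation makes the statistic
invariant to the overall scale of `V`, the scan reduces *exactly* to OLS
when the relatedness matrix is proportional to the identity (the stage-1
fit is then unidentifiable and is skipped). Monomorphic variants and
variants collinear with the fixed effects (including conditioning variants
themselves) are skipped with reasons. The effect allele is the VCF alt
allele; effects are in SD units of the prepared trait.

Multiple testing: eigen-decompose the correlation matrix of the prepared
trait panel over complete cases, count the components needed to reach the
variance fraction (default 0.95; `>= target` at the first k), and divide
the base genome-wide level (default 5e-8) by that count. Associations
between the adjusted threshold and the base level are "suggestive".
Conditional analysis dissects a locus (default: a +/- 1 Mb window around
the index variant, passed as a half-open `chr:start-end` region) by
repeatedly conditioning on the current top variant until nothing is
significant; the conditioning list is the set of independent signals.

Replication-exclusion power is the analytic two-sided Wald power for a
standardized additive effect, noncentrality
`beta * factor * sqrt(2 maf (1-maf) n)`, with `factor = 0.5` available to
halve the discovery effect against winner's curse. The exact analytic form
used by the original analyses is unstated; ours is validated against
Monte-Carlo OLS rejection to within 0.01.

## The synthetic founder population

The generator is the package's stand-in for restricted cohort data, and its
defaults are the study conditions at desk scale: 80 founders and 6
non-overlapping generations (scaled down from roughly 750 founders and 14
generations), with 650 phenotyped subjects drawn from the most recent
generations while the full pedigree connects them — mirroring a cohort
where only a fraction of the pedigree is profiled. Couples form within a
generation either at random or with kinship-weighted mate choice
(`mating = "cousin"`), the latter producing inbreeding and exercising the
dominance warning path; sibship sizes are Poisson with mean 3.

Genotypes are gene-dropped: founder alleles drawn at configured
frequencies, or seeded as exact copy counts for enriched variants so the
final frequency drifts across replicates (a two-copy default mirrors rare
founder alleles that may drift to several percent); transmission is by fair
meioses, with optional LD blocks that share one meiosis indicator per
transmission (no within-block recombination) so that a causal variant drags
50 proxies along — the input for conditional-analysis validation.

Traits realize the variance-component model generatively:
`y = sum_k sqrt(f_k) L_k z_k` with `L_k` a square root of the component
covariance. Species are drawn per class with configurable heritability,
within-class genetic correlation and environmental block correlation
(defaults 0.4 / 0.5 / 0.5, typical of lipid species panels); composite
(traditional-lipid-like) traits draw their class components through the
*realized* class covariance of those species — the rectangular root
`X/sqrt(m)` — so the configured fractions are exactly the estimands of the
downstream decomposition. The default composite mirrors a triglyceride-like
architecture (TAG 0.34, DAG 0.05, PC 0.05). Covariates (age, sex, batch)
are always attached; `mode = "raw"` additionally contaminates traits with
known covariate coefficients and exponentiates them, to exercise phenotype
preparation. One seed stream per operation (pedigree, genotypes, traits,
covariates) keeps trait draws unchanged when variants are added.

What the generator does *not* emulate: realistic recombination maps and
genome-wide LD beyond single-locus blocks, genotyping error and platform
artifacts, non-Gaussian trait tails beyond the raw-mode exponential,
assortative mating on phenotype, and shared-household environmental
covariance. Passing tests therefore demonstrate the estimators' correctness
under their own assumptions, not robustness to those real-data features.

## Problem sizes and test design

Recovery studies in the test suite use the 600-subject analyzed set of a
6-generation pedigree: 200 replicates for heritability recovery (truth
0.5), 100 for the four-component class decomposition (truth 0.34 / 0.05 /
0.05 / residual) and for bivariate genetic correlation (truth 0.8);
boundary-LRT size uses 1000 null replicates on a ~500-subject pedigree, and
Monte-Carlo IBD oracles use 1e5 gene drops on pedigrees of up to ~26
individuals. The GWAS null calibration deliberately uses gene-dropped
genotypes (which carry the pedigree covariance structure the two-stage GLS
test assumes) with an independently simulated trait; permuting genotypes
across subjects makes them exchangeable and measurably deflates the test —
a known property of two-stage mixed-model scans, not a defect of the
implementation.

## Known limitations

* Dominance under inbreeding is approximate (see above).
* The AI-REML engine targets a few hundred to a few thousand subjects with
  dense component matrices; it does not exploit sparsity or low-rank
  structure.
* Bivariate fits use a derivative-free optimizer with a quasi-Newton
  polish; pathological likelihoods (both heritabilities near zero) can
  terminate at out-of-range correlations — by design these are masked, not
  hidden.
* The pipeline's conditional stage dissects one locus per 2 Mb bucket per
  trait, keyed by the top hit; overlapping multi-trait loci are reported
  per trait.
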