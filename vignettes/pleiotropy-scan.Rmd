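---
title: "Scoring causal networks to detect SNP pleiotropy for BMI and smoking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring causal networks to detect SNP pleiotropy for BMI and smoking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pleioscan)
```

## The question and the model

A SNP is pleiotropic for BMI and smoking when it has *direct* effects on
both phenotypes — not merely an effect on one that propagates to the other
through their mutual relationship. Distinguishing these situations from
observational data requires committing to a family of causal structures.
`pleioscan` uses the twelve directed acyclic graphs (DAGs) over the trio
{G, B, P}, where G is the SNP dosage (exogenous: nothing points into a
germline genotype), B is BMI, and P is the smoking node — continuous
pack-years or binary ever/never smoking:

```{r}
for (d in enumerate_dags()) print(d)
```

The four categories encode which direct genetic edges exist: none
(category 1), G→B only (2), G→P only (3), or both (4, the pleiotropic
models). Within a category the three DAGs differ in the phenotype–phenotype
edge (absent, B→P, or P→B).

Each DAG is scored by fitting one regression per phenotype node — the node
on the shared covariates (age, sex, study site, four genetic principal
components) plus its structural parents among {G, B, P} — and summing:

$$\mathrm{AIC}(\text{dag}) = -2\,\ell_B - 2\,\ell_P + 2\,|\text{edges}|,$$

where $\ell_B$, $\ell_P$ are maximized log-likelihoods and the edge count
runs over the trio edges only. Covariate terms appear identically in all
twelve models, so their parameter counts are constants that cancel from
every AIC *difference*; including them in the penalty would change no
comparison, and leaving them out keeps the penalty equal to twice the
number of structural claims the DAG makes.

A SNP's **assigned category** is the argmin over the four per-category
minimum AICs (ties broken toward the lower category, so the less
pleiotropic description wins ties). The **pleiotropy margin** is

$$\min(\text{AIC}^{\min}_1, \text{AIC}^{\min}_2, \text{AIC}^{\min}_3)
  - \text{AIC}^{\min}_4,$$

and the SNP is **called** pleiotropic when the margin is at least
$\delta = 2$. We read "category 4 beats the others by 2" in its strictest
form — the category-4 minimum must undercut *every* other category's
minimum by $\delta$ — which is identical to undercutting their overall
best, so the two natural readings of the rule coincide. Assignment and
call are kept separate on purpose: the argmin is a description of the best
fit, the margin is a decision with an evidence threshold. A called SNP
additionally needs a nominally significant (p < 0.05) single-SNP
association with the smoking phenotype to become a **candidate**; that
association regression also adjusts for lung-cancer case status, whereas
the DAG regressions do not — both adjustment sets are arguments and can be
overridden.

## Likelihoods and their numerical discipline

The Gaussian log-likelihood uses the *maximum-likelihood* variance
$\hat\sigma^2 = \mathrm{RSS}/n$, not the unbiased $\mathrm{RSS}/(n-p)$:

$$\ell = -\tfrac{n}{2}\left(\log(2\pi\hat\sigma^2) + 1\right).$$

This matters because the chain rule for a joint Gaussian,
$\ell(B\mid\mathrm{cov}) + \ell(P\mid\mathrm{cov},B) =
 \ell(P\mid\mathrm{cov}) + \ell(B\mid\mathrm{cov},P)$,
holds *exactly* only at the ML variance. That identity is what makes DAG
pairs {2, 3} and {11, 12} likelihood-equivalent ("not differentiable"):
they factorize the same joint density in the two possible orders and carry
equal edge counts, so their AICs agree to numerical precision (observed
gaps around 10⁻¹² in the test suite, asserted below 10⁻⁶). The unbiased
variance enters only the Wald standard errors. With a binary smoking node
the logistic factorization has no such symmetry, so no equivalences are
claimed there and `equivalence_classes()` degrades to singletons with a
warning.

Logistic models are fitted by iteratively reweighted least squares to a
tight tolerance (50 iterations maximum); complete and quasi-complete
separation is detected (fitted probabilities within 10⁻¹⁰ of the boundary
together with runaway coefficients) and raised as an error rather than
returned as a spuriously huge estimate. Rank-deficient designs are refused
with the offending columns named; constant columns (for example a
single-site cohort's study-site factor) are dropped before fitting since
they carry no information. A regression with zero residual variance is a
degenerate-fit error. Wald p-values use the normal reference throughout,
matching the large-sample regression tests the analyses report.

Partial correlations are Pearson correlations of the two variables'
residuals after linear adjustment; intervals and p-values use the Fisher-z
transform with effective degrees of freedom $n - k - 3$ ($k$ = covariate
columns after dummy coding). The interval method is our choice — reported
intervals of this kind rarely state one — and is the standard one.
Adjusted group means use cell-means coding (one indicator per group, no
intercept — the "fixed intercept of zero" convention) with covariates
centered at their sample means, so each coefficient is the group mean at
the average covariate profile, and shifting a covariate by a constant
changes nothing. The BMI-category trend test codes the four categories
1–4 and treats the code as a continuous regressor.

## The risk score

Variants are selected at p < 10⁻⁵ (strictly below; the same pipeline with
5 × 10⁻⁸ gives a genome-wide-significant score), then pruned greedily in
ascending p-value order: a variant is kept only if, against every variant
already kept, its dosage r² is below 0.2 *and* it is at least 500 kb away
or on another chromosome. Greedy-by-significance is the standard clumping
convention; the source analyses say only "pruned", so the order is our
choice and is recorded here. r² is always computed in-sample from the
analysis dosages, not from a reference panel. Harmonization orients every
variant so its BMI effect is non-negative (swapping alleles and flipping
dosages to `2 − d` as needed) and is idempotent; strand-ambiguous A/T and
C/G variants are rejected by default. Imputed dosages are kept as real
values in [0, 2] — best-guess rounding would discard information the
linear models can use — and missing dosages drop the sample from the score
(per-SNP complete-case handling applies in the scan).

## What the synthetic cohorts do and do not emulate

The generator exists so that every stage has a ground truth. Genotypes are
Hardy–Weinberg draws with MAF uniform on a configured range (default
0.05–0.5); optional LD comes from a lag-1 latent Gaussian autoregression on
the haplotype level, which preserves marginal HWE while correlating
neighbours. Covariates are conventional: age ~ Normal(62, 10) truncated to
[30, 90], balanced sex, uniform study sites, standard-normal PCs,
independent Bernoulli case status. The joint covariate distribution of a
real consortium (site-specific age structures, case-control ascertainment,
smoking–age confounding) is deliberately *not* modelled: the analyses
adjust for these variables rather than model their generation, and an
independent-covariate world is exactly the setting in which the adjustment
is provably sufficient. Passing tests therefore demonstrate correctness of
the machinery under the stated structural models, not robustness to
ascertainment bias or covariate misspecification in real cohorts.

Phenotypes follow the assigned DAG in topological order: each node is its
covariate effects plus structural-parent effects plus Gaussian noise, or a
Bernoulli draw on the logit scale for binary smoking. Defaults place BMI
at 26.5 kg/m² (residual SD 4.8) and pack-years at 40 (residual SD 28),
the scale of a lung-cancer consortium population. Pack-years is generated
as an *unbounded* Gaussian by default — truncation at zero is available
but off, because the Gaussian likelihood equivalences that the scoring
relies on are exact only without truncation. In continuous mode the
pack-years node is generated for everyone and masked to missing for
individuals labelled never-smokers (labels drawn independently, default
25% never); scans restrict to ever-smokers, where pack-years is defined.
In a multi-SNP panel the genetic edges are additive across SNPs and all
assigned DAGs must agree on the phenotype–phenotype edge — mixing B→P and
P→B SNPs in one dataset would assert a cyclic world and is refused. One
master seed feeds independent named substreams (genotypes, covariates,
phenotypes), so enlarging the SNP panel never perturbs the covariate
draws and every dataset is a pure function of its configuration.

## Parameters that matter

| Parameter | Default | Units / scale | Why |
|---|---|---|---|
| selection threshold | 1e-5 | p-value | liberal discovery set for a risk score; 5e-8 for the conservative variant |
| `r2_max` | 0.2 | squared dosage correlation | standard clumping ceiling for "independent" SNPs |
| `min_distance_bp` | 500,000 | base pairs | removes long-range LD the r² sample estimate can miss |
| `delta` | 2 | AIC units | the conventional "positive support" gap; one parameter's worth of evidence |
| candidate filter | 0.05 | p-value | nominal screen before external validation |
| Bonferroni `alpha` | 0.05 | family-wise error | divided by the pooled candidate count (7 candidates → 0.007) |
| `beta_gb`, `beta_gp` | per-allele effects | kg/m², pack-years (or log-odds) | set to 0.5 phenotype SDs in the operating-characteristic studies |

Candidates from both trios are pooled before the Bonferroni division (a
per-trio correction is available); direction-discordant external hits are
flagged, never dropped.

## Problem sizes used in the checks

The operating characteristics reported by `scripts/acceptance.R` use 200
replicates per generating model at n = 5,000 with allele effects of 0.5
phenotype SDs — large effects by GWAS standards, chosen so a single SNP's
category is identifiable at cohort scale; the same code paths run
identically at biobank sizes. Likelihood-equivalence checks use 50 trios
at n = 500; null calibration uses 500 replicates at n = 2,000 and
Kolmogorov–Smirnov uniformity at the 1% level. Within-suite simulations
keep to a few thousand individuals so the whole test battery runs in a few
minutes on one CPU core.

## Known limitations

* The twelve-DAG family excludes latent confounders of B and P and any
  bidirectional feedback; a SNP whose association runs through an
  unmodelled confounder can be mis-assigned. Instrument-validity tests and
  mediation decompositions are out of scope.
* AIC model selection with $\delta = 2$ controls neither family-wise error
  nor FDR across SNPs; the downstream association filter and external
  Bonferroni validation carry that burden.
* In-sample r² pruning inherits sampling noise at small n; there is no
  reference-panel mode.
* The logistic branch sums a Bernoulli and a Gaussian log-likelihood into
  one AIC; that mixed-family comparison is the stated procedure, but its
  penalty calibration is cruder than in the all-Gaussian case.
* Case-control ascertainment is adjusted for (case status as a covariate),
  not modelled; simulated operating characteristics assume the covariates
  are exogenous.
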