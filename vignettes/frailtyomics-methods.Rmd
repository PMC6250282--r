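---
title: "Models and methods in frailtyomics"
author: "frailtyomics maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in frailtyomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`frailtyomics` implements a complete, testable pipeline for multi-omics twin
studies of the deficit-accumulation Frailty Index (FI) and chronic widespread
pain (CWP): a synthetic-cohort generator, FI construction and twin-pair
discordance, maximum-likelihood ACE variance decomposition (including a
liability-threshold model for the dichotomous CWP trait and a bivariate
continuous-binary genetic-correlation fit), metabolite association scans
with FDR control, SNP quality control and additive genome scans, a
split-sample discordant-MZ-twin EWAS with Fisher p-value combination,
gene-set overrepresentation, and a two-stage path analysis separating direct
from CWP-mediated effects. This vignette records the models, their
assumptions, the tunable parameters, and the design decisions behind the
numerical choices.

## The synthetic cohort

Real registry data of this kind cannot be redistributed, so the package
ships a generator (`cohort_config()` / `simulate_cohort()`) that reproduces
the statistical structure every downstream stage relies on, with planted
signals whose truth is recorded alongside the data.

**Family structure.** The default cohort mirrors a female twin registry:
848 monozygotic (MZ) pairs, 576 dizygotic (DZ) pairs and 778 singletons
(ages drawn uniformly on 17–93 years, shared within a pair). For each of
the two latent traits (FI liability, CWP liability), standardized A/C/E
components are drawn so that MZ co-twins share A and C, DZ co-twins share C
and have A-correlation 1/2, and singletons are independent. Cross-trait
structure is injected at the component level: the two A components of one
individual correlate `rg`, the C components `rc`, the E components `re`.
Each liability is `sqrt(a2)*A + sqrt(c2)*C + sqrt(1-a2-c2)*E`, giving unit
residual variance by construction.

**Defaults.** The FI additive-genetic fraction defaults to `a2_fi = 0.34`
and the cross-trait genetic correlation to `rg = 0.69`, the established
twin estimates for these phenotypes. Quantities for which no published
value exists are field-typical conventions chosen once: `c2_fi = 0.20`,
`a2_cwp = 0.45`, `c2_cwp = 0.10`, `rc = 0.30`, `re = 0.10`, and a CWP
prevalence of 0.20 (chronic widespread pain affects roughly one in five
adult women). Covariates act additively on the liability scale: age (0.25
SD per SD of age on FI; 0.20 on CWP), relative fat mass (0.15 both), and
smoking coded never/previous/current as 0/1/2 with 0.10 per category,
reflecting the monotone increase of FI across smoking categories.

**Deficits.** No generative model for individual health deficits is
established; we use a single-factor logistic item-response convention: item
j has a baseline prevalence drawn once per cohort from U(0.05, 0.35), and
an individual's deficit probability is `plogis(qlogis(p_j) + z)` where `z`
is the standardized FI liability. Any monotone link would serve; the
logistic choice keeps item prevalences interpretable. The resulting FI
(proportion of 33 binary deficits) correlates about 0.6–0.7 with the latent
liability.

**CWP status** is the indicator that the empirically standardized CWP
liability exceeds `qnorm(1 - prevalence)`. Standardization uses the
realized sample, so the attained prevalence fluctuates binomially around
the target.

**Omics layers.** Metabolites are lognormal abundances built from latent
standard-normal levels, multiplied by a run-day batch factor (20 run-days,
log-SD 0.25) with sparse missingness; 103 of the default 408 metabolites
are flagged as chemically unidentified. SNPs are independent biallelic
dosages with MAF ~ U(0.05, 0.5) (no linkage disequilibrium — a stated
non-goal). Methylation is simulated in 500-bp bins overlapping by 250 bp at
two timepoints at least three years apart: stable bins (default 80%) have
autocorrelation 0.6 across timepoints, unstable bins are independent noise.
Planted effects — metabolite→trait, SNP→metabolite, bin→trait — are
supplied as a table and recorded in `truth.json`; planted bins are always
longitudinally stable so the stability filter cannot silently remove the
signal being tested.

**Planted effects and the mediation switch.** The planted-effect table
defaults to empty and the causal CWP→FI path (`cwp_fi_effect`) to zero, so
the default generating model is the pure bivariate ACE structure and
variance-component recovery is unbiased by construction. Mediation
scenarios — an epiandrosterone-sulphate-like metabolite whose FI
association flows entirely through CWP — are switched on by planting a
`mediated` metabolite effect (which enters the CWP liability only) together
with a nonzero `cwp_fi_effect`.

Each layer draws from its own sub-seed derived from the master seed, so
resizing one layer never perturbs another, and runs are byte-identical
given a seed.

## Frailty Index and discordance

`compute_fi()` is the standard deficit-accumulation index: the proportion
of deficits present among non-excluded, non-missing items. The pain item
can be excluded wholesale (`exclude_items`) to avoid circularity with the
pain phenotype; individuals missing more than `max_missing_fraction`
(default 0.2 — a convention, the source analyses do not state one) of the
items get a missing FI. Pair discordance is
`D = (FI1 - FI2) / (0.5 (FI1 + FI2))`, antisymmetric and scale-invariant,
undefined when both twins have FI 0. "Most discordant" is interpreted as
largest `|D|` — the downstream paired test is two-sided, so the sign of the
difference carries no ranking information — with ties broken by family id
so selection is reproducible. Within a selected pair the higher-FI twin is
oriented first ("affected") for the paired test.

## ACE maximum likelihood

All three fits share one likelihood skeleton: a twin pair is bivariate
normal (or a bivariate orthant for binary traits) with correlation
`a2 + c2` (MZ) or `a2/2 + c2` (DZ); singletons and incomplete pairs
contribute univariate terms. Covariates enter the mean structure (or shift
the liability threshold on the probit scale). Variance fractions are
optimized on an unconstrained scale through a softmax map with `e2` as the
baseline — boundary solutions (`a2 → 0` or `c2 → 0`) are approached
smoothly and reported, with their standard errors flagged unreliable —
and cross-trait correlations through `tanh`.

For the bivariate continuous-binary fit the pair likelihood factorizes
exactly: the continuous pair contributes its bivariate normal density, and
the binary pair contributes the conditional orthant probability of the two
latent liabilities given the continuous observations. The conditional
covariance depends only on zygosity, so the whole likelihood is evaluated
with vectorized bivariate-normal upper-tail probabilities (a Gauss–Legendre
quadrature implementation accurate to ~1e-15, cross-checked in the test
suite against an independent adaptive-integration oracle). Cross-twin
cross-trait covariances are `rg*aX*aY + rc*cX*cY` (MZ) and
`rg*aX*aY/2 + rc*cX*cY` (DZ), with `re*eX*eY` added within a person.

**Optimization.** Each fit runs from multiple deterministic start points
(Falconer-style moment estimates and probit fits for location, with fixed
offsets on the correlation parameters), `nlminb` with relative tolerance
1e-8 followed by a BFGS polish — `nlminb` occasionally reports false
convergence on likelihood ridges, and the polish step resolves this —
keeping the best likelihood. Standard errors come from the delta method on
the observed-information inverse; when the information matrix is singular
at a boundary it is pseudo-inverted over the identified subspace.
Non-convergence flags the fit rather than raising an error. When a
component variance is effectively zero for either trait, the corresponding
correlation is non-identified and reported `NA`.

**Known finite-sample behavior.** The ML estimate of the genetic
correlation between a continuous trait and a rare dichotomous one is noisy
and biased upward in moderate samples: the estimate behaves like a
cross-covariance divided by `sqrt(a2_X * a2_Y)` estimates, and noise in
that denominator inflates the ratio (Jensen), compounded by pile-up at the
`rg = 1` boundary. In simulations at the package's default structure, the
estimator is consistent (recovering `rg` to within sampling error at 16,000
pairs) and its Wald intervals achieve ~91% empirical coverage at 1,000
pairs, but the mean estimate at 1,000 pairs sits about 0.04–0.05 above the
generating value of 0.69 (with ~16% of fits at the boundary). Point
estimates from a few hundred pairs should be read together with their
standard errors, not as unbiased values; replicate-averaged recovery at
1,000 pairs lands only just inside a ±0.05 band.

## Metabolome association

Normalization follows the two-step convention for non-targeted
metabolomics: divide by the run-day median (removing daily assay
fluctuation), then rank-based inverse-normal transform. The Blom offset
(c = 3/8) is used; the sources do not name an offset and any standard
choice alters nothing downstream because the scan is rank-based after the
transform. Metabolites missing in more than 20% of samples (strict
inequality) or of unknown identity are removed before testing.

The screen regresses FI on each metabolite (standardized to unit SD) plus
age, takes the two-sided coefficient p-value, and applies
Benjamini–Hochberg across metabolites; the printed significance threshold
for selection is an adjusted value of 5e-4. Selected metabolites enter a
joint multivariable model in two variants — ordinary least squares, and GLS
with a family-level random intercept (`lme4`) — mirroring the two-column
contrast of unadjusted versus family-adjusted estimates. The random
intercept is a deliberate simplification of the full ACE covariance for the
regression step; the full machinery lives in the variance-decomposition
module. Missing values are handled complete-case per model; no imputation.

## Genome scan

SNP QC retains markers with call rate ≥ 0.95 and exact Hardy–Weinberg
p ≥ 1e-4 (both boundaries inclusive, matching the stated "≥" rules). The
HWE test is the conditional exact test: given allele counts, sum the
probabilities of all heterozygote counts no more likely than the observed
one. The additive scan is per-SNP least squares of the trait on dosage plus
covariates (complete cases per SNP), reporting genomic-control lambda
(median chi-square over 0.4549). No kinship correction is applied inside
the scan: the synthetic benchmark documents the inflation a family
structure induces, and family modelling is the variance-decomposition
module's job — keeping the scan exact, fast, and testable against a
normal-equations oracle.

## Discordant-twin EWAS

Bins passing the longitudinal-stability filter (positive between-timepoint
correlation, two-sided p < 0.05 — so a null bin is retained with
probability ≈ 0.025) are tested in two non-overlapping samples: a paired t
test within the 50 most FI-discordant MZ pairs (higher-FI twin minus
lower-FI twin), and a Pearson correlation with FI in the remaining
individuals. The two p-values are combined by Fisher's method
(−2(ln p₁ + ln p₂) against chi-square with 4 df; p-values floored at 1e-300
before the log), and bins must show the same direction of association in
both samples. The two-sided p-values are combined first and the sign filter
applied afterwards; the final set is identical either way, so the order is
a presentation choice. Disjointness of the two samples is asserted at run
time — the combination is only valid for independent tests. Under the
global null the compound design passes a bin with probability ≤ α/2
(combined p < α and a 1/2 sign-agreement factor), which the test suite
verifies over 10⁴ null bins.

Degenerate bins follow documented conventions: within-pair differences all
zero → p = 1, sign = 0; a constant bin is excluded from the stability
filter with a flag.

**Gene assignment.** Each bin maps to the gene minimizing genomic distance:
0 if the bin interval overlaps the gene, otherwise the distance from the
bin midpoint to the nearest gene edge (the sources do not define the
metric; midpoint-to-edge is symmetric and cheap), ties to the
lower-start gene. Per gene, the assigned bin with the lowest combined
p-value is retained. The synthetic annotation is non-overlapping by
construction — a documented simplification relative to real gene models.
The Gr2 correlation is computed unadjusted (whether the original design
adjusted it for covariates is not stated); residualizing FI on covariates
first is a one-line preprocessing step if desired.

## Enrichment

Gene-set overrepresentation is the classic one-sided Fisher exact test per
set over the universe of genes with an assigned p-value, BH-corrected
across sets, with "significant genes" defaulting to nominal p < 0.05 (the
EWAS/GWAS gene lists feeding set-level analysis are nominally significant
genes). Graph-aware down-weighting schemes over an ontology DAG are out of
scope by design: the package tests user-supplied flat gene-set maps, which
is the DAG-free equivalent.

## Path analysis

The two-stage formulation separates the variance-decomposition question
(handled above) from the directional one: stage 1 is a probit regression of
CWP status on the candidate covariates — age, fat mass, smoking, selected
metabolites, leading SNP dosages — on the liability scale (logit available
behind a flag); stage 2 is a linear model of FI on CWP status plus the same
covariates, optionally with a family random intercept. The indirect effect
of a covariate on FI through CWP is the product of its stage-1 coefficient
and the stage-2 CWP coefficient, with the delta-method standard error
`sqrt(b² se_a² + a² se_b²)`; total = direct + indirect. Because observed
CWP status (not the latent liability) enters stage 2, the indirect effect
mixes probit and linear scales — a documented property of the
status-mediator formulation.

One structural caveat matters for interpretation and for testing: CWP
status is a collider for any latent path shared by the two traits. If the
cross-trait A/C/E correlations are nonzero, conditioning on status in
stage 2 induces dependence between a purely CWP-acting metabolite and FI,
so a "null direct effect under full mediation" is only the exact truth when
the mediation path is the sole cross-trait link. The mediation recovery
tests therefore switch `rg = rc = re = 0`, which is the clean experimental
condition for that claim; with the default correlated structure the direct
effect absorbs a small collider term.

## Pipeline and problem sizes

`run_pipeline()` chains simulate → FI → metabolites → GWAS → EWAS →
enrichment → variance components → path analysis, writing each stage's
outputs as TSV plus a JSON run report (stage counts, seed, versions,
wall-times). Runs are byte-identical for a fixed config and seed (the
report's wall-times are the one intentional exception). A stage failure
halts the run naming the stage; disabling a stage skips its dependents with
a warning.

Default test and demonstration sizes are chosen for desk-scale runtimes
with adequate statistical resolution: 10³–10⁴ methylation bins (the design
scales linearly to epigenome scale), 10²–10³ SNPs and metabolites, cohorts
of 500–5,000 pairs for variance-component recovery, 200 replicates for
coverage and replicate-mean checks, and 10⁴ null bins for the EWAS
calibration bound.

## Known limitations

- No linkage disequilibrium, no genomic autocorrelation of methylation, no
  read-level sequencing simulation; planted signals are single-feature.
- The genome scan is deliberately unadjusted for relatedness (see above).
- The liability-threshold machinery supports twin pairs and singletons
  only; no extended pedigrees, no dominance component, no GxE.
- Genetic-correlation estimates from continuous-binary fits carry the
  finite-sample upward bias described above; treat point estimates at a
  few hundred pairs with their standard errors, not as unbiased values.
- The synthetic annotation uses non-overlapping genes; real annotations
  require a tie policy for overlapping features that the assignment
  function's documented rules would need extending for.
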