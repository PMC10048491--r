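---
title: "Association mapping of milk traits in structured herds: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Association mapping of milk traits in structured herds: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(herdgwas)
```

herdgwas implements a complete genome-wide association workflow for 305-day
milk production traits (milk, fat and protein yield in kg; fat and protein
content in %) in small, strongly structured dairy cattle populations — herds
of a few thousand cows descending from a few dozen sires, kept on a handful
of farms. Populations like this violate the usual GWAS assumption of weak
relatedness: half-sib families, farm effects and cohort effects inflate test
statistics substantially, and the package's design centres on handling that
inflation with fixed effects and genomic control rather than a mixed model.

This vignette explains the statistical model behind each stage, the tunable
parameters and their defaults, the numerical choices, and what the built-in
simulator does and does not emulate.

## The association model

For each trait--lactation cell (LA1, LA2, LA3 and the lactation mean LAm) and
each variant, the package fits by ordinary least squares

```
Y = ps + f* + s* + by* + bs* + cy* + cs* + ac* + gt + e
```

where `ps` is the population-stratification cluster (categorical, always
included), the starred terms are optional fixed effects — farm, sire, birth
year, birth season, calving year, calving season (categorical) and age at
first calving in days (continuous) — `gt` is the additive minor-allele dosage
(0/1/2) and `e` the residual. The reported effect `beta_MA` is the
allele-substitution effect per copy of the minor allele, in trait units;
relabelling ref/alt alleles flips its sign and changes nothing else.

Rows with a missing response, covariate or dosage are dropped listwise per
trait--lactation cell, so sample sizes differ between lactations exactly as
they do in real milk-recording data. Internally a single
Frisch--Waugh--Lovell projection residualises the phenotype and all complete
dosage columns on the covariates at once; variants with missing calls are
refitted per variant on their complete rows. Both paths are exact OLS (the
tests assert equality with a closed-form normal-equations oracle to 1e-8).

### Covariate selection

Optional effects enter per trait: each candidate is compared singly against
the null model `Y = ps` and included when `AIC(extended) - AIC(null) <= -10`.
The AIC is the Gaussian OLS criterion `n log(2 pi RSS / n) + n + 2 (k + 1)`
(equal to `stats::AIC` on the corresponding `lm` fit, which the tests use as
an oracle). Candidates are never tested jointly — the selection is a set of
single-extension comparisons, not stepwise search. The residual sum of
squares is floored at 1e-12 so saturated toy fits stay finite; collinear
design columns are dropped left-to-right with a warning.

## Population stratification

Relatedness clusters are estimated from the identity-by-state (IBS) matrix:
for each pair, the mean over jointly called variants of `2 - |d_i - d_j|`
(score in [0, 2]; distance `1 - score/2`). Clustering is agglomerative
complete linkage on that distance with a *pairwise population concordance*
(PPC) constraint: two groups may merge only if no cross-group pair is
significantly discordant. The PPC test used here is a two-sided exact
binomial test of the count of sites where both individuals are heterozygous
(IBS2-het) against the count of opposite-homozygote sites (IBS0); under
panmixia these occur 2:1 regardless of allele frequency. The default
forbidding cut-off is p < 1e-5. Merges proceed in ascending distance order
with ties broken by the smallest member index, so the assignment is
deterministic and equivariant under permutation of individuals. The
resulting cluster id is the `ps` covariate.

The concordance test is specified here as the 2:1 exact binomial because
only the testing idea, not a formula, is fixed by the tooling this mirrors;
the two-sided form also forbids merging of *excessively* concordant pairs
(close relatives), which is what makes the clusters relatedness clusters.
A panmictic sample of unrelated animals collapses to a single cluster;
diverged subpopulations and strong families fragment into many.

## Inflation and genomic control

The inflation factor is the classic median-based lambda:
`median(chi2) / qchisq(0.5, 1)` with `chi2 = qchisq(1 - p, 1)`. In a
structured herd lambda well above 1 is expected even with `ps` in the model.
The correction rescales every chi-square statistic within a chromosome class
(autosomes and X separately, per trait--lactation) by `target / lambda_obs`
whenever `lambda_obs > target`, with `target = 1.2` by default; recomputing
lambda on the corrected p-values returns the target to numerical precision.
Two deliberate properties:

* when `lambda_obs <= target` nothing is changed — the correction never makes
  p-values smaller;
* a constant rescaling is rank-preserving within a class, so top-SNP
  identities are unaffected.

## Significance thresholds and QTL regions

Bonferroni thresholds divide each alpha level (0.01 highly significant, 0.05
significant, 0.1 suggestive) by the *effective* number of tests M, estimated
by sliding-window LD pruning: windows of 500 variants advanced by 100
(counts, not kb), and within each window every pair of retained variants with
r-squared > 0.6 loses its lower-MAF member (ties remove the later position).
Removals persist across windows; missing calls are mean-imputed for the
window correlations. Pairwise statistics for reporting (`ld_pair`) compute
r-squared on jointly called dosages and |D'| from two-locus haplotype
frequencies estimated by EM (tolerance 1e-8, max 1000 iterations).

QTL regions are defined in two stages from the corrected results of *all*
traits pooled: (1) suggestive variants on a chromosome are chained by single
linkage with a 2.5 Mb gap; chains with fewer than three pooled variants are
discarded; (2) within each surviving chain, each trait's top SNP (smallest
corrected p, ties to the smaller position) grows a region by repeatedly
adding suggestive variants within 500 kb of the current region bounds —
growth is measured from the bounds, not pairwise from the top SNP. Display
intervals add 100 kb flanks (floored at position 1). Both the per-trait
regions and their per-chain merge are emitted, since summary tables usually
need the merged view while effect plots need the per-trait one.

## Heritability

`build_grm()` uses the allele-frequency-standardised cross-product GRM
`G = Z Z' / (2 sum p (1 - p))` with mean-centred, mean-imputed dosages and a
1e-6 diagonal ridge. `reml_h2()` maximises the restricted likelihood of
`y ~ N(Xb, sg2 G + se2 I)`. Because there is a single genomic kernel, G is
eigendecomposed once and the model rotated into the eigenbasis where the
covariance is diagonal; each iteration is then O(n) plus a small solve,
which keeps n = 1000--2000 fits in seconds. Updates are average-information
steps with an expectation--maximisation fallback whenever an AI step leaves
the parameter space, plus step-halving if the restricted likelihood would
decrease; components are clamped at 1e-8 and convergence is
`|delta logL| < 1e-6` (200 iterations max). `SE(h2)` comes from the inverse
AI matrix by the delta method. With `G = I` the split between the components
is unidentifiable and only their sum (the sample variance) is meaningful;
the fit still converges and reports it.

## The simulator

`sim_config()` + `simulate_herd()` generate a full synthetic study with known
truth, sized by default like the motivating design: ~2000 cows from 37 sires
on 8 farms over 10 birth years.

*Genotypes.* Each chromosome is cut into LD blocks with exponential lengths
(mean `ld_block_mean_kb`, default 100 kb). A block's standing variation comes
from a small set of ancestral haplotypes (default 2) whose alleles are drawn
from the configured spectrum (default: 90% uniform on [0.05, 0.5] plus a 10%
rare tail); a founder pool of 16 haplotypes copies the ancestors with
Dirichlet usage weights — so ancestral segregating sites span the whole
frequency range instead of clustering at multiples of 1/2 — plus a small
per-site copy error (0.005) that contributes a rare-variant tail. Parental
haplotypes pick one founder per block; offspring inherit one haplotype from
their sire and one from their dam with free recombination at block
boundaries. The tiny per-block haplotype diversity is deliberate: it mimics
the long, strong LD of a closed breed with effective population size around
100, gives variants within a block high pairwise r-squared while variants in
different blocks are independent, and creates family structure (half sibs
within sire, occasional full sibs within mating groups) without coalescent
machinery. One consequence worth knowing: rare copy-error sites are in LD
with nothing, exactly like a private sequence variant. Optional cluster
divergence skews each relatedness cluster's founder-sampling weights,
creating allele-frequency divergence; with `cluster_effect_sd > 0` the
phenotype is confounded with the clusters and the no-`ps` model shows lambda
well above 1.2, which is the scenario the genomic-control stage exists for.
The X chromosome, when enabled, is an ordinary diploid chromosome labelled
"X"; it exists so the per-chromosome-class correction path is exercised, not
to model dosage compensation.

*Phenotypes.* Each yield trait gets a genetic value = planted QTL effects
(trait units per ALT allele at the nearest simulated variant) + a polygenic
term from 1000 background markers sampled at least 1 Mb away from any planted
QTL (so local LD cannot contaminate the planted allele-substitution effects).
The polygenic part is orthogonalised against the QTL part and both are
rescaled so the realized narrow-sense heritability equals the configured h2
exactly; residuals are likewise orthogonalised and rescaled per lactation. The three lactations share one
genetic value (scaled by the lactation means), so the cross-lactation
correlation of a trait is approximately its h2 — moderate, as observed in
milk recording. Genetic and residual deviations are correlated (0.8) across
the three yields, giving the high within-lactation yield correlations real
data show, while fat% and protein% (derived as 100 x yield / milk) end up
only weakly correlated. Default means/SDs: milk 6000/900, fat 255/40,
protein 210/30 kg; h2 0.40/0.35/0.35 — inside the ranges milk-recording
studies report. Records get DIM ~ N(330, 45) so a realistic fraction fails
the 270-day full-lactation rule, and lactation presence decays (0.95, 0.80,
0.65) so later lactations have fewer cows.

*What it does not emulate:* genotyping error and imputation artefacts,
selection and drift across generations, dominance/epistasis, X dosage
compensation, test-day curves, and real LD decay shapes within blocks.
Passing recovery tests on these data therefore demonstrates correctness of
the estimators under the stated generative model, not robustness to every
artefact of real chip/WGS data.

## Phenotype preparation rules

* Cohort: cows are kept only if every one of their farm, sire and birth-year
  groups has at least 20 members; removal iterates to a fixed point because
  removals shrink other groups. The filter runs before phenotype derivation.
* Full lactations: records with fewer than 270 days in milk are dropped.
* Contents: fat% and protein% are 100 x yield / milk per lactation (error on
  zero milk).
* Outliers: per trait--lactation column, values strictly outside
  mean +/- 3 SD are set missing; mean and SD are computed once on the input
  (single pass — removed values do not trigger re-screening). The boundary
  value itself is kept. Whether the fence should be pooled across lactations
  is ambiguous in practice; the per-column choice is the conservative one for
  traits whose level shifts between lactations.
* LAm exists only where all three lactations have a value and is their
  arithmetic mean; its calving covariates are taken from the first lactation
  (calving year/season are not defined for a mean record).
* Missing covariates disqualify a cow from the models that need them; nothing
  is imputed.

## Validation set-up and problem sizes

The test suite validates every stage against independent oracles (explicit
normal equations, exhaustive pruning, profile-likelihood D', hand-traced QTL
chains, `stats::AIC`, `binom.test`) and runs end-to-end recovery studies at
sizes chosen to make the checks sharp but fast: the null-calibration study
uses 2000 cows x 20,000 variants with a near-zero-h2 trait (expected: lambda
in [0.95, 1.05] and no variant beyond the Bonferroni threshold from the
pruned M); the recovery study uses 10 replicates of 1500 cows x 12,000
variants on 3 chromosomes of 25 Mb (WGS-like density) with three planted
milk-yield QTL of 0.5, 0.35 and 0.25 phenotypic SD at MAF 0.2--0.4, each
required to have at least two LD partners (r2 >= 0.6) as a sequence-level
causal variant would, and h2 = 0.4 with farm/sire/birth-year as covariate
candidates (expected: each causal variant inside an emitted QTL region in
>= 9/10 replicates, mean absolute effect recovered within 20%, mean GREML h2
within 0.05 of the truth). Under these conditions the raw association scans
show median inflation factors around 1.3--1.7 — the same regime the
genomic-control stage is built for.

## Known limitations

* Fixed-effects-only association: no GRM random effect in the scan itself, by
  design; residual family structure is handled by `ps` plus genomic control,
  which is conservative for true signals in proportion to the correction.
* The PPC clustering is O(n^2) in individuals and intended for herd-scale n
  (thousands), not biobank scale.
* Single genetic variance component; no genetic correlations or breeding
  values.
* `beta_MA` is additive; dominance is only visible qualitatively in the
  genotype-group effect plots (`plot_snp_effect`, pairwise Welch t-tests).
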