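---
title: "Detecting migratory chronotypes from clock-linked genetic variation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting migratory chronotypes from clock-linked genetic variation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chronopop)
```

## The question

Migration counts at a banding station often show allele frequencies at some
loci drifting over the season. Two very different biologies produce that
pattern. Either a single panmictic population harbours heritable *chronotypes*
— consistently early or late individuals — and genotype at timing loci shifts
the expected passage date; or several genetically distinct populations funnel
through the station at different times, so the temporal trend is just
population turnover. `chronopop` implements the full inference chain needed to
tell these apart from SNP genotypes: a relaxed F~ST~ outlier scan to nominate
candidate loci, designability filtering for genotyping assays, ordinal PCA of
candidate-gene genotypes, passage-date association models, weekly
allele-frequency trajectories, mixture-model stock identification, and an
explicit decision rule combining the evidence.

The package is organised as an analysis workflow: each numbered script under
`analysis/` is a thin driver over the functions documented here, writing its
tables under `results/`.

## Stage models and assumptions

### F~ST~ outlier scan

`wc_fst_locus()` and `fst_scan()` compute the Weir–Cockerham (1984) variance
components per biallelic locus — $a$ among groups, $b$ among individuals
within groups, $c$ within individuals — and $\theta = a/(a+b+c)$. The default
grouping pools sampling sites into two classes, migratory/partially-migratory
versus resident, because the behavioural contrast (not site structure) is the
target of the scan; any metadata column can be used instead, which gives the
per-site $r>2$ estimator from the same code path. Negative $\theta$ estimates
are retained in the distribution, as is standard for this estimator;
monomorphic loci ($a+b+c=0$) and loci with fewer than `min_calls = 5` called
genotypes per group are excluded before quantiles are taken. Sites of
ambiguous migratory status can be excluded up front (`exclude_sites`).

`select_outliers()` implements a deliberately permissive percentile rule
(default 0.90, empirical quantile with linear interpolation, ties at the
threshold all included): the goal is to carry forward many loci of potentially
small effect, not to certify individual outliers. `annotate_genes()` maps the
candidates onto gene intervals; loci overlapping several genes count once per
gene in the distinct-gene tally.

### Assay designability

`check_designable()` encodes the four rules used when turning candidate SNPs
into fluidic genotyping assays: GC fraction of a window around the target
must be below 0.65 (failure at $\ge 0.65$; the window is ±50 bases by
default, configurable, since the original rule does not define it); no indel
within 30 bp of the target and no additional SNP within 20 bp, both
distances inclusive — the conservative reading of "within"; and the two
20-base seeds flanking the target must each occur exactly once in the
reference (both strands, exact k-mer lookup). The k-mer lookup is a
deterministic, desk-scale proxy for primer alignment; it does not model
melting temperature, dimers or mismatch-tolerant mapping. Ambiguity bases
(`N`) are excluded from both GC numerator and denominator; an all-`N` window
fails the GC rule conservatively.

### Ordinal PCA

Genotype codes 0/1/2 are ordered but not interval-scaled: the phenotypic
spacing between 0 and 1 copies need not equal that between 1 and 2.
`fit_ordinal_pca()` therefore fits a PRINCALS-style optimal-scaling PCA by
alternating least squares. Each locus's categories receive numeric
quantifications, constrained monotone non-decreasing in allele count and
standardised to mean 0, variance 1 (divisor $n$); object scores and loadings
come from the SVD of the quantified matrix. One sweep alternates (i)
per-locus quantification — category means of the current rank-$d$ model
prediction, projected onto the monotone cone by weighted
pool-adjacent-violators, then standardised — with (ii) the SVD update. The
loss is the mean squared residual between the quantified matrix and its
rank-$d$ reconstruction, equivalently $1 - \sum_{k \le d}\lambda_k/p$; the
trace is checked non-increasing at every iteration and iteration stops when
the change drops below `tol = 1e-8`. Variance accounted for is
$\lambda_k / p \times 100$ with $p$ the number of active loci after drops,
reported alongside that count.

Numerical details worth knowing: initialisation is deterministic (classical
PCA of the standardised numeric codes), so results do not depend on a seed;
a quantification step that pools all categories (zero variance) keeps the
previous quantification, which cannot increase the loss; with binary loci
the monotone constraint is vacuous and the fit equals classical PCA of the
standardised codes to machine precision — a limit the tests assert.
Component signs are arbitrary; `fix_sign()` anchors each dimension so a
chosen locus loads positively. Missing genotypes are imputed to the locus
modal category by default (ties to the smaller code), or samples above 33%
missingness can be dropped; loci monomorphic after imputation are removed
with a warning.

### Timing models

`fit_pc_timing()` regresses capture day-of-year on a PC score with an
optional sex covariate (F = 0, M = 1) and optional PC-by-sex interaction —
the covariate absorbs differential migration between sexes, and the
interaction asks whether the genetic effect differs by sex.
`sex_timing_test()` is the sex-only model. `weekly_frequencies()` bins
migrants into 7-day windows anchored at the earliest capture day (a
convention that is reproducible without a calendar rule), reporting the
counted-allele frequency at each week's midpoint day (bin start + 3) with
binomial standard errors. `repolarize_major()` flips each locus to its major
allele over the full migrant sample — not per week, which would let polarity
flip between bins; frequency exactly 0.5 keeps the original polarity, making
the operation idempotent.

`fit_trend_lrt()` compares a straight-line fit of weekly frequency on
midpoint day against a polynomial (default quadratic — the minimal "curved"
alternative, the degree being an open modelling choice) via the standard
nested-OLS likelihood-ratio test: Gaussian log-likelihoods with
maximum-likelihood variance, $2(\ell_{full}-\ell_{reduced})$ against
$\chi^2_{d-1}$. A point documented rather than hidden: with $w$ weekly
points the statistic equals $w \log(RSS_r/RSS_f)$, an exact monotone
transform of the F statistic, so at the default 12–13 weeks the chi-square
reference is anticonservative — true size $\approx 0.098$ at nominal 0.05
for 12 points ($P\{F_{1,9} > 9(e^{\chi^2_{0.95,1}/12}-1)\}$), and the null
p-values are correspondingly non-uniform. The tests assert this exact
finite-sample law rather than the nominal level. Users wanting exact
calibration at few weeks should use the F test implicit in `anova()` on the
attached `lm` objects; the LRT is provided because it is the conventional
reporting choice for this analysis. Weekly points are unweighted by default;
inverse-variance weighting and a binomial GLM on allele counts are available
as sensitivity options.

### Stock identification

`build_baseline()` tallies counted-allele copies per population × locus over
reference (breeding) samples and forms posterior mean frequencies
$(x + \tfrac12)/(n + 1)$ — a Dirichlet-$\tfrac{1}{A}$ prior per allele with
$A=2$, the conditional-GSI convention, keeping frequencies strictly inside
$(0,1)$ so private alleles never zero out a likelihood. `genotype_loglik()`
is the Hardy–Weinberg product likelihood over called loci;
`mixture_em()` estimates mixture proportions $\pi$ and per-individual origin
posteriors by EM from uniform $\pi$ (E-step in log space with max-shifting;
M-step $\pi_c = \overline{post_{ic}}$), stopping when the observed-data
log-likelihood changes by less than $10^{-8}$. The log-likelihood trace is
checked monotone. "Assigned with certainty" means maximum a posteriori
probability at or above a configurable threshold, default 0.8 — the original
study does not state its cutoff, so the threshold is an explicit parameter
and the posteriors are always reported. `self_assign_loo()` validates a
baseline by leave-one-out self-assignment with per-individual frequency
recomputation. Migrant loci absent from the baseline are dropped with a
message, never imputed.

### The decision rule

`classify_scenario()` formalises the qualitative argument into a re-derivable
verdict from three statistics: the fraction of confidently assigned migrants
mapping to the modal population (threshold `modal_min = 0.9`); latitude
associations of PC1 and the focal loci over breeding samples, Holm-adjusted
across the (default five) tests; and temporal clustering of minority-assigned
migrants (two-sided rank-sum against the modal-assigned; with fewer than 3
minority birds, observed day-range coverage below `coverage_max = 0.25` of
the season counts as clustered, flagged low-power; with none, the criterion
is not applicable). `chronotype_consistent` requires a high modal fraction,
no significant adjusted latitude test, and no minority clustering;
`population_passage_consistent` requires a significant latitude association
*and* minority clustering; anything else is `indeterminate`. All raw
statistics and thresholds travel in the report, so the verdict can be
recomputed from it — a property the tests assert, along with monotonicity in
`modal_min`.

Two design choices here were genuinely open. First, the latitude tests run
over *all* breeding samples rather than only the modal cluster's: restricting
to one cluster would remove precisely the geographic signal that the
population-passage alternative predicts, making that verdict unreachable.
Second, the multiple-testing correction is Holm across the five latitude
tests: without it, the chronotype verdict would fail at roughly the
familywise false-positive rate of ~23% even when the chronotype model is
true. Unadjusted p-values are reported alongside.

## What the generators emulate — and what they do not

`gen_baseline()` draws per-population allele frequencies from the
Balding–Nichols model, Beta$\left(p_0\frac{1-F}{F}, (1-p_0)\frac{1-F}{F}\right)$,
chosen because its divergence parameter *is* the expected F~ST~, which makes
the scan calibratable (the tests check the multi-locus ratio-of-sums
estimate recovers $F$ to ±0.01 at 5000 loci). Genotypes are
Hardy–Weinberg within populations. Planted outlier loci shift the realised
resident-group frequency by exactly `outlier_delta`, so the planted signal
is not diluted by drift noise.

`gen_migration_series()` implements the two scenarios. Chronotype: one
source population; expected capture day = season midpoint
$+\sum_j \beta_j(g_j - 1) + \mathcal{N}(0, \sigma)$, rounded and truncated
to the season (truncation counted in the truth record, not resampled —
resampling would distort the genotype–day relationship at the season edges).
Defaults — 4 timing loci at $\beta = -5$ days per counted-allele copy,
$\sigma = 14$ days, a 92-day season, 165 migrants — were chosen once to give
passage spreads and early-to-late weekly frequency shifts of roughly
0.15–0.3, the visual scale of published station trajectories; they are
parameters, not estimates. Timing-locus genotypes are drawn through a
Gaussian copula sharing a latent chronotype factor (correlation 0.5,
Hardy–Weinberg marginals preserved by quantile thresholding): candidate
clock genes are empirically collinear, and without that collinearity the
leading PC of a small candidate panel would be a noise axis with no timing
information. This is a deliberate exception to the otherwise
linkage-free design. Population-confound: origin is drawn from two sources
(0.8/0.2) with mean passage dates 21 days apart and a planted west–east
frequency differential of 0.3 at the timing loci; genotype has no direct
effect on day.

Real data differ in ways the generators do not model: background linkage
disequilibrium, genotyping error and allele dropout, year effects and
detection-effort variation across weeks, isolation by distance within
clusters (latitude enters only through the two-cluster contrast), selection,
and family structure. Passing the scenario-classification tests therefore
shows the decision logic is sound under its stated model, not that the
thresholds are universally correct for field data.

## Problem sizes and determinism

Every generator is deterministic given its seed. The test suite and the
acceptance script run at desk scale, chosen as the smallest sizes at which
the checked properties are statistically crisp: 1000 random tables for the
F~ST~ oracle equivalence (to 1e-12), 5000 loci for calibration, 50 seeded
replicates per scenario for the disambiguation accuracy (≥90% required),
50 seeds × 200 individuals × 100 loci for mixture-proportion recovery
(mean absolute error < 0.05), 1000 replicates for the LRT null law, and a
285-sample × 9-locus panel for the ordinal-PCA pipeline stages.

## Known limitations

* The percentile outlier rule is intentionally not a significance test; it
  inherits the background distribution of the supplied grouping.
* VAF percentages from optimal scaling are not directly comparable with
  software that normalises the loss differently; the per-component
  eigenvalue/$p$ convention used here is stated explicitly so comparisons
  can be made deliberately.
* The assay uniqueness check is exact k-mer lookup, not alignment.
* The chi-square LRT's finite-sample inflation at few weekly points is
  documented above; single-locus trajectory p-values at 12–13 weeks should
  be read accordingly.
* `minority_spread_test()` conditions on the assignment labels; assignment
  uncertainty is not propagated into its p-value.
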