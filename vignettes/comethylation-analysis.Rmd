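---
title: "Candidate-gene co-methylation analysis: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Candidate-gene co-methylation analysis: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methblocks)
```

# The setting

`methblocks` analyses DNA methylation of a single candidate gene
measured at a small, ordered panel of CpG sites on the Illumina 450k
platform, in a birth cohort observed at two ages (birth and 9 years).
The packaged coordinate frame is a 23-site panel spanning a gene
promoter and body: sites 1–3 in the CpG-island north shore, 4–15 in the
island, 16–17 in the south shore, 18 in the south shelf, 19 in the
5'UTR and 20–23 in the gene body. The pipeline takes normalized beta
values as input; array preprocessing (background correction,
normalization, probe QC, cell-type deconvolution) is upstream and out
of scope.

The analysis stages are:

1. **Transforms and summaries.** Betas (methylated proportion,
   \[0,1\]) are converted to M-values, $M = \log_2\big(\beta/(1-\beta)\big)$,
   which are homoscedastic enough near the extremes to carry all
   statistics; betas are only used for display. Region summaries
   average per-site means within region classes.
2. **Co-methylation blocks.** Pairwise Pearson correlations between
   sites (on M-values), then detection of contiguous windows of
   mutually correlated sites, by analogy with linkage-disequilibrium
   blocks.
3. **Longitudinal structure.** Per-site correlation between birth and
   9-year values in paired children, and region-level age-change tests
   with generalized estimating equations (GEE).
4. **Associations.** Per-site sex differences (pooled-variance t), and
   sex-adjusted linear regressions of birth weight and 9-year BMI
   z-score on site M-values, with a Bonferroni frame for the
   perinatal-covariate screens.
5. **Synthetic cohorts.** A latent-factor generator that reproduces the
   statistical structure the analyses assume, used for calibration and
   parameter-recovery testing throughout the test suite.

# Transforms and region summaries

`beta2m()` clamps betas to $[\varepsilon, 1-\varepsilon]$ with
$\varepsilon = 10^{-6}$ before the logit so the transform stays finite;
exact 0/1 betas do not occur in the packaged tables, and the clamp only
matters for pathological inputs. `m2beta()` is the exact inverse away
from the clamp.

Published per-sex site means are pooled by stratum size
(`pooled_site_mean()`): with 188/185 children per sex at birth and
113/132 at 9 years, the size-weighted mean reproduces every published
region average to one decimal, including the 9-year south shelf value
that a simple average of the sexes misses. Region means then average
the pooled site means equally across a region's sites. Display
rounding is half-away-from-zero (`round_half_up()`), matching how the
reference tables are printed; internal computations are never rounded.

# Block detection

A window of $k \ge 3$ consecutive sites is a *candidate* block when at
least 50% of its $k(k-1)/2$ site pairs have squared Pearson
correlation strictly above 0.4. `find_blocks()` enumerates all
$O(S^2)$ windows (at $S = 23$ there is no need for anything faster),
and reports exactly the *maximal* candidates: those not strictly
contained in another candidate. Two overlapping but non-nested maximal
candidates are both reported, with a warning. Missing correlations
(fewer than 3 complete pairs) count as non-passing pairs, again with a
warning. Correlations are computed on M-values; a `use_betas` flag
exists for sensitivity analyses only.

Two consequences of this definition are worth knowing. First, the
density threshold is compared non-strictly, so a tight block of three
sites whose three internal pairs all pass can be absorbed into a
four-site window at exactly 50% density; maximality then reports the
wider window. Second, a fully correlated block of $k$ sites always
extends by at least one flanking site, because the extended window
retains density $\binom{k}{2}/\binom{k+1}{2} > 1/2$ for $k \ge 3$. In
real panels, where within-block densities are well below 100%, the
reported windows are tight; on idealized equicorrelated blocks the
reported window is systematically one to two sites wider than the
planted one. The test suite measures both behaviours; the package
reports the definition's answer rather than post-processing it,
because any trimming rule would contradict the stated maximality
contract.

`block_conservation()` quantifies cross-age conservation as the best
Jaccard overlap of each block's site set against the other timepoint's
blocks.

# Longitudinal analyses

`site_stability()` correlates birth and 9-year M-values over paired
children per site; p-values come from the usual $t$ transformation of
$r$ with $n-2$ degrees of freedom, which is exact under bivariate
normality — the scale on which the generator draws data.

`gee_fit()` implements Gaussian identity-link GEE with an exchangeable
working correlation and the robust sandwich variance. The working
correlation is the moment estimator from standardized residual
cross-products (denominator $N^* - p$ over within-cluster pairs,
dispersion from the residual sum of squares over $N - p$); estimation
alternates generalized-least-squares coefficient updates (using the
Sherman–Morrison closed form of the exchangeable inverse) with
correlation updates until coefficients move by less than $10^{-8}$,
capped at 50 iterations. The correlation parameter is kept inside its
valid range $(-1/(n_{max}-1), 1)$. No small-sample sandwich correction
is applied: the intended use is cohorts with hundreds of clusters. If
no cluster has repeated observations the fit degrades to the
independence working model with a warning.

On balanced complete two-period data the age-indicator estimate equals
the paired mean difference for *any* working correlation — a useful
exactness check that the test suite asserts to $10^{-10}$, alongside
agreement of the sandwich standard errors with an independently coded
textbook implementation to $10^{-8}$ and a type-I-error simulation at
within-child correlation 0.4.

`gee_age_change()` is run per region on region-mean M-values per
sample-visit (the package's reading of region-level age change; a
per-site run is available by passing single-site values), including
children observed at only one timepoint as singleton clusters, with
normal-reference p-values for the robust z — standard GEE practice.

# Association analyses

Sex differences use the pooled-variance Student's t per site and
timepoint on M-values; group means are displayed as beta percent. A
degenerate zero-variance comparison with equal means returns
$t = 0, p = 1$ rather than failing.

Outcome models regress body size on methylation
(`outcome ~ M + sex`), matching the orientation in which such results
are tabulated; the `reverse` flag fits `M ~ outcome + sex` for
sensitivity. Inference is classical OLS $t$ with $n - 3$ degrees of
freedom and no robust variance. Coefficients are in outcome units per
M-value unit — the interpretation the synthetic generator also uses
when planting effects. The default site subset for outcome models is
1–3 and 16–23, the island-flanking focus; it is configurable.

The multiple-testing frame for the perinatal covariate screens is
Bonferroni over 23 sites × (4 birth + 5 nine-year) variables = 207
tests, adjusted alpha $0.05/207 \approx 2.4\times10^{-4}$.

Missing values are handled complete-case per computation throughout;
how missing array values were treated upstream in the reference
analyses is not stated, and complete-case is the assumption this
package makes.

# The synthetic cohort generator

`generate_cohort()` draws per-site M-values from an additive Gaussian
factor model (see `?synthetic_config` for the formula). Its defaults
define the study conditions used by the test suite and acceptance
script, chosen once:

* **Cohort structure** 373 birth / 245 nine-year observations with 174
  children paired (199 birth-only, 71 year9-only; 444 children in
  all), mirroring the reference cohort.
* **Site means** The logit of the packaged sex-pooled site-mean table,
  per timepoint, so region summaries and age deltas of synthetic data
  sit near the published values.
* **Total per-site M sd 0.4** A typical inter-individual spread for
  450k sites; it also places the planted outcome effects' p-values in
  the published order of magnitude (~0.03 for −0.13 kg per M-unit at
  n = 373; ~0.015 for −0.41 BMI-z per M-unit at n = 240).
* **Correlation structure** A cohort-wide factor gives every pair a
  baseline correlation of 0.1; block factors raise within-block
  correlations to 0.7 (sites 1–3 and 18–23, both timepoints); one
  cross-block loading couples site 1 to the gene-body block at r ≈ 0.3.
* **Cross-age stability** A per-child, per-site effect shared across
  timepoints: share 0.20 at site 1, 0.25 at other block sites, 0.15
  elsewhere. Because variance shares must sum to at most 1, a block
  site with within-block share 0.6 cannot exceed stability ~0.3 in
  this additive model; the published per-site stabilities up to 0.42
  are therefore not all simultaneously representable — a known
  limitation of the factor decomposition.
* **Sex effects** Female-minus-male M shifts at the north-shore sites
  (taken from the packaged by-sex table), zero elsewhere;
  `table2_config()` plants the printed per-sex means at every site.
* **Outcomes** Birthweight centred at 3.46 kg (residual sd 0.47 kg,
  female shift −0.10 kg) and BMI z at 1.11 (residual sd 1.0, no sex
  shift, as z-scores are sex-standardized), with default planted
  effects −0.13/−0.09 (sites 1/20, birthweight) and −0.41/−0.23
  (BMI z). Covariates are drawn independently on their published
  scales and have no methylation effect, matching the reference null
  findings.

The generator emulates the *correlational* structure the analyses
assume — latent-Gaussian M-values, exchangeable within-child
dependence, linear outcome effects. It does not emulate probe-type
artefacts, batch effects, detection failures, cell-composition
confounding, or the skewed/bounded error structure of real betas near
0 and 1. Passing recovery tests on these cohorts therefore shows the
estimators are correct under their assumed model, not that the
assumptions hold in any particular real dataset.

Null configurations used in calibration tests disable *all* sources of
cross-feature dependence — blocks, baseline correlation, stability and
(for the cross-age null) the sex shifts, since a sex effect present at
both visits would itself correlate the timepoints.

# Problem sizes and numerical choices

The test suite and the acceptance script use: 200 random matrices
(S ≤ 12) for block-caller/oracle equivalence; 100 cohorts at n = 370
for block recovery and 100 for the block null; 200 replicates each for
the two outcome-recovery studies (n = 373 and n = 240); 500 GEE
type-I replicates at 250 clusters; 2000 sex-test and 2300
stability-test null replicates. These sizes give Monte-Carlo standard
errors comfortably inside the asserted bands while keeping a full run
in well under a minute.

Other numerical conventions: Pearson correlations use
pairwise-complete observations with a hard minimum of 3 pairs;
`find_blocks()` resolves ties purely by containment; the GEE
correlation estimate is clamped rather than allowed to leave its valid
range (relevant only for degenerate, perfectly correlated residuals);
`beta2m()`'s clamp is $10^{-6}$; equality tolerances quoted above are
asserted in `tests/testthat/`.

# Worked example

```{r example, eval = FALSE}
cfg <- synthetic_config(seed = 1)
cohort <- generate_cohort(cfg)
cm <- meth_cor(as_mvalues(subset_timepoint(cohort$betas, "birth")))
find_blocks(cm)
site_stability(cohort$betas)[1:3, ]
bonferroni_frame()
```

See the README for the same example with its printed output, and
`scripts/acceptance.R` at the repository root for the full
reproduction of the package's headline numbers.
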