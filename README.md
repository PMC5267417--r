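# methblocks

Candidate-gene CpG co-methylation analysis for two-timepoint birth
cohorts.

Epigenetic studies of a candidate gene often measure a small ordered
panel of CpG sites (here: 23 sites spanning a gene promoter and body,
annotated as CpG-island, north/south shore, shelf, 5'UTR and gene body)
on the Illumina 450k array, at birth and again in childhood. The
scientific questions are structural and longitudinal: which neighboring
sites move together ("co-methylation blocks"), how stable is a site's
methylation from birth to age 9, do the sexes differ, and is methylation
associated with body size? `methblocks` implements that full analysis as
a tested, reusable pipeline, plus a synthetic cohort generator so every
stage can be exercised and calibrated without access to cohort data.

## The statistics at its core

* **M-values.** All analyses run on M = log₂(β/(1−β)), the logit of the
  methylated proportion β ∈ [0,1]; betas are reported only for display
  (`beta2m()`, `m2beta()`).
* **Co-methylation blocks.** By analogy with linkage-disequilibrium
  blocks: a window of ≥ 3 contiguous sites is a candidate when ≥ 50% of
  its site pairs have Pearson r² > 0.4; all windows are enumerated and
  the maximal candidates (not strictly contained in another candidate)
  are reported (`meth_cor()`, `find_blocks()`).
* **Cross-age stability.** Per-site Pearson correlation of birth vs
  9-year M-values over paired children, with t-based p-values
  (`site_stability()`).
* **Age change by GEE.** Gaussian identity-link generalized estimating
  equations with an exchangeable working correlation and robust
  sandwich variance, implemented in-package, run on region-mean
  M-values with children as clusters (`gee_fit()`, `gee_age_change()`).
* **Sex and body-size associations.** Pooled-variance Student's t per
  site/timepoint (`sex_ttest()`), and sex-adjusted OLS of birth weight
  or 9-year BMI z-score on site M-values (`outcome_regression()`),
  with a Bonferroni frame of 23 × (4 + 5) = 207 covariate-screen tests
  at adjusted alpha 0.05/207 ≈ 2.4e-4 (`bonferroni_frame()`).
* **Synthetic cohorts.** A latent Gaussian factor model plants block
  correlations, cross-age stability, sex effects and outcome effects
  on the M scale, then maps to betas (`synthetic_config()`,
  `generate_cohort()`).

The package ships the published 23-site manifest
(`pparg_manifest()`), the per-sex site-mean table with stratum sizes
(`methylation_by_sex_fixture()`) and the cohort-characteristics table
(`cohort_characteristics_fixture()`) as plain-text fixtures.

## Worked example

```r
library(methblocks)

cfg <- synthetic_config(seed = 1)   # the default study conditions
cohort <- generate_cohort(cfg)
cohort$betas
#> meth_matrix: 23 probes x 618 sample-visits (beta scale)
#>   timepoints: birth=373, year9=245

# region summaries from the packaged by-sex table
region_summary(site_pooled_means(),
               regions = c("north_shore", "island", "south_shore"))
#>        region timepoint mean_beta_pct n_sites
#> 1 north_shore     birth     61.406613       3
#> 2 north_shore     year9     68.744354       3
#> 3      island     birth      4.504066      12
#> 4      island     year9      4.646803      12
#> 5 south_shore     birth     12.548794       2
#> 6 south_shore     year9     18.819388       2

# block detection on the synthetic birth samples
cm <- meth_cor(as_mvalues(subset_timepoint(cohort$betas, "birth")))
find_blocks(cm)[, 1:4]
#>   start_index end_index n_sites density
#> 1           1         4       4     0.5
#> 2          16        23       8     0.5

# cross-age stability at the north-shore sites
site_stability(cohort$betas)[1:3, ]
#>     probe_id         r n_pairs            p
#> 1 cg01412654 0.3276223     174 1.019963e-05
#> 2 cg25929976 0.3419833     174 3.863745e-06
#> 3 cg18063278 0.2907140     174 9.961452e-05

# GEE age change of the north-shore region mean (M-value units)
rv <- region_mvalues(cohort$betas, pparg_manifest(), "north_shore")
gee_age_change(rv$mean_m, rv$child_id, as.integer(rv$timepoint == "year9"))
#>    estimate  robust_se        z            p n_obs n_clusters   alpha
#> 1 0.4575631 0.02805236 16.31104 8.238036e-60   618        444 0.20934

# sex-adjusted association of site-1 methylation with birth weight
mv <- as_mvalues(subset_timepoint(cohort$betas, "birth"))
sh <- cohort$sheet[cohort$sheet$timepoint == "birth", ]
sh <- sh[match(colnames(mv), sh$sample_visit_id), ]
outcome_regression(sh$birthweight_kg, unclass(mv)[1, ], sh$sex)
#>         beta         se         t           p   n
#> 1 -0.1418734 0.05373761 -2.640114 0.008638631 373
```

Reading the output: the region summary reproduces the published region
averages (e.g. north shore 61.4% at birth); the block scan finds the
two planted correlated regions (reported with one flanking site each —
see the vignette for why the ≥50% pair-density rule extends fully
correlated blocks); the three north-shore sites are significantly
stable from birth to 9 years (r ≈ 0.29–0.34); the north-shore region
mean rises by ≈ 0.46 M-units with age (robust z ≈ 16); and site-1
methylation at birth is inversely associated with birth weight
(−0.14 kg per M-unit here, against a planted −0.13).

There is also a thin command-line wrapper:

```sh
Rscript inst/scripts/methblocks.R simulate --dir synth --seed 1
Rscript inst/scripts/methblocks.R report --betas synth/betas.tsv \
    --manifest synth/manifest.csv --sheet synth/sample_sheet.csv --out report
```

which writes one TSV/JSON per stage plus a structured run log, each
stamped with the package version, configuration hash and seed.

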