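#' Packaged per-sex site-mean methylation table
#'
#' Published per-site mean beta values (%) for the 23 PPARG CpG sites,
#' stratified by sex at both timepoints, with stratum sizes (birth
#' 188 male / 185 female; 9 years 113 male / 132 female). This is the
#' worked example consumed by [site_pooled_means()] and
#' [region_summary()].
#'
#' @return A `data.frame` with 46 rows and columns `order_index`,
#'   `probe_id`, `region`, `timepoint`, `mean_beta_pct_male`,
#'   `mean_beta_pct_female`, `n_male`, `n_female`.
#' @export
methylation_by_sex_fixture <- function() {
  d <- read.csv(system.file("extdata", "pparg_methylation_by_sex.csv",
                            package = "methblocks", mustWork = TRUE),
                stringsAsFactors = FALSE)
  d$region <- factor(d$region, levels = REGION_LEVELS)
  d$timepoint <- factor(d$timepoint, levels = TIMEPOINT_LEVELS)
  stopifnot(nrow(d) == 46)
  d
}

#' Packaged cohort-characteristics table
#'
#' Published cohort summaries (counts, means, ranges and 95% CIs) for the
#' maternal and child covariates and outcomes: gestational age, parity,
#' birth weight, first-six-months weight-gain rate, 9-year BMI and BMI
#' z-score, maternal age and pre-pregnancy BMI. These anchor the
#' synthetic generator's covariate and outcome scales.
#'
#' @return A `data.frame` with columns `characteristic`, `n`, `mean`,
#'   `range_min`, `range_max`, `ci_lo`, `ci_hi`.
#' @export
cohort_characteristics_fixture <- function() {
  read.csv(system.file("extdata", "cohort_characteristics.csv",
                       package = "methblocks", mustWork = TRUE),
           stringsAsFactors = FALSE)
}
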