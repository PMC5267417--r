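#' Beta / M-value conversion
#'
#' The M-value is the logit (base 2) of the methylated proportion:
#' `M = log2(beta / (1 - beta))`. M-values are the analysis scale
#' throughout this package because betas are heteroscedastic near 0 and
#' 1. Betas within `eps` of 0 or 1 are clamped to `[eps, 1 - eps]` so the
#' transform stays finite; betas outside `[0, 1]` are an error.
#'
#' @param beta numeric vector/matrix of proportions in `[0,1]`.
#' @param m numeric vector/matrix of M-values (finite).
#' @param eps clamping epsilon for extreme betas (default `1e-6`).
#' @return `beta2m()` returns M-values; `m2beta()` returns proportions in
#'   `(0,1)`. The two are inverse to each other away from the clamp.
#' @examples
#' beta2m(0.5)   # 0
#' beta2m(0.8)   # 2
#' m2beta(2.0)   # 0.8
#' @export
beta2m <- function(beta, eps = 1e-6) {
  if (any(beta < 0 | beta > 1, na.rm = TRUE))
    stop("beta values must lie in [0, 1]")
  b <- pmin(pmax(beta, eps), 1 - eps)
  log2(b / (1 - b))
}

#' @rdname beta2m
#' @export
m2beta <- function(m) {
  if (any(!is.finite(m) & !is.na(m)))
    stop("M-values must be finite")
  1 / (1 + 2^(-m))
}

#' Convert a methylation matrix between scales
#' @param x a [meth_matrix()].
#' @param eps clamping epsilon passed to [beta2m()].
#' @return A [meth_matrix()] on the requested scale (no-op if already).
#' @export
as_mvalues <- function(x, eps = 1e-6) {
  stopifnot(inherits(x, "meth_matrix"))
  if (meth_scale(x) == "mvalue") return(x)
  meth_matrix(beta2m(unclass(x), eps = eps), scale = "mvalue",
              timepoint = timepoints(x))
}

#' @rdname as_mvalues
#' @export
as_betas <- function(x) {
  stopifnot(inherits(x, "meth_matrix"))
  if (meth_scale(x) == "beta") return(x)
  meth_matrix(m2beta(unclass(x)), scale = "beta",
              timepoint = timepoints(x))
}

#' Pool per-sex site means by stratum size
#'
#' Size-weighted mean of the male and female strata:
#' `(male * n_male + female * n_female) / (n_male + n_female)`. With
#' equal stratum sizes this is the simple average. This pooling
#' convention reproduces the published region averages from the per-sex
#' table to one decimal.
#'
#' @param male,female per-site stratum means (any common unit; vectorized).
#' @param n_male,n_female positive stratum sizes.
#' @return Pooled means in the input unit.
#' @examples
#' pooled_site_mean(65.8, 67.8, 188, 185)  # 66.79 -> "66.8"
#' @export
pooled_site_mean <- function(male, female, n_male, n_female) {
  if (any(n_male <= 0) || any(n_female <= 0))
    stop("stratum sizes must be positive")
  (male * n_male + female * n_female) / (n_male + n_female)
}

#' Per-site sex-pooled means from the by-sex fixture
#'
#' @param fixture a by-sex table as returned by
#'   [methylation_by_sex_fixture()].
#' @return A `data.frame` with one row per site x timepoint and a
#'   `mean_beta_pct` column of size-weighted pooled means.
#' @export
site_pooled_means <- function(fixture = methylation_by_sex_fixture()) {
  out <- fixture[, c("order_index", "probe_id", "region", "timepoint")]
  out$mean_beta_pct <- pooled_site_mean(fixture$mean_beta_pct_male,
                                        fixture$mean_beta_pct_female,
                                        fixture$n_male, fixture$n_female)
  out
}

#' Region-level mean methylation
#'
#' Unweighted mean over a region's sites of the per-site pooled means,
#' reported in percent. `region = "all"` averages over every site (the
#' grand mean).
#'
#' @param site_means a `data.frame` as from [site_pooled_means()]
#'   (columns `region`, `timepoint`, `mean_beta_pct`).
#' @param region a region class, or `"all"`.
#' @param timepoint `"birth"` or `"year9"`.
#' @return A one-row `data.frame`: `region`, `timepoint`, `mean_beta_pct`,
#'   `n_sites`.
#' @examples
#' region_mean_beta(site_pooled_means(), "north_shore", "birth")
#' @export
region_mean_beta <- function(site_means, region, timepoint) {
  timepoint <- match.arg(timepoint, TIMEPOINT_LEVELS)
  region <- match.arg(region, c(REGION_LEVELS, "all"))
  keep <- site_means$timepoint == timepoint
  if (region != "all") keep <- keep & site_means$region == region
  vals <- site_means$mean_beta_pct[keep]
  if (!length(vals)) stop("no sites for region ", region, " at ", timepoint)
  data.frame(region = region, timepoint = timepoint,
             mean_beta_pct = mean(vals), n_sites = length(vals))
}

#' Region summary table over all regions and timepoints
#'
#' @param site_means as in [region_mean_beta()].
#' @param regions which regions to summarise (default all six plus the
#'   grand mean `"all"`).
#' @return A `data.frame` with one row per region x timepoint.
#' @export
region_summary <- function(site_means = site_pooled_means(),
                           regions = c(REGION_LEVELS, "all")) {
  do.call(rbind, lapply(regions, function(rg)
    do.call(rbind, lapply(TIMEPOINT_LEVELS, function(tp)
      region_mean_beta(site_means, rg, tp)))))
}

#' Age change of a region mean
#'
#' Difference of region means, 9 years minus birth, in percentage points.
#'
#' @param summary_birth,summary_year9 one-row data frames as returned by
#'   [region_mean_beta()], for the same region.
#' @return The difference (percentage points).
#' @export
region_age_delta <- function(summary_birth, summary_year9) {
  if (!identical(as.character(summary_birth$region),
                 as.character(summary_year9$region)))
    stop("region mismatch: ", summary_birth$region, " vs ",
         summary_year9$region)
  if (summary_birth$timepoint != "birth" ||
      summary_year9$timepoint != "year9")
    stop("summaries must be (birth, year9) in that order")
  summary_year9$mean_beta_pct - summary_birth$mean_beta_pct
}

#' Round half away from zero (display convention)
#'
#' Published tables round halves away from zero; base R's `round()`
#' rounds half to even. Internal computations are never rounded.
#'
#' @param x numeric.
#' @param digits decimal places.
#' @return Rounded numeric.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
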