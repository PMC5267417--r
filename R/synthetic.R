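#' Configuration for the synthetic two-timepoint cohort generator
#'
#' The generator draws per-site M-values from an additive Gaussian
#' factor model and maps them to betas by the inverse-logit of the
#' M-value formula. For child `i`, site `j`, timepoint `t`:
#'
#' ```
#' m_ijt = mu_jt + gamma_jt (female_i - 1/2)
#'         + sigma_j [ sqrt(a_g) g_it + sqrt(a_bj) f_b(j),it
#'                     + c_j f_link(j),it + sqrt(s_j) u_ij
#'                     + sqrt(1 - a_g - a_bj - c_j^2 - s_j) e_ijt ]
#' ```
#'
#' with independent standard-normal factors: `g` a cohort-wide factor
#' shared by all sites (baseline inter-site correlation `base_cor`),
#' `f_b` block factors (sites of block `b` gain pairwise correlation up
#' to the block's target `r`), `u` a per-child per-site effect shared
#' across timepoints (cross-age stability `s_j`), and `e` residual
#' noise. A `cross_block_links` entry gives one site an extra loading on
#' another block's factor, coupling it to that block's sites. Variance
#' shares must sum to at most 1 per site; this positive
#' semi-definiteness check runs at construction and failing it is an
#' error.
#'
#' Body-size outcomes are drawn as
#' `y_i = mean + sum_e beta_e (m_i,site(e),t(e) - mu_site(e),t(e)) +
#' delta * (female_i - 1/2) + noise`, with birthweight centred at
#' 3.46 kg and 9-year BMI z-score at 1.11. Covariates (gestational age,
#' maternal age, maternal pre-pregnancy BMI, parity, weight-gain rate)
#' are drawn independently on their published scales and have no effect
#' on methylation.
#'
#' @param n_birth,n_year9,n_paired cohort structure (defaults 373 / 245 /
#'   174; `n_paired <= min(n_birth, n_year9)`).
#' @param manifest a [cpg_manifest()] (default [pparg_manifest()]).
#' @param site_means S x 2 matrix of per-site mean M-values (columns
#'   birth, year9). Default: [beta2m()] of the sex-pooled packaged
#'   site-mean table.
#' @param sex_effects S x 2 matrix of female-minus-male M shifts.
#'   Default: the packaged north-shore sex gaps, 0 elsewhere.
#' @param blocks list of block definitions, each
#'   `list(sites =, r_birth =, r_year9 =)` (total within-block pairwise
#'   correlation). Default: sites 1-3 and 18-23 at r = 0.7 for both
#'   timepoints.
#' @param base_cor baseline correlation between all site pairs
#'   (default 0.1); this is also the cross-block correlation.
#' @param cross_block_links list of `list(site =, block =, r =)`: extra
#'   coupling of one site to another block's sites at total pairwise
#'   correlation `r`. Default: site 1 to block 2 at r = 0.3.
#' @param stability length-S vector of cross-age correlations `s_j`.
#'   Default: 0.20 at site 1, 0.25 at other block sites, 0.15 elsewhere.
#' @param age_shift length-S vector added to year-9 means (default 0;
#'   the default `site_means` already carry the observed age increase).
#' @param noise_sd per-site total M-value standard deviation `sigma_j`
#'   (scalar or length S; default 0.4).
#' @param outcome_effects data frame `site`, `outcome`
#'   (`birthweight_kg`/`bmi_z`), `beta` (outcome units per M-unit).
#'   Default: site 1 at -0.13 and site 20 at -0.09 on birthweight;
#'   site 1 at -0.41 and site 20 at -0.23 on BMI z.
#' @param outcome_sd named vector, residual sd of the outcomes
#'   (defaults: birthweight 0.47 kg, BMI z 1.0).
#' @param outcome_sex_effect named vector, female-minus-male outcome
#'   shift (defaults: birthweight -0.10 kg, BMI z 0).
#' @param seed integer seed making [generate_cohort()] deterministic.
#' @return A list of class `synthetic_config` (with a `shares` matrix of
#'   the per-site variance decomposition).
#' @export
synthetic_config <- function(n_birth = 373, n_year9 = 245, n_paired = 174,
                             manifest = pparg_manifest(),
                             site_means = NULL, sex_effects = NULL,
                             blocks = NULL, base_cor = 0.1,
                             cross_block_links = NULL, stability = NULL,
                             age_shift = NULL, noise_sd = 0.4,
                             outcome_effects = NULL,
                             outcome_sd = c(birthweight_kg = 0.47, bmi_z = 1.0),
                             outcome_sex_effect = c(birthweight_kg = -0.10,
                                                    bmi_z = 0),
                             seed = 1L) {
  S <- nrow(manifest)
  if (n_paired > min(n_birth, n_year9))
    stop("n_paired cannot exceed min(n_birth, n_year9)")
  fixture_defaults <- S == 23 &&
    identical(manifest$probe_id, pparg_manifest()$probe_id)
  if (is.null(site_means)) {
    if (!fixture_defaults)
      stop("site_means must be given for a non-default manifest")
    pm <- site_pooled_means()
    site_means <- cbind(
      birth = beta2m(pm$mean_beta_pct[pm$timepoint == "birth"] / 100),
      year9 = beta2m(pm$mean_beta_pct[pm$timepoint == "year9"] / 100))
  }
  site_means <- as.matrix(site_means)
  if (!all(dim(site_means) == c(S, 2)))
    stop("site_means must be S x 2 (birth, year9)")
  colnames(site_means) <- c("birth", "year9")
  if (is.null(sex_effects)) {
    sex_effects <- matrix(0, S, 2)
    if (fixture_defaults) {
      fx <- methylation_by_sex_fixture()
      ns <- which(manifest$region == "north_shore")
      for (tp in 1:2) {
        sub <- fx[fx$timepoint == TIMEPOINT_LEVELS[tp], ]
        sub <- sub[order(sub$order_index), ]
        gap <- beta2m(sub$mean_beta_pct_female / 100) -
          beta2m(sub$mean_beta_pct_male / 100)
        sex_effects[ns, tp] <- gap[ns]
      }
    }
  }
  sex_effects <- as.matrix(sex_effects)
  if (!all(dim(sex_effects) == c(S, 2)))
    stop("sex_effects must be S x 2")
  colnames(sex_effects) <- c("birth", "year9")
  if (is.null(blocks))
    blocks <- list(list(sites = 1:3, r_birth = 0.7, r_year9 = 0.7),
                   list(sites = 18:23, r_birth = 0.7, r_year9 = 0.7))
  blocks <- lapply(blocks, function(b) {
    if (is.null(b$r_birth)) b$r_birth <- b$r
    if (is.null(b$r_year9)) b$r_year9 <- b$r
    stopifnot(all(b$sites >= 1 & b$sites <= S),
              identical(b$sites, min(b$sites):max(b$sites)))
    b
  })
  if (is.null(cross_block_links)) {
    cross_block_links <- if (length(blocks) >= 2 && fixture_defaults)
      list(list(site = 1, block = 2, r = 0.3)) else list()
  }
  if (is.null(stability)) {
    stability <- rep(0.15, S)
    block_sites <- unlist(lapply(blocks, `[[`, "sites"))
    stability[intersect(block_sites, seq_len(S))] <- 0.25
    if (length(cross_block_links))
      for (lk in cross_block_links) stability[lk$site] <- 0.20
  }
  stability <- rep_len(stability, S)
  if (is.null(age_shift)) age_shift <- rep(0, S)
  age_shift <- rep_len(age_shift, S)
  noise_sd <- rep_len(noise_sd, S)
  if (any(noise_sd < 0)) stop("noise_sd must be nonnegative")
  if (is.null(outcome_effects))
    outcome_effects <- data.frame(
      site = c(1, 20, 1, 20),
      outcome = c("birthweight_kg", "birthweight_kg", "bmi_z", "bmi_z"),
      beta = c(-0.13, -0.09, -0.41, -0.23))

  # variance-share decomposition (per site x timepoint); PSD check
  shares <- array(0, dim = c(S, 2, 4),
                  dimnames = list(NULL, c("birth", "year9"),
                                  c("global", "block", "link", "child")))
  shares[, , "global"] <- base_cor
  for (b in blocks) {
    shares[b$sites, "birth", "block"] <- b$r_birth - base_cor
    shares[b$sites, "year9", "block"] <- b$r_year9 - base_cor
  }
  for (lk in cross_block_links) {
    tgt <- blocks[[lk$block]]
    for (tp in c("birth", "year9")) {
      a_b <- if (tp == "birth") tgt$r_birth else tgt$r_year9
      a_b <- a_b - base_cor
      if (a_b <= 0) stop("cross_block_links target block has no factor")
      c_load <- (lk$r - base_cor) / sqrt(a_b)
      shares[lk$site, tp, "link"] <- c_load^2
    }
  }
  shares[, , "child"] <- stability
  if (any(shares < 0))
    stop("implied latent covariance is not positive semi-definite ",
         "(negative variance share; is a block r below base_cor?)")
  resid <- 1 - apply(shares, c(1, 2), sum)
  if (any(resid < -1e-12))
    stop("implied latent covariance is not positive semi-definite ",
         "(variance shares exceed 1 at site ",
         paste(which(apply(resid, 1, min) < -1e-12), collapse = ", "), ")")

  structure(list(n_birth = n_birth, n_year9 = n_year9, n_paired = n_paired,
                 manifest = manifest, site_means = site_means,
                 sex_effects = sex_effects, blocks = blocks,
                 base_cor = base_cor, cross_block_links = cross_block_links,
                 stability = stability, age_shift = age_shift,
                 noise_sd = noise_sd, outcome_effects = outcome_effects,
                 outcome_sd = outcome_sd,
                 outcome_sex_effect = outcome_sex_effect,
                 shares = shares, resid_share = pmax(resid, 0),
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat(sprintf("synthetic_config: %d sites; %d birth / %d year9 (%d paired)\n",
              nrow(x$manifest), x$n_birth, x$n_year9, x$n_paired))
  for (b in x$blocks)
    cat(sprintf("  block %d-%d: r = %.2f (birth) / %.2f (year9)\n",
                min(b$sites), max(b$sites), b$r_birth, b$r_year9))
  cat(sprintf("  base correlation %.2f; noise sd %.2f; seed %d\n",
              x$base_cor, x$noise_sd[1], x$seed))
  invisible(x)
}

#' Generate a synthetic two-timepoint cohort
#'
#' Draws the latent per-child methylation panel and observed cohort
#' described by a [synthetic_config()]: a beta-scale [meth_matrix()]
#' over the observed sample-visits (paired children appear at both
#' timepoints, the remainder at one) and a sample sheet with sex,
#' perinatal covariates and the two body-size outcomes. Deterministic
#' given the config seed.
#'
#' @param config a [synthetic_config()].
#' @param seed overrides `config$seed` if given.
#' @return A list: `betas` (a [meth_matrix()]), `sheet` (a sample-sheet
#'   `data.frame`).
#' @export
generate_cohort <- function(config, seed = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  if (is.null(seed)) seed <- config$seed
  set.seed(seed)
  S <- nrow(config$manifest)
  n_children <- config$n_birth + config$n_year9 - config$n_paired
  child_id <- sprintf("child%04d", seq_len(n_children))
  # children 1..n_paired have both visits, then birth-only, then year9-only
  has_birth <- seq_len(n_children) <= config$n_birth
  has_year9 <- seq_len(n_children) <= config$n_paired |
    seq_len(n_children) > config$n_birth
  female <- rbinom(n_children, 1, 0.5)

  n_blocks <- length(config$blocks)
  sigma <- config$noise_sd
  m <- array(NA_real_, dim = c(S, n_children, 2),
             dimnames = list(config$manifest$probe_id, child_id,
                             TIMEPOINT_LEVELS))
  u <- matrix(rnorm(S * n_children), S, n_children)  # child effects
  for (tp in 1:2) {
    tpn <- TIMEPOINT_LEVELS[tp]
    g <- rnorm(n_children)
    f <- matrix(rnorm(n_blocks * n_children), max(n_blocks, 1), n_children)
    e <- matrix(rnorm(S * n_children), S, n_children)
    load_f <- matrix(0, S, max(n_blocks, 1))
    for (bi in seq_along(config$blocks)) {
      b <- config$blocks[[bi]]
      load_f[b$sites, bi] <- sqrt(config$shares[b$sites[1], tpn, "block"])
    }
    for (lk in config$cross_block_links)
      load_f[lk$site, lk$block] <- load_f[lk$site, lk$block] +
        sqrt(config$shares[lk$site, tpn, "link"])
    lat <- sqrt(config$shares[, tpn, "global"]) %o% g +
      (if (n_blocks) load_f %*% f else 0) +
      sqrt(config$shares[, tpn, "child"]) * u +
      sqrt(config$resid_share[, tpn]) * e
    mu <- config$site_means[, tpn] +
      (if (tpn == "year9") config$age_shift else 0)
    m[, , tp] <- mu + config$sex_effects[, tpn] %o% (female - 0.5) +
      sigma * lat
  }

  # observed matrix
  cols <- c(paste0(child_id[has_birth], ":birth"),
            paste0(child_id[has_year9], ":year9"))
  vals <- cbind(m[, , "birth"][, has_birth, drop = FALSE],
                m[, , "year9"][, has_year9, drop = FALSE])
  colnames(vals) <- cols
  betas <- meth_matrix(m2beta(vals), scale = "beta",
                       manifest = config$manifest)

  # outcomes from the latent panel
  outcome_for <- function(name, tpn) {
    eff <- config$outcome_effects[config$outcome_effects$outcome == name, ]
    y <- rep(0, n_children)
    for (k in seq_len(nrow(eff)))
      y <- y + eff$beta[k] *
        (m[eff$site[k], , tpn] - config$site_means[eff$site[k], tpn])
    y + config$outcome_sex_effect[[name]] * (female - 0.5) +
      rnorm(n_children, 0, config$outcome_sd[[name]])
  }
  birthweight <- 3.46 + outcome_for("birthweight_kg", "birth")
  bmi_z <- 1.11 + outcome_for("bmi_z", "year9")
  bmi_z[!has_year9] <- NA_real_

  covars <- data.frame(
    child_id = child_id,
    sex = SEX_LEVELS[female + 1],
    gestational_age_wk = round(rnorm(n_children, 38.9, 1.7), 1),
    maternal_age_yr = round(rnorm(n_children, 25.6, 5.0), 1),
    maternal_bmi = round(rnorm(n_children, 27.0, 4.5), 1),
    parity = rpois(n_children, 1.3),
    weight_gain_kg_per_mo = round(rnorm(n_children, 0.73, 0.15), 3),
    birthweight_kg = round(birthweight, 3),
    bmi_z = round(bmi_z, 3))

  sheet <- rbind(
    transform(covars[has_birth, ], timepoint = "birth"),
    transform(covars[has_year9, ], timepoint = "year9"))
  sheet <- validate_sample_sheet(sheet)
  rownames(sheet) <- NULL
  list(betas = betas, sheet = sheet)
}

#' Generator configuration reproducing the packaged by-sex table
#'
#' A [synthetic_config()] whose site means and sex effects are taken
#' from the packaged per-sex site-mean table at every site, so that the
#' noise-free expectations reproduce the published per-sex betas and the
#' sex-pooled means.
#'
#' @param ... overrides passed to [synthetic_config()].
#' @return A `synthetic_config`.
#' @export
table2_config <- function(...) {
  fx <- methylation_by_sex_fixture()
  get_m <- function(tp, col) {
    sub <- fx[fx$timepoint == tp, ]
    sub <- sub[order(sub$order_index), ]
    beta2m(sub[[col]] / 100)
  }
  m_male <- cbind(birth = get_m("birth", "mean_beta_pct_male"),
                  year9 = get_m("year9", "mean_beta_pct_male"))
  m_female <- cbind(birth = get_m("birth", "mean_beta_pct_female"),
                    year9 = get_m("year9", "mean_beta_pct_female"))
  synthetic_config(site_means = (m_male + m_female) / 2,
                   sex_effects = m_female - m_male, ...)
}

#' Noise-free expected betas of a configuration
#'
#' The inverse-logit of the configured mean M-values: the betas a
#' zero-noise cohort would show, by site, timepoint and (optionally) sex.
#'
#' @param config a [synthetic_config()].
#' @param sex `"pooled"`, `"male"` or `"female"`.
#' @return S x 2 matrix of betas in `[0,1]`.
#' @export
expected_betas <- function(config, sex = c("pooled", "male", "female")) {
  sex <- match.arg(sex)
  shift <- switch(sex, pooled = 0, male = -0.5, female = 0.5)
  m2beta(config$site_means + shift * config$sex_effects)
}
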