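#' Student's t-test for a sex difference at one site
#'
#' Pooled-variance two-sample t-test of M-values between males and
#' females, two-sided. If the pooled variance is zero and the group
#' means are equal the test is degenerate and `t = 0, p = 1` is
#' returned; zero pooled variance with unequal means is an error.
#'
#' @param m_male,m_female numeric M-value vectors (each of length >= 2
#'   after dropping missing values).
#' @return A one-row `data.frame`: `t`, `df`, `p`, `mean_male`,
#'   `mean_female`, `n_male`, `n_female`.
#' @examples
#' sex_ttest(c(1, 2, 3), c(2, 3, 4))  # t = -1.2247, df = 4
#' @export
sex_ttest <- function(m_male, m_female) {
  m_male <- m_male[!is.na(m_male)]
  m_female <- m_female[!is.na(m_female)]
  n1 <- length(m_male); n2 <- length(m_female)
  if (n1 < 2 || n2 < 2) stop("each group needs at least 2 observations")
  sp2 <- ((n1 - 1) * var(m_male) + (n2 - 1) * var(m_female)) / (n1 + n2 - 2)
  if (sp2 <= .Machine$double.eps) {
    if (abs(mean(m_male) - mean(m_female)) <= .Machine$double.eps^0.5) {
      return(data.frame(t = 0, df = n1 + n2 - 2, p = 1,
                        mean_male = mean(m_male),
                        mean_female = mean(m_female),
                        n_male = n1, n_female = n2))
    }
    stop("zero pooled variance with unequal means")
  }
  tt <- t.test(m_male, m_female, var.equal = TRUE)
  data.frame(t = unname(tt$statistic), df = unname(tt$parameter),
             p = tt$p.value, mean_male = mean(m_male),
             mean_female = mean(m_female), n_male = n1, n_female = n2)
}

#' Per-site sex-difference table
#'
#' Runs [sex_ttest()] on M-values for every site at a given timepoint
#' and reports group means back-transformed to beta percent for display,
#' as published tables do.
#'
#' @param x a [meth_matrix()].
#' @param sheet a sample sheet (see [read_sample_sheet()]).
#' @param timepoint `"birth"` or `"year9"`.
#' @return A `data.frame` with one row per site: `probe_id`, `timepoint`,
#'   `mean_beta_pct_male`, `mean_beta_pct_female`, `t`, `df`, `p`.
#' @export
sex_diff_table <- function(x, sheet, timepoint) {
  timepoint <- match.arg(timepoint, TIMEPOINT_LEVELS)
  xm <- as_mvalues(subset_timepoint(x, timepoint))
  sh <- sheet[sheet$timepoint == timepoint, ]
  cols <- intersect(colnames(xm), sh$sample_visit_id)
  sh <- sh[match(cols, sh$sample_visit_id), ]
  v <- unclass(xm)[, cols, drop = FALSE]
  male <- sh$sex == "male"
  out <- do.call(rbind, lapply(seq_len(nrow(v)), function(s) {
    tt <- sex_ttest(v[s, male], v[s, !male])
    data.frame(probe_id = rownames(v)[s], timepoint = timepoint,
               mean_beta_pct_male = 100 * m2beta(tt$mean_male),
               mean_beta_pct_female = 100 * m2beta(tt$mean_female),
               t = tt$t, df = tt$df, p = tt$p)
  }))
  rownames(out) <- NULL
  out
}

#' Sex-adjusted regression of a body-size outcome on site methylation
#'
#' Ordinary least squares `outcome ~ methylation + sex`; the reported
#' coefficient is the change in the outcome per unit M-value, with its
#' classical SE and two-sided t p-value (`n - 3` df). A `reverse` flag
#' fits `methylation ~ outcome + sex` instead for sensitivity.
#'
#' @param outcome numeric outcome (e.g. birthweight in kg, BMI z-score).
#' @param m site M-values.
#' @param sex 0/1 indicator (or `male`/`female` character; female = 1).
#' @param reverse regress methylation on the outcome instead.
#' @return A one-row `data.frame`: `beta`, `se`, `t`, `p`, `n`.
#' @export
outcome_regression <- function(outcome, m, sex, reverse = FALSE) {
  if (is.character(sex) || is.factor(sex))
    sex <- as.integer(as.character(sex) == "female")
  ok <- complete.cases(outcome, m, sex)
  if (sum(ok) < 4) stop("need at least 4 complete cases")
  d <- data.frame(y = outcome[ok], m = m[ok], sex = sex[ok])
  fit <- if (reverse) lm(m ~ y + sex, data = d) else lm(y ~ m + sex, data = d)
  if (any(is.na(coef(fit)))) stop("collinear design")
  sm <- summary(fit)$coefficients
  term <- if (reverse) "y" else "m"
  data.frame(beta = sm[term, "Estimate"], se = sm[term, "Std. Error"],
             t = sm[term, "t value"], p = sm[term, "Pr(>|t|)"],
             n = nrow(d))
}

#' Per-site screen of methylation against a perinatal covariate
#'
#' Simple linear regression of each site's M-values on one covariate.
#' Sites are flagged significant only when the p-value is below the
#' Bonferroni-adjusted alpha of the supplied testing frame.
#'
#' @param m_matrix sites x samples numeric matrix of M-values (or a
#'   [meth_matrix()], converted internally).
#' @param covariate numeric covariate per sample.
#' @param frame a [bonferroni_frame()].
#' @return A `data.frame` per site: `probe_id`, `slope`, `se`, `p`,
#'   `n`, `flagged`.
#' @export
covariate_screen <- function(m_matrix, covariate, frame = bonferroni_frame()) {
  if (inherits(m_matrix, "meth_matrix"))
    m_matrix <- unclass(as_mvalues(m_matrix))
  if (sd(covariate, na.rm = TRUE) == 0 || all(is.na(covariate)))
    stop("constant covariate")
  out <- do.call(rbind, lapply(seq_len(nrow(m_matrix)), function(s) {
    ok <- complete.cases(m_matrix[s, ], covariate)
    if (sum(ok) < 4) stop("need at least 4 complete cases")
    fit <- lm(m_matrix[s, ok] ~ covariate[ok])
    sm <- summary(fit)$coefficients
    data.frame(probe_id = if (!is.null(rownames(m_matrix)))
                 rownames(m_matrix)[s] else paste0("site", s),
               slope = sm[2, "Estimate"], se = sm[2, "Std. Error"],
               p = sm[2, "Pr(>|t|)"], n = sum(ok))
  }))
  out$flagged <- out$p < frame$adjusted_alpha
  rownames(out) <- NULL
  out
}

#' Bonferroni multiple-testing frame
#'
#' The family of covariate-screen tests: each site is tested against
#' `n_vars_birth` variables at birth and `n_vars_year9` variables at
#' 9 years, giving `n_sites * (n_vars_birth + n_vars_year9)` tests and
#' an adjusted alpha of `0.05 / n_tests`. The default frame (23 sites,
#' 4 birth variables, 5 nine-year variables) gives 207 tests.
#'
#' @param n_sites number of CpG sites (default 23).
#' @param n_vars_birth variables tested at birth (default 4).
#' @param n_vars_year9 variables tested at 9 years (default 5).
#' @param alpha family-wise alpha (default 0.05).
#' @return A one-row `data.frame`: `n_sites`, `n_vars_birth`,
#'   `n_vars_year9`, `n_tests`, `adjusted_alpha`.
#' @examples
#' bonferroni_frame()  # 207 tests, adjusted alpha 2.4e-4
#' @export
bonferroni_frame <- function(n_sites = 23, n_vars_birth = 4,
                             n_vars_year9 = 5, alpha = 0.05) {
  if (n_sites <= 0 || n_vars_birth < 0 || n_vars_year9 < 0 ||
      n_vars_birth + n_vars_year9 <= 0)
    stop("counts must be positive")
  n_tests <- n_sites * (n_vars_birth + n_vars_year9)
  data.frame(n_sites = n_sites, n_vars_birth = n_vars_birth,
             n_vars_year9 = n_vars_year9, n_tests = n_tests,
             adjusted_alpha = alpha / n_tests)
}
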