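test_that("configuration validates cohort structure and covariance", {
  expect_error(synthetic_config(n_paired = 300, n_year9 = 245),
               "n_paired")
  # variance shares beyond 1 (block 0.6 + base 0.1 + stability 0.5)
  expect_error(synthetic_config(stability = rep(0.5, 23)),
               "positive semi-definite")
  # block r below the baseline correlation
  expect_error(synthetic_config(
    blocks = list(list(sites = 1:3, r = 0.05))),
    "positive semi-definite")
  cfg <- synthetic_config()
  expect_s3_class(cfg, "synthetic_config")
  expect_true(all(cfg$resid_share >= 0))
})

test_that("zero-noise, zero-effect cohorts sit exactly at the site means", {
  cfg <- synthetic_config(n_birth = 10, n_year9 = 8, n_paired = 5,
                          noise_sd = 0, sex_effects = matrix(0, 23, 2),
                          outcome_effects = data.frame(
                            site = 1, outcome = "birthweight_kg", beta = 0))
  co <- generate_cohort(cfg)
  want <- expected_betas(cfg)
  b <- unclass(subset_timepoint(co$betas, "birth"))
  expect_equal(b, matrix(want[, "birth"], 23, ncol(b),
                         dimnames = dimnames(b)),
               tolerance = 1e-12, ignore_attr = TRUE)
  y <- unclass(subset_timepoint(co$betas, "year9"))
  expect_equal(y, matrix(want[, "year9"], 23, ncol(y),
                         dimnames = dimnames(y)),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("generation is deterministic given the seed", {
  cfg <- synthetic_config(n_birth = 40, n_year9 = 30, n_paired = 20,
                          seed = 99)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(unclass(a$betas), unclass(b$betas))
  expect_identical(a$sheet, b$sheet)
  c2 <- generate_cohort(cfg, seed = 100)
  expect_false(identical(unclass(a$betas), unclass(c2$betas)))
})

test_that("cohort structure matches the paired/unpaired design", {
  cfg <- synthetic_config(seed = 2)
  co <- generate_cohort(cfg)
  expect_equal(sum(timepoints(co$betas) == "birth"), 373)
  expect_equal(sum(timepoints(co$betas) == "year9"), 245)
  expect_equal(length(paired_children(co$sheet)), 174)
  expect_equal(length(unique(co$sheet$child_id)), 373 + 245 - 174)
  b <- unclass(co$betas)
  expect_true(all(b > 0 & b < 1))
  # BMI z only for children seen at 9 years
  y9_children <- unique(co$sheet$child_id[co$sheet$timepoint == "year9"])
  with_bmi <- unique(co$sheet$child_id[!is.na(co$sheet$bmi_z)])
  expect_setequal(with_bmi, y9_children)
})

test_that("planted correlation structure is reproduced in moments", {
  cfg <- synthetic_config(seed = 31)
  within1 <- within2 <- cross <- link <- numeric(10)
  for (k in 1:10) {
    co <- generate_cohort(cfg, seed = 3100 + k)
    cm <- meth_cor(as_mvalues(subset_timepoint(co$betas, "birth")))
    b1 <- cm$r[1:3, 1:3]; b2 <- cm$r[18:23, 18:23]
    within1[k] <- mean(b1[upper.tri(b1)])
    within2[k] <- mean(b2[upper.tri(b2)])
    cross[k] <- mean(abs(cm$r[2:3, 18:23]))
    link[k] <- mean(cm$r[1, 20:23])
  }
  expect_lt(abs(mean(within1) - 0.7), 0.05)
  expect_lt(abs(mean(within2) - 0.7), 0.05)
  expect_lt(mean(cross), 0.2)
  expect_gt(mean(link), 0.2)  # site-1 to gene-body coupling present
})

test_that("the by-sex configuration reproduces the printed means", {
  cfg <- table2_config()
  eb <- expected_betas(cfg)
  expect_equal(unname(eb[1, "birth"]), 0.668, tolerance = 1e-3)
  # configured female-male island gaps are the printed ones (mostly ~0)
  em <- expected_betas(cfg, "male")
  ef <- expected_betas(cfg, "female")
  fx <- methylation_by_sex_fixture()
  bx <- fx[fx$timepoint == "birth", ]
  bx <- bx[order(bx$order_index), ]
  expect_equal(100 * em[, "birth"], bx$mean_beta_pct_male,
               tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(100 * ef[, "birth"], bx$mean_beta_pct_female,
               tolerance = 1e-10, ignore_attr = TRUE)

  # law of large numbers: a big cohort reproduces the configured betas
  big <- generate_cohort(synthetic_config(n_birth = 5000, n_year9 = 10,
                                          n_paired = 10, seed = 17))
  bb <- unclass(subset_timepoint(big$betas, "birth"))
  got <- rowMeans(bb)
  want <- expected_betas(synthetic_config())[, "birth"]
  expect_lt(max(abs(got - want)), 0.005)
})

test_that("disabling planted features removes the corresponding signal", {
  cfg0 <- synthetic_config(blocks = list(), cross_block_links = list(),
                           base_cor = 0, stability = rep(0, 23),
                           n_birth = 174, n_year9 = 174, n_paired = 174,
                           seed = 41)
  co <- generate_cohort(cfg0)
  cm <- meth_cor(as_mvalues(subset_timepoint(co$betas, "birth")))
  off <- cm$r[upper.tri(cm$r)]
  expect_lt(mean(abs(off)), 0.1)
  expect_equal(nrow(find_blocks(cm)), 0)
  st <- site_stability(co$betas)
  expect_lt(mean(abs(st$r)), 0.12)
})
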