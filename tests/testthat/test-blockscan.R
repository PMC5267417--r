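test_that("pairwise correlations match the textbook formula", {
  set.seed(3)
  v <- matrix(rnorm(5 * 20), 5, 20,
              dimnames = list(paste0("p", 1:5), paste0("s", 1:20, ":birth")))
  x <- meth_matrix(v, scale = "mvalue")
  cm <- meth_cor(x)
  for (a in 1:4) for (b in (a + 1):5)
    expect_equal(cm$r[a, b], naive_pearson(v[a, ], v[b, ]),
                 tolerance = 1e-10)
  expect_equal(diag(cm$r), rep(1, 5), ignore_attr = TRUE)
  expect_equal(cm$r, t(cm$r), tolerance = 1e-12)
  expect_true(all(cm$n_pairs == 20))

  # identical rows correlate at 1, a row and its negation at -1
  v2 <- rbind(a = v[1, ], b = v[1, ], c = -v[1, ])
  colnames(v2) <- colnames(v)
  cm2 <- meth_cor(meth_matrix(v2, scale = "mvalue"))
  expect_equal(cm2$r["a", "b"], 1)
  expect_equal(cm2$r["a", "c"], -1)
})

test_that("pairs with too few complete observations become NA with warning", {
  v <- matrix(rnorm(3 * 6), 3, 6,
              dimnames = list(paste0("p", 1:3), paste0("s", 1:6, ":birth")))
  v[1, 1:4] <- NA  # leaves 2 complete pairs with every other row
  x <- meth_matrix(v, scale = "mvalue")
  expect_warning(cm <- meth_cor(x), "fewer than 3")
  expect_true(all(is.na(cm$r[1, 2:3])))
  expect_equal(cm$r[1, 1], 1)
  expect_equal(cm$n_pairs[1, 2], 2)
})

test_that("block detection handles the canonical cases", {
  # no correlation: no blocks
  expect_equal(nrow(find_blocks(diag(5))), 0)
  # perfect 3-site block
  r <- matrix(0.9, 3, 3); diag(r) <- 1
  bl <- find_blocks(r)
  expect_equal(bl$start_index, 1)
  expect_equal(bl$end_index, 3)
  expect_equal(bl$density, 1.0)
  # worked 5-site example: [1,3] passes 3/3 but is contained in [1,4]
  # (3/6 = 50% >= 50%); [1,5] fails at 3/10
  r <- matrix(0.1, 5, 5); diag(r) <- 1
  r[1, 2] <- r[2, 1] <- 0.8
  r[1, 3] <- r[3, 1] <- 0.7
  r[2, 3] <- r[3, 2] <- 0.75
  bl <- find_blocks(r)
  expect_equal(nrow(bl), 1)
  expect_equal(bl$start_index, 1)
  expect_equal(bl$end_index, 4)
  expect_equal(bl$density, 0.5)
})

test_that("block detection equals exhaustive enumeration on random inputs", {
  set.seed(7)
  for (rep in 1:80) {
    S <- sample(4:12, 1)
    r <- random_corr(S)
    thr <- sample(c(0.2, 0.4, 0.6), 1)
    dens <- sample(c(0.4, 0.5, 0.7), 1)
    got <- suppressWarnings(
      find_blocks(r, min_density = dens, r2_threshold = thr))
    want <- naive_find_blocks(r, min_density = dens, r2_threshold = thr)
    expect_equal(got$start_index, want$start_index)
    expect_equal(got$end_index, want$end_index)
    expect_equal(got$density, want$density, tolerance = 1e-12)
  }
})

test_that("stricter thresholds never increase block coverage", {
  covered <- function(bl) if (!nrow(bl)) 0 else
    length(unique(unlist(mapply(seq, bl$start_index, bl$end_index,
                                SIMPLIFY = FALSE))))
  set.seed(11)
  for (rep in 1:25) {
    r <- random_corr(10)
    c1 <- covered(suppressWarnings(find_blocks(r, r2_threshold = 0.3)))
    c2 <- covered(suppressWarnings(find_blocks(r, r2_threshold = 0.5)))
    expect_lte(c2, c1)
    d1 <- covered(suppressWarnings(find_blocks(r, min_density = 0.4)))
    d2 <- covered(suppressWarnings(find_blocks(r, min_density = 0.7)))
    expect_lte(d2, d1)
  }
})

test_that("blocks are invariant to sample relabeling and affine maps", {
  set.seed(13)
  v <- matrix(rnorm(8 * 60), 8, 60)
  v[2, ] <- v[1, ] + rnorm(60, 0, 0.4)
  v[3, ] <- v[1, ] + rnorm(60, 0, 0.4)
  dimnames(v) <- list(paste0("p", 1:8), paste0("s", 1:60, ":birth"))
  x <- meth_matrix(v, scale = "mvalue")
  bl <- find_blocks(meth_cor(x))
  perm <- sample(60)
  xp <- meth_matrix(v[, perm], scale = "mvalue")
  expect_equal(find_blocks(meth_cor(xp))[, 1:4], bl[, 1:4])
  xa <- meth_matrix(3 * v - 1, scale = "mvalue")
  expect_equal(find_blocks(meth_cor(xa))[, 1:4], bl[, 1:4])
})

test_that("excluded probes split candidate windows", {
  r <- matrix(0.9, 5, 5); diag(r) <- 1  # one solid 5-site block
  bl <- find_blocks(r)
  expect_equal(cbind(bl$start_index, bl$end_index), cbind(1L, 5L))
  # dropping the middle site leaves no run of 3 contiguous sites
  bl2 <- find_blocks(r, exclude = 3)
  expect_equal(nrow(bl2), 0)
  r6 <- matrix(0.9, 7, 7); diag(r6) <- 1
  bl3 <- find_blocks(r6, exclude = 4)
  expect_equal(bl3$start_index, c(1L, 5L))
  expect_equal(bl3$end_index, c(3L, 7L))
})

test_that("block conservation is the best Jaccard match", {
  b1 <- find_blocks(rbind(c(1, .9, .9), c(.9, 1, .9), c(.9, .9, 1)))
  expect_equal(block_conservation(b1, b1)$best_jaccard, 1.0)
  r <- matrix(0.1, 5, 5); diag(r) <- 1
  r[1, 2] <- r[2, 1] <- 0.8; r[1, 3] <- r[3, 1] <- 0.7
  r[2, 3] <- r[3, 2] <- 0.75
  b2 <- find_blocks(r)  # [1,4]
  expect_equal(block_conservation(b1, b2)$best_jaccard, 0.75)
  empty <- find_blocks(diag(4))
  expect_equal(block_conservation(b1, empty)$best_jaccard, 0)
})
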