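# Independent oracles used across test files. These deliberately use
# naive textbook formulas and explicit loops, sharing no code with the
# package implementations they check.

# exhaustive window enumeration for co-methylation blocks
naive_find_blocks <- function(r, min_len = 3, min_density = 0.5,
                              r2_threshold = 0.4) {
  S <- nrow(r)
  cand <- list()
  for (i in seq_len(S)) {
    for (j in seq_len(S)) {
      if (j - i + 1 < min_len) next
      pairs_pass <- 0
      pairs_tot <- 0
      for (a in i:(j - 1)) for (b in (a + 1):j) {
        pairs_tot <- pairs_tot + 1
        ra <- r[a, b]
        if (!is.na(ra) && ra^2 > r2_threshold) pairs_pass <- pairs_pass + 1
      }
      dens <- pairs_pass / pairs_tot
      if (dens >= min_density)
        cand[[length(cand) + 1]] <- list(i = i, j = j, d = dens)
    }
  }
  keep <- vapply(cand, function(w) {
    !any(vapply(cand, function(o)
      (o$i < w$i && o$j >= w$j) || (o$i <= w$i && o$j > w$j), logical(1)))
  }, logical(1))
  cand <- cand[keep]
  if (!length(cand))
    return(data.frame(start_index = integer(0), end_index = integer(0),
                      density = numeric(0)))
  out <- data.frame(start_index = vapply(cand, `[[`, 0, "i"),
                    end_index = vapply(cand, `[[`, 0, "j"),
                    density = vapply(cand, `[[`, 0, "d"))
  out[order(out$start_index, out$end_index), , drop = FALSE]
}

# random correlation matrix of S ordered sites with patchy block-ish
# structure, from finite data so it is a valid correlation matrix
random_corr <- function(S, n = 40) {
  k <- sample(1:3, 1)
  L <- matrix(runif(S * k, -1, 1), S, k)
  X <- L %*% matrix(rnorm(k * n), k, n) + matrix(rnorm(S * n), S, n)
  cor(t(X))
}

# textbook Pearson r from the raw sum formula
naive_pearson <- function(x, y) {
  n <- length(x)
  (n * sum(x * y) - sum(x) * sum(y)) /
    sqrt((n * sum(x^2) - sum(x)^2) * (n * sum(y^2) - sum(y)^2))
}

# independent GEE (Gaussian, identity link, exchangeable working
# correlation, Liang-Zeger sandwich): explicit R_i matrices inverted
# with solve(), no closed forms shared with the package code
naive_gee <- function(y, X, id, tol = 1e-8, max_iter = 50) {
  X <- as.matrix(X)
  p <- ncol(X)
  n <- length(y)
  idx <- split(seq_len(n), as.character(id))
  beta <- solve(t(X) %*% X, t(X) %*% y)
  alpha <- 0
  for (it in 1:max_iter) {
    e <- y - X %*% beta
    phi <- sum(e^2) / (n - p)
    num <- 0; npairs <- 0
    for (cl in idx) {
      ni <- length(cl)
      if (ni < 2) next
      for (a in 1:(ni - 1)) for (b in (a + 1):ni)
        num <- num + e[cl[a]] * e[cl[b]]
      npairs <- npairs + ni * (ni - 1) / 2
    }
    alpha <- if (npairs > p) num / phi / (npairs - p) else 0
    max_ni <- max(lengths(idx))
    if (max_ni > 1)
      alpha <- min(max(alpha, -1 / (max_ni - 1) + 1e-6), 1 - 1e-6)
    A <- matrix(0, p, p); bv <- numeric(p)
    for (cl in idx) {
      ni <- length(cl)
      Ri <- matrix(alpha, ni, ni); diag(Ri) <- 1
      Xi <- X[cl, , drop = FALSE]
      Rinv <- solve(Ri)
      A <- A + t(Xi) %*% Rinv %*% Xi
      bv <- bv + t(Xi) %*% Rinv %*% y[cl]
    }
    beta_new <- solve(A, bv)
    if (max(abs(beta_new - beta)) < tol) { beta <- beta_new; break }
    beta <- beta_new
  }
  e <- y - X %*% beta
  phi <- sum(e^2) / (n - p)
  A <- matrix(0, p, p); B <- matrix(0, p, p)
  for (cl in idx) {
    ni <- length(cl)
    Ri <- matrix(alpha, ni, ni); diag(Ri) <- 1
    Vinv <- solve(phi * Ri)
    Xi <- X[cl, , drop = FALSE]
    A <- A + t(Xi) %*% Vinv %*% Xi
    u <- t(Xi) %*% Vinv %*% e[cl]
    B <- B + u %*% t(u)
  }
  vc <- solve(A) %*% B %*% solve(A)
  list(coefficients = drop(beta), robust_se = sqrt(diag(vc)),
       alpha = alpha)
}

# tiny well-formed inputs built in code
toy_manifest <- function(S = 5) {
  cpg_manifest(sprintf("cg%06d", seq_len(S)), seq_len(S),
               c("north_shore", "island", "island", "south_shore",
                 "gene_body")[seq_len(S)])
}

toy_beta_matrix <- function(S = 5, n = 4, seed = 42) {
  set.seed(seed)
  man <- toy_manifest(S)
  v <- matrix(runif(S * n, 0.05, 0.95), S, n,
              dimnames = list(man$probe_id,
                              paste0("c", seq_len(n), ":birth")))
  meth_matrix(v, scale = "beta", manifest = man)
}

toy_sheet <- function() {
  data.frame(child_id = c("c1", "c2", "c3"),
             sex = c("male", "female", "male"),
             timepoint = "birth",
             gestational_age_wk = c(39, 38.5, 40),
             birthweight_kg = c(3.2, NA, 3.8),
             stringsAsFactors = FALSE)
}
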