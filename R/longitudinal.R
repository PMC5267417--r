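#' Cross-age stability of per-site methylation
#'
#' For children observed at both timepoints, the Pearson correlation per
#' CpG site between the birth and 9-year M-values, with the two-sided
#' p-value from the t transformation of r on `n - 2` degrees of freedom.
#'
#' @param x a [meth_matrix()] (converted to M-values internally) whose
#'   columns are `child_id:timepoint` sample-visits.
#' @param children optional child ids to use; defaults to every child
#'   present at both timepoints. At least 3 paired children are required.
#' @return A `data.frame`: `probe_id`, `r`, `n_pairs`, `p`.
#' @export
site_stability <- function(x, children = NULL) {
  stopifnot(inherits(x, "meth_matrix"))
  x <- as_mvalues(x)
  ids <- colnames(x)
  child <- sub(":[^:]*$", "", ids)
  tp <- timepoints(x)
  if (is.null(children))
    children <- intersect(child[tp == "birth"], child[tp == "year9"])
  if (length(children) < 3)
    stop("need at least 3 children with both timepoints")
  b_cols <- match(paste0(children, ":birth"), ids)
  y_cols <- match(paste0(children, ":year9"), ids)
  if (any(is.na(b_cols)) || any(is.na(y_cols)))
    stop("some requested children lack a timepoint")
  out <- data.frame(probe_id = rownames(x), r = NA_real_,
                    n_pairs = NA_integer_, p = NA_real_)
  for (s in seq_len(nrow(x))) {
    b <- unclass(x)[s, b_cols]
    y <- unclass(x)[s, y_cols]
    ok <- complete.cases(b, y)
    out$n_pairs[s] <- sum(ok)
    if (sum(ok) < 3) next
    ct <- cor.test(b[ok], y[ok], method = "pearson")
    out$r[s] <- unname(ct$estimate)
    out$p[s] <- ct$p.value
  }
  out
}

#' Generalized estimating equations: Gaussian, identity link,
#' exchangeable working correlation
#'
#' Marginal linear model for clustered observations, estimated by the
#' usual GEE iteration: the working correlation parameter is the moment
#' estimator from standardized residual cross-products, coefficients are
#' updated by generalized least squares given the working correlation,
#' and the two alternate until coefficients change by less than `tol`.
#' Standard errors are the robust (sandwich) estimator
#' `A^-1 B A^-1` with `A = sum X' V^-1 X` and
#' `B = sum X' V^-1 e e' V^-1 X` over clusters. Children observed at a
#' single timepoint contribute as singleton clusters. No small-sample
#' correction is applied (intended for cohorts of hundreds of clusters).
#'
#' @param y numeric response vector.
#' @param X design matrix (with intercept column).
#' @param id cluster identifier, same length as `y`.
#' @param tol convergence tolerance on coefficients (default 1e-8).
#' @param max_iter maximum iterations (default 50).
#' @return List of class `gee_fit`: `coefficients`, `robust_vcov`,
#'   `robust_se`, `alpha` (working correlation), `phi` (dispersion),
#'   `n_clusters`, `iterations`, `converged`.
#' @export
gee_fit <- function(y, X, id, tol = 1e-8, max_iter = 50) {
  X <- as.matrix(X)
  ok <- complete.cases(y, X, id)
  y <- y[ok]; X <- X[ok, , drop = FALSE]; id <- id[ok]
  n <- length(y); p <- ncol(X)
  if (n <= p) stop("more parameters than observations")
  clusters <- split(seq_len(n), as.character(id))
  sizes <- lengths(clusters)
  if (length(clusters) < 2) stop("need at least 2 clusters")
  if (all(sizes < 2)) {
    warning("no cluster has repeated observations; ",
            "using independence working correlation")
  }

  beta <- qr.solve(crossprod(X), crossprod(X, y))
  alpha <- 0
  iter <- 0L
  converged <- FALSE
  repeat {
    iter <- iter + 1L
    e <- y - X %*% beta
    phi <- sum(e^2) / (n - p)
    # moment estimator of the exchangeable correlation
    num <- 0; n_cross <- 0
    for (cl in clusters) {
      ni <- length(cl)
      if (ni < 2) next
      ec <- e[cl]
      num <- num + (sum(ec)^2 - sum(ec^2)) / 2
      n_cross <- n_cross + ni * (ni - 1) / 2
    }
    alpha_new <- if (n_cross > p) num / phi / (n_cross - p) else 0
    max_ni <- max(sizes)
    if (max_ni > 1)
      alpha_new <- min(max(alpha_new, -1 / (max_ni - 1) + 1e-6), 1 - 1e-6)
    else
      alpha_new <- 0

    # GLS update; exchangeable R^-1 has closed form
    A <- matrix(0, p, p)
    bvec <- numeric(p)
    for (cl in clusters) {
      Xi <- X[cl, , drop = FALSE]
      yi <- y[cl]
      WX <- exch_solve(Xi, alpha_new)
      A <- A + crossprod(WX, Xi)
      bvec <- bvec + crossprod(WX, yi)
    }
    beta_new <- solve(A, bvec)
    delta <- max(abs(beta_new - beta))
    beta <- beta_new
    alpha <- alpha_new
    if (delta < tol) { converged <- TRUE; break }
    if (iter >= max_iter) break
  }

  e <- y - X %*% beta
  phi <- sum(e^2) / (n - p)
  A <- matrix(0, p, p)
  B <- matrix(0, p, p)
  for (cl in clusters) {
    Xi <- X[cl, , drop = FALSE]
    ei <- e[cl]
    WX <- exch_solve(Xi, alpha) / phi   # V^-1 X with V = phi R
    A <- A + crossprod(WX, Xi)
    u <- crossprod(WX, ei)
    B <- B + tcrossprod(u)
  }
  Ainv <- solve(A)
  vc <- Ainv %*% B %*% Ainv
  cf <- drop(beta)
  names(cf) <- colnames(X)
  se <- sqrt(pmax(diag(vc), 0))  # guard tiny negative roundoff on exact fits
  names(se) <- colnames(X)
  structure(list(coefficients = cf, robust_vcov = vc, robust_se = se,
                 alpha = alpha, phi = phi, n_clusters = length(clusters),
                 iterations = iter, converged = converged),
            class = "gee_fit")
}

# R^-1 M for an exchangeable correlation matrix R = (1-a)I + a J,
# using the Sherman-Morrison closed form.
exch_solve <- function(M, a) {
  ni <- nrow(M)
  if (ni == 1) return(M)
  cs <- matrix(colSums(M), nrow = ni, ncol = ncol(M), byrow = TRUE)
  (M - cs * (a / (1 + (ni - 1) * a))) / (1 - a)
}

#' @export
print.gee_fit <- function(x, ...) {
  cat("GEE (identity link, exchangeable working correlation)\n")
  z <- x$coefficients / x$robust_se
  print(data.frame(estimate = x$coefficients, robust_se = x$robust_se,
                   z = z, p = 2 * pnorm(-abs(z))))
  cat(sprintf("alpha = %.4f, phi = %.4f, %d clusters, %d iterations\n",
              x$alpha, x$phi, x$n_clusters, x$iterations))
  invisible(x)
}

#' Age change in methylation by GEE
#'
#' Tests whether methylation changed between birth and 9 years using a
#' marginal model `value ~ age_indicator` with children as clusters, so
#' the repeated measures of children observed at both timepoints are
#' accounted for while children observed once still contribute. The
#' reported estimate is the coefficient on the age indicator (year 9
#' minus birth) with robust SE and normal-reference p-value.
#'
#' @param values numeric vector of per-sample-visit values (typically a
#'   region-mean M-value, or per-site M-values).
#' @param child cluster identifier per value.
#' @param age_indicator 0 for birth, 1 for year 9.
#' @param covariates optional numeric matrix/data.frame of additional
#'   covariates (e.g. cell proportions).
#' @return A one-row `data.frame`: `estimate`, `robust_se`, `z`, `p`,
#'   `n_obs`, `n_clusters`, `alpha`.
#' @export
gee_age_change <- function(values, child, age_indicator,
                           covariates = NULL) {
  X <- cbind(`(Intercept)` = 1, age = as.numeric(age_indicator))
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    X <- cbind(X, covariates)
  }
  fit <- gee_fit(values, X, child)
  est <- fit$coefficients["age"]
  se <- fit$robust_se["age"]
  z <- est / se
  data.frame(estimate = unname(est), robust_se = unname(se),
             z = unname(z), p = unname(2 * pnorm(-abs(z))),
             n_obs = length(values[complete.cases(values, child)]),
             n_clusters = fit$n_clusters, alpha = fit$alpha)
}

#' Region-mean M-values per sample-visit
#'
#' @param x a [meth_matrix()] (converted to M-values).
#' @param manifest a [cpg_manifest()] matching the matrix rows.
#' @param region region class, or `"all"` for the grand mean.
#' @return A `data.frame`: `sample_visit_id`, `child_id`, `timepoint`,
#'   `mean_m`.
#' @export
region_mvalues <- function(x, manifest, region) {
  stopifnot(inherits(x, "meth_matrix"))
  region <- match.arg(region, c(REGION_LEVELS, "all"))
  x <- as_mvalues(x)
  rows <- if (region == "all") manifest$probe_id else
    manifest$probe_id[manifest$region == region]
  if (!length(rows)) stop("empty region: ", region)
  v <- unclass(x)[rows, , drop = FALSE]
  data.frame(sample_visit_id = colnames(x),
             child_id = sub(":[^:]*$", "", colnames(x)),
             timepoint = timepoints(x),
             mean_m = colMeans(v, na.rm = TRUE))
}
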