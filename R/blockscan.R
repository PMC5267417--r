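#' Pairwise Pearson correlation of CpG sites
#'
#' Pearson correlation between every pair of sites across sample-visits,
#' using pairwise-complete observations, together with the
#' complete-pair count per cell. Correlations are computed on M-values;
#' pass a beta-scale matrix through [as_mvalues()] first (done
#' automatically unless `use_betas = TRUE`, which is provided for
#' sensitivity analyses only).
#'
#' A pair with fewer than 3 complete observations gets `NA` with a
#' warning. The diagonal is exactly 1 and the matrix is symmetric.
#'
#' @param x a [meth_matrix()].
#' @param use_betas compute on the beta scale instead (sensitivity flag).
#' @return A list of class `meth_cor`: `r` (S x S), `n_pairs` (S x S).
#' @export
meth_cor <- function(x, use_betas = FALSE) {
  stopifnot(inherits(x, "meth_matrix"))
  x <- if (use_betas) as_betas(x) else as_mvalues(x)
  v <- unclass(x)
  obs <- !is.na(v)
  n_pairs <- obs %*% t(obs)
  suppressWarnings(r <- cor(t(v), use = "pairwise.complete.obs"))
  too_few <- n_pairs < 3
  diag(too_few) <- FALSE
  if (any(too_few)) {
    warning("correlation set to NA for ", sum(too_few) / 2,
            " site pair(s) with fewer than 3 complete observations")
    r[too_few] <- NA_real_
  }
  diag(r) <- 1
  structure(list(r = r, n_pairs = n_pairs), class = "meth_cor")
}

#' @export
print.meth_cor <- function(x, ...) {
  cat(sprintf("meth_cor: %d sites, complete pairs %d-%d\n",
              nrow(x$r), min(x$n_pairs), max(x$n_pairs)))
  invisible(x)
}

#' Detect co-methylation blocks
#'
#' A co-methylation block is a contiguous run of CpG sites whose
#' methylation levels are mutually correlated, by analogy with linkage
#' disequilibrium blocks. A window `[i, j]` of ordered sites is a
#' *candidate* when it spans at least `min_len` sites and at least a
#' fraction `min_density` of its site pairs have squared Pearson
#' correlation strictly greater than `r2_threshold` (defaults: 3 sites,
#' 50%, 0.4). All `O(S^2)` windows are enumerated and exactly the
#' maximal candidates — those not strictly contained in another
#' candidate — are reported, sorted by start index. Two overlapping but
#' non-nested maximal windows are both reported, with a warning. A
#' missing correlation inside a window counts as a non-passing pair,
#' with a warning.
#'
#' @param corr a [meth_cor()], or a plain symmetric correlation matrix.
#' @param min_len minimum number of sites per block (default 3).
#' @param min_density minimum fraction of passing pairs (default 0.5,
#'   compared non-strictly).
#' @param r2_threshold squared-correlation threshold (default 0.4,
#'   compared strictly).
#' @param probe_ids optional probe names (defaults to the correlation
#'   matrix rownames, else `site<i>`).
#' @param exclude optional site indices (or probe ids) to drop before
#'   scanning; remaining sites keep their original indices and windows
#'   never bridge an excluded site.
#' @return A `data.frame` with one row per block: `start_index`,
#'   `end_index`, `n_sites`, `density`, and a `probe_ids` list column.
#' @examples
#' r <- diag(3); r[upper.tri(r)] <- 0.9; r[lower.tri(r)] <- 0.9
#' find_blocks(r)  # one block [1,3], density 1
#' @export
find_blocks <- function(corr, min_len = 3, min_density = 0.5,
                        r2_threshold = 0.4, probe_ids = NULL,
                        exclude = NULL) {
  r <- if (inherits(corr, "meth_cor")) corr$r else as.matrix(corr)
  if (nrow(r) != ncol(r)) stop("correlation matrix must be square")
  if (min_len < 2) stop("min_len must be at least 2")
  if (min_density <= 0 || min_density > 1) stop("min_density must be in (0,1]")
  if (r2_threshold <= 0 || r2_threshold >= 1)
    stop("r2_threshold must be in (0,1)")
  S <- nrow(r)
  if (is.null(probe_ids))
    probe_ids <- if (!is.null(rownames(r))) rownames(r) else
      paste0("site", seq_len(S))
  keep <- rep(TRUE, S)
  if (!is.null(exclude)) {
    idx <- if (is.character(exclude)) match(exclude, probe_ids) else
      as.integer(exclude)
    if (any(is.na(idx)) || any(idx < 1 | idx > S))
      stop("exclude refers to unknown sites")
    keep[idx] <- FALSE
  }

  pass <- r^2 > r2_threshold
  if (any(is.na(pass))) {
    # missing r counts as not passing
    warning("missing correlations treated as non-passing pairs")
    pass[is.na(pass)] <- FALSE
  }
  diag(pass) <- FALSE

  # candidate windows: contiguous runs of retained sites only
  cand <- list()
  runs <- rle(keep)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  for (k in seq_along(runs$values)) {
    if (!runs$values[k]) next
    lo <- starts[k]; hi <- ends[k]
    if (hi - lo + 1 < min_len) next
    for (i in lo:(hi - min_len + 1)) {
      n_pass <- 0L
      for (j in (i + 1):hi) {
        # incremental pair count: adding site j contributes pairs (i..j-1, j)
        n_pass <- n_pass + sum(pass[i:(j - 1), j])
        len <- j - i + 1
        if (len < min_len) next
        n_tot <- len * (len - 1) / 2
        dens <- n_pass / n_tot
        if (dens >= min_density)
          cand[[length(cand) + 1]] <- c(i, j, dens)
      }
    }
  }
  if (!length(cand))
    return(empty_blocks())
  cm <- do.call(rbind, cand)
  # maximal = not strictly contained in another candidate
  contained <- vapply(seq_len(nrow(cm)), function(a) {
    any(cm[, 1] <= cm[a, 1] & cm[, 2] >= cm[a, 2] &
          (cm[, 1] < cm[a, 1] | cm[, 2] > cm[a, 2]))
  }, logical(1))
  cm <- cm[!contained, , drop = FALSE]
  cm <- cm[order(cm[, 1], cm[, 2]), , drop = FALSE]
  if (nrow(cm) > 1) {
    overlap <- any(cm[-1, 1] <= cm[-nrow(cm), 2])
    if (overlap)
      warning("overlapping non-nested blocks reported")
  }
  out <- data.frame(start_index = as.integer(cm[, 1]),
                    end_index = as.integer(cm[, 2]),
                    n_sites = as.integer(cm[, 2] - cm[, 1] + 1),
                    density = cm[, 3])
  out$probe_ids <- lapply(seq_len(nrow(out)), function(b)
    probe_ids[out$start_index[b]:out$end_index[b]])
  out
}

empty_blocks <- function() {
  out <- data.frame(start_index = integer(0), end_index = integer(0),
                    n_sites = integer(0), density = numeric(0))
  out$probe_ids <- list()
  out
}

#' Block conservation between two block sets
#'
#' For each block detected in one condition (e.g. birth), the best
#' Jaccard index of its site set against the blocks of another condition
#' (e.g. 9 years), with the index of the matched block. Quantifies how
#' well block structure is conserved across timepoints.
#'
#' @param blocks_a,blocks_b block tables from [find_blocks()] on the
#'   same manifest.
#' @return A `data.frame`, one row per block of `blocks_a`: `start_index`,
#'   `end_index`, `best_jaccard`, `matched_block` (row index in
#'   `blocks_b`, `NA` if `blocks_b` is empty).
#' @export
block_conservation <- function(blocks_a, blocks_b) {
  jac <- function(a, b) length(intersect(a, b)) / length(union(a, b))
  out <- data.frame(start_index = blocks_a$start_index,
                    end_index = blocks_a$end_index,
                    best_jaccard = NA_real_,
                    matched_block = NA_integer_)
  for (i in seq_len(nrow(blocks_a))) {
    sa <- seq(blocks_a$start_index[i], blocks_a$end_index[i])
    if (!nrow(blocks_b)) {
      out$best_jaccard[i] <- 0
      next
    }
    js <- vapply(seq_len(nrow(blocks_b)), function(j)
      jac(sa, seq(blocks_b$start_index[j], blocks_b$end_index[j])),
      numeric(1))
    out$best_jaccard[i] <- max(js)
    out$matched_block[i] <- which.max(js)
  }
  out
}
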