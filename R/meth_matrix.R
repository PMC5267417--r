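#' Methylation matrix container
#'
#' A `meth_matrix` is a numeric matrix (rows = CpG probes in manifest
#' order, columns = sample-visits) carrying a `scale` attribute (`"beta"`
#' or `"mvalue"`) and a `timepoint` attribute (one of `"birth"`/`"year9"`
#' per column). Sample-visit ids are `child_id:timepoint`. Missing values
#' are allowed and propagate; every downstream statistic uses
#' complete-case handling per computation.
#'
#' @param values numeric matrix with rownames (probe ids) and colnames
#'   (sample-visit ids).
#' @param scale `"beta"` or `"mvalue"`.
#' @param timepoint character vector, one of `"birth"`, `"year9"` per
#'   column. Defaults to the suffix of the sample-visit id.
#' @param manifest optional [cpg_manifest()]; if given, rows are checked
#'   against and reordered to the manifest.
#' @return A matrix of class `meth_matrix`.
#' @export
meth_matrix <- function(values, scale = c("beta", "mvalue"),
                        timepoint = NULL, manifest = NULL) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values))
    stop("values must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("values must have probe rownames and sample-visit colnames")
  if (is.null(timepoint))
    timepoint <- sub("^.*:", "", colnames(values))
  timepoint <- as.character(timepoint)
  if (length(timepoint) != ncol(values))
    stop("timepoint must have one entry per column")
  bad_tp <- setdiff(timepoint, TIMEPOINT_LEVELS)
  if (length(bad_tp))
    stop("unknown timepoint: ", paste(unique(bad_tp), collapse = ", "))
  if (!is.null(manifest)) {
    stopifnot(inherits(manifest, "cpg_manifest"))
    unknown <- setdiff(rownames(values), manifest$probe_id)
    if (length(unknown))
      stop("unknown probe id: ", paste(unknown, collapse = ", "))
    missing_probes <- setdiff(manifest$probe_id, rownames(values))
    if (length(missing_probes))
      stop("matrix is missing manifest probes: ",
           paste(missing_probes, collapse = ", "))
    values <- values[manifest$probe_id, , drop = FALSE]
  }
  if (scale == "beta") {
    bad <- which(!is.na(values) & (values < 0 | values > 1), arr.ind = TRUE)
    if (nrow(bad))
      stop(sprintf("beta value out of [0,1] at probe %s, sample %s: %g",
                   rownames(values)[bad[1, 1]], colnames(values)[bad[1, 2]],
                   values[bad[1, , drop = FALSE]]))
  } else {
    if (any(!is.finite(values) & !is.na(values)))
      stop("M-values must be finite or missing")
  }
  structure(values, scale = scale, timepoint = timepoint,
            class = c("meth_matrix", class(values)))
}

#' @export
print.meth_matrix <- function(x, ...) {
  cat(sprintf("meth_matrix: %d probes x %d sample-visits (%s scale)\n",
              nrow(x), ncol(x), attr(x, "scale")))
  tp <- table(attr(x, "timepoint"))
  cat("  timepoints:",
      paste(sprintf("%s=%d", names(tp), tp), collapse = ", "), "\n")
  invisible(x)
}

#' Scale of a methylation matrix
#' @param x a [meth_matrix()].
#' @return `"beta"` or `"mvalue"`.
#' @export
meth_scale <- function(x) attr(x, "scale")

#' Timepoint labels of a methylation matrix
#' @param x a [meth_matrix()].
#' @return character vector, one of `"birth"`/`"year9"` per column.
#' @export
timepoints <- function(x) attr(x, "timepoint")

#' Subset a methylation matrix to one timepoint
#' @param x a [meth_matrix()].
#' @param timepoint `"birth"` or `"year9"`.
#' @export
subset_timepoint <- function(x, timepoint) {
  timepoint <- match.arg(timepoint, TIMEPOINT_LEVELS)
  keep <- timepoints(x) == timepoint
  meth_matrix(unclass(x)[, keep, drop = FALSE], scale = meth_scale(x),
              timepoint = timepoints(x)[keep])
}

#' Read a beta-value matrix from TSV
#'
#' TSV with a header row of sample-visit ids and a first column of probe
#' ids. Rows may be in any order; they are checked against and reordered
#' to the manifest. Values outside `[0,1]` are a hard error naming the
#' offending cell; missing values (empty or `NA`) are preserved.
#'
#' @param path TSV file path.
#' @param manifest a [cpg_manifest()].
#' @return A [meth_matrix()] on the beta scale.
#' @export
read_beta_matrix <- function(path, manifest) {
  d <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(d) < 2) stop("beta matrix TSV needs a probe column and samples")
  probes <- as.character(d[[1]])
  vals <- as.matrix(d[, -1, drop = FALSE])
  storage.mode(vals) <- "double"
  rownames(vals) <- probes
  meth_matrix(vals, scale = "beta", manifest = manifest)
}

#' @rdname read_beta_matrix
#' @param x a [meth_matrix()] to write.
#' @export
write_beta_matrix <- function(x, path) {
  stopifnot(inherits(x, "meth_matrix"))
  d <- data.frame(probe_id = rownames(x), unclass(x), check.names = FALSE)
  write.table(d, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @importFrom utils read.delim write.table
NULL
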