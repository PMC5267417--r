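#' CpG manifest: the ordered coordinate frame of the candidate gene
#'
#' A manifest is a data frame with one row per CpG site, columns
#' `probe_id` (character, unique), `order_index` (1..S, consecutive) and
#' `region` (one of `north_shore`, `island`, `south_shore`, `south_shelf`,
#' `five_utr`, `gene_body`). All site coordinates in this package are the
#' 1-based `order_index` along the gene; genomic positions are not used.
#'
#' @param probe_id character vector of probe identifiers.
#' @param order_index integer vector, unique and consecutive from 1.
#' @param region character vector of region classes.
#' @return A `data.frame` of class `cpg_manifest`, sorted by `order_index`.
#' @examples
#' cpg_manifest(c("cg0001", "cg0002", "cg0003"), 1:3,
#'              c("north_shore", "island", "island"))
#' @export
cpg_manifest <- function(probe_id, order_index, region) {
  probe_id <- as.character(probe_id)
  order_index <- as.integer(order_index)
  region <- as.character(region)
  if (length(probe_id) != length(order_index) ||
      length(probe_id) != length(region))
    stop("probe_id, order_index and region must have equal length")
  if (anyDuplicated(probe_id))
    stop("duplicated probe_id in manifest: ",
         paste(unique(probe_id[duplicated(probe_id)]), collapse = ", "))
  if (!identical(sort(order_index), seq_along(order_index)))
    stop("order_index must be unique and consecutive from 1")
  bad <- setdiff(region, REGION_LEVELS)
  if (length(bad))
    stop("unknown region class: ", paste(bad, collapse = ", "))
  m <- data.frame(probe_id = probe_id, order_index = order_index,
                  region = factor(region, levels = REGION_LEVELS),
                  stringsAsFactors = FALSE)
  m <- m[order(m$order_index), , drop = FALSE]
  rownames(m) <- NULL
  class(m) <- c("cpg_manifest", "data.frame")
  m
}

#' Read / write a CpG manifest CSV
#'
#' CSV with columns `probe_id,order_index,region`.
#'
#' @param path file path.
#' @return `read_manifest()` returns a [cpg_manifest()].
#' @export
read_manifest <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("probe_id", "order_index", "region")
  if (!all(need %in% names(d)))
    stop("manifest must have columns ", paste(need, collapse = ", "))
  cpg_manifest(d$probe_id, d$order_index, d$region)
}

#' @rdname read_manifest
#' @param manifest a [cpg_manifest()].
#' @export
write_manifest <- function(manifest, path) {
  stopifnot(inherits(manifest, "cpg_manifest"))
  out <- data.frame(probe_id = manifest$probe_id,
                    order_index = manifest$order_index,
                    region = as.character(manifest$region))
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' The packaged 23-site PPARG manifest
#'
#' The default coordinate frame: 23 CpG sites spanning the PPARG promoter
#' and gene body, ordered 5' to 3', with Illumina 450k region annotation
#' (sites 1-3 north shore, 4-15 island, 16-17 south shore, 18 south shelf,
#' 19 5'UTR, 20-23 gene body).
#'
#' @return A [cpg_manifest()] with 23 rows.
#' @examples
#' table(pparg_manifest()$region)
#' @export
pparg_manifest <- function() {
  read_manifest(system.file("extdata", "pparg_manifest.csv",
                            package = "methblocks", mustWork = TRUE))
}
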