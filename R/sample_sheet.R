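#' Read / write a sample sheet CSV
#'
#' One row per child per timepoint. Required columns: `child_id`, `sex`
#' (`male`/`female`), `timepoint` (`birth`/`year9`). Covariate columns
#' `gestational_age_wk`, `maternal_age_yr`, `maternal_bmi`, `parity`,
#' `weight_gain_kg_per_mo` and outcome columns `birthweight_kg`, `bmi_z`
#' are optional and may contain missing values. Optional `cell_*` columns
#' are cell-type proportions and must be nonnegative and sum to 1 per row
#' (tolerance 1e-6) where present. A child may contribute at most one row
#' per timepoint.
#'
#' @param path CSV file path.
#' @return A `data.frame` with a `sample_visit_id` column
#'   (`child_id:timepoint`).
#' @export
read_sample_sheet <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  validate_sample_sheet(d)
}

#' @rdname read_sample_sheet
#' @param sheet a sample-sheet `data.frame`.
#' @export
write_sample_sheet <- function(sheet, path) {
  out <- sheet[, setdiff(names(sheet), "sample_visit_id"), drop = FALSE]
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

validate_sample_sheet <- function(d) {
  need <- c("child_id", "sex", "timepoint")
  if (!all(need %in% names(d)))
    stop("sample sheet must have columns ", paste(need, collapse = ", "))
  d$child_id <- as.character(d$child_id)
  bad_sex <- setdiff(unique(d$sex), SEX_LEVELS)
  if (length(bad_sex))
    stop("non-parsable sex value: ", paste(bad_sex, collapse = ", "))
  bad_tp <- setdiff(unique(d$timepoint), TIMEPOINT_LEVELS)
  if (length(bad_tp))
    stop("non-parsable timepoint value: ", paste(bad_tp, collapse = ", "))
  key <- paste(d$child_id, d$timepoint, sep = ":")
  if (anyDuplicated(key))
    stop("duplicated (child_id, timepoint): ",
         paste(unique(key[duplicated(key)]), collapse = ", "))
  cell_cols <- grep("^cell_", names(d), value = TRUE)
  if (length(cell_cols)) {
    cp <- as.matrix(d[, cell_cols, drop = FALSE])
    has <- rowSums(is.na(cp)) == 0
    if (any(cp[has, ] < 0))
      stop("cell proportions must be nonnegative")
    s <- rowSums(cp[has, , drop = FALSE])
    if (any(abs(s - 1) > 1e-6))
      stop("cell proportions must sum to 1 (+/- 1e-6)")
  }
  d$sample_visit_id <- key
  d
}

#' Monthly weight-gain rate over the first six months
#'
#' `(weight_6mo - birthweight) / exact_age_months`, in kg/month; the
#' exact age at the six-month visit is used as the denominator.
#'
#' @param weight_6mo weight at the six-month visit (kg).
#' @param birthweight birth weight (kg).
#' @param exact_age_months exact age at the six-month visit (months, > 0).
#' @return kg/month (vectorized).
#' @examples
#' derive_weight_gain_rate(7.7, 3.5, 6.0)  # 0.70
#' @export
derive_weight_gain_rate <- function(weight_6mo, birthweight,
                                    exact_age_months) {
  if (any(exact_age_months <= 0, na.rm = TRUE))
    stop("exact_age_months must be positive")
  (weight_6mo - birthweight) / exact_age_months
}

#' Children present at both timepoints
#' @param sheet a sample sheet.
#' @return character vector of child ids with both a birth and a year9 row.
#' @export
paired_children <- function(sheet) {
  tab <- table(sheet$child_id, sheet$timepoint)
  if (!all(TIMEPOINT_LEVELS %in% colnames(tab))) return(character(0))
  rownames(tab)[tab[, "birth"] > 0 & tab[, "year9"] > 0]
}
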