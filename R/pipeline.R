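#' End-to-end analysis pipeline
#'
#' Runs the full analysis sequence on a beta matrix + manifest + sample
#' sheet: region summaries, per-timepoint correlation matrices and
#' co-methylation blocks (with cross-timepoint conservation), per-site
#' cross-age stability, per-region GEE age-change tests, per-site sex
#' difference tests, sex-adjusted outcome regressions over a site
#' subset, perinatal covariate screens, and the Bonferroni frame. Each
#' stage writes a self-contained TSV/JSON file into `out_dir`; stages
#' only hand off via files plus the three inputs, so they are
#' independently re-runnable. Every output names the package version,
#' a hash of the run configuration and the seed. Identical inputs and
#' configuration give byte-identical numeric outputs.
#'
#' If the matrix lacks one timepoint, the stages needing it are skipped
#' with a notice in the run log rather than failing the whole run.
#'
#' @param beta_path path to the beta-matrix TSV.
#' @param manifest_path path to the manifest CSV.
#' @param sheet_path path to the sample-sheet CSV.
#' @param out_dir output directory (created if needed).
#' @param min_len,min_density,r2_threshold block-scan parameters, see
#'   [find_blocks()].
#' @param exclude_probes probes dropped from the block scan
#'   (sensitivity analyses).
#' @param assoc_sites site order indices entering the outcome
#'   regressions (default 1-3 and 16-23, the island-flanking focus).
#' @param frame a [bonferroni_frame()].
#' @param adjust_cells add `cell_*` columns as GEE covariates.
#' @param seed recorded in the outputs (the analysis itself is
#'   deterministic).
#' @return Invisibly, a list with every stage's result and the output
#'   file paths.
#' @export
run_pipeline <- function(beta_path, manifest_path, sheet_path,
                         out_dir = "methblocks-report",
                         min_len = 3, min_density = 0.5,
                         r2_threshold = 0.4, exclude_probes = NULL,
                         assoc_sites = c(1:3, 16:23),
                         frame = bonferroni_frame(),
                         adjust_cells = FALSE, seed = 1L) {
  for (p in c(beta_path, manifest_path, sheet_path))
    if (!file.exists(p)) stop("input file does not exist: ", p)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- list(min_len = min_len, min_density = min_density,
              r2_threshold = r2_threshold,
              exclude_probes = exclude_probes,
              assoc_sites = assoc_sites, frame = frame,
              adjust_cells = adjust_cells, seed = seed)
  stamp <- c(package_version = as.character(packageVersion("methblocks")),
             config_hash = config_hash(cfg), seed = as.character(seed))
  log_lines <- character(0)
  note <- function(stage, event, ...) {
    line <- sprintf("stage=%s event=%s %s", stage, event,
                    paste(sprintf("%s", c(...)), collapse = " "))
    log_lines <<- c(log_lines, line)
  }
  emit <- function(d, name) {
    path <- file.path(out_dir, paste0(name, ".tsv"))
    con <- file(path, "w")
    writeLines(sprintf("# %s", paste(names(stamp), stamp,
                                     sep = "=", collapse = " ")), con)
    if ("probe_ids" %in% names(d))
      d$probe_ids <- vapply(d$probe_ids, paste, "", collapse = ",")
    suppressWarnings(write.table(d, con, sep = "\t", row.names = FALSE,
                                 quote = FALSE))
    close(con)
    path
  }

  manifest <- read_manifest(manifest_path)
  betas <- read_beta_matrix(beta_path, manifest)
  sheet <- read_sample_sheet(sheet_path)
  mvals <- as_mvalues(betas)
  results <- list()
  files <- character(0)
  tps_present <- intersect(TIMEPOINT_LEVELS, unique(timepoints(betas)))

  # region summaries from observed data (sex-pooled per-site means)
  site_means <- do.call(rbind, lapply(tps_present, function(tp) {
    sub <- subset_timepoint(betas, tp)
    data.frame(order_index = manifest$order_index,
               probe_id = manifest$probe_id, region = manifest$region,
               timepoint = tp,
               mean_beta_pct = 100 * rowMeans(unclass(sub), na.rm = TRUE))
  }))
  results$site_means <- site_means
  summ <- do.call(rbind, lapply(c(levels(manifest$region), "all"),
    function(rg) do.call(rbind, lapply(tps_present, function(tp)
      region_mean_beta(site_means, rg, tp)))))
  results$region_summary <- summ
  files["region_summary"] <- emit(summ, "region_summary")
  note("summarize", "done", paste0("timepoints=",
                                   paste(tps_present, collapse = ",")))

  # blocks per timepoint
  blocks_by_tp <- list()
  for (tp in tps_present) {
    cm <- meth_cor(subset_timepoint(mvals, tp))
    bl <- find_blocks(cm, min_len = min_len, min_density = min_density,
                      r2_threshold = r2_threshold,
                      probe_ids = manifest$probe_id,
                      exclude = exclude_probes)
    blocks_by_tp[[tp]] <- bl
    files[paste0("cor_", tp)] <- emit(as.data.frame(cm$r),
                                      paste0("correlation_", tp))
    files[paste0("blocks_", tp)] <- emit(bl, paste0("blocks_", tp))
    note("blocks", "done", sprintf("timepoint=%s n_blocks=%d", tp, nrow(bl)))
  }
  results$blocks <- blocks_by_tp
  if (length(tps_present) == 2) {
    cons <- block_conservation(blocks_by_tp$birth, blocks_by_tp$year9)
    results$block_conservation <- cons
    files["block_conservation"] <- emit(cons, "block_conservation")
  } else {
    note("blocks", "skipped_conservation", "reason=single_timepoint")
  }

  # longitudinal: stability + per-region GEE age change
  if (length(tps_present) == 2 &&
      length(paired_children(sheet)) >= 3) {
    stab <- site_stability(mvals)
    results$stability <- stab
    files["stability"] <- emit(stab, "site_stability")
    covars <- NULL
    age_change <- do.call(rbind, lapply(
      c(levels(manifest$region), "all"), function(rg) {
        rv <- region_mvalues(mvals, manifest, rg)
        if (adjust_cells) {
          cc <- grep("^cell_", names(sheet), value = TRUE)
          covars <- as.matrix(
            sheet[match(rv$sample_visit_id, sheet$sample_visit_id), cc])
        }
        cbind(region = rg,
              gee_age_change(rv$mean_m, rv$child_id,
                             as.integer(rv$timepoint == "year9"), covars))
      }))
    results$age_change <- age_change
    files["age_change"] <- emit(age_change, "age_change")
    note("longitudinal", "done")
  } else {
    note("longitudinal", "skipped", "reason=needs_both_timepoints")
  }

  # sex differences per site and timepoint
  sexdiff <- do.call(rbind, lapply(tps_present, function(tp)
    sex_diff_table(betas, sheet, tp)))
  results$sex_diff <- sexdiff
  files["sex_diff"] <- emit(sexdiff, "sex_differences")
  note("sex_tests", "done")

  # outcome regressions on the configured site subset
  assoc <- list()
  for (spec_row in list(list(tp = "birth", outcome = "birthweight_kg"),
                        list(tp = "year9", outcome = "bmi_z"))) {
    tp <- spec_row$tp
    if (!tp %in% tps_present || !spec_row$outcome %in% names(sheet)) {
      note("associations", "skipped",
           sprintf("outcome=%s", spec_row$outcome))
      next
    }
    sub <- subset_timepoint(mvals, tp)
    sh <- sheet[sheet$timepoint == tp, ]
    sh <- sh[match(colnames(sub), sh$sample_visit_id), ]
    for (s in intersect(assoc_sites, manifest$order_index)) {
      pid <- manifest$probe_id[manifest$order_index == s]
      res <- outcome_regression(sh[[spec_row$outcome]],
                                unclass(sub)[pid, ], sh$sex)
      assoc[[length(assoc) + 1]] <- cbind(
        data.frame(order_index = s, probe_id = pid,
                   outcome = spec_row$outcome, timepoint = tp), res)
    }
  }
  if (length(assoc)) {
    assoc <- do.call(rbind, assoc)
    results$associations <- assoc
    files["associations"] <- emit(assoc, "associations")
    note("associations", "done", sprintf("n=%d", nrow(assoc)))
  }

  # covariate screens (the Bonferroni family)
  screen_vars <- list(
    birth = c("gestational_age_wk", "maternal_age_yr", "maternal_bmi",
              "parity"),
    year9 = c("gestational_age_wk", "maternal_age_yr", "maternal_bmi",
              "parity", "weight_gain_kg_per_mo"))
  screens <- list()
  for (tp in tps_present) {
    sub <- subset_timepoint(mvals, tp)
    sh <- sheet[sheet$timepoint == tp, ]
    sh <- sh[match(colnames(sub), sh$sample_visit_id), ]
    for (v in intersect(screen_vars[[tp]], names(sheet))) {
      sc <- covariate_screen(sub, sh[[v]], frame)
      screens[[length(screens) + 1]] <-
        cbind(data.frame(timepoint = tp, covariate = v), sc)
    }
  }
  if (length(screens)) {
    screens <- do.call(rbind, screens)
    results$covariate_screen <- screens
    files["covariate_screen"] <- emit(screens, "covariate_screen")
  }
  results$frame <- frame
  jsonlite::write_json(
    c(as.list(stamp), as.list(frame)),
    file.path(out_dir, "alpha_frame.json"), auto_unbox = TRUE, digits = NA)
  files["alpha_frame"] <- file.path(out_dir, "alpha_frame.json")
  note("alpha_frame", "done", sprintf("n_tests=%d", frame$n_tests))

  writeLines(c(sprintf("# %s", paste(names(stamp), stamp, sep = "=",
                                     collapse = " ")), log_lines),
             file.path(out_dir, "run_log.txt"))
  files["run_log"] <- file.path(out_dir, "run_log.txt")
  results$files <- files
  results$stamp <- stamp
  invisible(results)
}

# deterministic polynomial hash of a deparsed configuration (no external
# dependency; stable across sessions for plain lists)
config_hash <- function(cfg) {
  txt <- paste(deparse(cfg), collapse = "")
  bytes <- utf8ToInt(txt)
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Write the three standard input files for a synthetic cohort
#'
#' Convenience wrapper around [generate_cohort()] that writes the beta
#' matrix TSV, manifest CSV and sample sheet CSV that [run_pipeline()]
#' consumes.
#'
#' @param config a [synthetic_config()].
#' @param dir output directory.
#' @param seed overrides the config seed.
#' @return Named character vector of the three file paths.
#' @export
write_synthetic_inputs <- function(config, dir, seed = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cohort <- generate_cohort(config, seed = seed)
  paths <- c(betas = file.path(dir, "betas.tsv"),
             manifest = file.path(dir, "manifest.csv"),
             sheet = file.path(dir, "sample_sheet.csv"))
  write_beta_matrix(cohort$betas, paths["betas"])
  write_manifest(config$manifest, paths["manifest"])
  write_sample_sheet(cohort$sheet, paths["sheet"])
  paths
}
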