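#' The cohort file schema
#'
#' Ordered column list and per-column constraints of the patient-level
#' cohort file: a `patient_id`, the nine territory lesion-count columns,
#' and thirteen clinical columns (`age`, `sex`, comorbidity flags,
#' `etiology`, `nihss` 0-42, `mrs` 0-6, the DWI and WMH volumes in ml,
#' and the `lacunar` flag). Flags are coded 0/1, sex 1 = female; missing
#' values are empty fields or `NA`.
#'
#' @return Data frame with columns `column`, `type` (`"id"`, `"count"`,
#'   `"numeric"`, `"integer"`, `"flag"`, `"character"`), `min`, `max`,
#'   `required`.
#' @export
cohort_schema <- function() {
  clin <- data.frame(
    column = c("age", "sex", "htn", "dm", "af", "cad", "smoker",
               "etiology", "nihss", "mrs", "dwi_vol_ml", "wmh_vol_ml",
               "lacunar"),
    type = c("numeric", "flag", "flag", "flag", "flag", "flag", "flag",
             "character", "integer", "integer", "numeric", "numeric",
             "flag"),
    min = c(0, 0, 0, 0, 0, 0, 0, NA, 0, 0, 0, 0, 0),
    max = c(130, 1, 1, 1, 1, 1, 1, NA, 42, 6, Inf, Inf, 1),
    required = FALSE,
    stringsAsFactors = FALSE)
  counts <- data.frame(column = territory_columns(), type = "count",
                       min = 0, max = Inf, required = FALSE,
                       stringsAsFactors = FALSE)
  rbind(data.frame(column = "patient_id", type = "id", min = NA, max = NA,
                   required = TRUE, stringsAsFactors = FALSE),
        counts, clin)
}

#' Read a cohort file
#'
#' Reads a delimited cohort file, normalizes missing markers, validates
#' every column against [cohort_schema()] (reporting the offending row
#' and column) and fills absent optional columns: missing territory-count
#' columns become 0, missing clinical columns become `NA`. In strict mode
#' columns outside the schema are rejected.
#'
#' @param path Path to a CSV file with a header row.
#' @param strict Reject unknown columns (default `FALSE`).
#' @return Validated cohort data frame in schema column order (plus any
#'   extra columns in non-strict mode).
#' @export
read_cohort <- function(path, strict = FALSE) {
  if (!file.exists(path))
    stop_mal(sprintf("cohort file not found: %s", path), "validation_error")
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("NA", ""))
  if (nrow(df) == 0L)
    stop_mal(sprintf("cohort file is empty: %s", path), "empty_input_error")
  validate_cohort(df, strict = strict)
}

#' Validate an in-memory cohort against the schema
#'
#' @param df Cohort data frame.
#' @param strict Reject unknown columns.
#' @return The validated, completed data frame.
#' @export
validate_cohort <- function(df, strict = FALSE) {
  sc <- cohort_schema()
  extra <- setdiff(names(df), sc$column)
  if (strict && length(extra) > 0L)
    stop_mal(sprintf("unknown column(s) in strict mode: %s",
                     paste(extra, collapse = ", ")), "validation_error")
  if (!"patient_id" %in% names(df))
    stop_mal("missing required column `patient_id`", "validation_error")
  if (anyDuplicated(df$patient_id) || any(is.na(df$patient_id)))
    stop_mal("patient_id must be unique and non-missing", "validation_error")
  for (i in seq_len(nrow(sc))) {
    col <- sc$column[i]
    if (!col %in% names(df)) {
      df[[col]] <- if (sc$type[i] == "count") 0L
                   else if (sc$type[i] == "character") NA_character_
                   else NA_real_
      next
    }
    v <- df[[col]]
    if (sc$type[i] %in% c("count", "integer", "flag", "numeric")) {
      if (!is.numeric(v) && !all(is.na(v)))
        stop_mal(sprintf("column `%s` must be numeric", col), "validation_error")
      v <- as.numeric(v)
      if (sc$type[i] == "count") v[is.na(v)] <- 0
      bad <- which(!is.na(v) &
                     (v < sc$min[i] | v > sc$max[i] |
                        (sc$type[i] != "numeric" & v != floor(v))))
      if (length(bad) > 0L)
        stop_mal(sprintf("column `%s`, row %d: value %s violates the schema range [%s, %s]",
                         col, bad[1L], format(v[bad[1L]]), sc$min[i], sc$max[i]),
                 "validation_error")
      df[[col]] <- if (sc$type[i] == "numeric") v else as.integer(v)
    }
  }
  df[, c(sc$column, extra), drop = FALSE]
}

#' Write a cohort file
#'
#' @param cohort Cohort data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Configure an end-to-end pipeline run
#'
#' @param generator A [generator_config()] for the simulate stage.
#' @param seed Master seed; stage seeds are derived from it.
#' @param battery Comparison specs for the compare stage.
#' @param strata Circulation strata fitted per model.
#' @param chains,draws,warmup Sampler settings for both hierarchical fits.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(generator = generator_config(), seed = 1L,
                            battery = default_battery(),
                            strata = c("all", "anterior", "posterior"),
                            chains = 4L, draws = 1000L, warmup = 1000L) {
  strata <- match.arg(strata, several.ok = TRUE)
  structure(list(generator = generator, seed = as.integer(seed),
                 battery = battery, strata = strata,
                 chains = as.integer(chains), draws = as.integer(draws),
                 warmup = as.integer(warmup)),
            class = "pipeline_config")
}

#' Run the full profiling pipeline
#'
#' Orchestrates simulate -> classify -> tabulate -> compare -> fit ->
#' report. Writes `cohort.csv`, `labels.csv`, `table2.csv`, `table1.csv`,
#' `results.csv`, a human-readable `report.txt` (constellation shares,
#' territory table, group comparisons, severity models, outcome models)
#' and `manifest.json` (config snapshot, seeds, package version, file
#' checksums and per-stage row counts) to `out_dir`. A hierarchical fit
#' that refuses to run (e.g. a stratum with fewer than 10 patients per
#' group) is reported as a diagnostic line rather than aborting the run.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @param cohort Optional pre-existing cohort data frame; when supplied
#'   the simulate stage is skipped.
#' @return List with the stage outputs (`cohort`, `labelled`, `table2`,
#'   `frequencies`, `table1`, `results`, `manifest`), invisibly.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = ".",
                         cohort = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  counts <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop_mal(sprintf("pipeline stage `%s` failed: %s", name,
                       conditionMessage(e)), "pipeline_error")
    })
  }
  # simulate
  if (is.null(cohort))
    cohort <- stage("simulate", generate_cohort(config$generator, config$seed))
  counts$simulate <- nrow(cohort)
  write_cohort(cohort, file.path(out_dir, "cohort.csv"))
  # classify
  labelled <- stage("classify", classify_cohort(validate_cohort(cohort)))
  counts$classify <- nrow(labelled)
  write_cohort(labelled, file.path(out_dir, "labels.csv"))
  freqs <- stage("classify", constellation_frequencies(labelled))
  # tabulate
  t2 <- stage("tabulate", tabulate_territories(labelled))
  utils::write.csv(t2, file.path(out_dir, "table2.csv"), row.names = FALSE)
  # compare
  t1 <- stage("compare", compare_groups(labelled, config$battery))
  counts$compare <- nrow(t1)
  utils::write.csv(t1, file.path(out_dir, "table1.csv"), row.names = FALSE)
  # fit
  res_rows <- list()
  fits <- list()
  for (model in c("linear", "logistic")) {
    for (st in config$strata) {
      sub <- stratify_cohort(labelled, st)
      spec <- hier_model_spec(model, chains = config$chains,
                              draws = config$draws, warmup = config$warmup,
                              seed = config$seed +
                                match(model, c("linear", "logistic")) * 100L +
                                match(st, c("all", "anterior", "posterior")))
      fit <- tryCatch(
        if (model == "linear") fit_hier_linear(sub, spec)
        else fit_hier_logistic(sub, spec),
        error = function(e) conditionMessage(e))
      fits[[paste(model, st, sep = "_")]] <- fit
      res_rows[[length(res_rows) + 1L]] <- if (is.character(fit)) {
        data.frame(model = model, stratum = st, fitted = FALSE, note = fit,
                   slope_single = NA_real_, hpdi_low_single = NA_real_,
                   hpdi_high_single = NA_real_, slope_multiple = NA_real_,
                   hpdi_low_multiple = NA_real_, hpdi_high_multiple = NA_real_,
                   diff_mean = NA_real_, diff_hpdi_low = NA_real_,
                   diff_hpdi_high = NA_real_, substantial = NA,
                   rhat_max = NA_real_, n_single = NA_integer_,
                   n_multiple = NA_integer_, stringsAsFactors = FALSE)
      } else {
        data.frame(model = model, stratum = st, fitted = TRUE, note = "",
                   slope_single = fit$slope_single$mean,
                   hpdi_low_single = fit$slope_single$hpdi_low,
                   hpdi_high_single = fit$slope_single$hpdi_high,
                   slope_multiple = fit$slope_multiple$mean,
                   hpdi_low_multiple = fit$slope_multiple$hpdi_low,
                   hpdi_high_multiple = fit$slope_multiple$hpdi_high,
                   diff_mean = fit$difference$mean,
                   diff_hpdi_low = fit$difference$hpdi_low,
                   diff_hpdi_high = fit$difference$hpdi_high,
                   substantial = fit$substantial,
                   rhat_max = fit$diagnostics$rhat_max,
                   n_single = fit$n_single, n_multiple = fit$n_multiple,
                   stringsAsFactors = FALSE)
      }
    }
  }
  results <- do.call(rbind, res_rows)
  utils::write.csv(results, file.path(out_dir, "results.csv"),
                   row.names = FALSE)
  # report
  report_path <- file.path(out_dir, "report.txt")
  write_report(report_path, freqs, t2, t1, results, config)
  manifest <- list(
    package = "malprofiler",
    version = as.character(utils::packageVersion("malprofiler")),
    seed = config$seed,
    generator = unclass(config$generator),
    sampler = list(chains = config$chains, draws = config$draws,
                   warmup = config$warmup),
    row_counts = counts,
    checksums = as.list(tools::md5sum(file.path(out_dir,
      c("cohort.csv", "labels.csv", "table2.csv", "table1.csv",
        "results.csv", "report.txt")))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(cohort = cohort, labelled = labelled, table2 = t2,
                 frequencies = freqs, table1 = t1, results = results,
                 fits = fits, manifest = manifest))
}

write_report <- function(path, freqs, t2, t1, results, config) {
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w("Multiple acute ischemic lesion profiling report")
  w("seed: %d; patients: %d", config$seed, freqs$n)
  w("")
  w("== 1. Lesion constellations ==")
  for (i in seq_len(nrow(freqs$categories)))
    w("  %-40s %6d  (%.1f%%)", freqs$categories$category[i],
      freqs$categories$n[i], freqs$categories$share_pct[i])
  for (i in seq_len(nrow(freqs$marginals)))
    w("  flag %-35s %6d  (%.1f%%)", freqs$marginals$flag[i],
      freqs$marginals$n[i], freqs$marginals$share_pct[i])
  w("")
  w("== 2. Single vs multiple lesions per territory ==")
  for (i in seq_len(nrow(t2)))
    w("  %-18s single %5d  multiple %5d  %% multiple %s", t2$territory[i],
      t2$n_single[i], t2$n_multiple[i], format(t2$percent_multiple[i]))
  w("")
  w("== 3. Clinical group comparisons (FDR-corrected) ==")
  for (i in seq_len(nrow(t1)))
    w("  %-18s single %s vs multiple %s  p_raw %.4g  p_fdr %.4g%s",
      t1$variable[i], t1$summary_single[i], t1$summary_multiple[i],
      t1$p_raw[i], t1$p_fdr[i], ifelse(t1$significant[i], "  *", ""))
  report_models <- function(kind, title) {
    w("")
    w("== %s ==", title)
    sub <- results[results$model == kind, , drop = FALSE]
    for (i in seq_len(nrow(sub))) {
      if (!sub$fitted[i]) {
        w("  stratum %-10s not fitted: %s", sub$stratum[i], sub$note[i])
      } else {
        w("  stratum %-10s slope single %.3f [%.3f, %.3f], multiple %.3f [%.3f, %.3f]",
          sub$stratum[i], sub$slope_single[i], sub$hpdi_low_single[i],
          sub$hpdi_high_single[i], sub$slope_multiple[i],
          sub$hpdi_low_multiple[i], sub$hpdi_high_multiple[i])
        w("             difference %.3f [%.3f, %.3f] -> %s (max Rhat %.3f)",
          sub$diff_mean[i], sub$diff_hpdi_low[i], sub$diff_hpdi_high[i],
          ifelse(sub$substantial[i], "substantial", "not substantial"),
          sub$rhat_max[i])
      }
    }
  }
  report_models("linear", "4. Stroke severity (hierarchical linear model, NIHSS ~ log volume)")
  report_models("logistic", "5. Functional outcome (hierarchical logistic model, mRS > 2 ~ log volume)")
  invisible(path)
}
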