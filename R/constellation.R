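#' Classify a patient's lesion constellation
#'
#' Derives the lesion-topology label from a patient's per-territory acute
#' lesion counts. A patient has multiple acute lesions (MAL) whenever the
#' total lesion count exceeds one, regardless of whether the lesions share
#' a vascular territory. The category string encodes the multiset of
#' per-territory statuses: a territory is "single" if it holds exactly one
#' lesion and "multiple" if it holds two or more.
#'
#' Bilaterality is assessed over the lateralized territories only (ACA,
#' MCA, PCA, cerebellum); the midline brainstem never contributes to it.
#' The circulation flag is `"anterior"` (ACA/MCA only), `"posterior"`
#' (PCA/cerebellum/brainstem only) or `"both"`.
#'
#' @param counts Named numeric vector of non-negative integer lesion
#'   counts. Names may be cohort-file columns (`n_mca_l`, ...) or
#'   territory display names (`"MCA-left"`, ...); omitted territories
#'   count as zero.
#' @param patient_id Optional identifier used in error messages.
#' @return An object of class `constellation_label`: a list with elements
#'   `n_lesions`, `n_territories`, `mal`, `category`, `bilateral`,
#'   `supra_and_infra`, `ant_and_post` and `circulation`.
#' @examples
#' classify_constellation(c(n_mca_l = 1))
#' classify_constellation(c(n_mca_l = 1, n_cereb_r = 1))
#' @export
classify_constellation <- function(counts, patient_id = NULL) {
  cnt <- normalize_counts(counts, patient_id)
  total <- sum(cnt)
  if (total < 1)
    stop_mal(sprintf("patient %s has zero acute lesions; only patients with a discernible acute infarct are admissible",
                     patient_id %||% "<unnamed>"), "invalid_record_error")
  inv <- .territories[cnt >= 1L, , drop = FALSE]
  inv_counts <- cnt[cnt >= 1L]
  k <- nrow(inv)
  statuses <- ifelse(inv_counts == 1L, "single", "multiple")
  category <- constellation_category(total, k, statuses)
  sides <- inv$side[inv$side != "midline"]
  circ <- unique(inv$circulation)
  structure(list(
    n_lesions = as.integer(total),
    n_territories = as.integer(k),
    mal = total > 1L,
    category = category,
    bilateral = length(unique(sides)) == 2L,
    supra_and_infra = length(unique(inv$compartment)) == 2L,
    ant_and_post = length(circ) == 2L,
    circulation = if (length(circ) == 2L) "both" else circ
  ), class = "constellation_label")
}

normalize_counts <- function(counts, patient_id = NULL) {
  if (is.null(names(counts)) || any(!nzchar(names(counts))))
    stop_mal("lesion counts must be a named vector", "validation_error")
  idx <- match(names(counts), .territories$column)
  alt <- match(names(counts), .territories$territory)
  idx[is.na(idx)] <- alt[is.na(idx)]
  if (anyNA(idx))
    stop_mal(sprintf("unknown territory name(s): %s",
                     paste(names(counts)[is.na(idx)], collapse = ", ")),
             "validation_error")
  if (any(is.na(counts)) || any(counts < 0) || any(counts != floor(counts)))
    stop_mal(sprintf("patient %s: lesion counts must be non-negative integers",
                     patient_id %||% "<unnamed>"), "validation_error")
  cnt <- integer(9L)
  cnt[idx] <- as.integer(counts)
  cnt
}

constellation_category <- function(total, k, statuses) {
  if (total == 1L) return("single-in-one-territory")
  if (k == 1L) return("multiple-in-one-territory")
  sprintf("%s-in-%d-territories", paste(sort(statuses), collapse = "+"), k)
}

#' @export
print.constellation_label <- function(x, ...) {
  cat(sprintf("Lesion constellation: %s\n", x$category))
  cat(sprintf("  lesions: %d in %d territorie(s); MAL: %s\n",
              x$n_lesions, x$n_territories, x$mal))
  cat(sprintf("  bilateral: %s; supra+infratentorial: %s; circulation: %s\n",
              x$bilateral, x$supra_and_infra, x$circulation))
  invisible(x)
}

#' Classify every patient in a cohort
#'
#' Applies [classify_constellation()] to each row of a cohort table and
#' appends the derived label columns.
#'
#' @param cohort Data frame with the nine territory count columns (see
#'   [territory_columns()]); missing count columns are treated as zero.
#'   A `patient_id` column, if present, is used in error messages.
#' @return The input data frame with appended columns `n_lesions`,
#'   `n_territories`, `mal`, `category`, `bilateral`, `supra_and_infra`,
#'   `ant_and_post`, `circulation`.
#' @export
classify_cohort <- function(cohort) {
  if (!is.data.frame(cohort) || nrow(cohort) == 0L)
    stop_mal("cohort must be a non-empty data frame", "empty_input_error")
  cols <- intersect(territory_columns(), names(cohort))
  if (length(cols) == 0L)
    stop_mal("cohort has no territory count columns", "validation_error")
  ids <- cohort$patient_id %||% seq_len(nrow(cohort))
  labs <- lapply(seq_len(nrow(cohort)), function(i) {
    cnt <- unlist(cohort[i, cols, drop = FALSE])
    classify_constellation(cnt, patient_id = ids[i])
  })
  for (f in c("n_lesions", "n_territories", "mal", "category",
              "bilateral", "supra_and_infra", "ant_and_post", "circulation"))
    cohort[[f]] <- unlist(lapply(labs, `[[`, f))
  cohort
}

#' Tabulate single versus multiple lesions per vascular territory
#'
#' For every territory, counts the patients whose lesion count in that
#' territory is exactly one ("single") versus two or more ("multiple"),
#' together with the percentage of multiple-lesion patients among those
#' involved. The single/multiple status is territory-local: a patient with
#' one lesion in each of two territories is counted "single" in both rows.
#' Percentages are rounded half-up to one decimal; territories with no
#' involved patients report `NA`.
#'
#' @param cohort Data frame of territory counts as in [classify_cohort()].
#' @return Data frame with columns `territory`, `n_single`, `n_multiple`,
#'   `percent_multiple`.
#' @export
tabulate_territories <- function(cohort) {
  if (!is.data.frame(cohort) || nrow(cohort) == 0L)
    stop_mal("cohort must be a non-empty data frame", "empty_input_error")
  out <- .territories[, c("territory", "column")]
  out$n_single <- 0L
  out$n_multiple <- 0L
  for (i in seq_len(nrow(out))) {
    col <- out$column[i]
    cnt <- if (col %in% names(cohort)) cohort[[col]] else rep(0L, nrow(cohort))
    cnt[is.na(cnt)] <- 0L
    out$n_single[i] <- sum(cnt == 1L)
    out$n_multiple[i] <- sum(cnt >= 2L)
  }
  tot <- out$n_single + out$n_multiple
  out$percent_multiple <- ifelse(tot > 0, round_half_up(100 * out$n_multiple / tot, 1), NA_real_)
  out$column <- NULL
  class(out) <- c("territory_table", "data.frame")
  out
}

#' Cohort-level constellation frequencies
#'
#' Counts patients per lesion-constellation category and computes the
#' marginal shares of the derived flags: multiple acute lesions (MAL),
#' bilateral involvement, combined supra- and infratentorial involvement,
#' combined anterior and posterior circulation involvement, and the share
#' of patients with lesions in more than one territory.
#'
#' @param cohort Data frame; either already labelled (via
#'   [classify_cohort()]) or holding the raw territory count columns, in
#'   which case it is labelled internally.
#' @return A list of class `constellation_frequencies` with `n` (cohort
#'   size), `categories` (data frame `category`, `n`, `share_pct`) and
#'   `marginals` (data frame `flag`, `n`, `share_pct`). Percentages are
#'   rounded half-up to one decimal.
#' @export
constellation_frequencies <- function(cohort) {
  if (!is.data.frame(cohort) || nrow(cohort) == 0L)
    stop_mal("cohort must be a non-empty data frame", "empty_input_error")
  if (!"category" %in% names(cohort)) cohort <- classify_cohort(cohort)
  n <- nrow(cohort)
  tab <- sort(table(cohort$category), decreasing = TRUE)
  categories <- data.frame(category = names(tab), n = as.integer(tab),
                           share_pct = round_half_up(100 * as.integer(tab) / n, 1),
                           stringsAsFactors = FALSE, row.names = NULL)
  flags <- c(mal = "mal", bilateral = "bilateral",
             supra_and_infra = "supra_and_infra", ant_and_post = "ant_and_post")
  mn <- vapply(flags, function(f) sum(cohort[[f]]), integer(1))
  mn <- c(mn, multi_territory = sum(cohort$n_territories > 1L))
  marginals <- data.frame(flag = names(mn), n = as.integer(mn),
                          share_pct = round_half_up(100 * as.integer(mn) / n, 1),
                          stringsAsFactors = FALSE, row.names = NULL)
  structure(list(n = n, categories = categories, marginals = marginals),
            class = "constellation_frequencies")
}

#' @export
print.constellation_frequencies <- function(x, ...) {
  cat(sprintf("Lesion constellations (%d patients)\n", x$n))
  print(x$categories, row.names = FALSE)
  cat("Marginal flags:\n")
  print(x$marginals, row.names = FALSE)
  invisible(x)
}
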