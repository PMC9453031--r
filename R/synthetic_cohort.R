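#' Solve the log-normal scale parameter from a median and IQR
#'
#' For a log-normal distribution whose location is fixed at
#' `log(median)`, finds the scale `sigma` whose interquartile range
#' equals `iqr`, by numerical root finding on the quantile equation
#' (absolute IQR error below 1e-6). Used to calibrate the DWI and WMH
#' volume models from published median/IQR summaries.
#'
#' @param median Target median (ml), > 0.
#' @param iqr Target interquartile range (ml), > 0.
#' @return The scale parameter `sigma`.
#' @examples
#' solve_lognormal_scale(1.7, 11.2)  # ~2.83
#' @export
solve_lognormal_scale <- function(median, iqr) {
  check_number(median, "median", min = 1e-12)
  check_number(iqr, "iqr", min = 1e-12)
  mu <- log(median)
  f <- function(s) stats::qlnorm(0.75, mu, s) - stats::qlnorm(0.25, mu, s) - iqr
  upper <- 1
  while (f(upper) < 0 && upper < 1e3) upper <- upper * 2
  stats::uniroot(f, c(1e-9, upper), tol = 1e-12)$root
}

.category_names <- c("single_one", "multiple_one", "two_singles",
                     "single_plus_multiple", "multiple_multiple", "three_plus")

#' Configuration of the synthetic cohort generator
#'
#' Collects every distributional parameter of the simulated stroke
#' cohort. Defaults reproduce the statistical structure the analysis
#' modules assume: constellation category shares (49.7% single lesions,
#' 37.4% multiple lesions within one territory, the remainder spread over
#' multi-territory patterns), MCA-dominant territory weights, group-wise
#' log-normal DWI volume models (medians 1.7 / 7.7 ml with IQRs
#' 11.2 / 30.4, single vs. multiple) and WMH models (6.1 / 5.3 ml,
#' 14.4 / 11.3), NIHSS generated as
#' `round(alpha_g + beta_g * log(V) + Normal(0, sigma))` clipped to 0-42
#' with circulation-stratum-specific slopes (anterior ~1.56 for both
#' groups; posterior 0.21 single vs. 0.39 multiple), a logistic model for
#' unfavorable outcome (mRS > 2), comorbidity/etiology prevalences per
#' group, age ~ Normal(63.4, 14.8) truncated to 18-100, 39% women, and
#' missingness rates that retain ~41% of patients for volume/NIHSS and
#' ~30% for mRS.
#'
#' @param n_patients Number of patients to simulate.
#' @param category_shares Named shares over
#'   `single_one, multiple_one, two_singles, single_plus_multiple,
#'   multiple_multiple, three_plus`; must sum to 1 (tolerance 1e-9).
#' @param territory_weights Named sampling weights for the nine territory
#'   count columns.
#' @param extra_lesion_rate Poisson rate of lesions beyond two in a
#'   "multiple"-status territory.
#' @param volume,wmh Per-group `list(median =, iqr =)` log-normal targets.
#' @param nihss Per-stratum (`anterior`, `posterior`, `both`) lists with
#'   `alpha`, `beta` (each named `single`/`multiple`) and `sigma`.
#' @param mrs `alpha`, `beta` (named `single`/`multiple`) of the logistic
#'   unfavorable-outcome model on log volume.
#' @param age `mean`, `sd`, `min`, `max` of the truncated normal age model.
#' @param p_female Probability of female sex.
#' @param comorbidities Named list of per-group prevalences
#'   (`c(single =, multiple =)`) for `htn`, `dm`, `af`, `cad`, `smoker`.
#' @param etiology_probs Per-group named probability vectors over the CCS
#'   categories (cardio-aortic embolism `CE`, large artery atherosclerosis
#'   `LAA`, small artery occlusion `SAO`, `other`, `undetermined`).
#' @param missingness Missingness probabilities: `severity` (DWI volume
#'   and NIHSS jointly), `wmh`, `mrs`; completely at random.
#' @param lacunar `rate` (flagging probability among eligible patients)
#'   and `vol_threshold` (ml; ~1.77 ml, the volume of a 1.5 cm sphere,
#'   used as a volume proxy for the diameter criterion).
#' @param seed Default seed used when [generate_cohort()] is called
#'   without one.
#' @return Validated list of class `generator_config`.
#' @export
generator_config <- function(
    n_patients = 2466L,
    category_shares = c(single_one = 0.497, multiple_one = 0.374,
                        two_singles = 0.032, single_plus_multiple = 0.041,
                        multiple_multiple = 0.030, three_plus = 0.026),
    territory_weights = c(n_aca_l = 39, n_aca_r = 44, n_mca_l = 945,
                          n_mca_r = 849, n_pca_l = 217, n_pca_r = 195,
                          n_cereb_l = 174, n_cereb_r = 182, n_brainstem = 337),
    extra_lesion_rate = 1,
    volume = list(single = list(median = 1.7, iqr = 11.2),
                  multiple = list(median = 7.7, iqr = 30.4)),
    wmh = list(single = list(median = 6.1, iqr = 14.4),
               multiple = list(median = 5.3, iqr = 11.3)),
    nihss = list(
      anterior = list(alpha = c(single = 3.77, multiple = 3.10),
                      beta = c(single = 1.56, multiple = 1.57), sigma = 4),
      posterior = list(alpha = c(single = 4.49, multiple = 5.50),
                       beta = c(single = 0.208, multiple = 0.39), sigma = 4),
      both = list(alpha = c(single = 3.99, multiple = 3.83),
                  beta = c(single = 1.15, multiple = 1.21), sigma = 4)),
    mrs = list(alpha = c(single = -1.2, multiple = -1.2),
               beta = c(single = 0.35, multiple = 0.35)),
    age = list(mean = 63.4, sd = 14.8, min = 18, max = 100),
    p_female = 0.390,
    comorbidities = list(htn = c(single = 0.666, multiple = 0.642),
                         dm = c(single = 0.242, multiple = 0.230),
                         af = c(single = 0.124, multiple = 0.169),
                         cad = c(single = 0.169, multiple = 0.180),
                         smoker = c(single = 0.567, multiple = 0.558)),
    etiology_probs = list(
      single = c(CE = 0.137, LAA = 0.160, SAO = 0.260,
                 other = 0.057, undetermined = 0.386),
      multiple = c(CE = 0.181, LAA = 0.301, SAO = 0.040,
                   other = 0.086, undetermined = 0.392)),
    missingness = list(severity = 1 - 1011 / 2466,
                       wmh = 1 - 856 / 2466,
                       mrs = 1 - 747 / 2466),
    lacunar = list(rate = 0.149, vol_threshold = 1.77),
    seed = 1L) {
  cfg <- list(n_patients = n_patients, category_shares = category_shares,
              territory_weights = territory_weights,
              extra_lesion_rate = extra_lesion_rate, volume = volume,
              wmh = wmh, nihss = nihss, mrs = mrs, age = age,
              p_female = p_female, comorbidities = comorbidities,
              etiology_probs = etiology_probs, missingness = missingness,
              lacunar = lacunar, seed = seed)
  bad <- character(0)
  if (!is.numeric(n_patients) || length(n_patients) != 1L ||
      is.na(n_patients) || n_patients < 0 || n_patients != floor(n_patients))
    bad <- c(bad, "n_patients")
  if (!setequal(names(category_shares), .category_names) ||
      any(category_shares < 0) || any(category_shares > 1) ||
      abs(sum(category_shares) - 1) > 1e-9)
    bad <- c(bad, "category_shares")
  if (!setequal(names(territory_weights), territory_columns()) ||
      any(territory_weights < 0) || sum(territory_weights) <= 0)
    bad <- c(bad, "territory_weights")
  if (extra_lesion_rate < 0) bad <- c(bad, "extra_lesion_rate")
  for (blk in c("volume", "wmh")) {
    v <- cfg[[blk]]
    if (!all(c("single", "multiple") %in% names(v)) ||
        any(vapply(v, function(z) z$median <= 0 || z$iqr <= 0, logical(1))))
      bad <- c(bad, blk)
  }
  probs <- c(p_female, unlist(comorbidities), unlist(etiology_probs),
             unlist(missingness), lacunar$rate)
  if (any(is.na(probs)) || any(probs < 0) || any(probs > 1))
    bad <- c(bad, "probabilities")
  if (any(vapply(etiology_probs, function(p) abs(sum(p) - 1) > 1e-6, logical(1))))
    bad <- c(bad, "etiology_probs")
  if (any(vapply(nihss, function(m) m$sigma <= 0, logical(1))))
    bad <- c(bad, "nihss$sigma")
  if (length(bad) > 0L)
    stop_mal(paste("invalid generator configuration field(s):",
                   paste(unique(bad), collapse = ", ")), "validation_error")
  structure(cfg, class = "generator_config")
}

category_territory_plan <- function(category) {
  # number of territories and per-territory lesion statuses per category;
  # three_plus statuses are completed at random by the caller
  switch(category,
         single_one = list(k = 1L, statuses = "single"),
         multiple_one = list(k = 1L, statuses = "multiple"),
         two_singles = list(k = 2L, statuses = c("single", "single")),
         single_plus_multiple = list(k = 2L, statuses = c("single", "multiple")),
         multiple_multiple = list(k = 2L, statuses = c("multiple", "multiple")),
         three_plus = list(k = 3L, statuses = NULL))
}

rtruncnorm_vec <- function(n, mean, sd, lo, hi) {
  out <- stats::rnorm(n, mean, sd)
  bad <- which(out < lo | out > hi)
  while (length(bad) > 0L) {
    out[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[out[bad] < lo | out[bad] > hi]
  }
  out
}

#' Generate a synthetic stroke cohort
#'
#' Simulates patient-level records with the full cohort schema: territory
#' lesion counts drawn from the configured constellation categories and
#' territory weights, group-wise log-normal DWI/WMH volumes, NIHSS and
#' mRS outcomes generated from the configured volume-outcome models, and
#' clinical covariates. Missingness is applied completely at random at
#' the configured rates. Reproducible: the same config and seed yield an
#' identical cohort.
#'
#' @param config A [generator_config()].
#' @param seed Integer seed; defaults to `config$seed`.
#' @return Data frame following the cohort schema (see [cohort_schema()]).
#' @export
generate_cohort <- function(config = generator_config(), seed = NULL) {
  if (!inherits(config, "generator_config"))
    config <- do.call(generator_config, config)
  seed <- as.integer(seed %||% config$seed)
  n <- as.integer(config$n_patients)
  tcols <- territory_columns()
  empty <- function() {
    cols <- c(list(patient_id = character(0)),
              stats::setNames(rep(list(integer(0)), 9L), tcols),
              list(age = numeric(0), sex = integer(0), htn = integer(0),
                   dm = integer(0), af = integer(0), cad = integer(0),
                   smoker = integer(0), etiology = character(0),
                   nihss = integer(0), mrs = integer(0),
                   dwi_vol_ml = numeric(0), wmh_vol_ml = numeric(0),
                   lacunar = integer(0)))
    as.data.frame(cols, stringsAsFactors = FALSE)
  }
  if (n == 0L) return(empty())
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  set.seed(seed)

  categories <- sample(.category_names, n, replace = TRUE,
                       prob = config$category_shares[.category_names])
  counts <- matrix(0L, nrow = n, ncol = 9L, dimnames = list(NULL, tcols))
  w <- config$territory_weights[tcols]
  for (i in seq_len(n)) {
    plan <- category_territory_plan(categories[i])
    terr <- sample.int(9L, plan$k, prob = w)
    statuses <- plan$statuses %||%
      sample(c("single", "multiple"), plan$k, replace = TRUE)
    cnt <- ifelse(statuses == "single", 1L,
                  2L + stats::rpois(plan$k, config$extra_lesion_rate))
    counts[i, terr] <- cnt
  }
  mal <- rowSums(counts) > 1L
  grp <- ifelse(mal, "multiple", "single")

  draw_lognormal <- function(block) {
    out <- numeric(n)
    for (g in c("single", "multiple")) {
      idx <- grp == g
      pars <- block[[g]]
      sdlog <- solve_lognormal_scale(pars$median, pars$iqr)
      out[idx] <- stats::rlnorm(sum(idx), log(pars$median), sdlog)
    }
    out
  }
  dwi_vol <- draw_lognormal(config$volume)
  wmh_vol <- draw_lognormal(config$wmh)

  circ_of_col <- stats::setNames(.territories$circulation, tcols)
  ant_any <- rowSums(counts[, circ_of_col == "anterior", drop = FALSE]) > 0L
  post_any <- rowSums(counts[, circ_of_col == "posterior", drop = FALSE]) > 0L
  stratum <- ifelse(ant_any & post_any, "both",
                    ifelse(ant_any, "anterior", "posterior"))

  log_v <- log(dwi_vol)
  nihss <- integer(n)
  for (st in c("anterior", "posterior", "both")) {
    m <- config$nihss[[st]]
    for (g in c("single", "multiple")) {
      idx <- stratum == st & grp == g
      if (!any(idx)) next
      raw <- m$alpha[[g]] + m$beta[[g]] * log_v[idx] +
        stats::rnorm(sum(idx), 0, m$sigma)
      nihss[idx] <- as.integer(pmin(42, pmax(0, round(raw))))
    }
  }
  p_unfav <- stats::plogis(ifelse(mal, config$mrs$alpha[["multiple"]],
                                  config$mrs$alpha[["single"]]) +
                           ifelse(mal, config$mrs$beta[["multiple"]],
                                  config$mrs$beta[["single"]]) * log_v)
  unfav <- stats::rbinom(n, 1L, p_unfav) == 1L
  mrs <- integer(n)
  mrs[unfav] <- sample(3:6, sum(unfav), replace = TRUE,
                       prob = c(0.45, 0.30, 0.15, 0.10))
  mrs[!unfav] <- sample(0:2, sum(!unfav), replace = TRUE,
                        prob = c(0.30, 0.35, 0.35))

  age <- rtruncnorm_vec(n, config$age$mean, config$age$sd,
                        config$age$min, config$age$max)
  sex <- stats::rbinom(n, 1L, config$p_female)  # 1 = female
  como <- lapply(config$comorbidities, function(p)
    stats::rbinom(n, 1L, ifelse(mal, p[["multiple"]], p[["single"]])))
  etiology <- character(n)
  for (g in c("single", "multiple")) {
    idx <- grp == g
    p <- config$etiology_probs[[g]]
    etiology[idx] <- sample(names(p), sum(idx), replace = TRUE, prob = p)
  }

  comp_of_col <- stats::setNames(.territories$compartment, tcols)
  n_terr <- rowSums(counts > 0L)
  supra_only <- rowSums(counts[, comp_of_col == "infratentorial", drop = FALSE]) == 0L
  eligible <- !mal & n_terr == 1L & supra_only &
    dwi_vol < config$lacunar$vol_threshold
  lacunar <- integer(n)
  lacunar[eligible] <- stats::rbinom(sum(eligible), 1L, config$lacunar$rate)

  miss_sev <- stats::rbinom(n, 1L, config$missingness$severity) == 1L
  miss_wmh <- stats::rbinom(n, 1L, config$missingness$wmh) == 1L
  miss_mrs <- stats::rbinom(n, 1L, config$missingness$mrs) == 1L
  dwi_out <- ifelse(miss_sev, NA_real_, dwi_vol)
  nihss_out <- ifelse(miss_sev, NA_integer_, nihss)
  wmh_out <- ifelse(miss_wmh, NA_real_, wmh_vol)
  mrs_out <- ifelse(miss_mrs, NA_integer_, mrs)

  out <- data.frame(patient_id = sprintf("P%06d", seq_len(n)),
                    as.data.frame(counts), age = round(age, 1), sex = sex,
                    htn = como$htn, dm = como$dm, af = como$af,
                    cad = como$cad, smoker = como$smoker,
                    etiology = etiology, nihss = nihss_out, mrs = mrs_out,
                    dwi_vol_ml = round(dwi_out, 4),
                    wmh_vol_ml = round(wmh_out, 4), lacunar = lacunar,
                    stringsAsFactors = FALSE)
  out
}

# territory-column pairs realizing each (bilateral, supra+infra,
# anterior+posterior) flag combination for planted two-territory patients
.flag_catalog <- list(
  "FFF" = c("n_aca_l", "n_mca_l"),
  "TFF" = c("n_mca_l", "n_mca_r"),
  "FTF" = c("n_pca_l", "n_cereb_l"),
  "TTF" = c("n_pca_l", "n_cereb_r"),
  "FFT" = c("n_mca_l", "n_pca_l"),
  "TFT" = c("n_mca_l", "n_pca_r"),
  "FTT" = c("n_mca_l", "n_cereb_l"),
  "TTT" = c("n_mca_l", "n_cereb_r"))

#' Plant a cohort with exact constellation or territory-table counts
#'
#' Deterministically constructs a cohort whose classification and
#' tabulation outputs reproduce requested counts exactly; used for
#' worked-example tests against published tables.
#'
#' `spec` is a list with either (or both) of:
#' \describe{
#'   \item{categories}{Named counts over `single_one`, `multiple_one`,
#'     `two_singles`, `single_plus_multiple`, `multiple_multiple`,
#'     optionally accompanied by `flags = c(bilateral =, supra_infra =,
#'     ant_post =)`, marginal counts realized among the multi-territory
#'     patients (each must not exceed the multi-territory total).}
#'   \item{territory_cells}{Data frame with columns `territory` (display
#'     name or count column), `n_single`, `n_multiple`; each planted
#'     patient has all lesions in exactly one territory.}
#' }
#'
#' @param spec Fixture specification list.
#' @return Cohort data frame (territory counts; clinical columns `NA`).
#' @export
plant_fixture <- function(spec) {
  tcols <- territory_columns()
  rows <- list()
  add_patient <- function(cols, cnts) {
    r <- stats::setNames(rep(0L, 9L), tcols)
    r[cols] <- as.integer(cnts)
    rows[[length(rows) + 1L]] <<- r
  }
  if (!is.null(spec$categories)) {
    cats <- spec$categories
    known <- c("single_one", "multiple_one", "two_singles",
               "single_plus_multiple", "multiple_multiple")
    if (any(!names(cats) %in% known) || any(cats < 0) ||
        any(cats != floor(cats)))
      stop_mal("categories must be non-negative integer counts over known category names",
               "validation_error")
    cats <- stats::setNames(as.integer(cats[known]), known)
    cats[is.na(cats)] <- 0L
    flags <- c(bilateral = 0L, supra_infra = 0L, ant_post = 0L)
    if (!is.null(spec$flags)) {
      if (any(!names(spec$flags) %in% names(flags)) || any(spec$flags < 0))
        stop_mal("flags must be non-negative counts named bilateral/supra_infra/ant_post",
                 "validation_error")
      flags[names(spec$flags)] <- as.integer(spec$flags)
    }
    multi_cats <- c("two_singles", "single_plus_multiple", "multiple_multiple")
    m_total <- sum(cats[multi_cats])
    for (nm in c("bilateral", "supra_infra", "ant_post"))
      if (flags[[nm]] > m_total)
        stop_mal(sprintf("infeasible fixture: %s count (%d) exceeds the multi-territory total (%d)",
                         nm, flags[[nm]], m_total), "infeasibility_error")
    for (i in seq_len(cats[["single_one"]])) add_patient("n_mca_l", 1L)
    for (i in seq_len(cats[["multiple_one"]])) add_patient("n_mca_l", 2L)
    status_by_cat <- list(two_singles = c(1L, 1L),
                          single_plus_multiple = c(1L, 2L),
                          multiple_multiple = c(2L, 2L))
    cat_seq <- rep(multi_cats, times = cats[multi_cats])
    for (i in seq_len(m_total)) {
      key <- paste0(ifelse(i <= flags[["bilateral"]], "T", "F"),
                    ifelse(i <= flags[["supra_infra"]], "T", "F"),
                    ifelse(i <= flags[["ant_post"]], "T", "F"))
      add_patient(.flag_catalog[[key]], status_by_cat[[cat_seq[i]]])
    }
  }
  if (!is.null(spec$territory_cells)) {
    tc <- spec$territory_cells
    if (!all(c("territory", "n_single", "n_multiple") %in% names(tc)))
      stop_mal("territory_cells needs columns territory, n_single, n_multiple",
               "validation_error")
    cols <- ifelse(tc$territory %in% tcols, tc$territory,
                   .territories$column[match(tc$territory, .territories$territory)])
    if (anyNA(cols))
      stop_mal("unknown territory in territory_cells", "validation_error")
    if (any(tc$n_single < 0) || any(tc$n_multiple < 0))
      stop_mal("infeasible fixture: negative territory cell counts",
               "infeasibility_error")
    for (i in seq_along(cols)) {
      for (k in seq_len(tc$n_single[i])) add_patient(cols[i], 1L)
      for (k in seq_len(tc$n_multiple[i])) add_patient(cols[i], 2L)
    }
  }
  if (length(rows) == 0L)
    stop_mal("fixture spec must supply `categories` and/or `territory_cells`",
             "validation_error")
  counts <- do.call(rbind, rows)
  out <- data.frame(patient_id = sprintf("F%06d", seq_len(nrow(counts))),
                    as.data.frame(counts), stringsAsFactors = FALSE)
  for (col in c("age", "sex", "htn", "dm", "af", "cad", "smoker"))
    out[[col]] <- NA_integer_
  out$etiology <- NA_character_
  out$nihss <- out$mrs <- NA_integer_
  out$dwi_vol_ml <- out$wmh_vol_ml <- NA_real_
  out$lacunar <- 0L
  out
}
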