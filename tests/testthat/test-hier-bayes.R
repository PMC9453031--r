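test_that("HPDI is the shortest window with first-window tie-breaking", {
  expect_equal(hpdi(rep(3.0, 10), 0.9), c(low = 3.0, high = 3.0))
  # all windows of 90 consecutive integers tie; the lowest wins
  expect_equal(hpdi(1:100, 0.90), c(low = 1, high = 90))
  set.seed(61)
  z <- rnorm(1e6)
  h <- hpdi(z, 0.90)
  expect_equal(unname(h), c(-1.645, 1.645), tolerance = 0.01)
  expect_error(hpdi(1.5, 0.9), "at least two draws")
  expect_error(hpdi(1:10, 1.2), class = "malprofiler_error")
})

test_that("HPDI matches brute-force shortest-window search", {
  set.seed(62)
  for (r in 1:20) {
    n <- sample(2:1000, 1)
    draws <- switch(1 + r %% 3,
                    rnorm(n), rexp(n), rlnorm(n, 0, 0.8))
    mass <- runif(1, 0.5, 0.98)
    expect_equal(unname(hpdi(draws, mass)), oracle_hpdi(draws, mass))
  }
})

test_that("HPDI width shrinks with mass and brackets the median of unimodal draws", {
  set.seed(63)
  draws <- rnorm(5000, 2, 1)
  widths <- vapply(c(0.95, 0.9, 0.8, 0.5), function(m) diff(hpdi(draws, m)),
                   numeric(1))
  expect_true(all(diff(widths) <= 0))
  for (m in c(0.5, 0.9)) {
    h <- hpdi(draws, m)
    expect_true(h[1] <= median(draws) && median(draws) <= h[2])
  }
})

test_that("posterior difference distributions behave linearly and flag zero overlap", {
  a <- rnorm(1000)
  d0 <- difference_distribution(a, a)
  expect_equal(d0$summary$mean, 0)
  expect_equal(d0$summary$hpdi_low, 0)
  expect_equal(d0$summary$hpdi_high, 0)
  expect_false(d0$substantial)

  ds <- difference_distribution(a, a + 0.5)
  expect_equal(ds$summary$mean, -0.5, tolerance = 1e-12)

  set.seed(64)
  x <- rnorm(1e5, 1.15, 0.08)
  y <- rnorm(1e5, 1.21, 0.08)
  dn <- difference_distribution(x, y)
  expect_lt(abs(dn$summary$mean - (-0.06)), 0.005)

  expect_error(difference_distribution(rnorm(10), rnorm(11)),
               class = "malprofiler_error")
})

test_that("circulation strata follow the lesion topology and lacunar protocol", {
  coh <- rbind(
    data.frame(patient_id = sprintf("S%03d", 1:140), n_mca_l = 1, n_cereb_r = 0,
               n_pca_l = 0, lacunar = 0),
    data.frame(patient_id = sprintf("M%03d", 1:292), n_mca_l = 2, n_cereb_r = 0,
               n_pca_l = 0, lacunar = 0),
    data.frame(patient_id = "LAC", n_mca_l = 1, n_cereb_r = 0, n_pca_l = 0,
               lacunar = 1),
    data.frame(patient_id = "MIX", n_mca_l = 1, n_cereb_r = 1, n_pca_l = 0,
               lacunar = 0),
    data.frame(patient_id = "PST", n_mca_l = 0, n_cereb_r = 0, n_pca_l = 2,
               lacunar = 0))
  lab <- classify_cohort(coh)
  ant <- stratify_cohort(lab, "anterior")
  expect_equal(sum(!ant$mal), 140L)
  expect_equal(sum(ant$mal), 292L)
  expect_false("LAC" %in% ant$patient_id)   # lacunar excluded by default
  expect_false("MIX" %in% ant$patient_id)   # both circulations -> neither stratum
  keep <- stratify_cohort(lab, "anterior", exclude_lacunar = FALSE)
  expect_true("LAC" %in% keep$patient_id)
  pst <- stratify_cohort(lab, "posterior")
  expect_equal(pst$patient_id, "PST")
  expect_false("MIX" %in% pst$patient_id)
  expect_error(stratify_cohort(coh, "anterior"), "not labelled")
})

test_that("the hierarchical linear fit recovers planted slopes and matches OLS", {
  cfg <- recovery_config(2000, flat_nihss(6, 6, 1.2, 1.2, 2))
  coh <- classify_cohort(generate_cohort(cfg, 71))
  fit <- fit_hier_linear(coh, fast_spec("linear", 71))
  expect_lt(abs(fit$slope_single$mean - 1.2), 0.15)
  expect_lt(abs(fit$slope_multiple$mean - 1.2), 0.15)
  expect_false(fit$substantial)
  expect_true(fit$difference$hpdi_low <= 0 && 0 <= fit$difference$hpdi_high)
  # flat-prior / large-n limit: posterior mean within 2 posterior SDs of OLS
  for (g in c(FALSE, TRUE)) {
    d <- coh[coh$mal == g & !is.na(coh$nihss), ]
    ols <- coef(lm(nihss ~ log(dwi_vol_ml), data = d))[2]
    ps <- if (g) fit$slope_multiple else fit$slope_single
    psd <- sd(fit$draws[, if (g) "beta[2]" else "beta[1]"])
    expect_lt(abs(ps$mean - ols), 2 * psd + 1e-8)
  }
  expect_equal(unname(fit$n_single + fit$n_multiple), nrow(coh))
})

test_that("a zero outcome yields slope posteriors concentrated at zero", {
  set.seed(72)
  coh <- data.frame(mal = rep(c(FALSE, TRUE), each = 100),
                    dwi_vol_ml = rlnorm(200, 1, 1), nihss = 0L)
  fit <- fit_hier_linear(coh, hier_model_spec("linear", chains = 2,
                                              draws = 500, warmup = 500,
                                              seed = 5))
  expect_equal(fit$slope_single$mean, 0, tolerance = 0.05)
  expect_equal(fit$slope_multiple$mean, 0, tolerance = 0.05)
  expect_false(fit$substantial)
})

test_that("the hierarchical logistic fit recovers planted slopes and matches ML", {
  cfg <- recovery_config(2000, flat_nihss(6, 6, 1.2, 1.2, 2))
  coh <- classify_cohort(generate_cohort(cfg, 73))
  fit <- fit_hier_logistic(coh, fast_spec("logistic", 73))
  expect_lt(abs(fit$slope_single$mean - 0.8), 0.2)
  expect_lt(abs(fit$slope_multiple$mean - 0.8), 0.2)
  for (g in c(FALSE, TRUE)) {
    d <- coh[coh$mal == g & !is.na(coh$mrs), ]
    ml <- coef(glm(I(mrs > 2) ~ log(dwi_vol_ml), data = d,
                   family = binomial))[2]
    ps <- if (g) fit$slope_multiple else fit$slope_single
    psd <- sd(fit$draws[, if (g) "beta[2]" else "beta[1]"])
    expect_lt(abs(ps$mean - ml), 2 * psd + 1e-8)
  }
})

test_that("degenerate model inputs are refused with informative errors", {
  base <- data.frame(mal = rep(c(FALSE, TRUE), each = 50),
                     dwi_vol_ml = rlnorm(100, 1, 1),
                     nihss = rpois(100, 4), mrs = rep(c(1, 4), 50))
  small <- base[c(1:5, 51:100), ]
  expect_error(fit_hier_linear(small, fast_spec("linear", 1)),
               "fewer than 10")
  const <- base
  const$dwi_vol_ml[!const$mal] <- 2.5
  expect_error(fit_hier_linear(const, fast_spec("linear", 1)),
               "constant in the single")
  sep <- base
  sep$mrs[sep$mal] <- 5   # every multiple-lesion outcome unfavorable
  expect_error(fit_hier_logistic(sep, fast_spec("logistic", 1)),
               "separation.*multiple")
  expect_error(fit_hier_linear(base, fast_spec("logistic", 1)),
               "outcome_kind")
})

test_that("identical spec and seed reproduce identical posterior summaries", {
  cfg <- recovery_config(300, flat_nihss(6, 6, 1.2, 1.2, 2))
  coh <- classify_cohort(generate_cohort(cfg, 74))
  spec <- hier_model_spec("linear", chains = 2, draws = 300, warmup = 300,
                          seed = 99)
  f1 <- fit_hier_linear(coh, spec)
  f2 <- fit_hier_linear(coh, spec)
  expect_identical(f1$slope_single, f2$slope_single)
  expect_identical(f1$difference, f2$difference)
  expect_identical(f1$draws, f2$draws)
})
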