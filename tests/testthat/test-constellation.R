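test_that("single-patient classification matches the lesion-topology definitions", {
  l1 <- classify_constellation(c(n_mca_l = 1))
  expect_false(l1$mal)
  expect_equal(l1$category, "single-in-one-territory")
  expect_equal(l1$circulation, "anterior")
  expect_false(l1$bilateral)

  l2 <- classify_constellation(c(n_mca_l = 3))
  expect_true(l2$mal)
  expect_equal(l2$category, "multiple-in-one-territory")
  expect_equal(l2$n_territories, 1L)

  l3 <- classify_constellation(c(n_mca_l = 1, n_cereb_r = 1))
  expect_true(l3$mal)
  expect_equal(l3$n_territories, 2L)
  expect_equal(l3$category, "single+single-in-2-territories")
  expect_true(l3$bilateral)
  expect_true(l3$supra_and_infra)
  expect_true(l3$ant_and_post)
  expect_equal(l3$circulation, "both")

  # brainstem carries no laterality and belongs to the posterior circulation
  l4 <- classify_constellation(c(n_brainstem = 2))
  expect_true(l4$mal)
  expect_false(l4$bilateral)
  expect_equal(l4$circulation, "posterior")

  # territory display names are accepted too
  l5 <- classify_constellation(c("MCA-left" = 1, "Brainstem" = 1))
  expect_equal(l5$circulation, "both")
})

test_that("zero-lesion records are rejected with the patient named", {
  expect_error(classify_constellation(c(n_mca_l = 0), patient_id = "P42"),
               "P42.*zero acute lesions")
  expect_error(classify_constellation(c(bogus = 1)), "unknown territory")
})

test_that("classification agrees with a brute-force flag computer on >512 patterns", {
  cols <- territory_columns()
  for (cnt in involvement_patterns()) {
    lab <- classify_constellation(setNames(cnt, cols))
    orc <- oracle_flags(cnt)
    expect_equal(lab$mal, orc$mal)
    expect_equal(lab$n_territories, orc$n_territories)
    expect_equal(lab$bilateral, orc$bilateral)
    expect_equal(lab$supra_and_infra, orc$supra_and_infra)
    expect_equal(lab$ant_and_post, orc$ant_and_post)
  }
})

test_that("adding a lesion never revokes multiple-lesion status", {
  cols <- territory_columns()
  set.seed(11)
  for (r in 1:200) {
    cnt <- rpois(9, 0.4)
    if (sum(cnt) < 1) cnt[sample.int(9, 1)] <- 1L
    base <- classify_constellation(setNames(cnt, cols))
    j <- sample.int(9, 1)
    cnt[j] <- cnt[j] + 1L
    more <- classify_constellation(setNames(cnt, cols))
    expect_true(more$mal >= base$mal)
    expect_gte(more$n_lesions, base$n_lesions)
  }
})

test_that("combined anterior/posterior involvement and supra/infratentorial involvement are independent flags", {
  # posterior-only but crossing the tentorium: PCA + cerebellum
  a <- classify_constellation(c(n_pca_l = 1, n_cereb_l = 1))
  expect_true(a$supra_and_infra)
  expect_false(a$ant_and_post)
  # both circulations but purely supratentorial: MCA + PCA
  b <- classify_constellation(c(n_mca_l = 1, n_pca_l = 1))
  expect_true(b$ant_and_post)
  expect_false(b$supra_and_infra)
})

test_that("territory tabulation is territory-local and rounds half-up", {
  fx <- plant_fixture(list(territory_cells = data.frame(
    territory = c("n_mca_l", "n_cereb_r"),
    n_single = c(476, 82), n_multiple = c(469, 100))))
  t2 <- tabulate_territories(fx)
  expect_equal(t2$percent_multiple[t2$territory == "MCA-left"], 49.6)
  # 100 / 182 = 54.945...% -> 54.9 under half-up rounding to one decimal
  expect_equal(t2$percent_multiple[t2$territory == "Cerebellum-right"], 54.9)

  # a patient with one lesion in each of two territories is "single" in both rows
  two <- data.frame(patient_id = "A", n_mca_l = 1, n_pca_r = 1)
  t2b <- tabulate_territories(two)
  expect_equal(t2b$n_single[t2b$territory == "MCA-left"], 1L)
  expect_equal(t2b$n_single[t2b$territory == "PCA-right"], 1L)

  one <- data.frame(patient_id = "B", n_pca_l = 1)
  t2c <- tabulate_territories(one)
  expect_equal(t2c$n_single[t2c$territory == "PCA-left"], 1L)
  expect_equal(t2c$percent_multiple[t2c$territory == "PCA-left"], 0)
  expect_true(all(is.na(t2c$percent_multiple[t2c$territory != "PCA-left"])))

  expect_error(tabulate_territories(data.frame()), "non-empty")
})

test_that("constellation frequencies partition the cohort and report marginal flags", {
  fx <- plant_fixture(list(
    categories = c(single_one = 1225, multiple_one = 922, two_singles = 79,
                   single_plus_multiple = 102, multiple_multiple = 138),
    flags = c(bilateral = 196, supra_infra = 138, ant_post = 46)))
  fr <- constellation_frequencies(fx)
  expect_equal(fr$n, 2466L)
  expect_equal(sum(fr$categories$n), fr$n)
  cat_share <- function(cat) fr$categories$share_pct[fr$categories$category == cat]
  expect_equal(cat_share("single-in-one-territory"), 49.7)
  expect_equal(cat_share("multiple-in-one-territory"), 37.4)
  expect_equal(cat_share("multiple+single-in-2-territories"), 4.1)
  marg <- function(f) fr$marginals$share_pct[fr$marginals$flag == f]
  expect_equal(marg("mal"), 50.3)
  expect_equal(marg("multi_territory"), 12.9)

  one <- constellation_frequencies(data.frame(patient_id = "A", n_mca_l = 1))
  expect_equal(one$categories$share_pct, 100)
  expect_error(constellation_frequencies(data.frame()), "non-empty")
})

test_that("category counts always partition randomly generated cohorts", {
  for (seed in 1:3) {
    coh <- generate_cohort(generator_config(n_patients = 400), seed)
    fr <- constellation_frequencies(coh)
    expect_equal(sum(fr$categories$n), 400L)
  }
})
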