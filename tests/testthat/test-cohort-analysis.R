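test_that("chi-square surface validates inputs and detects independence", {
  expect_error(chi_square_test(matrix(c(1.5, 2, 3, 4), 2)), "integers")
  expect_error(chi_square_test(matrix(1:3, 1)), "2 x 2")
  expect_error(chi_square_test(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)),
               "margin")
  # rows proportional to column margins -> statistic 0, p 1
  res <- chi_square_test(matrix(c(10, 20, 30, 20, 40, 60), 2, byrow = TRUE))
  expect_equal(res$statistic, 0, tolerance = 1e-12)
  expect_equal(res$p, 1)
  expect_equal(res$df, 2L)
})

test_that("Kruskal-Wallis H matches a from-scratch rank-sum oracle", {
  vals <- c(2.1, 3.5, 1.2, 4.4, 2.8, 5.0, 3.9, 0.7, 4.1)
  grp <- rep(c("a", "b", "c"), each = 3)
  res <- kruskal_wallis(vals, grp)
  r <- rank(vals)
  n <- length(vals)
  H <- 12 / (n * (n + 1)) *
    sum(tapply(r, grp, sum)^2 / tapply(r, grp, length)) - 3 * (n + 1)
  expect_equal(res$statistic, H, tolerance = 1e-12)
  expect_equal(res$df, 2L)

  # two groups: H equals the squared standardised rank-sum statistic
  v2 <- c(5.2, 1.1, 3.3, 2.2, 6.6, 4.4, 0.5, 7.7)
  g2 <- rep(c("x", "y"), 4)
  res2 <- kruskal_wallis(v2, g2)
  r2 <- rank(v2)
  n1 <- 4; n2 <- 4; N <- 8
  z <- (sum(r2[g2 == "x"]) - n1 * (N + 1) / 2) /
    sqrt(n1 * n2 * (N + 1) / 12)
  expect_lt(abs(res2$statistic - z^2), 1e-9)

  # degenerate: all values identical
  resd <- kruskal_wallis(rep(3, 9), grp)
  expect_equal(resd$statistic, 0)
  expect_equal(resd$p, 1)
})

test_that("model matrix dummy-codes against reference levels", {
  co <- make_test_cohort(n = 300, seed = 33)
  mm <- build_model_matrix(co, model_covariate_sets()$model1)
  expect_setequal(mm$labels, c("age", "sex_male", "season_summer",
                               "season_autumn", "season_winter"))
  # participant at every reference level -> all dummy columns zero
  i <- which(co$sex == "female" & co$season == "spring")[1]
  j <- which(mm$rows == i)
  expect_true(all(mm$x[j, c("sex_male", "season_summer", "season_autumn",
                            "season_winter")] == 0))
  # column count = sum(levels - 1) over categorical + continuous count
  mm3 <- build_model_matrix(co, model_covariate_sets()$model3)
  cats <- c(sex = 2, season = 4, smoking = 3, bmi_class = 3,
            physical_activity = 3, vit_supplement = 2, fish_gt1_week = 2,
            prevalent_cvd = 2, prevalent_diabetes = 2, prevalent_cancer = 2)
  expect_equal(ncol(mm3$x), sum(cats - 1) + 5)  # 5 continuous covariates
  expect_error(build_model_matrix(co, "no_such_column"), "unknown covariate")
})

test_that("complete-case filtering reports drops and can empty the design", {
  co <- make_test_cohort(n = 120, seed = 3)
  co$crp_mg_l[1:30] <- NA
  mm <- build_model_matrix(co, c("age", "crp_mg_l"))
  expect_equal(mm$n_dropped, 30)
  expect_equal(length(mm$rows), 90)
  co$age[] <- NA
  expect_error(build_model_matrix(co, "age"), "empty design")
})

test_that("covariate screening keeps by strict p < threshold on either predictor", {
  co <- make_test_cohort(n = 800, seed = 44)
  expect_equal(nrow(screen_covariates(co, character(0))), 0L)
  s <- screen_covariates(co)
  expect_identical(s$keep,
                   pmin(s$p_vs_vitd, s$p_vs_ms, na.rm = TRUE) < 0.2)
  # boundary: p just below threshold on one predictor is kept
  fake <- data.frame(covariate = "x", p_vs_vitd = 0.19, p_vs_ms = 0.9)
  expect_true(pmin(fake$p_vs_vitd, fake$p_vs_ms) < 0.2)
  # injected strong association is always kept
  co2 <- co
  co2$crp_mg_l <- co2$crp_mg_l + 5 * (co2$vitd_cat == "deficiency")
  s2 <- screen_covariates(co2)
  expect_true(s2$keep[s2$covariate == "crp_mg_l"])
  expect_lt(s2$p_vs_vitd[s2$covariate == "crp_mg_l"], 1e-6)
})

test_that("null candidates are kept near the nominal joint rate", {
  kept <- 0L
  reps <- 200
  for (k in seq_len(reps)) {
    set.seed(derive_seed(61, k))
    n <- 400
    vitd_cat <- factor(sample(c("sufficiency", "insufficiency", "deficiency"),
                              n, TRUE),
                       levels = c("sufficiency", "insufficiency", "deficiency"))
    ms_level <- factor(sample(c("low", "moderate", "high"), n, TRUE),
                       levels = c("low", "moderate", "high"))
    co <- data.frame(vitd_cat = vitd_cat, ms_level = ms_level,
                     noise = rnorm(n))
    s <- screen_covariates(co, "noise")
    kept <- kept + s$keep
  }
  # two tests at 0.2 each: joint keep rate in (0.2, 0.4); allow <= 2x nominal
  expect_gt(kept / reps, 0.15)
  expect_lt(kept / reps, 0.2 * 2 * 2)
})

test_that("descriptive table mirrors the baseline-table layout", {
  co <- make_test_cohort(n = 500, seed = 18)
  d <- descriptive_table(co)
  # percentages within a categorical characteristic sum to 100 per column
  for (nm in c("smoking", "bmi_class", "ms_level")) {
    blk <- d[d$characteristic == nm, ]
    expect_equal(sum(blk$overall_2), 100, tolerance = 1e-9)
    for (cc in c("sufficiency", "insufficiency", "deficiency"))
      expect_equal(sum(blk[[paste0(cc, "_2")]]), 100, tolerance = 1e-9)
  }
  age <- d[d$characteristic == "age", ]
  expect_equal(age$overall_1, mean(co$age))
  expect_equal(age$overall_2, sd(co$age))
  expect_true(all(is.finite(d$p[!is.na(d$p)])))

  # forced smoking/vitamin-D association is detected
  co2 <- co
  co2$smoking[co2$vitd_cat == "deficiency"] <- "current"
  d2 <- descriptive_table(co2)
  expect_lt(d2$p[d2$characteristic == "smoking"][1], 0.05)

  # single-category cohort: tests flagged not applicable
  co3 <- co[co$vitd_cat == "sufficiency", ]
  d3 <- descriptive_table(co3)
  expect_true(all(is.na(d3$p)))
})

test_that("sequential models nest and mutual adjustment is consistent", {
  co <- make_test_cohort(n = 1200, seed = 51)
  seqm <- fit_sequential_models(co)
  # shape: reference + two non-reference categories per exposure
  t3 <- seqm$vitd$model3
  expect_equal(t3$category,
               c("sufficiency", "insufficiency", "deficiency"))
  expect_true(t3$reference[1] && !any(t3$reference[-1]))
  expect_equal(t3$hr[1], 1)
  expect_true(all(is.na(t3$ci_low[1])))
  expect_true(all(t3$n_death <= t3$n_total))

  # nesting: log partial likelihood nondecreasing on identical rows
  rows <- build_model_matrix(co, model_covariate_sets()$model3)$rows
  sub <- seq_len(nrow(co)) %in% rows
  ll <- vapply(c("model1", "model2", "model3"), function(m) {
    f <- attr(fit_hr_table(co, "vitd", model_covariate_sets()[[m]],
                           subset = sub), "fit")
    f$loglik[2]
  }, numeric(1))
  expect_true(all(diff(ll) >= -1e-8))

  # dropping one exposure from the mutual model reproduces the
  # single-exposure model-3 fit exactly on the same rows
  mut <- epimort:::fit_mutual_model(co, "vitd", model_covariate_sets()$model3)
  solo <- fit_hr_table(co, "vitd", model_covariate_sets()$model3,
                       leukocyte = "full")
  expect_equal(attr(mut, "n_used"), attr(solo, "n_used"))
  fit_mut <- attr(mut, "fit")
  expect_true(all(c("vitd_insufficiency", "ms_moderate") %in%
                    fit_mut$summary_table$term))
})

test_that("joint analysis flags degenerate cells and prints reference HR 1", {
  co <- make_test_cohort(n = 1200, seed = 52)
  j <- joint_analysis(co)
  expect_equal(nrow(j), 9L)
  ref <- j[j$reference, ]
  expect_equal(ref$vitd_cat, "sufficiency")
  expect_equal(ref$ms_level, "low")
  expect_equal(ref$hr, 1)
  expect_true(all(j$n_death <= j$n_total))

  # force a zero-death cell: non-estimable, not HR 0
  co2 <- co
  cell <- co2$vitd_cat == "deficiency" & co2$ms_level == "high"
  co2$event[which(cell)] <- 0L
  j2 <- joint_analysis(co2)
  row <- j2[j2$vitd_cat == "deficiency" & j2$ms_level == "high", ]
  expect_false(row$estimable)
  expect_true(is.na(row$hr))
})

test_that("stratified analyses preserve the deaths/totals partition", {
  co <- make_test_cohort(n = 1500, seed = 53)
  st <- stratified_analysis(co, "vitd")
  expect_equal(unique(st$stratum),
               c("overall", "sufficiency", "insufficiency", "deficiency"))
  ov <- st[st$stratum == "overall", ]
  for (cat in unique(st$category)) {
    parts <- st[st$stratum != "overall" & st$category == cat, ]
    expect_equal(sum(parts$n_total), ov$n_total[ov$category == cat])
    expect_equal(sum(parts$n_death), ov$n_death[ov$category == cat])
  }
  het <- stratum_heterogeneity(st)
  expect_true(all(het$p >= 0 & het$p <= 1, na.rm = TRUE))
})

test_that("single-stratum stratification reduces to the unstratified fit", {
  co <- make_test_cohort(n = 800, seed = 54)
  co$vitd_cat <- factor("sufficiency",
                        levels = c("sufficiency", "insufficiency",
                                   "deficiency"))
  st <- stratified_analysis(co, "vitd")
  ov <- st[st$stratum == "overall", c("hr", "ci_low", "p")]
  one <- st[st$stratum == "sufficiency", c("hr", "ci_low", "p")]
  expect_equal(ov, one, ignore_attr = TRUE)
})

test_that("printed baseline cross-tabulations reproduce their test statistics", {
  tabs <- baseline_crosstabs()
  expect_true(all(vapply(tabs, function(m) all(colSums(m) > 0), logical(1))))
  # every fully printed table's column sums are the category sizes
  expect_equal(unname(colSums(tabs$ms_level)), c(223, 637, 607))
  expect_equal(unname(colSums(tabs$smoking)), c(223, 637, 607))
  p <- vapply(tabs, function(m) chi_square_test(m)$p, numeric(1))
  expect_equal(round(p[["ms_level"]], 3), 0.872)
  expect_lt(p[["sex"]], 0.0001)
  expect_lt(p[["physical_activity"]], 0.0001)
  expect_lt(p[["alcohol_cat"]], 0.0001)
})
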