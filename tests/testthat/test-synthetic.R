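test_that("frequency-table expansion is exact and round-trips through crosstab", {
  tabs <- hrb_fixture_tables()
  records <- expand_frequency_table(tabs$hrb_index)
  expect_equal(nrow(records), 22868)
  expect_equal(sum(records$comorbid), 7236)
  tab <- crosstab(records, "hrb_index")
  expect_equal(unname(as_counts(tab)),
               unname(as.matrix(tabs$hrb_index[, c("comorbid", "noncomorbid")])))

  # every packaged fixture sums to the study margins
  for (tb in c(tabs, confounder_fixture_tables())) {
    expect_equal(sum(tb$comorbid), 7236)
    expect_equal(sum(tb$noncomorbid), 15632)
  }

  empty <- frequency_table("x", c("a", "b"), c(0, 0), c(0, 0))
  expect_equal(nrow(expand_frequency_table(empty)), 0)
  expect_error(frequency_table("x", "a", -1, 2), "non-negative")

  set.seed(13)
  for (i in 1:10) {
    counts <- matrix(sample(0:9, 6, replace = TRUE), 3)
    counts[1, 1] <- counts[1, 1] + 1  # keep the table non-empty
    tb <- frequency_table("f", c("low", "medium", "high"),
                          counts[, 1], counts[, 2])
    rt <- crosstab(expand_frequency_table(tb), "f",
                   levels = c("low", "medium", "high"))
    expect_equal(unname(as_counts(rt)), unname(counts))
  }
})

test_that("inverse sampling always lands in the requested category", {
  set.seed(3)
  for (lv in hrb_levels()) {
    d <- inverse_score_sample("diet", lv, 60)
    expect_true(all(score_diet(d$fruit, d$vegetable, d$fastfood,
                               d$softdrink)$level == lv))
    s <- inverse_score_sample("smoking", lv, 60)
    expect_true(all(classify_smoking(s$days) == lv))
    sl <- inverse_score_sample("sleep", lv, 60)
    expect_true(all(score_sleep(sl$sleep_onset, sl$wake_time)$level == lv))
    p <- inverse_score_sample("par3", lv, 60)
    expect_true(all(score_par3(p$intensity_points, p$time_points,
                               p$frequency_points)$level == lv))
  }
  g <- inverse_score_sample("GAD7", "positive", 80)
  expect_true(all(rowSums(g) >= 5))
  g <- inverse_score_sample("GAD7", "negative", 80)
  expect_true(all(rowSums(g) <= 4))
  for (band in c("normal", "mild", "moderate", "severe")) {
    q <- inverse_score_sample("PHQ9", band, 40)
    expect_true(all(scale_severity(rowSums(q)) == band))
    expect_true(all(as.matrix(q) %in% 0:3))
  }
  expect_error(inverse_score_sample("smoking", "extreme", 5), "unknown")
  expect_error(inverse_score_sample("violin", "low", 5), "unknown instrument")
})

test_that("inverse sampling is uniform over the preimage", {
  # diet low risk: compare sampled combination frequencies against the
  # uniform distribution on the enumerated preimage
  set.seed(21)
  d <- inverse_score_sample("diet", "low", 8000)
  key <- paste(d$fruit, d$vegetable, d$fastfood, d$softdrink)
  grid <- expand.grid(f = 0:2, v = 0:2, ff = 0:2, sd = 0:2)
  lv <- score_diet(grid$f, grid$v, grid$ff, grid$sd)$level
  n_low <- sum(lv == "low")
  obs <- table(factor(key, levels = unique(paste(grid$f, grid$v, grid$ff,
                                                 grid$sd)[lv == "low"])))
  gof <- suppressWarnings(chisq.test(obs, p = rep(1 / n_low, n_low)))
  expect_gt(gof$p.value, 0.001)

  # GAD-7 positive totals follow the preimage-size weights; the oracle
  # enumerates vector counts per total by repeated convolution of {0..3}
  g <- inverse_score_sample("GAD7", "positive", 8000)
  tots <- rowSums(g)
  pmf <- 1
  for (i in 1:7) pmf <- convolve(pmf, rep(1, 4), type = "open")
  pmf <- round(pmf)  # counts of 7-item vectors by total 0..21
  w <- pmf[6:22] / sum(pmf[6:22])
  gof <- suppressWarnings(chisq.test(table(factor(tots, levels = 5:21)), p = w))
  expect_gt(gof$p.value, 0.001)
})

test_that("cohorts are seed-deterministic and records are stable under resizing", {
  a <- generate_cohort(cohort_config(n = 400, seed = 5))
  b <- generate_cohort(cohort_config(n = 400, seed = 5))
  expect_identical(a$records, b$records)
  expect_identical(a$levels, b$levels)
  c <- generate_cohort(cohort_config(n = 2000, seed = 5))
  expect_identical(a$records, c$records[seq_len(400), ])
  d <- generate_cohort(cohort_config(n = 400, seed = 6))
  expect_false(identical(a$records, d$records))
})

test_that("re-scoring generated raw responses reproduces every drawn category", {
  co <- generate_cohort(cohort_config(n = 10000, seed = 2))
  s <- score_records(co$records)
  expect_identical(s$diet, co$levels$diet)
  expect_identical(s$smoking, co$levels$smoking)
  expect_identical(s$physical_inactivity, co$levels$physical_inactivity)
  expect_identical(s$sleep, co$levels$sleep)
  expect_identical(s$hrb_index, co$levels$hrb_index)
  expect_identical(s$anxiety, co$levels$anxiety)
  expect_identical(s$depression, co$levels$depression)
  expect_identical(s$comorbid, co$levels$comorbid)
})

test_that("empirical marginals match the configured study marginals", {
  co <- generate_cohort(cohort_config(n = 100000, seed = 8))
  for (v in c("diet", "smoking", "physical_inactivity", "sleep")) {
    p <- default_hrb_marginals()[[v]]
    obs <- table(factor(co$levels[[v]], levels = names(p)))
    expect_gt(chisq.test(obs, p = p)$p.value, 0.001)
  }
  for (v in c("gender", "learning_burden", "family_income")) {
    p <- default_confounder_marginals()[[v]]
    obs <- table(factor(co$levels[[v]], levels = names(p)))
    expect_gt(chisq.test(obs, p = p)$p.value, 0.001)
  }
  # null outcome model reproduces the study prevalence within 3 MC SDs
  prev <- mean(co$levels$comorbid)
  target <- 7236 / 22868
  expect_lt(abs(prev - target), 3 * sqrt(target * (1 - target) / 100000))
})

test_that("the behavior-correlation knob induces positive rank correlation", {
  rho0 <- generate_cohort(cohort_config(n = 20000, seed = 4))
  rho5 <- generate_cohort(cohort_config(n = 20000, seed = 4,
                                        behavior_correlation = 0.5))
  w0 <- spearman_matrix(data.frame(
    d = risk_weight(rho0$levels$diet), s = risk_weight(rho0$levels$sleep)))
  w5 <- spearman_matrix(data.frame(
    d = risk_weight(rho5$levels$diet), s = risk_weight(rho5$levels$sleep)))
  expect_lt(abs(w0$rho["d", "s"]), 0.03)
  expect_gt(w5$rho["d", "s"], 0.2)
})

test_that("configuration errors are caught", {
  expect_error(cohort_config(confounder_marginals = list(gender = c(boy = 0.7,
                                                                    girl = 0.7))),
               "sum to 1")
  expect_error(cohort_config(hrb_marginals = list(diet = c(bad = 1))),
               "low/medium/high")
  expect_error(cohort_config(noncomorbid_split = c(0.5, 0.1, 0.1)),
               "sum to 1")
  expect_error(generate_cohort(cohort_config(
    n = 10, outcome_model = list(intercept = 0,
                                 coefficients = c("nope" = 1)))),
    "factor:level")
})
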