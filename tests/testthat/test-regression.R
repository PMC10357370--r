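test_that("design encoding uses treatment coding with declared references", {
  rec <- data.frame(
    comorbid = c(TRUE, FALSE, TRUE, FALSE),
    hrb_index = c("low", "medium", "high", "low"))
  des <- encode_design(rec, design_spec(exposure = "hrb_index"))
  expect_equal(colnames(des$X),
               c("(Intercept)", "hrb_index:medium", "hrb_index:high"))
  expect_equal(des$X[, "hrb_index:medium"], c(0, 1, 0, 0))
  expect_equal(des$n_dropped, 0)

  # all records at the reference level: intercept-only design
  ref_only <- data.frame(comorbid = c(TRUE, FALSE),
                         hrb_index = c("low", "low"))
  des <- encode_design(ref_only, design_spec(exposure = "hrb_index"))
  expect_equal(colnames(des$X), "(Intercept)")

  expect_error(
    encode_design(rec, design_spec(exposure = "hrb_index",
                                   covariates = "gender")),
    "absent")
  # a single non-reference level is unidentifiable against its reference
  only_high <- data.frame(comorbid = c(TRUE, FALSE),
                          hrb_index = c("high", "high"))
  expect_error(encode_design(only_high, design_spec(exposure = "hrb_index")),
               "collapses")
  # complete-case dropping is counted
  rec$hrb_index[2] <- NA
  des <- encode_design(rec, design_spec(exposure = "hrb_index"))
  expect_equal(des$n_dropped, 1)
})

test_that("intercept-only MLE is the closed-form logit of the prevalence", {
  records <- expand_frequency_table(hrb_fixture_tables()$hrb_index)
  X <- matrix(1, nrow(records), 1, dimnames = list(NULL, "(Intercept)"))
  fit <- fit_logistic(as.numeric(records$comorbid), X)
  expect_equal(unname(fit$coefficients), qlogis(7236 / 22868),
               tolerance = 1e-10)
  expect_true(fit$converged)
})

test_that("saturated logit equals the closed-form odds ratio on every behavior table", {
  for (tab in hrb_fixture_tables()) {
    records <- expand_frequency_table(tab)
    f <- attr(tab, "factor")
    des <- encode_design(records, design_spec(exposure = f))
    fit <- fit_logistic(des$y, des$X)
    m <- as.matrix(tab[, c("comorbid", "noncomorbid")])
    for (i in 2:3) {
      closed <- odds_ratio(m[i, 1], m[i, 2], m[1, 1], m[1, 2])
      b <- fit$coefficients[paste0(f, ":", tab$level[i])]
      expect_equal(unname(exp(b)), closed$estimate, tolerance = 1e-7)
      # Wald CI from the fit coincides with the Woolf interval
      se <- sqrt(diag(fit$covariance))[paste0(f, ":", tab$level[i])]
      expect_equal(unname(exp(b - qnorm(0.975) * se)), closed$ci_low,
                   tolerance = 1e-5)
      expect_equal(unname(exp(b + qnorm(0.975) * se)), closed$ci_high,
                   tolerance = 1e-5)
    }
  }
})

test_that("IRLS log-likelihood is non-decreasing and matches glm", {
  set.seed(31)
  n <- 500
  x1 <- rnorm(n); x2 <- rbinom(n, 1, 0.4)
  y <- rbinom(n, 1, plogis(-0.5 + 0.8 * x1 - 0.6 * x2))
  X <- cbind("(Intercept)" = 1, x1 = x1, x2 = x2)
  fit <- fit_logistic(y, X)
  expect_true(fit$converged)
  expect_true(all(diff(fit$loglik_trace) > -1e-8))
  ref <- glm(y ~ x1 + x2, family = binomial())
  expect_equal(unname(fit$coefficients), unname(coef(ref)), tolerance = 1e-7)
  expect_equal(unname(diag(fit$covariance)),
               unname(diag(vcov(ref))), tolerance = 1e-6)
  expect_equal(fit$log_likelihood, as.numeric(logLik(ref)), tolerance = 1e-8)
})

test_that("degenerate and separated responses raise explicit errors", {
  X <- cbind("(Intercept)" = 1, x = c(0, 0, 1, 1))
  expect_error(fit_logistic(c(0, 0, 0, 0), X), "degenerate")
  expect_error(fit_logistic(c(0, 0, 1, 1), X), "separation")
  Xc <- cbind("(Intercept)" = 1, a = c(1, 0, 1, 0), b = c(1, 0, 1, 0))
  expect_error(fit_logistic(c(0, 1, 1, 0), Xc), "rank deficient")
})

test_that("odds-ratio tables expose reference rows and Wald columns", {
  records <- expand_frequency_table(hrb_fixture_tables()$sleep)
  des <- encode_design(records, design_spec(exposure = "sleep"))
  fit <- fit_logistic(des$y, des$X)
  tab <- or_table(fit, des)
  ref <- tab[tab$reference, ]
  expect_equal(ref$level, "low")
  expect_equal(ref$or, 1)
  expect_true(is.na(ref$ci_low))
  med <- tab[!is.na(tab$level) & tab$level == "medium", ]
  expect_equal(round(med$or, 2), 1.43)
  expect_error(or_table(structure(list(converged = FALSE),
                                  class = "logistic_fit")), "converge")
})

test_that("adjusted model removes planted gender confounding", {
  # sleep marginals differ by gender and gender carries its own effect, so
  # the crude sleep OR is biased away from the conditional truth
  cfg <- cohort_config(
    n = 40000, seed = 91,
    hrb_marginals = modifyList(default_hrb_marginals(), list(
      sleep = list(boy = c(low = 0.55, medium = 0.30, high = 0.15),
                   girl = c(low = 0.15, medium = 0.30, high = 0.55)))),
    outcome_model = list(intercept = qlogis(0.2),
                         coefficients = c("sleep:high" = log(1.6),
                                          "sleep:medium" = log(1.2),
                                          "gender:girl" = log(1.8))))
  co <- generate_cohort(cfg)
  scored <- score_records(co$records)
  des <- encode_design(scored, design_spec(exposure = "sleep"))
  crude <- exp(fit_logistic(des$y, des$X)$coefficients["sleep:high"])
  desa <- encode_design(scored, design_spec(exposure = "sleep",
                                            covariates = "gender"))
  adj <- exp(fit_logistic(desa$y, desa$X)$coefficients["sleep:high"])
  expect_gt(abs(log(crude) - log(1.6)), abs(log(adj) - log(1.6)))
  expect_equal(unname(log(adj)), log(1.6), tolerance = 0.12)
})

test_that("run_model2 adjusts for the fixed confounder list and null confounding leaves the OR unchanged", {
  cfg <- cohort_config(
    n = 30000, seed = 17,
    outcome_model = list(intercept = qlogis(0.25),
                         coefficients = c("hrb_index:high" = log(1.7),
                                          "hrb_index:medium" = log(1.3))))
  co <- generate_cohort(cfg)
  scored <- score_records(co$records)
  des <- encode_design(scored, design_spec(exposure = "hrb_index"))
  crude <- exp(fit_logistic(des$y, des$X)$coefficients["hrb_index:high"])
  m2 <- run_model2(scored, "hrb_index")
  adj <- m2$or[m2$level == "high"]
  # no confounder enters the outcome model, so adjusted ~ crude
  expect_equal(log(adj), unname(log(crude)), tolerance = 0.03)
  expect_equal(m2$level, c("low", "medium", "high"))
  expect_error(run_model2(scored[, setdiff(names(scored), "gender")],
                          "hrb_index"), "absent")
})

test_that("stratified fits recover stratum-specific generating odds ratios", {
  cfg <- cohort_config(
    n = 60000, seed = 23,
    outcome_model = list(intercept = qlogis(0.25),
                         coefficients = c("hrb_index:medium" = log(1.3))),
    stratum_effects = list(boy = c("hrb_index:high" = log(2.5)),
                           girl = c("hrb_index:high" = log(1.5))))
  co <- generate_cohort(cfg)
  scored <- score_records(co$records)
  strat <- stratified_or(scored, "hrb_index", adjusted = FALSE)
  or_boy <- strat$boy$or[!is.na(strat$boy$level) &
                           strat$boy$level == "high" & !strat$boy$reference]
  or_girl <- strat$girl$or[!is.na(strat$girl$level) &
                             strat$girl$level == "high" & !strat$girl$reference]
  expect_equal(log(or_boy), log(2.5), tolerance = 0.12)
  expect_equal(log(or_girl), log(1.5), tolerance = 0.12)
})
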