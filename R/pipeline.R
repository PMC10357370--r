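#' Survey codebook: categorical columns and their admissible levels
#'
#' @return Named list of level vectors, in canonical display order.
#' @export
survey_codebook <- function() {
  list(
    gender = c("boy", "girl"),
    siblings = c("yes", "no"),
    region_level = c("first_line", "second_line"),
    residence = c("rural", "urban"),
    edu_status = c("junior", "senior"),
    father_edu = c("primary_or_below", "junior_high", "senior_high_or_above"),
    mother_edu = c("primary_or_below", "junior_high", "senior_high_or_above"),
    family_income = c("low", "medium", "high"),
    num_friends = c("le2", "ge3"),
    learning_burden = c("low", "medium", "high"),
    family_psychosis = c("yes", "no"),
    self_rated_health = c("good", "fair", "poor"))
}

#' Expected columns of a raw survey CSV
#'
#' @return Character vector of column names.
#' @export
survey_columns <- function() {
  c("id", "gender", "age", "siblings", "region_level", "residence",
    "edu_status", "father_edu", "mother_edu", "family_income", "num_friends",
    "learning_burden", "family_psychosis", "self_rated_health",
    paste0("gad", 1:7), paste0("phq", 1:9),
    "fruit_freq", "vegetable_freq", "fastfood_freq", "softdrink_freq",
    "smoke_days", "bedtime", "sleep_onset", "wake_time",
    "pa_intensity", "pa_time", "pa_freq")
}

#' Read a survey CSV
#'
#' UTF-8, comma-separated, header required; missing values as empty string
#' or "NA".
#'
#' @param path File path.
#' @return Raw data frame (unvalidated; see [validate_and_filter()]).
#' @export
read_survey_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, na.strings = c("", "NA"),
                  colClasses = "character", check.names = FALSE)
}

valid_clock <- function(x) {
  !is.na(x) & grepl("^([01]?[0-9]|2[0-3]):[0-5][0-9]$", x)
}

num_or_na <- function(x) suppressWarnings(as.numeric(x))

#' Validate raw survey rows and apply the completeness filter
#'
#' Drops records with more than 15% missing fields (mirroring the survey's
#' invalid-questionnaire rule) and records with codebook violations
#' ("obvious logical errors": values outside their codebooks, smoking days
#' beyond 31, unparseable clock times, implausible ages).  Exclusions are
#' counted per reason.
#'
#' @param raw Data frame from [read_survey_csv()] (character columns).
#' @param max_missing Maximum tolerated missing-field fraction, default 0.15.
#' @return List with `records` (typed, valid rows), `exclusions` (data frame
#'   of reason/n) and `n_input`.
#' @export
validate_and_filter <- function(raw, max_missing = 0.15) {
  missing_cols <- setdiff(survey_columns(), names(raw))
  if (length(missing_cols))
    stop("malformed header: missing column(s) ",
         paste(missing_cols, collapse = ", "))
  raw <- raw[, survey_columns(), drop = FALSE]
  n_input <- nrow(raw)
  fields <- setdiff(survey_columns(), "id")
  miss_frac <- rowMeans(is.na(raw[, fields, drop = FALSE]))
  too_missing <- miss_frac > max_missing

  bad <- rep(FALSE, n_input)
  flag <- function(x) { x[is.na(x)] <- FALSE; x }
  cb <- survey_codebook()
  for (v in names(cb)) bad <- bad | flag(!raw[[v]] %in% cb[[v]] & !is.na(raw[[v]]))
  num_rule <- list(age = c(8, 22), smoke_days = c(0, 31),
                   fruit_freq = c(0, 99), vegetable_freq = c(0, 99),
                   fastfood_freq = c(0, 99), softdrink_freq = c(0, 99),
                   pa_intensity = c(1, 5), pa_time = c(1, 5), pa_freq = c(1, 5))
  for (v in paste0("gad", 1:7)) num_rule[[v]] <- c(0, 3)
  for (v in paste0("phq", 1:9)) num_rule[[v]] <- c(0, 3)
  for (v in names(num_rule)) {
    x <- num_or_na(raw[[v]])
    bad <- bad | flag((is.na(x) & !is.na(raw[[v]])) |
                        x < num_rule[[v]][1L] | x > num_rule[[v]][2L] |
                        (v != "age" & x %% 1 != 0))
  }
  for (v in c("bedtime", "sleep_onset", "wake_time"))
    bad <- bad | (!is.na(raw[[v]]) & !valid_clock(raw[[v]]))

  logical_error <- bad & !too_missing
  keep <- !too_missing & !bad
  records <- raw[keep, , drop = FALSE]
  for (v in names(num_rule)) records[[v]] <- num_or_na(records[[v]])
  rownames(records) <- NULL
  exclusions <- data.frame(
    reason = c("missingness", "logical_error"),
    n = c(sum(too_missing), sum(logical_error)))
  list(records = records, exclusions = exclusions, n_input = n_input)
}

#' Score validated survey records
#'
#' Applies every instrument scorer and appends per-record results: scale
#' totals and symptom flags, comorbidity, the four behavior risk levels
#' (columns `diet`, `smoking`, `physical_inactivity`, `sleep`), and the
#' composite HRB risk index (`hrb_score`, `hrb_index`).
#'
#' @param records Validated records from [validate_and_filter()] (or the raw
#'   rows of a [generate_cohort()] cohort).
#' @return The records with scoring columns appended.
#' @export
score_records <- function(records) {
  gad <- score_scale_rows(as.matrix(records[, paste0("gad", 1:7)]), "GAD7")
  phq <- score_scale_rows(as.matrix(records[, paste0("phq", 1:9)]), "PHQ9")
  com <- classify_comorbidity(gad$positive, phq$positive)
  dcomp <- data.frame(
    fruit = map_diet_frequency(records$fruit_freq, "fruit"),
    vegetable = map_diet_frequency(records$vegetable_freq, "vegetable"),
    fastfood = map_diet_frequency(records$fastfood_freq, "fastfood"),
    softdrink = map_diet_frequency(records$softdrink_freq, "softdrink"))
  diet <- score_diet(dcomp$fruit, dcomp$vegetable, dcomp$fastfood,
                     dcomp$softdrink)
  sleep <- score_sleep(records$sleep_onset, records$wake_time)
  par <- score_par3(records$pa_intensity, records$pa_time - 1,
                    records$pa_freq)
  hrb <- hrb_risk_index(diet$level, classify_smoking(records$smoke_days),
                        par$level, sleep$level)
  cbind(records,
        gad7_total = gad$total, phq9_total = phq$total,
        anxiety = com$anxiety, depression = com$depression,
        comorbid = com$comorbid,
        diet_score = diet$total, diet = diet$level,
        smoking = classify_smoking(records$smoke_days),
        sleep_hours = sleep$duration_hours, sleep = sleep$level,
        par3_score = par$score, physical_inactivity = par$level,
        hrb_score = hrb$index_score, hrb_index = hrb$index_level)
}

hrb_factors <- function() {
  c("diet", "smoking", "physical_inactivity", "sleep", "hrb_index")
}

xtab_with_chi2 <- function(scored, factor) {
  tab <- crosstab(scored, factor)
  chi <- pearson_chi_square(tab)
  list(factor = factor, counts = unclass(tab),
       percent = round(100 * unclass(tab) / rowSums(unclass(tab)), 1),
       statistic = chi$statistic, df = chi$df, p_value = chi$p_value)
}

#' Run the full association analysis
#'
#' Scores every record, cross-tabulates confounders and behavior factors
#' against comorbidity with chi-square tests, computes the Spearman
#' correlation matrix of the four behavior risk weights, and fits the
#' unadjusted (Model 1) and, when the confounders are present,
#' confounder-adjusted (Model 2) logistic models for each behavior factor,
#' plus gender-stratified fits.  Deterministic given records and config.
#'
#' @param records Validated raw records (scored internally) or pre-scored
#'   records (detected by the presence of a `comorbid` column).
#' @param config List of options: `conf_level` (default 0.95), `model2`
#'   (fit the adjusted model, default TRUE), `stratify` (gender-stratified
#'   fits, default TRUE).
#' @return Object of class `hrb_report`.
#' @export
run_analysis <- function(records, config = list()) {
  conf_level <- config$conf_level %||% 0.95
  scored <- if ("comorbid" %in% names(records)) records
            else score_records(records)
  if (!nrow(scored)) stop("no records to analyse")

  safe_tab <- function(f) tryCatch(xtab_with_chi2(scored, f),
    error = function(e) {
      warning("table for '", f, "' skipped: ", conditionMessage(e))
      NULL
    })
  demog <- names(survey_codebook())
  demog <- demog[demog %in% names(scored)]
  sample_tables <- Filter(Negate(is.null), lapply(demog, safe_tab))
  hrbs <- hrb_factors()[hrb_factors() %in% names(scored)]
  hrb_tables <- Filter(Negate(is.null), lapply(hrbs, safe_tab))

  weights <- data.frame(
    diet = risk_weight(scored$diet), smoking = risk_weight(scored$smoking),
    physical_inactivity = risk_weight(scored$physical_inactivity),
    sleep = risk_weight(scored$sleep))
  spearman <- tryCatch(spearman_matrix(weights), error = function(e) NULL,
                       warning = function(w) suppressWarnings(
                         spearman_matrix(weights)))

  model1 <- lapply(hrbs, function(f) {
    des <- encode_design(scored, design_spec(exposure = f))
    or_table(fit_logistic(des$y, des$X), des, conf_level)
  })
  names(model1) <- hrbs

  have_covs <- all(model2_covariates() %in% names(scored))
  model2 <- if (isTRUE(config$model2 %||% TRUE) && have_covs) {
    out <- lapply(hrbs, function(f) run_model2(scored, f,
                                               conf_level = conf_level))
    names(out) <- hrbs
    out
  }
  stratified <- if (isTRUE(config$stratify %||% TRUE) &&
                    "gender" %in% names(scored) && have_covs) {
    out <- lapply(hrbs, function(f) stratified_or(scored, f,
                                                  conf_level = conf_level))
    names(out) <- hrbs
    out
  }

  structure(list(
    n = nrow(scored),
    prevalence = list(comorbid = sum(scored$comorbid),
                      total = nrow(scored),
                      percent = 100 * mean(scored$comorbid)),
    sample_tables = sample_tables, hrb_tables = hrb_tables,
    spearman = spearman, model1 = model1, model2 = model2,
    stratified = stratified,
    provenance = list(n_records = nrow(scored),
                      config = config,
                      config_hash = config_hash(config),
                      timestamp = NULL)),  # timestamp left NULL: reports byte-identical
    class = "hrb_report")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

config_hash <- function(config) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA), tf)
  unname(tools::md5sum(tf))
}

#' @export
print.hrb_report <- function(x, ...) {
  cat("HRB / comorbidity analysis of", x$n, "records\n")
  cat(sprintf("Comorbidity prevalence: %.1f%% (%d/%d)\n\n",
              x$prevalence$percent, x$prevalence$comorbid, x$prevalence$total))
  for (tb in x$hrb_tables)
    cat(sprintf("%-20s chi-square %.2f (df %d), p %s\n", tb$factor,
                tb$statistic, tb$df, format.pval(tb$p_value, eps = 1e-3)))
  if (length(x$model1)) {
    cat("\nUnadjusted odds ratios (low-risk reference):\n")
    for (f in names(x$model1)) {
      t1 <- x$model1[[f]]
      rows <- t1[!is.na(t1$factor) & !t1$reference, , drop = FALSE]
      for (i in seq_len(nrow(rows)))
        cat(sprintf("  %-20s %-7s %.2f (%.2f-%.2f)\n", f, rows$level[i],
                    rows$or[i], rows$ci_low[i], rows$ci_high[i]))
    }
  }
  invisible(x)
}

#' Write an analysis report to disk
#'
#' Emits `report.json` (full precision) plus per-table CSVs (counts,
#' percentages and statistics rounded to 2 decimals, as in the published
#' tables).
#'
#' @param report An `hrb_report`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, "report.json")
  jsonlite::write_json(unclass_report(report), paths[1L], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null")
  tab_df <- do.call(rbind, lapply(c(report$sample_tables, report$hrb_tables),
    function(tb) data.frame(
      factor = tb$factor, level = rownames(tb$counts),
      comorbid = tb$counts[, 1L], noncomorbid = tb$counts[, 2L],
      pct_comorbid = tb$percent[, 1L],
      statistic = round(tb$statistic, 2), df = tb$df,
      p_value = signif(tb$p_value, 3), row.names = NULL)))
  p <- file.path(dir, "crosstabs.csv")
  utils::write.csv(tab_df, p, row.names = FALSE)
  paths <- c(paths, p)
  for (model in c("model1", "model2")) {
    if (is.null(report[[model]])) next
    or_df <- do.call(rbind, lapply(names(report[[model]]), function(f) {
      t1 <- report[[model]][[f]]
      t1 <- t1[!is.na(t1$factor) & t1$factor == f, , drop = FALSE]
      data.frame(factor = f, level = t1$level, or = round(t1$or, 2),
                 ci_low = round(t1$ci_low, 2), ci_high = round(t1$ci_high, 2),
                 p_value = signif(t1$p_value, 3), reference = t1$reference)
    }))
    p <- file.path(dir, paste0(model, "_odds_ratios.csv"))
    utils::write.csv(or_df, p, row.names = FALSE, na = "")
    paths <- c(paths, p)
  }
  invisible(paths)
}

unclass_report <- function(report) {
  strip <- function(x) {
    if (inherits(x, "data.frame")) return(x)
    if (is.matrix(x)) return(as.data.frame(x))
    if (is.list(x)) return(lapply(x, strip))
    x
  }
  strip(unclass(report))
}

#' Reproduce the published aggregate tables from the packaged fixtures
#'
#' Expands the packaged behavior-by-comorbidity frequency tables into
#' individual records and recomputes the chi-square statistics and the
#' unadjusted (Model 1) odds ratios, both closed-form and by logistic
#' regression on the expansion.
#'
#' @param conf_level Confidence level for the CIs, default 0.95.
#' @return List with `chi_square` and `model1_or` data frames.
#' @export
#' @examples
#' reproduce_tables()$chi_square
reproduce_tables <- function(conf_level = 0.95) {
  tabs <- hrb_fixture_tables()
  chi <- do.call(rbind, lapply(tabs, function(tb) {
    m <- as.matrix(tb[, c("comorbid", "noncomorbid")])
    rownames(m) <- tb$level
    r <- pearson_chi_square(m)
    data.frame(factor = attr(tb, "factor"), statistic = r$statistic,
               df = r$df, p_value = r$p_value, row.names = NULL)
  }))
  ors <- do.call(rbind, lapply(tabs, function(tb) {
    m <- as.matrix(tb[, c("comorbid", "noncomorbid")])
    rownames(m) <- tb$level
    closed <- odds_ratio_table(m, conf_level)
    records <- expand_frequency_table(tb)
    des <- encode_design(records,
                         design_spec(exposure = attr(tb, "factor")))
    logit <- or_table(fit_logistic(des$y, des$X), des, conf_level)
    logit <- logit[!is.na(logit$factor) & !logit$reference, , drop = FALSE]
    data.frame(factor = attr(tb, "factor"), level = closed$level,
               or = closed$estimate, ci_low = closed$ci_low,
               ci_high = closed$ci_high, p_value = closed$p_value,
               or_logistic = logit$or[match(closed$level, logit$level)],
               row.names = NULL)
  }))
  list(chi_square = chi, model1_or = ors)
}
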