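#' Declare a logistic-model design
#'
#' Names the binary outcome, the exposure factor, the categorical
#' confounders and their reference levels, and an optional stratifying
#' variable.  Reference levels default to the low-risk group for behavior
#' factors and to the codebook defaults (see [reference_levels()]) for
#' confounders; any can be overridden.
#'
#' @param outcome Name of the logical outcome column (default "comorbid").
#' @param exposure Name of the exposure factor column.
#' @param covariates Character vector of confounder columns (default none:
#'   the unadjusted model).
#' @param references Named list overriding reference levels.
#' @param strata Optional name of a stratifying variable.
#' @return An object of class `design_spec`.
#' @export
design_spec <- function(outcome = "comorbid", exposure,
                        covariates = character(), references = list(),
                        strata = NULL) {
  if (exposure %in% covariates)
    stop("exposure '", exposure, "' may not also be a covariate")
  structure(list(outcome = outcome, exposure = exposure,
                 covariates = covariates, references = references,
                 strata = strata),
            class = "design_spec")
}

#' Default reference levels for the survey factors
#'
#' Behavior risk factors are referenced at low risk (as in the report
#' tables).  Confounder references are a fixed convention: boy, no siblings,
#' second-line city, junior high school, good self-rated health, the highest
#' parental education band, medium income, three or more friends, low
#' learning burden, no family history of psychosis.
#'
#' @return Named character vector of reference levels.
#' @export
reference_levels <- function() {
  c(diet = "low", smoking = "low", physical_inactivity = "low",
    sleep = "low", hrb_index = "low",
    gender = "boy", siblings = "no", region_level = "second_line",
    residence = "urban", edu_status = "junior",
    father_edu = "senior_high_or_above", mother_edu = "senior_high_or_above",
    family_income = "medium", num_friends = "ge3", learning_burden = "low",
    family_psychosis = "no", self_rated_health = "good")
}

factor_levels_for <- function(var, values) {
  cb <- survey_codebook()
  if (var %in% names(cb)) cb[[var]]
  else if (all(values %in% hrb_levels())) hrb_levels()
  else unique(values)
}

#' Encode a logistic design matrix with treatment (dummy) coding
#'
#' Each k-level factor contributes k - 1 indicator columns named
#' `factor:level`, omitting the reference level.  Rows with a missing
#' outcome, exposure or covariate are dropped (complete-case analysis) and
#' counted.
#'
#' @param records Data frame of classified records.
#' @param spec A [design_spec()].
#' @return List with `y` (0/1 vector), `X` (design matrix incl. intercept),
#'   `terms` (data frame mapping columns to factors/levels), `references`,
#'   and `n_dropped`.
#' @export
encode_design <- function(records, spec) {
  stopifnot(inherits(spec, "design_spec"))
  vars <- c(spec$exposure, spec$covariates)
  missing_cols <- setdiff(c(spec$outcome, vars), names(records))
  if (length(missing_cols))
    stop("columns absent from records: ", paste(missing_cols, collapse = ", "))
  used <- records[, c(spec$outcome, vars), drop = FALSE]
  keep <- stats::complete.cases(used)
  used <- used[keep, , drop = FALSE]
  if (!nrow(used)) stop("no complete-case records to fit")
  y <- as.numeric(as.logical(used[[spec$outcome]]))

  refs <- reference_levels()
  refs[names(spec$references)] <- unlist(spec$references)
  X <- matrix(1, nrow(used), 1L, dimnames = list(NULL, "(Intercept)"))
  terms <- data.frame(column = "(Intercept)", factor = NA, level = NA)
  for (v in vars) {
    vals <- as.character(used[[v]])
    levs <- factor_levels_for(v, vals)
    if (!all(vals %in% levs))
      stop("unseen level(s) in '", v, "': ",
           paste(setdiff(unique(vals), levs), collapse = ", "))
    ref <- if (v %in% names(refs)) refs[[v]] else levs[1L]
    if (!ref %in% levs)
      stop("reference level '", ref, "' not a level of '", v, "'")
    present <- levs[levs %in% unique(vals)]
    if (length(present) == 1L && present != ref)
      stop("factor '", v, "' collapses to the single non-reference level '",
           present, "' after filtering")
    for (l in setdiff(present, ref)) {
      X <- cbind(X, as.numeric(vals == l))
      colnames(X)[ncol(X)] <- paste0(v, ":", l)
      terms <- rbind(terms, data.frame(column = paste0(v, ":", l),
                                       factor = v, level = l))
    }
  }
  list(y = y, X = X, terms = terms, references = refs[vars[vars %in% names(refs)]],
       n_dropped = sum(!keep))
}

# log-likelihood of a logit fit, computed stably for large |eta|
logit_loglik <- function(y, eta) {
  sum(y * eta - ifelse(eta > 0, eta + log1p(exp(-eta)), log1p(exp(eta))))
}

#' Fit binary logistic regression by iteratively reweighted least squares
#'
#' Maximum-likelihood Newton-Raphson/IRLS with the observed (= expected)
#' information.  Convergence is declared when the largest score component
#' falls below `tol_score` or the relative log-likelihood change falls below
#' `tol_ll`.  Quasi-complete separation (fitted probabilities degenerating
#' to 0/1 with diverging coefficients) and rank deficiency raise explicit
#' errors rather than returning a silently unstable fit.
#'
#' @param y Binary response (0/1 or logical).
#' @param X Design matrix including the intercept column.
#' @param max_iter Iteration cap, default 25.
#' @param tol_score Score-norm tolerance, default 1e-8.
#' @param tol_ll Relative log-likelihood tolerance, default 1e-10.
#' @return An object of class `logistic_fit`: `coefficients`, `covariance`,
#'   `n_iterations`, `converged`, `log_likelihood`, `loglik_trace`, `n`.
#' @export
fit_logistic <- function(y, X, max_iter = 25L, tol_score = 1e-8,
                         tol_ll = 1e-10) {
  y <- as.numeric(y)
  stopifnot(is.matrix(X), length(y) == nrow(X), all(y %in% c(0, 1)))
  if (all(y == y[1L]))
    stop("degenerate response: all outcomes equal, model is inestimable")
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }
  p <- ncol(X)
  beta <- numeric(p)
  ll <- logit_loglik(y, drop(X %*% beta))
  trace <- ll
  converged <- FALSE
  iter <- 0L
  info <- NULL
  while (iter < max_iter) {
    iter <- iter + 1L
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- mu * (1 - mu)
    score <- drop(crossprod(X, y - mu))
    info <- crossprod(X, X * w)
    if (max(abs(beta)) > 30 || min(diag(info)) < 1e-10)
      stop("separation detected: coefficients diverging (|beta| > 30); ",
           "the likelihood has no finite maximum")
    beta <- beta + solve(info, score)
    ll_new <- logit_loglik(y, drop(X %*% beta))
    trace <- c(trace, ll_new)
    if (max(abs(score)) < tol_score ||
        abs(ll_new - ll) < tol_ll * (abs(ll) + tol_ll)) {
      converged <- TRUE
      ll <- ll_new
      break
    }
    ll <- ll_new
  }
  # covariance at the final estimate
  eta <- drop(X %*% beta)
  w <- stats::plogis(eta) * (1 - stats::plogis(eta))
  info <- crossprod(X, X * w)
  cov <- solve(info)
  names(beta) <- colnames(X)
  dimnames(cov) <- list(colnames(X), colnames(X))
  structure(list(coefficients = beta, covariance = cov,
                 n_iterations = iter, converged = converged,
                 log_likelihood = ll, loglik_trace = trace, n = length(y)),
            class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat("Logistic fit:", length(x$coefficients), "coefficients, n =", x$n,
      "\n  log-likelihood", format(x$log_likelihood),
      if (x$converged) paste0("(converged in ", x$n_iterations, " iterations)")
      else "(NOT converged)", "\n")
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Odds-ratio table of a fitted logistic model
#'
#' Exponentiates each coefficient into an odds ratio with a Wald confidence
#' interval exp(beta +/- z * SE) and a two-sided Wald p-value.  When the
#' design metadata are supplied, reference levels are inserted as OR 1 rows
#' without a CI, grouped under their factor.
#'
#' @param fit A converged [fit_logistic()] result.
#' @param design Optional `encode_design()` result (for reference rows).
#' @param conf_level Confidence level, default 0.95.
#' @return Data frame with `term`, `factor`, `level`, `or`, `ci_low`,
#'   `ci_high`, `p_value`, `reference`.
#' @export
or_table <- function(fit, design = NULL, conf_level = 0.95) {
  stopifnot(inherits(fit, "logistic_fit"))
  if (!fit$converged)
    stop("fit did not converge; odds ratios would be unreliable")
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  beta <- fit$coefficients
  se <- sqrt(diag(fit$covariance))
  tab <- data.frame(term = names(beta), factor = NA_character_,
                    level = NA_character_, or = exp(beta),
                    ci_low = exp(beta - z * se), ci_high = exp(beta + z * se),
                    p_value = 2 * stats::pnorm(-abs(beta / se)),
                    reference = FALSE, row.names = NULL)
  if (!is.null(design)) {
    tm <- design$terms
    tab$factor <- tm$factor[match(tab$term, tm$column)]
    tab$level <- tm$level[match(tab$term, tm$column)]
    refs <- design$references
    ref_rows <- data.frame(term = paste0(names(refs), ":", unlist(refs)),
                           factor = names(refs), level = unlist(refs),
                           or = 1, ci_low = NA, ci_high = NA, p_value = NA,
                           reference = TRUE, row.names = NULL)
    out <- tab[tab$term == "(Intercept)", , drop = FALSE]
    for (f in unique(stats::na.omit(tab$factor))) {
      out <- rbind(out, ref_rows[ref_rows$factor == f, , drop = FALSE],
                   tab[!is.na(tab$factor) & tab$factor == f, , drop = FALSE])
    }
    tab <- out
  }
  rownames(tab) <- NULL
  tab
}

#' The fixed confounder list of the adjusted model
#'
#' @param include_gender Keep gender as a covariate (drop it when fitting
#'   within gender strata).
#' @return Character vector of covariate column names.
#' @export
model2_covariates <- function(include_gender = TRUE) {
  covs <- c("gender", "siblings", "region_level", "edu_status",
            "self_rated_health", "father_edu", "mother_edu", "family_income",
            "num_friends", "learning_burden", "family_psychosis")
  if (!include_gender) setdiff(covs, "gender") else covs
}

#' Fit the confounder-adjusted logistic model for one exposure
#'
#' Adjusts for the fixed demographic confounder set (presence of siblings,
#' regional economic level, educational status, self-rated health, parental
#' education, family income, number of friends, learning burden, family
#' history of psychosis, and gender unless stratified) and returns the
#' exposure's odds-ratio rows.
#'
#' @param records Data frame of classified records.
#' @param exposure Exposure factor column name.
#' @param include_gender Include gender as a covariate, default TRUE.
#' @param conf_level Confidence level, default 0.95.
#' @return Odds-ratio table restricted to the exposure's rows (reference
#'   included), with the full table as attribute `"full"`.
#' @export
run_model2 <- function(records, exposure, include_gender = TRUE,
                       conf_level = 0.95) {
  spec <- design_spec(exposure = exposure,
                      covariates = model2_covariates(include_gender))
  des <- encode_design(records, spec)
  fit <- fit_logistic(des$y, des$X)
  full <- or_table(fit, des, conf_level)
  out <- full[!is.na(full$factor) & full$factor == exposure, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "full") <- full
  attr(out, "n_dropped") <- des$n_dropped
  out
}

#' Gender-stratified unadjusted and adjusted exposure fits
#'
#' Fits the exposure model separately within each stratum (gender by
#' default), dropping the stratifying variable from the covariate list.
#'
#' @param records Data frame of classified records.
#' @param exposure Exposure factor column name.
#' @param strata Stratifying column, default "gender".
#' @param adjusted Fit the confounder-adjusted model (default) or the
#'   unadjusted one.
#' @param conf_level Confidence level, default 0.95.
#' @return Named list of per-stratum odds-ratio tables.
#' @export
stratified_or <- function(records, exposure, strata = "gender",
                          adjusted = TRUE, conf_level = 0.95) {
  if (!strata %in% names(records)) stop("no stratum column '", strata, "'")
  lv <- factor_levels_for(strata, records[[strata]])
  lv <- lv[lv %in% unique(records[[strata]])]
  out <- lapply(lv, function(s) {
    sub <- records[!is.na(records[[strata]]) & records[[strata]] == s, ,
                   drop = FALSE]
    if (adjusted) {
      run_model2(sub, exposure,
                 include_gender = !identical(strata, "gender"),
                 conf_level = conf_level)
    } else {
      des <- encode_design(sub, design_spec(exposure = exposure))
      or_table(fit_logistic(des$y, des$X), des, conf_level)
    }
  })
  names(out) <- lv
  out
}
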