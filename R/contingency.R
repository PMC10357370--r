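#' Cross-tabulate a factor against comorbidity status
#'
#' Builds the r x 2 table underlying the report tables: one row per factor
#' level (risk factors in low/medium/high order), columns comorbid and
#' non-comorbid.
#'
#' @param records Data frame of classified records.
#' @param row_factor Name of the factor column.
#' @param outcome Name of the logical comorbidity column.
#' @param levels Optional explicit row ordering; defaults to
#'   low/medium/high when the observed levels are risk levels, otherwise to
#'   order of first appearance.
#' @return An object of class `hrb_xtab`: the counts matrix with row/column
#'   totals as attributes.
#' @export
crosstab <- function(records, row_factor, outcome = "comorbid",
                     levels = NULL) {
  if (!is.data.frame(records) || nrow(records) == 0L)
    stop("records must be a non-empty data frame")
  if (!row_factor %in% names(records))
    stop("unknown factor column '", row_factor, "'")
  if (!outcome %in% names(records))
    stop("unknown outcome column '", outcome, "'")
  f <- records[[row_factor]]
  y <- records[[outcome]]
  keep <- !is.na(f) & !is.na(y)
  f <- as.character(f[keep]); y <- as.logical(y[keep])
  if (!length(f)) stop("no complete records for '", row_factor, "'")
  if (is.null(levels)) {
    levels <- if (all(unique(f) %in% hrb_levels()))
      intersect(hrb_levels(), unique(f)) else unique(f)
  }
  if (!all(f %in% levels))
    stop("factor values outside declared levels: ",
         paste(setdiff(unique(f), levels), collapse = ", "))
  counts <- t(vapply(levels, function(l)
    c(comorbid = sum(f == l & y), noncomorbid = sum(f == l & !y)),
    numeric(2)))
  structure(counts, class = c("hrb_xtab", class(counts)),
            factor = row_factor)
}

#' @export
print.hrb_xtab <- function(x, ...) {
  cat("Cross-tabulation of", attr(x, "factor"), "by comorbidity\n")
  m <- unclass(x)
  pct <- sprintf("(%.1f)", 100 * m / rowSums(m))
  out <- matrix(paste(format(m, big.mark = ","), pct), nrow(m),
                dimnames = dimnames(m))
  print(out, quote = FALSE)
  invisible(x)
}

#' Pearson chi-square test of a contingency table
#'
#' Uncorrected Pearson statistic, sum((O - E)^2 / E), with
#' df = (r - 1)(c - 1) and an upper-tail chi-square p-value.  No continuity
#' correction is applied: the published df-bearing statistics this package
#' reproduces are uncorrected.
#'
#' @param counts An `hrb_xtab` or plain matrix of non-negative counts.
#' @return List with `statistic`, `df`, `p_value`.
#' @export
#' @examples
#' pearson_chi_square(rbind(c(3203, 8375), c(4033, 7257)))
pearson_chi_square <- function(counts) {
  m <- unclass(counts)
  stopifnot(is.matrix(m), all(m >= 0))
  if (nrow(m) < 2L || ncol(m) < 2L)
    stop("degenerate table: fewer than two rows or columns")
  if (sum(m) == 0) stop("degenerate table: grand total is zero")
  if (any(rowSums(m) == 0) || any(colSums(m) == 0))
    stop("degenerate table: a zero row or column marginal")
  ct <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p_value = unname(ct$p.value))
}

#' Odds ratio of a 2x2 table with a Woolf confidence interval
#'
#' For cell counts (a, b, c, d) = exposed-case, exposed-control,
#' reference-case, reference-control, the estimate is ad/bc; the CI is the
#' Woolf log-scale interval exp(log(OR) +/- z * sqrt(1/a + 1/b + 1/c + 1/d))
#' and the p-value the two-sided Wald test of log(OR) = 0.
#'
#' @param a,b,c,d Positive cell counts.
#' @param conf_level Confidence level, default 0.95.
#' @return List with `estimate`, `ci_low`, `ci_high`, `conf_level`,
#'   `p_value`.
#' @export
#' @examples
#' odds_ratio(4775, 7912, 294, 1507)  # high vs low HRB risk index
odds_ratio <- function(a, b, c, d, conf_level = 0.95) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(is.na(cells)) || any(cells <= 0))
    stop("odds_ratio requires four strictly positive cell counts; ",
         "zero cells need an explicit correction chosen by the analyst")
  est <- (a * d) / (b * c)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  list(estimate = est,
       ci_low = est * exp(-z * se),
       ci_high = est * exp(z * se),
       conf_level = conf_level,
       p_value = 2 * stats::pnorm(-abs(log(est) / se)))
}

#' Odds ratios of every non-reference row of a contingency table
#'
#' The first row (the low-risk group in the report tables) is the reference;
#' each later level is compared to it with [odds_ratio()].
#'
#' @param counts An `hrb_xtab` or r x 2 matrix (columns case, control).
#' @param conf_level Confidence level, default 0.95.
#' @return Data frame with one row per non-reference level: `level`,
#'   `estimate`, `ci_low`, `ci_high`, `p_value`.
#' @export
odds_ratio_table <- function(counts, conf_level = 0.95) {
  m <- unclass(counts)
  stopifnot(is.matrix(m), nrow(m) >= 2L)
  ref <- m[1L, ]
  rows <- lapply(2:nrow(m), function(i) {
    o <- odds_ratio(m[i, 1L], m[i, 2L], ref[1L], ref[2L], conf_level)
    data.frame(level = rownames(m)[i], estimate = o$estimate,
               ci_low = o$ci_low, ci_high = o$ci_high, p_value = o$p_value)
  })
  do.call(rbind, rows)
}

#' Spearman correlation matrix with t-approximation p-values
#'
#' Pairwise Spearman rank correlations (midranks for ties) over the supplied
#' ordinal columns, with two-sided p-values from the t approximation
#' t = rho * sqrt((n - 2) / (1 - rho^2)) on n - 2 df.  A constant column has
#' no defined rank correlation; its entries are returned as `NA` with a
#' warning.
#'
#' @param x Data frame or matrix of ordinal columns (e.g. the four HRB risk
#'   weights per record).
#' @return List with `labels`, `rho` and `p_values` matrices.
#' @export
spearman_matrix <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 3L) stop("at least 3 records are required")
  k <- ncol(x)
  labels <- colnames(x)
  constant <- apply(x, 2L, function(v) length(unique(v[!is.na(v)])) < 2L)
  if (any(constant))
    warning("constant column(s) ", paste(labels[constant], collapse = ", "),
            ": correlation undefined, reported as NA")
  rho <- suppressWarnings(  # sd-zero warning superseded by the one above
    stats::cor(x, method = "spearman", use = "pairwise.complete.obs"))
  rho[constant, ] <- NA; rho[, constant] <- NA
  diag(rho) <- ifelse(constant, NA, 1)
  n <- crossprod(!is.na(x))
  tstat <- rho * sqrt((n - 2) / pmax(1 - rho^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  diag(p) <- NA
  list(labels = labels, rho = rho, p_values = p)
}
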