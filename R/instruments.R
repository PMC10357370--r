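#' Risk levels and their index weights
#'
#' Every behavior classifier in the package returns one of three ordered risk
#' levels.  The composite HRB risk index sums per-behavior weights of 0 (low),
#' 0.5 (medium) and 1 (high).
#'
#' @return `hrb_levels()` returns the ordered level names; `risk_weight()`
#'   maps a vector of level names to their index weights.
#' @export
hrb_levels <- function() c("low", "medium", "high")

#' @param level Character vector of risk levels.
#' @rdname hrb_levels
#' @export
risk_weight <- function(level) {
  w <- c(low = 0, medium = 0.5, high = 1)[match(level, hrb_levels())]
  if (any(is.na(w) & !is.na(level))) {
    bad <- which(is.na(w) & !is.na(level))[1L]
    stop("unknown risk level '", level[bad], "' at position ", bad)
  }
  unname(w)
}

# factor with the canonical low < medium < high ordering, NA-preserving
risk_factor <- function(level) factor(level, levels = hrb_levels())

scale_n_items <- c(GAD7 = 7L, PHQ9 = 9L)
scale_max     <- c(GAD7 = 21L, PHQ9 = 27L)

#' Score the GAD-7 or PHQ-9 screening scale
#'
#' Items are 4-point Likert responses, 0 ("not at all") to 3 ("nearly every
#' day").  The total is banded 0-4 normal, 5-9 mild, 10-14 moderate and >= 15
#' severe, and a symptom flag is raised at the conventional cutoff of 5.
#'
#' @param items Integer vector of item responses in 0-3; length 7 for GAD7,
#'   9 for PHQ9.  Any `NA` item yields an `NA` result (no imputation).
#' @param scale `"GAD7"` or `"PHQ9"`.
#' @return List with `total`, `severity` (normal/mild/moderate/severe) and
#'   `positive` (total >= 5).
#' @export
#' @examples
#' score_scale(c(1, 1, 1, 1, 1, 0, 0, 0, 0), "PHQ9")
score_scale <- function(items, scale = c("GAD7", "PHQ9")) {
  scale <- match.arg(scale)
  k <- scale_n_items[[scale]]
  if (length(items) != k)
    stop(scale, " requires exactly ", k, " items, got ", length(items))
  bad <- which(!is.na(items) & (items %% 1 != 0 | items < 0 | items > 3))
  if (length(bad))
    stop(scale, " item ", bad[1L], " is out of range 0-3: ", items[bad[1L]])
  total <- sum(items)
  list(total = total,
       severity = scale_severity(total),
       positive = if (is.na(total)) NA else total >= 5)
}

scale_severity <- function(total) {
  c("normal", "mild", "moderate", "severe")[
    findInterval(total, c(0, 5, 10, 15))]
}

# vectorised scorer for the pipeline: one row of items per record
score_scale_rows <- function(m, scale) {
  k <- scale_n_items[[scale]]
  stopifnot(ncol(m) == k)
  ok <- !is.na(m)
  if (any(m[ok] %% 1 != 0 | m[ok] < 0 | m[ok] > 3))
    stop(scale, " items outside 0-3 present; filter records first")
  total <- rowSums(m)
  data.frame(total = total,
             severity = ifelse(is.na(total), NA, scale_severity(total)),
             positive = total >= 5)
}

#' Classify comorbid anxiety and depression
#'
#' Comorbidity requires both symptom flags: a GAD-7 total >= 5 and a PHQ-9
#' total >= 5.
#'
#' @param anxiety,depression Logical vectors (recycled to common length).
#' @return Data frame with logical columns `anxiety`, `depression`,
#'   `comorbid`.
#' @export
classify_comorbidity <- function(anxiety, depression) {
  if (missing(anxiety) || missing(depression) ||
      is.null(anxiety) || is.null(depression))
    stop("both anxiety and depression flags are required")
  stopifnot(is.logical(anxiety), is.logical(depression))
  data.frame(anxiety = anxiety, depression = depression,
             comorbid = anxiety & depression)
}

#' Score the four-item diet composite
#'
#' Each component (fruit, vegetable, fast food, soft drink) carries a risk
#' score in 0/1/2 mapped from last-week consumption frequency (see
#' [map_diet_frequency()]).  The composite total runs 0-8.  A total of 2 is
#' ambiguous between "two medium components" (1+1) and "one high component"
#' (2): the former is low risk, the latter medium, because a low-risk diet
#' may not contain any high-risk component.  Totals <= 1 are low, 3 medium
#' and >= 4 high.
#'
#' @param fruit,vegetable,fastfood,softdrink Integer component risk scores in
#'   0-2 (vectors recycled to common length; `NA` propagates).
#' @return Data frame with `total` (0-8) and `level` (low/medium/high).
#' @export
#' @examples
#' score_diet(1, 1, 0, 0)  # total 2, low
#' score_diet(0, 0, 2, 0)  # total 2, medium
score_diet <- function(fruit, vegetable, fastfood, softdrink) {
  comp <- cbind(fruit, vegetable, fastfood, softdrink)
  ok <- !is.na(comp)
  if (any(comp[ok] %% 1 != 0 | comp[ok] < 0 | comp[ok] > 2)) {
    bad <- which(matrix(ok & (comp %% 1 != 0 | comp < 0 | comp > 2),
                        nrow(comp)), arr.ind = TRUE)[1, ]
    stop("diet component ", colnames(comp)[bad[2L]],
         " out of range {0,1,2} in record ", bad[1L])
  }
  total <- rowSums(comp)
  any_high <- apply(comp == 2, 1L, any)
  level <- ifelse(total <= 1, "low",
           ifelse(total == 2, ifelse(any_high, "medium", "low"),
           ifelse(total == 3, "medium", "high")))
  data.frame(total = total, level = ifelse(is.na(total), NA, level))
}

#' Map raw diet consumption frequencies to component risk scores
#'
#' Default thresholds on last-week frequency replies: fruit and vegetable
#' score 0 at 3+, 1 at exactly 2, 2 at 1 or fewer; fast food scores 0 at 0,
#' 1 at 1-4, 2 at 5+; soft drinks score 0 at 1 or fewer, 1 at 2, 2 at 3 or
#' more.  The survey's exact response wording is not fixed by the scoring
#' rules, so the cut points are configurable per item.
#'
#' @param freq Integer vector of weekly consumption frequencies (>= 0).
#' @param item One of `"fruit"`, `"vegetable"`, `"fastfood"`, `"softdrink"`.
#' @param cuts Optional named list overriding the per-item lower bounds of
#'   the score-1 and score-2 bands, e.g. `list(fastfood = c(1, 5))`.
#' @return Integer risk scores in 0-2.
#' @export
map_diet_frequency <- function(freq,
                               item = c("fruit", "vegetable", "fastfood",
                                        "softdrink"),
                               cuts = NULL) {
  item <- match.arg(item)
  ok <- !is.na(freq)
  if (any(freq[ok] < 0 | freq[ok] %% 1 != 0))
    stop("diet frequency must be a non-negative integer count per week")
  out <- rep(NA_integer_, length(freq))
  if (item %in% c("fruit", "vegetable")) {
    # protective items: infrequent consumption is the risk
    out[ok] <- ifelse(freq[ok] >= 3, 0L, ifelse(freq[ok] == 2, 1L, 2L))
  } else {
    b <- if (!is.null(cuts[[item]])) cuts[[item]]
         else if (item == "fastfood") c(1, 5) else c(2, 3)
    out[ok] <- findInterval(freq[ok], c(0, b)) - 1L
  }
  out
}

#' Classify last-month smoking days
#'
#' Bands: 0-2 days low risk, 3-19 medium, 20 or more high.  (The published
#' bands "less than 2" and "3 to 19" leave exactly 2 days unassigned; 2 is
#' placed in the low band so the medium band starts at its stated lower
#' bound of 3.)
#'
#' @param days Integer vector of smoking days in the last month, 0-31.
#' @return Character vector of risk levels.
#' @export
classify_smoking <- function(days) {
  ok <- !is.na(days)
  if (any(days[ok] < 0 | days[ok] > 31 | days[ok] %% 1 != 0)) {
    bad <- which(ok & (days < 0 | days > 31 | days %% 1 != 0))[1L]
    stop("smoking days out of range 0-31 in record ", bad, ": ", days[bad])
  }
  ifelse(is.na(days), NA,
         ifelse(days <= 2, "low", ifelse(days <= 19, "medium", "high")))
}

#' Parse "HH:MM" clock times to minutes past midnight
#'
#' @param x Character vector of 24-hour clock times.
#' @return Integer minutes in 0-1439 (`NA` passes through).
#' @export
parse_clock_time <- function(x) {
  out <- rep(NA_integer_, length(x))
  ok <- !is.na(x)
  m <- regmatches(x[ok], regexec("^([01]?[0-9]|2[0-3]):([0-5][0-9])$", x[ok]))
  good <- lengths(m) == 3L
  if (!all(good))
    stop("unparseable clock time '", x[ok][!good][1L], "' (expected HH:MM)")
  out[ok] <- vapply(m, function(p) 60L * as.integer(p[2L]) + as.integer(p[3L]),
                    integer(1))
  out
}

#' Compute sleep duration and its risk band
#'
#' Duration is wake time minus fall-asleep time modulo 24 h (the short-form
#' chronotype questionnaire reports bedtime, fall-asleep time and wake time;
#' duration is taken from sleep onset, the time actually asleep).  Bands
#' follow the 8-10 h recommendation for adolescents: 8-10 h inclusive low
#' risk, 7 h up to (not including) 8 h or above 10 up to 11 h inclusive
#' medium, under 7 h or over 11 h high.
#'
#' @param sleep_onset,wake_time "HH:MM" strings or minutes past midnight.
#' @return Data frame with `duration_hours` and `level`.
#' @export
#' @examples
#' score_sleep("23:00", "07:00")  # 8 h, low risk
score_sleep <- function(sleep_onset, wake_time) {
  to_min <- function(v) if (is.character(v)) parse_clock_time(v) else v
  onset <- to_min(sleep_onset); wake <- to_min(wake_time)
  dur_min <- (wake - onset) %% 1440L
  dur_min[!is.na(dur_min) & dur_min == 0L] <- 1440L  # duration in (0, 24]
  h <- dur_min / 60
  level <- ifelse(h >= 8 & h <= 10, "low",
           ifelse((h >= 7 & h < 8) | (h > 10 & h <= 11), "medium", "high"))
  data.frame(duration_hours = h, level = ifelse(is.na(h), NA, level))
}

#' Score the three-item physical activity rating (PAR-3)
#'
#' Activity amount is intensity points (1-5) times time points (0-4) times
#' frequency points (1-5), giving 0-100.  Because low activity is the health
#' risk, the bands invert: score <= 19 is high risk (physical inactivity),
#' 20-42 medium, >= 43 low.
#'
#' @param intensity_points Integer 1-5.
#' @param time_points Integer 0-4 (response category minus one).
#' @param frequency_points Integer 1-5.
#' @return Data frame with `score` (0-100) and `level`.
#' @export
score_par3 <- function(intensity_points, time_points, frequency_points) {
  chk <- function(v, lo, hi, what) {
    ok <- !is.na(v)
    if (any(v[ok] < lo | v[ok] > hi | v[ok] %% 1 != 0))
      stop(what, " points out of range ", lo, "-", hi)
  }
  chk(intensity_points, 1, 5, "intensity")
  chk(time_points, 0, 4, "time")
  chk(frequency_points, 1, 5, "frequency")
  score <- intensity_points * time_points * frequency_points
  level <- ifelse(score <= 19, "high", ifelse(score <= 42, "medium", "low"))
  data.frame(score = score, level = ifelse(is.na(score), NA, level))
}

#' Combine four behavior risk levels into the weighted HRB risk index
#'
#' Each behavior contributes 0 (low), 0.5 (medium) or 1 (high); the sum runs
#' 0-4 and is banded 0-0.5 low, 1-1.5 medium, 2-4 high.
#'
#' @param diet,smoking,physical_inactivity,sleep Character vectors of risk
#'   levels (recycled to common length; `NA` propagates).
#' @return Data frame with `index_score` and `index_level`.
#' @export
#' @examples
#' hrb_risk_index("high", "high", "low", "low")  # score 2, high risk
hrb_risk_index <- function(diet, smoking, physical_inactivity, sleep) {
  w <- cbind(risk_weight(diet), risk_weight(smoking),
             risk_weight(physical_inactivity), risk_weight(sleep))
  if (ncol(w) != 4L) stop("all four behavior levels are required")
  score <- rowSums(w)
  level <- ifelse(score <= 0.5, "low", ifelse(score <= 1.5, "medium", "high"))
  data.frame(index_score = score,
             index_level = ifelse(is.na(score), NA, level))
}
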