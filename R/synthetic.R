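# ---- preimage tables -------------------------------------------------------
# Enumerations of every raw-response combination per risk band, so that the
# generator can draw uniformly from the exact preimage of each category under
# the corresponding scorer.  Built lazily and cached for the session.

.preimage <- new.env(parent = emptyenv())

# N[m + 1, s + 1] = number of m-item vectors over {0..3} summing to s
likert_sum_counts <- function(k_max = 9L, item_max = 3L) {
  key <- paste0("likert", k_max)
  if (!is.null(.preimage[[key]])) return(.preimage[[key]])
  s_max <- k_max * item_max
  N <- matrix(0, k_max + 1L, s_max + 1L)
  N[1L, 1L] <- 1
  for (m in seq_len(k_max)) {
    for (s in 0:(m * item_max)) {
      v <- 0:min(item_max, s)
      N[m + 1L, s + 1L] <- sum(N[m, s - v + 1L])
    }
  }
  .preimage[[key]] <- N
  N
}

diet_preimage <- function() {
  if (is.null(.preimage$diet)) {
    grid <- as.matrix(expand.grid(fruit = 0:2, vegetable = 0:2,
                                  fastfood = 0:2, softdrink = 0:2))
    lev <- score_diet(grid[, 1], grid[, 2], grid[, 3], grid[, 4])$level
    .preimage$diet <- list(grid = grid, level = lev)
  }
  .preimage$diet
}

par3_preimage <- function() {
  if (is.null(.preimage$par3)) {
    grid <- as.matrix(expand.grid(intensity_points = 1:5, time_points = 0:4,
                                  frequency_points = 1:5))
    lev <- score_par3(grid[, 1], grid[, 2], grid[, 3])$level
    .preimage$par3 <- list(grid = grid, level = lev)
  }
  .preimage$par3
}

# duration preimages in minutes; the sleep scorer's domain is (0, 24] h
sleep_duration_sets <- function() {
  list(low = 480:600, medium = c(420:479, 601:660),
       high = c(1:419, 661:1440))
}

smoking_day_sets <- function() list(low = 0:2, medium = 3:19, high = 20:31)

# inverse of the default diet frequency -> component-score map
diet_freq_sets <- list(
  fruit     = list(`0` = 3:7, `1` = 2L, `2` = 0:1),
  vegetable = list(`0` = 3:7, `1` = 2L, `2` = 0:1),
  fastfood  = list(`0` = 0L, `1` = 1:4, `2` = 5:7),
  softdrink = list(`0` = 0:1, `1` = 2L, `2` = 3:7))

# pick uniformly from a finite set, one draw per uniform in u
pick_from_set <- function(set, u) set[pmin(length(set), 1L + floor(u * length(set)))]

# uniformly sample item vectors over {0..3}^k conditional on the total lying
# in `totals`: first the total (weighted by its preimage size), then each item
# sequentially from the dynamic-programming counts
sample_likert_conditional <- function(k, totals, u_total, u_items) {
  N <- likert_sum_counts()
  getN <- function(m, s) ifelse(s < 0 | s > 3 * m, 0, N[m + 1L, pmax(s, 0) + 1L])
  n <- length(u_total)
  w <- N[k + 1L, totals + 1L]
  cum <- cumsum(w) / sum(w)
  tot <- totals[findInterval(u_total, cum, left.open = TRUE) + 1L]
  items <- matrix(0L, n, k)
  r <- tot
  for (t in seq_len(k - 1L)) {
    m <- k - t  # items remaining after this one
    W <- vapply(0:3, function(v) getN(m, r - v), numeric(n))
    if (n == 1L) W <- matrix(W, 1L)
    tw <- rowSums(W)
    c1 <- W[, 1L] / tw
    c2 <- (W[, 1L] + W[, 2L]) / tw
    c3 <- (W[, 1L] + W[, 2L] + W[, 3L]) / tw
    u <- u_items[, t]
    v <- (u > c1) + (u > c2) + (u > c3)
    items[, t] <- v
    r <- r - v
  }
  items[, k] <- r
  items
}

#' Draw raw responses uniformly from the preimage of a target category
#'
#' Returns raw instrument responses that are guaranteed to score back into
#' the requested category, drawn uniformly over all raw combinations that do
#' so (the scorer's preimage).  This is what keeps the cohort generator and
#' the scorers exactly consistent.
#'
#' @param instrument One of `"diet"`, `"smoking"`, `"sleep"`, `"par3"`,
#'   `"GAD7"`, `"PHQ9"`.
#' @param level Target category: a risk level (low/medium/high) for the
#'   behavior instruments; for the scales either `"positive"`/`"negative"`
#'   (the cutoff-5 flag) or a severity band
#'   (normal/mild/moderate/severe).
#' @param n Number of draws.
#' @param rng Function `rng(m)` returning `m` uniforms in (0, 1); defaults
#'   to [stats::runif()] (seed via `set.seed`).
#' @return Data frame of raw responses: components for diet, `days` for
#'   smoking, `sleep_onset`/`wake_time` clock strings for sleep, the three
#'   point scores for par3, or an item matrix for the scales.
#' @export
#' @examples
#' set.seed(1)
#' inverse_score_sample("par3", "medium", 3)
inverse_score_sample <- function(instrument, level, n = 1L,
                                 rng = stats::runif) {
  stopifnot(n >= 1L)
  switch(instrument,
    diet = {
      pi <- diet_preimage()
      idx <- which(pi$level == level)
      if (!length(idx)) stop("no diet combination scores as '", level, "'")
      as.data.frame(pi$grid[pick_from_set(idx, rng(n)), , drop = FALSE])
    },
    smoking = {
      set <- smoking_day_sets()[[level]]
      if (is.null(set)) stop("unknown smoking level '", level, "'")
      data.frame(days = pick_from_set(set, rng(n)))
    },
    sleep = {
      set <- sleep_duration_sets()[[level]]
      if (is.null(set)) stop("unknown sleep level '", level, "'")
      dur <- pick_from_set(set, rng(n))
      onset <- pick_from_set(0:1439, rng(n))
      data.frame(sleep_onset = format_clock(onset),
                 wake_time = format_clock((onset + dur) %% 1440L))
    },
    par3 = {
      pi <- par3_preimage()
      idx <- which(pi$level == level)
      if (!length(idx)) stop("no PAR-3 triple scores as '", level, "'")
      as.data.frame(pi$grid[pick_from_set(idx, rng(n)), , drop = FALSE])
    },
    GAD7 = ,
    PHQ9 = {
      k <- scale_n_items[[instrument]]
      smax <- scale_max[[instrument]]
      totals <- switch(level,
        positive = 5:smax, negative = 0:4, normal = 0:4, mild = 5:9,
        moderate = 10:14, severe = 15:smax,
        stop("unknown scale band '", level, "'"))
      u <- matrix(rng(n * k), n, k)
      items <- sample_likert_conditional(k, totals, u[, 1L],
                                         u[, -1L, drop = FALSE])
      items <- as.data.frame(items)
      names(items) <- paste0(tolower(substr(instrument, 1, 3)), seq_len(k))
      items
    },
    stop("unknown instrument '", instrument, "'"))
}

format_clock <- function(minutes) {
  sprintf("%02d:%02d", minutes %/% 60L, minutes %% 60L)
}

# ---- frequency tables ------------------------------------------------------

#' Construct a factor-by-comorbidity frequency table
#'
#' @param factor Factor name.
#' @param level Character vector of factor levels.
#' @param comorbid,noncomorbid Non-negative integer counts per level.
#' @return Object of class `freq_table`.
#' @export
frequency_table <- function(factor, level, comorbid, noncomorbid) {
  stopifnot(length(level) == length(comorbid),
            length(level) == length(noncomorbid))
  if (any(comorbid < 0) || any(noncomorbid < 0) ||
      any(c(comorbid, noncomorbid) %% 1 != 0))
    stop("counts must be non-negative integers")
  structure(data.frame(level = as.character(level),
                       comorbid = as.integer(comorbid),
                       noncomorbid = as.integer(noncomorbid)),
            factor = factor, class = c("freq_table", "data.frame"))
}

#' Packaged frequency-table fixtures from the published report
#'
#' `hrb_fixture_tables()` returns the five behavior-by-comorbidity tables
#' (poor diet, smoking, physical inactivity, poor sleep and the composite
#' HRB risk index); `confounder_fixture_tables()` the demographic tables.
#' Each sums to 7236 comorbid and 15,632 non-comorbid adolescents (22,868 in
#' total).  One demographic row (mother's education, senior high and above)
#' is reconstructed from the column totals because the published row is an
#' evident misprint; the family-income counts are kept as printed (their row
#' label n=786 is inconsistent, the counts are not).
#'
#' @return Named list of [frequency_table()] objects keyed by factor.
#' @export
hrb_fixture_tables <- function() {
  read_fixture("table2_hrb_counts.csv")
}

#' @rdname hrb_fixture_tables
#' @export
confounder_fixture_tables <- function() {
  read_fixture("table1_confounder_counts.csv")
}

read_fixture <- function(file) {
  path <- system.file("extdata", file, package = "hrbindex", mustWork = TRUE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  out <- lapply(split(raw, factor(raw$factor, levels = unique(raw$factor))),
                function(d) frequency_table(d$factor[1L], d$level,
                                            d$comorbid, d$noncomorbid))
  out
}

#' Expand a frequency table into individual records
#'
#' Emits exactly `comorbid + noncomorbid` records per level, each carrying
#' the factor level and a logical comorbidity flag, in deterministic order
#' (levels in table order, comorbid cases first).  Record-level statistics
#' computed on the expansion reproduce the aggregate table exactly.
#'
#' @param table A [frequency_table()].
#' @return Data frame with the factor column (named after the factor) and
#'   `comorbid`.
#' @export
#' @examples
#' tab <- frequency_table("smoking", c("low", "high"), c(2, 1), c(3, 4))
#' expand_frequency_table(tab)
expand_frequency_table <- function(table) {
  stopifnot(inherits(table, "freq_table"))
  lev <- rep(table$level, table$comorbid + table$noncomorbid)
  flag <- unlist(lapply(seq_len(nrow(table)), function(i)
    rep(c(TRUE, FALSE), c(table$comorbid[i], table$noncomorbid[i]))))
  out <- data.frame(level = lev, comorbid = as.logical(flag))
  names(out)[1L] <- attr(table, "factor")
  out
}

# ---- cohort simulation -----------------------------------------------------

#' Default marginal distributions of the emulated study population
#'
#' Confounder level probabilities follow the published demographic table and
#' behavior risk-level probabilities the published behavior tables (each out
#' of 22,868 adolescents).  Residence and self-rated health have no
#' published distribution and carry conventional defaults.
#'
#' @return Named list of per-level probability vectors.
#' @export
default_confounder_marginals <- function() {
  list(
    gender = c(boy = 11578, girl = 11290) / 22868,
    siblings = c(yes = 6560, no = 16308) / 22868,
    region_level = c(first_line = 11466, second_line = 11402) / 22868,
    residence = c(rural = 0.5, urban = 0.5),
    edu_status = c(junior = 11840, senior = 11028) / 22868,
    father_edu = c(primary_or_below = 2890, junior_high = 8733,
                   senior_high_or_above = 11245) / 22868,
    mother_edu = c(primary_or_below = 4331, junior_high = 8350,
                   senior_high_or_above = 10187) / 22868,
    family_income = c(low = 2771, medium = 16656, high = 3441) / 22868,
    num_friends = c(le2 = 16039, ge3 = 6829) / 22868,
    learning_burden = c(low = 1481, medium = 13694, high = 7693) / 22868,
    family_psychosis = c(yes = 1367, no = 21501) / 22868,
    self_rated_health = c(good = 0.55, fair = 0.35, poor = 0.10))
}

#' @rdname default_confounder_marginals
#' @export
default_hrb_marginals <- function() {
  list(
    diet = c(low = 6082, medium = 7442, high = 9344) / 22868,
    smoking = c(low = 22336, medium = 277, high = 255) / 22868,
    physical_inactivity = c(low = 3173, medium = 5110, high = 14585) / 22868,
    sleep = c(low = 7472, medium = 8784, high = 6612) / 22868)
}

#' Configure a synthetic survey cohort
#'
#' Defaults emulate the study population: confounder marginals from the
#' published demographic table, behavior risk-level marginals from the
#' behavior tables, and an outcome model whose intercept reproduces the
#' 31.6% comorbidity prevalence with no behavior effects.  Coefficients are
#' named `"factor:level"` on the log-odds scale (e.g.
#' `c("hrb_index:high" = log(2))`); `stratum_effects` optionally adds
#' gender-specific log-odds on top (an exposure-by-gender interaction).
#'
#' @param n Cohort size.
#' @param seed Master seed for the counter-based generator.
#' @param confounder_marginals,hrb_marginals Named lists of per-level
#'   probability vectors (must each sum to 1).  A behavior entry may instead
#'   be a list keyed by gender level, giving gender-dependent behavior
#'   marginals; this plants an exposure-confounder association for
#'   de-confounding experiments.
#' @param outcome_model List with `intercept` and named `coefficients`.
#' @param stratum_effects Optional named list (by gender level) of named
#'   coefficient vectors added for records in that stratum.
#' @param behavior_correlation Exchangeable Gaussian-copula correlation among
#'   the four behaviors, default 0 (independent).
#' @param noncomorbid_split Probabilities of (anxiety only, depression only,
#'   neither) among non-comorbid records.
#' @param age_mean,age_sd Age distribution (years), rounded and clamped to
#'   10-19.
#' @return Object of class `cohort_config`.
#' @export
cohort_config <- function(n = 22868L, seed = 1L,
                          confounder_marginals = default_confounder_marginals(),
                          hrb_marginals = default_hrb_marginals(),
                          outcome_model = list(
                            intercept = stats::qlogis(7236 / 22868),
                            coefficients = numeric()),
                          stratum_effects = NULL,
                          behavior_correlation = 0,
                          noncomorbid_split = c(anxiety_only = 0.15,
                                                depression_only = 0.15,
                                                neither = 0.70),
                          age_mean = 14.6, age_sd = 1.8) {
  stopifnot(n > 0, behavior_correlation >= 0, behavior_correlation < 1)
  for (nm in names(confounder_marginals)) {
    p <- confounder_marginals[[nm]]
    if (any(p < 0) || abs(sum(p) - 1) > 1e-8)
      stop("marginal probabilities for '", nm, "' must be >= 0 and sum to 1")
  }
  for (nm in names(hrb_marginals)) {
    ps <- hrb_marginals[[nm]]
    if (!is.list(ps)) ps <- list(ps)
    for (p in ps) {
      if (any(p < 0) || abs(sum(p) - 1) > 1e-8)
        stop("marginal probabilities for '", nm, "' must be >= 0 and sum to 1")
      if (!identical(names(p), hrb_levels()))
        stop("behavior marginals must be named low/medium/high")
    }
  }
  if (abs(sum(noncomorbid_split) - 1) > 1e-8)
    stop("noncomorbid_split must sum to 1")
  structure(list(n = as.integer(n), seed = as.integer(seed),
                 confounder_marginals = confounder_marginals,
                 hrb_marginals = hrb_marginals,
                 outcome_model = outcome_model,
                 stratum_effects = stratum_effects,
                 behavior_correlation = behavior_correlation,
                 noncomorbid_split = noncomorbid_split,
                 age_mean = age_mean, age_sd = age_sd),
            class = "cohort_config")
}

# fixed slot ids of the counter-based generator (one per sampled variable)
.slots <- c(confounder_base = 1L, behavior_base = 20L, outcome = 30L,
            split = 31L, gad = 32L, phq = 40L, diet_combo = 50L,
            diet_freq = 51L, smoking = 55L, sleep_dur = 56L,
            sleep_onset = 57L, bedtime = 58L, par3 = 59L, age = 60L)

sample_categorical <- function(levels, p, u) {
  levels[findInterval(u, cumsum(p), left.open = TRUE) + 1L]
}

#' Generate a synthetic survey cohort with known truth
#'
#' Samples confounders and the four behavior risk levels from configured
#' marginals (optionally rank-correlated through a Gaussian copula), draws
#' comorbidity from the configured logistic outcome model, then
#' inverse-samples raw questionnaire responses uniformly from the preimage
#' of each drawn category, so that re-scoring the raw records through the
#' instrument scorers reproduces every drawn category exactly.  All
#' randomness flows through counter-based substreams keyed by
#' (seed, record, variable): the same seed always yields the same cohort,
#' and record i is identical whatever `n`.
#'
#' @param config A [cohort_config()].
#' @return Object of class `synthetic_cohort`: `records` (raw survey rows),
#'   `levels` (the drawn per-record categories, the generating truth), and
#'   `config`.
#' @export
#' @examples
#' co <- generate_cohort(cohort_config(n = 100, seed = 42))
#' head(co$records)[, 1:6]
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n; seed <- config$seed; ids <- seq_len(n)
  U <- function(slot, draw = 0L) cb_runif(seed, ids, slot, draw)

  conf <- lapply(seq_along(config$confounder_marginals), function(j) {
    p <- config$confounder_marginals[[j]]
    sample_categorical(names(p), p, U(.slots[["confounder_base"]] + j - 1L))
  })
  names(conf) <- names(config$confounder_marginals)

  # behavior levels, optionally correlated through a Gaussian copula
  rho <- config$behavior_correlation
  Z <- vapply(seq_along(config$hrb_marginals), function(j)
    stats::qnorm(U(.slots[["behavior_base"]] + j - 1L)), numeric(n))
  if (n == 1L) Z <- matrix(Z, 1L)
  if (rho > 0) {
    k <- ncol(Z)
    Sigma <- matrix(rho, k, k); diag(Sigma) <- 1
    Z <- Z %*% chol(Sigma)
  }
  beh <- lapply(seq_along(config$hrb_marginals), function(j) {
    p <- config$hrb_marginals[[j]]
    u <- stats::pnorm(Z[, j])
    if (!is.list(p))
      return(sample_categorical(names(p), p, u))
    # gender-dependent marginals: plants an exposure-confounder association
    out <- character(n)
    for (g in names(p))
      out[conf$gender == g] <-
        sample_categorical(names(p[[g]]), p[[g]], u[conf$gender == g])
    out
  })
  names(beh) <- names(config$hrb_marginals)

  hrb <- hrb_risk_index(beh$diet, beh$smoking, beh$physical_inactivity,
                        beh$sleep)
  levels_df <- data.frame(conf, beh, hrb_index = hrb$index_level,
                          stringsAsFactors = FALSE)

  # outcome from the configured logistic model
  eta <- rep(config$outcome_model$intercept, n)
  add_terms <- function(eta, coefs, mask) {
    for (nm in names(coefs)) {
      parts <- strsplit(nm, ":", fixed = TRUE)[[1L]]
      if (length(parts) != 2L || !parts[1L] %in% names(levels_df))
        stop("coefficient '", nm, "' is not of the form 'factor:level'")
      hit <- levels_df[[parts[1L]]] == parts[2L]
      eta <- eta + coefs[[nm]] * (hit & mask)
    }
    eta
  }
  eta <- add_terms(eta, config$outcome_model$coefficients, TRUE)
  for (s in names(config$stratum_effects))
    eta <- add_terms(eta, config$stratum_effects[[s]],
                     levels_df$gender == s)
  comorbid <- U(.slots[["outcome"]]) < stats::plogis(eta)

  # symptom flags: comorbid records are positive on both scales; the rest
  # split into anxiety-only / depression-only / neither
  sp <- config$noncomorbid_split
  u_split <- U(.slots[["split"]])
  anxiety <- comorbid | (!comorbid & u_split < sp[[1L]])
  depression <- comorbid |
    (!comorbid & u_split >= sp[[1L]] & u_split < sp[[1L]] + sp[[2L]])

  scale_items <- function(scale, positive, slot) {
    k <- scale_n_items[[scale]]; smax <- scale_max[[scale]]
    u_tot <- U(slot)
    u_items <- vapply(seq_len(k - 1L), function(t) U(slot + 1L, t), numeric(n))
    if (n == 1L) u_items <- matrix(u_items, 1L)
    items <- matrix(0L, n, k)
    for (pos in c(TRUE, FALSE)) {
      sel <- which(positive == pos)
      if (!length(sel)) next
      totals <- if (pos) 5:smax else 0:4
      items[sel, ] <- sample_likert_conditional(
        k, totals, u_tot[sel], u_items[sel, , drop = FALSE])
    }
    items
  }
  gad <- scale_items("GAD7", anxiety, .slots[["gad"]])
  phq <- scale_items("PHQ9", depression, .slots[["phq"]])

  # diet: component combo uniform in the level's preimage, then raw weekly
  # frequencies uniform in each component score's frequency band
  dpi <- diet_preimage()
  combo <- matrix(0L, n, 4L,
                  dimnames = list(NULL, colnames(dpi$grid)))
  u_combo <- U(.slots[["diet_combo"]])
  for (l in hrb_levels()) {
    sel <- which(beh$diet == l)
    if (!length(sel)) next
    idx <- which(dpi$level == l)
    combo[sel, ] <- dpi$grid[pick_from_set(idx, u_combo[sel]), , drop = FALSE]
  }
  freq <- matrix(0L, n, 4L)
  for (j in 1:4) {
    item <- names(diet_freq_sets)[j]
    u <- U(.slots[["diet_freq"]] + j - 1L)
    for (s in 0:2) {
      sel <- which(combo[, j] == s)
      if (!length(sel)) next
      freq[sel, j] <- pick_from_set(diet_freq_sets[[item]][[as.character(s)]],
                                    u[sel])
    }
  }

  days <- integer(n)
  u_smoke <- U(.slots[["smoking"]])
  for (l in hrb_levels()) {
    sel <- which(beh$smoking == l)
    if (length(sel))
      days[sel] <- pick_from_set(smoking_day_sets()[[l]], u_smoke[sel])
  }

  dur <- integer(n)
  u_dur <- U(.slots[["sleep_dur"]])
  for (l in hrb_levels()) {
    sel <- which(beh$sleep == l)
    if (length(sel))
      dur[sel] <- pick_from_set(sleep_duration_sets()[[l]], u_dur[sel])
  }
  onset <- pick_from_set(0:1439, U(.slots[["sleep_onset"]]))
  wake <- (onset + dur) %% 1440L
  bedtime <- (onset - floor(U(.slots[["bedtime"]]) * 31)) %% 1440L

  ppi <- par3_preimage()
  par <- matrix(0L, n, 3L, dimnames = list(NULL, colnames(ppi$grid)))
  u_par <- U(.slots[["par3"]])
  for (l in hrb_levels()) {
    sel <- which(beh$physical_inactivity == l)
    if (!length(sel)) next
    idx <- which(ppi$level == l)
    par[sel, ] <- ppi$grid[pick_from_set(idx, u_par[sel]), , drop = FALSE]
  }

  age <- pmin(19L, pmax(10L, as.integer(round(
    stats::qnorm(U(.slots[["age"]]), config$age_mean, config$age_sd)))))

  records <- data.frame(
    id = sprintf("S%06d", ids), conf["gender"], age = age,
    conf[setdiff(names(conf), "gender")],
    as.data.frame(gad) |> stats::setNames(paste0("gad", 1:7)),
    as.data.frame(phq) |> stats::setNames(paste0("phq", 1:9)),
    fruit_freq = freq[, 1L], vegetable_freq = freq[, 2L],
    fastfood_freq = freq[, 3L], softdrink_freq = freq[, 4L],
    smoke_days = days,
    bedtime = format_clock(bedtime), sleep_onset = format_clock(onset),
    wake_time = format_clock(wake),
    pa_intensity = par[, 1L], pa_time = par[, 2L] + 1L, pa_freq = par[, 3L],
    stringsAsFactors = FALSE)

  levels_df$comorbid <- comorbid
  levels_df$anxiety <- anxiety
  levels_df$depression <- depression
  structure(list(records = records, levels = levels_df, config = config),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("Synthetic cohort: n =", nrow(x$records), ", seed =", x$config$seed,
      "\n  comorbidity prevalence:",
      sprintf("%.1f%%", 100 * mean(x$levels$comorbid)), "\n")
  invisible(x)
}
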