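# Build small, fully valid raw survey rows in code (no stored fixtures).
make_raw_records <- function(n = 4L) {
  data.frame(
    id = sprintf("R%03d", seq_len(n)),
    gender = rep(c("boy", "girl"), length.out = n),
    age = rep(14, n),
    siblings = "no", region_level = "second_line", residence = "urban",
    edu_status = "junior", father_edu = "senior_high_or_above",
    mother_edu = "senior_high_or_above", family_income = "medium",
    num_friends = "ge3", learning_burden = "low", family_psychosis = "no",
    self_rated_health = "good",
    gad1 = 1, gad2 = 1, gad3 = 1, gad4 = 1, gad5 = 1, gad6 = 0, gad7 = 0,
    phq1 = 1, phq2 = 1, phq3 = 1, phq4 = 1, phq5 = 1, phq6 = 0, phq7 = 0,
    phq8 = 0, phq9 = 0,
    fruit_freq = 4, vegetable_freq = 5, fastfood_freq = 0, softdrink_freq = 1,
    smoke_days = 0,
    bedtime = "22:45", sleep_onset = "23:00", wake_time = "07:00",
    pa_intensity = 5, pa_time = 5, pa_freq = 5,
    stringsAsFactors = FALSE)
}

# character version as read_survey_csv would deliver it
make_raw_character <- function(n = 4L) {
  r <- make_raw_records(n)
  r[] <- lapply(r, as.character)
  r
}

# plain counts matrix from an hrb_xtab (drops class and bookkeeping attrs)
as_counts <- function(tab) {
  matrix(as.vector(unclass(tab)), nrow = nrow(tab), dimnames = dimnames(tab))
}

# brute-force diet classifier applying the published rules literally:
# totals 0-1 low, 4-8 high; the ambiguous total of 2 is low when reached as
# 1+1 and medium when reached as a single 2; 3 is medium
diet_oracle <- function(comp) {
  total <- sum(comp)
  if (total >= 4) return("high")
  if (total == 3) return("medium")
  if (total == 2) return(if (any(comp == 2)) "medium" else "low")
  "low"
}
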