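# shared fixtures and independent oracles, built in code at test time

# a fully-answered response at the least symptomatic level, with overrides
complete_response <- function(...) {
  base <- list(
    snores = "no", snore_volume = NA, snore_frequency = NA,
    snoring_bothers_others = NA, witnessed_apnea_frequency = "never",
    tired_after_sleep_frequency = "never",
    tired_during_waketime_frequency = "never",
    nodded_off_driving = "no", hypertension_history = "no"
  )
  over <- list(...)
  base[names(over)] <- over
  if (!is.na(base$snores) && base$snores == "yes") {
    defaults <- list(snore_volume = "breathing_level", snore_frequency = "never",
                     snoring_bothers_others = "no")
    for (nm in names(defaults)) {
      if (is.na(base[[nm]]) && !nm %in% names(over)) base[[nm]] <- defaults[[nm]]
    }
  }
  do.call(berlin_response, base[!vapply(base, function(x) all(is.na(x)), TRUE)])
}

bind_responses <- function(...) do.call(rbind, list(...))

# independent Pearson chi-square oracle: expected-counts summation
chisq_oracle <- function(m) {
  e <- outer(rowSums(m), colSums(m)) / sum(m)
  sum((m - e)^2 / e)
}

# independent AUC oracle: brute force over all positive-negative pairs
auc_pairwise_oracle <- function(scores, status) {
  pos <- scores[as.logical(status)]
  neg <- scores[!as.logical(status)]
  g <- expand.grid(p = pos, n = neg)
  mean((g$p > g$n) + 0.5 * (g$p == g$n))
}

# a mother-only cohort row whose Berlin/Wilson labels are forced by design;
# used to assemble cohorts matching reconstructed 2x2 tables exactly
fixture_row <- function(berlin, wilson, sdb_pos) {
  # berlin high needs >= 2 positive categories; wilson high needs score > 18.1
  # (synthetic weights: yes 4.2 + very_loud 7.2 + nearly_every_day 8.2 = 19.6)
  items <- if (berlin && wilson) {
    list(snores = "yes", snore_volume = "very_loud",
         snore_frequency = "nearly_every_day",
         tired_after_sleep_frequency = "nearly_every_day",
         tired_during_waketime_frequency = "nearly_every_day",
         nodded_off_driving = "yes", hypertension_history = "no")
  } else if (berlin && !wilson) {
    # cat1 via frequency+bothers, cat2 via waketime+nodding; low score items
    list(snores = "yes", snore_volume = "breathing_level",
         snore_frequency = "nearly_every_day", snoring_bothers_others = "yes",
         tired_after_sleep_frequency = "never",
         tired_during_waketime_frequency = "nearly_every_day",
         nodded_off_driving = "yes", hypertension_history = "no")
  } else if (!berlin && wilson) {
    # only category 1 positive (snores + very loud), score 19.6 > 18.1
    list(snores = "yes", snore_volume = "very_loud",
         snore_frequency = "never",
         tired_after_sleep_frequency = "nearly_every_day",
         tired_during_waketime_frequency = "never",
         nodded_off_driving = "no", hypertension_history = "no")
  } else {
    list(snores = "no", tired_after_sleep_frequency = "never",
         tired_during_waketime_frequency = "never",
         nodded_off_driving = "no", hypertension_history = "no")
  }
  resp <- do.call(complete_response, items)
  row <- data.frame(id = NA_character_, study_type = "home",
                    rdi = if (sdb_pos) 6 else 1, hdp = "no", bmi = 28,
                    stringsAsFactors = FALSE)
  for (nm in names(resp)) row[[paste0("mother_", nm)]] <- resp[[nm]]
  row
}

# cohort with given joint (berlin, wilson) label counts among positives and
# negatives: each argument is c(hh, hl, lh, ll)
fixture_cohort <- function(pos_counts, neg_counts) {
  combos <- list(c(TRUE, TRUE), c(TRUE, FALSE), c(FALSE, TRUE), c(FALSE, FALSE))
  rows <- list()
  for (sdb in c(TRUE, FALSE)) {
    counts <- if (sdb) pos_counts else neg_counts
    for (k in seq_along(combos)) {
      if (counts[k] == 0) next
      row <- fixture_row(combos[[k]][1], combos[[k]][2], sdb)
      rows <- c(rows, rep(list(row), counts[k]))
    }
  }
  out <- do.call(rbind, rows)
  out$id <- sprintf("F%04d", seq_len(nrow(out)))
  out
}
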