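#' Berlin Questionnaire item vocabulary
#'
#' Enumerated levels for every Berlin Questionnaire (BQ) item handled by the
#' package. Ordinal items are stored as lowercase tokens (never integers) so a
#' mis-keyed level is caught at validation time rather than silently reordered.
#' Missing answers are `NA`, never a default level.
#'
#' @format A named list; each element is the ordered character vector of
#'   allowed levels for one item, lowest (least symptomatic) first.
#' @export
bq_levels <- list(
  snores                          = c("no", "do_not_know", "yes"),
  snore_volume                    = c("breathing_level", "talking_level",
                                      "louder_than_talking", "very_loud"),
  snore_frequency                 = c("never", "one_two_per_month", "one_two_per_week",
                                      "three_four_per_week", "nearly_every_day"),
  snoring_bothers_others          = c("no", "yes"),
  witnessed_apnea_frequency       = c("never", "one_two_per_month", "one_two_per_week",
                                      "three_four_per_week", "nearly_every_day"),
  tired_after_sleep_frequency     = c("never", "one_two_per_month", "one_two_per_week",
                                      "three_four_per_week", "nearly_every_day"),
  tired_during_waketime_frequency = c("never", "one_two_per_month", "one_two_per_week",
                                      "three_four_per_week", "nearly_every_day"),
  nodded_off_driving              = c("no", "yes"),
  hypertension_history            = c("no", "yes")
)

#' Declarative symptomatic-level table for the Berlin Questionnaire
#'
#' Which answer levels count as symptomatic for each item. The BQ category
#' rules are counts over this table, so an implementer with access to a
#' different edition of the instrument can adjust levels here without touching
#' the scoring code. "do_not_know" snoring is deliberately non-symptomatic
#' (conservative reading of the instrument).
#'
#' @format Named list of character vectors (symptomatic levels per item).
#' @export
bq_symptomatic <- list(
  snores                          = "yes",
  snore_volume                    = c("louder_than_talking", "very_loud"),
  snore_frequency                 = c("three_four_per_week", "nearly_every_day"),
  snoring_bothers_others          = "yes",
  witnessed_apnea_frequency       = c("three_four_per_week", "nearly_every_day"),
  tired_after_sleep_frequency     = c("three_four_per_week", "nearly_every_day"),
  tired_during_waketime_frequency = c("three_four_per_week", "nearly_every_day"),
  nodded_off_driving              = "yes"
)

# item membership of the two symptom-count categories
bq_category_items <- list(
  category1 = c("snores", "snore_volume", "snore_frequency",
                "snoring_bothers_others", "witnessed_apnea_frequency"),
  category2 = c("tired_after_sleep_frequency", "tired_during_waketime_frequency",
                "nodded_off_driving")
)

#' Construct a single Berlin Questionnaire response
#'
#' Builds a one-row response table, validating every supplied answer against
#' [bq_levels]. Unsupplied items are `NA` (explicitly missing). Snore-conditional
#' items (volume, frequency, bothers-others) may legitimately be missing when
#' `snores` is not `"yes"`.
#'
#' @param ... Named item answers, e.g. `snores = "yes"`,
#'   `snore_volume = "very_loud"`. Names must be a subset of `names(bq_levels)`.
#' @return A one-row `data.frame` with one character column per BQ item.
#' @examples
#' berlin_response(snores = "yes", snore_volume = "very_loud",
#'                 snore_frequency = "nearly_every_day")
#' @export
berlin_response <- function(...) {
  ans <- list(...)
  unknown <- setdiff(names(ans), names(bq_levels))
  if (length(unknown) > 0) {
    stop_sdb("unknown BQ item(s): ", paste(unknown, collapse = ", "),
             class = "sdbscreen_item_error")
  }
  out <- as.data.frame(
    lapply(stats::setNames(names(bq_levels), names(bq_levels)),
           function(nm) as.character(ans[[nm]] %||% NA_character_)),
    stringsAsFactors = FALSE
  )
  validate_bq_items(out)
  out
}

# validate item columns of a response table against the vocabulary;
# returns (invisibly) a logical matrix of per-cell validity
validate_bq_items <- function(resp, items = names(bq_levels)) {
  items <- intersect(items, names(resp))
  for (nm in items) {
    bad <- !is.na(resp[[nm]]) & !(resp[[nm]] %in% bq_levels[[nm]])
    if (any(bad)) {
      stop_sdb("invalid level(s) for ", nm, ": ",
               paste(unique(resp[[nm]][bad]), collapse = ", "),
               class = "sdbscreen_level_error")
    }
  }
  invisible(TRUE)
}

# count of symptomatic answers among `items`; NA answers count as
# non-symptomatic (partial responses stay scoreable)
symptomatic_count <- function(resp, items) {
  counts <- rep(0L, nrow(resp))
  for (nm in items) {
    counts <- counts + as.integer(!is.na(resp[[nm]]) &
                                    resp[[nm]] %in% bq_symptomatic[[nm]])
  }
  counts
}

all_missing <- function(resp, items) {
  miss <- rep(TRUE, nrow(resp))
  for (nm in items) miss <- miss & is.na(resp[[nm]])
  miss
}

#' Berlin Questionnaire category 1 (snoring and breathing pauses)
#'
#' Positive when at least two of the five snoring/apnea items are at a
#' symptomatic level (per [bq_symptomatic]). Missing answers are counted as
#' non-symptomatic; a response with all five items missing is an error.
#'
#' @param resp A response table (see [berlin_response]); may have many rows.
#' @return Logical vector, one flag per row.
#' @export
berlin_category1 <- function(resp) {
  validate_bq_items(resp, bq_category_items$category1)
  if (any(all_missing(resp, bq_category_items$category1))) {
    stop_sdb("category 1 has no answered items for some response(s)",
             class = "sdbscreen_missing_category")
  }
  symptomatic_count(resp, bq_category_items$category1) >= 2L
}

#' Berlin Questionnaire category 2 (daytime sleepiness)
#'
#' Positive when at least two of the three sleepiness items are symptomatic.
#'
#' @inheritParams berlin_category1
#' @return Logical vector, one flag per row.
#' @export
berlin_category2 <- function(resp) {
  validate_bq_items(resp, bq_category_items$category2)
  if (any(all_missing(resp, bq_category_items$category2))) {
    stop_sdb("category 2 has no answered items for some response(s)",
             class = "sdbscreen_missing_category")
  }
  symptomatic_count(resp, bq_category_items$category2) >= 2L
}

#' Berlin Questionnaire category 3 (hypertension or obesity)
#'
#' Positive when the respondent reports a history of high blood pressure or
#' the measured BMI exceeds 30 kg/m2 (strict inequality).
#'
#' @inheritParams berlin_category1
#' @param bmi Numeric vector of body-mass indices (kg/m2), recycled to rows of
#'   `resp`. Values outside (10, 80) trigger a plausibility warning, not an
#'   error.
#' @return Logical vector.
#' @export
berlin_category3 <- function(resp, bmi) {
  validate_bq_items(resp, "hypertension_history")
  bmi <- check_bmi(bmi)
  htn <- !is.na(resp$hypertension_history) & resp$hypertension_history == "yes"
  htn | (!is.na(bmi) & bmi > 30)
}

check_bmi <- function(bmi) {
  bmi <- as.numeric(bmi)
  if (any(!is.na(bmi) & bmi <= 0)) {
    stop_sdb("bmi must be positive", class = "sdbscreen_bmi_error")
  }
  implausible <- !is.na(bmi) & (bmi <= 10 | bmi >= 80)
  if (any(implausible)) {
    warning("implausible BMI value(s) outside (10, 80): ",
            paste(utils::head(bmi[implausible], 5), collapse = ", "))
  }
  bmi
}

#' Risk-label factor
#'
#' The package-wide binary screening outcome: `"high"` or `"low"` risk of
#' sleep-disordered breathing, stored as a factor with levels `low < high`.
#'
#' @param x Character or logical vector (`TRUE` means high risk).
#' @return Factor with levels `c("low", "high")`.
#' @export
risk_label <- function(x) {
  if (is.logical(x)) x <- ifelse(x, "high", "low")
  bad <- !is.na(x) & !(x %in% c("high", "low"))
  if (any(bad)) {
    stop_sdb("risk labels must be \"high\" or \"low\"",
             class = "sdbscreen_level_error")
  }
  factor(x, levels = c("low", "high"))
}

#' Classify Berlin Questionnaire risk
#'
#' High risk when at least two of the three symptom categories are positive;
#' depends on the responses only through the three category flags.
#'
#' @inheritParams berlin_category3
#' @return A [risk_label] factor, one label per row of `resp`.
#' @examples
#' r <- berlin_response(snores = "yes", snore_volume = "very_loud",
#'                      snore_frequency = "nearly_every_day",
#'                      hypertension_history = "no",
#'                      tired_after_sleep_frequency = "never",
#'                      tired_during_waketime_frequency = "never",
#'                      nodded_off_driving = "no")
#' classify_berlin(r, bmi = 28)
#' @export
classify_berlin <- function(resp, bmi) {
  flags <- cbind(berlin_category1(resp),
                 berlin_category2(resp),
                 berlin_category3(resp, bmi))
  risk_label(rowSums(flags) >= 2L)
}
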