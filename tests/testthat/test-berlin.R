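test_that("category 1 counts symptomatic snoring items with the >=2 rule", {
  loud_frequent <- complete_response(snores = "yes", snore_volume = "very_loud",
                                     snore_frequency = "nearly_every_day")
  expect_true(berlin_category1(loud_frequent))

  non_snorer <- complete_response(snores = "no")
  expect_false(berlin_category1(non_snorer))

  # brute force over all 2^5 symptomatic/non-symptomatic patterns:
  # category positive iff at least two items symptomatic ("do_not_know"
  # keeps the conditional items answerable while staying non-symptomatic)
  items <- c("snores", "snore_volume", "snore_frequency",
             "snoring_bothers_others", "witnessed_apnea_frequency")
  sympt <- list(snores = "yes", snore_volume = "very_loud",
                snore_frequency = "nearly_every_day",
                snoring_bothers_others = "yes",
                witnessed_apnea_frequency = "nearly_every_day")
  benign <- list(snores = "do_not_know", snore_volume = "breathing_level",
                 snore_frequency = "never", snoring_bothers_others = "no",
                 witnessed_apnea_frequency = "never")
  for (mask in 0:31) {
    bits <- as.logical(bitwAnd(mask, 2^(0:4)))
    args <- lapply(seq_along(items), function(i) {
      if (bits[i]) sympt[[items[i]]] else benign[[items[i]]]
    })
    names(args) <- items
    expect_identical(berlin_category1(do.call(complete_response, args)),
                     sum(bits) >= 2, info = paste("mask", mask))
  }
})

test_that("do-not-know snoring is non-symptomatic and partial answers score", {
  dk <- complete_response(snores = "do_not_know")
  expect_false(berlin_category1(dk))
  # two symptomatic among answered items is enough even with items missing
  partial <- berlin_response(snores = "yes", snore_volume = "very_loud",
                             witnessed_apnea_frequency = "never")
  expect_true(berlin_category1(partial))
  # a category with no answered items at all is an explicit error
  no_cat1 <- berlin_response(tired_after_sleep_frequency = "never")
  expect_error(berlin_category1(no_cat1), class = "sdbscreen_missing_category")
  no_cat2 <- berlin_response(snores = "yes", snore_volume = "very_loud")
  expect_error(berlin_category2(no_cat2), class = "sdbscreen_missing_category")
})

test_that("category 2 applies the >=2-of-3 sleepiness rule", {
  expect_true(berlin_category2(complete_response(
    tired_after_sleep_frequency = "nearly_every_day",
    tired_during_waketime_frequency = "nearly_every_day")))
  expect_false(berlin_category2(complete_response()))
  # brute force over all 2^3 patterns
  items <- c("tired_after_sleep_frequency", "tired_during_waketime_frequency",
             "nodded_off_driving")
  sympt <- c("nearly_every_day", "three_four_per_week", "yes")
  benign <- c("never", "one_two_per_week", "no")
  for (mask in 0:7) {
    bits <- as.logical(bitwAnd(mask, 2^(0:2)))
    args <- as.list(ifelse(bits, sympt, benign))
    names(args) <- items
    expect_identical(berlin_category2(do.call(complete_response, args)),
                     sum(bits) >= 2, info = paste("mask", mask))
  }
})

test_that("category 3 is hypertension OR bmi strictly above 30", {
  r_no <- complete_response(hypertension_history = "no")
  r_yes <- complete_response(hypertension_history = "yes")
  expect_false(berlin_category3(r_no, bmi = 29.9))
  expect_false(berlin_category3(r_no, bmi = 30))
  expect_true(berlin_category3(r_no, bmi = 30.1))
  expect_true(berlin_category3(r_yes, bmi = 22))
  expect_warning(berlin_category3(r_no, bmi = 9.5), "implausible")
  expect_error(berlin_category3(r_no, bmi = -1), class = "sdbscreen_bmi_error")
})

test_that("overall Berlin risk is >=2 positive categories, exhaustively", {
  # responses engineered to switch each category independently
  cat1_on <- list(snores = "yes", snore_volume = "very_loud")
  cat1_off <- list(snores = "no")
  cat2_on <- list(tired_after_sleep_frequency = "nearly_every_day",
                  tired_during_waketime_frequency = "nearly_every_day")
  cat2_off <- list(tired_after_sleep_frequency = "never",
                   tired_during_waketime_frequency = "never")
  for (c1 in c(TRUE, FALSE)) for (c2 in c(TRUE, FALSE)) for (c3 in c(TRUE, FALSE)) {
    args <- c(if (c1) cat1_on else cat1_off,
              if (c2) cat2_on else cat2_off,
              list(hypertension_history = if (c3) "yes" else "no"))
    resp <- do.call(complete_response, args)
    expect_identical(
      as.character(classify_berlin(resp, bmi = 25)),
      if (c1 + c2 + c3 >= 2) "high" else "low",
      info = paste(c1, c2, c3)
    )
  }
})

test_that("classification is invariant to item column order", {
  resp <- complete_response(snores = "yes", snore_volume = "very_loud",
                            snore_frequency = "nearly_every_day",
                            hypertension_history = "yes")
  shuffled <- resp[, rev(names(resp))]
  expect_identical(classify_berlin(resp, 31), classify_berlin(shuffled, 31))
})

test_that("invalid item levels are rejected at validation", {
  expect_error(berlin_response(snores = "sometimes"),
               class = "sdbscreen_level_error")
  bad <- complete_response(snores = "yes")
  bad$snore_volume <- "deafening"
  expect_error(berlin_category1(bad), class = "sdbscreen_level_error")
})
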