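#' Default class-conditional questionnaire response probabilities
#'
#' One probability table per sleep-disordered-breathing severity class
#' (`none`: RDI < 5, `mild`: 5 <= RDI < 15, `moderate_severe`: RDI >= 15).
#' Each table gives, for every Berlin Questionnaire item, the categorical
#' distribution of the mother's answer given her class; the snore-conditional
#' items (volume, frequency, bothers-others) are distributions conditional on
#' answering `snores = "yes"` (non-snorers leave them missing).
#'
#' The defaults encode the study conditions the generator emulates: they were
#' chosen once, by exact enumeration (see [implied_screen_prob]), so that the
#' class-conditional screen-positive rates match the operating
#' characteristics of the validation cohort (Wilson model positive in about
#' 17/33/67% and Berlin positive in about 63/78/93% of the none/mild/
#' moderate-severe classes).
#'
#' @return Named list (`none`, `mild`, `moderate_severe`) of named lists of
#'   probability vectors, each summing to 1 over the item's [bq_levels].
#' @export
default_item_prob_table <- function() {
  tab <- list(
    none = list(
      snores                          = c(0.26, 0.12, 0.62),
      snore_volume                    = c(0.46, 0.35, 0.12, 0.07),
      snore_frequency                 = c(0.16, 0.20, 0.20, 0.26, 0.18),
      snoring_bothers_others          = c(0.64, 0.36),
      witnessed_apnea_frequency       = c(0.78, 0.10, 0.04, 0.05, 0.03),
      tired_after_sleep_frequency     = c(0.12, 0.18, 0.25, 0.25, 0.20),
      tired_during_waketime_frequency = c(0.04, 0.10, 0.16, 0.38, 0.32),
      nodded_off_driving              = c(0.87, 0.13)
    ),
    mild = list(
      snores                          = c(0.16, 0.12, 0.72),
      snore_volume                    = c(0.18, 0.32, 0.33, 0.17),
      snore_frequency                 = c(0.08, 0.15, 0.22, 0.30, 0.25),
      snoring_bothers_others          = c(0.55, 0.45),
      witnessed_apnea_frequency       = c(0.55, 0.20, 0.10, 0.10, 0.05),
      tired_after_sleep_frequency     = c(0.08, 0.15, 0.22, 0.30, 0.25),
      tired_during_waketime_frequency = c(0.04, 0.10, 0.22, 0.34, 0.30),
      nodded_off_driving              = c(0.84, 0.16)
    ),
    moderate_severe = list(
      snores                          = c(0.03, 0.04, 0.93),
      snore_volume                    = c(0.04, 0.10, 0.28, 0.58),
      snore_frequency                 = c(0.03, 0.07, 0.15, 0.30, 0.45),
      snoring_bothers_others          = c(0.35, 0.65),
      witnessed_apnea_frequency       = c(0.30, 0.15, 0.15, 0.20, 0.20),
      tired_after_sleep_frequency     = c(0.04, 0.08, 0.16, 0.32, 0.40),
      tired_during_waketime_frequency = c(0.03, 0.08, 0.17, 0.34, 0.38),
      nodded_off_driving              = c(0.75, 0.25)
    )
  )
  for (cls in names(tab)) {
    for (nm in names(tab[[cls]])) {
      names(tab[[cls]][[nm]]) <- bq_levels[[nm]]
    }
  }
  tab
}

sdb_classes <- c("none", "mild", "moderate_severe")

#' Specify a synthetic pregnant cohort
#'
#' All parameters of the synthetic-data generator, with defaults matching the
#' third-trimester validation cohort the package emulates: 96 mothers of whom
#' 81/96 have a bedpartner response, a log-normal RDI with median 4.3 and IQR
#' close to (2.2, 9.3) — hence SDB prevalence around 44% at RDI >= 5 — a 54%
#' rate of hypertensive disorders of pregnancy (HDP), BMI ~ Normal(35.8, 6.3)
#' truncated at 15, and class-conditional questionnaire answers from
#' [default_item_prob_table].
#'
#' HDP and SDB are positively associated: the odds of being in an SDB class
#' (mild or moderate-severe, in fixed proportion) are multiplied by
#' `hdp_odds_multiplier` for HDP mothers and by the compensating factor
#' `hdp_odds_multiplier^(-hdp_fraction/(1-hdp_fraction))` for normotensive
#' mothers, keeping the marginal class distribution at the log-normal tail
#' probabilities. RDI is then drawn from the log-normal truncated to the
#' class interval, so SDB status always equals the RDI threshold rule.
#'
#' Bedpartner answers are the mother's with per-item disagreement: each item
#' is replaced with probability `partner_flip_prob`, by the item's most
#' symptomatic level with probability `partner_up_bias` (else its least
#' symptomatic), emulating partners who notice snoring the mother does not.
#'
#' @param n_mothers Cohort size (default 96).
#' @param partner_fraction Probability a mother has a bedpartner response
#'   (default 81/96).
#' @param rdi_log_mu,rdi_log_sigma Log-normal RDI parameters (defaults 1.459
#'   and 1.07, quantile-matched to median 4.3 and IQR 2.2-9.3).
#' @param hdp_fraction HDP prevalence (default 0.54).
#' @param hdp_odds_multiplier Odds multiplier coupling HDP to SDB class
#'   (default 2; 1 = no coupling).
#' @param item_prob_table Class-conditional item distributions; see
#'   [default_item_prob_table].
#' @param partner_flip_prob Per-item disagreement probability (default 0.45,
#'   calibrated to about 75% mother-partner risk agreement on the Wilson
#'   model with partner-high/mother-low discordance dominating).
#' @param partner_up_bias Probability a disagreement moves toward the
#'   symptomatic extreme (default 0.70).
#' @param bmi_mu,bmi_sigma BMI normal parameters (defaults 35.8, 6.3 kg/m2).
#' @param seed Integer RNG seed; identical seeds give bit-identical cohorts.
#' @return Object of class `cohort_spec` (a validated list of the above).
#' @export
cohort_spec <- function(n_mothers = 96,
                        partner_fraction = 81 / 96,
                        rdi_log_mu = 1.459,
                        rdi_log_sigma = 1.07,
                        hdp_fraction = 0.54,
                        hdp_odds_multiplier = 2,
                        item_prob_table = default_item_prob_table(),
                        partner_flip_prob = 0.45,
                        partner_up_bias = 0.70,
                        bmi_mu = 35.8,
                        bmi_sigma = 6.3,
                        seed = 1L) {
  spec <- structure(list(
    n_mothers = as.integer(n_mothers), partner_fraction = partner_fraction,
    rdi_log_mu = rdi_log_mu, rdi_log_sigma = rdi_log_sigma,
    hdp_fraction = hdp_fraction, hdp_odds_multiplier = hdp_odds_multiplier,
    item_prob_table = item_prob_table,
    partner_flip_prob = partner_flip_prob, partner_up_bias = partner_up_bias,
    bmi_mu = bmi_mu, bmi_sigma = bmi_sigma, seed = as.integer(seed)
  ), class = "cohort_spec")
  validate_cohort_spec(spec)
}

validate_cohort_spec <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  with(spec, {
    stopifnot(n_mothers >= 0,
              partner_fraction >= 0, partner_fraction <= 1,
              rdi_log_sigma > 0,
              hdp_fraction >= 0, hdp_fraction <= 1,
              hdp_odds_multiplier > 0,
              partner_flip_prob >= 0, partner_flip_prob <= 1,
              partner_up_bias >= 0, partner_up_bias <= 1,
              bmi_sigma > 0, length(seed) == 1)
  })
  if (!identical(sort(names(spec$item_prob_table)), sort(sdb_classes))) {
    stop_sdb("item_prob_table must have classes ", paste(sdb_classes, collapse = ", "),
             class = "sdbscreen_spec_error")
  }
  for (cls in sdb_classes) {
    tab <- spec$item_prob_table[[cls]]
    for (nm in setdiff(names(bq_levels), "hypertension_history")) {
      p <- tab[[nm]]
      if (is.null(p) || length(p) != length(bq_levels[[nm]]) ||
          any(p < 0) || abs(sum(p) - 1) > 1e-8) {
        stop_sdb("item_prob_table$", cls, "$", nm,
                 " must be a probability vector over its levels",
                 class = "sdbscreen_spec_error")
      }
    }
  }
  invisible(spec)
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf("cohort_spec: %d mothers (partner fraction %.2f), seed %d\n",
              x$n_mothers, x$partner_fraction, x$seed))
  cat(sprintf("  RDI ~ logN(%.3f, %.2f); HDP %.0f%% (odds x%.1f); BMI ~ N(%.1f, %.1f)\n",
              x$rdi_log_mu, x$rdi_log_sigma, 100 * x$hdp_fraction,
              x$hdp_odds_multiplier, x$bmi_mu, x$bmi_sigma))
  invisible(x)
}

# class distribution: base log-normal tail masses, HDP-adjusted by the odds
# multiplier with a compensating factor so the marginal stays at base
class_probabilities <- function(spec) {
  p_sdb <- stats::plnorm(5, spec$rdi_log_mu, spec$rdi_log_sigma, lower.tail = FALSE)
  p_ms <- stats::plnorm(15, spec$rdi_log_mu, spec$rdi_log_sigma, lower.tail = FALSE)
  split_ms <- p_ms / p_sdb
  f <- spec$hdp_fraction; m <- spec$hdp_odds_multiplier
  base_odds <- p_sdb / (1 - p_sdb)
  mult_n <- if (f < 1) m^(-f / (1 - f)) else 1
  p_sdb_h <- (base_odds * m) / (1 + base_odds * m)
  p_sdb_n <- (base_odds * mult_n) / (1 + base_odds * mult_n)
  probs <- rbind(
    hdp  = c(1 - p_sdb_h, p_sdb_h * (1 - split_ms), p_sdb_h * split_ms),
    norm = c(1 - p_sdb_n, p_sdb_n * (1 - split_ms), p_sdb_n * split_ms)
  )
  colnames(probs) <- sdb_classes
  marginal <- f * probs["hdp", ] + (1 - f) * probs["norm", ]
  hdp_given_class <- f * probs["hdp", ] / marginal
  list(by_hdp = probs, marginal = marginal, hdp_given_class = hdp_given_class)
}

# P(bmi > cut) under the truncated-at-15 normal BMI model
bmi_exceed_prob <- function(spec, cut) {
  stats::pnorm(cut, spec$bmi_mu, spec$bmi_sigma, lower.tail = FALSE) /
    stats::pnorm(15, spec$bmi_mu, spec$bmi_sigma, lower.tail = FALSE)
}

#' Exact class-conditional screen-positive probabilities
#'
#' Computes, by enumeration over the generator's class-conditional item
#' distributions (no simulation), the probability that a mother in each SDB
#' class screens high risk on the Wilson Optimized Model or the Berlin
#' Questionnaire. This is the generator's "ground truth": the
#' parameter-recovery tests check that the simulated pipeline reproduces
#' these numbers.
#'
#' @param spec A [cohort_spec].
#' @param weights A [wom_weights] table (used for `screen = "wom"`).
#' @param screen `"wom"` or `"berlin"`.
#' @return Named numeric vector of P(high risk | class) over
#'   none/mild/moderate-severe.
#' @export
implied_screen_prob <- function(spec, weights = wom_weights(),
                                screen = c("wom", "berlin")) {
  screen <- match.arg(screen)
  validate_cohort_spec(spec)
  p32 <- bmi_exceed_prob(spec, 32)
  p30 <- bmi_exceed_prob(spec, 30)
  hdp_gc <- class_probabilities(spec)$hdp_given_class
  out <- vapply(sdb_classes, function(cls) {
    tab <- spec$item_prob_table[[cls]]
    if (screen == "wom") {
      validate_wom_weights(weights)
      grid <- expand.grid(s = seq_along(bq_levels$snores),
                          v = seq_along(bq_levels$snore_volume),
                          t = seq_along(bq_levels$tired_after_sleep_frequency),
                          b = 1:2)
      # non-snorers leave volume unanswered; it resolves to the minimum level
      p_v <- ifelse(grid$s == 3L, tab$snore_volume[grid$v],
                    as.numeric(grid$v == 1L))
      prob <- tab$snores[grid$s] * p_v *
        tab$tired_after_sleep_frequency[grid$t] *
        ifelse(grid$b == 2L, p32, 1 - p32)
      sc <- weights$items$snores[grid$s] +
        weights$items$snore_volume[grid$v] +
        weights$items$tired_after_sleep_frequency[grid$t] +
        weights$items$bmi_gt32[grid$b]
      sum(prob[sc > weights$threshold])
    } else {
      sympt_p <- function(nm) sum(tab[[nm]][bq_levels[[nm]] %in% bq_symptomatic[[nm]]])
      # snores="yes" is itself a category-1 point, so cat1 needs >=1 of the
      # other four; a non-snorer can collect at most one point (apneas)
      p_more <- 1 - prod(1 - c(sympt_p("snore_volume"), sympt_p("snore_frequency"),
                               sympt_p("snoring_bothers_others"),
                               sympt_p("witnessed_apnea_frequency")))
      p1 <- tab$snores[["yes"]] * p_more
      q <- c(sympt_p("tired_after_sleep_frequency"),
             sympt_p("tired_during_waketime_frequency"),
             sympt_p("nodded_off_driving"))
      p2 <- q[1] * q[2] * (1 - q[3]) + q[1] * (1 - q[2]) * q[3] +
        (1 - q[1]) * q[2] * q[3] + q[1] * q[2] * q[3]
      p3 <- 1 - (1 - hdp_gc[[cls]]) * (1 - p30)
      pc <- c(p1, p2, p3)
      pc[1] * pc[2] * (1 - pc[3]) + pc[1] * (1 - pc[2]) * pc[3] +
        (1 - pc[1]) * pc[2] * pc[3] + prod(pc)
    }
  }, 0)
  names(out) <- sdb_classes
  out
}
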