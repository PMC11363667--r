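#' Sample respiratory disturbance indices
#'
#' Draws i.i.d. log-normal RDI values from the marginal distribution of the
#' cohort spec (median `exp(rdi_log_mu)`, 4.3 at defaults).
#'
#' @param n Number of draws.
#' @param spec A [cohort_spec].
#' @param seed Optional seed; when supplied the draw is made on a temporary
#'   RNG stream and the caller's stream is left untouched.
#' @return Non-negative numeric vector of length `n`.
#' @export
sample_rdi <- function(n, spec = cohort_spec(), seed = NULL) {
  with_seed(seed, stats::rlnorm(n, spec$rdi_log_mu, spec$rdi_log_sigma))
}

# log-normal truncated to the half-open class interval, via inverse CDF
sample_rdi_given_class <- function(sdb_class, spec) {
  bounds <- list(none = c(0, 5), mild = c(5, 15), moderate_severe = c(15, Inf))
  lo <- vapply(bounds[sdb_class], `[[`, 0, 1)
  hi <- vapply(bounds[sdb_class], `[[`, 0, 2)
  u <- stats::runif(length(sdb_class),
                    stats::plnorm(lo, spec$rdi_log_mu, spec$rdi_log_sigma),
                    stats::plnorm(hi, spec$rdi_log_mu, spec$rdi_log_sigma))
  stats::qlnorm(u, spec$rdi_log_mu, spec$rdi_log_sigma)
}

# severity class draw given HDP status
sample_sdb_class <- function(hdp, spec) {
  probs <- class_probabilities(spec)$by_hdp
  u <- stats::runif(length(hdp))
  pick <- function(p) sdb_classes[findInterval(u, cumsum(p), left.open = TRUE) + 1L]
  out <- character(length(hdp))
  out[hdp] <- pick(probs["hdp", ])[hdp]
  out[!hdp] <- pick(probs["norm", ])[!hdp]
  out
}

# BMI truncated below at 15 kg/m2 by inverse-CDF sampling
sample_bmi <- function(n, spec) {
  u <- stats::runif(n, stats::pnorm(15, spec$bmi_mu, spec$bmi_sigma), 1)
  stats::qnorm(u, spec$bmi_mu, spec$bmi_sigma)
}

draw_level <- function(n, probs, levels) {
  levels[findInterval(stats::runif(n), cumsum(probs), left.open = TRUE) + 1L]
}

#' Sample mothers' questionnaire responses given SDB class
#'
#' Each item is drawn from its class-conditional categorical distribution in
#' `spec$item_prob_table`; snore-conditional items (volume, frequency,
#' bothers-others) are left missing unless the mother answered
#' `snores = "yes"`. BMI is drawn from the truncated normal;
#' `hypertension_history` equals the HDP flag (drawn from the class-implied
#' HDP probability when `hdp` is not supplied).
#'
#' @param sdb_class Character vector over `"none"`, `"mild"`,
#'   `"moderate_severe"`.
#' @param spec A [cohort_spec].
#' @param hdp Optional logical vector of HDP status, recycled.
#' @param seed Optional seed (see [sample_rdi]).
#' @return `data.frame` with the nine [bq_levels] item columns plus `bmi`.
#' @export
sample_mother_response <- function(sdb_class, spec = cohort_spec(), hdp = NULL,
                                   seed = NULL) {
  stopifnot(all(sdb_class %in% sdb_classes))
  with_seed(seed, {
    n <- length(sdb_class)
    if (is.null(hdp)) {
      hdp <- stats::runif(n) < class_probabilities(spec)$hdp_given_class[sdb_class]
    }
    hdp <- rep_len(as.logical(hdp), n)
    out <- data.frame(matrix(NA_character_, n, length(bq_levels)),
                      stringsAsFactors = FALSE)
    names(out) <- names(bq_levels)
    for (cls in unique(sdb_class)) {
      idx <- which(sdb_class == cls)
      tab <- spec$item_prob_table[[cls]]
      for (nm in names(tab)) {
        out[[nm]][idx] <- draw_level(length(idx), tab[[nm]], bq_levels[[nm]])
      }
    }
    conditional <- c("snore_volume", "snore_frequency", "snoring_bothers_others")
    for (nm in conditional) out[[nm]][out$snores != "yes"] <- NA_character_
    out$hypertension_history <- ifelse(hdp, "yes", "no")
    out$bmi <- sample_bmi(n, spec)
    out
  })
}

#' Sample bedpartner responses as noisy copies of the mother's
#'
#' Each item is kept with probability `1 - partner_flip_prob`; a flipped item
#' is replaced by the item's most symptomatic level with probability
#' `partner_up_bias`, else by its least symptomatic level — partners
#' disagreeing mostly by reporting more snoring and tiredness than the mother
#' does. Snore-conditional items follow the partner's own `snores` answer:
#' they are missing unless it is `"yes"`, and an item the mother left
#' unanswered is filled by the same biased draw.
#'
#' @param mother_resp Response table from [sample_mother_response].
#' @param spec A [cohort_spec].
#' @param seed Optional seed.
#' @return Response `data.frame` with the nine item columns.
#' @export
sample_partner_response <- function(mother_resp, spec = cohort_spec(), seed = NULL) {
  with_seed(seed, {
    n <- nrow(mother_resp)
    out <- mother_resp[names(bq_levels)]
    extreme_or_min <- function(k, lv) {
      ifelse(stats::runif(k) < spec$partner_up_bias, lv[length(lv)], lv[1])
    }
    for (nm in setdiff(names(bq_levels), "hypertension_history")) {
      lv <- bq_levels[[nm]]
      flip <- stats::runif(n) < spec$partner_flip_prob
      out[[nm]][flip] <- extreme_or_min(sum(flip), lv)
    }
    conditional <- c("snore_volume", "snore_frequency", "snoring_bothers_others")
    for (nm in conditional) {
      lv <- bq_levels[[nm]]
      fill <- out$snores == "yes" & is.na(out[[nm]])
      out[[nm]][fill] <- extreme_or_min(sum(fill), lv)
      out[[nm]][out$snores != "yes"] <- NA_character_
    }
    rownames(out) <- NULL
    out
  })
}

#' Generate a complete synthetic cohort
#'
#' Draws a full cohort table from a [cohort_spec]: HDP status, SDB class (and
#' an RDI consistent with it), BMI, the mother's questionnaire answers, and —
#' for `partner_fraction` of mothers — a bedpartner's answers. A third of
#' participants are assigned a laboratory sleep study, the rest a home study
#' (presentation only; the analysis does not use it). The draw is fully
#' determined by `spec$seed`.
#'
#' @param spec A [cohort_spec].
#' @return A cohort `data.frame` conforming to [cohort_schema]: columns `id`,
#'   `study_type`, `rdi`, `hdp`, `bmi`, `mother_*` and `partner_*` item
#'   columns (partner columns `NA` where no partner responded).
#' @examples
#' cohort <- generate_cohort(cohort_spec(n_mothers = 20, seed = 7))
#' table(cohort$rdi >= 5)
#' @export
generate_cohort <- function(spec = cohort_spec()) {
  validate_cohort_spec(spec)
  with_seed(spec$seed, {
    n <- spec$n_mothers
    hdp <- stats::runif(n) < spec$hdp_fraction
    cls <- sample_sdb_class(hdp, spec)
    rdi <- sample_rdi_given_class(cls, spec)
    mother <- sample_mother_response(cls, spec, hdp = hdp)
    partner <- sample_partner_response(mother, spec)
    has_partner <- stats::runif(n) < spec$partner_fraction
    for (nm in names(bq_levels)) partner[[nm]][!has_partner] <- NA_character_
    study <- ifelse(stats::runif(n) < 1 / 3, "laboratory", "home")

    out <- data.frame(
      id = sprintf("P%04d", seq_len(max(n, 0))),
      study_type = study, rdi = rdi,
      hdp = ifelse(hdp, "yes", "no"), bmi = mother$bmi,
      stringsAsFactors = FALSE
    )
    for (nm in names(bq_levels)) out[[paste0("mother_", nm)]] <- mother[[nm]]
    for (nm in names(bq_levels)) out[[paste0("partner_", nm)]] <- partner[[nm]]
    if (n == 0) out <- out[0, , drop = FALSE]
    out
  })
}

# pull the mother_/partner_ item columns of a cohort into a response table
rater_responses <- function(cohort, rater = c("mother", "partner")) {
  rater <- match.arg(rater)
  cols <- paste0(rater, "_", names(bq_levels))
  missing_cols <- setdiff(cols, names(cohort))
  for (nm in missing_cols) cohort[[nm]] <- NA_character_
  out <- cohort[cols]
  names(out) <- names(bq_levels)
  out
}
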