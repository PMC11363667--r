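#' Construct a 2x2 confusion table
#'
#' Screen result (high/low risk) against polysomnography-defined
#' sleep-disordered breathing status.
#'
#' @param tp,fp,fn,tn Non-negative integer cell counts (true positive, false
#'   positive, false negative, true negative).
#' @return Object of class `confusion_table`.
#' @export
confusion_table <- function(tp, fp, fn, tn) {
  cells <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(is.na(cells)) || any(cells < 0) || any(cells != round(cells))) {
    stop_sdb("confusion cells must be non-negative integers",
             class = "sdbscreen_table_error")
  }
  structure(as.list(as.integer(cells)), names = names(cells),
            class = "confusion_table")
}

#' @export
print.confusion_table <- function(x, ...) {
  m <- matrix(c(x$tp, x$fp, x$fn, x$tn), 2, byrow = TRUE,
              dimnames = list(screen = c("high", "low"),
                              sdb = c("present", "absent")))
  print(m)
  invisible(x)
}

#' Cross-tabulate screen labels against RDI-defined SDB status
#'
#' SDB status at threshold `t` is `rdi >= t` (inclusive). Pairs with a missing
#' label or missing RDI are dropped; the number dropped is attached as
#' attribute `"excluded"` so denominators are always explicit.
#'
#' @param risk [risk_label] vector (screen outcome).
#' @param rdi Numeric respiratory disturbance index, events/hour, same length.
#' @param rdi_threshold SDB cutoff in events/hour (5 = mild, 15 =
#'   moderate-severe).
#' @return A [confusion_table] with attribute `excluded`.
#' @export
confusion_from_labels <- function(risk, rdi, rdi_threshold) {
  risk <- risk_label(as.character(risk))
  rdi <- as.numeric(rdi)
  if (length(risk) != length(rdi)) {
    stop_sdb("risk and rdi must have equal length", class = "sdbscreen_table_error")
  }
  if (any(!is.na(rdi) & rdi < 0)) {
    stop_sdb("rdi must be non-negative", class = "sdbscreen_table_error")
  }
  keep <- !is.na(risk) & !is.na(rdi)
  pos <- rdi[keep] >= rdi_threshold
  high <- risk[keep] == "high"
  out <- confusion_table(tp = sum(high & pos), fp = sum(high & !pos),
                         fn = sum(!high & pos), tn = sum(!high & !pos))
  attr(out, "excluded") <- sum(!keep)
  out
}

#' Diagnostic accuracy metrics from a confusion table
#'
#' The standard screening metric set: sensitivity, specificity, positive and
#' negative predictive value (all percentages), positive likelihood ratio
#' LR+ = sensitivity / (100 - specificity), and percent of cases classified
#' correctly. A zero-denominator ratio yields `NA` (an explicit not-a-value
#' marker), never an error. Full precision is retained; rounding (percentages
#' to 1 dp, LR+ to 2 dp) happens only in rendered output.
#'
#' @param conf A [confusion_table].
#' @return Object of class `diagnostic_summary`: list with `sensitivity`,
#'   `specificity`, `ppv`, `npv`, `lr_pos`, `pct_correct`, `n`, `n_pos`.
#' @examples
#' metrics_from_confusion(confusion_table(tp = 19, fp = 9, fn = 23, tn = 45))
#' @export
metrics_from_confusion <- function(conf) {
  stopifnot(inherits(conf, "confusion_table"))
  n <- conf$tp + conf$fp + conf$fn + conf$tn
  if (n <= 0) stop_sdb("empty confusion table", class = "sdbscreen_table_error")
  ratio <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  sens <- ratio(conf$tp, conf$tp + conf$fn)
  spec <- ratio(conf$tn, conf$tn + conf$fp)
  lr <- if (!is.na(sens) && !is.na(spec) && spec < 100) sens / (100 - spec) else NA_real_
  structure(list(
    sensitivity = sens,
    specificity = spec,
    ppv = ratio(conf$tp, conf$tp + conf$fp),
    npv = ratio(conf$tn, conf$tn + conf$fn),
    lr_pos = lr,
    pct_correct = 100 * (conf$tp + conf$tn) / n,
    n = n, n_pos = conf$tp + conf$fn
  ), class = "diagnostic_summary")
}

#' @export
print.diagnostic_summary <- function(x, ...) {
  cat(sprintf("n = %d (%d SDB-positive)\n", x$n, x$n_pos))
  cat(sprintf("  sensitivity %s%%  specificity %s%%  LR+ %s\n",
              fmt1(x$sensitivity), fmt1(x$specificity), fmt2(x$lr_pos)))
  cat(sprintf("  PPV %s%%  NPV %s%%  correct %s%%\n",
              fmt1(x$ppv), fmt1(x$npv), fmt1(x$pct_correct)))
  invisible(x)
}

#' Reconstruct a confusion table from published summary metrics
#'
#' Validation papers print sensitivity/specificity and class sizes but rarely
#' the underlying 2x2 cells. Given the evaluable `n`, the number of
#' SDB-positive cases and the two percentages, this recovers the integer
#' cells by nearest-integer inversion and then verifies the round trip: the
#' recomputed sensitivity and specificity must round (1 dp) back to the
#' inputs, otherwise the printed numbers are inconsistent and an error is
#' raised.
#'
#' @param n Evaluable sample size.
#' @param n_pos Number of SDB-positive participants (0 <= n_pos <= n).
#' @param sensitivity_pct,specificity_pct Printed percentages.
#' @return A [confusion_table].
#' @examples
#' counts_from_metrics(96, 42, 83.3, 37.0)  # mother-Berlin at RDI >= 5
#' @export
counts_from_metrics <- function(n, n_pos, sensitivity_pct, specificity_pct) {
  stopifnot(n_pos >= 0, n_pos <= n)
  n_neg <- n - n_pos
  tp <- round_half_up(sensitivity_pct * n_pos / 100)
  tn <- round_half_up(specificity_pct * n_neg / 100)
  out <- confusion_table(tp = tp, fp = n_neg - tn, fn = n_pos - tp, tn = tn)
  m <- metrics_from_confusion(out)
  ok <- function(got, want, n_side) {
    n_side == 0 || abs(round(got, 1) - round(want, 1)) < 0.05 + 1e-9
  }
  if (!ok(m$sensitivity, sensitivity_pct, n_pos) ||
      !ok(m$specificity, specificity_pct, n_neg)) {
    stop_sdb("reconstructed cells do not round-trip to the stated metrics",
             class = "sdbscreen_consistency_error")
  }
  out
}

#' Pearson chi-square test on a 2x2 table
#'
#' Uncorrected (no Yates continuity correction) Pearson chi-square with 1
#' degree of freedom: `N (ad - bc)^2` over the product of the four marginals.
#' A table with any zero marginal is degenerate and raises an error.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return Object of class `chisq_result`: list with `statistic`, `df`, `p`.
#' @export
pearson_chisq_2x2 <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2, 2)) || any(table < 0) || any(is.na(table))) {
    stop_sdb("expected a 2x2 table of non-negative counts",
             class = "sdbscreen_table_error")
  }
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop_sdb("degenerate table: zero marginal", class = "sdbscreen_table_error")
  }
  ht <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  structure(list(statistic = unname(ht$statistic), df = 1L,
                 p = unname(ht$p.value)),
            class = "chisq_result")
}

#' @export
print.chisq_result <- function(x, ...) {
  cat(sprintf("X2(%d) = %s, p = %.3g\n", x$df, fmt2(x$statistic), x$p))
  invisible(x)
}

#' Compare the correct-classification fractions of two screens
#'
#' Builds the 2x2 table [correct, incorrect] x [screen A, screen B], with
#' correct = tp + tn, and applies the uncorrected Pearson chi-square. The two
#' proportions are treated as independent samples even when the screens were
#' scored on the same subjects; for a paired analysis on per-subject
#' correctness indicators use [mcnemar_correct].
#'
#' @param confA,confB [confusion_table]s for the two screens.
#' @return A `chisq_result`.
#' @export
compare_correct_fraction <- function(confA, confB) {
  stopifnot(inherits(confA, "confusion_table"), inherits(confB, "confusion_table"))
  corr <- function(x) c(x$tp + x$tn, x$fp + x$fn)
  pearson_chisq_2x2(rbind(A = corr(confA), B = corr(confB)))
}

#' McNemar test on paired per-subject correctness
#'
#' Paired alternative to [compare_correct_fraction]: takes the two logical
#' correctness vectors (same subjects, same order) and tests the discordant
#' counts. Uncorrected, 1 df.
#'
#' @param correctA,correctB Logical vectors: was each subject classified
#'   correctly by screen A / screen B?
#' @return A `chisq_result`.
#' @export
mcnemar_correct <- function(correctA, correctB) {
  stopifnot(length(correctA) == length(correctB))
  keep <- !is.na(correctA) & !is.na(correctB)
  b <- sum(correctA[keep] & !correctB[keep])
  c <- sum(!correctA[keep] & correctB[keep])
  if (b + c == 0) {
    return(structure(list(statistic = 0, df = 1L, p = 1), class = "chisq_result"))
  }
  stat <- (b - c)^2 / (b + c)
  structure(list(statistic = stat, df = 1L,
                 p = stats::pchisq(stat, 1, lower.tail = FALSE)),
            class = "chisq_result")
}

#' Mother versus bedpartner risk cross-tabulation
#'
#' Four-cell tally of paired risk labels over complete pairs (either label
#' missing drops the pair).
#'
#' @param mother,partner [risk_label] vectors of equal length.
#' @return Object of class `agreement_table`: list with `hh`, `hl`, `lh`,
#'   `ll` (mother-risk x partner-risk, h = high first).
#' @export
cross_tab_raters <- function(mother, partner) {
  mother <- risk_label(as.character(mother))
  partner <- risk_label(as.character(partner))
  if (length(mother) != length(partner)) {
    stop_sdb("rater vectors must have equal length", class = "sdbscreen_table_error")
  }
  keep <- !is.na(mother) & !is.na(partner)
  m <- mother[keep] == "high"
  p <- partner[keep] == "high"
  structure(list(hh = sum(m & p), hl = sum(m & !p),
                 lh = sum(!m & p), ll = sum(!m & !p)),
            class = "agreement_table")
}

#' @export
print.agreement_table <- function(x, ...) {
  m <- matrix(c(x$hh, x$hl, x$lh, x$ll), 2, byrow = TRUE,
              dimnames = list(mother = c("high", "low"),
                              partner = c("high", "low")))
  print(m)
  cat(sprintf("percent agreement: %s%%\n", fmt1(percent_agreement(x))))
  invisible(x)
}

#' Raw percent agreement between raters
#'
#' @param tab An [cross_tab_raters] agreement table.
#' @return Percentage in \[0, 100\]: `100 * (hh + ll) / total`.
#' @export
percent_agreement <- function(tab) {
  stopifnot(inherits(tab, "agreement_table"))
  total <- tab$hh + tab$hl + tab$lh + tab$ll
  if (total == 0) return(NA_real_)
  100 * (tab$hh + tab$ll) / total
}

#' Cohen's kappa for a 2x2 rater table
#'
#' Chance-corrected agreement, offered as supplementary output alongside the
#' raw percent agreement.
#'
#' @inheritParams percent_agreement
#' @return Kappa in \[-1, 1\], or `NA` when chance agreement is 1.
#' @export
cohen_kappa <- function(tab) {
  stopifnot(inherits(tab, "agreement_table"))
  n <- tab$hh + tab$hl + tab$lh + tab$ll
  if (n == 0) return(NA_real_)
  po <- (tab$hh + tab$ll) / n
  pe <- ((tab$hh + tab$hl) * (tab$hh + tab$lh) +
           (tab$lh + tab$ll) * (tab$hl + tab$ll)) / n^2
  if (abs(1 - pe) < .Machine$double.eps^0.5) return(NA_real_)
  (po - pe) / (1 - pe)
}
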