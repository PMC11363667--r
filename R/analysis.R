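#' Run the full screening-validation analysis on a cohort
#'
#' Executes the whole pipeline on a validated cohort table: scores the Berlin
#' Questionnaire and the Wilson Optimized Model for the mother (and the
#' bedpartner where present), cross-tabulates each screen against
#' polysomnography SDB status at each RDI threshold, computes the diagnostic
#' metric set, compares classifiers (Berlin vs Wilson) and raters (mother vs
#' partner) on correct-classification fractions, cross-tabulates
#' mother-partner Wilson risk agreement, runs ROC/AUC analysis of the
#' continuous Wilson score (with DeLong confidence intervals and the paired
#' mother-vs-partner AUC test), and evaluates the Wilson and Berlin screens
#' within the hypertensive-disorder subgroup. Every number in the report is
#' recomputable from the stored confusion tables; nothing is free-floating.
#'
#' @param cohort Cohort table (see [read_cohort] / [generate_cohort]).
#' @param weights A [wom_weights] table.
#' @param rdi_thresholds RDI cutoffs defining SDB status (default `c(5, 15)`).
#' @return Object of class `analysis_report`; see the elements documented in
#'   the methods vignette. Partner-dependent sections are `NULL` when the
#'   cohort carries no partner responses.
#' @export
run_full_analysis <- function(cohort, weights = wom_weights(),
                              rdi_thresholds = c(5, 15)) {
  cohort <- validate_cohort(as.data.frame(cohort))
  mother <- rater_responses(cohort, "mother")
  partner <- rater_responses(cohort, "partner")
  has_partner <- rowSums(!is.na(partner)) > 0

  labels <- list(
    mother_berlin = classify_berlin(mother, cohort$bmi),
    mother_wilson = classify_wom(score_wom(mother, cohort$bmi, weights),
                                 weights$threshold)
  )
  scores <- list(mother_wilson = score_wom(mother, cohort$bmi, weights))
  if (any(has_partner)) {
    psc <- rep(NA_real_, nrow(cohort))
    plab <- rep(NA_character_, nrow(cohort))
    idx <- which(has_partner)
    psc[idx] <- score_wom(partner[idx, , drop = FALSE], cohort$bmi[idx], weights)
    plab[idx] <- as.character(classify_wom(psc[idx], weights$threshold))
    scores$partner_wilson <- psc
    labels$partner_wilson <- risk_label(plab)
  }

  thr_name <- function(t) paste0("rdi", t)
  screens <- list()
  for (t in rdi_thresholds) {
    for (nm in names(labels)) {
      conf <- confusion_from_labels(labels[[nm]], cohort$rdi, t)
      screens[[nm]][[thr_name(t)]] <- list(confusion = conf,
                                           metrics = metrics_from_confusion(conf))
    }
  }

  comparisons <- list()
  for (t in rdi_thresholds) {
    tn <- thr_name(t)
    comparisons$berlin_vs_wilson[[tn]] <-
      compare_correct_fraction(screens$mother_berlin[[tn]]$confusion,
                               screens$mother_wilson[[tn]]$confusion)
    if (!is.null(screens$partner_wilson)) {
      comparisons$mother_vs_partner_wilson[[tn]] <-
        compare_correct_fraction(screens$mother_wilson[[tn]]$confusion,
                                 screens$partner_wilson[[tn]]$confusion)
    }
  }

  agreement <- NULL
  if (!is.null(labels$partner_wilson)) {
    tab <- cross_tab_raters(labels$mother_wilson, labels$partner_wilson)
    agreement <- list(table = tab,
                      percent = percent_agreement(tab),
                      kappa = cohen_kappa(tab))
  }

  roc <- list()
  for (t in rdi_thresholds) {
    tn <- thr_name(t)
    status <- cohort$rdi >= t
    for (nm in names(scores)) {
      keep <- !is.na(scores[[nm]]) & !is.na(status)
      roc[[nm]][[tn]] <- if (sum(status[keep]) > 0 && sum(!status[keep]) > 0) {
        list(curve = roc_points(scores[[nm]][keep], status[keep]),
             auc = auc_confidence_interval(scores[[nm]][keep], status[keep]))
      }
    }
    if (!is.null(scores$partner_wilson)) {
      ok <- tryCatch(
        compare_auc_paired(scores$mother_wilson, scores$partner_wilson, status),
        sdbscreen_degenerate_outcome = function(e) NULL)
      roc$mother_vs_partner[[tn]] <- ok
    }
  }

  hdp <- NULL
  in_hdp <- !is.na(cohort$hdp) & cohort$hdp == "yes"
  in_norm <- !is.na(cohort$hdp) & cohort$hdp == "no"
  if ("hdp" %in% names(cohort) && any(in_hdp) && any(in_norm)) {
    sub <- function(lab, rows) confusion_from_labels(lab[rows], cohort$rdi[rows], min(rdi_thresholds))
    hdp <- list(threshold = min(rdi_thresholds))
    for (nm in c("mother_wilson", "mother_berlin")) {
      ch <- sub(labels[[nm]], in_hdp)
      cn <- sub(labels[[nm]], in_norm)
      hdp[[nm]] <- list(
        hdp_confusion = ch, hdp_metrics = metrics_from_confusion(ch),
        normotensive_confusion = cn, normotensive_metrics = metrics_from_confusion(cn),
        comparison = compare_correct_fraction(ch, cn)
      )
    }
  }

  structure(list(
    n = nrow(cohort), n_partner = sum(has_partner),
    rdi_thresholds = rdi_thresholds,
    row_issues = attr(cohort, "row_issues"),
    screens = screens, comparisons = comparisons,
    agreement = agreement, roc = roc, hdp = hdp
  ), class = "analysis_report")
}

#' Render an analysis report as plain text tables
#'
#' Deterministic layout mirroring a validation-paper results section: the
#' per-screen diagnostic table (percentages to 1 decimal, likelihood ratios
#' to 2), classifier and rater chi-square comparisons (2 decimals), the
#' mother-partner agreement cross-tab, AUC results and the HDP sub-analysis.
#' Partner sections are omitted when absent.
#'
#' @param report An [run_full_analysis] report.
#' @return Character vector of lines (also printed by `print.analysis_report`).
#' @export
render_report <- function(report) {
  stopifnot(inherits(report, "analysis_report"))
  out <- character()
  add <- function(...) out <<- c(out, paste0(...))
  thr <- report$rdi_thresholds
  tn <- function(t) paste0("rdi", t)

  add("Screening validation report")
  add(sprintf("Participants: %d (%d with bedpartner responses)",
              report$n, report$n_partner))
  if (nrow(report$row_issues) > 0) {
    add(sprintf("Row-level validation issues: %d (see row_issues)",
                nrow(report$row_issues)))
  }
  add("")
  add("Diagnostic accuracy")
  header <- c("screen", "rdi_cutoff", "sens", "spec", "lr_pos", "ppv", "npv",
              "pct_correct")
  add(paste(header, collapse = "\t"))
  for (nm in names(report$screens)) {
    for (t in thr) {
      m <- report$screens[[nm]][[tn(t)]]$metrics
      add(paste(c(nm, t, fmt1(m$sensitivity), fmt1(m$specificity),
                  fmt2(m$lr_pos), fmt1(m$ppv), fmt1(m$npv),
                  fmt1(m$pct_correct)), collapse = "\t"))
    }
  }
  add("")
  add("Classifier comparisons (correct-fraction chi-square, 1 df)")
  for (cmp in names(report$comparisons)) {
    for (t in thr) {
      x <- report$comparisons[[cmp]][[tn(t)]]
      add(sprintf("  %s @ RDI>=%g: X2 = %s, p = %.3g", cmp, t,
                  fmt2(x$statistic), x$p))
    }
  }
  if (!is.null(report$agreement)) {
    a <- report$agreement
    add("")
    add("Mother vs bedpartner (Wilson Optimized Model)")
    add(sprintf("  high/high %d  high/low %d  low/high %d  low/low %d",
                a$table$hh, a$table$hl, a$table$lh, a$table$ll))
    add(sprintf("  percent agreement %s%%, kappa %s", fmt1(a$percent),
                fmt2(a$kappa)))
  }
  add("")
  add("ROC analysis (Wilson score)")
  for (nm in setdiff(names(report$roc), "mother_vs_partner")) {
    for (t in thr) {
      r <- report$roc[[nm]][[tn(t)]]
      if (is.null(r)) next
      add(sprintf("  %s @ RDI>=%g: AUC %s (95%% CI %s-%s)", nm, t,
                  fmt2(r$auc$auc), fmt2(r$auc$ci_low), fmt2(r$auc$ci_high)))
    }
  }
  if (!is.null(report$roc$mother_vs_partner)) {
    for (t in thr) {
      x <- report$roc$mother_vs_partner[[tn(t)]]
      if (is.null(x)) next
      add(sprintf("  paired mother-vs-partner @ RDI>=%g: X2 = %s, p = %.3g",
                  t, fmt2(x$statistic), x$p))
    }
  }
  if (!is.null(report$hdp)) {
    add("")
    add(sprintf("Hypertensive-disorder subgroup (RDI>=%g)", report$hdp$threshold))
    for (nm in c("mother_wilson", "mother_berlin")) {
      h <- report$hdp[[nm]]
      add(sprintf("  %s: HDP correct %s%% vs normotensive %s%% (X2 = %s, p = %.3g)",
                  nm, fmt1(h$hdp_metrics$pct_correct),
                  fmt1(h$normotensive_metrics$pct_correct),
                  fmt2(h$comparison$statistic), h$comparison$p))
      add(sprintf("    HDP subgroup: sens %s%%, spec %s%%, PPV %s%%, NPV %s%%, LR+ %s",
                  fmt1(h$hdp_metrics$sensitivity), fmt1(h$hdp_metrics$specificity),
                  fmt1(h$hdp_metrics$ppv), fmt1(h$hdp_metrics$npv),
                  fmt2(h$hdp_metrics$lr_pos)))
    }
  }
  out
}

#' @export
print.analysis_report <- function(x, ...) {
  cat(render_report(x), sep = "\n")
  invisible(x)
}
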