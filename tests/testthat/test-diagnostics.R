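test_that("confusion tables tally labels against the RDI threshold", {
  conf <- confusion_from_labels(risk_label(c("high", "low")), c(6, 1), 5)
  expect_equal(unclass(conf)[c("tp", "fp", "fn", "tn")],
               list(tp = 1L, fp = 0L, fn = 0L, tn = 1L))

  all_high <- confusion_from_labels(risk_label(rep("high", 4)), c(5, 7, 15, 20), 5)
  expect_equal(all_high$fn, 0L)
  expect_equal(all_high$tn, 0L)

  # random 20-pair input equals a cell-by-cell hand tally
  set.seed(7)
  for (rep in 1:10) {
    risk <- sample(c("high", "low"), 20, replace = TRUE)
    rdi <- round(rexp(20, 0.15), 1)
    conf <- confusion_from_labels(risk_label(risk), rdi, 5)
    expect_equal(conf$tp, sum(risk == "high" & rdi >= 5))
    expect_equal(conf$fp, sum(risk == "high" & rdi < 5))
    expect_equal(conf$fn, sum(risk == "low" & rdi >= 5))
    expect_equal(conf$tn, sum(risk == "low" & rdi < 5))
  }

  # missing pairs are dropped and tallied
  conf <- confusion_from_labels(risk_label(c("high", NA, "low")), c(6, 3, NA), 5)
  expect_equal(attr(conf, "excluded"), 2L)
  expect_equal(conf$tp + conf$fp + conf$fn + conf$tn, 1L)
})

test_that("diagnostic metrics match their defining formulas", {
  # the mother-Wilson RDI>=5 cell pattern reconstructed from class sizes
  m <- metrics_from_confusion(confusion_table(tp = 19, fp = 9, fn = 23, tn = 45))
  expect_equal(round(m$sensitivity, 1), 45.2)
  expect_equal(round(m$specificity, 1), 83.3)
  expect_equal(round(m$ppv, 1), 67.9)
  expect_equal(round(m$npv, 1), 66.2)
  expect_equal(round(m$lr_pos, 2), 2.71)

  perfect <- metrics_from_confusion(confusion_table(10, 0, 0, 10))
  expect_equal(perfect$sensitivity, 100)
  expect_equal(perfect$specificity, 100)
  expect_true(is.na(perfect$lr_pos))

  # random tables match an independent formula oracle
  set.seed(11)
  for (rep in 1:20) {
    cells <- rpois(4, 12) + 1
    m <- metrics_from_confusion(confusion_table(cells[1], cells[2], cells[3], cells[4]))
    expect_equal(m$sensitivity, 100 * cells[1] / (cells[1] + cells[3]))
    expect_equal(m$specificity, 100 * cells[4] / (cells[4] + cells[2]))
    expect_equal(m$ppv, 100 * cells[1] / (cells[1] + cells[2]))
    expect_equal(m$npv, 100 * cells[4] / (cells[4] + cells[3]))
    expect_equal(m$lr_pos, m$sensitivity / (100 - m$specificity))
    # percent correct is the prevalence-weighted mean of sens and spec
    expect_equal(m$pct_correct,
                 (m$n_pos * m$sensitivity + (m$n - m$n_pos) * m$specificity) / m$n)
    # LR+ >= 1 exactly when sensitivity >= 100 - specificity
    expect_identical(m$lr_pos >= 1, m$sensitivity >= 100 - m$specificity)
  }

  # zero-denominator ratios are NA markers, never errors
  degenerate <- metrics_from_confusion(confusion_table(0, 0, 0, 5))
  expect_true(is.na(degenerate$sensitivity))
  expect_true(is.na(degenerate$ppv))
})

test_that("published metrics reconstruct to integer cells and round-trip", {
  expect_equal(unclass(counts_from_metrics(96, 42, 83.3, 37.0))[c("tp", "fn", "tn", "fp")],
               list(tp = 35L, fn = 7L, tn = 20L, fp = 34L))
  expect_equal(unclass(counts_from_metrics(96, 15, 66.7, 77.8))[c("tp", "fn", "tn", "fp")],
               list(tp = 10L, fn = 5L, tn = 63L, fp = 18L))
  expect_equal(unclass(counts_from_metrics(10, 5, 100, 100))[c("tp", "fp", "fn", "tn")],
               list(tp = 5L, fp = 0L, fn = 0L, tn = 5L))
  # inconsistent printed metrics are refused
  expect_error(counts_from_metrics(96, 42, 85.9, 37.0),
               class = "sdbscreen_consistency_error")

  # round trip: reconstructed cells reproduce the metrics within 0.05 points
  set.seed(3)
  for (rep in 1:50) {
    n <- sample(40:150, 1)
    n_pos <- sample(seq(5, n - 5), 1)
    sens <- round(100 * sample(0:n_pos, 1) / n_pos, 1)
    spec <- round(100 * sample(0:(n - n_pos), 1) / (n - n_pos), 1)
    m <- metrics_from_confusion(counts_from_metrics(n, n_pos, sens, spec))
    expect_lt(abs(m$sensitivity - sens), 0.05 + 1e-9)
    expect_lt(abs(m$specificity - spec), 0.05 + 1e-9)
  }
})

test_that("uncorrected Pearson chi-square matches the expected-counts oracle", {
  wilson_vs_berlin_15 <- pearson_chisq_2x2(rbind(c(73, 23), c(40, 56)))
  expect_equal(round(wilson_vs_berlin_15$statistic, 2), 23.42)
  expect_lt(wilson_vs_berlin_15$p, 0.001)

  expect_equal(pearson_chisq_2x2(rbind(c(10, 10), c(10, 10)))$statistic, 0)

  expect_equal(pearson_chisq_2x2(rbind(c(5, 5), c(2, 8)))$statistic,
               chisq_oracle(rbind(c(5, 5), c(2, 8))))
  set.seed(5)
  for (rep in 1:20) {
    m <- matrix(rpois(4, 15) + 1, 2)
    got <- pearson_chisq_2x2(m)
    expect_equal(got$statistic, chisq_oracle(m))
    expect_equal(got$p, pchisq(got$statistic, 1, lower.tail = FALSE))
    # invariance to transposition and to joint row+column reversal
    expect_equal(pearson_chisq_2x2(t(m))$statistic, got$statistic)
    expect_equal(pearson_chisq_2x2(m[2:1, 2:1])$statistic, got$statistic)
  }

  expect_error(pearson_chisq_2x2(rbind(c(0, 0), c(3, 4))),
               class = "sdbscreen_table_error")
})

test_that("classifier and rater correct-fraction comparisons match print", {
  berlin5 <- counts_from_metrics(96, 42, 83.3, 37.0)   # 55/96 correct
  wilson5 <- counts_from_metrics(96, 42, 45.2, 83.3)   # 64/96 correct
  cmp <- compare_correct_fraction(berlin5, wilson5)
  expect_equal(round(cmp$statistic, 2), 1.79)

  mother15 <- counts_from_metrics(96, 15, 66.7, 77.8)         # 73/96 correct
  partner15 <- counts_from_metrics(81, 14, 64.3, 67.2)        # 54/81 correct
  expect_equal(round(compare_correct_fraction(mother15, partner15)$statistic, 2),
               1.91)

  same <- confusion_table(12, 3, 4, 20)
  expect_equal(compare_correct_fraction(same, same)$statistic, 0)
})

test_that("McNemar alternative handles paired correctness vectors", {
  a <- c(TRUE, TRUE, TRUE, FALSE, FALSE, TRUE)
  b <- c(TRUE, FALSE, FALSE, FALSE, TRUE, TRUE)
  got <- mcnemar_correct(a, b)
  expect_equal(got$statistic, (2 - 1)^2 / 3)
  expect_equal(mcnemar_correct(a, a)$statistic, 0)
  expect_equal(mcnemar_correct(a, a)$p, 1)
})

test_that("rater cross-tab and percent agreement reproduce the published pattern", {
  # perfect agreement
  same <- risk_label(c("high", "low", "low"))
  tab <- cross_tab_raters(same, same)
  expect_equal(tab$hl + tab$lh, 0L)
  expect_equal(percent_agreement(tab), 100)

  # the published mother-vs-partner pattern: 17/6/14/44 -> 75.3%
  mother <- risk_label(rep(c("high", "high", "low", "low"), c(17, 6, 14, 44)))
  partner <- risk_label(rep(c("high", "low", "high", "low"), c(17, 6, 14, 44)))
  tab <- cross_tab_raters(mother, partner)
  expect_equal(unclass(tab)[c("hh", "hl", "lh", "ll")],
               list(hh = 17L, hl = 6L, lh = 14L, ll = 44L))
  expect_equal(round(percent_agreement(tab), 1), 75.3)

  balanced <- structure(list(hh = 1L, hl = 1L, lh = 1L, ll = 1L),
                        class = "agreement_table")
  expect_equal(percent_agreement(balanced), 50)
  expect_equal(cohen_kappa(balanced), 0)

  # random labels equal a hand-count oracle; incomplete pairs are dropped
  set.seed(9)
  for (rep in 1:10) {
    m <- sample(c("high", "low", NA), 30, replace = TRUE)
    p <- sample(c("high", "low", NA), 30, replace = TRUE)
    tab <- cross_tab_raters(risk_label(m), risk_label(p))
    keep <- !is.na(m) & !is.na(p)
    expect_equal(tab$hh, sum(m[keep] == "high" & p[keep] == "high"))
    expect_equal(tab$ll, sum(m[keep] == "low" & p[keep] == "low"))
    expect_equal(tab$hh + tab$hl + tab$lh + tab$ll, sum(keep))
  }
})
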