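#' ROC operating points for a continuous score
#'
#' Sweeps the decision threshold over every distinct score value (ties grouped
#' at one threshold, higher score = more at risk, a tied score at the
#' threshold classifies positive) and returns the (false-positive rate,
#' true-positive rate) operating points anchored at (0,0) and (1,1).
#'
#' @param scores Numeric score vector.
#' @param status Binary SDB status (logical, or 0/1), same length.
#' @return Object of class `roc_curve`: data.frame with columns `threshold`,
#'   `fpr`, `tpr`, both rates non-decreasing along the sweep.
#' @export
roc_points <- function(scores, status) {
  xy <- check_scores_status(scores, status)
  pos <- xy$scores[xy$status]
  neg <- xy$scores[!xy$status]
  thr <- sort(unique(xy$scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) mean(pos >= t), 0)
  fpr <- vapply(thr, function(t) mean(neg >= t), 0)
  out <- data.frame(threshold = c(Inf, thr), fpr = c(0, fpr), tpr = c(0, tpr))
  # the lowest threshold always yields (1,1); keep it as the explicit anchor
  structure(out, class = c("roc_curve", "data.frame"))
}

check_scores_status <- function(scores, status, what = "status") {
  scores <- as.numeric(scores)
  if (is.factor(status)) status <- status == levels(status)[2]
  status <- as.logical(status)
  if (length(scores) != length(status)) {
    stop_sdb("scores and status must have equal length", class = "sdbscreen_roc_error")
  }
  keep <- !is.na(scores) & !is.na(status)
  scores <- scores[keep]; status <- status[keep]
  if (!any(status) || all(status)) {
    stop_sdb("both outcome classes must be present", class = "sdbscreen_degenerate_outcome")
  }
  list(scores = scores, status = status)
}

#' Trapezoidal area under an ROC curve
#'
#' Equals the tie-corrected rank-sum probability
#' P(score_pos > score_neg) + 0.5 P(score_pos = score_neg).
#'
#' @param curve A [roc_points] curve, or a numeric score vector (then `status`
#'   must be supplied).
#' @param status Binary status when `curve` is a score vector.
#' @return AUC in \[0, 1\].
#' @export
auc_trapezoid <- function(curve, status = NULL) {
  if (!inherits(curve, "roc_curve")) curve <- roc_points(curve, status)
  sum(diff(curve$fpr) * (utils::head(curve$tpr, -1) + utils::tail(curve$tpr, -1)) / 2)
}

# DeLong placement components: V10[i] = P-hat(neg < pos_i) (+ half ties),
# V01[j] likewise for negatives. midrank formulation, O((m+n) log(m+n)).
delong_components <- function(scores, status) {
  pos <- scores[status]; neg <- scores[!status]
  m <- length(pos); n <- length(neg)
  v10 <- vapply(pos, function(x) (sum(neg < x) + 0.5 * sum(neg == x)) / n, 0)
  v01 <- vapply(neg, function(y) (sum(pos > y) + 0.5 * sum(pos == y)) / m, 0)
  list(theta = mean(v10), v10 = v10, v01 = v01, m = m, n = n)
}

# variance of one AUC from its DeLong components; single-observation classes
# fall back to the Bernoulli bound so degenerate inputs yield a wide CI
delong_var <- function(cmp) {
  s10 <- if (cmp$m > 1) stats::var(cmp$v10) else cmp$theta * (1 - cmp$theta)
  s01 <- if (cmp$n > 1) stats::var(cmp$v01) else cmp$theta * (1 - cmp$theta)
  s10 / cmp$m + s01 / cmp$n
}

#' AUC with a confidence interval
#'
#' AUC of a continuous score against binary SDB status with an asymptotic
#' confidence interval. The default variance is DeLong's (covariance of the
#' placement components); Hanley-McNeil's exponential approximation is
#' available for comparison. The interval is clipped to \[0, 1\].
#'
#' @inheritParams roc_points
#' @param level Confidence level (default 0.95).
#' @param method `"delong"` (default) or `"hanley-mcneil"`.
#' @return Object of class `auc_result`: list with `auc`, `ci_low`, `ci_high`,
#'   `se`, `method`, `level`, `n_pos`, `n_neg`.
#' @export
auc_confidence_interval <- function(scores, status, level = 0.95,
                                    method = c("delong", "hanley-mcneil")) {
  method <- match.arg(method)
  xy <- check_scores_status(scores, status)
  cmp <- delong_components(xy$scores, xy$status)
  theta <- cmp$theta
  v <- if (method == "delong") {
    delong_var(cmp)
  } else {
    q1 <- theta / (2 - theta)
    q2 <- 2 * theta^2 / (1 + theta)
    (theta * (1 - theta) + (cmp$m - 1) * (q1 - theta^2) +
        (cmp$n - 1) * (q2 - theta^2)) / (cmp$m * cmp$n)
  }
  se <- sqrt(max(v, 0))
  z <- stats::qnorm(1 - (1 - level) / 2)
  structure(list(auc = theta,
                 ci_low = max(0, theta - z * se),
                 ci_high = min(1, theta + z * se),
                 se = se, method = method, level = level,
                 n_pos = cmp$m, n_neg = cmp$n),
            class = "auc_result")
}

#' @export
print.auc_result <- function(x, ...) {
  cat(sprintf("AUC = %.2f (%.0f%% CI %.2f-%.2f, %s; %d pos / %d neg)\n",
              x$auc, 100 * x$level, x$ci_low, x$ci_high, x$method,
              x$n_pos, x$n_neg))
  invisible(x)
}

#' Paired comparison of two correlated AUCs
#'
#' DeLong's test for two scores measured on the same subjects against the
#' same binary status. The z statistic is squared onto a 1-df chi-square
#' scale, matching how screening comparisons are conventionally reported.
#' Subjects missing either score are dropped.
#'
#' @param scoresA,scoresB Numeric score vectors (same subjects, same order).
#' @param status Binary SDB status.
#' @return A `chisq_result` with additional fields `aucA`, `aucB`, `se_diff`.
#' @export
compare_auc_paired <- function(scoresA, scoresB, status) {
  scoresA <- as.numeric(scoresA); scoresB <- as.numeric(scoresB)
  if (is.factor(status)) status <- status == levels(status)[2]
  status <- as.logical(status)
  stopifnot(length(scoresA) == length(scoresB),
            length(scoresA) == length(status))
  keep <- !is.na(scoresA) & !is.na(scoresB) & !is.na(status)
  scoresA <- scoresA[keep]; scoresB <- scoresB[keep]; status <- status[keep]
  if (!any(status) || all(status)) {
    stop_sdb("both outcome classes must be present", class = "sdbscreen_degenerate_outcome")
  }
  ca <- delong_components(scoresA, status)
  cb <- delong_components(scoresB, status)
  m <- ca$m; n <- ca$n
  cov10 <- if (m > 1) stats::cov(ca$v10, cb$v10) else 0
  cov01 <- if (n > 1) stats::cov(ca$v01, cb$v01) else 0
  v <- delong_var(ca) + delong_var(cb) - 2 * (cov10 / m + cov01 / n)
  d <- ca$theta - cb$theta
  if (v <= .Machine$double.eps) {
    stat <- if (abs(d) < .Machine$double.eps^0.5) 0 else Inf
  } else {
    stat <- d^2 / v
  }
  structure(list(statistic = stat, df = 1L,
                 p = stats::pchisq(stat, 1, lower.tail = FALSE),
                 aucA = ca$theta, aucB = cb$theta, se_diff = sqrt(max(v, 0))),
            class = "chisq_result")
}

#' @export
plot.roc_curve <- function(x, ..., col = "steelblue", lwd = 2) {
  plot(x$fpr, x$tpr, type = "l", col = col, lwd = lwd,
       xlab = "False-positive rate (1 - specificity)",
       ylab = "True-positive rate (sensitivity)",
       xlim = c(0, 1), ylim = c(0, 1), ...)
  graphics::abline(0, 1, lty = 3, col = "grey50")
  invisible(x)
}
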