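#' Load and validate a Wilson Optimized Model weight table
#'
#' The Wilson Optimized Model (WOM) is an additive risk score over three
#' Berlin Questionnaire items — having been told one snores, snoring volume,
#' and tiredness after sleep — plus an indicator for BMI > 32 kg/m2. Each item
#' level carries a weight; the total ranges from `score_min` (2.2) to
#' `score_max` (25.2) and a total strictly above `threshold` (18.1) is high
#' risk.
#'
#' Weights are read from a plain key/value text file, one `item.level = value`
#' line per weight plus `threshold`, `score_min` and `score_max` lines
#' (`#` starts a comment). The file shipped with the package,
#' `wom_weights_synthetic.conf`, is a synthetic placeholder that satisfies the
#' published range/threshold invariants but is NOT the published weight table;
#' users with the original supplement should transcribe it into this format.
#'
#' Load-time invariants, all enforced: every level of every item has a finite
#' non-negative weight; weights are non-decreasing in level order; the minimum
#' possible total equals `score_min` and the maximum equals `score_max`.
#'
#' @param path Path to a weight config file; default is the shipped synthetic
#'   placeholder.
#' @return An object of class `wom_weights`: a list with elements `items`
#'   (named list of per-level weight vectors), `threshold`, `score_min`,
#'   `score_max`, and `source`.
#' @examples
#' w <- wom_weights()
#' w$threshold
#' @export
wom_weights <- function(path = system.file("extdata", "wom_weights_synthetic.conf",
                                           package = "sdbscreen")) {
  if (!file.exists(path)) {
    stop_sdb("weight config not found: ", path, class = "sdbscreen_io_error")
  }
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  if (any(lengths(kv) != 2)) {
    stop_sdb("malformed weight config line(s): expected 'key = value'",
             class = "sdbscreen_io_error")
  }
  keys <- trimws(vapply(kv, `[[`, "", 1))
  vals <- suppressWarnings(as.numeric(trimws(vapply(kv, `[[`, "", 2))))
  if (any(is.na(vals))) {
    stop_sdb("non-numeric value(s) in weight config",
             class = "sdbscreen_io_error")
  }
  scalars <- c(threshold = 18.1, score_min = 2.2, score_max = 25.2)
  for (s in names(scalars)) {
    if (s %in% keys) scalars[[s]] <- vals[match(s, keys)]
  }
  item_keys <- keys[!keys %in% names(scalars)]
  item_vals <- vals[!keys %in% names(scalars)]
  parts <- strsplit(item_keys, ".", fixed = TRUE)
  if (any(lengths(parts) != 2)) {
    stop_sdb("weight keys must look like item.level", class = "sdbscreen_io_error")
  }
  item_levels <- c(bq_levels[wom_items], list(bmi_gt32 = c("no", "yes")))
  items <- lapply(stats::setNames(names(item_levels), names(item_levels)), function(nm) {
    lv <- item_levels[[nm]]
    w <- rep(NA_real_, length(lv))
    names(w) <- lv
    sel <- vapply(parts, `[[`, "", 1) == nm
    w[vapply(parts[sel], `[[`, "", 2)] <- item_vals[sel]
    if (anyNA(w)) {
      stop_sdb("missing weight(s) for ", nm, ": ",
               paste(lv[is.na(w)], collapse = ", "), class = "sdbscreen_weight_error")
    }
    w
  })
  out <- structure(
    list(items = items, threshold = scalars[["threshold"]],
         score_min = scalars[["score_min"]], score_max = scalars[["score_max"]],
         source = path),
    class = "wom_weights"
  )
  validate_wom_weights(out)
  out
}

# the three questionnaire items entering the WOM (BMI indicator handled apart)
wom_items <- c("snores", "snore_volume", "tired_after_sleep_frequency")

validate_wom_weights <- function(w, tol = 1e-8) {
  stopifnot(inherits(w, "wom_weights"))
  for (nm in names(w$items)) {
    wi <- w$items[[nm]]
    if (any(!is.finite(wi)) || any(wi < 0)) {
      stop_sdb("weights for ", nm, " must be finite and non-negative",
               class = "sdbscreen_weight_error")
    }
    if (any(diff(wi) < 0)) {
      stop_sdb("weights for ", nm, " must be non-decreasing in level",
               class = "sdbscreen_weight_error")
    }
  }
  lo <- sum(vapply(w$items, min, 0))
  hi <- sum(vapply(w$items, max, 0))
  if (abs(lo - w$score_min) > tol) {
    stop_sdb("minimum total ", lo, " != declared score_min ", w$score_min,
             class = "sdbscreen_weight_error")
  }
  if (abs(hi - w$score_max) > tol) {
    stop_sdb("maximum total ", hi, " != declared score_max ", w$score_max,
             class = "sdbscreen_weight_error")
  }
  invisible(w)
}

#' @export
print.wom_weights <- function(x, ...) {
  cat("Wilson Optimized Model weights (", basename(x$source), ")\n", sep = "")
  cat("  range [", x$score_min, ", ", x$score_max, "], high risk > ",
      x$threshold, "\n", sep = "")
  for (nm in names(x$items)) {
    cat("  ", nm, ": ", paste(sprintf("%s=%g", names(x$items[[nm]]),
                                      x$items[[nm]]), collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Compute the Wilson Optimized Model score
#'
#' Additive total of the level weights for the three WOM items plus the
#' BMI > 32 kg/m2 indicator weight. Missing required items raise an error that
#' names the item; there is no silent imputation. The one documented
#' exception: a respondent who answered `snores = "no"` or `"do_not_know"`
#' cannot rate her own snoring volume, so a missing `snore_volume` then
#' resolves to the minimum-risk level (`nonsnorer_volume = "minimum"`, the
#' default) — set `nonsnorer_volume = "error"` to forbid this too.
#'
#' @param resp Response table (see [berlin_response]); may have many rows.
#' @param bmi Numeric BMI vector (kg/m2), recycled to rows of `resp`.
#' @param weights A [wom_weights] object.
#' @param nonsnorer_volume `"minimum"` (default) or `"error"`; see Details.
#' @return Numeric score vector in `[weights$score_min, weights$score_max]`.
#' @examples
#' w <- wom_weights()
#' r <- berlin_response(snores = "yes", snore_volume = "very_loud",
#'                      tired_after_sleep_frequency = "nearly_every_day")
#' score_wom(r, bmi = 36, weights = w)
#' @export
score_wom <- function(resp, bmi, weights = wom_weights(),
                      nonsnorer_volume = c("minimum", "error")) {
  nonsnorer_volume <- match.arg(nonsnorer_volume)
  validate_wom_weights(weights)
  validate_bq_items(resp, wom_items)
  bmi <- rep_len(check_bmi(bmi), nrow(resp))
  if (anyNA(bmi)) {
    stop_sdb("missing item: bmi", class = "sdbscreen_missing_item")
  }

  vol <- resp$snore_volume
  resolvable <- is.na(vol) & !is.na(resp$snores) & resp$snores != "yes"
  if (nonsnorer_volume == "minimum") {
    vol[resolvable] <- bq_levels$snore_volume[1]
  }
  values <- list(snores = resp$snores, snore_volume = vol,
                 tired_after_sleep_frequency = resp$tired_after_sleep_frequency)
  for (nm in wom_items) {
    if (anyNA(values[[nm]])) {
      stop_sdb("missing item: ", nm, class = "sdbscreen_missing_item")
    }
  }
  score <- rep(0, nrow(resp))
  for (nm in wom_items) {
    score <- score + unname(weights$items[[nm]][values[[nm]]])
  }
  score + unname(weights$items$bmi_gt32[ifelse(bmi > 32, "yes", "no")])
}

#' Classify a Wilson Optimized Model score
#'
#' High risk when the score strictly exceeds the threshold: 18.2 is high,
#' 18.1 is low at the default cutoff.
#'
#' @param score Numeric WOM score vector.
#' @param threshold Cutoff; default 18.1.
#' @return A [risk_label] factor.
#' @export
classify_wom <- function(score, threshold = 18.1) {
  stopifnot(is.numeric(score), is.numeric(threshold), length(threshold) == 1)
  risk_label(score > threshold)
}
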