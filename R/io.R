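#' Cohort table schema
#'
#' The versioned column contract for cohort CSV files: participant id, study
#' type, RDI, HDP flag, BMI, and one column per Berlin Questionnaire item for
#' the mother (`mother_*`) and optionally the bedpartner (`partner_*`).
#' Ordinal answers are stored as lowercase tokens from [bq_levels], never as
#' integers, so a level mismatch is caught by validation instead of silently
#' reordering the scale.
#'
#' @return `data.frame` with columns `column`, `type` (`"character"`,
#'   `"numeric"`, `"enum"`), `required` (logical) and `levels`
#'   (comma-separated allowed tokens, `""` for free columns); attribute
#'   `version` carries the schema version string.
#' @export
cohort_schema <- function() {
  enum_row <- function(col, levels, required) {
    data.frame(column = col, type = "enum", required = required,
               levels = paste(levels, collapse = ","), stringsAsFactors = FALSE)
  }
  rows <- rbind(
    data.frame(column = c("id", "rdi", "bmi"),
               type = c("character", "numeric", "numeric"),
               required = TRUE, levels = "", stringsAsFactors = FALSE),
    enum_row("study_type", c("laboratory", "home"), required = FALSE),
    enum_row("hdp", c("yes", "no"), required = FALSE)
  )
  for (rater in c("mother", "partner")) {
    for (nm in names(bq_levels)) {
      rows <- rbind(rows, enum_row(paste0(rater, "_", nm), bq_levels[[nm]],
                                   required = (rater == "mother")))
    }
  }
  attr(rows, "version") <- "cohort-schema/1"
  rows
}

#' Write a cohort table to CSV
#'
#' Plain comma-separated text with a header row; missing values are empty
#' fields. Inverse of [read_cohort].
#'
#' @param cohort Cohort `data.frame` (see [cohort_schema]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read and validate a cohort table
#'
#' Reads a delimited cohort file against [cohort_schema]. Mandatory columns
#' must be present (schema error otherwise); unknown columns are preserved
#' but ignored by the analysis. Per-row problems — an unparseable RDI, an
#' ordinal token outside its level set — do not abort the load: the offending
#' cell becomes `NA` and the problem is recorded, with its row number, in the
#' `"row_issues"` attribute of the result.
#'
#' @param path CSV file path.
#' @return Validated cohort `data.frame` with attribute `row_issues`
#'   (data.frame of `row`, `column`, `problem`; zero rows when clean).
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) {
    stop_sdb("cohort file not found: ", path, class = "sdbscreen_io_error")
  }
  raw <- utils::read.csv(path, colClasses = "character",
                         stringsAsFactors = FALSE, na.strings = c("", "NA"))
  validate_cohort(raw)
}

#' Validate an in-memory cohort table against the schema
#'
#' @param cohort `data.frame` of character/numeric columns.
#' @return The coerced, validated cohort with attribute `row_issues`.
#' @export
validate_cohort <- function(cohort) {
  schema <- cohort_schema()
  required <- schema$column[schema$required]
  missing_cols <- setdiff(required, names(cohort))
  if (length(missing_cols) > 0) {
    stop_sdb("missing mandatory column(s): ", paste(missing_cols, collapse = ", "),
             class = "sdbscreen_schema_error")
  }
  issues <- list()
  note <- function(row, col, problem) {
    issues[[length(issues) + 1L]] <<- data.frame(row = row, column = col,
                                                 problem = problem,
                                                 stringsAsFactors = FALSE)
  }
  if (anyDuplicated(cohort$id)) {
    stop_sdb("participant ids must be unique", class = "sdbscreen_schema_error")
  }
  for (i in seq_len(nrow(schema))) {
    col <- schema$column[i]
    if (!col %in% names(cohort)) next
    if (schema$type[i] == "numeric") {
      val <- suppressWarnings(as.numeric(cohort[[col]]))
      bad <- which(!is.na(cohort[[col]]) & is.na(val))
      for (r in bad) note(r, col, "unparseable number")
      if (col == "rdi") {
        neg <- which(!is.na(val) & val < 0)
        for (r in neg) note(r, col, "negative rdi")
        val[val < 0] <- NA_real_
      }
      cohort[[col]] <- val
    } else if (schema$type[i] == "enum") {
      allowed <- strsplit(schema$levels[i], ",", fixed = TRUE)[[1]]
      bad <- which(!is.na(cohort[[col]]) & !(cohort[[col]] %in% allowed))
      for (r in bad) note(r, col, paste0("invalid level '", cohort[[col]][bad[match(r, bad)]], "'"))
      cohort[[col]][bad] <- NA_character_
    }
  }
  attr(cohort, "row_issues") <- if (length(issues) > 0) {
    do.call(rbind, issues)
  } else {
    data.frame(row = integer(), column = character(), problem = character(),
               stringsAsFactors = FALSE)
  }
  cohort
}
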