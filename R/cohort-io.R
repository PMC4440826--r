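cohort_columns <- function() {
  c("subject_id", "group", "stage", "sex", "age", "smoker", marker_names())
}

valid_groups <- function() c("SCLC", "NSCLC", "CONTROL")

check_cohort <- function(data, require_demo = FALSE) {
  need <- c("group", marker_names())
  if (require_demo) need <- cohort_columns()
  missing <- setdiff(need, names(data))
  if (length(missing) > 0) {
    format_error(sprintf("Cohort is missing required column(s): %s.",
                         paste(missing, collapse = ", ")))
  }
  invisible(data)
}

#' Read a cohort from CSV
#'
#' Reads a comma-separated, UTF-8, `.`-decimal cohort file with a mandatory
#' header row. Required columns are `subject_id`, `group`, `stage`, `sex`,
#' `age`, `smoker` and the six markers `ldh`, `crp`, `na`, `cl`, `cea`,
#' `nse`; any further columns are preserved untouched. Validation failures
#' name the offending row and column.
#'
#' @param path Path to a CSV file.
#' @return A cohort tibble.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) format_error(sprintf("No such file: %s.", path))
  data <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(cohort_columns(), names(data))
  if (length(missing) > 0) {
    format_error(sprintf("Cohort file %s is missing required column(s): %s.",
                         path, paste(missing, collapse = ", ")))
  }
  data$group <- toupper(as.character(data$group))
  bad_group <- which(!data$group %in% valid_groups())
  if (length(bad_group) > 0) {
    format_error(sprintf(
      "Unknown group label %s in column 'group', row %d.",
      dQuote(data$group[bad_group[1]]), bad_group[1]))
  }
  for (m in marker_names()) {
    v <- data[[m]]
    if (!is.numeric(v)) {
      suppressWarnings(num <- as.numeric(v))
      bad <- which(is.na(num) & !is.na(v))
      if (length(bad) > 0) {
        format_error(sprintf("Non-numeric marker value in column '%s', row %d.",
                             m, bad[1]))
      }
      data[[m]] <- num
    }
    bad <- which(!is.na(data[[m]]) & (!is.finite(data[[m]]) | data[[m]] <= 0))
    if (length(bad) > 0) {
      format_error(sprintf(
        "Marker values must be strictly positive and finite: column '%s', row %d.",
        m, bad[1]))
    }
  }
  data$stage <- as.character(data$stage)
  data$smoker <- as.logical(data$smoker)
  data
}

#' Write a cohort to CSV
#'
#' Inverse of [read_cohort()]: `write_cohort()` followed by [read_cohort()]
#' returns the same records up to floating-point round-trip. Extra columns
#' are written as-is.
#'
#' @param data A cohort data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(data, path) {
  check_cohort(data, require_demo = TRUE)
  readr::write_csv(data, path, progress = FALSE)
  invisible(path)
}
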