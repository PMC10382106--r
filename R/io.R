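#' Read and validate a scan table
#'
#' Expects a UTF-8 CSV with header columns `subject_id, group, sex,
#' ga_birth_weeks, pma_scan_weeks, postnatal_days, timepoint` followed by
#' regional volume columns in mL. Empty cells are missing volumes (never
#' zero). Row-level validation enforces known sex codes, the 37-week PMA
#' floor and 46-week ceiling of the supported scan window, scan-after-birth
#' consistency, and strictly positive volumes where present; violations are
#' reported with their line numbers.
#'
#' @param path CSV file.
#' @return validated scan data.frame.
#' @export
read_scan_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("", "NA"))
  need <- scan_id_cols()
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("scan table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  line <- seq_len(nrow(df)) + 1L  # header is line 1
  problems <- character()
  bad <- !df$sex %in% c("F", "M")
  if (any(bad)) {
    problems <- c(problems, sprintf("line %d: unknown sex code '%s'",
                                    line[bad], df$sex[bad]))
  }
  bad <- !is.na(df$pma_scan_weeks) & df$pma_scan_weeks < 37
  if (any(bad)) {
    problems <- c(problems, sprintf(
      "line %d: pma_scan_weeks %.2f below the 37-week scan floor",
      line[bad], df$pma_scan_weeks[bad]))
  }
  bad <- !is.na(df$pma_scan_weeks) & df$pma_scan_weeks > 46
  if (any(bad)) {
    problems <- c(problems, sprintf(
      "line %d: pma_scan_weeks %.2f above the 46-week scan ceiling",
      line[bad], df$pma_scan_weeks[bad]))
  }
  bad <- !is.na(df$pma_scan_weeks) & !is.na(df$ga_birth_weeks) &
    df$pma_scan_weeks < df$ga_birth_weeks
  if (any(bad)) {
    problems <- c(problems,
                  sprintf("line %d: scan PMA precedes gestational age at birth",
                          line[bad]))
  }
  vol_cols <- setdiff(names(df), need)
  for (v in vol_cols) {
    bad <- !is.na(df[[v]]) & df[[v]] <= 0
    if (any(bad)) {
      problems <- c(problems, sprintf("line %d: non-positive volume in '%s'",
                                      line[bad], v))
    }
  }
  if (length(problems)) {
    stop("scan-table validation failed:\n  ",
         paste(problems, collapse = "\n  "), call. = FALSE)
  }
  df
}

#' Write a scan or covariate table as CSV
#'
#' UTF-8, "." decimal separator, empty string for missing values — the
#' round-trip through [read_scan_table()] / [read_covariate_table()] is
#' lossless, including missingness.
#'
#' @param df data.frame.
#' @param path output CSV file.
#' @return `path`, invisibly.
#' @export
write_table_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, na = "", quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read and validate a per-subject clinical covariate table
#'
#' CSV keyed by `subject_id` (duplicates are an error). Boolean covariates
#' are 0/1, durations are in their stated units (days or minutes),
#' creatinine in micromol/L, and `chd_category` (if present) is normalised
#' case-insensitively to `streaming`/`left`/`right`. Unknown columns are
#' preserved untouched.
#'
#' @param path CSV file.
#' @return validated covariate data.frame.
#' @export
read_covariate_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("", "NA"))
  if (!"subject_id" %in% names(df)) {
    stop("covariate table must contain subject_id", call. = FALSE)
  }
  dup <- duplicated(df$subject_id)
  if (any(dup)) {
    stop("duplicate subject_id: ",
         paste(unique(df$subject_id[dup]), collapse = ", "), call. = FALSE)
  }
  if ("chd_category" %in% names(df)) {
    norm <- tolower(trimws(df$chd_category))
    ok <- is.na(norm) | norm %in% c("streaming", "left", "right")
    if (!all(ok)) {
      stop("unknown chd_category value(s): ",
           paste(unique(df$chd_category[!ok]), collapse = ", "),
           call. = FALSE)
    }
    df$chd_category <- norm
  }
  for (flag in intersect(c("rrt", "nec", "injury_pre", "injury_post"),
                         names(df))) {
    if (!all(df[[flag]] %in% c(0, 1, NA))) {
      stop("boolean covariate '", flag, "' must be 0/1", call. = FALSE)
    }
  }
  df
}
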