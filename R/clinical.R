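#' Validate and normalise a clinical table
#'
#' Coerces a data frame to the clinical layout used by the package:
#' `patient_id`, overall-survival time in days (`os_time`), event indicator
#' (`os_event`, 0 = censored, 1 = death) and the numeric covariate
#' encodings used for Cox modelling — `age` in years, `gender` (1 = male,
#' 2 = female), `stage` 1-4, `t_stage`, `n_stage`, `m_stage` small
#' integers, `smoking` 0/1. Covariates may be missing (`NA`); survival
#' fields may be `NA` only for patients that are later removed by
#' [exclude_short_followup()].
#'
#' @param df data frame with at least `patient_id`, `os_time`, `os_event`.
#' @return the validated data frame, classed `clinical_table`.
#' @export
clinical_table <- function(df) {
  req <- c("patient_id", "os_time", "os_event")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols)) {
    stopf("clinical table is missing column(s): %s",
          paste(missing_cols, collapse = ", "))
  }
  df$patient_id <- as.character(df$patient_id)
  if (anyDuplicated(df$patient_id)) {
    stopf("duplicated patient_id: %s",
          paste(unique(df$patient_id[duplicated(df$patient_id)]), collapse = ", "))
  }
  for (col in c("os_time", "os_event", "age", "gender", "stage",
                "t_stage", "n_stage", "m_stage", "smoking")) {
    if (col %in% names(df)) df[[col]] <- as.numeric(df[[col]])
  }
  bad <- which(!is.na(df$os_time) & df$os_time <= 0)
  if (length(bad)) {
    stopf("os_time must be > 0 (patient %s)", df$patient_id[bad[1L]])
  }
  bad <- which(!is.na(df$os_event) & !df$os_event %in% c(0, 1))
  if (length(bad)) {
    stopf("os_event must be 0 or 1 (patient %s)", df$patient_id[bad[1L]])
  }
  if ("stage" %in% names(df)) {
    bad <- which(!is.na(df$stage) & !df$stage %in% 1:4)
    if (length(bad)) {
      stopf("stage must be in 1..4 when present (patient %s)", df$patient_id[bad[1L]])
    }
  }
  class(df) <- c("clinical_table", "data.frame")
  df
}

#' Read a clinical table from delimited text
#'
#' @param path TSV or CSV file path (dialect from the extension or `sep`).
#' @param col_map optional named character vector renaming file columns to
#'   package names, e.g. `c(patient_id = "bcr_patient_barcode")`.
#' @param sep field separator; `NULL` auto-detects.
#' @return a `clinical_table`.
#' @export
read_clinical_table <- function(path, col_map = NULL, sep = NULL) {
  sep <- sep %||% if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.delim(path, sep = sep, stringsAsFactors = FALSE,
                          check.names = FALSE)
  if (!is.null(col_map)) {
    for (to in names(col_map)) {
      from <- col_map[[to]]
      if (!from %in% names(df)) stopf("col_map column '%s' not in file", from)
      names(df)[names(df) == from] <- to
    }
  }
  clinical_table(df)
}

#' Write a clinical table to delimited text
#' @param c a `clinical_table`.
#' @param path output path (TSV unless `.csv`).
#' @return `path`, invisibly.
#' @export
write_clinical_table <- function(c, path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::write.table(c, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Encode pathologic stage strings as integers 1-4
#'
#' Maps AJCC-style stage strings (`"Stage I"` .. `"Stage IVB"`, with or
#' without sub-stage letters) to the numeric 1-4 encoding used in the Cox
#' models. Unrecognised or absent values become `NA`.
#'
#' @param x character vector of stage annotations.
#' @return integer vector in 1..4 (or `NA`).
#' @export
encode_stage <- function(x) {
  x <- toupper(trimws(as.character(x)))
  x <- sub("^STAGE\\s*", "", x)
  x <- sub("[AB12]+$", "", x)
  unname(c(I = 1L, II = 2L, III = 3L, IV = 4L)[x])
}

#' Encode gender as the numeric covariate used in the Cox models
#'
#' Male is encoded 1 and female 2; the mapping is recorded here so that
#' hazard-ratio directions for the gender covariate are interpretable.
#'
#' @param x character vector (`"male"`/`"female"`, case-insensitive, or
#'   abbreviations `"m"`/`"f"`).
#' @return integer vector with 1 = male, 2 = female, `NA` otherwise.
#' @export
encode_gender <- function(x) {
  x <- tolower(trimws(as.character(x)))
  out <- rep(NA_integer_, length(x))
  out[x %in% c("male", "m")] <- 1L
  out[x %in% c("female", "f")] <- 2L
  out
}
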