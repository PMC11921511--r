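# Cohort data model: one row = one woman (cross-sectional), CSV I/O.

#' Raw cohort column names, in canonical on-disk order
#'
#' The cohort CSV is comma-separated UTF-8 with a header row and "." as the
#' decimal separator. Missing values are empty strings on disk and `NA` in
#' memory, never silently zero. `amh_below_lod` is optional on input: a value
#' below the assay limit of detection may be encoded either as the raw value
#' itself or as `amh_below_lod = TRUE` with an empty `amh_raw`.
#'
#' @return Character vector of column names.
#' @export
cohort_columns <- function() {
  c("subject_id", "age", "amh_raw", "amh_below_lod", "amh_assay",
    "tt_raw", "shbg", "insulin", "glucose", "bmi",
    "menstrual_answer", "hc_use", "reproductive_surgery", "smoker")
}

#' Columns added by [derive_cohort()]
#' @return Character vector of derived column names.
#' @export
derived_columns <- function() {
  c("amh_ng_ml", "amh_imputed", "amh_pmol_l", "log10_amh",
    "tt_used", "fai", "hyperandrogenemia", "homa_ir", "insulin_resistant",
    "bmi_class", "om_am", "hc_assumed_no")
}

MENSTRUAL_LEVELS <- c("now", "within_1mo", "1_3mo",
                      "3_6mo", "6_9mo", "9_12mo", "none_12mo")
ASSAY_LEVELS <- c("ultrasensitive", "pico")
HC_LEVELS <- c("yes", "no")

#' Construct a cohort table
#'
#' Light S3 wrapper around a data.frame: class `amh_cohort` plus provenance
#' attributes (`provenance` label, generation `seed` for synthetic cohorts,
#' and whether derived columns are present).
#'
#' @param df data.frame with the columns of [cohort_columns()] (derived
#'   columns optional).
#' @param provenance character label describing where the table came from.
#' @param seed integer seed for synthetic cohorts, or `NULL`.
#' @param validate run [validate_cohort()]?
#' @return An `amh_cohort` data.frame.
#' @export
as_amh_cohort <- function(df, provenance = "unspecified", seed = NULL,
                          validate = TRUE) {
  stopifnot(is.data.frame(df))
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (!"amh_below_lod" %in% names(df)) df$amh_below_lod <- FALSE
  df$amh_below_lod[is.na(df$amh_below_lod)] <- FALSE
  missing_cols <- setdiff(cohort_columns(), names(df))
  if (length(missing_cols) > 0L) {
    stop("cohort schema error: missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  rownames(df) <- NULL
  structure(df,
            class = c("amh_cohort", "data.frame"),
            provenance = provenance,
            seed = seed)
}

#' Validate cohort invariants
#'
#' Checks uniqueness of `subject_id`, `age > 0`, `amh_raw >= 0` where present,
#' BMI within the plausible physiological range seen in field data
#' (default 18.0-59.9 kg/m2), and enum values.
#'
#' @param cohort an `amh_cohort` or data.frame.
#' @param bmi_range length-2 numeric plausible BMI bounds.
#' @return Invisibly `TRUE`; errors describe the first violation found.
#' @export
validate_cohort <- function(cohort, bmi_range = c(18.0, 59.9)) {
  df <- as.data.frame(cohort)
  if (anyDuplicated(df$subject_id)) {
    dup <- df$subject_id[duplicated(df$subject_id)][1L]
    stop("cohort validation error: duplicate subject_id '", dup, "'",
         call. = FALSE)
  }
  if (nrow(df) == 0L) return(invisible(TRUE))
  bad_row <- function(ok, what) {
    idx <- which(!ok)
    if (length(idx) > 0L) {
      stop("cohort validation error: ", what, " at row ", idx[1L],
           " (subject_id '", df$subject_id[idx[1L]], "')", call. = FALSE)
    }
  }
  bad_row(is.na(df$age) | df$age > 0, "age must be > 0")
  bad_row(is.na(df$amh_raw) | df$amh_raw >= 0, "amh_raw must be >= 0")
  bad_row(is.na(df$bmi) |
            (df$bmi >= bmi_range[1L] & df$bmi <= bmi_range[2L]),
          sprintf("bmi outside plausible range [%.1f, %.1f]",
                  bmi_range[1L], bmi_range[2L]))
  bad_row(is.na(df$amh_assay) | df$amh_assay %in% ASSAY_LEVELS,
          "unknown amh_assay")
  bad_row(is.na(df$menstrual_answer) |
            df$menstrual_answer %in% MENSTRUAL_LEVELS,
          "unknown menstrual_answer")
  bad_row(is.na(df$hc_use) | df$hc_use %in% HC_LEVELS, "unknown hc_use")
  invisible(TRUE)
}

#' @export
print.amh_cohort <- function(x, ...) {
  derived <- all(derived_columns() %in% names(x))
  cat(sprintf("amh_cohort: %d women (%s)%s\n", nrow(x),
              attr(x, "provenance") %||% "unspecified",
              if (derived) ", derived" else ", raw"))
  if (!is.null(attr(x, "seed"))) cat("  seed:", attr(x, "seed"), "\n")
  NextMethod()
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.numeric_cols <- c("age", "amh_raw", "tt_raw", "shbg", "insulin", "glucose",
                   "bmi", "amh_ng_ml", "amh_pmol_l", "log10_amh", "tt_used",
                   "fai", "homa_ir")
.logical_cols <- c("amh_below_lod", "reproductive_surgery", "smoker",
                   "amh_imputed", "hyperandrogenemia", "insulin_resistant",
                   "om_am", "hc_assumed_no")

#' Read a cohort CSV
#'
#' Parses the cohort schema with explicit type checking: empty cells become
#' `NA`, malformed numerics are reported with their row index, missing
#' required columns raise a schema error naming the column, and duplicated
#' subject ids raise a validation error.
#'
#' @param path file path to a cohort CSV.
#' @param schema optional named character vector mapping canonical column
#'   names to the names used in the file, e.g. `c(age = "AgeYears")`.
#' @return An `amh_cohort`.
#' @export
read_cohort <- function(path, schema = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, na.strings = NULL)
  if (!is.null(schema)) {
    for (canon in names(schema)) {
      if (schema[[canon]] %in% names(raw)) {
        names(raw)[names(raw) == schema[[canon]]] <- canon
      }
    }
  }
  required <- setdiff(cohort_columns(), "amh_below_lod")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0L) {
    stop("cohort schema error: missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  keep <- intersect(c(cohort_columns(), derived_columns()), names(raw))
  df <- raw[, keep, drop = FALSE]
  df[df == ""] <- NA
  parse_num <- function(col) {
    v <- df[[col]]
    out <- suppressWarnings(as.numeric(v))
    bad <- which(!is.na(v) & is.na(out))
    if (length(bad) > 0L) {
      stop(sprintf("malformed numeric in column '%s' at row %d: '%s'",
                   col, bad[1L], v[bad[1L]]), call. = FALSE)
    }
    out
  }
  parse_lgl <- function(col) {
    v <- toupper(trimws(df[[col]]))
    out <- rep(NA, length(v))
    out[v %in% c("TRUE", "T", "1")] <- TRUE
    out[v %in% c("FALSE", "F", "0")] <- FALSE
    bad <- which(!is.na(v) & is.na(out))
    if (length(bad) > 0L) {
      stop(sprintf("malformed logical in column '%s' at row %d: '%s'",
                   col, bad[1L], df[[col]][bad[1L]]), call. = FALSE)
    }
    as.logical(out)
  }
  for (col in intersect(.numeric_cols, names(df))) df[[col]] <- parse_num(col)
  for (col in intersect(.logical_cols, names(df))) df[[col]] <- parse_lgl(col)
  cohort <- as_amh_cohort(df, provenance = paste0("file:", path),
                          validate = FALSE)
  validate_cohort(cohort)
  cohort
}

#' Write a cohort CSV
#'
#' Columns are written in the canonical order ([cohort_columns()] followed by
#' any derived columns present); missing values are empty strings. Numerics
#' are printed with 17 significant digits so that a write/read round trip
#' reproduces them bit-for-bit.
#'
#' @param cohort an `amh_cohort`.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_cohort <- function(cohort, path) {
  df <- as.data.frame(cohort)
  order_cols <- c(cohort_columns(),
                  intersect(derived_columns(), names(df)))
  df <- df[, order_cols, drop = FALSE]
  for (col in names(df)) {
    v <- df[[col]]
    out <- if (is.numeric(v)) {
      vapply(v, function(x) {
        if (is.na(x)) "" else sprintf("%.17g", x)
      }, character(1L))
    } else if (is.logical(v)) {
      ifelse(is.na(v), "", ifelse(v, "TRUE", "FALSE"))
    } else {
      ifelse(is.na(v), "", as.character(v))
    }
    df[[col]] <- out
  }
  ok <- tryCatch({
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("cannot write cohort to '", path, "': ",
                        conditionMessage(ok), call. = FALSE)
  invisible(path)
}
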