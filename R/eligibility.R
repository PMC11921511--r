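# Inclusion/exclusion pipeline with an auditable exclusion ledger.

#' Apply study eligibility criteria
#'
#' Retains women with age inside `age_range` (half-open, `[lower, upper)` by
#' default), no history of reproductive surgery, no hormonal-contraceptive
#' use (after the missing-to-"no" imputation), and complete AMH (after
#' censoring substitution), total testosterone, SHBG, insulin, glucose and
#' menstrual-cycle data. Membership in the retained set is precedence-free;
#' the per-subject *reported* exclusion reason is the first hit in the order
#' age, surgery, hormonal contraceptive, missing measures.
#'
#' @param cohort a derived `amh_cohort` (see [derive_cohort()]).
#' @param age_range numeric length 2; eligible ages in years.
#' @param include_upper treat the upper age bound as inclusive?
#' @return A list with `cohort` (the retained `amh_cohort`) and `ledger`
#'   (an `amh_exclusions` object).
#' @export
apply_eligibility <- function(cohort, age_range = c(25, 51),
                              include_upper = FALSE) {
  if (!is_derived(cohort)) {
    stop("apply_eligibility requires a derived cohort; run derive_cohort()",
         call. = FALSE)
  }
  df <- as.data.frame(cohort)
  age_ok <- !is.na(df$age) & df$age >= age_range[1L] &
    (if (include_upper) df$age <= age_range[2L] else df$age < age_range[2L])
  surgery <- df$reproductive_surgery %in% TRUE
  hc <- df$hc_use %in% "yes"
  missing_measures <- is.na(df$amh_ng_ml) | is.na(df$tt_raw) |
    is.na(df$shbg) | is.na(df$insulin) | is.na(df$glucose) |
    is.na(df$menstrual_answer)
  keep <- age_ok & !surgery & !hc & !missing_measures

  reason <- rep(NA_character_, nrow(df))
  reason[missing_measures] <- "missing_measures"
  reason[hc] <- "hormonal_contraceptive"
  reason[surgery] <- "reproductive_surgery"
  reason[!age_ok] <- "age_out_of_range"
  reason[keep] <- NA_character_

  reasons <- c("age_out_of_range", "reproductive_surgery",
               "hormonal_contraceptive", "missing_measures")
  counts <- vapply(reasons, function(r) sum(reason %in% r, na.rm = TRUE),
                   integer(1L))
  ledger <- structure(
    list(counts = counts,
         subjects = data.frame(subject_id = df$subject_id[!keep],
                               reason = reason[!keep],
                               stringsAsFactors = FALSE),
         n_in = nrow(df), n_out = sum(keep)),
    class = "amh_exclusions")
  retained <- as_amh_cohort(df[keep, , drop = FALSE],
                            provenance = attr(cohort, "provenance") %||%
                              "unspecified",
                            seed = attr(cohort, "seed"), validate = FALSE)
  list(cohort = retained, ledger = ledger)
}

#' @export
print.amh_exclusions <- function(x, ...) {
  cat(sprintf("eligibility: %d in, %d retained, %d excluded\n",
              x$n_in, x$n_out, x$n_in - x$n_out))
  for (r in names(x$counts)) {
    cat(sprintf("  %-24s %d\n", r, x$counts[[r]]))
  }
  invisible(x)
}

#' Serialize an exclusion ledger to JSON
#'
#' @param ledger an `amh_exclusions` object.
#' @param path optional file to write; when `NULL` the JSON string is
#'   returned.
#' @return JSON string (invisibly when written to file).
#' @export
exclusions_json <- function(ledger, path = NULL) {
  obj <- list(n_in = ledger$n_in, n_out = ledger$n_out,
              counts = as.list(ledger$counts))
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
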