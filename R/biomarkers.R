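# Deterministic biomarker derivation: SI conversion, limit-of-detection
# substitution, free androgen index, HOMA-IR, category flags.

#' Limit-of-detection policy
#'
#' Assay-specific AMH limits of detection and the substitution constants for
#' left-censored values. The ultrasensitive ELISA has an LoD of 0.08 ng/mL;
#' the picoAMH ELISA is more sensitive with an LoD of 0.006 ng/mL. Values
#' below the LoD are substituted with 0.005 ng/mL, the next theoretically
#' measurable value below the pico LoD. Total testosterone below its LoD
#' (20, in the assay's reporting unit) is substituted with 19.
#'
#' Note the substitution constant 0.005 sits below the pico LoD but far below
#' the ultrasensitive LoD, so an ultrasensitive value in (0.005, 0.08) is
#' replaced by a smaller number; the blanket rule is applied as stated.
#'
#' @param assay_lod named numeric, ng/mL per assay.
#' @param imputation_value ng/mL substituted for censored AMH.
#' @param tt_lod,tt_imputation total-testosterone LoD and substitute.
#' @return A list of class `lod_policy`.
#' @export
lod_policy <- function(assay_lod = c(ultrasensitive = 0.08, pico = 0.006),
                       imputation_value = 0.005,
                       tt_lod = 20, tt_imputation = 19) {
  stopifnot(all(c("ultrasensitive", "pico") %in% names(assay_lod)),
            imputation_value > 0, imputation_value < assay_lod[["pico"]],
            tt_lod > 0, tt_imputation > 0)
  structure(list(assay_lod = assay_lod, imputation_value = imputation_value,
                 tt_lod = tt_lod, tt_imputation = tt_imputation),
            class = "lod_policy")
}

#' Classification cutoffs
#'
#' Thresholds used for category flags: hyperandrogenemia is FAI > 8.5;
#' insulin resistance is HOMA-IR > 3.80; Polynesian body-composition BMI
#' classes are overweight 26-32 kg/m2 (inclusive both ends) and obese
#' > 32 kg/m2; AMH converts to SI units at 7.14 pmol/L per ng/mL.
#' All comparisons against these cutoffs are strict (">").
#'
#' @param fai_hyperandrogenemia FAI cutoff.
#' @param homa_ir_insulin_resistance HOMA-IR cutoff.
#' @param bmi_overweight_low,bmi_obese_low BMI class boundaries (kg/m2).
#' @param amh_si_factor pmol/L per ng/mL.
#' @return A list of class `amh_cutoffs`.
#' @export
amh_cutoffs <- function(fai_hyperandrogenemia = 8.5,
                        homa_ir_insulin_resistance = 3.80,
                        bmi_overweight_low = 26, bmi_obese_low = 32,
                        amh_si_factor = 7.14) {
  stopifnot(bmi_overweight_low < bmi_obese_low, amh_si_factor > 0)
  structure(list(fai_hyperandrogenemia = fai_hyperandrogenemia,
                 homa_ir_insulin_resistance = homa_ir_insulin_resistance,
                 bmi_overweight_low = bmi_overweight_low,
                 bmi_obese_low = bmi_obese_low,
                 amh_si_factor = amh_si_factor),
            class = "amh_cutoffs")
}

#' Convert AMH from ng/mL to pmol/L
#'
#' @param value numeric vector, ng/mL, non-negative.
#' @param factor conversion factor (pmol/L per ng/mL).
#' @return numeric vector in pmol/L.
#' @examples
#' convert_amh_to_si(1.0)    # 7.14
#' convert_amh_to_si(0.005)  # 0.0357, i.e. 0.036 at 3 decimals
#' @export
convert_amh_to_si <- function(value, factor = 7.14) {
  if (any(!is.na(value) & value < 0)) {
    stop("AMH must be non-negative (ng/mL)", call. = FALSE)
  }
  value * factor
}

#' Substitute left-censored AMH values
#'
#' A value is censored when it lies below its assay's limit of detection, or
#' when the explicit below-LoD flag is set (a lab may report "< LoD" with no
#' numeric value). Censored values are replaced with the policy's
#' substitution constant. Genuinely missing values (NA without the flag)
#' stay missing.
#'
#' @param value numeric vector, ng/mL (NA allowed).
#' @param assay character vector, `"ultrasensitive"` or `"pico"`.
#' @param policy a [lod_policy()].
#' @param below_lod optional logical vector: explicit censoring flag.
#' @return A data.frame with columns `amh_ng_ml` and `amh_imputed`.
#' @export
impute_amh <- function(value, assay, policy = lod_policy(),
                       below_lod = NULL) {
  n <- max(length(value), length(assay))
  value <- rep_len(value, n)
  assay <- rep_len(assay, n)
  if (is.null(below_lod)) below_lod <- rep(FALSE, n)
  below_lod <- rep_len(below_lod, n)
  below_lod[is.na(below_lod)] <- FALSE
  unknown <- !is.na(assay) & !(assay %in% names(policy$assay_lod))
  if (any(unknown)) {
    stop("unknown AMH assay: ", assay[which(unknown)[1L]], call. = FALSE)
  }
  lod <- unname(policy$assay_lod[assay])
  censored <- below_lod | (!is.na(value) & !is.na(lod) & value < lod)
  out <- value
  out[censored] <- policy$imputation_value
  data.frame(amh_ng_ml = out, amh_imputed = censored)
}

#' Substitute left-censored total testosterone
#'
#' @param tt numeric vector in the assay's reporting unit.
#' @param policy a [lod_policy()].
#' @return numeric vector with censored values replaced.
#' @export
impute_tt <- function(tt, policy = lod_policy()) {
  ifelse(!is.na(tt) & tt < policy$tt_lod, policy$tt_imputation, tt)
}

#' Free androgen index
#'
#' FAI = 100 x total testosterone / SHBG, a proxy for bioavailable androgen.
#' Total testosterone below its LoD is first substituted via [impute_tt()].
#' Missing or non-positive SHBG gives a missing FAI (the record is later
#' excluded by eligibility), not an error.
#'
#' @param tt total testosterone (assay reporting unit).
#' @param shbg sex hormone binding globulin, nmol/L.
#' @param policy a [lod_policy()].
#' @return numeric FAI vector.
#' @export
compute_fai <- function(tt, shbg, policy = lod_policy()) {
  tt_used <- impute_tt(tt, policy)
  fai <- tt_used * 100 / shbg
  fai[is.na(shbg) | shbg <= 0] <- NA_real_
  fai
}

#' HOMA-IR
#'
#' Homeostatic model assessment of insulin resistance:
#' fasting insulin (uU/mL) x fasting glucose (mg/dL) / 405.
#' Missing inputs give a missing result.
#'
#' @param insulin fasting insulin, uU/mL.
#' @param glucose fasting glucose, mg/dL.
#' @return numeric HOMA-IR vector.
#' @export
compute_homa_ir <- function(insulin, glucose) {
  if (any(!is.na(insulin) & insulin <= 0) ||
      any(!is.na(glucose) & glucose <= 0)) {
    stop("insulin and glucose must be positive", call. = FALSE)
  }
  insulin * glucose / 405
}

#' Polynesian BMI classification
#'
#' Body-composition-defined classes: normal/underweight (< 26 kg/m2,
#' collapsed), overweight (26 <= BMI <= 32), obese (> 32). The boundaries
#' differ from WHO cutoffs.
#'
#' @param bmi numeric, kg/m2.
#' @param cutoffs an [amh_cutoffs()].
#' @return factor with levels normal_or_under, overweight, obese.
#' @export
classify_bmi <- function(bmi, cutoffs = amh_cutoffs()) {
  if (any(!is.na(bmi) & bmi <= 0)) stop("bmi must be positive", call. = FALSE)
  out <- ifelse(is.na(bmi), NA_character_,
         ifelse(bmi < cutoffs$bmi_overweight_low, "normal_or_under",
         ifelse(bmi <= cutoffs$bmi_obese_low, "overweight", "obese")))
  factor(out, levels = c("normal_or_under", "overweight", "obese"))
}

#' Menstrual-cycle classification
#'
#' Normal cycles: last period within the last 3 months (answers `now`,
#' `within_1mo`, `1_3mo`). Oligomenorrhea: last period 3-12 months ago
#' (`3_6mo`, `6_9mo`, `9_12mo`). Amenorrhea: no period in 12 months
#' (`none_12mo`). OM and AM are collapsed into one irregular-cycle flag.
#'
#' @param answer character vector of questionnaire answers.
#' @return logical `om_am` vector (NA when the answer is missing).
#' @export
classify_menstrual <- function(answer) {
  bad <- !is.na(answer) & !(answer %in% MENSTRUAL_LEVELS)
  if (any(bad)) {
    stop("unknown menstrual answer: ", answer[which(bad)[1L]], call. = FALSE)
  }
  ifelse(is.na(answer), NA,
         answer %in% c("3_6mo", "6_9mo", "9_12mo", "none_12mo"))
}

#' Impute missing hormonal-contraceptive use
#'
#' Because HC use is uncommon in the source population, a missing answer is
#' assumed to mean "no", with a flag recording the assumption.
#'
#' @param hc_use character vector: `"yes"`, `"no"`, or NA.
#' @return data.frame with columns `hc_use` and `hc_assumed_no`.
#' @export
impute_hc <- function(hc_use) {
  assumed <- is.na(hc_use)
  out <- hc_use
  out[assumed] <- "no"
  data.frame(hc_use = out, hc_assumed_no = assumed)
}

#' Derive all analysis variables
#'
#' Recomputes every derived column from the raw columns: AMH censoring
#' substitution and SI conversion, log10 AMH (substituted values
#' participate: log10(0.0357) is about -1.447), total-testosterone
#' substitution, FAI and the hyperandrogenemia flag (FAI > 8.5), HOMA-IR and
#' the insulin-resistance flag (> 3.80), BMI class, the collapsed OM/AM
#' flag, and HC imputation. Always recomputed from raw columns, so the
#' operation is idempotent and never drops rows.
#'
#' @param cohort an `amh_cohort` (raw or already derived).
#' @param cutoffs an [amh_cutoffs()].
#' @param policy a [lod_policy()].
#' @return A derived `amh_cohort` with the columns of [derived_columns()].
#' @export
derive_cohort <- function(cohort, cutoffs = amh_cutoffs(),
                          policy = lod_policy()) {
  df <- as.data.frame(cohort)
  amh <- impute_amh(df$amh_raw, df$amh_assay, policy, df$amh_below_lod)
  df$amh_ng_ml <- amh$amh_ng_ml
  df$amh_imputed <- amh$amh_imputed
  df$amh_pmol_l <- convert_amh_to_si(df$amh_ng_ml, cutoffs$amh_si_factor)
  df$log10_amh <- ifelse(is.na(df$amh_pmol_l) | df$amh_pmol_l <= 0,
                         NA_real_, log10(df$amh_pmol_l))
  df$tt_used <- impute_tt(df$tt_raw, policy)
  df$fai <- compute_fai(df$tt_raw, df$shbg, policy)
  df$hyperandrogenemia <- df$fai > cutoffs$fai_hyperandrogenemia
  df$homa_ir <- compute_homa_ir(df$insulin, df$glucose)
  df$insulin_resistant <- df$homa_ir > cutoffs$homa_ir_insulin_resistance
  df$bmi_class <- classify_bmi(df$bmi, cutoffs)
  df$om_am <- classify_menstrual(df$menstrual_answer)
  hc <- impute_hc(df$hc_use)
  # hc_use is overwritten in place, so keep the assumption flag sticky to
  # preserve idempotence of derivation
  prior_assumed <- if ("hc_assumed_no" %in% names(df)) {
    df$hc_assumed_no %in% TRUE
  } else {
    FALSE
  }
  df$hc_use <- hc$hc_use
  df$hc_assumed_no <- hc$hc_assumed_no | prior_assumed
  as_amh_cohort(df, provenance = attr(cohort, "provenance") %||% "unspecified",
                seed = attr(cohort, "seed"), validate = FALSE)
}

is_derived <- function(cohort) all(derived_columns() %in% names(cohort))
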