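# Two-of-three PCOS classification and prevalence estimation.

#' Two-of-three PCOS rule
#'
#' A woman is classified as suspected PCOS when at least two of the three
#' criteria hold: irregular menstrual cycles (OM/AM), hyperandrogenemia
#' (FAI above its cutoff), and AMH above the chosen reference percentile.
#' The rule is symmetric in its arguments. Unresolved (NA) flags are an
#' error: classification requires complete criteria.
#'
#' @param om_am,hyperandrogenemia,high_amh logical vectors.
#' @return logical vector.
#' @export
classify_pcos <- function(om_am, hyperandrogenemia, high_amh) {
  n <- max(length(om_am), length(hyperandrogenemia), length(high_amh))
  flags <- cbind(rep_len(om_am, n), rep_len(hyperandrogenemia, n),
                 rep_len(high_amh, n))
  if (anyNA(flags)) {
    stop("all three PCOS criteria must be resolved (no NA) at row ",
         which(rowSums(is.na(flags)) > 0)[1L], call. = FALSE)
  }
  rowSums(flags) >= 2L
}

#' PCOS prevalence at a reference AMH threshold
#'
#' Applies the two-of-three rule to a derived cohort. The AMH threshold is
#' taken from a reference range computed on the cohort's own
#' normal-FAI/regular-cycle subpopulation (the internal-reference mode
#' mirroring the source analysis), or can be fixed via `threshold` for
#' cross-cohort application of published values.
#'
#' An optional Wilson score interval for the prevalence is reported as a
#' package extension (the source analysis prints no interval).
#'
#' @param cohort a derived `amh_cohort`.
#' @param range an [amh_reference_range()]; computed from `cohort` when
#'   `NULL` and no fixed `threshold` is given.
#' @param prob which reference percentile to use (must be among the range's
#'   probs), typically 0.90 or 0.95.
#' @param threshold optional fixed AMH threshold in pmol/L (overrides
#'   `range`).
#' @param conf_level confidence level for the Wilson interval.
#' @return An object of class `amh_pcos`: per-subject criterion flags, the
#'   positive count, prevalence in percent, and the threshold used.
#' @export
pcos_prevalence <- function(cohort, range = NULL, prob = 0.90,
                            threshold = NULL, conf_level = 0.95) {
  if (!is_derived(cohort)) {
    stop("pcos_prevalence requires a derived cohort", call. = FALSE)
  }
  if (is.null(threshold)) {
    if (is.null(range)) range <- amh_reference_range(cohort)
    i <- match(prob, range$probs)
    if (is.na(i)) {
      stop("prob ", prob, " not among the reference range's probabilities",
           call. = FALSE)
    }
    threshold <- range$thresholds[[i]]
  }
  flags <- data.frame(
    subject_id = cohort$subject_id,
    om_am = cohort$om_am,
    hyperandrogenemia = cohort$hyperandrogenemia,
    high_amh = cohort$amh_pmol_l > threshold)
  pcos <- classify_pcos(flags$om_am, flags$hyperandrogenemia,
                        flags$high_amh)
  flags$pcos <- pcos
  n <- nrow(flags)
  n_positive <- sum(pcos)
  structure(list(
    flags = flags,
    n = n,
    n_positive = n_positive,
    prevalence = 100 * n_positive / n,
    threshold_prob = prob,
    threshold = threshold,
    wilson_ci = wilson_interval(n_positive, n, conf_level),
    conf_level = conf_level),
    class = "amh_pcos")
}

# Wilson score interval on a proportion (package extension; returned in
# percent to match the prevalence scale)
wilson_interval <- function(k, n, conf_level = 0.95) {
  if (n == 0L) return(c(lower = NA_real_, upper = NA_real_))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  p <- k / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  100 * c(lower = max(0, centre - half), upper = min(1, centre + half))
}

#' @export
print.amh_pcos <- function(x, ...) {
  cat(sprintf(
    "PCOS (two-of-three rule, AMH > %.2f pmol/L = %gth percentile)\n",
    x$threshold, x$threshold_prob * 100))
  cat(sprintf("  %d of %d positive: prevalence %.1f%%\n",
              x$n_positive, x$n, x$prevalence))
  cat(sprintf("  Wilson %g%% CI (extension): %.1f%% - %.1f%%\n",
              x$conf_level * 100, x$wilson_ci[["lower"]],
              x$wilson_ci[["upper"]]))
  invisible(x)
}
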