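# Polynomial models of the log10 AMH age trajectory, fitted by OLS with the
# model chosen by adjusted R-squared; stratified and sensitivity refits.

#' Fit a polynomial age trajectory for log10 AMH
#'
#' Ordinary least squares of log10 AMH (pmol/L) on age, age^2, ..., up to
#' `degree` (1-3, as in the analysis the package implements; higher degrees
#' are rejected). Age is centered internally before polynomial expansion for
#' numerical conditioning (raw age^3 reaches ~1.3e5), and coefficients are
#' reported back on the raw-age scale. The interpretation is strictly
#' cross-sectional.
#'
#' @param cohort a derived `amh_cohort` with `log10_amh` and `age`.
#' @param degree polynomial degree, 1 to 3.
#' @param stratum optional label recorded in the fit.
#' @return An object of class `amh_trajfit` with raw-scale `coefficients`,
#'   `r2`, `adj_r2`, `n`, `degree`, the underlying `lm` fit, and metadata.
#' @examples
#' cohort <- derive_cohort(generate_cohort(generator_config(seed = 42)))
#' fit <- fit_amh_trajectory(cohort, degree = 1)
#' coef(fit)
#' @export
fit_amh_trajectory <- function(cohort, degree = 1L, stratum = NULL) {
  degree <- as.integer(degree)
  if (degree < 1L || degree > 3L) {
    stop("degree must be 1, 2 or 3", call. = FALSE)
  }
  df <- as.data.frame(cohort)
  keep <- !is.na(df$age) & !is.na(df$log10_amh)
  df <- df[keep, , drop = FALSE]
  n <- nrow(df)
  if (n <= degree + 1L) {
    stop("need more than degree + 1 observations to fit", call. = FALSE)
  }
  if (stats::sd(df$age) == 0) {
    stop("age is constant; polynomial fit is rank-deficient", call. = FALSE)
  }
  center <- mean(df$age)
  a <- df$age - center
  X <- stats::poly(a, degree = degree, raw = TRUE)
  colnames(X) <- paste0("a", seq_len(degree))
  dat <- data.frame(log10_amh = df$log10_amh, X)
  fit <- stats::lm(log10_amh ~ ., data = dat)
  # summary.lm warns on exact interpolation; R2 extraction is still valid
  sm <- suppressWarnings(summary(fit))
  coefficients <- uncenter_poly(stats::coef(fit), center)
  names(coefficients) <- c("(Intercept)",
                           paste0("age", c("", "^2", "^3")[seq_len(degree)]))
  structure(list(
    coefficients = coefficients,
    degree = degree,
    r2 = sm$r.squared,
    adj_r2 = sm$adj.r.squared,
    n = n,
    center = center,
    included_imputed = if ("amh_imputed" %in% names(df)) any(df$amh_imputed)
                       else NA,
    stratum = stratum,
    lm = fit,
    call = match.call()),
    class = "amh_trajfit")
}

# polynomial in (age - c) -> polynomial in age via binomial expansion
uncenter_poly <- function(b, center) {
  degree <- length(b) - 1L
  out <- numeric(degree + 1L)
  for (k in 0:degree) {
    for (j in 0:k) {
      out[j + 1L] <- out[j + 1L] +
        b[k + 1L] * choose(k, j) * (-center)^(k - j)
    }
  }
  out
}

#' @export
coef.amh_trajfit <- function(object, ...) object$coefficients

#' @export
print.amh_trajfit <- function(x, ...) {
  cat(sprintf("log10 AMH (pmol/L) ~ age polynomial, degree %d%s\n",
              x$degree,
              if (!is.null(x$stratum)) paste0(" [", x$stratum, "]") else ""))
  cat("  coefficients (raw-age scale):\n")
  print(round(x$coefficients, 6))
  cat(sprintf("  n = %d, R2 = %.4f, adjusted R2 = %.4f\n",
              x$n, x$r2, x$adj_r2))
  if (isFALSE(x$included_imputed)) {
    cat("  censoring-substituted AMH values excluded\n")
  }
  invisible(x)
}

#' @export
summary.amh_trajfit <- function(object, ...) {
  structure(list(fit = object, lm_summary = summary(object$lm)),
            class = "summary.amh_trajfit")
}

#' @export
print.summary.amh_trajfit <- function(x, ...) {
  print(x$fit)
  cat("\nCentered-age OLS summary:\n")
  stats::printCoefmat(x$lm_summary$coefficients)
  invisible(x)
}

#' @export
predict.amh_trajfit <- function(object, newdata = NULL, ...) {
  age <- if (is.null(newdata)) {
    object$center + object$lm$model[[2L]]
  } else if (is.numeric(newdata)) {
    newdata
  } else {
    newdata$age
  }
  trajectory_mean(age, object$coefficients)
}

#' @export
residuals.amh_trajfit <- function(object, ...) stats::residuals(object$lm)

#' @export
fitted.amh_trajfit <- function(object, ...) stats::fitted(object$lm)

#' Scatter of log10 AMH against age with the fitted trajectory
#' @param x an `amh_trajfit`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.amh_trajfit <- function(x, ...) {
  age <- x$center + x$lm$model[["a1"]]
  y <- x$lm$model[["log10_amh"]]
  graphics::plot(age, y, xlab = "Age (years)",
                 ylab = "log10 AMH (pmol/L)", pch = 16,
                 col = grDevices::adjustcolor("grey30", 0.5), ...)
  grid_age <- seq(min(age), max(age), length.out = 200L)
  graphics::lines(grid_age, trajectory_mean(grid_age, x$coefficients),
                  lwd = 2, col = "firebrick")
  invisible(x)
}

#' Choose the best model by adjusted R-squared
#'
#' Largest adjusted R2 wins; exact ties go to the lowest degree.
#'
#' @param fits list of `amh_trajfit` objects on the same data.
#' @return The selected `amh_trajfit`.
#' @export
select_best_model <- function(fits) {
  if (length(fits) == 0L) stop("no fits supplied", call. = FALSE)
  adj <- vapply(fits, function(f) f$adj_r2, numeric(1L))
  deg <- vapply(fits, function(f) f$degree, integer(1L))
  best <- which(adj == max(adj))
  fits[[best[which.min(deg[best])]]]
}

#' Fit degrees 1-3 and select the best
#'
#' @inheritParams fit_amh_trajectory
#' @param degrees degrees to fit.
#' @return list with `fits` (one per degree) and `best`.
#' @export
fit_trajectories <- function(cohort, degrees = 1:3) {
  fits <- lapply(degrees, function(d) fit_amh_trajectory(cohort, d))
  list(fits = fits, best = select_best_model(fits))
}

#' Stratified trajectory fits
#'
#' Independent fits per level of a stratifying variable (e.g. `bmi_class`
#' or `om_am`). Strata too small to fit are skipped with a warning.
#'
#' @inheritParams fit_amh_trajectory
#' @param by name of a column in the cohort to stratify on.
#' @return Named list of `amh_trajfit` objects.
#' @export
stratified_fits <- function(cohort, by = "bmi_class", degree = 1L) {
  df <- as.data.frame(cohort)
  if (!by %in% names(df)) stop("no column '", by, "' in cohort",
                               call. = FALSE)
  levels <- unique(stats::na.omit(df[[by]]))
  out <- list()
  for (lev in as.character(sort(levels))) {
    sub <- df[!is.na(df[[by]]) & as.character(df[[by]]) == lev, ,
              drop = FALSE]
    fit <- tryCatch(
      fit_amh_trajectory(sub, degree, stratum = paste0(by, "=", lev)),
      error = function(e) {
        warning("stratum '", lev, "' skipped: ", conditionMessage(e),
                call. = FALSE)
        NULL
      })
    if (!is.null(fit)) out[[lev]] <- fit
  }
  out
}

#' Sensitivity refit excluding censoring-substituted AMH values
#'
#' Refits the age trajectory on the rows whose AMH was measured above the
#' limit of detection. Excluding the substituted (left-censored) values
#' removes the oldest, lowest-AMH observations and therefore attenuates the
#' apparent decline.
#'
#' @inheritParams fit_amh_trajectory
#' @return An `amh_trajfit` with `included_imputed = FALSE`.
#' @export
sensitivity_excluding_imputed <- function(cohort, degree = 1L) {
  df <- as.data.frame(cohort)
  if (!"amh_imputed" %in% names(df)) {
    stop("cohort must be derived (amh_imputed column missing)",
         call. = FALSE)
  }
  sub <- df[!df$amh_imputed, , drop = FALSE]
  if (nrow(sub) == 0L) {
    stop("all AMH values are censoring-substituted; nothing to refit",
         call. = FALSE)
  }
  fit <- fit_amh_trajectory(sub, degree)
  fit$included_imputed <- FALSE
  fit
}
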