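#' Error moments of model predictions
#'
#' Errors are observed minus predicted. Returns the mean and sample
#' (n-1 denominator) standard deviation of the errors and of their
#' absolute values, all in avoidance-index units.
#'
#' @param observed observed AI values.
#' @param predicted predicted AI values, same length (>= 2).
#' @return list with `mean_error`, `std_error`, `mean_abs_error`,
#'   `std_abs_error`.
#' @export
error_stats <- function(observed, predicted) {
  if (length(observed) != length(predicted) || length(observed) < 2L)
    stop("'observed' and 'predicted' must have equal length >= 2",
         call. = FALSE)
  e <- observed - predicted
  list(mean_error = mean(e), std_error = stats::sd(e),
       mean_abs_error = mean(abs(e)), std_abs_error = stats::sd(abs(e)))
}

#' Coefficient of determination
#'
#' `R^2 = 1 - SSE/SST`, with SST taken about the mean of the observations.
#'
#' @param observed observed AI values (not all equal).
#' @param predicted predicted AI values, same length (>= 2).
#' @return scalar R-squared (<= 1; can be negative for fits worse than the
#'   mean).
#' @export
r_squared <- function(observed, predicted) {
  if (length(observed) != length(predicted) || length(observed) < 2L)
    stop("'observed' and 'predicted' must have equal length >= 2",
         call. = FALSE)
  sst <- sum((observed - mean(observed))^2)
  if (sst == 0)
    stop("'observed' must not be constant", call. = FALSE)
  1 - sum((observed - predicted)^2) / sst
}

#' F statistic of the determination coefficient
#'
#' The simple-regression F for testing R^2 against zero:
#' `F = R^2 * (n - 2) / (1 - R^2)` on (1, n - 2) degrees of freedom.
#' A perfect fit (R^2 = 1) returns `Inf`.
#'
#' @param r2 coefficient of determination in `[0, 1]`.
#' @param n number of observation points, >= 3.
#' @return scalar F value.
#' @export
f_statistic <- function(r2, n) {
  if (!is.numeric(r2) || length(r2) != 1L || r2 < 0 || r2 > 1)
    stop("'r2' must be a single value in [0, 1]", call. = FALSE)
  if (n < 3) stop("'n' must be at least 3", call. = FALSE)
  if (r2 == 1) return(Inf)
  r2 * (n - 2) / (1 - r2)
}

#' Upper critical value of the F distribution
#'
#' @param alpha_level upper tail probability in (0, 1).
#' @param df1 numerator degrees of freedom, >= 1.
#' @param df2 denominator degrees of freedom, >= 1.
#' @return the upper `alpha_level` quantile of F(df1, df2).
#' @export
f_critical <- function(alpha_level, df1, df2) {
  if (alpha_level <= 0 || alpha_level >= 1)
    stop("'alpha_level' must be in (0, 1)", call. = FALSE)
  if (df1 < 1 || df2 < 1)
    stop("degrees of freedom must be >= 1", call. = FALSE)
  stats::qf(1 - alpha_level, df1, df2)
}

#' Full goodness-of-fit report
#'
#' Composes the error moments, R-squared and the F test at the given
#' level into one validation report.
#'
#' @param observed observed AI values.
#' @param predicted predicted AI values, same length.
#' @param alpha_level significance level of the F test (default 0.01).
#' @return list of class `fit_validation`: the four error moments plus
#'   `r_squared`, `f_value`, `f_critical`, `passes_f_test`, `n_points`,
#'   `alpha_level`.
#' @export
validate_fit <- function(observed, predicted, alpha_level = 0.01) {
  es <- error_stats(observed, predicted)
  r2 <- r_squared(observed, predicted)
  n <- length(observed)
  fv <- f_statistic(max(r2, 0), n)
  fc <- f_critical(alpha_level, 1, n - 2)
  structure(c(es, list(r_squared = r2, f_value = fv, f_critical = fc,
                       passes_f_test = fv > fc, n_points = n,
                       alpha_level = alpha_level)),
            class = "fit_validation")
}
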