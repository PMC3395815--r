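# Plain-text interchange: comma-separated, UTF-8, no row names.

#' Write a prediction curve to CSV
#'
#' Columns `time_min,intensity_lux,f_raw,ai_capped`.
#'
#' @param predictions data.frame from [predict_series()] or
#'   [predict_intensity_response()].
#' @param path output file.
#' @export
write_predictions <- function(predictions, path) {
  need <- c("time_min", "intensity_lux", "f_raw", "ai_capped")
  if (!all(need %in% names(predictions)))
    stop("predictions must contain columns ",
         paste(need, collapse = ", "), call. = FALSE)
  utils::write.csv(predictions[need], path, row.names = FALSE,
                   quote = FALSE)
}

#' Write plate counts to CSV
#'
#' Columns `time_min,n_dark,n_light`.
#'
#' @param counts data.frame with `time_min`, `n_dark`, `n_light` columns
#'   (e.g. from [simulate_dynamics()]).
#' @param path output file.
#' @export
write_counts <- function(counts, path) {
  need <- c("time_min", "n_dark", "n_light")
  if (!all(need %in% names(counts)))
    stop("counts must contain columns ", paste(need, collapse = ", "),
         call. = FALSE)
  utils::write.csv(counts[need], path, row.names = FALSE, quote = FALSE)
}

#' Read plate counts from CSV
#'
#' Expects columns `time_min,n_dark,n_light`; reports the first malformed
#' line by number.
#'
#' @param path input file.
#' @return data.frame with an added `ai` column from [ai_from_counts()].
#' @export
read_counts <- function(path) {
  df <- utils::read.csv(path)
  need <- c("time_min", "n_dark", "n_light")
  if (!all(need %in% names(df)))
    stop("'", path, "' must have header ", paste(need, collapse = ","),
         call. = FALSE)
  bad <- which(!is.finite(df$time_min) | !is.finite(df$n_dark) |
                 !is.finite(df$n_light) | df$n_dark < 0 | df$n_light < 0 |
                 (df$n_dark + df$n_light) == 0)
  if (length(bad))
    stop("'", path, "': malformed record at data line ", bad[1],
         call. = FALSE)
  df$ai <- ai_from_counts(df$n_dark, df$n_light)
  df
}

#' Write an avoidance-index series to CSV
#'
#' Columns `time_min,ai`.
#'
#' @param series data.frame with `time_min` and `ai` columns.
#' @param path output file.
#' @export
write_ai_series <- function(series, path) {
  need <- c("time_min", "ai")
  if (!all(need %in% names(series)))
    stop("series must contain columns time_min, ai", call. = FALSE)
  utils::write.csv(series[need], path, row.names = FALSE, quote = FALSE)
}

#' Read an avoidance-index series from CSV
#'
#' @param path input file with header `time_min,ai`.
#' @param intensity light intensity (lux) of the assay the series came
#'   from.
#' @return an [ai_dataset()] object.
#' @export
read_ai_series <- function(path, intensity) {
  df <- utils::read.csv(path)
  if (!all(c("time_min", "ai") %in% names(df)))
    stop("'", path, "' must have header time_min,ai", call. = FALSE)
  bad <- which(!is.finite(df$time_min) | !is.finite(df$ai) |
                 df$time_min <= 0 | abs(df$ai) > 1)
  if (length(bad))
    stop("'", path, "': malformed record at data line ", bad[1],
         call. = FALSE)
  ai_dataset(df$time_min, df$ai, intensity)
}

#' Export SCEM sequence traces to CSV
#'
#' One row per retained draw with columns
#' `shuffle,chain,alpha,beta,log_density`.
#'
#' @param result a `scem_result` from [run_scem()] on the two-parameter
#'   utility model.
#' @param path output file.
#' @export
write_chain_trace <- function(result, path) {
  stopifnot(inherits(result, "scem_result"))
  rows <- lapply(seq_along(result$chains), function(k) {
    ch <- as.data.frame(result$chains[[k]])
    data.frame(shuffle = ch$shuffle, chain = k, alpha = ch$par1,
               beta = ch$par2, log_density = ch$log_density)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE,
                   quote = FALSE)
}

#' Write an ISCEM fit report as JSON
#'
#' Parameters, best log density, outer-iteration count, convergence flag,
#' the bound-refinement history, the seed and a configuration echo.
#'
#' @param fit an `iscem_fit` from [run_iscem()].
#' @param path output file.
#' @param seed the seed the fit was run with (recorded verbatim).
#' @param cfg the [iscem_config()] used (recorded verbatim).
#' @export
write_fit_report <- function(fit, path, seed = NULL, cfg = NULL) {
  stopifnot(inherits(fit, "iscem_fit"))
  report <- list(
    parameters = list(alpha = fit$theta[1], beta = fit$theta[2]),
    log_density = fit$log_density,
    converged = fit$converged,
    n_outer_iters = fit$n_outer_iters,
    bound_history = lapply(fit$bound_history, function(b)
      list(lower = b$lower, upper = b$upper)),
    seed = seed
  )
  if (!is.null(cfg))
    report$config <- list(
      epsilon = cfg$epsilon, max_outer_iters = cfg$max_outer_iters,
      initial_bounds = list(lower = cfg$initial_bounds$lower,
                            upper = cfg$initial_bounds$upper),
      scem = unclass(cfg$scem))
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
}

#' Write a validation report as JSON
#'
#' @param validation a `fit_validation` from [validate_fit()].
#' @param path output file.
#' @export
write_validation_report <- function(validation, path) {
  stopifnot(inherits(validation, "fit_validation"))
  jsonlite::write_json(unclass(validation), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
}
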