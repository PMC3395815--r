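#' Parameter bounds (interval vectors)
#'
#' The componentwise box `lower <= theta <= upper` that serves both as the
#' uniform prior support of the sampler and as the interval vectors refined
#' by the ISCEM outer loop.
#'
#' @param lower numeric vector of lower limits.
#' @param upper numeric vector of upper limits, componentwise > `lower`.
#' @return object of class `param_bounds`.
#' @export
param_bounds <- function(lower, upper) {
  if (!is.numeric(lower) || !is.numeric(upper) ||
      length(lower) != length(upper) || length(lower) == 0L)
    stop("'lower' and 'upper' must be numeric vectors of equal length",
         call. = FALSE)
  if (any(!is.finite(lower)) || any(!is.finite(upper)))
    stop("bounds must be finite", call. = FALSE)
  if (any(lower >= upper))
    stop("'lower' must be componentwise below 'upper'", call. = FALSE)
  structure(list(lower = lower, upper = upper), class = "param_bounds")
}

#' Avoidance-index dataset for fitting
#'
#' An observed AI time series at a single light intensity, the unit of
#' observation for parameter estimation.
#'
#' @param times observation times in minutes, strictly increasing, all > 0.
#' @param ai observed avoidance indices in `[-1, 1]`.
#' @param intensity light intensity of the assay in lux.
#' @return object of class `ai_dataset`.
#' @export
ai_dataset <- function(times, ai, intensity) {
  if (length(times) == 0L || length(times) != length(ai))
    stop("'times' and 'ai' must be nonempty and of equal length",
         call. = FALSE)
  if (any(times <= 0) || any(diff(times) <= 0))
    stop("'times' must be positive and strictly increasing", call. = FALSE)
  if (any(abs(ai) > 1))
    stop("'ai' values must lie in [-1, 1]", call. = FALSE)
  if (!is.numeric(intensity) || length(intensity) != 1L || intensity < 0)
    stop("'intensity' must be a single nonnegative number", call. = FALSE)
  structure(list(times = times, ai = ai, intensity = intensity),
            class = "ai_dataset")
}

#' Residuals of the capped model against observed avoidance indices
#'
#' Observed minus predicted, using the capped prediction (the avoidance
#' index is what is observed; values above 1 cannot occur in data).
#'
#' @param u a [utility_params()] object.
#' @param dataset an [ai_dataset()] object.
#' @return numeric residual vector, same length as the dataset.
#' @export
ai_residuals <- function(u, dataset) {
  stopifnot(inherits(dataset, "ai_dataset"))
  pred <- cap_avoidance(utility_raw(u, dataset$intensity, dataset$times))
  dataset$ai - pred
}

# Floor protecting log(SSE) when noiseless data make SSE -> 0.
.sse_floor <- 1e-12

#' Log posterior density of the utility parameters
#'
#' Uniform (box) prior on the bounds times the variance-marginalized
#' Gaussian likelihood, `p(theta | y) \propto SSE(theta)^(-N/2)`, evaluated
#' on the log scale: `-(N/2) * log(max(SSE, 1e-12))` for in-bounds `theta`,
#' `-Inf` outside the box. Monotone decreasing in the sum of squared
#' residuals, so its argmax is the least-squares estimate.
#'
#' @param theta numeric parameter vector `c(alpha, beta)`.
#' @param dataset an [ai_dataset()] object.
#' @param bounds a [param_bounds()] object.
#' @return scalar log density (`-Inf` allowed).
#' @export
log_posterior <- function(theta, dataset, bounds) {
  stopifnot(inherits(bounds, "param_bounds"))
  if (any(!is.finite(theta)) || any(theta < bounds$lower) ||
      any(theta > bounds$upper))
    return(-Inf)
  # alpha or beta exactly 0 can enter via bounds at 0; the model needs > 0
  if (any(theta <= 0)) return(-Inf)
  u <- utility_params(theta[1], theta[2])
  r <- ai_residuals(u, dataset)
  n <- length(r)
  -(n / 2) * log(max(sum(r^2), .sse_floor))
}

#' Build the sampler objective for a dataset
#'
#' Convenience closure: returns `function(theta, bounds)` evaluating
#' [log_posterior()] on the given dataset.
#'
#' @param dataset an [ai_dataset()] object.
#' @return function of `(theta, bounds)`.
#' @export
make_objective <- function(dataset) {
  force(dataset)
  function(theta, bounds) log_posterior(theta, dataset, bounds)
}
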