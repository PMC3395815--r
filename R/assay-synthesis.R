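#' Avoidance index from plate-half counts
#'
#' `AI = (n_dark - n_light) / (n_dark + n_light)`: +1 when all larvae sit in
#' the dark half, -1 when all sit in the light half.
#'
#' @param n_dark larva count in the dark half (nonnegative integer,
#'   vectorized).
#' @param n_light larva count in the light half (nonnegative integer,
#'   vectorized).
#' @return avoidance index value(s) in `[-1, 1]`.
#' @export
ai_from_counts <- function(n_dark, n_light) {
  if (!is.numeric(n_dark) || !is.numeric(n_light) ||
      any(n_dark < 0) || any(n_light < 0) ||
      any(n_dark != round(n_dark)) || any(n_light != round(n_light)))
    stop("counts must be nonnegative integers", call. = FALSE)
  total <- n_dark + n_light
  if (any(total == 0))
    stop("total larva count must be positive", call. = FALSE)
  (n_dark - n_light) / total
}

#' Plate-assay configuration
#'
#' Describes the two-choice phototaxis assay: `n_larvae` animals on an
#' agar plate half-covered from light, counted on each half every
#' `interval` minutes for `duration` minutes under `intensity` lux.
#' Defaults match the standard 11-minute assay with 20 larvae counted
#' every half minute.
#'
#' @param intensity light intensity in lux, >= 0.
#' @param n_larvae number of larvae per plate, >= 1.
#' @param duration assay length in minutes.
#' @param interval counting interval in minutes, > 0.
#' @return object of class `assay_config`.
#' @export
assay_config <- function(intensity, n_larvae = 20, duration = 11,
                         interval = 0.5) {
  if (!is.numeric(intensity) || length(intensity) != 1L || intensity < 0)
    stop("'intensity' must be a single nonnegative number", call. = FALSE)
  if (!is.numeric(n_larvae) || length(n_larvae) != 1L || n_larvae < 1 ||
      n_larvae != round(n_larvae))
    stop("'n_larvae' must be a positive integer", call. = FALSE)
  if (!is.numeric(interval) || length(interval) != 1L || interval <= 0)
    stop("'interval' must be a single positive number", call. = FALSE)
  if (!is.numeric(duration) || length(duration) != 1L || duration < interval)
    stop("'duration' must be at least one interval", call. = FALSE)
  structure(list(intensity = intensity, n_larvae = as.integer(n_larvae),
                 duration = duration, interval = interval),
            class = "assay_config")
}

#' Simulate a two-choice plate assay
#'
#' Generates synthetic avoidance-index dynamics emulating the 11-minute
#' assay in which larvae start in the light half and redistribute toward
#' the dark half. At each grid time `t` (starting at the first counting
#' interval; there is no `t = 0` observation) the dark-half count is drawn
#' `Binomial(n_larvae, p(t))` with `p(t) = (AI_model(t) + 1) / 2`, where
#' `AI_model` is the capped utility curve; the observed AI follows from the
#' counts. Time points are drawn independently: the generator models the
#' counting noise of the assay, not larval persistence between counts.
#' With `noise = FALSE` the returned AI series is exactly the capped model
#' curve (no counts are drawn).
#'
#' @param u a [utility_params()] object.
#' @param config an [assay_config()] object.
#' @param noise draw binomial counting noise? Default `TRUE`.
#' @param seed optional integer seed applied via [set.seed()] for a
#'   reproducible draw; `NULL` uses the current RNG state.
#' @return data.frame with columns `time_min`, `n_dark`, `n_light`, `ai`
#'   (count columns are `NA` in noiseless mode).
#' @export
simulate_dynamics <- function(u, config, noise = TRUE, seed = NULL) {
  stopifnot(inherits(u, "utility_params"), inherits(config, "assay_config"))
  times <- seq(config$interval, config$duration, by = config$interval)
  model_ai <- cap_avoidance(utility_raw(u, config$intensity, times))
  if (!noise) {
    return(data.frame(time_min = times, n_dark = NA_integer_,
                      n_light = NA_integer_, ai = model_ai))
  }
  if (!is.null(seed)) set.seed(seed)
  p_dark <- (model_ai + 1) / 2
  n_dark <- stats::rbinom(length(times), size = config$n_larvae,
                          prob = p_dark)
  n_light <- config$n_larvae - n_dark
  data.frame(time_min = times, n_dark = n_dark, n_light = n_light,
             ai = ai_from_counts(n_dark, n_light))
}

#' Reference intensity-response data and fitted parameters
#'
#' The embedded w1118 third-instar experimental avoidance indices at five
#' light intensities (11-minute assay) together with the fitted utility
#' parameters; these anchor the worked examples, the validation statistics
#' and the parameter-recovery studies.
#'
#' @return list with `intensity_table` (data.frame `intensity_lux`, `ai`)
#'   and `params` (a [utility_params()] object).
#' @export
w1118_reference <- function() {
  list(
    intensity_table = data.frame(
      intensity_lux = c(150, 350, 550, 750, 950),
      ai = c(0.2, 0.4, 0.7, 0.8, 0.9)
    ),
    params = utility_params(alpha = 0.001459, beta = 0.56532)
  )
}
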