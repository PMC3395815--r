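#' Error function
#'
#' The Gauss error function erf(z) = (2/sqrt(pi)) * integral_0^z exp(-c^2) dc,
#' computed exactly from the normal CDF via erf(z) = 2*pnorm(z*sqrt(2)) - 1.
#'
#' @param z numeric vector.
#' @return numeric vector of erf values in (-1, 1).
#' @export
erf <- function(z) 2 * stats::pnorm(z * sqrt(2)) - 1

#' Diffusion source parameters
#'
#' Parameters of the semi-infinite constant-source solution of the diffusion
#' equation (Fick's second law): a source held at concentration `Vs`,
#' a diffusion coefficient `D` (area/time), and a distance `x` from the
#' source at which concentration is observed.
#'
#' @param Vs source concentration, > 0 (arbitrary units).
#' @param D diffusion coefficient, > 0.
#' @param x distance from the source, >= 0.
#' @return object of class `diffusion_params`.
#' @export
diffusion_params <- function(Vs, D, x) {
  if (!is.numeric(Vs) || length(Vs) != 1L || !is.finite(Vs) || Vs <= 0)
    stop("'Vs' must be a single positive number", call. = FALSE)
  if (!is.numeric(D) || length(D) != 1L || !is.finite(D) || D <= 0)
    stop("'D' must be a single positive number", call. = FALSE)
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0)
    stop("'x' must be a single nonnegative number", call. = FALSE)
  structure(list(Vs = Vs, D = D, x = x), class = "diffusion_params")
}

#' Concentration profile of a constant diffusion source
#'
#' Closed-form solution of the diffusion equation for a semi-infinite medium
#' with the boundary held at `Vs`:
#' `V(x, t) = Vs * (1 - erf(x / (2 * sqrt(D * t))))`.
#' At `x = 0` the profile equals `Vs` for any `t > 0`; for `x > 0` it tends
#' to 0 as `t -> 0+` and to `Vs` as `t -> Inf`.
#'
#' @param p a [diffusion_params()] object.
#' @param t time(s), all > 0.
#' @return concentration value(s) in `[0, Vs]`.
#' @export
concentration_profile <- function(p, t) {
  stopifnot(inherits(p, "diffusion_params"))
  if (!is.numeric(t) || length(t) == 0L || any(!is.finite(t)) || any(t <= 0))
    stop("'t' must be positive and finite", call. = FALSE)
  p$Vs * (1 - erf(p$x / (2 * sqrt(p$D * t))))
}

#' Utility-model parameters
#'
#' The two phenomenological constants of the light-avoidance utility model
#' `f(l, t) = alpha * l * (1 - erf(beta / sqrt(t)))`: `alpha` scales the
#' asymptotic avoidance per lux and `beta` (units sqrt(minutes)) sets how
#' quickly the response develops with exposure time.
#'
#' @param alpha avoidance index per lux, > 0.
#' @param beta time-course constant, > 0.
#' @return object of class `utility_params` (named numeric of length 2).
#' @export
utility_params <- function(alpha, beta) {
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) || alpha <= 0)
    stop("'alpha' must be a single positive number", call. = FALSE)
  if (!is.numeric(beta) || length(beta) != 1L || !is.finite(beta) || beta <= 0)
    stop("'beta' must be a single positive number", call. = FALSE)
  structure(c(alpha = unname(alpha), beta = unname(beta)),
            class = "utility_params")
}

#' Raw (uncapped) utility of the light stimulus
#'
#' Evaluates `f = alpha * l * (1 - erf(beta / sqrt(t)))` for light intensity
#' `l` (lux) and exposure time `t` (minutes). The value is nonnegative,
#' proportional to `l`, strictly increasing in `t` for `l > 0`, and tends
#' to `alpha * l` as `t -> Inf`.
#'
#' @param u a [utility_params()] object.
#' @param intensity light intensity in lux, >= 0 (vectorized).
#' @param time exposure time in minutes, > 0 (vectorized).
#' @return raw utility value(s), unitless.
#' @export
utility_raw <- function(u, intensity, time) {
  stopifnot(inherits(u, "utility_params"))
  if (!is.numeric(intensity) || any(!is.finite(intensity)) || any(intensity < 0))
    stop("'intensity' must be nonnegative and finite", call. = FALSE)
  if (!is.numeric(time) || length(time) == 0L || any(!is.finite(time)) ||
      any(time <= 0))
    stop("'time' must be positive and finite", call. = FALSE)
  unname(u["alpha"]) * intensity * (1 - erf(unname(u["beta"]) / sqrt(time)))
}

#' Cap the utility at the avoidance-index ceiling
#'
#' Once all larvae have reached the dark half the avoidance index saturates
#' at 1, so any model value exceeding 1 is set to 1.
#'
#' @param f raw utility value(s), >= 0.
#' @return capped avoidance index value(s) in `[0, 1]`.
#' @export
cap_avoidance <- function(f) {
  if (!is.numeric(f) || any(!is.finite(f)) || any(f < 0))
    stop("'f' must be nonnegative and finite", call. = FALSE)
  pmin(f, 1)
}

#' Predicted avoidance-index time course at one light intensity
#'
#' @param u a [utility_params()] object.
#' @param intensity light intensity in lux, a single value >= 0.
#' @param times strictly increasing time grid (minutes), all > 0.
#' @return data.frame with columns `time_min`, `intensity_lux`, `f_raw`,
#'   `ai_capped`; the capped series is nondecreasing.
#' @export
predict_series <- function(u, intensity, times) {
  if (length(intensity) != 1L)
    stop("'intensity' must be a single value", call. = FALSE)
  if (!is.numeric(times) || length(times) == 0L)
    stop("'times' must be a nonempty numeric vector", call. = FALSE)
  if (any(diff(times) <= 0))
    stop("'times' must be strictly increasing", call. = FALSE)
  f <- utility_raw(u, intensity, times)
  data.frame(time_min = times, intensity_lux = intensity,
             f_raw = f, ai_capped = cap_avoidance(f))
}

#' Predicted avoidance index across light intensities at fixed exposure
#'
#' Evaluates the intensity-response curve at a single exposure time: below
#' the cap the capped value is linear in intensity.
#'
#' @param u a [utility_params()] object.
#' @param intensities light intensities in lux, all >= 0.
#' @param time single exposure time in minutes, > 0.
#' @return data.frame with columns `intensity_lux`, `time_min`, `f_raw`,
#'   `ai_capped`.
#' @export
predict_intensity_response <- function(u, intensities, time) {
  if (length(time) != 1L)
    stop("'time' must be a single value", call. = FALSE)
  f <- utility_raw(u, intensities, time)
  data.frame(intensity_lux = intensities, time_min = time,
             f_raw = f, ai_capped = cap_avoidance(f))
}

#' Round half away from zero
#'
#' Reporting convention for comparison against printed tables: 2-decimal
#' half-up rounding (R's `round()` rounds half to even). Applied only when
#' reporting, never inside the model.
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}
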