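#' Melt-curve acquisition grid
#'
#' The temperature grid on which fluorescence is acquired during the melt
#' ramp. The instrument ramps from 40 to 87 degrees C; at the default
#' resolution each barcode segment is read at 4,076 evenly spaced
#' temperatures, so the two concatenated segments give 8,152 classifier
#' features.
#'
#' @param t_min,t_max Ramp start and end temperature (degrees C).
#' @param n_points Number of acquisition points per segment (>= 16).
#' @return An object of class `acq_grid`: a list with `t_min`, `t_max`,
#'   `n_points`, the `temperature` vector and the grid `step`.
#' @examples
#' g <- acquisition_grid()
#' g$n_points
#' @export
acquisition_grid <- function(t_min = 40, t_max = 87, n_points = 4076L) {
  stopifnot(is.numeric(t_min), is.numeric(t_max), length(t_min) == 1,
            length(t_max) == 1, is.finite(t_min), is.finite(t_max))
  if (t_min >= t_max) stop("`t_min` must be strictly less than `t_max`")
  n_points <- as.integer(n_points)
  if (n_points < 16L) stop("`n_points` must be at least 16")
  temperature <- seq(t_min, t_max, length.out = n_points)
  structure(
    list(t_min = t_min, t_max = t_max, n_points = n_points,
         temperature = temperature,
         step = (t_max - t_min) / (n_points - 1)),
    class = "acq_grid"
  )
}

#' @export
print.acq_grid <- function(x, ...) {
  cat(sprintf("<acq_grid> %.1f-%.1f degC, %d points (step %.4f degC)\n",
              x$t_min, x$t_max, x$n_points, x$step))
  invisible(x)
}

same_grid <- function(a, b, tol = 1e-8) {
  a$n_points == b$n_points && abs(a$t_min - b$t_min) < tol &&
    abs(a$t_max - b$t_max) < tol
}

#' One melting transition of a probe-target duplex
#'
#' A single dissociation transition, parameterised by its midpoint
#' temperature `tm`, the steepness `width` of the sigmoid, and the
#' fluorescence `amplitude` lost across the transition.
#'
#' @param tm Transition midpoint (degrees C).
#' @param width Transition steepness (degrees C, > 0).
#' @param amplitude Fluorescence drop across the transition (> 0).
#' @return A list of class `melt_component`.
#' @export
melt_component <- function(tm, width, amplitude) {
  stopifnot(is.finite(tm), is.finite(width), is.finite(amplitude))
  if (width <= 0) stop("`width` must be > 0")
  if (amplitude <= 0) stop("`amplitude` must be > 0")
  structure(list(tm = tm, width = width, amplitude = amplitude),
            class = "melt_component")
}

#' Internal temperature-marker parameters
#'
#' The assay spikes a temperature marker into the BS1 channel; it melts at a
#' fixed temperature above every species transition, producing the rightmost
#' trough of the BS1 signature, and is used to correct run-to-run
#' temperature drift.
#'
#' @return A `melt_component` at the marker melting temperature (84 degC).
#' @export
tm_marker_component <- function() melt_component(tm = 84, width = 0.5, amplitude = 0.8)

#' Default marker melting temperature (degrees C)
#' @export
TM_MARKER_TM <- 84

#' A one-segment generative melt model
#'
#' The set of melting transitions a species produces in one barcode-segment
#' channel. BS1 models always carry the internal temperature marker as their
#' rightmost component. Component midpoints must be separated by at least
#' twice the largest width in the segment so transitions stay resolvable.
#'
#' @param components List of [melt_component()]s (may be empty).
#' @param channel `"BS1"` or `"BS2"`.
#' @param include_marker Add the temperature-marker component (BS1 only).
#' @param baseline_slope Linear baseline drift (fluorescence per degC,
#'   typically <= 0).
#' @return A list of class `segment_model`.
#' @export
segment_model <- function(components = list(), channel = c("BS1", "BS2"),
                          include_marker = (channel == "BS1"),
                          baseline_slope = 0) {
  channel <- match.arg(channel)
  include_marker <- isTRUE(include_marker[1])
  if (include_marker && channel != "BS1")
    stop("the temperature marker is present only in the BS1 channel")
  if (include_marker) components <- c(components, list(tm_marker_component()))
  tms <- vapply(components, `[[`, numeric(1), "tm")
  widths <- vapply(components, `[[`, numeric(1), "width")
  if (length(tms) > 1) {
    sep <- min(diff(sort(tms)))
    if (sep < 2 * max(widths))
      stop(sprintf(
        "component tms too close: min separation %.2f < 2 x max width %.2f",
        sep, max(widths)))
  }
  structure(list(components = components, channel = channel,
                 includes_tm_marker = include_marker,
                 baseline_slope = baseline_slope),
            class = "segment_model")
}

#' Measurement-noise model for simulated melt curves
#'
#' Three noise sources act on each simulated curve: a global log-normal
#' amplitude scale (DNA quantity/degradation), a rigid temperature offset
#' applied to the whole run (instrument drift, removed downstream by the
#' marker correction), and i.i.d. additive fluorescence noise. A small
#' per-component amplitude jitter models within-species variation.
#'
#' @param amplitude_scale_sigma Log-scale s.d. of the global amplitude
#'   factor (0.08 for fresh tissue; see `processed_amplitude_sigma`).
#' @param temperature_offset_sigma S.d. (degC) of the per-run temperature
#'   offset before marker correction.
#' @param additive_noise_sigma S.d. of additive fluorescence noise.
#' @param per_component_jitter Relative log-s.d. of per-transition
#'   amplitude jitter.
#' @param processed_amplitude_sigma Log-scale amplitude s.d. used for
#'   degraded ("processed") samples.
#' @return A list of class `noise_model`.
#' @export
noise_model <- function(amplitude_scale_sigma = 0.08,
                        temperature_offset_sigma = 0.3,
                        additive_noise_sigma = 1e-4,
                        per_component_jitter = 0.02,
                        processed_amplitude_sigma = 0.2) {
  vals <- c(amplitude_scale_sigma, temperature_offset_sigma,
            additive_noise_sigma, per_component_jitter,
            processed_amplitude_sigma)
  if (any(!is.finite(vals)) || any(vals < 0))
    stop("all noise sigmas must be finite and >= 0")
  structure(list(amplitude_scale_sigma = amplitude_scale_sigma,
                 temperature_offset_sigma = temperature_offset_sigma,
                 additive_noise_sigma = additive_noise_sigma,
                 per_component_jitter = per_component_jitter,
                 processed_amplitude_sigma = processed_amplitude_sigma),
            class = "noise_model")
}

#' Noise-free measurement model
#'
#' Convenience constructor with every noise source switched off; curves are
#' then exactly the closed-form sigmoid mixture.
#' @return A `noise_model` with all sigmas zero.
#' @export
zero_noise <- function() {
  noise_model(0, 0, 0, 0, processed_amplitude_sigma = 0)
}

# noise model for a given sample condition
condition_noise <- function(noise, condition) {
  if (identical(condition, "processed")) {
    noise$amplitude_scale_sigma <- noise$processed_amplitude_sigma
  }
  noise
}

# derive a stream of child seeds below 2^31 from one parent seed
derive_seeds <- function(seed, n) {
  set.seed(as.integer(seed) %% .Machine$integer.max)
  sample.int(.Machine$integer.max - 1L, n, replace = FALSE)
}
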