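#' Stimulus specification for detector simulations
#'
#' A one-dimensional luminance pattern moving across the retinotopic plane:
#' either a single ON step edge (`moving_edge`) or a drifting sinusoidal
#' grating. Positions are in ommatidial units; the edge crosses the origin
#' at `duration / 2` so both channels see the full transition.
#'
#' @param kind `"moving_edge"` or `"drifting_sinusoid"`.
#' @param direction Motion direction, radians.
#' @param speed Speed in ommatidial units per second (> 0).
#' @param contrast Luminance amplitude.
#' @param duration Seconds (> 0).
#' @param spatial_period Grating wavelength in ommatidial units (sinusoid
#'   only); temporal frequency is `speed / spatial_period`.
#' @return A `stimulus_spec` list.
#' @export
stimulus_spec <- function(kind = c("moving_edge", "drifting_sinusoid"),
                          direction = 0, speed = 2, contrast = 1,
                          duration = 4, spatial_period = 4) {
  kind <- match.arg(kind)
  stopifnot(speed > 0, is.finite(duration), duration > 0, spatial_period > 0)
  structure(list(kind = kind, direction = direction, speed = speed,
                 contrast = contrast, duration = duration,
                 spatial_period = spatial_period),
            class = "stimulus_spec")
}

#' Sample a stimulus at one spatial point
#'
#' Luminance time series seen by a receptor at `point`. Two points offset
#' along the motion direction see time-shifted copies of the same signal,
#' with shift `offset / speed`.
#'
#' @param spec A [stimulus_spec()].
#' @param point Numeric `c(x, y)` in ommatidial units.
#' @param times Increasing numeric vector of sample times (seconds).
#' @return Numeric luminance vector.
#' @export
sample_stimulus <- function(spec, point, times) {
  stopifnot(inherits(spec, "stimulus_spec"), length(point) == 2L)
  if (is.unsorted(times)) stop("sample_stimulus: times must be increasing")
  proj <- sum(point * unit_vec(spec$direction))
  phase <- spec$speed * (times - spec$duration / 2) - proj
  switch(spec$kind,
         moving_edge = spec$contrast * as.numeric(phase >= 0),
         drifting_sinusoid = spec$contrast *
           sin(2 * pi * phase / spec$spatial_period))
}

#' First-order low-pass filter (the delay line of a motion detector)
#'
#' Exponential filter with time constant `tau` and DC gain 1, discretized
#' by zero-order hold: `y[i] = a * x[i] + (1 - a) * y[i-1]` with
#' `a = 1 - exp(-dt / tau)`.
#'
#' @param signal Numeric input series.
#' @param tau Time constant, seconds (> 0).
#' @param dt Sample interval, seconds (> 0).
#' @return Filtered series of the same length.
#' @export
lowpass <- function(signal, tau, dt) {
  stopifnot(tau > 0, dt > 0)
  a <- 1 - exp(-dt / tau)
  as.numeric(stats::filter(a * signal, 1 - a, method = "recursive"))
}

#' Detector configuration
#'
#' Two input channels with spatially offset fields of view; channel 1
#' carries the delay component (a first-order low-pass with time constant
#' `tau`). The HR (Hassenstein-Reichardt) model combines the channels
#' multiplicatively and fully opponently; the BL (Barlow-Levick) model
#' subtracts delayed channel-1 inhibition from channel-2 excitation with
#' gain `g` and half-wave rectifies.
#'
#' @param offset1,offset2 Channel field-of-view centres, `c(x, y)` in
#'   ommatidial units (must differ for direction selectivity).
#' @param sign1,sign2 Channel signs, `+1` or `-1` (BL expects `sign1 = -1`,
#'   the delayed inhibitory channel).
#' @param tau Delay time constant in seconds (default 0.15; the measured
#'   Mi1/Tm3 latency difference of ~15 ms is likely too small to set this,
#'   so it is a free parameter, not a fit).
#' @param model `"HR"` or `"BL"`.
#' @param gain Inhibitory gain `g` of the BL subtraction (default 1).
#' @param dt Simulation time step, seconds.
#' @return A `detector_config` list.
#' @export
detector_config <- function(offset1, offset2, sign1 = -1, sign2 = 1,
                            tau = 0.15, model = c("BL", "HR"), gain = 1,
                            dt = 0.002) {
  model <- match.arg(model)
  stopifnot(tau > 0, dt > 0, length(offset1) == 2L, length(offset2) == 2L)
  if (all(offset1 == offset2)) {
    warning("detector_config: identical channel offsets; ",
            "no direction selectivity possible")
  }
  structure(list(offset1 = as.numeric(offset1),
                 offset2 = as.numeric(offset2),
                 sign1 = sign1, sign2 = sign2, tau = tau, model = model,
                 gain = gain, dt = dt),
            class = "detector_config")
}

#' Time-averaged detector response to a stimulus
#'
#' Simulates the configured detector: `HR` computes the opponent correlator
#' `mean(LP(s1) * s2 - s1 * LP(s2))`, which is exactly antisymmetric under
#' channel swap; `BL` computes `mean(rect(s2 - g * LP(s1)))`, null-direction
#' suppression by delayed inhibition. The first `tau` seconds are discarded
#' as filter transient before averaging.
#'
#' @param config A [detector_config()].
#' @param spec A [stimulus_spec()].
#' @return Scalar time-averaged response.
#' @export
detector_response <- function(config, spec) {
  stopifnot(inherits(config, "detector_config"),
            inherits(spec, "stimulus_spec"))
  times <- seq(0, spec$duration, by = config$dt)
  s1 <- sample_stimulus(spec, config$offset1, times)
  s2 <- sample_stimulus(spec, config$offset2, times)
  keep <- times >= config$tau
  if (config$model == "HR") {
    r <- lowpass(s1, config$tau, config$dt) * s2 -
      s1 * lowpass(s2, config$tau, config$dt)
  } else {
    inh <- if (config$sign1 < 0) config$gain * lowpass(s1, config$tau, config$dt)
           else -config$gain * lowpass(s1, config$tau, config$dt)
    r <- pmax(0, s2 - inh)
  }
  mean(r[keep])
}

#' Direction selectivity index
#'
#' `(r_pd - r_nd) / (r_pd + r_nd)` in `[-1, 1]`. Responses are first offset
#' to be non-negative (by subtracting the smaller of the two when it is
#' negative); a zero denominator after offsetting is a degenerate input.
#'
#' @param r_pd,r_nd Responses to preferred- and null-direction motion.
#' @return Scalar in `[-1, 1]`.
#' @export
dsi <- function(r_pd, r_nd) {
  lo <- min(r_pd, r_nd)
  if (lo < 0) {
    r_pd <- r_pd - lo
    r_nd <- r_nd - lo
  }
  if (r_pd + r_nd == 0) stop("dsi: degenerate input, both responses zero")
  (r_pd - r_nd) / (r_pd + r_nd)
}

#' Build a BL detector from measured anatomy
#'
#' Maps a T4's anatomical subfield centres onto a Barlow-Levick
#' configuration: the non-delayed excitatory channel sits at the combined
#' Mi1/Tm3 (dendrite shaft) centre and the delayed inhibitory channel at
#' the combined Mi4/C3/CT1 (dendrite base) centre. The predicted preferred
#' direction of such a detector runs from the excitatory towards the
#' inhibitory centre.
#'
#' @param excitatory Named list / data frame of excitatory subfield centres,
#'   or a single `c(x, y)`; multiple centres are synapse-weight averaged if
#'   a `weights` vector is given, else averaged equally.
#' @param inhibitory Inhibitory subfield centre(s), same conventions.
#' @param weights_exc,weights_inh Optional synapse-count weights.
#' @param tau,gain,dt Passed to [detector_config()].
#' @return A `detector_config` with `model = "BL"` and a
#'   `predicted_pd` attribute (radians).
#' @export
circuit_from_anatomy <- function(excitatory, inhibitory,
                                 weights_exc = NULL, weights_inh = NULL,
                                 tau = 0.15, gain = 1, dt = 0.002) {
  combine <- function(centres, w) {
    m <- if (is.matrix(centres)) centres
         else if (is.list(centres)) do.call(rbind, centres)
         else matrix(centres, ncol = 2L)
    if (is.null(w)) w <- rep(1, nrow(m))
    c(sum(m[, 1L] * w), sum(m[, 2L] * w)) / sum(w)
  }
  exc <- combine(excitatory, weights_exc)
  inh <- combine(inhibitory, weights_inh)
  cfg <- suppressWarnings(
    detector_config(offset1 = inh, offset2 = exc, sign1 = -1, sign2 = 1,
                    tau = tau, model = "BL", gain = gain, dt = dt))
  if (all(exc == inh)) {
    warning("circuit_from_anatomy: excitatory and inhibitory centres ",
            "coincide; the detector has no direction preference")
    attr(cfg, "predicted_pd") <- NaN
  } else {
    attr(cfg, "predicted_pd") <- atan2(inh[2L] - exc[2L],
                                       inh[1L] - exc[1L]) %% (2 * pi)
  }
  cfg
}

#' Direction tuning of a detector over speeds
#'
#' Evaluates the time-averaged response to a moving ON edge along a set of
#' directions and speeds, and the DSI between a chosen preferred direction
#' and its opposite.
#'
#' @param config A [detector_config()].
#' @param pd Preferred direction to test (radians); default the config's
#'   `predicted_pd` attribute.
#' @param speeds Speeds in ommatidial units per second.
#' @param contrast Edge contrast.
#' @return Data frame `speed`, `r_pd`, `r_nd`, `dsi`.
#' @export
direction_tuning <- function(config, pd = NULL, speeds = c(0.5, 1, 2, 5),
                             contrast = 1) {
  if (is.null(pd)) pd <- attr(config, "predicted_pd")
  if (is.null(pd)) stop("direction_tuning: no preferred direction given")
  sep <- sqrt(sum((config$offset1 - config$offset2)^2))
  rows <- lapply(speeds, function(v) {
    # long enough for the edge to clear both fields plus filter settling
    dur <- 2 * (max(abs(c(config$offset1, config$offset2))) + sep + 1) / v +
      10 * config$tau
    r_pd <- detector_response(config, stimulus_spec(
      "moving_edge", direction = pd, speed = v, contrast = contrast,
      duration = dur))
    r_nd <- detector_response(config, stimulus_spec(
      "moving_edge", direction = pd + pi, speed = v, contrast = contrast,
      duration = dur))
    data.frame(speed = v, r_pd = r_pd, r_nd = r_nd, dsi = dsi(r_pd, r_nd))
  })
  do.call(rbind, rows)
}
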