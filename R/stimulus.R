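#' Describe a light stimulus program for one eye
#'
#' A stimulus pattern is one eye's light program: a shape (single pulse,
#' sinusoid, triangle, rectangle, positive/negative ramp, or a pseudorandom
#' level sequence), a luminance amplitude in `[1, 100]` cd/m2, an LED color
#' (white, or red/green/blue with peak wavelengths 625/520/470 nm), timing,
#' and a seed for the pseudorandom shape. Periodic shapes additionally need
#' a frequency.
#'
#' @param shape One of `"single_pulse"`, `"sinusoid"`, `"triangle"`,
#'   `"rectangle"`, `"ramp_positive"`, `"ramp_negative"`, `"pseudorandom"`.
#' @param luminance_cd_m2 Amplitude in cd/m2, within `[1, 100]`.
#' @param duration_s Total program duration in seconds (> 0).
#' @param eye `"left"`, `"right"`, `"both"` or `"alternating"`.
#' @param color `"white"`, `"red"`, `"green"` or `"blue"`.
#' @param frequency_hz Frequency for periodic shapes (> 0).
#' @param onset_s Stimulus start relative to recording start (default 0);
#'   samples before onset are dark.
#' @param pulse_width_s Active width of a single pulse; defaults to
#'   `duration_s - onset_s`.
#' @param hold_s Hold interval between pseudorandom level changes.
#' @param seed Seed for the pseudorandom shape.
#' @return An object of class `stimulus_pattern`.
#' @examples
#' p <- stimulus_pattern("single_pulse", 100, duration_s = 14,
#'                       onset_s = 2, pulse_width_s = 10)
#' w <- generate_waveform(p, sample_rate_hz = 75)
#' range(which(w$luminance > 0))  # samples 151..900 (1-based)
#' @export
stimulus_pattern <- function(shape = c("single_pulse", "sinusoid", "triangle",
                                       "rectangle", "ramp_positive",
                                       "ramp_negative", "pseudorandom"),
                             luminance_cd_m2, duration_s,
                             eye = c("both", "left", "right", "alternating"),
                             color = c("white", "red", "green", "blue"),
                             frequency_hz = NULL, onset_s = 0,
                             pulse_width_s = NULL, hold_s = 0.5, seed = NULL) {
  shape <- match.arg(shape)
  eye <- match.arg(eye)
  color <- match.arg(color)
  if (!is_scalar_num(luminance_cd_m2) ||
      luminance_cd_m2 < 1 || luminance_cd_m2 > 100) {
    abort("`luminance_cd_m2` must lie within [1, 100]")
  }
  if (!is_scalar_num(duration_s) || duration_s <= 0) abort("`duration_s` must be > 0")
  if (!is_scalar_num(onset_s) || onset_s < 0 || onset_s >= duration_s) {
    abort("`onset_s` must be in [0, duration_s)")
  }
  periodic <- shape %in% c("sinusoid", "triangle", "rectangle")
  if (periodic && (is.null(frequency_hz) || !is_scalar_num(frequency_hz) ||
                   frequency_hz <= 0)) {
    abort("periodic shapes require `frequency_hz` > 0")
  }
  if (shape == "single_pulse") {
    pulse_width_s <- pulse_width_s %||% (duration_s - onset_s)
    if (!is_scalar_num(pulse_width_s) || pulse_width_s <= 0) {
      abort("`pulse_width_s` must be > 0")
    }
  }
  if (shape == "pseudorandom" && (!is_scalar_num(hold_s) || hold_s <= 0)) {
    abort("`hold_s` must be > 0")
  }
  structure(
    list(shape = shape, eye = eye, color = color,
         luminance_cd_m2 = luminance_cd_m2, frequency_hz = frequency_hz,
         duration_s = duration_s, onset_s = onset_s,
         pulse_width_s = pulse_width_s, hold_s = hold_s,
         seed = if (is.null(seed)) NULL else as.integer(seed)),
    class = "stimulus_pattern"
  )
}

#' Sample a stimulus pattern as a luminance waveform
#'
#' Produces `round(duration_s * sample_rate_hz)` samples at times
#' `k / rate`, zero (dark) before the onset. Shapes span `[0, luminance]`:
#' the sinusoid is an offset sine starting dark, triangle and rectangle are
#' the standard periodic forms, ramps run linearly from 0 to the luminance
#' (or back), and the pseudorandom shape holds seeded uniform levels for
#' `hold_s` at a time.
#'
#' @param pattern A [stimulus_pattern()].
#' @param sample_rate_hz Sampling rate; must be at least twice the
#'   frequency of a periodic shape.
#' @return A tibble of class `stimulus_waveform` with columns `time_s`,
#'   `luminance`, `eye`.
#' @export
generate_waveform <- function(pattern, sample_rate_hz) {
  if (!inherits(pattern, "stimulus_pattern")) abort("`pattern` must be a stimulus_pattern()")
  if (!is_scalar_num(sample_rate_hz) || sample_rate_hz <= 0) {
    abort("`sample_rate_hz` must be > 0")
  }
  periodic <- pattern$shape %in% c("sinusoid", "triangle", "rectangle")
  if (periodic && sample_rate_hz < 2 * pattern$frequency_hz) {
    abort("`sample_rate_hz` must be >= 2 * frequency_hz for periodic shapes")
  }
  n <- round(pattern$duration_s * sample_rate_hz)
  t <- (seq_len(n) - 1) / sample_rate_hz
  tp <- t - pattern$onset_s  # time since onset
  L <- pattern$luminance_cd_m2
  f <- pattern$frequency_hz
  active_len <- pattern$duration_s - pattern$onset_s
  lum <- switch(
    pattern$shape,
    single_pulse = ifelse(tp >= 0 & tp < pattern$pulse_width_s, L, 0),
    sinusoid = L / 2 * (1 - cos(2 * pi * f * tp)),
    triangle = {
      ph <- (f * tp) %% 1
      L * (1 - 2 * abs(ph - 0.5))
    },
    rectangle = ifelse((f * tp) %% 1 < 0.5, L, 0),
    ramp_positive = L * tp / active_len,
    ramp_negative = L * (1 - tp / active_len),
    pseudorandom = {
      n_lev <- ceiling(active_len / pattern$hold_s)
      levels <- with_seed(pattern$seed, runif(n_lev, 0, L))
      levels[pmin(n_lev, floor(tp / pattern$hold_s) + 1)]
    }
  )
  lum[tp < 0] <- 0
  structure(
    tibble(time_s = t, luminance = lum, eye = pattern$eye),
    class = c("stimulus_waveform", class(tibble())),
    pattern = pattern, sample_rate_hz = sample_rate_hz
  )
}

#' Build the binocular trigger and stimulus event timeline
#'
#' The controller couples light stimuli to the camera trigger: the rising
#' edge of the frame trigger also carries the stimulus control pulse, so
#' each stimulus onset snaps to the first frame trigger at or after its
#' requested onset. Frame triggers fire at the exact frame period over the
#' half-open interval `[0, duration_s)`: that is `floor(duration * rate) + 1`
#' triggers when the product is non-integral and exactly `duration * rate`
#' when it is integral. A sync pulse at t = 0 marks the master clock for
#' co-recording bio-measurement systems.
#'
#' @param patterns A [stimulus_pattern()] or list of them; per-eye programs
#'   must not overlap in time.
#' @param frame_rate_hz Camera frame rate.
#' @param duration_s Recording duration.
#' @return A tibble of class `event_timeline` with columns `time_s`,
#'   `event` (`frame_trigger`, `stimulus_on`, `stimulus_off`, `sync_pulse`)
#'   and `eye`.
#' @export
build_timeline <- function(patterns, frame_rate_hz, duration_s) {
  if (inherits(patterns, "stimulus_pattern")) patterns <- list(patterns)
  if (!length(patterns) || !all(vapply(patterns, inherits, logical(1), "stimulus_pattern"))) {
    abort("`patterns` must be stimulus_pattern objects")
  }
  if (!is_scalar_num(frame_rate_hz) || frame_rate_hz <= 0) abort("`frame_rate_hz` must be > 0")
  if (!is_scalar_num(duration_s) || duration_s <= 0) abort("`duration_s` must be > 0")

  k_max <- ceiling(duration_s * frame_rate_hz - 1e-9) - 1
  triggers <- tibble(time_s = (0:k_max) / frame_rate_hz,
                     event = "frame_trigger", eye = NA_character_)

  snap <- function(t) ceiling(t * frame_rate_hz - 1e-9) / frame_rate_hz
  stim <- purrr::map_dfr(patterns, function(p) {
    on <- snap(p$onset_s)
    width <- if (p$shape == "single_pulse") p$pulse_width_s else p$duration_s - p$onset_s
    off <- min(snap(p$onset_s + width), duration_s)
    tibble(time_s = c(on, off),
           event = c("stimulus_on", "stimulus_off"),
           eye = p$eye)
  })

  # overlap check per physical eye
  for (side in c("left", "right")) {
    ivals <- purrr::keep(patterns, ~ .x$eye %in% c(side, "both"))
    if (length(ivals) > 1) {
      spans <- t(vapply(ivals, function(p) {
        width <- if (p$shape == "single_pulse") p$pulse_width_s else p$duration_s - p$onset_s
        c(p$onset_s, p$onset_s + width)
      }, numeric(2)))
      o <- order(spans[, 1])
      spans <- spans[o, , drop = FALSE]
      if (any(spans[-1, 1] < spans[-nrow(spans), 2] - 1e-12)) {
        abort(sprintf("conflicting simultaneous patterns on the %s eye", side))
      }
    }
  }

  ev <- dplyr::bind_rows(
    tibble(time_s = 0, event = "sync_pulse", eye = NA_character_),
    triggers, stim
  )
  ev <- dplyr::arrange(ev, .data$time_s, .data$event)
  structure(ev, class = c("event_timeline", class(tibble())),
            frame_rate_hz = frame_rate_hz, duration_s = duration_s)
}

#' Construct one of the four binocular stimulation classes
#'
#' The system generates four classes of pupil response: stimulate the left
#' eye only, the right eye only, both simultaneously, or the eyes
#' alternately. For the alternating class the base pattern is repeated as
#' interleaved single pulses, starting with the left eye.
#'
#' @param class `"left"`, `"right"`, `"both"` or `"alternating"`.
#' @param base A [stimulus_pattern()] used as the template.
#' @param period_s Alternation period (one eye's on-time) for the
#'   alternating class.
#' @return A list of [stimulus_pattern()]s suitable for [build_timeline()].
#' @export
stimulation_class <- function(class = c("left", "right", "both", "alternating"),
                              base, period_s = 1) {
  class <- match.arg(class)
  if (!inherits(base, "stimulus_pattern")) abort("`base` must be a stimulus_pattern()")
  remake <- function(...) {
    args <- modifyList(
      list(shape = base$shape, luminance_cd_m2 = base$luminance_cd_m2,
           duration_s = base$duration_s, color = base$color,
           frequency_hz = base$frequency_hz, onset_s = base$onset_s,
           pulse_width_s = base$pulse_width_s, hold_s = base$hold_s,
           seed = base$seed),
      list(...))
    do.call(stimulus_pattern, args)
  }
  if (class %in% c("left", "right", "both")) {
    return(list(remake(eye = class)))
  }
  # alternating: interleaved pulses, left first
  starts <- seq(base$onset_s, base$duration_s - 1e-9, by = period_s)
  purrr::imap(starts, function(s, i) {
    remake(shape = "single_pulse", eye = if (i %% 2 == 1) "left" else "right",
           onset_s = s, pulse_width_s = min(period_s, base$duration_s - s))
  })
}
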