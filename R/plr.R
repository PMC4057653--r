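#' Pupil light reflex model parameters
#'
#' Parameters of the synthetic PLR generator used to exercise the pipeline
#' end-to-end without subjects. The model is deliberately simple — a
#' first-order constriction/redilation element per eye driven by delayed
#' log-luminance, consensual coupling between the eyes, band-limited
#' spontaneous fluctuations (hippus) and scripted blinks — chosen to
#' reproduce the qualitative shapes of recorded pupil responses, not to
#' claim physiological fidelity.
#'
#' @param baseline_diameter_px Resting (dark-adapted) pupil diameter in
#'   pixels.
#' @param constriction_gain Fractional constriction per unit
#'   `log10(1 + L)` of luminance drive.
#' @param latency_s Pure response delay in seconds.
#' @param tau_constrict_s,tau_redilate_s First-order time constants for
#'   constriction and redilation.
#' @param consensual_gain Fraction of the direct response expressed in the
#'   unstimulated eye, in `[0, 1]`.
#' @param hippus_amplitude_px SD of the spontaneous fluctuation, in pixels.
#' @param hippus_band_hz Two-element passband of the hippus noise in Hz.
#' @param blink_schedule List of `c(onset_s, duration_s)` blink intervals.
#' @param seed RNG seed for hippus; fixed seed gives bit-reproducible
#'   traces.
#' @return An object of class `plr_model`.
#' @export
plr_model <- function(baseline_diameter_px = 119, constriction_gain = 0.15,
                      latency_s = 0.25, tau_constrict_s = 0.4,
                      tau_redilate_s = 1.2, consensual_gain = 0.85,
                      hippus_amplitude_px = 0, hippus_band_hz = c(0.05, 0.5),
                      blink_schedule = NULL, seed = NULL) {
  if (!is_scalar_num(baseline_diameter_px) || baseline_diameter_px <= 0) {
    abort("`baseline_diameter_px` must be > 0")
  }
  if (tau_constrict_s <= 0 || tau_redilate_s <= 0) abort("time constants must be > 0")
  if (consensual_gain < 0 || consensual_gain > 1) {
    abort("`consensual_gain` must lie in [0, 1]")
  }
  if (hippus_amplitude_px < 0) abort("`hippus_amplitude_px` must be >= 0")
  if (length(hippus_band_hz) != 2 || hippus_band_hz[1] <= 0 ||
      hippus_band_hz[2] <= hippus_band_hz[1]) {
    abort("`hippus_band_hz` must be an increasing positive pair")
  }
  structure(
    list(baseline_diameter_px = baseline_diameter_px,
         constriction_gain = constriction_gain, latency_s = latency_s,
         tau_constrict_s = tau_constrict_s, tau_redilate_s = tau_redilate_s,
         consensual_gain = consensual_gain,
         hippus_amplitude_px = hippus_amplitude_px,
         hippus_band_hz = hippus_band_hz,
         blink_schedule = blink_schedule,
         seed = if (is.null(seed)) NULL else as.integer(seed)),
    class = "plr_model"
  )
}

# luminance series -> log-luminance drive
plr_drive <- function(lum) log10(1 + pmax(lum, 0))

#' Simulate ground-truth binocular pupil diameter series
#'
#' Integrates the first-order PLR dynamics for both eyes under the given
#' per-eye stimulus waveforms. The state is updated with the exact
#' exponential step for a piecewise-constant drive, so for a step stimulus
#' the sampled trace equals the closed-form first-order step response. The
#' unstimulated eye receives `consensual_gain` times the other eye's drive.
#' Hippus noise (if enabled) is seeded Gaussian noise band-passed to the
#' configured band and added to the diameter.
#'
#' @param params A [plr_model()].
#' @param stim_left,stim_right Per-eye luminance series: numeric vectors or
#'   [generate_waveform()] tibbles; `NULL` means no stimulus (darkness).
#' @param rate_hz Sampling rate of the series.
#' @return A tibble with columns `time_s`, `eye`, `diameter_px`, `blink`.
#' @examples
#' p <- plr_model(seed = 1)
#' stim <- c(rep(0, 25), rep(50, 75))
#' d <- simulate_diameter(p, stim_left = stim, rate_hz = 25)
#' @export
simulate_diameter <- function(params, stim_left = NULL, stim_right = NULL,
                              rate_hz) {
  if (!inherits(params, "plr_model")) abort("`params` must be a plr_model()")
  if (!is_scalar_num(rate_hz) || rate_hz <= 0) abort("`rate_hz` must be > 0")
  as_series <- function(s) {
    if (is.null(s)) return(NULL)
    if (inherits(s, "stimulus_waveform") || is.data.frame(s)) s$luminance else as.numeric(s)
  }
  sl <- as_series(stim_left); sr <- as_series(stim_right)
  n <- max(length(sl), length(sr))
  if (n == 0) abort("at least one stimulus series is required")
  pad <- function(s) { if (is.null(s)) rep(0, n) else c(s, rep(0, n - length(s))) }
  sl <- pad(sl); sr <- pad(sr)

  lag_k <- round(params$latency_s * rate_hz)
  delay <- function(u) if (lag_k > 0) c(rep(0, min(lag_k, n)), head(u, n - lag_k)) else u
  uL <- delay(plr_drive(sl)); uR <- delay(plr_drive(sr))
  effL <- uL + params$consensual_gain * uR
  effR <- uR + params$consensual_gain * uL

  dt <- 1 / rate_hz
  # piecewise-constant drive held over [t_k, t_{k+1}); exact exponential step
  integrate_eye <- function(eff) {
    deq <- params$baseline_diameter_px * (1 - params$constriction_gain * eff)
    d <- numeric(n)
    d[1] <- deq[1]
    for (k in seq_len(n - 1)) {
      tau <- if (deq[k] < d[k]) params$tau_constrict_s else params$tau_redilate_s
      d[k + 1] <- deq[k] + (d[k] - deq[k]) * exp(-dt / tau)
    }
    d
  }
  dL <- integrate_eye(effL)
  dR <- integrate_eye(effR)

  if (params$hippus_amplitude_px > 0) {
    noise <- with_seed(params$seed, list(rnorm(n), rnorm(n)))
    bp <- signal::butter(2, pmin(params$hippus_band_hz / (rate_hz / 2), 0.99),
                         type = "pass")
    shape <- function(x) {
      y <- as.numeric(signal::filtfilt(bp, x))
      s <- sd(y)
      if (s > 0) y / s * params$hippus_amplitude_px else y
    }
    dL <- dL + shape(noise[[1]])
    dR <- dR + shape(noise[[2]])
  }

  t <- (seq_len(n) - 1) / rate_hz
  blink <- rep(FALSE, n)
  for (b in params$blink_schedule %||% list()) {
    blink <- blink | (t >= b[1] & t < b[1] + b[2])
  }
  dplyr::bind_rows(
    tibble(time_s = t, eye = "left", diameter_px = dL, blink = blink),
    tibble(time_s = t, eye = "right", diameter_px = dR, blink = blink)
  )
}

#' Synthetic eye geometry for rendered videos
#'
#' Layout of the rendered synthetic eye: frame size, pupil center (default:
#' the center pixel of the frame, fixed across frames), iris background and
#' eyelid intensities, and an optional corneal reflection spot.
#'
#' @param image_size `(width, height)` in pixels (>= 64 each).
#' @param center Optional fixed `(x, y)` pupil center; default the center
#'   pixel's center.
#' @param iris_intensity Background (iris/sclera) intensity, 8-bit.
#' @param eyelid_intensity Intensity of a blink-occluded frame.
#' @param reflection Optional [reflection_spot()] rendered inside the pupil.
#' @return An object of class `eye_geometry`.
#' @export
eye_geometry <- function(image_size = c(256, 256), center = NULL,
                         iris_intensity = 200, eyelid_intensity = 230,
                         reflection = NULL) {
  if (length(image_size) != 2 || any(image_size < 64)) {
    abort("`image_size` must be (width, height), each >= 64")
  }
  if (!is.null(reflection) && !inherits(reflection, "reflection_spot")) {
    abort("`reflection` must be a reflection_spot()")
  }
  structure(
    list(image_size = as.numeric(image_size),
         center = center %||% c(floor(image_size[1] / 2) + 0.5,
                                floor(image_size[2] / 2) + 0.5),
         iris_intensity = iris_intensity,
         eyelid_intensity = eyelid_intensity,
         reflection = reflection),
    class = "eye_geometry"
  )
}

#' Render a scripted diameter series as an eye video
#'
#' Renders one frame per diameter sample: a dark pupil disk of the scripted
#' diameter on an iris background (with an optional reflection spot),
#' rasterized with the same pixel-center rule as the phantom renderer.
#' Blink samples are rendered as eyelid occlusion (a uniformly bright
#' frame). Frames are then passed through the [acquisition_model()] noise
#' chain. The scripted series is returned alongside as ground truth.
#'
#' @param diameters Numeric vector of pupil diameters in pixels, or a
#'   [simulate_diameter()] tibble filtered to one eye.
#' @param geometry An [eye_geometry()].
#' @param model An [acquisition_model()]; use zero scales for noiseless
#'   rendering.
#' @param eye Eye label for the frames.
#' @param rate_hz Frame rate used for timestamps.
#' @param blink Logical vector marking blink frames (recycled from a
#'   `simulate_diameter()` tibble when given).
#' @return `list(frames, truth)`: a list of [raw_frame()]s and a tibble
#'   `(frame_index, time_s, diameter_px, blink)`.
#' @export
render_eye_video <- function(diameters, geometry = eye_geometry(),
                             model = acquisition_model(), eye = "left",
                             rate_hz = 25, blink = NULL) {
  if (is.data.frame(diameters)) {
    blink <- blink %||% diameters$blink
    diameters <- diameters$diameter_px
  }
  diameters <- as.numeric(diameters)
  if (any(!is.finite(diameters)) || any(diameters <= 0)) {
    abort("diameters must be positive")
  }
  w <- geometry$image_size[1]; h <- geometry$image_size[2]
  cx <- geometry$center[1]; cy <- geometry$center[2]
  if (any(cx - diameters / 2 < 0 | cx + diameters / 2 > w |
          cy - diameters / 2 < 0 | cy + diameters / 2 > h)) {
    abort("pupil exceeds the frame")
  }
  blink <- blink %||% rep(FALSE, length(diameters))

  xs <- seq_len(w) - 0.5 - cx
  ys <- seq_len(h) - 0.5 - cy
  r2 <- outer(ys^2, xs^2, "+")
  spot <- NULL
  if (!is.null(geometry$reflection)) {
    sc <- geometry$reflection$center %||% c(cx, cy)
    rx <- (seq_len(w) - 0.5 - sc[1]) / geometry$reflection$radius_px
    ry <- (seq_len(h) - 0.5 - sc[2]) / geometry$reflection$radius_px
    spot <- outer(ry^2, rx^2, "+") <= 1
  }

  degrade <- function(px, k) {
    if (model$blur_sigma_px > 0) {
      px <- as.matrix(EBImage::imageData(
        EBImage::gblur(px / 255, sigma = model$blur_sigma_px,
                       boundary = "replicate"))) * 255
    }
    if (model$blur_sigma_px == 0 && model$noise_sd == 0 &&
        model$illumination_drift == 0 && model$jitter_px == 0) {
      return(px)
    }
    shift <- if (model$jitter_px > 0) rnorm(2, 0, model$jitter_px) else c(0, 0)
    offset <- model$illumination_drift / 2 * sin(2 * pi * k / model$drift_period)
    acquire_frame_cpp(px, shift[1], shift[2], offset, model$noise_sd)
  }

  frames <- with_seed(model$seed, {
    lapply(seq_along(diameters), function(i) {
      k <- i - 1L
      if (blink[i]) {
        px <- matrix(geometry$eyelid_intensity, h, w)
      } else {
        px <- matrix(geometry$iris_intensity, h, w)
        px[r2 <= (diameters[i] / 2)^2] <- 0
        if (!is.null(spot)) {
          inside <- spot & r2 <= (diameters[i] / 2)^2
          px[inside] <- geometry$reflection$intensity
        }
      }
      raw_frame(degrade(px, k), eye = eye, timestamp_s = k / rate_hz,
                frame_index = k)
    })
  })
  truth <- tibble(frame_index = seq_along(diameters) - 1L,
                  time_s = (seq_along(diameters) - 1) / rate_hz,
                  diameter_px = diameters, blink = blink)
  list(frames = frames, truth = truth)
}
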