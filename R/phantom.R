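#' Describe a reflection spot inside a phantom
#'
#' Validation phantoms exist in two versions: plain, and with a small white
#' circle simulating the corneal reflection of the IR illuminator inside the
#' dark pupil region. The spot must lie strictly inside the phantom.
#'
#' @param radius_px Spot radius in pixels.
#' @param center Optional `(x, y)` continuous image coordinates; defaults to
#'   the phantom center at render time.
#' @param intensity 8-bit intensity of the spot (default 255, white).
#' @return An object of class `reflection_spot`.
#' @export
reflection_spot <- function(radius_px, center = NULL, intensity = 255) {
  if (!is_scalar_num(radius_px) || radius_px <= 0) abort("`radius_px` must be > 0")
  if (!is.null(center) && (length(center) != 2 || !is.numeric(center))) {
    abort("`center` must be NULL or a numeric (x, y) pair")
  }
  if (!is_scalar_num(intensity) || intensity < 0 || intensity > 255) {
    abort("`intensity` must be in [0, 255]")
  }
  structure(list(radius_px = radius_px, center = center, intensity = intensity),
            class = "reflection_spot")
}

#' Describe a validation phantom
#'
#' A phantom is a solid black circle or axis-aligned ellipse on a white
#' background, the software analogue of the printed test objects used to
#' validate a pupillometer. Axis lengths are full lengths in pixels; the
#' invariant `major >= minor` always holds and `orientation` states which
#' screen axis carries the major axis (the "major axis < minor axis" phantom
#' variant is the `"vertical"` orientation).
#'
#' By default the center is snapped per axis so that the phantom's bounding
#' box lies on pixel-grid lines (each axis covers an integer run of pixels),
#' which is what drawing an integer-sized shape in a raster editor produces.
#' An explicit `center` is used as-is.
#'
#' @param shape `"circle"` or `"ellipse"`.
#' @param major_axis_px,minor_axis_px Full axis lengths in pixels
#'   (`minor_axis_px` defaults to the major axis).
#' @param orientation `"horizontal"` (major axis along x) or `"vertical"`.
#' @param center Optional `(x, y)` continuous center; default grid-aligned
#'   near the image center.
#' @param image_size `(width, height)` in pixels, default `c(1024, 1024)`.
#' @param reflection Optional [reflection_spot()].
#' @param true_size_mm Optional physical size of the printed phantom in
#'   millimeters, used for linear-resolution calibration.
#' @return An object of class `phantom_spec`.
#' @examples
#' spec <- phantom_spec("circle", 119)
#' frame <- render_phantom(spec)
#' sum(frame$pixels == 0)  # dark-pixel count
#' @export
phantom_spec <- function(shape = c("circle", "ellipse"),
                         major_axis_px, minor_axis_px = major_axis_px,
                         orientation = c("horizontal", "vertical"),
                         center = NULL, image_size = c(1024, 1024),
                         reflection = NULL, true_size_mm = NULL) {
  shape <- match.arg(shape)
  orientation <- match.arg(orientation)
  if (!is_scalar_num(major_axis_px) || !is_scalar_num(minor_axis_px) ||
      minor_axis_px <= 0 || major_axis_px < minor_axis_px) {
    abort("axis lengths must satisfy major_axis_px >= minor_axis_px > 0")
  }
  if (shape == "circle" && major_axis_px != minor_axis_px) {
    abort("a circle phantom must have equal axes")
  }
  if (length(image_size) != 2 || !all(image_size >= 64)) {
    abort("`image_size` must be (width, height), each >= 64")
  }
  if (!is.null(reflection) && !inherits(reflection, "reflection_spot")) {
    abort("`reflection` must be a reflection_spot()")
  }
  if (!is.null(center) && (length(center) != 2 || !is.numeric(center))) {
    abort("`center` must be NULL or a numeric (x, y) pair")
  }
  if (!is.null(true_size_mm) && (!is_scalar_num(true_size_mm) || true_size_mm <= 0)) {
    abort("`true_size_mm` must be a positive number")
  }
  spec <- structure(
    list(shape = shape, major_axis_px = major_axis_px,
         minor_axis_px = minor_axis_px, orientation = orientation,
         center = center, image_size = as.numeric(image_size),
         reflection = reflection, true_size_mm = true_size_mm),
    class = "phantom_spec"
  )
  geom <- phantom_geometry(spec)  # validates bounds and reflection placement
  spec
}

# Resolve screen-axis semi-lengths and center; check bounds invariants.
phantom_geometry <- function(spec) {
  ax <- if (spec$orientation == "horizontal") spec$major_axis_px else spec$minor_axis_px
  ay <- if (spec$orientation == "horizontal") spec$minor_axis_px else spec$major_axis_px
  w <- spec$image_size[1]; h <- spec$image_size[2]
  if (is.null(spec$center)) {
    cx <- floor(w / 2 - ax / 2 + 0.5) + ax / 2
    cy <- floor(h / 2 - ay / 2 + 0.5) + ay / 2
  } else {
    cx <- spec$center[1]; cy <- spec$center[2]
  }
  if (cx - ax / 2 < 0 || cx + ax / 2 > w || cy - ay / 2 < 0 || cy + ay / 2 > h) {
    abort("phantom exceeds image bounds")
  }
  refl <- NULL
  if (!is.null(spec$reflection)) {
    rc <- spec$reflection$center %||% c(cx, cy)
    r <- spec$reflection$radius_px
    a <- ax / 2; b <- ay / 2
    if (a - r <= 0 || b - r <= 0 ||
        ((rc[1] - cx) / (a - r))^2 + ((rc[2] - cy) / (b - r))^2 >= 1) {
      abort("reflection spot must lie strictly inside the phantom")
    }
    refl <- list(cx = rc[1], cy = rc[2], r = r,
                 intensity = spec$reflection$intensity)
  }
  list(cx = cx, cy = cy, a = ax / 2, b = ay / 2, w = w, h = h, refl = refl)
}

#' Render a phantom as an 8-bit frame
#'
#' Rasterization rule: a pixel is dark (intensity 0) iff its center satisfies
#' the analytic inside-ellipse inequality; all other pixels are white (255).
#' No anti-aliasing is applied, so dark-pixel counts are exactly reproducible
#' by a brute-force point-in-ellipse test. A reflection spot, if present,
#' overwrites its interior pixels with the spot intensity.
#'
#' @param spec A [phantom_spec()].
#' @return A [raw_frame()].
#' @export
render_phantom <- function(spec) {
  if (!inherits(spec, "phantom_spec")) abort("`spec` must be a phantom_spec()")
  g <- phantom_geometry(spec)
  xs <- (seq_len(g$w) - 0.5 - g$cx) / g$a
  ys <- (seq_len(g$h) - 0.5 - g$cy) / g$b
  inside <- outer(ys^2, xs^2, "+") <= 1  # [row = y, col = x]
  m <- matrix(255, g$h, g$w)
  m[inside] <- 0
  if (!is.null(g$refl)) {
    rx <- (seq_len(g$w) - 0.5 - g$refl$cx) / g$refl$r
    ry <- (seq_len(g$h) - 0.5 - g$refl$cy) / g$refl$r
    spot <- outer(ry^2, rx^2, "+") <= 1
    m[spot] <- g$refl$intensity
  }
  raw_frame(m)
}

#' Simulated image acquisition noise model
#'
#' Stands in for camera capture when running the repeatability protocol
#' without hardware: Gaussian optical blur, per-frame sub-pixel translational
#' jitter, a slow sinusoidal illumination drift and additive Gaussian
#' intensity noise, applied in that order, then clipped to `[0, 255]` and
#' quantized to the 8-bit grid.
#'
#' The defaults are deliberately mild: they produce nonzero frame-to-frame
#' spread while keeping the size bias of the mean-threshold pipeline well
#' under the 0.5 percent accuracy bound of the validation protocol.
#'
#' @param blur_sigma_px Gaussian blur scale in pixels (applied once; the
#'   source frame is static).
#' @param noise_sd Additive Gaussian noise SD in 8-bit intensity levels.
#' @param illumination_drift Peak-to-peak slow background modulation in
#'   intensity levels (one cycle per `drift_period` frames).
#' @param jitter_px Per-frame translational jitter SD in pixels.
#' @param seed RNG seed; a fixed seed makes the frame sequence
#'   bit-reproducible.
#' @param drift_period Drift cycle length in frames.
#' @return An object of class `acquisition_model`.
#' @export
acquisition_model <- function(blur_sigma_px = 0.5, noise_sd = 2,
                              illumination_drift = 4, jitter_px = 0.3,
                              seed = NULL, drift_period = 100) {
  for (v in c(blur_sigma_px, noise_sd, illumination_drift, jitter_px)) {
    if (!is_scalar_num(v) || v < 0) abort("all noise scales must be >= 0")
  }
  if (!is_count(drift_period)) abort("`drift_period` must be a positive count")
  structure(
    list(blur_sigma_px = blur_sigma_px, noise_sd = noise_sd,
         illumination_drift = illumination_drift, jitter_px = jitter_px,
         seed = if (is.null(seed)) NULL else as.integer(seed),
         drift_period = drift_period),
    class = "acquisition_model"
  )
}

#' Simulate the acquisition of an image sequence
#'
#' Produces `n_frames` degraded copies of a static source frame under an
#' [acquisition_model()]: blur, then jitter, then illumination drift, then
#' additive noise. With all scales zero the output frames are bit-identical
#' to the input; with a fixed model seed the sequence is bit-reproducible.
#'
#' @param frame A [raw_frame()] or numeric matrix (8-bit intensities).
#' @param model An [acquisition_model()].
#' @param n_frames Number of frames to produce.
#' @return A list of [raw_frame()]s with frame indices `0:(n_frames - 1)`.
#' @export
simulate_acquisition <- function(frame, model = acquisition_model(), n_frames) {
  if (!inherits(model, "acquisition_model")) abort("`model` must be an acquisition_model()")
  if (!is_count(n_frames)) abort("`n_frames` must be >= 1")
  px <- frame_pixels(frame)
  eye <- if (inherits(frame, "raw_frame")) frame$eye else "unknown"
  base <- if (model$blur_sigma_px > 0) {
    as.matrix(EBImage::imageData(
      EBImage::gblur(px / 255, sigma = model$blur_sigma_px, boundary = "replicate")
    )) * 255
  } else px
  pure_copy <- model$blur_sigma_px == 0 && model$noise_sd == 0 &&
    model$illumination_drift == 0 && model$jitter_px == 0
  with_seed(model$seed, {
    lapply(seq_len(n_frames) - 1L, function(k) {
      if (pure_copy) return(raw_frame(px, eye = eye, frame_index = k))
      shift <- if (model$jitter_px > 0) rnorm(2, 0, model$jitter_px) else c(0, 0)
      offset <- model$illumination_drift / 2 *
        sin(2 * pi * k / model$drift_period)
      out <- acquire_frame_cpp(base, shift[1], shift[2], offset, model$noise_sd)
      raw_frame(out, eye = eye, frame_index = k)
    })
  })
}
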