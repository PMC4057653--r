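#' Construct a pupil trace
#'
#' A pupil trace is the per-eye pupil dynamic waveform: a tibble of
#' per-frame ellipse parameters ordered by strictly increasing timestamp,
#' with a validity flag per sample. The nominal per-eye sampling rate is
#' capped at 75 Hz (full-resolution binocular acquisition alternates a
#' 150 fps camera between the eyes). Units are pixels (`major_px`,
#' `minor_px`) until converted with [to_mm()].
#'
#' @param df Tibble with columns `frame_index`, `timestamp_s`, `eye`,
#'   `center_x`, `center_y`, `major_px`/`major_mm`, `minor_px`/`minor_mm`,
#'   `orientation_rad`, `valid`, `fail_reason`.
#' @param sampling_rate_hz Nominal per-eye rate, <= 75.
#' @param units `"px"` or `"mm"`.
#' @param mm_per_px Calibration scale when `units = "mm"`.
#' @return A tibble of class `pupil_trace`.
#' @export
new_pupil_trace <- function(df, sampling_rate_hz = 75, units = "px",
                            mm_per_px = NA_real_) {
  if (!is_scalar_num(sampling_rate_hz) || sampling_rate_hz <= 0 ||
      sampling_rate_hz > 75) {
    abort("`sampling_rate_hz` must be in (0, 75]")
  }
  df <- as_tibble(df)
  ts <- df$timestamp_s
  if (length(ts) > 1 && any(diff(ts) <= 0)) {
    abort("timestamps must be strictly increasing")
  }
  structure(df,
            class = c("pupil_trace", class(tibble())),
            sampling_rate_hz = sampling_rate_hz,
            units = units,
            mm_per_px = mm_per_px)
}

trace_units <- function(trace) attr(trace, "units") %||% "px"

axis_cols <- function(trace) {
  if (trace_units(trace) == "mm") c("major_mm", "minor_mm") else c("major_px", "minor_px")
}

#' Demultiplex an alternating binocular frame stream
#'
#' The acquisition method illuminates the eyes interchangeably so a single
#' camera records an alternating left/right image stream. This splits the
#' stream into per-eye sequences using the frames' eye labels, or, for
#' unlabeled frames, a stated parity phase. Eye assignment is never
#' inferred from image content.
#'
#' @param frames List of [raw_frame()]s.
#' @param phase For unlabeled frames: `"even_left"` or `"even_right"`,
#'   assigning frames by the parity of their position in the stream
#'   (0-based).
#' @return `list(left = , right = )` of frame lists; every input frame is
#'   assigned to exactly one eye.
#' @export
demux_binocular <- function(frames, phase = NULL) {
  if (!is.list(frames) || length(frames) == 0) abort("`frames` must be a non-empty list")
  labels <- vapply(frames, function(f) {
    if (inherits(f, "raw_frame")) f$eye else "unknown"
  }, character(1))
  pos <- seq_along(frames) - 1L
  if (!is.null(phase)) {
    phase <- match.arg(phase, c("even_left", "even_right"))
    by_parity <- ifelse(pos %% 2L == 0L,
                        if (phase == "even_left") "left" else "right",
                        if (phase == "even_left") "right" else "left")
    conflict <- labels != "unknown" & labels != by_parity
    if (any(conflict)) {
      abort(paste0("eye labels conflict with parity phase at frame index(es): ",
                   paste(pos[conflict], collapse = ", ")))
    }
    assigned <- by_parity
  } else {
    if (any(labels == "unknown")) {
      abort(paste0("unlabeled frames and no `phase` given at frame index(es): ",
                   paste(pos[labels == "unknown"], collapse = ", ")))
    }
    assigned <- labels
  }
  relabel <- function(side) {
    fs <- frames[assigned == side]
    lapply(fs, function(f) { f$eye <- side; f })
  }
  list(left = relabel("left"), right = relabel("right"))
}

#' Remove blink artifacts from a pupil trace by neighbor averaging
#'
#' Samples flagged invalid by segmentation, and valid samples whose major
#' axis deviates from a centered moving average by more than 3 local
#' standard deviations, are replaced by the mean of the nearest valid
#' samples on either side (the nearest valid value alone for leading or
#' trailing gaps). The moving statistics use a window of `window_s`
#' seconds. The output contains no invalid samples; a clean trace is
#' returned unchanged and the operation is idempotent.
#'
#' @param trace A `pupil_trace`.
#' @param window_s Moving-average window in seconds (default 1).
#' @return A `pupil_trace` with invalid samples repaired and a logical
#'   `interpolated` column marking them.
#' @export
remove_blinks <- function(trace, window_s = 1) {
  if (!inherits(trace, "pupil_trace")) abort("`trace` must be a pupil_trace")
  if (nrow(trace) == 0) abort("no valid pupil samples")
  rate <- attr(trace, "sampling_rate_hz")
  acols <- axis_cols(trace)
  vcols <- c("center_x", "center_y", acols, "orientation_rad")

  x <- trace[[acols[1]]]
  bad <- !trace$valid | is.na(x)
  if (all(bad)) abort("no valid pupil samples")

  # 3-SD moving-average outlier guard on the axis length
  w <- max(3, 2 * floor(window_s * rate / 2) + 1)
  xs <- ifelse(bad, NA_real_, x)
  rs <- roll_stats(xs, w)
  out <- !bad & rs$n > 2 & !is.na(rs$sd) & rs$sd > 1e-9 &
    abs(x - rs$mean) > 3 * rs$sd
  bad <- bad | out
  if (all(bad)) abort("no valid pupil samples")
  if (!any(bad)) return(trace)

  good <- which(!bad)
  df <- as_tibble(trace)
  for (i in which(bad)) {
    lo <- good[good < i]; hi <- good[good > i]
    nb <- c(if (length(lo)) max(lo), if (length(hi)) min(hi))
    for (cn in vcols) {
      df[[cn]][i] <- mean(df[[cn]][nb])
    }
  }
  df$valid <- TRUE
  df$fail_reason <- NA_character_
  df$interpolated <- bad
  new_pupil_trace(df, sampling_rate_hz = rate, units = trace_units(trace),
                  mm_per_px = attr(trace, "mm_per_px"))
}

#' Convert a pupil trace from pixels to millimeters
#'
#' Multiplies the center coordinates and axis lengths by the calibration
#' scale (millimeters per pixel, obtained from [linear_resolution()] on a
#' phantom of known physical size). The telecentric imaging assumption
#' makes this scale constant across the frame. [to_px()] restores the
#' original pixel values exactly (the pixel columns are stashed in an
#' attribute, so the round trip is bit-identical).
#'
#' @param trace A `pupil_trace` in pixel units.
#' @param mm_per_px Millimeters per pixel (> 0).
#' @return A `pupil_trace` with columns `major_mm`, `minor_mm` and scaled
#'   centers.
#' @examples
#' \dontrun{to_mm(trace, mm_per_px = 0.0111)}
#' @export
to_mm <- function(trace, mm_per_px) {
  if (!inherits(trace, "pupil_trace")) abort("`trace` must be a pupil_trace")
  if (missing(mm_per_px) || is.null(mm_per_px) || !is_scalar_num(mm_per_px) ||
      mm_per_px <= 0) {
    abort("`mm_per_px` must be a positive number")
  }
  if (trace_units(trace) == "mm") abort("trace is already in millimeters")
  df <- as_tibble(trace)
  stash <- df[, c("center_x", "center_y", "major_px", "minor_px")]
  df$center_x <- df$center_x * mm_per_px
  df$center_y <- df$center_y * mm_per_px
  df$major_mm <- df$major_px * mm_per_px
  df$minor_mm <- df$minor_px * mm_per_px
  df$major_px <- NULL
  df$minor_px <- NULL
  df <- dplyr::relocate(df, "major_mm", "minor_mm", .after = "center_y")
  out <- new_pupil_trace(df, sampling_rate_hz = attr(trace, "sampling_rate_hz"),
                         units = "mm", mm_per_px = mm_per_px)
  attr(out, "px_values") <- stash
  out
}

#' @rdname to_mm
#' @export
to_px <- function(trace) {
  if (!inherits(trace, "pupil_trace")) abort("`trace` must be a pupil_trace")
  if (trace_units(trace) == "px") return(trace)
  s <- attr(trace, "mm_per_px")
  df <- as_tibble(trace)
  stash <- attr(trace, "px_values")
  if (!is.null(stash) && nrow(stash) == nrow(df)) {
    df$center_x <- stash$center_x
    df$center_y <- stash$center_y
    df$major_px <- stash$major_px
    df$minor_px <- stash$minor_px
  } else {
    df$center_x <- df$center_x / s
    df$center_y <- df$center_y / s
    df$major_px <- df$major_mm / s
    df$minor_px <- df$minor_mm / s
  }
  df$major_mm <- NULL
  df$minor_mm <- NULL
  df <- dplyr::relocate(df, "major_px", "minor_px", .after = "center_y")
  new_pupil_trace(df, sampling_rate_hz = attr(trace, "sampling_rate_hz"),
                  units = "px", mm_per_px = s)
}
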