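#' Median smoothing of a frame
#'
#' 5 x 5 median filtering is the first stage of the pupil analysis pipeline;
#' it suppresses impulse noise from ambient-light changes while preserving
#' the pupil edge. Borders are handled by edge replication.
#'
#' @param frame A [raw_frame()] or numeric 8-bit matrix.
#' @param window Odd window size, default 5.
#' @return Same type as the input.
#' @export
median_smooth <- function(frame, window = 5) {
  if (!is_count(window, min = 3) || window %% 2 == 0) {
    abort("`window` must be an odd count >= 3")
  }
  px <- frame_pixels(frame)
  rewrap_frame(median_filter_u8(px, as.integer(window)), frame)
}

#' Mean-intensity threshold from the image histogram
#'
#' The binarization threshold is the average image intensity, computed from
#' the 256-bin intensity histogram. On a mostly bright IR eye image (or a
#' black-on-white phantom) this places the pupil strictly below threshold.
#'
#' @param frame A [raw_frame()] or numeric matrix.
#' @return The threshold as a single intensity level.
#' @export
compute_threshold <- function(frame) {
  px <- frame_pixels(frame)
  if (length(px) == 0) abort("empty frame")
  counts <- intensity_hist(px)
  sum(counts * 0:255) / length(px)
}

#' Binarize a frame against a threshold
#'
#' Pixels strictly below the threshold are flagged as pupil candidates
#' (dark class). Bright reflections inside the pupil become holes at this
#' stage and are repaired by [close_and_fill()].
#'
#' @param frame A [raw_frame()] or numeric matrix.
#' @param threshold Intensity level in `[0, 255]`.
#' @return A logical matrix (`TRUE` = candidate pupil).
#' @export
binarize <- function(frame, threshold) {
  if (!is_scalar_num(threshold) || threshold < 0 || threshold > 255) {
    abort("`threshold` must be in [0, 255]")
  }
  frame_pixels(frame) < threshold
}

#' Close and fill the candidate pupil region
#'
#' Morphological closing with a disc structuring element (radius 5 px at
#' 1024 x 1024 scale, scaled proportionally for smaller frames), hole
#' filling (any background region not connected to the image border becomes
#' foreground), and selection of the largest connected component. This
#' repairs reflection holes and edge notches and discards stray specks.
#'
#' Morphology is evaluated on a padded crop around the candidate region and
#' mapped back, which is exact (the operations are local within the brush
#' radius) and much faster on large frames.
#'
#' @param mask Logical matrix from [binarize()].
#' @param brush_radius Disc radius in pixels; default scales with frame size.
#' @return Logical matrix; an empty input yields an empty mask flagged with
#'   attribute `empty = TRUE`.
#' @export
close_and_fill <- function(mask, brush_radius = NULL) {
  if (!is.matrix(mask) || !is.logical(mask)) abort("`mask` must be a logical matrix")
  if (!any(mask)) {
    attr(mask, "empty") <- TRUE
    return(mask)
  }
  h <- nrow(mask); w <- ncol(mask)
  r <- brush_radius %||% max(1, round(5 * min(h, w) / 1024))
  pad <- 2L * as.integer(r) + 2L
  ri <- range(which(rowSums(mask) > 0))
  ci <- range(which(colSums(mask) > 0))
  r0 <- max(1L, ri[1] - pad); r1 <- min(h, ri[2] + pad)
  c0 <- max(1L, ci[1] - pad); c1 <- min(w, ci[2] + pad)
  crop <- mask[r0:r1, c0:c1, drop = FALSE]

  brush <- EBImage::makeBrush(2L * as.integer(r) + 1L, shape = "disc")
  closed <- EBImage::closing(crop + 0, brush)
  filled <- EBImage::fillHull(closed)
  lab <- EBImage::bwlabel(filled)
  sizes <- tabulate(as.integer(lab))
  keep <- as.matrix(EBImage::imageData(lab)) == which.max(sizes)

  out <- matrix(FALSE, h, w)
  out[r0:r1, c0:c1] <- keep
  out
}

#' Extract the inner boundary of the pupil region
#'
#' Returns the centers of component pixels that have at least one 4-neighbor
#' outside the component (pixels on the image border count as boundary), in
#' continuous image coordinates. For a rasterized disk of diameter `d` the
#' extreme boundary-point span is `d - 1` pixel units, which is the
#' mechanism behind the systematic "fitted axis = drawn axis minus one"
#' behavior of the software validation test.
#'
#' @param mask Logical matrix with a single connected component.
#' @return A tibble with columns `x`, `y`.
#' @export
extract_boundary <- function(mask) {
  if (!is.matrix(mask) || !is.logical(mask)) abort("`mask` must be a logical matrix")
  if (!any(mask)) abort("no pupil found")
  # work on a one-pixel-padded crop of the occupied region; pixels at the
  # image border keep counting as boundary because the crop cannot extend
  # past the image
  ri <- range(which(rowSums(mask) > 0))
  ci <- range(which(colSums(mask) > 0))
  r0 <- max(1L, ri[1] - 1L); r1 <- min(nrow(mask), ri[2] + 1L)
  c0 <- max(1L, ci[1] - 1L); c1 <- min(ncol(mask), ci[2] + 1L)
  m <- mask[r0:r1, c0:c1, drop = FALSE]
  h <- nrow(m); w <- ncol(m)
  up <- rbind(m[-1, , drop = FALSE], FALSE)
  dn <- rbind(FALSE, m[-h, , drop = FALSE])
  lf <- cbind(m[, -1, drop = FALSE], FALSE)
  rt <- cbind(FALSE, m[, -w, drop = FALSE])
  bd <- m & !(up & dn & lf & rt)
  idx <- which(bd, arr.ind = TRUE)
  tibble(x = unname(idx[, 2]) + (c0 - 1L) - 0.5,
         y = unname(idx[, 1]) + (r0 - 1L) - 0.5)
}

#' Segment the pupil in one frame
#'
#' Runs the full analysis pipeline: median smoothing, mean-intensity
#' thresholding, binarization, closing/filling with largest-component
#' selection, inner-boundary extraction and least-squares ellipse fitting.
#' Any stage failure (all-bright frame, occluded pupil, degenerate fit)
#' yields an invalid [pupil_ellipse()] with a reason rather than an error,
#' so sequence processing continues across blinks.
#'
#' Plausibility guards reject masks smaller than 25 px or covering more than
#' half the frame (an eyelid-occluded frame binarizes to either nothing or a
#' noise blob); such frames report `"no pupil found"`.
#'
#' @param frame A [raw_frame()] or numeric matrix.
#' @param window Median filter window (odd).
#' @param keep_intermediates If `TRUE`, attach the smoothed frame, threshold,
#'   masks and boundary as attribute `"intermediates"` for diagnostics.
#' @return A [pupil_ellipse()].
#' @examples
#' seg <- segment_pupil(render_phantom(phantom_spec("circle", 119)))
#' round(c(seg$major_px, seg$minor_px))
#' @export
segment_pupil <- function(frame, window = 5, keep_intermediates = FALSE) {
  res <- tryCatch({
    sm <- median_smooth(frame, window)
    th <- compute_threshold(sm)
    bin <- binarize(sm, th)
    mask <- close_and_fill(bin)
    area <- sum(mask)
    if (area < 25 || area > 0.5 * length(mask)) {
      ell <- invalid_pupil_ellipse("no pupil found")
      bnd <- NULL
    } else {
      bnd <- extract_boundary(mask)
      ell <- fit_ellipse(bnd)
      if (ell$valid && boundary_rms_residual(bnd, ell) > 0.15) {
        # ragged boundary far from any ellipse: occlusion/noise, not a pupil
        ell <- invalid_pupil_ellipse("no pupil found")
      }
    }
    if (keep_intermediates) {
      attr(ell, "intermediates") <- list(
        smoothed = sm, threshold = th, binary = bin, mask = mask,
        boundary = bnd)
    }
    ell
  }, error = function(e) invalid_pupil_ellipse(conditionMessage(e)))
  res
}

# Normalized radial RMS residual of boundary points against a fitted
# ellipse; ~0.01 for a rasterized pupil edge, large for noise blobs.
boundary_rms_residual <- function(bnd, ell) {
  th <- ell$orientation_rad
  dx <- bnd$x - ell$center_x
  dy <- bnd$y - ell$center_y
  xr <- cos(th) * dx + sin(th) * dy
  yr <- -sin(th) * dx + cos(th) * dy
  v <- sqrt((xr / (ell$major_px / 2))^2 + (yr / (ell$minor_px / 2))^2)
  sqrt(mean((v - 1)^2))
}

#' Segment a frame sequence into a pupil trace
#'
#' Applies [segment_pupil()] to each frame and assembles the per-frame
#' ellipse parameters into a tidy pupil trace. Missing timestamps are
#' synthesized from `rate_hz` (frame 0 at t = 0).
#'
#' @param frames List of [raw_frame()]s.
#' @param rate_hz Nominal per-eye sampling rate (<= 75), used for missing
#'   timestamps and stored as a trace attribute.
#' @param window Median filter window.
#' @return A `pupil_trace` tibble (see [new_pupil_trace()]).
#' @export
segment_frames <- function(frames, rate_hz = 75, window = 5) {
  if (!is.list(frames) || length(frames) == 0) abort("`frames` must be a non-empty list")
  rows <- purrr::imap(frames, function(f, i) {
    ell <- segment_pupil(f, window = window)
    idx <- if (inherits(f, "raw_frame") && !is.na(f$frame_index)) f$frame_index else i - 1L
    ts <- if (inherits(f, "raw_frame") && !is.na(f$timestamp_s)) f$timestamp_s else idx / rate_hz
    eye <- if (inherits(f, "raw_frame")) f$eye else "unknown"
    dplyr::bind_cols(tibble(frame_index = as.integer(idx), timestamp_s = ts,
                            eye = eye), tidy(ell))
  })
  new_pupil_trace(dplyr::bind_rows(rows), sampling_rate_hz = rate_hz)
}
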