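#' Construct a raw acquisition frame
#'
#' A `raw_frame` is the unit of acquisition: one 8-bit grayscale image with
#' an eye label, a timestamp and a frame index. Pixel `(i, j)` (0-based) has
#' its center at continuous image coordinates `(x = j + 0.5, y = i + 0.5)`;
#' this convention is shared by the phantom renderer and the boundary
#' extractor. In the backing R matrix, rows index `y` and columns index `x`.
#'
#' @param pixels Numeric matrix of intensities in `[0, 255]`, at least
#'   64 x 64.
#' @param eye One of `"left"`, `"right"`, `"unknown"`.
#' @param timestamp_s Acquisition time in seconds (may be `NA`).
#' @param frame_index Zero-based frame counter (may be `NA`).
#' @return An object of class `raw_frame`.
#' @examples
#' f <- raw_frame(matrix(255, 64, 64))
#' dim(f$pixels)
#' @export
raw_frame <- function(pixels, eye = c("unknown", "left", "right"),
                      timestamp_s = NA_real_, frame_index = NA_integer_) {
  eye <- match.arg(eye)
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    abort("`pixels` must be a numeric matrix")
  }
  if (nrow(pixels) < 64 || ncol(pixels) < 64) {
    abort("frame dimensions must be at least 64 x 64")
  }
  rng <- range(pixels)
  if (is.na(rng[1]) || rng[1] < 0 || rng[2] > 255) {
    abort("pixel intensities must lie in [0, 255]")
  }
  structure(
    list(pixels = pixels, eye = eye,
         timestamp_s = as.numeric(timestamp_s),
         frame_index = as.integer(frame_index)),
    class = "raw_frame"
  )
}

#' @export
print.raw_frame <- function(x, ...) {
  cat(sprintf("<raw_frame> %d x %d, eye=%s, index=%s, t=%s s\n",
              ncol(x$pixels), nrow(x$pixels), x$eye,
              ifelse(is.na(x$frame_index), "?", x$frame_index),
              ifelse(is.na(x$timestamp_s), "?", format(x$timestamp_s))))
  invisible(x)
}

# Accept either a raw_frame or a bare matrix; return the pixel matrix.
frame_pixels <- function(frame) {
  if (inherits(frame, "raw_frame")) frame$pixels
  else if (is.matrix(frame) && is.numeric(frame)) frame
  else abort("expected a `raw_frame` or a numeric matrix")
}

# Rebuild a frame carrying over metadata from `template` when present.
rewrap_frame <- function(pixels, template) {
  if (inherits(template, "raw_frame")) {
    raw_frame(pixels, eye = template$eye, timestamp_s = template$timestamp_s,
              frame_index = template$frame_index)
  } else {
    pixels
  }
}
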