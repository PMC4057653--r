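# Image, trace and configuration I/O.

#' Write and read 8-bit grayscale BMP images
#'
#' Minimal palette-BMP codec for the acquisition storage format (8-bit,
#' uncompressed, bottom-up rows padded to 4 bytes, 256-entry gray palette).
#' No installed package handles BMP, so the format is implemented here.
#'
#' @param pixels Numeric matrix of intensities in `[0, 255]` (rows = y,
#'   columns = x) or a [raw_frame()].
#' @param path File path.
#' @return `write_bmp` returns `path` invisibly; `read_bmp` returns an
#'   integer-valued numeric matrix.
#' @export
write_bmp <- function(pixels, path) {
  m <- round(frame_pixels(pixels))
  h <- nrow(m); w <- ncol(m)
  row_bytes <- 4L * ceiling(w / 4L)
  data_size <- row_bytes * h
  off <- 14L + 40L + 256L * 4L
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("BM"), con)
  writeBin(as.integer(off + data_size), con, size = 4, endian = "little")
  writeBin(0L, con, size = 4, endian = "little")
  writeBin(as.integer(off), con, size = 4, endian = "little")
  writeBin(40L, con, size = 4, endian = "little")            # BITMAPINFOHEADER
  writeBin(as.integer(w), con, size = 4, endian = "little")
  writeBin(as.integer(h), con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")             # planes
  writeBin(8L, con, size = 2, endian = "little")             # bits per pixel
  writeBin(0L, con, size = 4, endian = "little")             # BI_RGB
  writeBin(as.integer(data_size), con, size = 4, endian = "little")
  writeBin(2835L, con, size = 4, endian = "little")          # 72 dpi
  writeBin(2835L, con, size = 4, endian = "little")
  writeBin(256L, con, size = 4, endian = "little")
  writeBin(0L, con, size = 4, endian = "little")
  pal <- as.raw(rbind(0:255, 0:255, 0:255, rep(0L, 256)))    # B G R 0
  writeBin(pal, con)
  pad <- raw(row_bytes - w)
  for (i in h:1) {                                           # bottom-up
    writeBin(c(as.raw(m[i, ]), pad), con)
  }
  invisible(path)
}

#' @rdname write_bmp
#' @export
read_bmp <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 54 || rawToChar(raw[1:2]) != "BM") abort("not a BMP file")
  u32 <- function(i) sum(as.integer(raw[i:(i + 3)]) * 256^(0:3))
  u16 <- function(i) sum(as.integer(raw[i:(i + 1)]) * 256^(0:1))
  off <- u32(11)
  w <- u32(19); h <- u32(23)
  bpp <- u16(29); comp <- u32(31)
  if (bpp != 8 || comp != 0) abort("only uncompressed 8-bit BMP is supported")
  n_pal <- u32(47); if (n_pal == 0) n_pal <- 256
  pal <- matrix(as.integer(raw[55:(54 + 4 * n_pal)]), nrow = 4)  # B G R 0
  gray <- if (all(pal[1, ] == pal[3, ])) pal[3, ] else {
    warn("non-gray BMP palette; converting by channel mean")
    round(colMeans(pal[1:3, ]))
  }
  row_bytes <- 4L * ceiling(w / 4L)
  m <- matrix(0, h, w)
  for (i in seq_len(h)) {
    start <- off + (i - 1L) * row_bytes
    m[h - i + 1L, ] <- gray[as.integer(raw[(start + 1):(start + w)]) + 1L]
  }
  m
}

#' Write and read single frames by extension
#'
#' Dispatches on the file extension: `.bmp` (package codec) or `.png`
#' (via the png package). Color PNGs are converted to grayscale with a
#' warning.
#'
#' @param frame A [raw_frame()] or matrix.
#' @param path File path ending in `.bmp` or `.png`.
#' @return `read_frame` returns a numeric matrix.
#' @export
write_frame <- function(frame, path) {
  ext <- tolower(tools::file_ext(path))
  px <- round(frame_pixels(frame))
  switch(ext,
         bmp = write_bmp(px, path),
         png = png::writePNG(px / 255, path),
         abort(sprintf("unsupported image format '.%s'", ext)))
  invisible(path)
}

#' @rdname write_frame
#' @export
read_frame <- function(path) {
  ext <- tolower(tools::file_ext(path))
  m <- switch(ext,
              bmp = read_bmp(path),
              png = {
                a <- png::readPNG(path)
                if (length(dim(a)) == 3) {
                  warn("color image converted to grayscale")
                  a <- apply(a[, , 1:min(3, dim(a)[3]), drop = FALSE], c(1, 2), mean)
                }
                round(a * 255)
              },
              abort(sprintf("unsupported image format '.%s'", ext)))
  m
}

frame_filename <- function(prefix, eye, index, ext) {
  sprintf("%s_%s_%05d.%s", prefix, eye, index, ext)
}

#' Write a frame sequence to a directory
#'
#' Files follow the canonical naming schema
#' `<prefix>_<eye>_<index>.<ext>` with the index zero-padded to 5 digits.
#'
#' @param frames List of [raw_frame()]s.
#' @param dir Output directory (created if missing).
#' @param prefix Filename prefix.
#' @param format `"bmp"` or `"png"`.
#' @return Character vector of written paths, invisibly.
#' @export
write_frames <- function(frames, dir, prefix = "frame", format = c("bmp", "png")) {
  format <- match.arg(format)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- purrr::imap_chr(frames, function(f, i) {
    idx <- if (inherits(f, "raw_frame") && !is.na(f$frame_index)) f$frame_index else i - 1L
    eye <- if (inherits(f, "raw_frame")) f$eye else "unknown"
    p <- file.path(dir, frame_filename(prefix, eye, idx, format))
    write_frame(f, p)
    p
  })
  invisible(paths)
}

#' Read a frame sequence
#'
#' Accepts a directory or a glob pattern; frames are ordered by the index
#' encoded in their filenames, with eye labels parsed from the names. All
#' frames must share one image size.
#'
#' @param path Directory or glob (e.g. `"frames/run1_*.bmp"`).
#' @return List of [raw_frame()]s.
#' @export
read_frames <- function(path) {
  files <- if (length(path) == 1 && dir.exists(path)) {
    list.files(path, pattern = "\\.(bmp|png)$", full.names = TRUE,
               ignore.case = TRUE)
  } else {
    Sys.glob(path)
  }
  if (length(files) == 0) abort("no frames found")
  info <- regmatches(basename(files),
                     regexec("^(.*)_(left|right|unknown)_([0-9]+)\\.(bmp|png)$",
                             basename(files), ignore.case = TRUE))
  eye <- vapply(info, function(x) if (length(x)) tolower(x[3]) else "unknown",
                character(1))
  idx <- vapply(info, function(x) if (length(x)) as.integer(x[4]) else NA_integer_,
                integer(1))
  if (anyNA(idx)) idx[is.na(idx)] <- seq_len(sum(is.na(idx))) - 1L
  ord <- order(idx)
  frames <- purrr::map(ord, function(i) {
    m <- read_frame(files[i])
    raw_frame(m, eye = eye[i], frame_index = idx[i])
  })
  dims <- vapply(frames, function(f) paste(dim(f$pixels), collapse = "x"),
                 character(1))
  if (length(unique(dims)) > 1) abort("frames have mixed dimensions")
  frames
}

#' Write and read pupil traces as CSV
#'
#' The trace schema is `frame_index, timestamp_s, eye, center_x, center_y,
#' major_px, minor_px, orientation_rad, valid, fail_reason` (axis columns
#' are `_mm` after [to_mm()]). Values round-trip exactly; the decimal
#' separator is always `"."` regardless of locale.
#'
#' @param trace A `pupil_trace`.
#' @param path CSV path.
#' @param sampling_rate_hz Nominal rate to attach on read.
#' @return `read_trace` returns a `pupil_trace`.
#' @export
write_trace <- function(trace, path) {
  readr::write_csv(as_tibble(trace), path, na = "")
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path, sampling_rate_hz = 75) {
  df <- readr::read_csv(path, show_col_types = FALSE, na = "",
                        progress = FALSE)
  if (nrow(df) > 0) {
    df$frame_index <- as.integer(df$frame_index)
    df$eye <- as.character(df$eye)
    df$fail_reason <- as.character(df$fail_reason)
    df$valid <- as.logical(df$valid)
  }
  units <- if ("major_mm" %in% names(df)) "mm" else "px"
  new_pupil_trace(df, sampling_rate_hz = sampling_rate_hz, units = units)
}

run_config_keys <- c("seed", "out_dir", "log_level", "phantom", "acquisition",
                     "stimulus", "model", "validation")

#' Read and write run configurations
#'
#' A run configuration holds command-specific parameter blocks (`phantom`,
#' `acquisition`, `stimulus`, `model`, `validation`) plus a global `seed`,
#' `out_dir` and `log_level`. JSON and YAML are supported, chosen by
#' extension; unknown keys are rejected, and configurations round-trip
#' losslessly.
#'
#' @param path `.json`, `.yaml` or `.yml` file.
#' @return `read_run_config` returns a named list of class `run_config`.
#' @export
read_run_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  cfg <- switch(ext,
                json = jsonlite::fromJSON(path, simplifyVector = TRUE),
                yaml = ,
                yml = yaml::read_yaml(path),
                abort(sprintf("unsupported config format '.%s'", ext)))
  unknown <- setdiff(names(cfg), run_config_keys)
  if (length(unknown)) {
    abort(paste0("unknown configuration key(s): ", paste(unknown, collapse = ", ")))
  }
  structure(cfg, class = "run_config")
}

#' @rdname read_run_config
#' @param config A `run_config` or plain named list.
#' @export
write_run_config <- function(config, path) {
  cfg <- unclass(config)
  unknown <- setdiff(names(cfg), run_config_keys)
  if (length(unknown)) {
    abort(paste0("unknown configuration key(s): ", paste(unknown, collapse = ", ")))
  }
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         json = jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA,
                                     null = "null"),
         yaml = ,
         yml = yaml::write_yaml(cfg, path),
         abort(sprintf("unsupported config format '.%s'", ext)))
  invisible(path)
}

#' Serialize phantom and acquisition descriptions
#'
#' [phantom_spec()] and [acquisition_model()] objects can be written to and
#' re-read from JSON or YAML (by extension) without loss.
#'
#' @param x A `phantom_spec` or `acquisition_model`.
#' @param path `.json`, `.yaml` or `.yml` file.
#' @return `read_phantom_spec` / `read_acquisition_model` return the
#'   reconstructed object.
#' @export
write_spec <- function(x, path) {
  lst <- if (inherits(x, "phantom_spec")) {
    l <- unclass(x)
    if (!is.null(l$reflection)) l$reflection <- purrr::compact(unclass(l$reflection))
    l
  } else if (inherits(x, "acquisition_model")) {
    unclass(x)
  } else {
    abort("`x` must be a phantom_spec or acquisition_model")
  }
  lst <- purrr::compact(lst)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         json = jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA),
         yaml = ,
         yml = yaml::write_yaml(lst, path),
         abort(sprintf("unsupported format '.%s'", ext)))
  invisible(path)
}

read_spec_list <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         json = jsonlite::fromJSON(path, simplifyVector = TRUE),
         yaml = ,
         yml = yaml::read_yaml(path),
         abort(sprintf("unsupported format '.%s'", ext)))
}

#' @rdname write_spec
#' @export
read_phantom_spec <- function(path) {
  l <- read_spec_list(path)
  for (k in c("image_size", "center")) {
    if (!is.null(l[[k]])) l[[k]] <- as.numeric(unlist(l[[k]]))
  }
  if (!is.null(l$reflection)) {
    r <- l$reflection
    ctr <- as.numeric(unlist(r$center))
    r$center <- if (length(ctr)) ctr else NULL
    l$reflection <- do.call(reflection_spot, r)
  }
  do.call(phantom_spec, l)
}

#' @rdname write_spec
#' @export
read_acquisition_model <- function(path) {
  do.call(acquisition_model, read_spec_list(path))
}
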