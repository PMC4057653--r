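#' The software-test phantom set
#'
#' The 16 phantoms of the analysis-software test: six circles (119 to 321
#' px) and two ellipse families of five — one with the major axis on the
#' horizontal screen axis, one with it on the vertical ("major axis less
#' than minor axis" in screen terms).
#'
#' @return A tibble with columns `phantom`, `shape`, `major_axis_px`,
#'   `minor_axis_px`, `orientation`.
#' @export
table1_phantoms <- function() {
  circles <- c(119, 160, 201, 242, 283, 321)
  pairs <- cbind(major = c(160, 201, 242, 283, 321),
                 minor = c(119, 160, 201, 242, 283))
  dplyr::bind_rows(
    tibble(phantom = paste0("circle_", circles), shape = "circle",
           major_axis_px = circles, minor_axis_px = circles,
           orientation = "horizontal"),
    tibble(phantom = paste0("ellipse_v_", pairs[, "minor"], "x", pairs[, "major"]),
           shape = "ellipse", major_axis_px = pairs[, "major"],
           minor_axis_px = pairs[, "minor"], orientation = "vertical"),
    tibble(phantom = paste0("ellipse_h_", pairs[, "major"], "x", pairs[, "minor"]),
           shape = "ellipse", major_axis_px = pairs[, "major"],
           minor_axis_px = pairs[, "minor"], orientation = "horizontal")
  )
}

#' The printed-phantom set of the acquisition experiment
#'
#' Six circular phantoms with microscope-measured physical diameters and
#' their sizes on the sensor in pixels. These printed values calibrate the
#' linear resolution (millimeters per pixel) of the imaging chain.
#'
#' @return A tibble with columns `true_size_mm`, `size_px`.
#' @export
table2_phantoms <- function() {
  tibble(true_size_mm = c(3.01, 3.96, 4.90, 5.83, 6.78, 7.70),
         size_px = c(271, 356, 441, 525, 610, 693))
}

#' Run the analysis-software test on noise-free phantoms
#'
#' Renders every phantom of the software-test set (plain and, optionally, a
#' variant with a central reflection spot), runs the full segmentation
#' pipeline on each, and reports fitted axes (continuous and rounded to
#' integer pixels) with relative errors against the drawn sizes. The
#' closing/filling stage must make the reflection variant yield the same
#' rounded axes as the plain one.
#'
#' @param phantoms Tibble as returned by [table1_phantoms()].
#' @param with_reflection Also run the reflection-spot variant of each
#'   phantom (default `TRUE`).
#' @param reflection_radius_px Spot radius for the reflection variants.
#' @param image_size Rendered image size.
#' @return A tibble, one row per phantom, with attribute
#'   `max_rel_error_percent` (computed from the rounded axes).
#' @export
software_test <- function(phantoms = table1_phantoms(), with_reflection = TRUE,
                          reflection_radius_px = 8, image_size = c(1024, 1024)) {
  rows <- purrr::pmap(phantoms, function(phantom, shape, major_axis_px,
                                          minor_axis_px, orientation) {
    spec <- phantom_spec(shape, major_axis_px, minor_axis_px,
                         orientation = orientation, image_size = image_size)
    fit <- segment_pupil(render_phantom(spec))
    out <- tibble(
      phantom = phantom, shape = shape,
      true_major_px = major_axis_px, true_minor_px = minor_axis_px,
      fitted_major_px = fit$major_px, fitted_minor_px = fit$minor_px,
      major_round = round(fit$major_px), minor_round = round(fit$minor_px),
      valid = fit$valid
    )
    if (with_reflection) {
      rspec <- phantom_spec(shape, major_axis_px, minor_axis_px,
                            orientation = orientation, image_size = image_size,
                            reflection = reflection_spot(reflection_radius_px))
      rfit <- segment_pupil(render_phantom(rspec))
      out$refl_major_round <- round(rfit$major_px)
      out$refl_minor_round <- round(rfit$minor_px)
      out$refl_valid <- rfit$valid
    }
    out
  })
  res <- dplyr::bind_rows(rows)
  res <- dplyr::mutate(
    res,
    rel_err_major_percent = abs(.data$major_round - .data$true_major_px) /
      .data$true_major_px * 100,
    rel_err_minor_percent = abs(.data$minor_round - .data$true_minor_px) /
      .data$true_minor_px * 100
  )
  attr(res, "max_rel_error_percent") <-
    max(res$rel_err_major_percent, res$rel_err_minor_percent)
  res
}

#' Accuracy and repeatability from per-run mean sizes
#'
#' Accuracy is the absolute difference between the (rounded) overall mean
#' measured size and the true size, relative to the true size, in percent.
#' Repeatability is the standard deviation of the run means relative to
#' their mean, in percent. Both are invariant under relabeling of the
#' runs.
#'
#' @param run_means Numeric vector of per-run mean sizes.
#' @param true_px True size in pixels.
#' @param round_mean Round the overall mean to the integer pixel grid
#'   before comparing (the reporting convention for sizes).
#' @return A percentage.
#' @export
accuracy_percent <- function(run_means, true_px, round_mean = TRUE) {
  m <- mean(run_means)
  if (round_mean) m <- round(m)
  abs(m - true_px) / true_px * 100
}

#' @rdname accuracy_percent
#' @export
repeatability_percent <- function(run_means) {
  sd(run_means) / mean(run_means) * 100
}

#' Repeatability experiment for one phantom
#'
#' Simulates the acquisition protocol: the phantom's image sequence is
#' "recorded" `runs` times, `frames_per_run` frames each, under the given
#' acquisition noise model (run `r` uses seed `model$seed + r`). Every
#' frame is segmented; per run the mean and SD of the fitted sizes are
#' computed, and across runs the mean of means, the SD of means, the
#' accuracy and the repeatability, per axis. Runs with more than 10%
#' invalid frames are flagged.
#'
#' @param spec A [phantom_spec()].
#' @param model An [acquisition_model()]; its seed anchors all
#'   randomization.
#' @param runs Number of repeated recordings (default 5).
#' @param frames_per_run Frames per recording (default 100).
#' @param pooled_repeatability Also report the pooled per-frame SD variant
#'   of repeatability.
#' @return An object of class `repeatability_result` with elements `runs`
#'   (per-run stats) and `summary` (per-axis accuracy/repeatability).
#' @export
repeatability_experiment <- function(spec, model = acquisition_model(seed = 1),
                                     runs = 5, frames_per_run = 100,
                                     pooled_repeatability = FALSE) {
  if (!is_count(runs) || !is_count(frames_per_run)) {
    abort("`runs` and `frames_per_run` must be positive counts")
  }
  base_seed <- model$seed %||% 0L
  source_frame <- render_phantom(spec)
  per_run <- purrr::map(seq_len(runs), function(r) {
    m <- model
    m$seed <- as.integer(base_seed + r)
    frames <- simulate_acquisition(source_frame, m, frames_per_run)
    fits <- purrr::map(frames, segment_pupil)
    ok <- vapply(fits, function(f) f$valid, logical(1))
    maj <- vapply(fits, function(f) f$major_px %||% NA_real_, numeric(1))
    mnr <- vapply(fits, function(f) f$minor_px %||% NA_real_, numeric(1))
    tibble(run = r,
           axis = c("major", "minor"),
           mean_px = c(mean(maj[ok]), mean(mnr[ok])),
           sd_px = c(sd(maj[ok]), sd(mnr[ok])),
           n_frames = frames_per_run,
           n_invalid = sum(!ok),
           flagged = sum(!ok) > 0.1 * frames_per_run)
  })
  run_tbl <- dplyr::bind_rows(per_run)

  true_axes <- c(major = spec$major_axis_px, minor = spec$minor_axis_px)
  summary <- run_tbl |>
    dplyr::group_by(.data$axis) |>
    dplyr::summarise(
      overall_mean_px = mean(.data$mean_px),
      sd_of_means_px = sd(.data$mean_px),
      mean_within_run_sd_px = mean(.data$sd_px),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      true_px = unname(true_axes[.data$axis]),
      accuracy_percent = purrr::map_dbl(
        .data$axis, ~ accuracy_percent(
          run_tbl$mean_px[run_tbl$axis == .x], true_axes[.x])),
      repeatability_percent = purrr::map_dbl(
        .data$axis, ~ repeatability_percent(run_tbl$mean_px[run_tbl$axis == .x]))
    )
  if (pooled_repeatability) {
    summary$pooled_repeatability_percent <- purrr::map_dbl(
      summary$axis,
      function(a) {
        sub <- run_tbl[run_tbl$axis == a, ]
        sqrt(mean(sub$sd_px^2)) / mean(sub$mean_px) * 100
      })
  }
  structure(
    list(spec = spec, model = model, runs = run_tbl, summary = summary,
         mm_per_px = if (!is.null(spec$true_size_mm)) {
           linear_resolution(spec$true_size_mm,
                             mean(summary$overall_mean_px))
         } else NA_real_),
    class = "repeatability_result"
  )
}

#' @rdname repeatability_experiment
#' @param x A `repeatability_result`.
#' @param ... Unused.
#' @export
glance.repeatability_result <- function(x, ...) {
  tibble(
    true_major_px = x$spec$major_axis_px,
    true_minor_px = x$spec$minor_axis_px,
    true_size_mm = x$spec$true_size_mm %||% NA_real_,
    overall_mean_px = mean(x$summary$overall_mean_px),
    max_accuracy_percent = max(x$summary$accuracy_percent),
    max_repeatability_percent = max(x$summary$repeatability_percent),
    mm_per_px = x$mm_per_px,
    n_flagged_runs = sum(x$runs$flagged) / 2
  )
}

#' @export
print.repeatability_result <- function(x, ...) {
  cat(sprintf("<repeatability_result> phantom %g x %g px, %d runs x %d frames\n",
              x$spec$major_axis_px, x$spec$minor_axis_px,
              max(x$runs$run), x$runs$n_frames[1]))
  print(x$summary)
  invisible(x)
}

#' Linear resolution of the imaging chain
#'
#' The calibration scale is the ratio of the phantom's physical size in
#' millimeters to its measured size in pixels. Under the telecentric
#' imaging assumption this ratio is constant across the frame, and twice
#' the ratio bounds the smallest resolvable size change.
#'
#' @param true_mm Physical size in millimeters (> 0).
#' @param measured_px Measured size in pixels (> 0).
#' @return Millimeters per pixel.
#' @examples
#' linear_resolution(3.01, 271)  # ~0.0111
#' @export
linear_resolution <- function(true_mm, measured_px) {
  if (any(!is.finite(true_mm)) || any(true_mm <= 0)) abort("`true_mm` must be > 0")
  if (any(!is.finite(measured_px)) || any(measured_px <= 0)) {
    abort("`measured_px` must be > 0")
  }
  true_mm / measured_px
}

#' Run the full acquisition validation protocol
#'
#' Applies [repeatability_experiment()] to each phantom of the printed set
#' (or any set of specs), collecting per-phantom accuracy, repeatability
#' and millimeter-per-pixel calibration into a validation report.
#'
#' @param phantoms Tibble with columns `size_px` and optionally
#'   `true_size_mm` (default [table2_phantoms()]).
#' @param model An [acquisition_model()].
#' @param runs,frames_per_run Protocol size (defaults 5 x 100).
#' @param image_size Rendered frame size.
#' @return A tibble of class `validation_report`, one row per phantom,
#'   with attributes `max_accuracy_percent`, `max_repeatability_percent`
#'   and `resolution_mm`.
#' @export
validate_system <- function(phantoms = table2_phantoms(),
                            model = acquisition_model(seed = 1),
                            runs = 5, frames_per_run = 100,
                            image_size = c(1024, 1024)) {
  rows <- purrr::pmap(phantoms, function(size_px, true_size_mm = NULL, ...) {
    spec <- phantom_spec("circle", size_px, image_size = image_size,
                         true_size_mm = true_size_mm)
    glance(repeatability_experiment(spec, model, runs, frames_per_run))
  })
  rep <- dplyr::bind_rows(rows)
  structure(rep,
            class = c("validation_report", class(tibble())),
            max_accuracy_percent = max(rep$max_accuracy_percent),
            max_repeatability_percent = max(rep$max_repeatability_percent),
            resolution_mm = if (all(is.finite(rep$mm_per_px))) {
              2 * max(rep$mm_per_px)
            } else NA_real_,
            runs = runs, frames_per_run = frames_per_run,
            seed = model$seed)
}
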