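test_that("median smoothing matches the exhaustive sort-and-pick oracle", {
  const <- matrix(37, 64, 64)
  expect_identical(median_smooth(const), const)

  salt <- matrix(0, 64, 64)
  salt[20, 30] <- 255
  expect_true(all(median_smooth(salt) == 0))

  set.seed(5)
  img <- matrix(sample(0:255, 32 * 32, replace = TRUE), 32, 32)
  for (w in c(3, 5)) {
    expect_identical(median_smooth(img, w), brute_median(img, w))
  }
  expect_error(median_smooth(img, 4), "odd")
  expect_error(median_smooth(img, 1), "odd")
})

test_that("the threshold is the histogram-weighted mean intensity", {
  expect_identical(compute_threshold(matrix(10, 64, 64)), 10)
  half <- matrix(c(0, 200), 64, 64)
  expect_identical(compute_threshold(half), 100)
  phantom <- render_phantom(phantom_spec("circle", 119))
  expect_lt(abs(compute_threshold(phantom) - mean(phantom$pixels)), 0.5)
})

test_that("binarization selects the strictly-below-threshold dark class", {
  white <- matrix(255, 64, 64)
  expect_false(any(binarize(white, compute_threshold(white))))
  expect_false(any(binarize(matrix(0, 64, 64), 0)))  # strict inequality

  spec <- phantom_spec("circle", 119, reflection = reflection_spot(8))
  frame <- render_phantom(spec)
  mask <- binarize(frame, compute_threshold(frame))
  expect_identical(mask, frame$pixels == 0)  # dark disk minus the spot
})

test_that("closing and filling repairs holes, keeps the largest component", {
  spec <- phantom_spec("circle", 119, reflection = reflection_spot(8))
  holey <- render_phantom(spec)$pixels == 0
  solid <- render_phantom(phantom_spec("circle", 119))$pixels == 0
  expect_identical(close_and_fill(holey), solid)
  expect_identical(close_and_fill(solid), solid)  # idempotent on solid disks

  speck <- solid
  speck[50:51, 50] <- TRUE  # distant 2-px speck
  expect_identical(close_and_fill(speck), solid)

  empty <- matrix(FALSE, 64, 64)
  out <- close_and_fill(empty)
  expect_false(any(out))
  expect_true(isTRUE(attr(out, "empty")))
})

test_that("the inner boundary has the expected point set", {
  sq <- matrix(FALSE, 64, 64)
  sq[11:13, 21:23] <- TRUE
  b <- extract_boundary(sq)
  expect_identical(nrow(b), 8L)  # all but the center of a 3x3 square
  expect_false(any(b$x == 21.5 & b$y == 11.5))

  one <- matrix(FALSE, 64, 64); one[5, 6] <- TRUE
  b1 <- extract_boundary(one)
  expect_equal(c(b1$x, b1$y), c(5.5, 4.5))

  disk <- render_phantom(phantom_spec("circle", 119))$pixels == 0
  bd <- extract_boundary(disk)
  expect_identical(diff(range(bd$x)), 118)
  expect_identical(diff(range(bd$y)), 118)

  expect_error(extract_boundary(matrix(FALSE, 64, 64)), "no pupil found")
})

test_that("full pipeline reproduces drawn phantom axes minus one pixel", {
  fit <- segment_pupil(render_phantom(phantom_spec("ellipse", 160, 119)))
  expect_identical(round(fit$major_px), 159)
  expect_identical(round(fit$minor_px), 118)

  blank <- segment_pupil(matrix(255, 256, 256))
  expect_false(blank$valid)
  expect_match(blank$fail_reason, "no pupil found")
})

test_that("a fully interior reflection spot barely moves the fit", {
  plain <- segment_pupil(render_phantom(phantom_spec("circle", 119)))
  refl <- segment_pupil(render_phantom(
    phantom_spec("circle", 119, reflection = reflection_spot(8))))
  expect_lt(abs(plain$major_px - refl$major_px), 0.5)
  expect_lt(abs(plain$minor_px - refl$minor_px), 0.5)
})

test_that("segmentation is equivariant under translation and 90-degree rotation", {
  spec0 <- phantom_spec("ellipse", 90, 61, center = c(120.5, 110.5),
                        image_size = c(256, 256))
  spec1 <- phantom_spec("ellipse", 90, 61, center = c(120.5 + 17, 110.5 + 9),
                        image_size = c(256, 256))
  f0 <- segment_pupil(render_phantom(spec0))
  f1 <- segment_pupil(render_phantom(spec1))
  expect_equal(f1$center_x - f0$center_x, 17, tolerance = 1e-8)
  expect_equal(f1$center_y - f0$center_y, 9, tolerance = 1e-8)
  expect_equal(f1$major_px, f0$major_px, tolerance = 1e-8)

  # rotate the image by 90 degrees: x' = y, so major/minor roles swap axes
  m <- render_phantom(spec0)$pixels
  rot <- t(m)[, nrow(m):1]
  fr <- segment_pupil(rot)
  expect_equal(fr$major_px, f0$major_px, tolerance = 1e-6)
  expect_equal(fr$minor_px, f0$minor_px, tolerance = 1e-6)
  th0 <- f0$orientation_rad
  thr <- fr$orientation_rad
  expect_equal(abs(abs(th0 - thr)), pi / 2, tolerance = 1e-4)
})

test_that("fitted major axis is strictly increasing across circle sizes", {
  majors <- vapply(c(119, 160, 201, 242, 283, 321), function(d) {
    segment_pupil(render_phantom(phantom_spec("circle", d)))$major_px
  }, numeric(1))
  expect_true(all(diff(majors) > 0))
})
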