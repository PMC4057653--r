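test_that("rendered dark-pixel counts match the brute-force analytic count", {
  cases <- list(
    list(shape = "circle", maj = 119, min = 119, size = c(1024, 1024)),
    list(shape = "ellipse", maj = 160, min = 119, size = c(1024, 1024)),
    list(shape = "circle", maj = 41, min = 41, size = c(128, 128)),
    list(shape = "ellipse", maj = 60, min = 33, size = c(128, 96))
  )
  for (cs in cases) {
    spec <- phantom_spec(cs$shape, cs$maj, cs$min, image_size = cs$size)
    frame <- render_phantom(spec)
    g <- binopupil:::phantom_geometry(spec)
    expected <- brute_inside_count(cs$size[1], cs$size[2], g$cx, g$cy, g$a, g$b)
    expect_identical(sum(frame$pixels == 0), expected)
    expect_true(all(frame$pixels %in% c(0, 255)))
  }
})

test_that("a reflection spot removes exactly its own pixel count", {
  plain <- render_phantom(phantom_spec("circle", 119))
  spec <- phantom_spec("circle", 119, reflection = reflection_spot(8))
  withr <- render_phantom(spec)
  g <- binopupil:::phantom_geometry(spec)
  spot_n <- brute_inside_count(1024, 1024, g$cx, g$cy, 8, 8)
  expect_identical(sum(withr$pixels == 0), sum(plain$pixels == 0) - spot_n)
  expect_identical(sum(withr$pixels == 255), sum(plain$pixels == 255) + spot_n)
})

test_that("degenerate and out-of-bounds phantoms are rejected", {
  expect_error(phantom_spec("circle", 0), "major_axis_px >= minor_axis_px > 0")
  expect_error(phantom_spec("circle", 2000), "bounds")
  expect_error(phantom_spec("circle", 100, center = c(20, 512)), "bounds")
  expect_error(phantom_spec("ellipse", 100, 120), "major_axis_px >= minor")
  expect_error(phantom_spec("circle", 100, 80), "equal axes")
  expect_error(phantom_spec("circle", 100,
                            reflection = reflection_spot(60)),
               "strictly inside")
})

test_that("rendering is equivariant under integer center translation", {
  base <- phantom_spec("circle", 61, center = c(200.5, 200.5),
                       image_size = c(512, 512))
  shifted <- phantom_spec("circle", 61, center = c(200.5 + 37, 200.5 - 12),
                          image_size = c(512, 512))
  m1 <- render_phantom(base)$pixels
  m2 <- render_phantom(shifted)$pixels
  # crop a common 101x101 region around each center
  crop <- function(m, cx, cy) m[(cy - 50):(cy + 50), (cx - 50):(cx + 50)]
  expect_identical(crop(m1, 200, 200), crop(m2, 237, 188))
})

test_that("zero-noise acquisition is the identity and seeds reproduce", {
  frame <- render_phantom(phantom_spec("circle", 41, image_size = c(128, 128)))
  silent <- acquisition_model(0, 0, 0, 0)
  frames <- simulate_acquisition(frame, silent, 3)
  expect_length(frames, 3)
  for (f in frames) expect_identical(f$pixels, frame$pixels)

  noisy <- acquisition_model(seed = 42)
  a <- simulate_acquisition(frame, noisy, 4)
  b <- simulate_acquisition(frame, noisy, 4)
  expect_identical(lapply(a, `[[`, "pixels"), lapply(b, `[[`, "pixels"))
  # different seeds differ
  c2 <- simulate_acquisition(frame, acquisition_model(seed = 43), 4)
  expect_false(identical(a[[1]]$pixels, c2[[1]]$pixels))
})

test_that("additive noise matches its configured scale on a flat region", {
  flat <- matrix(128, 96, 96)
  model <- acquisition_model(blur_sigma_px = 0, noise_sd = 2,
                             illumination_drift = 0, jitter_px = 0, seed = 7)
  frames <- simulate_acquisition(flat, model, 100)
  stack <- vapply(frames, function(f) f$pixels[48, 48], numeric(1))
  expect_lt(abs(sd(stack) - 2) / 2, 0.2)
  # per-pixel SD pooled over a region
  pix <- sapply(frames, function(f) as.vector(f$pixels[40:50, 40:50]))
  sds <- apply(pix, 1, sd)
  expect_lt(abs(mean(sds) - 2) / 2, 0.2)
})

test_that("phantom and acquisition specs round-trip through JSON and YAML", {
  spec <- phantom_spec("ellipse", 160, 119, orientation = "vertical",
                       reflection = reflection_spot(8, intensity = 200),
                       true_size_mm = 3.96)
  model <- acquisition_model(0.5, 2, 4, 0.3, seed = 11)
  for (ext in c("json", "yaml")) {
    ps <- tempfile(fileext = paste0(".", ext))
    write_spec(spec, ps)
    back <- read_phantom_spec(ps)
    expect_equal(back, spec)
    pm <- tempfile(fileext = paste0(".", ext))
    write_spec(model, pm)
    expect_equal(read_acquisition_model(pm), model)
  }
})
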