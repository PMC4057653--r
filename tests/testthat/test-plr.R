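test_that("darkness with hippus off holds the baseline diameter", {
  p <- plr_model(baseline_diameter_px = 110)
  d <- simulate_diameter(p, stim_left = rep(0, 100), rate_hz = 25)
  expect_true(all(d$diameter_px == 110))
})

test_that("a step stimulus follows the closed-form first-order response", {
  p <- plr_model(baseline_diameter_px = 100, constriction_gain = 0.2,
                 latency_s = 0, tau_constrict_s = 0.4)
  L <- 50
  n_pre <- 10; n_post <- 200; rate <- 25
  stim <- c(rep(0, n_pre), rep(L, n_post))
  d <- simulate_diameter(p, stim_left = stim, rate_hz = rate)
  left <- d$diameter_px[d$eye == "left"]
  deq <- 100 * (1 - 0.2 * log10(1 + L))
  t_since <- (seq_len(n_post) - 1) / rate
  analytic <- deq + (100 - deq) * exp(-t_since / 0.4)
  expect_equal(left[(n_pre + 1):(n_pre + n_post)], analytic, tolerance = 1e-6)
  # monotone constriction toward the asymptote
  expect_true(all(diff(left[(n_pre + 1):(n_pre + n_post)]) <= 0))
  expect_equal(left[n_pre + n_post], deq, tolerance = 1e-3)
})

test_that("consensual coupling scales the fellow eye's response exactly", {
  stim <- c(rep(0, 20), rep(80, 120))
  full <- plr_model(baseline_diameter_px = 100, consensual_gain = 1,
                    latency_s = 0.2)
  d1 <- simulate_diameter(full, stim_left = stim, rate_hz = 25)
  expect_equal(d1$diameter_px[d1$eye == "left"],
               d1$diameter_px[d1$eye == "right"], tolerance = 1e-12)

  part <- plr_model(baseline_diameter_px = 100, consensual_gain = 0.4,
                    latency_s = 0.2)
  d2 <- simulate_diameter(part, stim_left = stim, rate_hz = 25)
  direct <- 100 - d2$diameter_px[d2$eye == "left"]
  consensual <- 100 - d2$diameter_px[d2$eye == "right"]
  nz <- direct > 1e-9
  expect_equal(consensual[nz] / direct[nz], rep(0.4, sum(nz)),
               tolerance = 1e-6)
})

test_that("hippus is band-limited noise, reproducible under a fixed seed", {
  p <- plr_model(baseline_diameter_px = 100, hippus_amplitude_px = 2, seed = 8)
  d1 <- simulate_diameter(p, stim_left = rep(0, 500), rate_hz = 25)
  d2 <- simulate_diameter(p, stim_left = rep(0, 500), rate_hz = 25)
  expect_identical(d1$diameter_px, d2$diameter_px)
  x <- d1$diameter_px[d1$eye == "left"] - 100
  expect_gt(sd(x), 0.5)
  expect_lt(abs(sd(x) - 2), 1)
  # left and right hippus are independent streams
  y <- d1$diameter_px[d1$eye == "right"] - 100
  expect_lt(abs(cor(x, y)), 0.5)
})

test_that("a noiseless rendered video reproduces the fencepost diameter", {
  v <- render_eye_video(rep(119, 3), model = acquisition_model(0, 0, 0, 0),
                        rate_hz = 25)
  for (f in v$frames) {
    fit <- segment_pupil(f)
    expect_true(fit$valid)
    expect_identical(round(fit$major_px), 118)
    expect_identical(round(fit$minor_px), 118)
  }
  expect_identical(v$truth$diameter_px, rep(119, 3))
})

test_that("blink frames render as occlusion and segment as invalid", {
  v <- render_eye_video(c(100, 100, 100), model = acquisition_model(0, 0, 0, 0),
                        blink = c(FALSE, TRUE, FALSE))
  expect_true(all(v$frames[[2]]$pixels == 230))
  fits <- purrr::map(v$frames, segment_pupil)
  expect_true(fits[[1]]$valid)
  expect_false(fits[[2]]$valid)
  expect_true(fits[[3]]$valid)
})

test_that("the pipeline recovers a scripted pulse response end to end", {
  rate <- 25
  stim <- generate_waveform(
    stimulus_pattern("single_pulse", 60, duration_s = 8, onset_s = 2,
                     pulse_width_s = 4), rate)
  p <- plr_model(baseline_diameter_px = 119, constriction_gain = 0.12,
                 blink_schedule = list(c(1.0, 0.2), c(5.4, 0.2)), seed = 3)
  truth <- simulate_diameter(p, stim_left = stim, rate_hz = rate)
  left <- dplyr::filter(truth, eye == "left")
  v <- render_eye_video(left, model = acquisition_model(0.5, 2, 2, 0.2, seed = 4),
                        rate_hz = rate)
  trace <- segment_frames(v$frames, rate_hz = rate)
  expect_identical(sum(!trace$valid), sum(left$blink))
  clean <- remove_blinks(trace)
  expect_gt(cor(clean$major_px, left$diameter_px), 0.99)
  # noiseless recovery: scripted diameter minus the one-pixel fencepost
  v0 <- render_eye_video(left, model = acquisition_model(0, 0, 0, 0),
                         rate_hz = rate)
  tr0 <- remove_blinks(segment_frames(v0$frames, rate_hz = rate))
  ok <- !left$blink
  expect_lt(max(abs(tr0$major_px[ok] - (left$diameter_px[ok] - 1))), 1)
})

test_that("pupils larger than the frame are rejected", {
  expect_error(render_eye_video(rep(300, 2), eye_geometry(c(256, 256))),
               "exceeds")
  expect_error(render_eye_video(c(100, -5)), "positive")
})
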