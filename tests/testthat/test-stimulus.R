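test_that("a single pulse is active exactly over its sample window", {
  p <- stimulus_pattern("single_pulse", 100, duration_s = 14, onset_s = 2,
                        pulse_width_s = 10)
  w <- generate_waveform(p, 75)
  expect_identical(nrow(w), 14L * 75L)
  on <- which(w$luminance > 0)
  expect_identical(range(on), c(151L, 900L))  # 0-based samples [150, 900)
  expect_true(all(w$luminance[on] == 100))
})

test_that("the 0.5 Hz sinusoid over 10 s holds 5 exact periods with mean L/2", {
  p <- stimulus_pattern("sinusoid", 80, duration_s = 10, frequency_hz = 0.5)
  w <- generate_waveform(p, 75)
  expect_identical(nrow(w), 750L)
  expect_lt(abs(mean(w$luminance) - 40), 1e-9)
  # period-exact self-similarity at lag 1/f (150 samples)
  expect_equal(w$luminance[1:600], w$luminance[151:750], tolerance = 1e-9)
  # count full periods via minima at the period boundaries
  expect_equal(w$luminance[1 + 150 * (0:4)], rep(0, 5), tolerance = 1e-9)
})

test_that("all seven shapes generate within [0, luminance]", {
  shapes <- c("single_pulse", "sinusoid", "triangle", "rectangle",
              "ramp_positive", "ramp_negative", "pseudorandom")
  for (s in shapes) {
    p <- stimulus_pattern(s, 60, duration_s = 4,
                          frequency_hz = if (s %in% c("sinusoid", "triangle",
                                                      "rectangle")) 1 else NULL,
                          seed = 5)
    w <- generate_waveform(p, 50)
    expect_identical(nrow(w), 200L)
    expect_true(all(w$luminance >= 0 & w$luminance <= 60), info = s)
    expect_gt(max(w$luminance), 0)
  }
  # periodic self-similarity for triangle and rectangle
  for (s in c("triangle", "rectangle")) {
    w <- generate_waveform(
      stimulus_pattern(s, 60, duration_s = 4, frequency_hz = 1), 50)
    expect_equal(w$luminance[1:150], w$luminance[51:200], tolerance = 1e-12)
  }
})

test_that("luminance and rate constraints are enforced", {
  expect_error(stimulus_pattern("single_pulse", 0.5, duration_s = 1), "\\[1, 100\\]")
  expect_error(stimulus_pattern("single_pulse", 150, duration_s = 1), "\\[1, 100\\]")
  expect_error(stimulus_pattern("sinusoid", 50, duration_s = 1), "frequency")
  p <- stimulus_pattern("sinusoid", 50, duration_s = 1, frequency_hz = 30)
  expect_error(generate_waveform(p, 50), "2 \\* frequency")
})

test_that("pseudorandom stimuli are reproducible under a fixed seed", {
  p <- stimulus_pattern("pseudorandom", 100, duration_s = 6, hold_s = 0.5,
                        seed = 99)
  w1 <- generate_waveform(p, 75)
  w2 <- generate_waveform(p, 75)
  expect_identical(w1$luminance, w2$luminance)
  expect_gt(length(unique(w1$luminance)), 5)  # levels actually change
  p2 <- stimulus_pattern("pseudorandom", 100, duration_s = 6, seed = 100)
  expect_false(identical(generate_waveform(p2, 75)$luminance, w1$luminance))
})

test_that("the timeline counts triggers over the half-open recording window", {
  p <- stimulus_pattern("single_pulse", 100, duration_s = 14, onset_s = 2,
                        pulse_width_s = 10)
  tl <- build_timeline(p, 75, 14)
  expect_identical(sum(tl$event == "frame_trigger"), 1050L)  # 14 * 75 exactly
  expect_identical(sum(tl$event == "stimulus_on"), 1L)
  expect_identical(sum(tl$event == "stimulus_off"), 1L)
  expect_identical(sum(tl$event == "sync_pulse"), 1L)
  # non-integral product: floor(d * r) + 1
  tl2 <- build_timeline(p, 75, 14.01)
  expect_identical(sum(tl2$event == "frame_trigger"), 1051L)  # floor(d*r) + 1
})

test_that("stimulus onsets snap to the next frame trigger", {
  p <- stimulus_pattern("single_pulse", 100, duration_s = 4, onset_s = 2.003,
                        pulse_width_s = 1)
  tl <- build_timeline(p, 75, 4)
  on <- tl$time_s[tl$event == "stimulus_on"]
  expect_equal(on, 151 / 75, tolerance = 1e-12)
  # an onset already on the grid stays put
  p2 <- stimulus_pattern("single_pulse", 100, duration_s = 4, onset_s = 2,
                         pulse_width_s = 1)
  expect_equal(build_timeline(p2, 75, 4)$time_s[
    build_timeline(p2, 75, 4)$event == "stimulus_on"], 2)
})

test_that("the four binocular stimulation classes are constructible", {
  base <- stimulus_pattern("single_pulse", 100, duration_s = 6, onset_s = 0)
  for (cl in c("left", "right", "both")) {
    pats <- stimulation_class(cl, base)
    expect_length(pats, 1)
    expect_identical(pats[[1]]$eye, cl)
  }
  alt <- stimulation_class("alternating", base, period_s = 1)
  expect_length(alt, 6)
  tl <- build_timeline(alt, 75, 6)
  ons <- tl[tl$event == "stimulus_on", ]
  expect_setequal(unique(ons$eye), c("left", "right"))
  # left and right onsets never co-occur
  expect_identical(anyDuplicated(ons$time_s), 0L)
})

test_that("conflicting simultaneous patterns on one eye are rejected", {
  a <- stimulus_pattern("single_pulse", 100, duration_s = 5, onset_s = 0,
                        pulse_width_s = 3, eye = "left")
  b <- stimulus_pattern("single_pulse", 100, duration_s = 5, onset_s = 2,
                        pulse_width_s = 2, eye = "left")
  expect_error(build_timeline(list(a, b), 75, 5), "conflicting")
  c2 <- stimulus_pattern("single_pulse", 100, duration_s = 5, onset_s = 3,
                         pulse_width_s = 2, eye = "left")
  expect_s3_class(build_timeline(list(a, c2), 75, 5), "event_timeline")
})
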