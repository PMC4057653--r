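# binopupil

Offline analysis, simulation and validation toolkit for **binocular video
pupillometry** — for instrument builders and vision researchers who need to
turn infrared eye-image sequences into calibrated pupil-size waveforms and to
verify, with test objects of known geometry, that the whole measurement chain
is accurate and repeatable.

In a binocular instrument the two eyes are illuminated alternately and a
single 150 fps camera records an interleaved stream, giving up to 75 Hz per
eye. Each frame is reduced to the **equivalent ellipse** of the pupil: the
boundary points of the segmented pupil region are fitted with the
least-squares ellipse, whose center $(x_0, y_0)$, orientation $\theta$ and
full axes $(2a, 2b)$ are the reported pupil parameters.

## The method

Per frame, `segment_pupil()` runs

1. 5×5 **median filter** (edge replication);
2. **threshold at the mean intensity** of the 256-bin histogram — pupil
   pixels are strictly below it;
3. **morphological closing + hole filling** (disc brush, radius 5 px at
   1024²) and largest-component selection, which absorbs the corneal
   reflection of the IR illuminator;
4. **inner-boundary extraction** (pixel centers with a 4-neighbor outside);
5. **direct least-squares ellipse fit** — the conic
   $ax^2 + bxy + cy^2 + dx + ey + f = 0$ minimizing algebraic error under
   the ellipse constraint $4ac - b^2 = 1$ (Fitzgibbon/Halir–Flusser),
   converted to geometric parameters.

Around the pipeline: per-eye demultiplexing (`demux_binocular()`), blink
repair by neighbor averaging with a 3-SD moving-average guard
(`remove_blinks()`), millimeter calibration (`to_mm()`), a seven-shape light
stimulus generator with a trigger-synchronous event timeline
(`generate_waveform()`, `build_timeline()`), a ground-truthed PLR simulator
(`simulate_diameter()`, `render_eye_video()`), and the phantom validation
protocol (`software_test()`, `repeatability_experiment()`,
`validate_system()`, `linear_resolution()`).

## Worked example

Render a validation phantom — a black 119 px circle on a white 1024×1024
background — and measure it:

```r
library(binopupil)

fit <- segment_pupil(render_phantom(phantom_spec("circle", 119)))
fit
#> <pupil_ellipse> center (512.50, 512.50), axes 118.11 x 118.11 px, theta 0.000 rad
```

The fitted axes are one pixel below the drawn diameter: pixel-center
rasterization puts the outermost pixel *centers* 118 apart, and the
inner-boundary fit measures exactly that. Across the full 16-phantom
software-test set the rounded fitted axes are `drawn − 1` everywhere and the
worst relative deviation is 1/119 ≈ 0.84 %:

```r
sw <- software_test()
attr(sw, "max_rel_error_percent")
#> [1] 0.8403361
```

Simulated acquisition (blur, jitter, illumination drift, sensor noise) and
the repeatability protocol — 5 recordings × 100 frames of a 271 px phantom
with physical size 3.01 mm:

```r
res <- repeatability_experiment(
  phantom_spec("circle", 271, true_size_mm = 3.01),
  acquisition_model(seed = 1))
glance(res)[, c("overall_mean_px", "max_accuracy_percent",
                "max_repeatability_percent", "mm_per_px")]
#> # A tibble: 1 × 4
#>   overall_mean_px max_accuracy_percent max_repeatability_percent mm_per_px
#>             <dbl>                <dbl>                     <dbl>     <dbl>
#> 1            272.                0.369                   0.00425    0.0111
```

Accuracy stays below 0.5 %, the run-to-run repeatability far below 4 %, and
the calibration comes out at ≈ 0.0111 mm/pixel — a linear resolution better
than 0.02 mm.

End-to-end with the simulator: script a pupil light reflex, render the eye
video with noise and blinks, and recover the trace:

```r
stim <- generate_waveform(
  stimulus_pattern("single_pulse", 60, duration_s = 8, onset_s = 2,
                   pulse_width_s = 4), sample_rate_hz = 25)
truth <- simulate_diameter(plr_model(blink_schedule = list(c(1, 0.2)), seed = 1),
                           stim_left = stim, rate_hz = 25)
video <- render_eye_video(subset(truth, eye == "left"),
                          model = acquisition_model(seed = 2), rate_hz = 25)
trace <- remove_blinks(segment_frames(video$frames, rate_hz = 25))
cor(trace$major_px, subset(truth, eye == "left")$diameter_px)
#> [1] 0.9999392
```

A thin command-line front end covering `phantom`, `segment`, `process`,
`stimulus`, `simulate` and `validate` lives at `inst/cli/binopupil.R`; the
methods vignette (`vignettes/binocular-pupillometry.Rmd`) documents the
model choices, defaults and limitations.

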