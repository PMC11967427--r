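# flowmp

Automated detection, counting, sizing and shape classification of
fluorescently stained microplastic particles in flow-cell video.

## The problem

Quantifying microplastics (MPs) in sediment or water samples is a counting
bottleneck: after Nile-Red staining, particles between ~18 µm and 500 µm
fluoresce under a stereomicroscope, but tallying and sizing them by eye is
slow and error-prone. When the stained suspension is pumped through a
shallow flow cell and recorded as video, the problem becomes tractable by
software: detect every bright particle in a fixed *detection window*, link
detections across frames so each physical particle is counted exactly
once, measure it, and classify it as **grain** (compact fragment) or
**fiber** (thin thread). `flowmp` implements that pipeline for
environmental scientists who need rapid desk- or ship-board MP counts, plus
a synthetic flow-cell simulator with exact ground truth so the whole system
is testable end to end.

## Method at a glance

* **Detection** — per frame, a Canny cascade: 5×5 Gaussian smoothing, Sobel
  gradient, non-maximum suppression, hysteresis thresholding; closed
  contours are filled and measured. Only candidates whose centroid falls in
  the detection window count.
* **Tracking** — greedy nearest-predicted-neighbour linking with distance,
  lateral and size-ratio gates; each finished track is counted once at its
  largest-area (best-focus) member.
* **Morphometry** — area A, perimeter P, horizontal/vertical/max/min feret
  diameters, circularity 4πA/P², aspect ratio max/min feret. Size is the
  maximum feret in pixels; at the default 18 µm/px the size categories are
  small < 108 µm, medium 108–180, large 180–360, extra-large ≥ 360 µm.
* **Classification** — a rule-based rough split (fiber if aspect ≥ 4), then
  a small CNN trained on 100×100 crops with the standard protocol: 250
  images per class, mirror + 90° rotation augmentation (×8), ≤ 200 epochs,
  early stop at training error < 0.005. Predictions carry a confidence (%);
  evaluation counts an answer correct only at ≥ 90% confidence.

## Worked example

Simulate a clean benchmark scene (noise-free, non-touching particles),
run the full pipeline, and compare with ground truth:

```r
library(flowmp)

cfg <- scene_config(seed = 7, background_noise_sd = 0,
                    n_distractors = 0, allow_touching = FALSE)
sim <- render_video(cfg)
truth_traversals(sim$truth)
#> [1] 9

res <- run_pipeline(run_config(sim$frames, "out", window = cfg$window))
res$records[, c("particle_id", "crop_file", "size_px", "size_um",
                "size_category", "class", "frame")]
#>  particle_id     crop_file size_px size_um size_category class frame
#>            1 run_p0001.jpg      48     864   extra_large fiber     7
#>            2 run_p0002.jpg       7     126        medium grain    13
#>            3 run_p0003.jpg      53     954   extra_large fiber    15
#>            4 run_p0004.jpg      57    1026   extra_large fiber    23
#>            5 run_p0005.jpg       6     108        medium grain    34
#>            6 run_p0006.jpg       6     108        medium grain    54
#>            7 run_p0007.jpg       8     144        medium grain    56
#>            8 run_p0008.jpg       6     108        medium grain    67
#>            9 run_p0009.jpg       26    468   extra_large grain    72

res$summary$count_by_class
#> grain fiber
#>     6     3

detection_efficiency(res$records, sim$truth)$efficiency_pct
#> [1] 100
```

All nine simulated particles (six grains, three fibers) are counted exactly
once — detection efficiency 100%, zero false positives — and each record
points at a cross-referenced JPEG/PNG crop on disk. Each row's `size_um` is
`size_px × 18` and its category follows the boundaries above. The flow-cell
geometry helper reproduces the reference instrument's field-of-view
coverage:

```r
fov_coverage(11.2, 12)
#> [1] 93.3
```

To train and evaluate the CNN classifier on simulated crops:

```r
sim <- simulate_crops(275, 275, seed = 101)       # labeled grain/fiber crops
g <- which(sim$labels == "grain"); f <- which(sim$labels == "fiber")
ts <- build_training_set(sim$crops[c(g[1:250], f[1:250])],
                         sim$labels[c(g[1:250], f[1:250])],
                         n_per_class = 250, seed = 101)
model  <- train_classifier(ts, max_epochs = 200, seed = 101)
pred   <- classify_crops(model, sim$crops[c(g[251:275], f[251:275])])
confusion_summary(pred, sim$labels[c(g[251:275], f[251:275])])
#> Correct-answer rates (confidence >= 90%): grain 100.0%, fiber 96.0%
#> Average: 98.0%
```

A command-line front end (`inst/cli/flowmp`) wraps the same functions as
`simulate`, `detect`, `train`, `classify` and `evaluate` subcommands.

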