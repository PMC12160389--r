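# spontdyn

Spatiotemporal analysis of spontaneous activity in developing cortex
imaged with fast wide-field calcium indicators.

Before eye opening, the visual cortex generates spontaneous events in
which millimetre-scale *modules* of coactive neurons light up, shift, and
propagate over tens to hundreds of milliseconds. `spontdyn` implements a
complete analysis chain for such recordings (pixels × time movies at
~50 Hz), aimed at the questions this activity raises: how large and how
fast are events, do they travel as planar waves, do the same
spatiotemporal patterns repeat across hours, and for how long does a
single frame of activity predict what comes next?

## What the package computes

Starting from raw fluorescence `F`, the pipeline derives

- a running 36th-percentile baseline `F0` (28.5 s window) and
  `r = (F − F0) / F0`;
- deconvolved activity by prior-frame subtraction,
  `y_t = r_t − γ·r_{t−1}` with `γ = 0.89` per 20 ms frame (GCaMP8m);
- **events**: maximal runs of frames with ≥1 active pixel (per-pixel
  mean + 4 SD threshold, morphological cleanup at 0.028 mm², events
  ≥ 1 mm²);
- **wavelength** of modular patterns: twice the first minimum of the
  radially averaged spatial autocorrelation of band-passed frames
  (difference of Gaussians, SD 23/194 µm);
- **seed-point correlation networks** with a rotation/reflection
  surrogate null for long-range (1.3–1.7 mm) significance;
- **static vs dynamic classification**: the propagation area PA is the
  active area beyond a ~420 µm dilated exclusion zone around the onset
  frame; `PA = 0` defines a static event;
- **linear traveling-wave fits** of per-pixel onset times,
  `t̂_ON = x·[cosθ, sinθ]/v + t_SHIFT`, minimised by grid search plus
  refinement, with frame-permutation significance, a 150 mm/s
  detectability ceiling (3 mm window / 20 ms), and Rayleigh/binomial
  axial direction statistics;
- **repeated motifs**: 5-frame (100 ms) dynamic events, PCA-denoised,
  correlated event-against-event, thresholded at the 99th percentile of
  a within-timestep permutation null, greedily clustered (≥10 events per
  cluster) with temporal-coverage metrics `Fr` and `Fb`;
- **template groups and decoding**: multi-Gaussian template patterns
  fitted to frames of ≤200 ms events, greedy grouping by template match,
  and per-offset PCA + RBF-SVM classification of group identity from
  −2000 to +2000 ms around the template frame.

A first-class synthetic generator (`sim_config()`,
`synthesize_session()`) plants static, planar-wave, and repeated-motif
events with known parameters behind a calcium forward model
(`c_t = y_t + γ·c_{t−1}`, multiplicative baseline, drift, camera noise),
so every stage is testable by parameter recovery.

## Worked example

Simulate a short session, preprocess it, and ask the standard questions:

```r
library(spontdyn)

cfg <- sim_config(grid_shape = c(48, 48),   # 2.25 mm at 46.9 um/px
                  n_events = 80, seed = 1)
ses <- synthesize_session(cfg)
pp  <- preprocess_movie(ses$movie)          # baseline, dF/F, deconvolution
ev  <- detect_events(pp$deconvolved)

waves <- fit_event_waves(ev, n_perm = 50, seed = 1)
dplyr::count(waves, is_static)
summary(waves$v_mm_s[waves$significant %in% TRUE])

wl <- vapply(ev, event_wavelength, numeric(1))
median(wl, na.rm = TRUE)
```

```
#> # A tibble: 2 x 2
#>   is_static     n
#>   <lgl>     <int>
#> 1 FALSE        74
#> 2 TRUE          6
#>    Min. 1st Qu.  Median    Mean 3rd Qu.    Max.
#>   30.31   31.82   32.66   37.17   33.34   87.88
#> [1] 0.6566
```

The counts recover the planted composition (static events are the small
minority), the significant wave fits cluster around the planted
32 mm/s, and the median wavelength sits within one pixel pitch of the
planted 0.69 mm. `tidy()`, `glance()`, and `autoplot()` methods are
available for the fitted objects (wave fits, motif clusterings,
correlation maps, accuracy curves), and
`run_pipeline(pipeline_config(), sim = cfg)` chains every stage with one
seed. A thin command-line wrapper lives at `inst/cli/spontdyn.R`
(`Rscript spontdyn.R simulate|run ...`).

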