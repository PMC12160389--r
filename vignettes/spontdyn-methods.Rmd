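---
title: "Analysing fast spatiotemporal structure in spontaneous wide-field calcium imaging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing fast spatiotemporal structure in spontaneous wide-field calcium imaging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spontdyn)
```

## The problem

Before eye opening, the developing visual cortex generates spontaneous
activity organised into millimetre-scale *modules* — spatially segregated
patches of coactive cortex a few hundred micrometres across — linked by
long-range correlations. Imaged with a fast calcium indicator at 50 Hz,
this activity resolves into discrete events lasting tens to hundreds of
milliseconds whose module patterns shift *within* an event. `spontdyn`
implements the full analysis chain for such recordings: signal extraction,
event segmentation, correlation networks with surrogate nulls, wavelength
estimation, static/dynamic classification, linear wavefront fitting,
repeated-motif discovery, and template-trajectory decoding — together with
a ground-truth synthetic movie generator so that every stage can be
verified by parameter recovery, with no dependence on any particular
recording.

## Signal model and preprocessing

Raw fluorescence is modelled per pixel as
\(F_{pt} = B_t\,(1 + c_{pt}) + \varepsilon_{pt}\), where \(B_t\) is a slow
baseline and \(c_{pt}\) the accumulated calcium signal. Preprocessing has
three stages, each a `pixel_movie`:

1. **Baseline** \(F_{0,pt}\): a running 36th-percentile (nearest-rank)
   filter over a 28.5 s window centred on \(t\). The rank sits below the
   typical activity duty cycle, so transients do not drag the baseline up;
   the window is long relative to events but short relative to drift.
   Windows are truncated at the recording edges rather than padded —
   padding would invent data; truncation only widens the effective rank
   slightly at the first and last 14 s.
2. **Normalisation**: \(r_{pt} = (F_{pt} - F_{0,pt}) / F_{0,pt}\).
3. **Prior-frame subtraction**: \(y_{pt} = r_{pt} - \gamma\, r_{p,t-1}\)
   with \(\gamma = 0.89\), the per-20 ms decay factor of GCaMP8m. This
   one-step deconvolution removes indicator decay and emphasises new
   activity. The first frame uses \(y_{p1} = r_{p1}\) (the frame before
   the recording is taken as silent), which is exact whenever recordings
   begin in a quiet period.

At zero noise this chain is the exact algebraic inverse of the forward
model below; the test suite verifies the round trip to below \(10^{-9}\).

## Event segmentation

A pixel is *active* when \(y_{pt}\) exceeds its own whole-recording mean
plus 4 SD. Masks are cleaned per frame by binary opening with a 3×3
all-ones element followed by removal of 8-connected components smaller
than 0.028 mm² (13 pixels at 0.0022 mm²/pixel); an *event* is a maximal
run of frames each containing at least one active pixel, bounded by fully
inactive frames, and only events activating at least 1 mm² across their
duration (455 pixels) are analysed. Events touching the first or last
recorded frame are flagged and excluded from duration statistics and wave
fitting, since truncation would bias both. Note the 4 SD rule presumes
sparse activity: per-pixel SDs include the events themselves, so duty
cycles above roughly 5% inflate thresholds and suppress detection. The
synthetic defaults (quiet gaps of 0.2–2 s) keep duty near 2%.

Two conventions are fixed once: components and peaks use 8-connectivity
(matching the 3×3 structuring element used throughout), and frame/pixel
indices are 1-based as is natural in R, with onset times reported in ms
relative to event start so no downstream quantity depends on the indexing
origin.

## Spatial statistics

Single frames are band-passed with a difference of Gaussians (SDs 23 and
194 µm) implemented by normalised convolution, so pixels outside the ROI
contribute no support. Seed-point correlation maps are plain Pearson
correlations across events using one frame per event — the maximally
active frame, or the within-event sum.

**Surrogate null.** To test long-range correlation strength, every frame
is independently rotated (uniform over 0–350° in 10° steps) and reflected
(probability 0.5 per axis) about the ROI centroid, and the map is
recomputed; 100 such ensembles give the null distribution of median peak
correlation at 1.3–1.7 mm from the seed (local maxima, 8-neighbourhood,
minimum separation 800 µm). Rotation uses nearest-neighbour resampling:
interpolation would smooth the surrogates and bias their correlations
downward, making the test anticonservative. Peaks are located on the
band-passed correlation map (the raw map's broad seed-centred structure
otherwise dominates peak finding) while the reported correlation
strengths are read from the raw map. The p value is the fraction of
surrogate medians at or above the real one; a map with no peaks in the
band is flagged undefined rather than given p = 0. The test presumes a
roughly convex ROI: rotations are then isometries of the ROI and the
surrogate ensemble is exchangeable with the real map. On strongly
non-convex ROIs (including a full square grid), rotated corners leave
the ROI, peripheral surrogate correlations rest on fewer events, their
maxima inflate, and the test becomes conservative — it loses power but
never overstates significance.

**Wavelength.** The modular wavelength of a frame is twice the distance
from the origin to the first local minimum of its radially averaged 2-D
spatial autocorrelation, with radial bins one pixel pitch wide. This
definition is *operational*: the synthetic generator is calibrated to it
(below), and the estimator's resolution is one pixel pitch (±47 µm) by
construction of the binning.

## Propagation and wavefront fitting

The onset mask (first-frame active pixels) is dilated nine times with the
3×3 element — a Chebyshev exclusion radius of 9 pixels ≈ 420 µm — and the
*propagation area* PA is the ever-active area outside that zone. PA = 0
defines a static event; PA > 0 a dynamic one. The exclusion zone absorbs
noise-driven fringe activations, so the dynamic fraction is a conservative
estimate.

For dynamic events, per-pixel onset times \(t_{ON}\) are fit with a planar
wave \(\hat t_{ON} = \mathbf{x}_p \cdot [\cos\theta, \sin\theta] / v +
t_{SHIFT}\) by minimising MSE over a grid of 30 log-spaced speeds
(1–300 mm/s) and 10° direction steps — \(t_{SHIFT}\) has a closed-form
optimum at fixed \((v, \theta)\) — followed by Nelder–Mead refinement.
Coordinates are pixel centres in mm relative to the ROI centroid, x along
columns, y along rows (increasing downward), \(\theta\) measured from +x.
Significance uses frame-order permutations: onset times are recomputed for
each permuted event and refit, and the real fit is significant when its
fit quality (−MSE) exceeds the 95th percentile of permuted qualities. The
permuted statistic is not uniquely pinned down by the procedure's verbal
description; −MSE (equivalently, real MSE below the 5th percentile of
permuted MSEs) is the single convention used everywhere here. Events
shorter than 5 frames are excluded (too few distinct permutations), and
fitted speeds above the detectability ceiling (field-of-view diameter over
one frame interval; 150 mm/s for 3 mm at 20 ms) are excluded from the
fraction-linear statistic. Direction structure is summarised by the
Rayleigh test on doubled axial angles, followed, when significant, by a
binomial test of direction counts split at ±90° around the mean axis.

## Repeated motifs

Dynamic events of exactly 5 frames (100 ms) are band-passed, denoised by
per-frame-position PCA (20 components — fitting one basis per position
matches the permutation scheme below), concatenated into vectors, and
correlated event against event. The null preserves each event's generic
rise-and-fall while destroying event identity: frame content is permuted
*within a time step* (all first frames shuffled across events, all second
frames, and so on), 1000 times, and the pooled 99th percentile of permuted
off-diagonal correlations is the repetition threshold — a single global
threshold rather than per-pair thresholds, since the calibration pools all
pairs. Clusters are extracted greedily (the event with most
above-threshold partners seeds a cluster; members are removed; repeat)
until a cluster would fall below 10 events. Coverage per cluster is
summarised by the fractional range \(F_r = (\max t - \min t)/t_{TOTAL}\)
of initiation times and the fraction of represented 10-minute bins
\(F_b\). Cluster quality is compared against hierarchical (Ward) and
k-means alternatives at matched cluster count via mean silhouette over
clustered events, and temporal sensitivity is checked by a frame-shuffle
control: each event's frames are deranged (every frame displaced), the
vector is correlated with each cluster's mean vector — the mean is the
cluster representative, the simplest choice consistent with "correlation
to each cluster" — and assigned to the best cluster only above threshold.

## Template groups and trajectory decoding

All frames of events ≤200 ms are pooled and each is fit with a sum of
axis-aligned 2-D Gaussians, one per connected active component (capped at
10), by Levenberg–Marquardt with moment initialisation and an analytic
Jacobian. Component SDs are bounded at 3 pixels (~140 µm), the scale of a
cortical module: without the bound the optimiser absorbs background into
one broad component, which collapses the matching threshold below. Each
template's threshold is the minimum correlation with copies of itself
translated up to one SD (the largest component SD — the most permissive
reading of "one standard deviation", stated here once). Events are grouped
greedily by template match, one frame (the best) per event, keeping the
top 7 groups with at least 15 members.

Decodability of group identity over time uses, at each offset from the
template frame, the session frames at (template time + offset) — drawn
from the continuous deconvolved movie whether or not inside an event,
which is what makes ±2000 ms around ≤200 ms events meaningful — projected
onto the first 8 principal components fit *at that offset only* (fitting
across offsets would leak information between time points). Groups are
size-matched by subsampling (100 times), each subsample scored by
stratified 5-fold cross-validated RBF-kernel SVM accuracy (cost 1, the
kernel library's default bandwidth — the classifier's hyperparameters are
not critical and are fixed, not tuned). Each subsample is compared with
100 label-shuffled copies of itself; an offset is significant when ≥95% of
subsamples beat their own 95th shuffle percentile. The per-offset PCA is
fit on the group frames entering that offset's classification rather than
all session frames; both readings are defensible, and the group-frame
choice keeps the feature space matched to the classified sample.

## The synthetic generator

`synthesize_session()` plants three event kinds at configurable fractions
(defaults: 6.9% static, 50% planar waves at 32 mm/s, remainder repeated
motifs), separated by fully inactive gaps drawn uniformly from 0.2–2 s,
then passes the session through the calcium forward model
\(c_t = y_t + \gamma c_{t-1}\), \(F_t = B_t (1 + c_t) + \varepsilon\),
with multiplicative baseline 100, optional sinusoidal drift (amplitude 5,
period 60 s) and additive Gaussian camera noise (SD 2 — the camera noise
model is a free parameter, not a claim about any particular sensor).

Design choices that matter for interpretation:

* **Wavelength calibration.** Modular patterns are white noise band-passed
  on a frequency annulus. Ring noise at centre frequency \(f_0\) has
  radial autocorrelation \(J_0(2\pi f_0 r)\), whose first minimum sits at
  \(r = 0.61/f_0\), not at half the ring period. The generator therefore
  places \(f_0 = (3.8317/\pi)/\lambda\) so that a pattern "of wavelength
  λ" has its first autocorrelation minimum at exactly λ/2 — i.e. the
  planted wavelength equals the wavelength *as the estimator defines it*.
  This was fixed analytically when the generator was designed.
* **Event anatomy.** Activity ramps linearly up to a mid-event peak and
  back down to 75% of peak at the event edges. Static events activate one
  spatially localised 1.4 mm² modular footprint for 40 ms. Wave events
  sweep half the ROI with planar onsets quantised to the frame grid
  (quantisation happens after the continuous model, matching acquisition).
  Motif events initiate in a localised ~1 mm² region and progress into
  distributed modules; later frames mix a motif-specific core pattern
  (weight 0.85) with frame-specific structure and carry graded amplitudes,
  so frames are correlated within an event yet temporally ordered.
  Footprints are cleaned with the same opening/minimum-area rule the
  analysis applies, so planted masks survive cleanup unchanged.
* **What the generator does not emulate.** Optics and point-spread,
  motion artifacts, indicator nonlinearity beyond single-frame decay,
  inhomogeneous expression, and vascular occlusion. Sessions contain a
  handful of motif types rather than the rich continuum of real activity;
  one visible consequence is that single-frame and summed-event
  correlation maps, while strongly positively related, do not reach the
  near-identity seen in real recordings — their similarity is limited by
  the small number of distinct motif categories a desk-scale session
  contains. Passing tests therefore demonstrate correctness of the
  *algorithms* under the stated statistical structure, not performance on
  real data.

## Numerical and scale choices

Problem sizes in the tests and the acceptance script are desk-scale:
40–64 pixel grids (1.9–3 mm at the 46.9 µm pitch), sessions of 60–1000
events, 100–200 permutations where the analysis default is 1000, and
reduced subsample counts in the decoding tests. These sizes were chosen so
the full suite exercises every stage at meaningful statistical power on a
single CPU; all analysis defaults remain the full-scale values. Memory is
kept flat by single-allocation kernels for the forward model, rank filter,
and deconvolution, so a 60,000-frame session fits comfortably in a few GB.

Degenerate inputs are handled explicitly: zero-variance pixels are never
active; events with identical onsets yield a flagged degenerate wave fit
rather than an arbitrary speed; correlation maps with no band peaks give
an undefined (not zero) p value; silhouettes require at least two
clusters; and a baseline window longer than the recording falls back to
the whole-trace percentile with a message.

## Known limitations

The rank-order baseline uses nearest-rank indexing; an interpolating rank
would differ in the fourth decimal and is not exposed. Per-pixel
thresholds assume whole-session stationarity of the noise floor; recordings
with strong slow state changes would need block-wise statistics (the block
length is exposed as a future extension point, not implemented). The
wavefront model fits onset times only — amplitude dynamics within events
carry no weight — and nonlinear wave forms (spiral, radial) are out of
scope. Template fitting assumes axis-aligned Gaussian components; oriented
elliptical modules are absorbed by slightly larger SDs.
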