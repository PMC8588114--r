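---
title: "Methods: pupil tracking, shape metrics and agreement statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pupil tracking, shape metrics and agreement statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(pupilgram)
```

# The measurement problem

Rodent pupillometry under constant dim (infrared) illumination measures
arousal-linked pupil fluctuations rather than the light reflex. The raw data
are long 8-bit monochrome videos (the target rig records 1024×1280 px at
10 fps) of a dark pupil on a only-slightly-brighter iris, crossed by
vibrissae, dotted with specular highlights, and softened by the moisturising
gel on the cornea. The quantity of interest per frame is the pupil
*diameter*, defined as the largest distance between two pixels of the
segmented pupil region, alongside area, centroid and circularity; the
diameter-versus-time curve is the pupillogram.

This package implements the classical (non-learning) analysis chain for
such recordings and the statistics used to validate any segmenter against
manual annotation. A two-function backend contract
(`adaptive_threshold_backend()` is the reference implementation) lets a
trained model be substituted for the classical tracker without touching the
rest of the pipeline.

# The adaptive-threshold tracker

`tracker_init()` implements the only manual step: a bounding box drawn
around the pupil in the first frame. Inside the box an automatic Otsu
threshold (exhaustive 256-bin search for the gray level maximising
between-class variance) separates dark from bright pixels, and the largest
dark 8-connected component becomes the initial pupil. Otsu-within-box was
chosen as the least-parameterised automatic rule for this step; a uniform
box (no split possible) is an initialisation error, not a guess.

Each subsequent frame (`track_frame()`) is segmented in four steps:

1. *Adaptive threshold.* Candidate pixels have intensity at most
   `reference + margin_gray_levels`. The reference is the mean of 13 pixels
   sampled inside the previous frame's pupil; the margin (default 10 gray
   levels) absorbs the blurred edge and slow illumination drift. The
   comparison direction (darker-than) reflects the dark-pupil geometry of
   IR illumination.
2. *Labelling.* Candidates are grouped by 8-connectivity (stated
   explicitly because it changes component counts; the labeller is compiled
   code in `src/`).
3. *Filtering.* Components smaller than `min_region_fraction` (default
   0.005) of the initial box area are noise; components whose *centroid*
   falls outside the initial box are distractors (vibrissae, eyelid
   shadow). Centroid-outside — rather than any-pixel-outside — lets a pupil
   straddling the box edge survive partial occlusion.
4. *Selection.* Among survivors, the component whose centroid is nearest
   (Euclidean) to the previous pupil centroid is the pupil.

The 13-point sampling policy (`sample_reference_intensity()`) is: the mask
centroid, plus 6 points on a ring of radius r/3 and 6 on a ring of radius
2r/3, where r is the equivalent-circle radius `sqrt(area/π)` and angles run
0°, 60°, …, 300° from the +column axis. Points snap to the nearest pixel;
a snapped point outside the mask is replaced by the nearest mask pixel, and
duplicates are kept so exactly 13 values are always averaged. The count is
fixed by the algorithm's published description; the *locations* are this
package's deterministic choice (exposed as a replaceable policy via the
backend contract), covering the interior without privileging the centre.
The reference is re-sampled on every successfully tracked frame — the
literal reading of using the pupil "detected just in the previous frame" —
so the threshold follows slow intensity drift.

When no component survives (blink, saturating flash, full occlusion) the
frame is flagged invalid, an *empty* mask is returned, and the state
carries forward unchanged; tracking resumes on the next usable frame. Long
recordings must survive artifacts, so aborting is reserved for
initialisation failures.

Determinism: the tracker contains no randomness anywhere; identical video,
box and configuration give bit-identical mask sequences.

# Shape metrics

All metrics (`measure_region()`) are computed on the largest 8-connected
component of the mask — a pupil is a single instance, and stray islands are
segmentation debris. Coordinates are R-native: 1-based pixel centers,
`(row, col)` internally, with the CSV exposing `centroid_x = col`,
`centroid_y = row`.

**Perimeter** is a weighted chain code on the Moore-traced 8-connected
boundary: orthogonal steps weigh 1, diagonal steps weigh
`chain_diag_weight()`. The diagonal weight deserves its own paragraph
because circularity depends on it quadratically. The naive weight √2 makes
the chain length of a digitised *straight* edge overestimate its true
length by up to 8 % (worst at 22.5°), and averaging over orientations the
boundary of a digitised disc measures ~5 % long — a perfect disc would
score circularity ≈ 0.90. We therefore fix the orthogonal weight at 1
(keeping axis-aligned rectangles exact: a 10×10 square traces 36.0) and
calibrate the diagonal weight to be unbiased on straight edges averaged
over orientation:

$$b \;=\; 1 + \frac{\pi/4 - \sqrt 2/2}{1 - \sqrt 2/2} \;\approx\; 1.2673,$$

which brings a rasterised disc of radius 100 within 0.3 % of $2\pi r$ and
its circularity to ≈ 1.004. The weight is an explicit argument
(`diag_weight`) for anyone wanting the plain Euclidean chain.

**Circularity** is $4\pi\,\mathrm{area}/\mathrm{perimeter}^2$, not clamped
to 1: small rasters can legitimately exceed 1 by a few hundredths and
clamping would hide estimator bias.

**Diameter** is the maximum Feret diameter between *pixel centers*,
computed by convex hull plus rotating calipers and verified in the tests to
equal the all-pairs brute force exactly. Measuring between centers rather
than outer pixel edges subtracts ~1 px from the geometric diameter —
negligible at pupil scale (~40 px) and consistent with
"distance between the farthest pixels".

Degenerate inputs produce invalid sentinel rows (`valid = FALSE`, `NA`
metrics) from `measure_region()`, while the low-level functions
(`region_perimeter()`, `max_feret_diameter()`, …) treat an empty mask as a
contract violation and error.

# Segmentation evaluation

`confusion_tally()` builds the exact 2×2 pixel table (classes pupil /
background) from which pixel accuracy, mean accuracy, per-class IoU and
mIoU follow. The headline per-frame metric is the **pupil-class IoU**: with
a small pupil on a large background, pixel accuracy and mIoU are dominated
by the background class and look flattering regardless of pupil quality.
A class absent from both truth and prediction makes its IoU an error — not
silently 0 or 1 — but an empty *prediction* against non-empty truth is a
legitimate failure and scores pupil IoU 0.

`mape()` is $100 \cdot \frac1N \sum_t |G_t - P_t|/G_t$ — reported in
percent, matching how such errors are quoted. `evaluate_dataset()` reports
both the mean per-frame IoU (the headline) and a pooled-pixel IoU, since
either aggregation is defensible; per-frame APEs of diameter, circularity
and centroid coordinates are averaged into their MAPEs.

# Agreement statistics

`agreement_analysis()` mirrors how an automatic method is validated against
manual annotation:

- **Normality screen** (`normality_screen()`): the D'Agostino–Pearson K²
  omnibus (skewness and kurtosis z-scores with the standard small-sample
  corrections, n ≥ 20; verified against an independent implementation) and
  a one-sample Kolmogorov–Smirnov test against a normal with the sample's
  fitted mean/sd. Diameter distributions over a session are typically
  non-normal (baseline/dilated mixtures), which is why association is
  reported with rank statistics.
- **Correlations**: Spearman's rho (average ranks under ties) and
  Kendall's tau-b, two-sided p-values by the large-sample approximations.
- **Regression**: OLS of predicted on ground truth (prediction on the y
  axis), with R² and Pearson r.
- **Bland–Altman** (`bland_altman()`): differences are *relative*,
  $d_t = 100\,(G_t - P_t) / ((G_t+P_t)/2)$ — percent of the pair mean, the
  standard variant when bias and limits of agreement are quoted in percent.
  Bias is mean(d); LoA are bias ± 1.96·sd(d) (large-sample multiplier);
  the bias CI uses $t_{0.975,n-1}\,s/\sqrt n$ and each LoA CI
  $t_{0.975,n-1}\,s\sqrt{3/n}$. The sign convention (G − P; positive bias =
  prediction underestimates) and denominator are recorded as attributes on
  the result because neither choice is universal.

# The synthetic scene generator

No annotated recordings are distributable with this package, so testability
rests on `generate_video_with_truth()`: deterministic synthetic videos with
per-frame ground truth. The generator emulates the *measurement* conditions,
not mouse physiology:

- **Protocol** (`protocol_config()`): 60 s baseline, then 4 stimuli at
  100 s intervals, 10 fps — the recording protocol of the targeted
  experiments; at these defaults the stimulus onsets fall 600, 1600, 2600
  and 3600 frames into the recording. The evoked dilation is a
  double-exponential kernel (rise 2 s, decay 15 s, unit peak scaled to
  `dilation_amplitude_px`): the minimal smooth rise/decay transient.
  Published recordings show such transients qualitatively but no amplitude
  or functional form, so the defaults (baseline 40 px, amplitude 12 px —
  a ~30 % dilation, with mild random-walk drift and white tremor) are
  plausible magnitudes chosen once for testing, never claims about
  physiology.
- **Scene** (`scene_config()`): 128×160 px frames (the rig's 1024×1280
  aspect at 1/8 scale, keeping desk-scale runtimes), iris 120 / pupil 35
  gray levels (low contrast), eccentricity-jittered near-circular pupil,
  optional saturated highlight straddling the pupil edge, dark anti-aliased
  vibrissa strokes, Gaussian gel blur (σ = 1 px), additive sensor noise
  (σ = 3 gray levels), per-frame illumination jitter, and a slow
  random-walk centre drift.
- **Ground truth** is the *pre-blur, pre-noise* ellipse — the analogue of a
  human-annotated contour — with semi-axes inflated by half a pixel so the
  farthest-pixel distance of the raster reproduces the requested diameter
  (within 1 px, enforced by test).

What the generator does **not** emulate: eyelids and real blinks (blink
handling is tested with synthetic all-bright frames), anesthesia-depth and
luminance reflexes, perspective foreshortening of the eyeball, and
photorealistic texture. Passing end-to-end tests therefore demonstrates
correct *mechanics* (threshold adaptation, component filtering, metric
arithmetic, statistics) under controlled degradation — not performance on
any particular laboratory's recordings.

# Problem sizes and numerical choices

The test-suite and acceptance-script problem sizes are chosen as the
smallest that still exercise every mechanism: tracking runs on 300–500
frame videos at 128×160 px (one or two evoked dilations), metric-oracle
equivalence uses 200 random mask pairs up to 64×64, Feret/calipers
equivalence 200 masks up to 40×40, and the Bland–Altman coverage study 200
replicate series of 300 pairs. The artifact-free ("clean") scene used for
recovery checks sets noise, jitter and occluders to zero and keeps a mild
0.8 px blur.

Other numerical conventions, gathered in one place: 8-connectivity
throughout; ties in largest-component selection resolved by scan order;
Otsu split failure = initialisation error; masks read from images binarise
at > 127; colour inputs collapse by ITU-R BT.601 luma weights; CSV output
uses '.' decimals, no thousands separators, and the fixed column order
`frame,timestamp_s,centroid_x,centroid_y,area_px,circularity,diameter_px,valid`.
Timestamps fall back to uniform spacing at `fps_fallback` (default 10 fps)
when a source carries none. All CLI outputs are written atomically
(temp file + rename).

# Known limitations

- The tracker assumes the pupil stays the *darkest coherent region* near
  its previous position; a pupil darker than `reference + margin` that
  drifts outside the initial bounding box is lost by design (the box is the
  algorithm's spatial prior).
- The adaptive threshold cuts the blurred pupil edge slightly inside the
  true contour, so tracked diameters run a fraction of a pixel low; the
  agreement module exists precisely to quantify such systematic offsets.
- Frame sources are numbered PNG/TIFF sequences; container videos should
  be exported to frames first (the synthetic generator writes PNG
  sequences directly).
- The perimeter estimator is calibrated for smooth convex shapes; on
  deeply concave or 1-px-thin regions, chain-code perimeters (and hence
  circularity) are raster artifacts more than geometry.

```{r example, eval = FALSE}
# a complete run, for reference
gen <- generate_video_with_truth(
  protocol_config(baseline_s = 10, n_stimuli = 1, inter_stimulus_s = 20),
  scene_config(), file.path(tempdir(), "vid"), seed = 1)
trk <- track_video(frame_source(gen$frames_dir), bbox(40, 55, 90, 105))
autoplot(trk)
glance(evaluate_dataset(read_mask_dir(gen$masks_dir), trk$mask))
```
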