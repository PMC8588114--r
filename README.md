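# pupilgram

Automated pupillometry for rodent eye recordings: track the pupil through a
grayscale video from a single user-drawn bounding box, turn every frame into
shape measurements, and export the **pupillogram** — pupil diameter against
time — together with the statistics needed to trust it.

Pupil size in dim, constant light is a window on arousal and noradrenergic
(locus coeruleus) activity, so experiments record long videos of a dark,
low-contrast pupil on a brighter iris, disturbed by whiskers, specular
highlights and moisturising-gel blur. This package provides the classical
analysis chain for such recordings:

- **Adaptive-threshold tracker.** Initialised by Otsu thresholding inside
  the first-frame bounding box; in every later frame, pixels darker than a
  reference gray level (the mean of 13 deterministic sample points inside
  the previous pupil, plus a configurable margin) are labelled into
  8-connected components, small components and components centred outside
  the initial box are discarded, and the component whose centroid is nearest
  the previous pupil centroid wins. Blinks yield flagged invalid frames, not
  aborts. Any other segmenter (e.g. a trained network) can be plugged in
  through the same two-function backend contract.
- **Shape metrics** per binary mask: area, centroid, chain-code perimeter,
  circularity `4π·area/perimeter²`, and the maximum Feret diameter (the
  distance between the farthest pixels, computed by convex hull + rotating
  calipers and exactly equal to the all-pairs maximum).
- **Segmentation evaluation** against ground-truth masks: pixel accuracy,
  mean accuracy, IoU (`p_ii / (Σ_j p_ij + Σ_j p_ji − p_ii)`), mIoU, and the
  mean absolute percentage error `MAPE = (100/N) Σ_t |G_t − P_t| / G_t` of
  diameter, circularity and centroid coordinates.
- **Method agreement** between two diameter series: D'Agostino–Pearson and
  Kolmogorov–Smirnov normality screens, Spearman/Kendall rank correlations,
  OLS regression of predicted on ground truth, and Bland–Altman bias with
  95 % limits of agreement on relative (percent-of-pair-mean) differences.
- **Synthetic scene generator**: deterministic eye videos with per-frame
  ground-truth masks and a known diameter trace (baseline, drift, tremor,
  stimulus-evoked double-exponential dilations), so the whole pipeline is
  testable end to end without recorded data.

## Worked example

Generate a 30 s synthetic recording (10 fps, one stimulus-evoked dilation),
track it from a bounding box, and evaluate against the generator's truth:

```r
library(pupilgram)

out   <- file.path(tempdir(), "demo")
proto <- protocol_config(baseline_s = 10, n_stimuli = 1, inter_stimulus_s = 20)
scene <- scene_config(noise_sd = 0, blur_sigma = 0.8, vibrissae_count = 0,
                      highlight = FALSE, contrast_jitter_sd = 0)
gen <- generate_video_with_truth(proto, scene, out, seed = 7)

src <- frame_source(gen$frames_dir)
#> <pupil_frame_source> 300 frames of 128x160 px from /tmp/.../demo/frames

trk <- track_video(src, bbox(40, 55, 90, 105))
trk[1:3, c("frame", "timestamp_s", "area_px", "circularity", "diameter_px", "valid")]
#>   frame timestamp_s area_px circularity diameter_px valid
#> 1     1         0      1322        1.03        41.0 TRUE
#> 2     2         0.1    1198        1.03        39.2 TRUE
#> 3     3         0.2    1192        1.04        39.2 TRUE
```

Each row is one frame of the pupillogram: the pupil covers ~1200 px², is
nearly circular (circularity ≈ 1), and spans ~39 px at its widest chord.
`autoplot(trk)` draws the diameter trace; `write_pupillogram(trk, "p.csv")`
exports the standard CSV schema.

Compare the tracked masks with the ground truth and quantify agreement:

```r
truth_masks <- read_mask_dir(gen$masks_dir)
ev <- evaluate_dataset(truth_masks, trk$mask)
glance(ev)
#>   n_frames mean_iou pooled_iou mape_pd mape_pc mape_cx mape_cy
#> 1      300    0.924      0.925    3.57   0.665 0.00606 0.00693

truth <- read.csv(gen$truth_csv)
fit <- agreement_analysis(data.frame(manual = truth$true_diameter_px,
                                     auto = trk$diameter_px), manual, auto)
fit
#> <pupil_agreement> n = 300 pairs
#>   Spearman rho 0.990, Kendall tau 0.949
#>   fit: p = 1.000 g -0.768, R^2 = 0.9990
#>   relative bias 1.745% (LoA 0.96% .. 2.53%)
```

The tracker recovers the masks with mean IoU 0.92 and the diameter with a
3.6 % MAPE; the regression slope of 1.00 and the small positive bias (the
adaptive threshold cuts the blurred pupil edge slightly inside the true
contour, so tracked diameters run ~0.8 px under truth) summarise the
systematic part of that error. `autoplot(fit)` draws the Bland–Altman plot
and `plot_agreement_scatter(fit)` the regression scatter.

The same pipeline is scriptable from a shell via the bundled CLI
(`inst/cli/pupilgram`, or `pupil_cli()` in R) with subcommands `synthesize`,
`track`, `evaluate` and `agreement`.

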