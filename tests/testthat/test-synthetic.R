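test_that("null dynamics give a constant trace at baseline", {
  proto <- protocol_config(baseline_s = 5, n_stimuli = 2, inter_stimulus_s = 10,
                           dilation_amplitude_px = 0, drift_sd = 0,
                           tremor_sd = 0, baseline_diameter_px = 38)
  tr <- simulate_pupil_trace(proto, fps = 10, seed = 1)
  expect_equal(nrow(tr), 250)
  expect_true(all(tr$diameter_px == 38))
})

test_that("default protocol timing puts stimulus onsets at the expected frames", {
  tr <- simulate_pupil_trace(protocol_config(), fps = 10, seed = 1)
  ev <- attr(tr, "events")
  expect_equal(ev$time_s, c(60, 160, 260, 360))
  expect_equal(ev$frames_elapsed, c(600, 1600, 2600, 3600))
  expect_equal(nrow(tr), 4600)
  expect_equal(tr$event[ev$frame], 1:4)
})

test_that("each evoked response peaks near the configured amplitude", {
  proto <- protocol_config(baseline_s = 10, n_stimuli = 2, inter_stimulus_s = 40,
                           drift_sd = 0, tremor_sd = 0,
                           dilation_amplitude_px = 10)
  tr <- simulate_pupil_trace(proto, fps = 10, seed = 3)
  ev <- attr(tr, "events")
  for (k in seq_len(nrow(ev))) {
    onset <- ev$frame[k]
    window <- tr$diameter_px[onset:(onset + 40 * 10 - 1)]
    pre <- mean(tr$diameter_px[max(1, onset - 50):(onset - 1)])
    expect_gte(max(window) - pre, 0.8 * 10)
  }
})

test_that("rendered masks reproduce the requested diameter", {
  scene <- scene_config(noise_sd = 0, blur_sigma = 0, vibrissae_count = 0,
                        highlight = FALSE, contrast_jitter_sd = 0,
                        eccentricity_max = 0)
  set.seed(9)
  fr <- render_frame(60, c(64, 80), scene)
  expect_lte(abs(measure_region(fr$mask)$diameter_px - 60), 1)
  expect_true(all(fr$pixels[fr$mask] == scene$pupil_intensity))
  expect_error(render_frame(300, c(64, 80), scene), "does not fit")
})

test_that("the specular highlight saturates pixels near the pupil edge", {
  scene <- scene_config(noise_sd = 0, blur_sigma = 0, vibrissae_count = 0,
                        highlight = TRUE, contrast_jitter_sd = 0)
  set.seed(5)
  fr <- render_frame(50, c(64, 80), scene)
  idx <- which(fr$mask, arr.ind = TRUE)
  roi <- fr$pixels[min(idx[, 1]):max(idx[, 1]), min(idx[, 2]):max(idx[, 2])]
  expect_true(any(roi == 255))
})

test_that("rendering is bit-identical under a fixed seed", {
  scene <- scene_config()
  set.seed(77)
  a <- render_frame(40, c(64, 80), scene)
  set.seed(77)
  b <- render_frame(40, c(64, 80), scene)
  expect_identical(a, b)
})

test_that("a generated fixture set is complete, faithful and self-consistent", {
  out <- withr::local_tempdir()
  proto <- protocol_config(baseline_s = 30, n_stimuli = 0, inter_stimulus_s = 1,
                           drift_sd = 0.02, tremor_sd = 0.08)
  gen <- generate_video_with_truth(proto, clean_scene(c(96, 96)), out, seed = 6)
  expect_equal(gen$n_frames, 300)
  expect_length(list.files(gen$frames_dir, pattern = "frame_.*png"), 300)
  expect_length(list.files(gen$masks_dir, pattern = "mask_.*png"), 300)
  expect_length(readLines(gen$truth_csv), 301)

  truth <- utils::read.csv(gen$truth_csv)
  # ground-truth fidelity: measured mask diameter within 1 px of the trace
  expect_true(all(abs(truth$diameter_px - truth$true_diameter_px) <= 1))

  # identity loop closure through the evaluation module
  masks <- read_mask_dir(gen$masks_dir)
  ev <- evaluate_dataset(masks, masks)
  expect_equal(ev$aggregate$mean_iou, 1)
  expect_equal(ev$aggregate$mape_pd, 0)
})

test_that("identical configs and seed give byte-identical fixtures", {
  proto <- short_protocol(baseline_s = 2, n_stimuli = 0, inter_stimulus_s = 1)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  generate_video_with_truth(proto, scene_config(), d1, seed = 12)
  generate_video_with_truth(proto, scene_config(), d2, seed = 12)
  f1 <- list.files(d1, recursive = TRUE)
  f2 <- list.files(d2, recursive = TRUE)
  expect_identical(f1, f2)
  for (f in f1) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = f)
  }
})

test_that("tracker quality degrades monotonically with sensor noise", {
  proto <- short_protocol(baseline_s = 4, n_stimuli = 0, inter_stimulus_s = 1)
  med_iou <- vapply(c(0, 5, 15, 30), function(ns) {
    out <- withr::local_tempdir()
    scene <- scene_config(frame_shape = c(96, 96), noise_sd = ns,
                          blur_sigma = 0.8, vibrissae_count = 0,
                          highlight = FALSE, contrast_jitter_sd = 0)
    gen <- generate_video_with_truth(proto, scene, out, seed = 20)
    src <- frame_source(gen$frames_dir)
    truth <- read_mask_dir(gen$masks_dir)
    trk <- track_video(src, box_around(truth[[1]], pad = 8))
    ev <- evaluate_dataset(truth, trk$mask)
    stats::median(ev$per_frame$iou)
  }, numeric(1))
  expect_true(all(diff(med_iou) <= 0))
  expect_gte(med_iou[1], 0.9)
})
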