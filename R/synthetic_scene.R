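#' Scene configuration for the synthetic eye-video generator
#'
#' Describes the optical conditions the generator emulates: a dark,
#' low-contrast pupil on a brighter iris under dim infrared illumination,
#' recorded as 8-bit monochrome frames. Defaults model the target recording
#' setup at a desk-friendly resolution (the rig records 1024x1280 at 10 fps;
#' the default frame is the same aspect at 1/8 scale).
#'
#' @param frame_shape Integer `(rows, cols)` of each frame.
#' @param fps Frame rate in frames/second (default 10).
#' @param iris_intensity,pupil_intensity Mean 8-bit gray levels of iris and
#'   pupil (defaults 120 and 35; the pupil must be darker).
#' @param contrast_jitter_sd Per-frame Gaussian jitter (gray levels) applied
#'   to both intensities, emulating illumination flicker.
#' @param highlight Draw a specular corneal highlight (a saturated disc
#'   overlapping the pupil edge)?
#' @param highlight_radius Radius of that highlight in px.
#' @param vibrissae_count Number of dark whisker strokes crossing the frame.
#' @param vibrissa_width Stroke half-width in px.
#' @param blur_sigma Gaussian blur sigma in px (moisturising-gel softening).
#' @param noise_sd Additive Gaussian noise sigma in gray levels (clipped to
#'   0..255).
#' @param eccentricity_max Upper bound of the per-frame pupil eccentricity
#'   jitter (the pupil is nearly circular; default 0.15).
#' @param center_jitter_sd Per-frame random-walk step (px) of the pupil
#'   center, emulating slow eye drift.
#' @return A `scene_config` list.
#' @export
scene_config <- function(frame_shape = c(128, 160), fps = 10,
                         iris_intensity = 120, pupil_intensity = 35,
                         contrast_jitter_sd = 2,
                         highlight = TRUE, highlight_radius = 3,
                         vibrissae_count = 2, vibrissa_width = 1.2,
                         blur_sigma = 1.0, noise_sd = 3,
                         eccentricity_max = 0.15, center_jitter_sd = 0.2) {
  if (pupil_intensity >= iris_intensity) {
    rlang::abort("The pupil must be darker than the iris (pupil_intensity < iris_intensity).")
  }
  if (fps <= 0) rlang::abort("`fps` must be positive.")
  if (any(c(iris_intensity, pupil_intensity) < 0) ||
      any(c(iris_intensity, pupil_intensity) > 255)) {
    rlang::abort("Intensities must be within 0..255.")
  }
  structure(as.list(environment()), class = "scene_config")
}

#' Stimulation-protocol configuration
#'
#' Timing and dynamics of the recorded experiment the generator emulates:
#' a baseline period followed by evenly spaced stimulus-evoked pupil
#' dilations. Defaults follow the recording protocol this tool targets —
#' 60 s of baseline, then four stimuli at 100 s intervals, at 10 fps.
#' The evoked response is a double-exponential kernel (fast rise, slow
#' decay) with unit peak scaled by `dilation_amplitude_px`; published
#' recordings show such transient dilations only qualitatively, so kernel
#' shape and amplitude are exposed here and default to physiologically
#' plausible magnitudes (a 25-30\% diameter increase).
#'
#' @param baseline_s Baseline duration before the first stimulus (s).
#' @param n_stimuli Number of stimuli.
#' @param inter_stimulus_s Interval between consecutive stimuli (s); the
#'   recording ends one interval after the last stimulus.
#' @param baseline_diameter_px Resting pupil diameter (px).
#' @param dilation_amplitude_px Peak evoked dilation above baseline (px).
#' @param rise_s,decay_s Time constants of the double-exponential kernel (s).
#' @param drift_sd Per-frame random-walk step of slow baseline drift (px).
#' @param tremor_sd Per-frame white tremor of the diameter (px).
#' @return A `protocol_config` list.
#' @export
protocol_config <- function(baseline_s = 60, n_stimuli = 4,
                            inter_stimulus_s = 100,
                            baseline_diameter_px = 40,
                            dilation_amplitude_px = 12,
                            rise_s = 2, decay_s = 15,
                            drift_sd = 0.02, tremor_sd = 0.08) {
  if (baseline_s <= 0 || inter_stimulus_s <= 0) {
    rlang::abort("Durations must be positive.")
  }
  if (rise_s <= 0 || decay_s <= 0 || rise_s >= decay_s) {
    rlang::abort("Need 0 < rise_s < decay_s for the evoked-response kernel.")
  }
  if (dilation_amplitude_px < 0) rlang::abort("Amplitude must be >= 0.")
  if (n_stimuli < 0) rlang::abort("`n_stimuli` must be >= 0.")
  structure(as.list(environment()), class = "protocol_config")
}

# double-exponential evoked kernel, unit peak, zero before onset
evoked_kernel <- function(s, rise_s, decay_s) {
  peak_t <- rise_s * decay_s / (decay_s - rise_s) * log(decay_s / rise_s)
  peak <- exp(-peak_t / decay_s) - exp(-peak_t / rise_s)
  ifelse(s < 0, 0, (exp(-s / decay_s) - exp(-s / rise_s)) / peak)
}

#' Simulate a ground-truth pupil diameter trace
#'
#' Builds the per-frame true diameter: baseline, slow random-walk drift,
#' one double-exponential evoked dilation per stimulus, and white tremor.
#' Deterministic for a fixed seed.
#'
#' @param protocol A [protocol_config()].
#' @param fps Frame rate (frames/second).
#' @param seed Integer seed for drift and tremor.
#' @return A tibble with `frame` (1-based), `time_s`, `diameter_px` and
#'   `event` (0 away from stimuli, the stimulus number at its onset frame).
#'   Attribute `events` holds a tibble of stimulus onsets with `event`,
#'   `time_s`, `frame` (1-based row index) and `frames_elapsed`
#'   (`time_s * fps`, the number of frames before the onset).
#' @export
simulate_pupil_trace <- function(protocol = protocol_config(), fps = 10,
                                 seed = 1) {
  stopifnot(inherits(protocol, "protocol_config"))
  if (fps <= 0) rlang::abort("`fps` must be positive.")
  total_s <- protocol$baseline_s + protocol$n_stimuli * protocol$inter_stimulus_s
  n <- round(total_s * fps)
  t <- (seq_len(n) - 1) / fps
  set.seed(seed)
  drift <- cumsum(stats::rnorm(n, 0, protocol$drift_sd))
  tremor <- stats::rnorm(n, 0, protocol$tremor_sd)
  d <- protocol$baseline_diameter_px + drift + tremor
  ev_times <- if (protocol$n_stimuli > 0) {
    protocol$baseline_s + (seq_len(protocol$n_stimuli) - 1) * protocol$inter_stimulus_s
  } else {
    numeric(0)
  }
  for (te in ev_times) {
    d <- d + protocol$dilation_amplitude_px *
      evoked_kernel(t - te, protocol$rise_s, protocol$decay_s)
  }
  d <- pmax(d, 2)
  event <- integer(n)
  ev_frames <- round(ev_times * fps) + 1L
  event[ev_frames] <- seq_along(ev_frames)
  out <- tibble::tibble(frame = seq_len(n), time_s = t, diameter_px = d,
                        event = event)
  attr(out, "events") <- tibble::tibble(
    event = seq_along(ev_times),
    time_s = ev_times,
    frame = ev_frames,
    frames_elapsed = round(ev_times * fps)
  )
  out
}

# pixel-center ellipse mask; semi-axes inflated by half a pixel so that the
# farthest-pixel distance of the raster matches the requested diameter
ellipse_mask <- function(shape, center, diameter_px, ecc = 0, angle = 0) {
  a <- diameter_px / 2 + 0.5
  b <- (diameter_px / 2) * sqrt(1 - ecc^2) + 0.5
  rows <- seq_len(shape[1]) - center[1]
  cols <- seq_len(shape[2]) - center[2]
  dr <- matrix(rows, shape[1], shape[2])
  dc <- matrix(cols, shape[1], shape[2], byrow = TRUE)
  u <- dc * cos(angle) + dr * sin(angle)
  v <- -dc * sin(angle) + dr * cos(angle)
  (u / a)^2 + (v / b)^2 <= 1
}

# row/column Gaussian smoothing matrix with truncated, renormalised kernels
blur_matrix <- function(n, sigma) {
  if (sigma <= 0) return(NULL)
  i <- seq_len(n)
  w <- exp(-outer(i, i, "-")^2 / (2 * sigma^2))
  w[abs(outer(i, i, "-")) > ceiling(3 * sigma)] <- 0
  w / rowSums(w)
}

#' Render one synthetic eye frame with its ground-truth mask
#'
#' Draws an elliptical pupil of the requested diameter on an iris
#' background, then applies the configured artifacts in order: specular
#' highlight, vibrissae strokes, Gaussian blur, additive noise. The
#' ground-truth mask is the noiseless, pre-blur pupil ellipse — blur and
#' noise degrade the image, never the truth.
#'
#' Uses the current RNG state for all jitters; seed the session (or use
#' [generate_video_with_truth()]) for reproducibility.
#'
#' @param diameter_px True pupil diameter in px.
#' @param center Pupil center `(row, col)`.
#' @param scene A [scene_config()].
#' @return A list with `pixels` (matrix of 0..255 intensities) and `mask`
#'   (logical ground-truth matrix).
#' @export
render_frame <- function(diameter_px, center, scene = scene_config()) {
  stopifnot(inherits(scene, "scene_config"))
  shape <- scene$frame_shape
  if (center[1] - diameter_px / 2 < 1 || center[1] + diameter_px / 2 > shape[1] ||
      center[2] - diameter_px / 2 < 1 || center[2] + diameter_px / 2 > shape[2]) {
    rlang::abort("Pupil does not fit within the frame at the given center.")
  }
  ecc <- stats::runif(1, 0, scene$eccentricity_max)
  angle <- stats::runif(1, 0, pi)
  mask <- ellipse_mask(shape, center, diameter_px, ecc, angle)

  jit <- stats::rnorm(1, 0, scene$contrast_jitter_sd)
  img <- matrix(scene$iris_intensity + jit, shape[1], shape[2])
  img[mask] <- scene$pupil_intensity + jit

  if (isTRUE(scene$highlight)) {
    # saturated disc straddling the pupil edge at a random bearing
    th <- stats::runif(1, 0, 2 * pi)
    hc <- center + (diameter_px / 2) * c(-sin(th), cos(th))
    hr <- seq_len(shape[1]) - hc[1]
    hcl <- seq_len(shape[2]) - hc[2]
    d2 <- outer(hr^2, hcl^2, "+")
    img[d2 <= scene$highlight_radius^2] <- 255
  }

  if (scene$vibrissae_count > 0) {
    rows <- matrix(seq_len(shape[1]), shape[1], shape[2])
    cols <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
    for (k in seq_len(scene$vibrissae_count)) {
      # a dark stroke through a random point, at a random angle
      p0 <- c(stats::runif(1, 1, shape[1]), stats::runif(1, 1, shape[2]))
      th <- stats::runif(1, 0, pi)
      # distance from each pixel to the infinite line through p0
      dist <- abs(-sin(th) * (cols - p0[2]) + cos(th) * (rows - p0[1]))
      w <- pmax(0, 1 - dist / scene$vibrissa_width) # anti-aliased profile
      img <- img * (1 - 0.6 * w) + 45 * 0.6 * w
    }
  }

  if (scene$blur_sigma > 0) {
    kr <- blur_matrix(shape[1], scene$blur_sigma)
    kc <- blur_matrix(shape[2], scene$blur_sigma)
    img <- kr %*% img %*% t(kc)
  }
  if (scene$noise_sd > 0) {
    img <- img + stats::rnorm(length(img), 0, scene$noise_sd)
  }
  img <- matrix(pmin(pmax(round(img), 0), 255), shape[1], shape[2])
  list(pixels = img, mask = mask)
}

#' Generate a synthetic eye video with per-frame ground truth
#'
#' Simulates the diameter trace for the protocol, renders every frame, and
#' writes a complete fixture set: a numbered PNG frame sequence (readable by
#' [frame_source()]), one ground-truth mask PNG per frame, and a truth CSV
#' in the pupillogram schema (measurements taken on the truth masks) plus
#' `true_diameter_px` (the requested trace value) and `event` columns.
#' Byte-identical outputs for identical configurations and seed.
#'
#' @param protocol A [protocol_config()].
#' @param scene A [scene_config()].
#' @param out_dir Output directory (created if missing); frames go to
#'   `out_dir/frames`, masks to `out_dir/masks`, the table to
#'   `out_dir/truth.csv`.
#' @param seed Integer seed driving the trace and every rendering jitter.
#' @param center Pupil center `(row, col)`; default the frame center.
#' @return Invisibly, a list with `frames_dir`, `masks_dir`, `truth_csv`,
#'   `trace` (the simulated trace tibble) and `n_frames`.
#' @export
generate_video_with_truth <- function(protocol = protocol_config(),
                                      scene = scene_config(),
                                      out_dir, seed = 1, center = NULL) {
  stopifnot(inherits(protocol, "protocol_config"),
            inherits(scene, "scene_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) rlang::abort(sprintf("Cannot create %s", out_dir))
  frames_dir <- file.path(out_dir, "frames")
  masks_dir <- file.path(out_dir, "masks")
  dir.create(frames_dir, showWarnings = FALSE)
  dir.create(masks_dir, showWarnings = FALSE)
  if (is.null(center)) center <- (scene$frame_shape + 1) / 2

  trace <- simulate_pupil_trace(protocol, fps = scene$fps, seed = seed)
  n <- nrow(trace)
  # trace simulation reseeded the stream; rendering continues from here
  cen <- center
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    step <- stats::rnorm(2, 0, scene$center_jitter_sd)
    cen_new <- cen + step
    # keep the pupil inside the frame with a margin for the largest diameter
    lim <- max(trace$diameter_px) / 2 + 2
    cen_new[1] <- min(max(cen_new[1], 1 + lim), scene$frame_shape[1] - lim)
    cen_new[2] <- min(max(cen_new[2], 1 + lim), scene$frame_shape[2] - lim)
    cen <- cen_new
    fr <- render_frame(trace$diameter_px[i], cen, scene)
    png::writePNG(fr$pixels / 255, file.path(frames_dir, sprintf("frame_%06d.png", i)))
    png::writePNG(fr$mask * 1.0, file.path(masks_dir, sprintf("mask_%06d.png", i)))
    meas <- measure_region(fr$mask)
    rows[[i]] <- tibble::tibble(
      frame = i,
      timestamp_s = trace$time_s[i],
      centroid_x = meas$centroid_col,
      centroid_y = meas$centroid_row,
      area_px = meas$area_px,
      circularity = meas$circularity,
      diameter_px = meas$diameter_px,
      valid = meas$valid,
      true_diameter_px = trace$diameter_px[i],
      event = trace$event[i]
    )
  }
  truth <- dplyr::bind_rows(rows)
  truth_csv <- file.path(out_dir, "truth.csv")
  utils::write.csv(as.data.frame(truth), truth_csv, row.names = FALSE,
                   quote = FALSE)
  invisible(list(frames_dir = frames_dir, masks_dir = masks_dir,
                 truth_csv = truth_csv, trace = trace, n_frames = n))
}

#' Read the ground-truth masks of a generated fixture
#'
#' @param masks_dir Directory of `mask_*.png` files.
#' @return List of logical masks in frame order.
#' @export
read_mask_dir <- function(masks_dir) {
  files <- sort(list.files(masks_dir, pattern = "\\.(png|tif|tiff)$",
                           ignore.case = TRUE, full.names = TRUE))
  if (length(files) == 0L) {
    rlang::abort(sprintf("No mask images found in %s", masks_dir))
  }
  lapply(files, read_mask)
}
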