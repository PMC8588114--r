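# Fixture builders and independent brute-force oracles. The oracles here are
# deliberately naive (exhaustive loops, all-pairs distances) so they share no
# code path with the package implementations they check.

disc_mask <- function(r, pad = 3, center = NULL) {
  n <- 2 * r + 2 * pad + 1
  if (is.null(center)) center <- c(r + pad + 1, r + pad + 1)
  outer(seq_len(n), seq_len(n),
        function(i, j) (i - center[1])^2 + (j - center[2])^2 <= r^2)
}

# raster ellipse built independently of the generator's ellipse_mask
raster_ellipse <- function(shape, center, a, b, angle = 0) {
  m <- matrix(FALSE, shape[1], shape[2])
  for (i in seq_len(shape[1])) {
    for (j in seq_len(shape[2])) {
      u <- (j - center[2]) * cos(angle) + (i - center[1]) * sin(angle)
      v <- -(j - center[2]) * sin(angle) + (i - center[1]) * cos(angle)
      m[i, j] <- (u / a)^2 + (v / b)^2 <= 1
    }
  }
  m
}

random_mask <- function(nr, nc, p = 0.3) {
  matrix(stats::runif(nr * nc) < p, nr, nc)
}

# all-pairs maximum distance between TRUE pixel centers
bf_feret <- function(mask) {
  pts <- which(mask, arr.ind = TRUE)
  if (nrow(pts) < 2) return(0)
  max(stats::dist(pts))
}

# exhaustive per-pixel confusion counts
bf_confusion <- function(truth, pred) {
  tp <- fn <- fp <- tn <- 0L
  for (i in seq_len(nrow(truth))) {
    for (j in seq_len(ncol(truth))) {
      if (truth[i, j] && pred[i, j]) tp <- tp + 1L
      else if (truth[i, j]) fn <- fn + 1L
      else if (pred[i, j]) fp <- fp + 1L
      else tn <- tn + 1L
    }
  }
  list(tp = tp, fn = fn, fp = fp, tn = tn)
}

# two-intensity synthetic eye frame (no generator involvement)
flat_pupil_frame <- function(shape, center, r, pupil = 30, iris = 120) {
  px <- matrix(iris, shape[1], shape[2])
  m <- disc_like <- outer(seq_len(shape[1]), seq_len(shape[2]),
                          function(i, j) (i - center[1])^2 + (j - center[2])^2 <= r^2)
  px[m] <- pupil
  list(pixels = px, mask = m)
}

clean_scene <- function(frame_shape = c(128, 160)) {
  scene_config(frame_shape = frame_shape, noise_sd = 0, blur_sigma = 0.8,
               vibrissae_count = 0, highlight = FALSE, contrast_jitter_sd = 0)
}

short_protocol <- function(baseline_s = 10, n_stimuli = 1, inter_stimulus_s = 20) {
  protocol_config(baseline_s = baseline_s, n_stimuli = n_stimuli,
                  inter_stimulus_s = inter_stimulus_s)
}

# bounding box around the TRUE pixels of a mask, padded
box_around <- function(mask, pad = 8) {
  idx <- which(mask, arr.ind = TRUE)
  bbox(max(1, min(idx[, 1]) - pad), max(1, min(idx[, 2]) - pad),
       min(nrow(mask), max(idx[, 1]) + pad), min(ncol(mask), max(idx[, 2]) + pad))
}
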