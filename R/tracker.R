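#' Bounding box constructor
#'
#' Rows and columns are 1-based and inclusive, matching R matrix indexing.
#'
#' @param row_min,col_min,row_max,col_max Integer box edges, inclusive.
#' @return An integer vector of class `pupil_bbox`.
#' @export
bbox <- function(row_min, col_min, row_max, col_max) {
  b <- as.integer(c(row_min, col_min, row_max, col_max))
  if (anyNA(b)) rlang::abort("Bounding box edges must be integers.")
  if (b[1] < 1L || b[2] < 1L || b[3] < b[1] || b[4] < b[2]) {
    rlang::abort("Degenerate bounding box: need 1 <= row_min <= row_max and 1 <= col_min <= col_max.")
  }
  structure(b, names = c("row_min", "col_min", "row_max", "col_max"),
            class = "pupil_bbox")
}

assert_box_in_frame <- function(box, dm) {
  if (box[3] > dm[1] || box[4] > dm[2]) {
    rlang::abort(sprintf(
      "Bounding box [%d,%d]x[%d,%d] exceeds frame of %dx%d px.",
      box[1], box[3], box[2], box[4], dm[1], dm[2]))
  }
}

box_area <- function(box) (box[3] - box[1] + 1L) * (box[4] - box[2] + 1L)

# Otsu threshold on a 256-bin histogram of 8-bit intensities; returns the
# gray level t maximising between-class variance (pixels <= t are "dark").
# NULL when the histogram cannot be split (uniform region).
otsu_threshold <- function(values) {
  h <- tabulate(as.integer(values) + 1L, nbins = 256L)
  n <- sum(h)
  lev <- 0:255
  w0 <- cumsum(h)
  w1 <- n - w0
  mu0 <- cumsum(h * lev) / pmax(w0, 1)
  mu_tot <- sum(h * lev) / n
  mu1 <- (mu_tot * n - cumsum(h * lev)) / pmax(w1, 1)
  valid <- w0 > 0 & w1 > 0
  if (!any(valid)) return(NULL)
  sigma_b <- w0 * w1 * (mu0 - mu1)^2
  sigma_b[!valid] <- -Inf
  if (max(sigma_b) <= 0) return(NULL)
  lev[which.max(sigma_b)]
}

#' Initialise the pupil tracker from a bounding box
#'
#' Reproduces the classical first-frame step: inside the user-drawn box an
#' automatic (Otsu) threshold separates the dark pupil from the brighter
#' iris, the largest dark 8-connected component becomes the initial pupil
#' mask, and its mean intensity the initial reference gray level.
#'
#' @param pixels Matrix of 8-bit intensities (one grayscale frame).
#' @param box A [bbox()] (or 4-vector `row_min,col_min,row_max,col_max`)
#'   drawn around the pupil in this frame; must contain at least 25 pixels.
#' @param margin_gray_levels Threshold slack in gray levels added to the
#'   reference intensity when segmenting subsequent frames (default 10).
#' @param min_region_fraction Components smaller than this fraction of the
#'   box area are discarded as noise in subsequent frames (default 0.005).
#' @return A `pupil_tracker` state list with fields `prev_mask`,
#'   `prev_centroid` (row, col), `reference_intensity`, `init_box`,
#'   `margin_gray_levels`, `min_region_fraction`, `dim`.
#' @export
tracker_init <- function(pixels, box, margin_gray_levels = 10,
                         min_region_fraction = 0.005) {
  if (!is.matrix(pixels)) rlang::abort("`pixels` must be a matrix.")
  if (!inherits(box, "pupil_bbox")) box <- bbox(box[1], box[2], box[3], box[4])
  assert_box_in_frame(box, dim(pixels))
  if (box_area(box) < 25L) {
    rlang::abort("Bounding box must contain at least 25 pixels.")
  }
  if (!(min_region_fraction > 0 && min_region_fraction < 1)) {
    rlang::abort("`min_region_fraction` must be in (0, 1).")
  }
  roi <- pixels[box[1]:box[3], box[2]:box[4], drop = FALSE]
  thr <- otsu_threshold(roi)
  if (is.null(thr)) {
    rlang::abort("Initialisation failed: no dark component found inside the box (uniform intensity).")
  }
  dark <- roi <= thr
  if (!any(dark)) {
    rlang::abort("Initialisation failed: no dark component found inside the box.")
  }
  comp <- largest_component(dark)
  mask <- matrix(FALSE, nrow(pixels), ncol(pixels))
  mask[box[1]:box[3], box[2]:box[4]] <- comp
  ac <- region_area_centroid(mask)
  structure(
    list(
      prev_mask = mask,
      prev_centroid = ac$centroid,
      reference_intensity = mean(pixels[mask]),
      init_box = box,
      margin_gray_levels = margin_gray_levels,
      min_region_fraction = min_region_fraction,
      dim = dim(pixels)
    ),
    class = "pupil_tracker"
  )
}

#' Reference intensity from 13 deterministic sample points
#'
#' The adaptive threshold for each frame is the mean gray level of 13 pixels
#' inside the previous frame's pupil: the mask centroid plus 6 points on a
#' ring of radius r/3 and 6 on a ring of radius 2r/3, where r is the
#' equivalent-circle radius of the mask (`sqrt(area/pi)`) and the ring
#' angles are 0, 60, ..., 300 degrees. Each point is snapped to the nearest
#' pixel; a snapped point falling outside the mask is replaced by the
#' nearest mask pixel. Duplicates are kept so exactly 13 samples are always
#' averaged. Angles are measured from the +column axis, counter-clockwise in
#' image coordinates (row offset \eqn{-r\sin\theta}, column offset
#' \eqn{r\cos\theta}).
#'
#' @param pixels Intensity matrix of the frame to sample.
#' @param mask Non-empty logical pupil mask of the same shape.
#' @return Mean of the 13 sampled intensities.
#' @export
sample_reference_intensity <- function(pixels, mask) {
  assert_mask(mask, allow_empty = FALSE)
  if (!identical(dim(pixels), dim(mask))) {
    rlang::abort("`pixels` and `mask` must have the same shape.")
  }
  pts <- sample_points_13(mask)
  mean(pixels[pts])
}

# the 13 sampling coordinates as an n x 2 index matrix (duplicates kept)
sample_points_13 <- function(mask) {
  ac <- region_area_centroid(mask)
  r <- sqrt(ac$area / pi)
  ang <- seq(0, 300, by = 60) * pi / 180
  offs <- rbind(
    c(0, 0),
    cbind(-(r / 3) * sin(ang), (r / 3) * cos(ang)),
    cbind(-(2 * r / 3) * sin(ang), (2 * r / 3) * cos(ang))
  )
  pts <- cbind(round(ac$centroid[1] + offs[, 1]),
               round(ac$centroid[2] + offs[, 2]))
  idx <- which(mask, arr.ind = TRUE)
  for (k in seq_len(nrow(pts))) {
    r0 <- pts[k, 1]; c0 <- pts[k, 2]
    inside <- r0 >= 1 && r0 <= nrow(mask) && c0 >= 1 && c0 <= ncol(mask) &&
      mask[r0, c0]
    if (!inside) {
      d2 <- (idx[, 1] - r0)^2 + (idx[, 2] - c0)^2
      pts[k, ] <- idx[which.min(d2), ]
    }
  }
  storage.mode(pts) <- "integer"
  pts
}

#' Segment the pupil in one frame and advance the tracker
#'
#' One step of the frame-to-frame adaptive-threshold algorithm:
#' \enumerate{
#'   \item candidate pixels are those with intensity at most
#'     `reference_intensity + margin_gray_levels`;
#'   \item candidates are labelled into 8-connected components;
#'   \item components smaller than `min_region_fraction` of the initial box
#'     area, and components whose centroid lies outside the initial box, are
#'     removed;
#'   \item of the survivors, the component whose centroid is nearest
#'     (Euclidean) to the previous pupil centroid is the pupil.
#' }
#' On success the state advances: the mask and centroid are stored and the
#' reference intensity is re-sampled on the new mask via
#' [sample_reference_intensity()]. If no component survives (blink, flash,
#' occlusion) the frame is flagged invalid, an empty mask is returned and
#' the state carries forward unchanged so tracking resumes after the
#' artifact.
#'
#' @param state A `pupil_tracker` from [tracker_init()].
#' @param pixels Intensity matrix of the next frame (same shape as at init).
#' @return A list with `mask` (logical matrix), `valid` (flag) and `state`
#'   (updated tracker state).
#' @export
track_frame <- function(state, pixels) {
  if (!inherits(state, "pupil_tracker")) {
    rlang::abort("`state` must be a `pupil_tracker` (see tracker_init()).")
  }
  if (!identical(dim(pixels), state$dim)) {
    rlang::abort("Frame shape does not match the tracker state.")
  }
  thr <- state$reference_intensity + state$margin_gray_levels
  cand <- pixels <= thr
  empty <- matrix(FALSE, state$dim[1], state$dim[2])
  if (!any(cand)) {
    return(list(mask = empty, valid = FALSE, state = state))
  }
  lab <- cc_label_8(cand)
  n <- max(lab)
  sizes <- tabulate(lab[lab > 0L], nbins = n)
  min_area <- state$min_region_fraction * box_area(state$init_box)
  idx <- which(cand, arr.ind = TRUE)
  labs <- lab[cand]
  cen_r <- rowsum(as.numeric(idx[, 1]), labs)[, 1] / sizes
  cen_c <- rowsum(as.numeric(idx[, 2]), labs)[, 1] / sizes
  box <- state$init_box
  keep <- sizes >= min_area &
    cen_r >= box[1] & cen_r <= box[3] &
    cen_c >= box[2] & cen_c <= box[4]
  if (!any(keep)) {
    return(list(mask = empty, valid = FALSE, state = state))
  }
  d2 <- (cen_r - state$prev_centroid[1])^2 + (cen_c - state$prev_centroid[2])^2
  d2[!keep] <- Inf
  sel <- which.min(d2)
  mask <- lab == sel
  state$prev_mask <- mask
  state$prev_centroid <- c(cen_r[sel], cen_c[sel])
  state$reference_intensity <- sample_reference_intensity(pixels, mask)
  list(mask = mask, valid = TRUE, state = state)
}

#' Adaptive-threshold segmentation backend
#'
#' Wraps the classical tracker in the generic backend contract used by
#' [track_video()]: `reset(pixels, box)` initialises on a first frame and
#' returns its mask; `segment(pixels)` segments a subsequent frame and
#' returns `list(mask, valid)`. Any other segmenter (e.g. a trained model
#' behind an external process) can be substituted by providing the same two
#' closures.
#'
#' @inheritParams tracker_init
#' @return An object of class `pupil_backend`.
#' @export
adaptive_threshold_backend <- function(margin_gray_levels = 10,
                                       min_region_fraction = 0.005) {
  env <- new.env(parent = emptyenv())
  structure(
    list(
      name = "adaptive_threshold",
      reset = function(pixels, box) {
        env$state <- tracker_init(pixels, box,
                                  margin_gray_levels = margin_gray_levels,
                                  min_region_fraction = min_region_fraction)
        list(mask = env$state$prev_mask, valid = TRUE)
      },
      segment = function(pixels) {
        res <- track_frame(env$state, pixels)
        env$state <- res$state
        res[c("mask", "valid")]
      }
    ),
    class = "pupil_backend"
  )
}

#' Track the pupil through a whole video
#'
#' Initialises the segmentation backend on the first frame using the
#' user-drawn bounding box, then segments every subsequent frame. The output
#' has exactly one row per input frame and is fully deterministic for a
#' fixed input, box and configuration.
#'
#' @param source A `pupil_frame_source` (see [frame_source()]), or a list of
#'   intensity matrices.
#' @param box Initial pupil [bbox()] on the first frame.
#' @param backend Segmentation backend; default the classical
#'   [adaptive_threshold_backend()].
#' @param fps_fallback Frame rate used for timestamps when `source` is a
#'   plain list of matrices.
#' @param keep_masks Keep per-frame masks as a list-column (default `TRUE`;
#'   turn off for very long videos).
#' @param mm_per_px Optional calibration passed to [measure_region()].
#' @return A tibble of class `pupil_tracking`: one row per frame with
#'   `frame`, `timestamp_s`, `valid`, the [measure_region()] metrics and
#'   (optionally) a `mask` list-column.
#' @export
track_video <- function(source, box, backend = adaptive_threshold_backend(),
                        fps_fallback = 10, keep_masks = TRUE,
                        mm_per_px = NULL) {
  if (is.list(source) && !inherits(source, "pupil_frame_source")) {
    frames <- source
    n <- length(frames)
    if (n == 0L) rlang::abort("Empty frame source.")
    get_frame <- function(i) list(index = i, timestamp_s = (i - 1) / fps_fallback,
                                  pixels = frames[[i]])
  } else {
    n <- length(source)
    get_frame <- function(i) source_frame(source, i)
  }
  rows <- vector("list", n)
  masks <- if (keep_masks) vector("list", n) else NULL
  for (i in seq_len(n)) {
    fr <- get_frame(i)
    res <- if (i == 1L) {
      tryCatch(
        backend$reset(fr$pixels, box),
        error = function(e) {
          rlang::abort(sprintf("Tracker initialisation failed on frame 1: %s",
                               conditionMessage(e)))
        }
      )
    } else {
      backend$segment(fr$pixels)
    }
    meas <- measure_region(res$mask, mm_per_px = mm_per_px)
    meas$valid <- res$valid && meas$valid
    rows[[i]] <- tibble::add_column(meas, frame = fr$index,
                                    timestamp_s = fr$timestamp_s, .before = 1)
    if (keep_masks) masks[[i]] <- res$mask
  }
  out <- dplyr::bind_rows(rows)
  if (keep_masks) out$mask <- masks
  class(out) <- c("pupil_tracking", class(out))
  out
}

#' Plot a tracked pupillogram
#'
#' Pupil diameter against time, with invalid frames marked along the axis.
#'
#' @param object A `pupil_tracking` tibble from [track_video()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pupil_tracking <- function(object, ...) {
  df <- as.data.frame(object[, c("timestamp_s", "diameter_px", "valid")])
  p <- ggplot2::ggplot(df[df$valid, ],
                       ggplot2::aes(x = .data$timestamp_s, y = .data$diameter_px)) +
    ggplot2::geom_line(colour = "#2c7fb8") +
    ggplot2::labs(x = "time (s)", y = "pupil diameter (px)",
                  title = "Pupillogram") +
    ggplot2::theme_minimal()
  if (any(!df$valid)) {
    p <- p + ggplot2::geom_rug(data = df[!df$valid, ],
                               ggplot2::aes(x = .data$timestamp_s),
                               inherit.aes = FALSE, colour = "red")
  }
  p
}
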