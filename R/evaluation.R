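#' Pixel confusion tally between a ground-truth and a predicted mask
#'
#' The 2x2 table of pixel counts feeding every segmentation metric:
#' `p[i, j]` is the number of pixels whose true class is `i` and predicted
#' class is `j`, with classes `pupil` and `background`.
#'
#' @param truth,pred Logical matrices of equal shape, `TRUE` = pupil.
#' @return A `confusion_tally`: 2x2 integer matrix with dimnames
#'   `truth`/`pred` over classes `c("pupil", "background")`.
#' @export
confusion_tally <- function(truth, pred) {
  assert_mask(truth, arg = "truth")
  assert_mask(pred, arg = "pred")
  if (!identical(dim(truth), dim(pred))) {
    rlang::abort("`truth` and `pred` must have the same shape.")
  }
  tp <- sum(truth & pred)
  fn <- sum(truth & !pred)
  fp <- sum(!truth & pred)
  tn <- sum(!truth & !pred)
  p <- matrix(c(tp, fp, fn, tn), nrow = 2,
              dimnames = list(truth = c("pupil", "background"),
                              pred = c("pupil", "background")))
  structure(p, class = c("confusion_tally", "matrix"))
}

assert_tally <- function(tally) {
  if (!inherits(tally, "confusion_tally")) {
    rlang::abort("Expected a `confusion_tally` (see confusion_tally()).")
  }
  invisible(tally)
}

resolve_class <- function(tally, class) {
  cls <- rownames(tally)
  if (is.numeric(class)) class <- cls[class]
  if (!class %in% cls) {
    rlang::abort(sprintf("Unknown class '%s'.", as.character(class)))
  }
  class
}

#' Intersection over union for one class
#'
#' \eqn{IoU_i = p_{ii} / (\sum_j p_{ij} + \sum_j p_{ji} - p_{ii})}: the
#' intersection of ground truth and prediction over their union. The
#' headline per-frame metric is the pupil-class IoU — with a small pupil on
#' a large background, pixel accuracy and mIoU are dominated by the
#' background class.
#'
#' @param tally A [confusion_tally()].
#' @param class Class name (`"pupil"` or `"background"`) or index; default
#'   the pupil class.
#' @return IoU in `[0, 1]`.
#' @export
iou <- function(tally, class = "pupil") {
  assert_tally(tally)
  class <- resolve_class(tally, class)
  pii <- tally[class, class]
  denom <- sum(tally[class, ]) + sum(tally[, class]) - pii
  if (denom <= 0) {
    rlang::abort(sprintf(
      "IoU undefined for class '%s': absent from both truth and prediction.",
      class))
  }
  as.numeric(pii / denom)
}

#' Mean intersection over union across classes
#'
#' @inheritParams iou
#' @return Mean of the per-class IoU values.
#' @export
miou <- function(tally) {
  assert_tally(tally)
  mean(vapply(rownames(tally), function(cl) iou(tally, cl), numeric(1)))
}

#' Pixel accuracy
#'
#' \eqn{\sum_i p_{ii} / \sum_i t_i}: the fraction of all pixels classified
#' correctly.
#'
#' @inheritParams iou
#' @return Accuracy in `[0, 1]`.
#' @export
pixel_accuracy <- function(tally) {
  assert_tally(tally)
  total <- sum(tally)
  if (total <= 0) rlang::abort("Empty tally.")
  as.numeric(sum(diag(tally)) / total)
}

#' Mean per-class accuracy
#'
#' \eqn{(1/k) \sum_i p_{ii} / t_i} with \eqn{t_i} the true pixel count of
#' class `i`.
#'
#' @inheritParams iou
#' @return Accuracy in `[0, 1]`.
#' @export
mean_accuracy <- function(tally) {
  assert_tally(tally)
  t_i <- rowSums(tally)
  if (any(t_i == 0)) {
    rlang::abort(sprintf(
      "Mean accuracy undefined: class '%s' absent from ground truth.",
      rownames(tally)[which(t_i == 0)[1]]))
  }
  mean(diag(tally) / t_i)
}

#' Mean absolute percentage error
#'
#' \eqn{\mathrm{MAPE} = \frac{100}{N}\sum_t |G_t - P_t| / G_t} between a
#' ground-truth series `g` and a predicted series `p`, reported in percent.
#'
#' @param g Ground-truth values, all strictly positive.
#' @param p Predicted values, same length as `g`.
#' @return MAPE in percent (single non-negative number).
#' @export
#' @examples
#' mape(c(100, 50), c(110, 45)) # 10
mape <- function(g, p) {
  if (length(g) != length(p)) rlang::abort("`g` and `p` must have equal length.")
  if (length(g) == 0L) rlang::abort("Empty series.")
  bad <- which(!(g > 0))
  if (length(bad) > 0L) {
    rlang::abort(paste0("MAPE requires positive ground truth; offending frames: ",
                        paste(utils::head(bad, 10), collapse = ", ")))
  }
  100 * mean(abs(g - p) / g)
}

#' Evaluate a predicted segmentation against ground truth
#'
#' Per-frame pupil IoU plus the absolute percentage errors of the derived
#' measurements (diameter, circularity, centroid coordinates), and their
#' aggregates: mean per-frame IoU (a pooled-pixel IoU is also reported) and
#' the MAPE of each measurement.
#'
#' @param truth_masks,pred_masks Lists of logical masks, aligned and of
#'   equal length.
#' @param truth_measures,pred_measures Optional data frames of per-frame
#'   measurements (as from [measure_region()], one row per frame); computed
#'   from the masks when omitted.
#' @return An object of class `pupil_eval` with elements `per_frame`
#'   (tibble: `frame`, `iou`, `ape_pd`, `ape_pc`, `ape_cx`, `ape_cy`) and
#'   `aggregate` (tibble: `n_frames`, `mean_iou`, `pooled_iou`, `mape_pd`,
#'   `mape_pc`, `mape_cx`, `mape_cy`). `tidy()` returns the per-frame table,
#'   `glance()` the aggregate row.
#' @export
evaluate_dataset <- function(truth_masks, pred_masks,
                             truth_measures = NULL, pred_measures = NULL) {
  n <- length(truth_masks)
  if (n == 0L) rlang::abort("Empty dataset.")
  if (length(pred_masks) != n) {
    rlang::abort(sprintf("Mask sequences must align: %d truth vs %d predicted.",
                         n, length(pred_masks)))
  }
  measure_all <- function(masks) {
    dplyr::bind_rows(lapply(masks, measure_region))
  }
  if (is.null(truth_measures)) truth_measures <- measure_all(truth_masks)
  if (is.null(pred_measures)) pred_measures <- measure_all(pred_masks)
  if (nrow(truth_measures) != n || nrow(pred_measures) != n) {
    rlang::abort("Measure tables must have one row per frame.")
  }

  per_iou <- numeric(n)
  inter <- 0; uni <- 0
  for (i in seq_len(n)) {
    tm <- truth_masks[[i]]; pm <- pred_masks[[i]]
    if (!identical(dim(tm), dim(pm))) {
      rlang::abort(sprintf("Frame %d: mask shapes differ.", i))
    }
    it <- sum(tm & pm); un <- sum(tm | pm)
    per_iou[i] <- if (un > 0) it / un else NA_real_
    inter <- inter + it; uni <- uni + un
  }
  ape <- function(gt, pr) 100 * abs(gt - pr) / gt
  per_frame <- tibble::tibble(
    frame = seq_len(n),
    iou = per_iou,
    ape_pd = ape(truth_measures$diameter_px, pred_measures$diameter_px),
    ape_pc = ape(truth_measures$circularity, pred_measures$circularity),
    ape_cx = ape(truth_measures$centroid_col, pred_measures$centroid_col),
    ape_cy = ape(truth_measures$centroid_row, pred_measures$centroid_row)
  )
  aggregate <- tibble::tibble(
    n_frames = n,
    mean_iou = mean(per_frame$iou, na.rm = TRUE),
    pooled_iou = if (uni > 0) inter / uni else NA_real_,
    mape_pd = mean(per_frame$ape_pd, na.rm = TRUE),
    mape_pc = mean(per_frame$ape_pc, na.rm = TRUE),
    mape_cx = mean(per_frame$ape_cx, na.rm = TRUE),
    mape_cy = mean(per_frame$ape_cy, na.rm = TRUE)
  )
  structure(list(per_frame = per_frame, aggregate = aggregate),
            class = "pupil_eval")
}

#' @export
print.pupil_eval <- function(x, ...) {
  cat("<pupil_eval>", x$aggregate$n_frames, "frames\n")
  print(x$aggregate)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname evaluate_dataset
#' @param x A `pupil_eval` object.
#' @param ... Unused.
#' @export
tidy.pupil_eval <- function(x, ...) x$per_frame

#' @rdname evaluate_dataset
#' @export
glance.pupil_eval <- function(x, ...) x$aggregate

#' Plot per-frame IoU against diameter percentage error
#'
#' The standard quality scatter: low-IoU frames need not imply large
#' diameter errors when the missed region does not span the farthest-pixel
#' chord.
#'
#' @param object A `pupil_eval` from [evaluate_dataset()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pupil_eval <- function(object, ...) {
  ggplot2::ggplot(object$per_frame,
                  ggplot2::aes(x = .data$iou, y = .data$ape_pd)) +
    ggplot2::geom_point(alpha = 0.5, colour = "#2c7fb8") +
    ggplot2::labs(x = "per-frame IoU", y = "diameter APE (%)",
                  title = "Segmentation quality vs diameter error") +
    ggplot2::theme_minimal()
}
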