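test_that("confusion tallies match the exhaustive per-pixel loop", {
  m <- random_mask(8, 8, 0.5)
  t_id <- confusion_tally(m, m)
  expect_equal(t_id["pupil", "background"], 0)
  expect_equal(t_id["background", "pupil"], 0)

  all_t <- matrix(TRUE, 4, 4)
  all_f <- matrix(FALSE, 4, 4)
  t2 <- confusion_tally(all_t, all_f)
  expect_equal(unname(t2["pupil", "background"]), 16)
  expect_equal(sum(t2) - t2["pupil", "background"], 0)

  set.seed(21)
  for (rep in 1:5) {
    truth <- random_mask(64, 64, runif(1, 0.1, 0.5))
    pred <- random_mask(64, 64, runif(1, 0.1, 0.5))
    tl <- confusion_tally(truth, pred)
    bf <- bf_confusion(truth, pred)
    expect_equal(unname(tl["pupil", "pupil"]), bf$tp)
    expect_equal(unname(tl["pupil", "background"]), bf$fn)
    expect_equal(unname(tl["background", "pupil"]), bf$fp)
    expect_equal(unname(tl["background", "background"]), bf$tn)
  }

  expect_error(confusion_tally(matrix(TRUE, 2, 2), matrix(TRUE, 3, 3)),
               "same shape")
})

test_that("IoU: identity, disjoint, and the hand-counted overlap case", {
  m <- disc_mask(5)
  expect_equal(iou(confusion_tally(m, m)), 1)
  expect_equal(miou(confusion_tally(m, m)), 1)

  a <- matrix(FALSE, 10, 10); a[1:2, 1:2] <- TRUE
  b <- matrix(FALSE, 10, 10); b[6:7, 6:7] <- TRUE
  expect_equal(iou(confusion_tally(a, b)), 0)

  # truth 4 px, prediction shifted to overlap 2 px: IoU = 2/6
  tr <- matrix(FALSE, 6, 6); tr[2:3, 2:3] <- TRUE
  pr <- matrix(FALSE, 6, 6); pr[3:4, 2:3] <- TRUE
  expect_equal(iou(confusion_tally(tr, pr)), 2 / 6)

  # pupil absent from both masks: undefined, not silently 0 or 1
  none <- matrix(FALSE, 5, 5)
  expect_error(iou(confusion_tally(none, none)), "absent")
})

test_that("pixel and mean accuracy behave at the boundary cases", {
  m <- random_mask(12, 12, 0.4)
  expect_equal(pixel_accuracy(confusion_tally(m, m)), 1)
  expect_equal(mean_accuracy(confusion_tally(m, m)), 1)
  expect_equal(pixel_accuracy(confusion_tally(m, !m)), 0)
  all_t <- matrix(TRUE, 5, 5)
  expect_error(mean_accuracy(confusion_tally(all_t, all_t)), "absent")
})

test_that("mIoU lies between the per-class IoUs", {
  set.seed(8)
  for (rep in 1:20) {
    truth <- random_mask(20, 20, runif(1, 0.2, 0.6))
    pred <- random_mask(20, 20, runif(1, 0.2, 0.6))
    tl <- confusion_tally(truth, pred)
    ious <- c(iou(tl, "pupil"), iou(tl, "background"))
    expect_gte(miou(tl), min(ious))
    expect_lte(miou(tl), max(ious))
  }
})

test_that("MAPE reproduces hand-evaluated cases and is scale invariant", {
  expect_equal(mape(c(5, 6, 7), c(5, 6, 7)), 0)
  expect_equal(mape(100, 98), 2, tolerance = 1e-12)
  expect_equal(mape(c(100, 50), c(110, 45)), 10, tolerance = 1e-12)

  set.seed(13)
  g <- runif(50, 10, 100)
  p <- g * runif(50, 0.8, 1.2)
  for (c0 in runif(5, 0.1, 50)) {
    expect_equal(mape(c0 * g, c0 * p), mape(g, p), tolerance = 1e-9)
  }
  expect_error(mape(c(1, 0, -2), c(1, 1, 1)), "offending frames: 2, 3")
  expect_error(mape(1:3, 1:2), "equal length")
})

test_that("dataset evaluation aggregates per-frame metrics faithfully", {
  set.seed(99)
  truth <- lapply(1:10, function(i) disc_mask(8 + (i %% 3), pad = 6))
  identical_eval <- evaluate_dataset(truth, truth)
  expect_equal(identical_eval$aggregate$mean_iou, 1)
  expect_equal(identical_eval$aggregate$mape_pd, 0)
  expect_equal(identical_eval$aggregate$mape_cx, 0)

  # dilate each prediction by one pixel ring and check the aggregate equals
  # the mean of independently computed per-frame values
  dilate1 <- function(m) {
    out <- m
    n <- nrow(m); p <- ncol(m)
    for (dr in -1:1) for (dc in -1:1) {
      rs <- pmin(pmax(1:n + dr, 1), n)
      cs <- pmin(pmax(1:p + dc, 1), p)
      out <- out | m[rs, cs]
    }
    out
  }
  pred <- lapply(truth, dilate1)
  ev <- evaluate_dataset(truth, pred)
  per_iou <- vapply(1:10, function(i) {
    sum(truth[[i]] & pred[[i]]) / sum(truth[[i]] | pred[[i]])
  }, numeric(1))
  expect_equal(ev$aggregate$mean_iou, mean(per_iou))
  per_pd <- vapply(1:10, function(i) {
    g <- measure_region(truth[[i]])$diameter_px
    p <- measure_region(pred[[i]])$diameter_px
    100 * abs(g - p) / g
  }, numeric(1))
  expect_equal(ev$aggregate$mape_pd, mean(per_pd))

  expect_error(evaluate_dataset(list(), list()), "Empty dataset")
  expect_error(evaluate_dataset(truth, truth[1:3]), "align")

  td <- tidy(ev)
  expect_equal(nrow(td), 10)
  expect_s3_class(glance(ev), "tbl_df")
})

test_that("pupil IoU is symmetric and decreases on nested masks", {
  set.seed(4)
  truth <- random_mask(30, 30, 0.4)
  pred <- random_mask(30, 30, 0.4)
  expect_equal(iou(confusion_tally(truth, pred)), iou(confusion_tally(pred, truth)))

  prev <- Inf
  for (r in c(12, 10, 8, 6)) {
    cur <- iou(confusion_tally(disc_mask(12, pad = 4), disc_mask(r, pad = 4 + 12 - r)))
    expect_lt(cur, prev)
    prev <- cur
  }
})
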