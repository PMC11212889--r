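toy_vol <- function(fill) {
  arr <- array(0L, c(2, 10, 10))
  for (i in seq_along(fill)) {
    box <- fill[[i]]
    arr[, box[1]:box[2], box[3]:box[4]] <- i
  }
  label_volume(arr)
}

test_that("iou3d on identical, disjoint and half-shifted supports", {
  a <- array(FALSE, c(4, 5, 5)); a[1:4, 1:5, 1:5] <- TRUE
  expect_equal(iou3d(a, a), 1)
  b <- array(FALSE, c(4, 5, 5))
  expect_true(is.na(iou3d(b, b)))
  expect_equal(iou3d(a, b), 0)

  # 100-voxel block vs the same block shifted half-way in z:
  # 50 shared voxels, union 150
  g <- array(FALSE, c(6, 10, 10)); g[1:4, 1:5, 1:5] <- TRUE
  p <- array(FALSE, c(6, 10, 10)); p[3:6, 1:5, 1:5] <- TRUE
  expect_equal(iou3d(g, p), 1 / 3)
  expect_error(iou3d(a, array(FALSE, c(2, 2, 2))), "shapes")
})

test_that("identity prediction scores perfectly at every threshold", {
  vol <- toy_vol(list(c(1, 4, 1, 4), c(6, 9, 6, 9)))
  sw <- sweep_thresholds(vol, vol)
  expect_equal(nrow(sw), 19)
  expect_true(all(sw$f1 == 1))
  expect_true(all(sw$tp == 2 & sw$fp == 0 & sw$fn == 0))
})

test_that("a split GT instance yields one TP and one FP", {
  gt <- toy_vol(list(c(1, 8, 1, 8)))            # one 2x8x8 instance
  pr <- array(0L, c(2, 10, 10))
  pr[, 1:8, 1:6] <- 1L                          # IoU 48/64 = 0.75
  pr[, 1:8, 7:8] <- 2L                          # IoU 16/64 = 0.25
  res <- match_instances(gt, label_volume(pr), 0.5)
  expect_equal(res$tp, 1)
  expect_equal(res$fp, 1)
  expect_equal(res$fn, 0)
  pairs <- attr(res, "pairs")
  expect_equal(pairs$pred_id, 1L)  # largest overlap wins the GT
})

test_that("conservation and the accuracy identity hold on the sweep", {
  withr::local_seed(31)
  ph <- generate_stack(small_config(seed = 31))
  series <- degrade_to_frame_masks(ph$labels, dropout_rate = 0.15,
                                   seed = 32)
  ts <- assign_tracks(series, max_gap = 1)
  pred <- tracks_to_label_volume(ts, series,
                                 n_frames = dim(ph$labels$labels)[1])
  sw <- sweep_thresholds(ph$labels, pred)
  n_gt <- length(label_ids(ph$labels))
  n_pr <- length(label_ids(pred))
  expect_true(all(sw$tp + sw$fn == n_gt))
  expect_true(all(sw$tp + sw$fp == n_pr))
  expect_true(all(diff(sw$tp) <= 0))
  expect_true(all(diff(sw$fp) >= 0) && all(diff(sw$fn) >= 0))
  ok <- !is.na(sw$f1) & sw$f1 > 0
  expect_equal(sw$detection_accuracy[ok], sw$f1[ok] / (2 - sw$f1[ok]))
})

test_that("greedy matching agrees with the exhaustive matcher on toys", {
  withr::local_seed(17)
  for (rep in 1:12) {
    mk <- function() {
      arr <- array(0L, c(2, 12, 12))
      for (k in seq_len(sample(1:5, 1))) {
        cy <- sample(2:11, 1); cx <- sample(2:11, 1)
        arr[, max(1, cy - 2):min(12, cy + 2),
            max(1, cx - 2):min(12, cx + 2)] <- k
      }
      label_volume(arr)
    }
    gt <- mk(); pr <- mk()
    for (th in c(0.3, 0.5, 0.8)) {
      got <- match_instances(gt, pr, th)
      want <- brute_force_match(gt, pr, th)
      expect_equal(got$tp, want$tp)
      expect_equal(got$fp, want$fp)
      expect_equal(got$fn, want$fn)
    }
  }
})

test_that("greedy and optimal assignment agree on the toy suite", {
  withr::local_seed(19)
  ph <- generate_stack(small_config(seed = 19))
  series <- degrade_to_frame_masks(ph$labels, split_rate = 0.3, seed = 20)
  ts <- assign_tracks(series)
  pred <- tracks_to_label_volume(ts, series,
                                 n_frames = dim(ph$labels$labels)[1])
  g <- match_instances(ph$labels, pred, 0.5, method = "greedy")
  o <- match_instances(ph$labels, pred, 0.5, method = "optimal")
  expect_equal(c(g$tp, g$fp, g$fn), c(o$tp, o$fp, o$fn))
})

test_that("descriptives use population normalization by default", {
  d <- descriptives(c(1, 2, 3, 4))
  expect_equal(d$mean, 2.5)
  expect_equal(d$median, 2.5)
  expect_equal(d$std, sqrt(1.25))
  expect_equal(descriptives(c(1, 2, 3, 4), "sample")$std, sd(1:4))

  one <- descriptives(7)
  expect_equal(one$mean, 7); expect_equal(one$median, 7)
  expect_equal(one$std, 0)
  expect_error(descriptives(numeric()), "no values")
})

test_that("agreement statistics behave on identities and shifts", {
  x <- c(3.1, 2.8, 4.1, 3.7, 3.0, 2.2, 3.9, 3.3, 2.7, 3.5)
  ag <- agreement(x, x, tests = c("pearson", "paired_t"))
  td <- tidy(ag)
  expect_equal(td$estimate[td$test == "pearson"], 1)
  expect_equal(td$statistic[td$test == "paired_t"], 0)

  ag2 <- agreement(x, x + 0.5, tests = c("pearson", "paired_t", "wilcoxon"))
  td2 <- tidy(ag2)
  expect_equal(td2$estimate[td2$test == "pearson"], 1)
  expect_lt(td2$p_value[td2$test == "paired_t"], 1e-6)
  expect_equal(td2$df[td2$test == "paired_t"], 9)

  gl <- glance(ag2)
  expect_equal(gl$n, 10)
  expect_equal(gl$mean_y - gl$mean_x, 0.5)

  const <- rep(2, 5)
  agc <- agreement(const, c(1, 2, 1, 2, 1), tests = "pearson")
  expect_true(is.na(tidy(agc)$estimate))
  expect_error(agreement(1:2, 1:2), "n >= 3")
  expect_error(agreement(1:5, 1:4, tests = "paired_t"), "equal lengths")
})
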