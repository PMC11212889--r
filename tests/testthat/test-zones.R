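test_that("confusion metrics match hand arithmetic", {
  perfect <- diag(c(5, 7, 9))
  m <- confusion_metrics(perfect)
  expect_equal(m$accuracy, 1); expect_equal(m$f1, 1)
  expect_equal(m$error_rate, 0)

  cm <- matrix(c(8, 1, 2, 9), 2)  # rows = truth: [[8, 2], [1, 9]]
  m2 <- confusion_metrics(cm)
  expect_equal(m2$error_rate, 3 / 20)
  # class-0 precision 8/9, class-1 precision 9/11; macro mean
  expect_equal(m2$precision, mean(c(8 / 9, 9 / 11)))
  # internal identity: F1 recomputable from returned P and R
  expect_equal(m2$f1, mean(c(2 * (8 / 9) * (8 / 10) / (8 / 9 + 8 / 10),
                             2 * (9 / 11) * (9 / 10) / (9 / 11 + 9 / 10))))

  # two-class: macro accuracy + error rate = 1
  withr::local_seed(3)
  for (i in 1:5) {
    cm <- matrix(sample(0:20, 4, replace = TRUE), 2)
    if (sum(cm) == 0) next
    mm <- confusion_metrics(cm)
    expect_equal(mm$accuracy + mm$error_rate, 1)
  }

  # a never-predicted class yields NA precision, not 0
  cm3 <- matrix(c(3, 0, 2, 0, 0, 0, 0, 0, 4), 3, byrow = TRUE)
  expect_true(is.na(confusion_metrics(cm3)$precision))
})

test_that("switch counting scores monotone runs 0 and fluctuations > 0", {
  expect_equal(count_switches(c(0, 0, 1, 1, 1, 2, 2)), 0L)
  expect_equal(count_switches(c(2, 2, 2)), 0L)
  expect_equal(count_switches(c(0, 1, 0, 1, 2)), 2L)
  expect_equal(count_switches(c(0, 2, 1, 2)), 1L)  # one backward step
  expect_error(count_switches(c(0, 3)), "labels")

  # property: 0 switches iff non-decreasing (over random valid sequences)
  withr::local_seed(11)
  for (i in 1:20) {
    s <- sample(0:2, 8, replace = TRUE)
    expect_equal(count_switches(s) == 0L, !is.unsorted(s))
  }
})

test_that("ccz_range returns the longest run of class 1", {
  expect_equal(unname(ccz_range(c(0, 0, 1, 1, 1, 2))), c(3, 5))
  expect_null(ccz_range(c(0, 0, 2, 2)))
  expect_equal(unname(ccz_range(c(1, 1, 0, 1, 1, 1, 1, 2))), c(4, 7))
})

test_that("rotation aggregation averages frames and breaks ties low", {
  one_hot <- matrix(0, 4, 72); one_hot[, 19] <- 1  # class 18 (0-based)
  r <- aggregate_rotation(one_hot)
  expect_equal(r$predicted_angle_deg, 90)
  expect_equal(r$correction_deg, 270)

  zero <- matrix(0, 2, 72); zero[, 1] <- 1
  expect_equal(aggregate_rotation(zero)$correction_deg, 0)

  # frame 1 favors class 10, frame 2 favors class 30; averages tie -> 10
  s <- matrix(0, 2, 72)
  s[1, 11] <- 0.6; s[1, 31] <- 0.4
  s[2, 11] <- 0.4; s[2, 31] <- 0.6
  r2 <- aggregate_rotation(s)
  expect_equal(r2$predicted_angle_deg, 50)
  expect_equal(r2$correction_deg, 310)

  # frame order invariance
  expect_equal(aggregate_rotation(s[2:1, ]), r2)
  expect_error(aggregate_rotation(matrix(0, 0, 72)), "72")
})

test_that("rotate-and-crop output never contains padding", {
  fr <- matrix(seq_len(64 * 64), 64, 64)
  expect_identical(rotate_and_crop_max_rect(fr, 0), fr)
  sq90 <- rotate_and_crop_max_rect(fr, 90)
  expect_equal(dim(sq90), c(64, 64))
  expect_setequal(as.vector(sq90), as.vector(fr))

  big <- matrix(1, 256, 256)
  expect_equal(dim(rotate_and_crop_max_rect(big, 45)), c(181, 181))

  for (ang in seq(0, 355, by = 5)) {
    out <- rotate_and_crop_max_rect(fr, ang)
    expect_false(anyNA(out))
    expect_true(all(dim(out) >= 1))
  }
})

test_that("tonotopic vote uses the 13-frame window from the median", {
  expect_equal(tonotopic_vote(rep("BASE", 9)), "BASE")

  labs <- rep("APEX", 20); labs[11:17] <- "MIDDLE"
  # median frame m = 9 (0-based), window 13 clipped to frames 10..20
  expect_equal(tonotopic_vote(labs), "MIDDLE")

  short <- c("BASE", "BASE", "MIDDLE", "APEX", "APEX", "APEX")
  expect_equal(tonotopic_vote(short), "APEX")

  # tie resolved by summed scores when available
  tied <- c("BASE", "BASE", "BASE", "BASE", "APEX", "APEX")
  sc <- c(0.5, 0.5, 0.5, 0.5, 0.9, 0.9)  # window = frames 3..6: 2 vs 2
  expect_equal(tonotopic_vote(tied, window = 4), "BASE")  # level order
  expect_equal(tonotopic_vote(tied, scores = sc, window = 4), "APEX")
})

test_that("heuristic zone scores round-trip through the zone logic", {
  zs <- generate_zone_scores(15, c(4, 11), noise = 0.2, seed = 5)
  pred <- max.col(zs$scores) - 1L
  cm <- table(factor(zs$truth, levels = 0:2),
              factor(pred, levels = 0:2))
  m <- confusion_metrics(unclass(cm))
  expect_gte(m$accuracy, 0.8)
  rng <- ccz_range(zs$truth)
  expect_equal(unname(rng), c(5, 11))
  expect_equal(count_switches(zs$truth), 0L)
})
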