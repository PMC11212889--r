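test_that("overlap_area counts shared pixels", {
  a <- matrix(0L, 5, 5); a[2:4, 2:4] <- 1L       # 3x3 square
  b <- matrix(0L, 5, 5); b[2:4, 3:5] <- 1L       # shifted by 1 in x
  expect_identical(overlap_area(a, b), 6L)
  expect_identical(overlap_area(a, a), 9L)
  expect_identical(overlap_area(b, a), overlap_area(a, b))
  d <- matrix(0L, 5, 5); d[1, 1] <- 1L
  expect_identical(overlap_area(a, d), 0L)
  expect_error(overlap_area(a, matrix(0L, 4, 4)), "shapes")
})

test_that("single persistent object yields one track; disjoint objects two", {
  m <- matrix(0L, 8, 8); m[3:5, 3:5] <- 1L
  series <- frame_masks(replicate(5, m, simplify = FALSE))
  ts <- assign_tracks(series)
  expect_length(ts$tracks, 1)
  expect_equal(nrow(ts$tracks[[1]]$entries), 5)

  m2 <- matrix(0L, 8, 8); m2[1:2, 1:2] <- 1L; m2[6:8, 6:8] <- 2L
  ts2 <- assign_tracks(frame_masks(list(m2, m2, m2)))
  expect_length(ts2$tracks, 2)
  expect_equal(vapply(ts2$tracks, function(t) nrow(t$entries), numeric(1)),
               c(3, 3))
})

test_that("contested track goes to the largest-overlap detection", {
  # frame 1: one 7-px-wide bar seeds track T
  f1 <- matrix(0L, 10, 12); f1[5, 2:11] <- 1L
  # frame 2: A overlaps T on 8 px, B on 2 px
  f2 <- matrix(0L, 10, 12)
  f2[5, 2:9] <- 1L   # A: overlap 8
  f2[5, 10:11] <- 2L # B: overlap 2
  ts <- assign_tracks(frame_masks(list(f1, f2)))
  expect_length(ts$tracks, 2)
  tl <- tidy(ts)
  expect_equal(tl$local_id[tl$track_id == 1 & tl$frame == 2], 1)
  expect_equal(tl$local_id[tl$track_id == 2], 2)
})

test_that("no detection is lost or duplicated (conservation)", {
  withr::local_seed(21)
  for (rep in 1:10) {
    series <- random_series(4, 4)
    ts <- assign_tracks(series)
    n_det <- sum(vapply(series$masks, function(m) {
      length(setdiff(unique(as.integer(m)), 0L))
    }, numeric(1)))
    expect_equal(nrow(tidy(ts)), n_det)
    # each (frame, local id) appears exactly once
    expect_false(any(duplicated(tidy(ts)[c("frame", "local_id")])))
  }
})

test_that("assignment matches the independent matrix-form oracle", {
  withr::local_seed(42)
  for (rep in 1:25) {
    series <- random_series(3, 4)
    ts <- assign_tracks(series)
    oracle <- oracle_assign(series)
    got <- tidy(ts)
    want <- purrr::imap_dfr(oracle, function(a, fi) {
      tibble::tibble(frame = series$frame_index[fi],
                     local_id = as.integer(names(a)),
                     track_id = unname(a))
    })
    merged <- dplyr::inner_join(got, want, by = c("frame", "local_id"),
                                suffix = c("_pkg", "_orc"))
    expect_equal(nrow(merged), nrow(got))
    expect_identical(merged$track_id_pkg, merged$track_id_orc)
  }
})

test_that("noise-free phantom reconstructs with per-instance IoU 1", {
  for (seed in c(1, 8, 33)) {
    ph <- generate_stack(small_config(seed = seed))
    series <- degrade_to_frame_masks(ph$labels, 0, 0, seed = seed + 1)
    ts <- assign_tracks(series)
    vol <- tracks_to_label_volume(ts, series,
                                  n_frames = dim(ph$labels$labels)[1])
    expect_length(ts$tracks, nrow(ph$truth))
    res <- match_instances(ph$labels, vol, iou_threshold = 1)
    expect_equal(res$tp, nrow(ph$truth))
    expect_equal(res$fp + res$fn, 0)
  }
})

test_that("max_gap bridges single-frame dropouts", {
  ph <- generate_stack(small_config(seed = 9, depth_layers = 5L))
  series <- degrade_to_frame_masks(ph$labels, 0, 0, seed = 2)
  # blank one interior occupied plane entirely
  series$masks[[3]][] <- 0L
  ts0 <- assign_tracks(series, max_gap = 0)
  ts1 <- assign_tracks(series, max_gap = 1)
  expect_gt(length(ts0$tracks), nrow(ph$truth))
  expect_length(ts1$tracks, nrow(ph$truth))
})

test_that("tracks_to_label_volume paints tracks and empty set gives zeros", {
  m <- matrix(0L, 6, 6); m[2:3, 2:6] <- 1L
  series <- frame_masks(replicate(5, m, simplify = FALSE))
  vol <- tracks_to_label_volume(assign_tracks(series), series)
  expect_equal(sum(vol$labels == 1L), 5 * 10)
  expect_identical(label_ids(vol), 1L)

  empty <- frame_masks(list(matrix(0L, 4, 4)))
  vol0 <- tracks_to_label_volume(assign_tracks(empty), empty)
  expect_true(all(vol0$labels == 0L))
})

test_that("filter_components drops short or small instances only", {
  ph <- generate_stack(small_config(seed = 10,
                                    depth_layers = c(3L, 5L)))
  vol <- ph$labels
  expect_identical(filter_components(vol, 0, 0)$labels, vol$labels)

  filt <- filter_components(vol, min_frames = 4)
  short_ids <- ph$truth$bundle_id[ph$truth$depth_layers == 3]
  expect_identical(label_ids(filt),
                   sort(setdiff(label_ids(vol), short_ids)))

  speck <- array(0L, c(4, 8, 8)); speck[2, 3, 3:5] <- 1L
  expect_identical(label_ids(filter_components(label_volume(speck), 2, 10)),
                   integer(0))
})
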