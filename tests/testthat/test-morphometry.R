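make_vol <- function(planes, ...) {
  arr <- aperm(array(unlist(planes), c(dim(planes[[1]]), length(planes))),
               c(3, 1, 2))
  storage.mode(arr) <- "integer"
  label_volume(arr, ...)
}

test_that("project_z is the union of per-plane supports", {
  p1 <- matrix(0L, 6, 6); p1[2, 2:4] <- 1L
  p2 <- matrix(0L, 6, 6); p2[5, 5] <- 1L
  vol <- make_vol(list(p1, p2))
  pr <- project_z(vol, 1)
  expect_identical(pr, p1 > 0 | p2 > 0)

  # idempotent clamp: same support over 5 planes projects identically
  vol5 <- make_vol(replicate(5, p1, simplify = FALSE))
  expect_identical(project_z(vol5, 1), p1 > 0)

  expect_error(project_z(vol, 7), "unknown")
})

test_that("tip and base points follow the documented rules", {
  ph <- generate_stack(small_config(seed = 13, noise_sd = 0))
  for (id in ph$truth$bundle_id) {
    tb <- tip_base_points(ph$labels, id)
    tr <- ph$truth[ph$truth$bundle_id == id, ]
    expect_equal(tb$x1, tr$tip_x); expect_equal(tb$y1, tr$tip_y)
    expect_equal(tb$z1, tr$tip_z); expect_equal(tb$z2, tr$base_z)
    expect_equal(tb$y2, tr$base_y)
    expect_false(tb$degenerate_centroid)
  }

  # single voxel: tip = base, height 0
  v1 <- array(0L, c(6, 9, 9)); v1[4, 8, 8] <- 1L
  tb <- tip_base_points(label_volume(v1), 1)
  expect_equal(unlist(tb[c("x1", "y1", "z1", "x2", "z2")]),
               c(x1 = 8, y1 = 8, z1 = 4, x2 = 8, z2 = 4))
  expect_equal(bundle_height(tb)$height_um, 0)

  # tie at minimal y resolved to minimal x
  p <- matrix(0L, 6, 12); p[2, c(4, 9)] <- 1L; p[3, 4:9] <- 1L
  tb2 <- tip_base_points(make_vol(list(p)), 1)
  expect_equal(tb2$x1, 4)
})

test_that("bundle_height applies per-axis scaling", {
  e345 <- data.frame(x1 = 0, y1 = 0, z1 = 0, x2 = 3, y2 = 4, z2 = 0)
  expect_equal(bundle_height(e345)$height_um, 5)
  ezero <- data.frame(x1 = 2, y1 = 2, z1 = 2, x2 = 2, y2 = 2, z2 = 2)
  expect_equal(bundle_height(ezero)$height_um, 0)
  # hand arithmetic: sqrt((10*.043)^2 + (20*.043)^2 + (4*.110)^2)
  ed <- data.frame(x1 = 0, y1 = 0, z1 = 0, x2 = 10, y2 = 20, z2 = 4)
  expect_equal(bundle_height(ed, c(0.110, 0.043, 0.043))$height_um,
               sqrt(0.43^2 + 0.86^2 + 0.44^2), tolerance = 1e-12)
})

test_that("phantom heights are recovered within a voxel diagonal", {
  diag_um <- function(vs) sqrt(sum(vs^2))
  for (seed in c(2, 5, 19)) {
    ph <- generate_stack(small_config(seed = seed))
    h <- measure_heights(ph$labels)
    m <- dplyr::inner_join(h, ph$truth, by = "bundle_id")
    expect_true(all(abs(m$height_um.x - m$height_um.y) <=
                      diag_um(ph$labels$voxel_size)))
  }
})

test_that("height is stable under in-plane rotation", {
  cfgr <- function(rot) phantom_config(
    shape = c(12, 256, 256), bundles_per_row = 3,
    rows_y = c(190, 155, 120, 85), wing_length_px = 36,
    x_range = c(75, 180), seed = 2, rotation_deg = rot
  )
  h0 <- measure_heights(generate_stack(cfgr(0))$labels)
  h15 <- measure_heights(generate_stack(cfgr(15))$labels)
  rel <- abs(sort(h15$height_um) - sort(h0$height_um)) / sort(h0$height_um)
  expect_lt(max(rel), 0.05)
})

test_that("region measurements: cube closed forms and degenerate voxel", {
  cube <- array(0L, c(14, 14, 14))
  cube[3:12, 3:12, 3:12] <- 1L
  m <- region_measurements(label_volume(cube))
  expect_equal(m$volume_voxels, 1000)
  expect_equal(m$volume_um3, 1000)
  expect_equal(m$surface_area_um2, 600)
  expect_equal(m$depth_layers, 10)
  expect_equal(m$projection_area_px, 100)
  expect_equal(m$extent, 1)
  expect_equal(m$eccentricity, 0)
  expect_equal(m$solidity, 1)
  expect_equal(m$equivalent_diameter_px, sqrt(400 / pi))

  one <- array(0L, c(3, 5, 5)); one[2, 3, 3] <- 1L
  vs <- c(0.110, 0.043, 0.043)
  m1 <- region_measurements(label_volume(one, voxel_size = vs))
  expect_equal(m1$volume_voxels, 1)
  expect_equal(m1$surface_area_um2,
               2 * (vs[2] * vs[3] + vs[1] * vs[3] + vs[1] * vs[2]))
  expect_equal(m1$perimeter_um, 4 * vs[3])
  expect_equal(m1$eccentricity, 0)
  expect_equal(m1$solidity, 1)

  expect_error(region_measurements(label_volume(array(0L, c(2, 2, 2)))),
               "empty")
})

test_that("surface area of a box matches 2(ab + bc + ca)", {
  arr <- array(0L, c(10, 12, 9))
  arr[2:6, 3:10, 2:7] <- 1L  # 5 x 8 x 6 box in (z, y, x)
  m <- region_measurements(label_volume(arr))
  expect_equal(m$surface_area_um2, 2 * (5 * 8 + 8 * 6 + 6 * 5))
})

test_that("measurements are invariant to ID relabeling", {
  ph <- generate_stack(small_config(seed = 23))
  m1 <- region_measurements(ph$labels)
  perm <- sample(label_ids(ph$labels))
  relab <- ph$labels$labels
  relab[ph$labels$labels > 0L] <-
    perm[ph$labels$labels[ph$labels$labels > 0L]]
  m2 <- region_measurements(label_volume(relab,
                                         voxel_size = ph$labels$voxel_size))
  m2 <- m2[match(perm, m2$bundle_id), ]
  for (col in setdiff(names(m1), "bundle_id")) {
    expect_equal(unname(m2[[col]]), unname(m1[[col]]), tolerance = 1e-12)
  }
})

test_that("phantom voxel counts match the generator's truth", {
  ph <- generate_stack(small_config(seed = 3))
  m <- region_measurements(ph$labels)
  tr <- ph$truth[match(m$bundle_id, ph$truth$bundle_id), ]
  expect_equal(m$volume_voxels, tr$n_voxels)
  expect_equal(m$depth_layers, tr$depth_layers)
})
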