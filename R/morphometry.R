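#' Binary z-projection of one bundle
#'
#' Collapses a bundle's 3D support along z: a pixel is foreground iff the
#' bundle occupies that (y, x) position in at least one plane (sums along z
#' clamped to binary).
#'
#' @param vol a [label_volume()].
#' @param bundle_id a positive ID present in `vol`.
#' @return A logical (y, x) matrix.
#' @export
project_z <- function(vol, bundle_id) {
  stopifnot(inherits(vol, "label_volume"))
  if (!bundle_id %in% label_ids(vol)) {
    stop("unknown bundle id: ", bundle_id, call. = FALSE)
  }
  apply(vol$labels == bundle_id, c(2, 3), any)
}

#' Tip and base points of a bundle
#'
#' Finds the endpoints the tip-to-base height is measured between, on the
#' binary z-projection of the bundle:
#' * tip `(x1, y1)`: the topmost foreground pixel (minimal y; ties broken by
#'   minimal x); `z1` is the shallowest plane in which the bundle occupies
#'   that (x, y).
#' * base `(x2, y2)`: starting from the projection centroid, walk straight
#'   down (+y) at fixed x until the first background pixel and step back one;
#'   `z2` is the deepest plane in which the bundle is present at all. If the
#'   centroid itself is off-support (possible for strongly concave shapes),
#'   x snaps to the nearest support column within the centroid row and the
#'   result is flagged `degenerate_centroid`.
#'
#' @param vol a [label_volume()].
#' @param bundle_id a positive ID present in `vol`.
#' @return A one-row tibble: `bundle_id`, `x1,y1,z1`, `x2,y2,z2`,
#'   `degenerate_centroid`.
#' @export
tip_base_points <- function(vol, bundle_id) {
  proj <- project_z(vol, bundle_id)
  pix <- which(proj, arr.ind = TRUE)  # (y, x)
  y1 <- min(pix[, 1])
  x1 <- min(pix[pix[, 1] == y1, 2])
  zcol <- which(vol$labels[, y1, x1] == bundle_id)
  z1 <- min(zcol)
  z2 <- max(which(apply(vol$labels == bundle_id, 1, any)))

  cy <- round(mean(pix[, 1])); cx <- round(mean(pix[, 2]))
  degenerate <- FALSE
  if (!proj[cy, cx]) {
    row_support <- which(proj[cy, ])
    if (length(row_support) == 0) {
      # centroid row entirely empty: snap to the nearest support pixel
      dd <- (pix[, 1] - cy)^2 + (pix[, 2] - cx)^2
      cy <- pix[which.min(dd), 1]; cx <- pix[which.min(dd), 2]
    } else {
      cx <- row_support[which.min(abs(row_support - cx))]
    }
    degenerate <- TRUE
  }
  y2 <- cy
  while (y2 + 1 <= nrow(proj) && proj[y2 + 1, cx]) y2 <- y2 + 1
  tibble::tibble(
    bundle_id = bundle_id,
    x1 = x1, y1 = y1, z1 = z1,
    x2 = cx, y2 = y2, z2 = z2,
    degenerate_centroid = degenerate
  )
}

#' Physical tip-to-base distance
#'
#' 3D Euclidean distance between two voxel coordinates with per-axis scaling:
#' `sqrt((sx dx)^2 + (sy dy)^2 + (sz dz)^2)`.
#'
#' @param endpoints a data frame with columns `x1,y1,z1,x2,y2,z2` (one or
#'   more rows), e.g. from [tip_base_points()].
#' @param voxel_size `(z, y, x)` voxel size in µm.
#' @return `endpoints` with a `height_um` column appended.
#' @examples
#' bundle_height(data.frame(x1 = 0, y1 = 0, z1 = 0, x2 = 3, y2 = 4, z2 = 0))
#' @export
bundle_height <- function(endpoints, voxel_size = c(1, 1, 1)) {
  vs <- check_voxel_size(voxel_size)
  dplyr::mutate(
    tibble::as_tibble(endpoints),
    height_um = sqrt((vs[3] * (.data$x2 - .data$x1))^2 +
                       (vs[2] * (.data$y2 - .data$y1))^2 +
                       (vs[1] * (.data$z2 - .data$z1))^2)
  )
}

#' Measure tip-to-base heights for every bundle
#'
#' @param vol a [label_volume()]; its voxel size scales the distances.
#' @return A tibble with one row per bundle: endpoint coordinates and
#'   `height_um`.
#' @export
measure_heights <- function(vol) {
  stopifnot(inherits(vol, "label_volume"))
  purrr::map_dfr(label_ids(vol), function(id) tip_base_points(vol, id)) |>
    bundle_height(voxel_size = vol$voxel_size)
}

#' Per-bundle 2D/3D region measurements
#'
#' Fifteen measurements per instance. 3D, on the voxel support: voxel count,
#' physical volume (µm³), centroid (y, x, z in voxels), exposed-face surface
#' area (µm²), z-depth in layers. 2D, on the binary z-projection: area (px),
#' perimeter (exposed pixel-edge length, µm), eccentricity, major/minor axis
#' lengths (central-moment ellipse, px), equivalent diameter (px), solidity
#' (area / convex hull area), extent (area / bounding-box area), and
#' major-axis orientation (degrees in `[0, 180)`). Single-voxel instances get
#' defined degenerate values (perimeter `4*sx`, eccentricity 0, solidity 1).
#'
#' @param vol a [label_volume()].
#' @return A tibble with one row per bundle ID and 15 measurement columns.
#' @export
region_measurements <- function(vol) {
  stopifnot(inherits(vol, "label_volume"))
  ids <- label_ids(vol)
  if (length(ids) == 0) stop("empty label volume", call. = FALSE)
  vs <- vol$voxel_size  # (z, y, x)
  purrr::map_dfr(ids, function(id) {
    w <- which(vol$labels == id, arr.ind = TRUE)  # (z, y, x)
    proj <- project_z(vol, id)
    shp <- shape_metrics_2d(proj, px = vs[3])
    tibble::tibble(
      bundle_id = id,
      volume_voxels = nrow(w),
      volume_um3 = nrow(w) * prod(vs),
      centroid_z = mean(w[, 1]), centroid_y = mean(w[, 2]),
      centroid_x = mean(w[, 3]),
      surface_area_um2 = surface_area(vol$labels, id, vs),
      depth_layers = max(w[, 1]) - min(w[, 1]) + 1L,
      projection_area_px = sum(proj),
      perimeter_um = shp$perimeter,
      eccentricity = shp$eccentricity,
      major_axis_px = shp$major, minor_axis_px = shp$minor,
      equivalent_diameter_px = sqrt(4 * sum(proj) / pi),
      solidity = shp$solidity, extent = shp$extent,
      orientation_deg = shp$orientation
    )
  })
}

# exposed voxel faces weighted by per-face physical area
surface_area <- function(labs, id, vs) {
  m <- labs == id
  d <- dim(m)
  face_area <- c(vs[2] * vs[3], vs[1] * vs[3], vs[1] * vs[2])  # z,y,x faces
  total <- 0
  for (ax in 1:3) {
    padded <- array(FALSE, dim = d + c(ax == 1, ax == 2, ax == 3) * 2)
    idx <- lapply(seq_len(3), function(k) seq_len(d[k]) + (k == ax))
    padded[idx[[1]], idx[[2]], idx[[3]]] <- m
    sh <- dim(padded)
    a <- switch(ax,
                padded[1:(sh[1] - 1), , , drop = FALSE],
                padded[, 1:(sh[2] - 1), , drop = FALSE],
                padded[, , 1:(sh[3] - 1), drop = FALSE])
    b <- switch(ax,
                padded[2:sh[1], , , drop = FALSE],
                padded[, 2:sh[2], , drop = FALSE],
                padded[, , 2:sh[3], drop = FALSE])
    total <- total + sum(a != b) * face_area[ax]
  }
  total
}

shape_metrics_2d <- function(proj, px = 1) {
  pix <- which(proj, arr.ind = TRUE)  # (y, x)
  n <- nrow(pix)
  # perimeter: exposed pixel edges (4-connectivity), scaled by pixel size
  per_edges <- 0
  pm <- matrix(FALSE, nrow(proj) + 2, ncol(proj) + 2)
  pm[2:(nrow(proj) + 1), 2:(ncol(proj) + 1)] <- proj
  for (dd in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
    shifted <- pm[seq_len(nrow(pm) - 2) + 1 + dd[1],
                  seq_len(ncol(pm) - 2) + 1 + dd[2]]
    per_edges <- per_edges + sum(proj & !shifted)
  }
  cy <- mean(pix[, 1]); cx <- mean(pix[, 2])
  myy <- mean((pix[, 1] - cy)^2); mxx <- mean((pix[, 2] - cx)^2)
  mxy <- mean((pix[, 1] - cy) * (pix[, 2] - cx))
  ev <- eigen(matrix(c(mxx, mxy, mxy, myy), 2), symmetric = TRUE)
  lam <- pmax(ev$values, 0)
  major <- 4 * sqrt(lam[1]); minor <- 4 * sqrt(lam[2])
  ecc <- if (lam[1] > 0) sqrt(1 - lam[2] / lam[1]) else 0
  v <- ev$vectors[, 1]  # (x, y) components of the major axis
  orientation <- if (lam[1] > lam[2]) {
    (atan2(v[2], v[1]) * 180 / pi) %% 180
  } else 0
  hull_area <- if (n >= 3) {
    h <- grDevices::chull(pix[, 2], pix[, 1])
    polygon_area(pix[h, 2], pix[h, 1])
  } else 0
  solidity <- if (hull_area > 0) min(1, n / hull_area) else 1
  bbox_area <- (diff(range(pix[, 1])) + 1) * (diff(range(pix[, 2])) + 1)
  list(perimeter = per_edges * px, eccentricity = ecc,
       major = major, minor = minor, solidity = solidity,
       extent = n / bbox_area, orientation = orientation)
}

polygon_area <- function(x, y) {
  n <- length(x)
  if (n < 3) return(0)
  j <- c(2:n, 1)
  abs(sum(x * y[j] - x[j] * y)) / 2
}
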