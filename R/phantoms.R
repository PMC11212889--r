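#' Phantom stack configuration
#'
#' Describes a synthetic cochlear z-stack: four horizontal rows of V-shaped
#' stereocilia bundles (IHC row bottom-most, then OHC1..OHC3 upward), painted
#' as filled wedges (triangle with apex at top) extruded over a z-range, on a
#' noisy background. Defaults mirror the imaging scale of the real data
#' (0.043 µm xy pixels, 0.110 µm z-step) so physical bundle heights land in
#' the 1–5 µm range typical of neonatal mouse cochleae.
#'
#' @param shape stack dimensions `(z, y, x)` in voxels.
#' @param voxel_size `(z, y, x)` voxel size in µm.
#' @param rows_y base-line y positions of the 4 rows, ordered IHC, OHC1,
#'   OHC2, OHC3 (IHC bottom-most, i.e. largest y).
#' @param bundles_per_row number of bundles in each row.
#' @param wing_half_angle_deg wing half-angle from the vertical, degrees.
#' @param wing_length_px wing length in pixels (apex to wing tip).
#' @param z_start first occupied z-plane (1-based).
#' @param depth_layers occupied z-extent in planes; scalar or one per bundle
#'   (recycled across all `4 * bundles_per_row` bundles).
#' @param amplitude,background mean foreground intensity added on bundle
#'   voxels, and constant background level; `amplitude > background >= 0`.
#' @param noise_sd Gaussian intensity noise s.d. (the label volume stays
#'   noise-free).
#' @param base_y_jitter_sd per-bundle jitter s.d. of the base y position, px.
#' @param rotation_deg optional global in-plane rotation applied to both the
#'   intensity stack and the label volume as the final step (positive =
#'   clockwise on screen with y pointing down).
#' @param x_range optional `(lo, hi)` x interval the bundle peaks are spread
#'   over; defaults to the full width minus a wing margin. Narrow it when a
#'   global rotation would otherwise carry edge bundles off the canvas.
#' @param seed integer seed; fixed seed + config gives bit-identical output.
#' @return A `phantom_config` list.
#' @export
phantom_config <- function(shape = c(12L, 256L, 256L),
                           voxel_size = c(0.110, 0.043, 0.043),
                           rows_y = c(215, 160, 110, 62),
                           bundles_per_row = 5L,
                           wing_half_angle_deg = 35,
                           wing_length_px = 42,
                           z_start = 3L,
                           depth_layers = 6L,
                           amplitude = 180,
                           background = 20,
                           noise_sd = 8,
                           base_y_jitter_sd = 2,
                           rotation_deg = 0,
                           x_range = NULL,
                           seed = 1L) {
  stopifnot(length(shape) == 3, all(shape >= 1),
            length(rows_y) == 4, bundles_per_row >= 1,
            wing_half_angle_deg > 0, wing_half_angle_deg < 90,
            wing_length_px >= 2, z_start >= 1, all(depth_layers >= 1),
            amplitude > background, background >= 0, noise_sd >= 0)
  structure(list(
    shape = as.integer(shape), voxel_size = check_voxel_size(voxel_size),
    rows_y = rows_y, bundles_per_row = as.integer(bundles_per_row),
    wing_half_angle_deg = wing_half_angle_deg,
    wing_length_px = wing_length_px, z_start = as.integer(z_start),
    depth_layers = as.integer(depth_layers), amplitude = amplitude,
    background = background, noise_sd = noise_sd,
    base_y_jitter_sd = base_y_jitter_sd, rotation_deg = rotation_deg,
    x_range = x_range, seed = as.integer(seed)
  ), class = "phantom_config")
}

row_labels <- function() c("IHC", "OHC1", "OHC2", "OHC3")

#' Generate a phantom z-stack with ground truth
#'
#' Paints each bundle as a filled V wedge (apex on top, base horizontal) over
#' its z-range, adds background and Gaussian noise to the intensity stack,
#' and returns the noise-free label volume plus a truth table with each
#' bundle's row, tip/base voxel coordinates, physical height, and true
#' orientation angles. The optional global rotation is applied last, to both
#' stack and labels, so alignment logic can be tested against a known angle;
#' truth angles account for it (the stored tip/base coordinates refer to the
#' unrotated geometry).
#'
#' @param config a [phantom_config()].
#' @return A list with elements `stack` ([zstack()]), `labels`
#'   ([label_volume()]), and `truth` (tibble: `bundle_id`, `row`, `tip_x/y/z`,
#'   `base_x/y/z`, `height_um`, `axis_angle_deg`, `baseline_angle_deg`,
#'   `depth_layers`, `n_voxels`), plus `truth_layers` (per-bundle per-plane
#'   painted voxel counts).
#' @examples
#' ph <- generate_stack(phantom_config(bundles_per_row = 2, seed = 7))
#' nrow(ph$truth)
#' @export
generate_stack <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  cfg <- config
  set.seed(cfg$seed)
  Z <- cfg$shape[1]; Y <- cfg$shape[2]; X <- cfg$shape[3]
  n_bundles <- 4L * cfg$bundles_per_row
  depths <- rep_len(cfg$depth_layers, n_bundles)

  theta <- cfg$wing_half_angle_deg * pi / 180
  drop_px <- round(cfg$wing_length_px * cos(theta))   # apex-to-base in y
  half_w <- cfg$wing_length_px * sin(theta)           # base half-width

  # bundle placement: evenly spaced x peaks per row, jittered base y
  margin <- ceiling(half_w) + 4
  xr <- cfg$x_range %||% c(margin, X - margin)
  xs <- round(seq(xr[1], xr[2], length.out = cfg$bundles_per_row))
  placements <- vector("list", n_bundles)
  id <- 0L
  for (r in seq_len(4)) {
    for (b in seq_len(cfg$bundles_per_row)) {
      id <- id + 1L
      y_base <- round(cfg$rows_y[r] + stats::rnorm(1, 0, cfg$base_y_jitter_sd))
      placements[[id]] <- list(
        id = id, row = row_labels()[r], x_peak = xs[b],
        y_base = y_base, y_peak = y_base - drop_px,
        z1 = cfg$z_start, z2 = cfg$z_start + depths[id] - 1L
      )
    }
  }

  # bounds check: no silent clipping, also under the final global rotation
  rmargin <- 2
  a <- cfg$rotation_deg * pi / 180
  cyx <- c((Y + 1) / 2, (X + 1) / 2)
  inside <- function(x, y) {
    if (cfg$rotation_deg != 0) {
      # forward content map of rotate2d: dest = [[cos, sin], [-sin, cos]] src
      xr <- cos(a) * (x - cyx[2]) + sin(a) * (y - cyx[1]) + cyx[2]
      yr <- -sin(a) * (x - cyx[2]) + cos(a) * (y - cyx[1]) + cyx[1]
      x <- xr; y <- yr
    }
    x >= 1 + rmargin & x <= X - rmargin & y >= 1 + rmargin & y <= Y - rmargin
  }
  bad <- vapply(placements, function(p) {
    corners_x <- c(p$x_peak, p$x_peak - half_w, p$x_peak + half_w)
    corners_y <- c(p$y_peak, p$y_base, p$y_base)
    !all(inside(corners_x, corners_y)) || p$z1 < 1 || p$z2 > Z
  }, logical(1))
  if (any(bad)) {
    stop("bundle(s) exceed stack bounds: ",
         paste(which(bad), collapse = ", "), call. = FALSE)
  }

  labels <- array(0L, dim = c(Z, Y, X))
  layer_counts <- list()
  for (p in placements) {
    wedge <- wedge_pixels(p$x_peak, p$y_peak, p$y_base, half_w)
    for (z in p$z1:p$z2) {
      labels[cbind(z, wedge[, "y"], wedge[, "x"])] <- p$id
    }
    layer_counts[[p$id]] <- tibble::tibble(
      bundle_id = p$id, z = p$z1:p$z2, n_voxels = nrow(wedge)
    )
  }

  intens <- array(cfg$background, dim = c(Z, Y, X))
  intens[labels > 0L] <- intens[labels > 0L] + cfg$amplitude
  if (cfg$noise_sd > 0) {
    intens <- intens + stats::rnorm(length(intens), 0, cfg$noise_sd)
  }
  intens <- pmax(round(intens), 0)
  storage.mode(intens) <- "integer"
  dim(intens) <- c(Z, Y, X)

  if (cfg$rotation_deg != 0) {
    for (z in seq_len(Z)) {
      intens[z, , ] <- rotate2d(intens[z, , ], cfg$rotation_deg,
                                fill = cfg$background)
      labels[z, , ] <- rotate2d(labels[z, , ], cfg$rotation_deg, fill = 0L)
    }
    storage.mode(labels) <- "integer"
    storage.mode(intens) <- "integer"
  }

  vs <- cfg$voxel_size
  truth <- purrr::map_dfr(placements, function(p) {
    tibble::tibble(
      bundle_id = p$id, row = p$row,
      tip_x = p$x_peak, tip_y = p$y_peak, tip_z = p$z1,
      base_x = p$x_peak, base_y = p$y_base, base_z = p$z2,
      height_um = sqrt((vs[3] * 0)^2 + (vs[2] * (p$y_base - p$y_peak))^2 +
                         (vs[1] * (p$z2 - p$z1))^2),
      axis_angle_deg = (90 - cfg$rotation_deg) %% 180,
      baseline_angle_deg = (-cfg$rotation_deg) %% 180,
      depth_layers = p$z2 - p$z1 + 1L,
      n_voxels = sum(labels == p$id)
    )
  })

  list(
    stack = zstack(intens, voxel_size = vs),
    labels = label_volume(labels, voxel_size = vs),
    truth = truth,
    truth_layers = dplyr::bind_rows(layer_counts)
  )
}

# filled triangle (apex up) by scanline; returns (y, x) pixel matrix
wedge_pixels <- function(x_peak, y_peak, y_base, half_w) {
  ys <- y_peak:y_base
  h <- y_base - y_peak
  out <- lapply(ys, function(y) {
    w <- half_w * (y - y_peak) / max(h, 1)
    xr <- round(x_peak - w):round(x_peak + w)
    cbind(y = rep(y, length(xr)), x = xr)
  })
  do.call(rbind, out)
}

#' Degrade a label volume into per-frame 2D detections
#'
#' Emulates an imperfect 2D segmenter: each bundle's per-plane support is
#' re-labeled with a random frame-local ID; with probability `dropout_rate` a
#' bundle's mask is deleted from a frame; with probability `split_rate` a
#' mask is split in two across its major axis (a cut along the minor axis at
#' the median projection). With rates (0, 0) the frame masks exactly
#' partition the volume's per-plane supports.
#'
#' @param vol a [label_volume()].
#' @param dropout_rate,split_rate probabilities in `[0, 1]`.
#' @param seed integer seed.
#' @return A [frame_masks()] covering every z-plane of `vol`.
#' @export
degrade_to_frame_masks <- function(vol, dropout_rate = 0, split_rate = 0,
                                   seed = 1L) {
  stopifnot(inherits(vol, "label_volume"),
            dropout_rate >= 0, dropout_rate <= 1,
            split_rate >= 0, split_rate <= 1)
  set.seed(as.integer(seed))
  d <- dim(vol$labels)
  masks <- vector("list", d[1])
  for (z in seq_len(d[1])) {
    plane <- vol$labels[z, , ]
    out <- array(0L, dim = dim(plane))
    ids <- sort(unique(as.integer(plane)))
    ids <- ids[ids > 0L]
    pieces <- list()
    for (id in ids) {
      if (stats::runif(1) < dropout_rate) next
      pix <- which(plane == id, arr.ind = TRUE)  # (y, x)
      if (stats::runif(1) < split_rate && nrow(pix) >= 2) {
        pieces <- c(pieces, split_mask(pix))
      } else {
        pieces <- c(pieces, list(pix))
      }
    }
    if (length(pieces)) {
      local_ids <- sample(seq_along(pieces))
      for (k in seq_along(pieces)) {
        out[pieces[[k]]] <- local_ids[k]
      }
    }
    masks[[z]] <- out
  }
  frame_masks(masks)
}

# cut a pixel set in two at the median projection on its principal axis
split_mask <- function(pix) {
  xy <- cbind(pix[, 2], pix[, 1])
  ctr <- colMeans(xy)
  cc <- sweep(xy, 2, ctr)
  v <- eigen(crossprod(cc) / nrow(cc), symmetric = TRUE)$vectors[, 1]
  proj <- cc %*% v
  left <- proj <= stats::median(proj)
  if (all(left) || !any(left)) return(list(pix))
  list(pix[left, , drop = FALSE], pix[!left, , drop = FALSE])
}

#' Simulate per-frame zone classifier scores with known truth
#'
#' Frames before `pcz_end` are pre-cellular (class 0), frames up to `ccz_end`
#' are cellular-clarity (class 1), the rest noise-saturation (class 2).
#' Scores are one-hot truth plus non-negative noise, renormalized per frame.
#'
#' @param n_frames number of frames.
#' @param boundaries `(pcz_end, ccz_end)`: counts of frames in PCZ and in
#'   PCZ+CCZ, with `0 <= pcz_end <= ccz_end <= n_frames`.
#' @param noise uniform noise amplitude added to the one-hot scores.
#' @param seed integer seed.
#' @return A list with `truth` (integer vector of 0/1/2 per frame) and
#'   `scores` (`n_frames` x 3 matrix, rows summing to 1).
#' @export
generate_zone_scores <- function(n_frames, boundaries, noise = 0, seed = 1L) {
  stopifnot(n_frames >= 1, length(boundaries) == 2)
  p <- boundaries[1]; c2 <- boundaries[2]
  if (p < 0 || p > c2 || c2 > n_frames) {
    stop("need 0 <= pcz_end <= ccz_end <= n_frames", call. = FALSE)
  }
  set.seed(as.integer(seed))
  truth <- c(rep(0L, p), rep(1L, c2 - p), rep(2L, n_frames - c2))
  scores <- matrix(0, n_frames, 3)
  scores[cbind(seq_len(n_frames), truth + 1L)] <- 1
  if (noise > 0) {
    scores <- scores + matrix(stats::runif(n_frames * 3, 0, noise),
                              n_frames, 3)
  }
  list(truth = truth, scores = scores / rowSums(scores))
}

#' Texture phantom crops: organized vs disorganized bundles
#'
#' Organized crops are smooth periodic stripe patterns (regular stereocilia
#' packing); disorganized crops contain the same intensity histogram with the
#' spatial arrangement scrambled, emulating disrupted bundles: local contrast
#' rises and homogeneity falls while first-order statistics stay fixed.
#'
#' @param n_per_group crops per group.
#' @param size crop side length in pixels.
#' @param seed integer seed.
#' @return A tibble with columns `crop_id`, `group` ("organized" /
#'   "disorganized") and a list-column `crop` of matrices.
#' @export
generate_texture_crops <- function(n_per_group = 20, size = 32, seed = 1L) {
  set.seed(as.integer(seed))
  mk_org <- function() {
    ph <- stats::runif(1, 0, 2 * pi)
    per <- stats::runif(1, 6, 9)
    base <- outer(seq_len(size), seq_len(size), function(y, x) {
      100 + 60 * sin(2 * pi * x / per + ph) + 10 * sin(2 * pi * y / (2 * per))
    })
    pmax(round(base + stats::rnorm(size^2, 0, 3)), 0)
  }
  org <- replicate(n_per_group, mk_org(), simplify = FALSE)
  dis <- lapply(org, function(m) {
    matrix(sample(as.vector(m)), nrow(m), ncol(m))
  })
  tibble::tibble(
    crop_id = seq_len(2 * n_per_group),
    group = rep(c("organized", "disorganized"), each = n_per_group),
    crop = c(org, dis)
  )
}
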