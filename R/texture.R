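#' GLCM texture features of a 2D crop
#'
#' Builds symmetric, normalized gray-level co-occurrence matrices at the
#' given pixel distances and angles, averages the four standard Haralick
#' scalars over the offset set, and returns them:
#' contrast `sum p(i,j) (i-j)^2`, energy `sum p^2`, homogeneity
#' `sum p / (1 + |i-j|)`, and correlation via the marginal means/s.d.s.
#' Intensities are binned to `levels` gray levels by linear rescaling of the
#' crop's own range (offset-invariant); a constant crop has contrast 0,
#' energy 1, homogeneity 1 and an undefined (NA) correlation.
#'
#' @param crop numeric matrix, at least 2x2.
#' @param levels number of gray levels (>= 2).
#' @param distances integer pixel distances.
#' @param angles offset angles in degrees (0, 45, 90, 135 supported).
#' @return A one-row tibble: `contrast`, `correlation`, `energy`,
#'   `homogeneity`.
#' @examples
#' glcm_features(matrix(c(0, 1, 0, 1, 0, 1, 0, 1, 0), 3), levels = 2)
#' @export
glcm_features <- function(crop, levels = 256L, distances = 1L,
                          angles = c(0, 45, 90, 135)) {
  if (!is.matrix(crop) || nrow(crop) < 2 || ncol(crop) < 2) {
    stop("`crop` must be a matrix of at least 2x2", call. = FALSE)
  }
  if (levels < 2) stop("levels must be >= 2", call. = FALSE)
  rng <- range(crop)
  q <- if (rng[1] == rng[2]) {
    matrix(0L, nrow(crop), ncol(crop))
  } else {
    matrix(as.integer(pmin(floor((crop - rng[1]) / diff(rng) * levels),
                           levels - 1)), nrow(crop), ncol(crop))
  }
  feats <- purrr::map(distances, function(d) {
    purrr::map(angles, function(ang) {
      glcm_single(q, levels, d, ang)
    })
  })
  feats <- purrr::flatten(feats)
  out <- purrr::map_dfr(feats, glcm_scalars)
  dplyr::summarise(out, dplyr::across(dplyr::everything(), mean))
}

# co-occurrence offsets follow the usual image convention:
# 0 deg -> (0, d); 45 -> (-d, d); 90 -> (-d, 0); 135 -> (-d, -d) in (dy, dx)
glcm_single <- function(q, levels, d, ang) {
  off <- switch(as.character(ang %% 180),
                "0" = c(0, d), "45" = c(-d, d), "90" = c(-d, 0),
                "135" = c(-d, -d),
                stop("angle must be one of 0, 45, 90, 135", call. = FALSE))
  H <- nrow(q); W <- ncol(q)
  ys <- seq_len(H); xs <- seq_len(W)
  y2 <- ys + off[1]; x2 <- xs + off[2]
  ok_y <- ys[y2 >= 1 & y2 <= H]; ok_x <- xs[x2 >= 1 & x2 <= W]
  a <- q[ok_y, ok_x, drop = FALSE]
  b <- q[ok_y + off[1], ok_x + off[2], drop = FALSE]
  cm <- matrix(0, levels, levels)
  tab <- table(factor(a, levels = 0:(levels - 1)),
               factor(b, levels = 0:(levels - 1)))
  cm <- cm + tab + t(tab)        # symmetric
  cm / sum(cm)
}

glcm_scalars <- function(p) {
  L <- nrow(p)
  i <- matrix(0:(L - 1), L, L)
  j <- t(i)
  pi_m <- rowSums(p)
  mu <- sum((0:(L - 1)) * pi_m)
  sig2 <- sum(((0:(L - 1)) - mu)^2 * pi_m)
  corr <- if (sig2 > 0) sum(p * (i - mu) * (j - mu)) / sig2 else NA_real_
  tibble::tibble(
    contrast = sum(p * (i - j)^2),
    correlation = corr,
    energy = sum(p^2),
    homogeneity = sum(p / (1 + abs(i - j)))
  )
}

#' Uniform LBP histogram of a 2D crop
#'
#' Classic 8-neighbor local binary patterns (P = 8, R = 1, nearest-pixel
#' sampling): each interior pixel's neighbors are thresholded at the center
#' value (neighbor >= center gives bit 1), and the circular pattern is
#' mapped to the uniform code set — patterns with at most two 0/1
#' transitions map to their number of set bits (bins 0..8), all others to
#' the non-uniform bin 9. The 10-bin histogram is normalized to sum 1 and is
#' invariant to any strictly increasing intensity transform.
#'
#' @param crop numeric matrix larger than 3x3.
#' @return Numeric vector of 10 bin proportions (names `lbp0`..`lbp9`).
#' @export
lbp_histogram <- function(crop) {
  if (!is.matrix(crop) || nrow(crop) < 3 || ncol(crop) < 3) {
    stop("`crop` must be at least 3x3", call. = FALSE)
  }
  H <- nrow(crop); W <- ncol(crop)
  ctr <- crop[2:(H - 1), 2:(W - 1)]
  # neighbors in circular order starting east, counter-clockwise (y down)
  offs <- list(c(0, 1), c(-1, 1), c(-1, 0), c(-1, -1),
               c(0, -1), c(1, -1), c(1, 0), c(1, 1))
  bits <- lapply(offs, function(o) {
    crop[2:(H - 1) + o[1], 2:(W - 1) + o[2]] >= ctr
  })
  codes <- mapply(function(b, k) as.integer(b) * 2^(k - 1),
                  bits, seq_along(bits), SIMPLIFY = FALSE)
  code <- Reduce(`+`, codes)
  bins <- uniform_lbp_map()[code + 1L]
  h <- tabulate(bins + 1L, nbins = 10L)
  setNames(h / sum(h), paste0("lbp", 0:9))
}

# code -> uniform bin: #set bits if <= 2 circular transitions, else 9
uniform_lbp_map <- function() {
  vapply(0:255, function(code) {
    b <- as.integer(intToBits(code)[1:8])
    trans <- sum(b != c(b[-1], b[1]))
    if (trans <= 2) sum(b) else 9L
  }, integer(1))
}

#' Extract texture features for a set of crops
#'
#' @param crops tibble with `crop_id`, `group` and list-column `crop`
#'   (matrices), e.g. from [generate_texture_crops()] or
#'   [bundle_crops()].
#' @param levels,distances,angles passed to [glcm_features()].
#' @return A tibble with one row per crop: GLCM scalars and `lbp0`..`lbp9`.
#' @export
texture_features <- function(crops, levels = 256L, distances = 1L,
                             angles = c(0, 45, 90, 135)) {
  stopifnot(all(c("crop_id", "crop") %in% names(crops)))
  purrr::map_dfr(seq_len(nrow(crops)), function(i) {
    m <- crops$crop[[i]]
    dplyr::bind_cols(
      tibble::tibble(crop_id = crops$crop_id[i],
                     group = if ("group" %in% names(crops))
                       crops$group[i] else NA_character_),
      glcm_features(m, levels, distances, angles),
      tibble::as_tibble_row(lbp_histogram(m))
    )
  })
}

#' Per-bundle intensity crops from a labeled stack
#'
#' Cuts one crop per bundle from the maximum-intensity projection: the
#' bundle's projected bounding box, masked to the bundle with background
#' pixels replaced by the plane background mean.
#'
#' @param vol a [label_volume()].
#' @param stack a matching [zstack()].
#' @return A tibble `crop_id`, `crop` (list-column of matrices).
#' @export
bundle_crops <- function(vol, stack) {
  stopifnot(inherits(vol, "label_volume"), inherits(stack, "zstack"))
  mip <- apply(stack$frames, c(2, 3), max)
  bg <- mean(mip[apply(vol$labels == 0L, c(2, 3), all)])
  purrr::map_dfr(label_ids(vol), function(id) {
    proj <- project_z(vol, id)
    pix <- which(proj, arr.ind = TRUE)
    yr <- range(pix[, 1]); xr <- range(pix[, 2])
    cr <- mip[yr[1]:yr[2], xr[1]:xr[2], drop = FALSE]
    msk <- proj[yr[1]:yr[2], xr[1]:xr[2], drop = FALSE]
    cr[!msk] <- bg
    tibble::tibble(crop_id = id, crop = list(cr))
  })
}

#' Two-group nonparametric feature comparison
#'
#' Two-sided Mann-Whitney U tests per feature column (exact for small
#' tie-free samples, normal approximation with tie correction otherwise,
#' as implemented in [stats::wilcox.test()]), with group medians reported
#' alongside. Columns whose pooled values are all identical get `p = 1`
#' and a tie note.
#'
#' @param features tibble with a `group` column (exactly 2 levels) and
#'   numeric feature columns.
#' @return A tibble with one row per feature: `feature`, `median_a`,
#'   `median_b`, `statistic` (U), `p_value`, `note`.
#' @export
group_compare <- function(features) {
  stopifnot("group" %in% names(features))
  gl <- unique(features$group)
  if (length(gl) != 2) stop("need exactly two groups", call. = FALSE)
  num_cols <- names(features)[vapply(features, is.numeric, logical(1))]
  num_cols <- setdiff(num_cols, "crop_id")
  purrr::map_dfr(num_cols, function(col) {
    a <- features[[col]][features$group == gl[1]]
    b <- features[[col]][features$group == gl[2]]
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    if (length(a) == 0 || length(b) == 0) {
      return(tibble::tibble(feature = col, median_a = NA_real_,
                            median_b = NA_real_, statistic = NA_real_,
                            p_value = NA_real_, note = "empty group"))
    }
    if (length(unique(c(a, b))) == 1) {
      return(tibble::tibble(feature = col, median_a = median(a),
                            median_b = median(b), statistic = NA_real_,
                            p_value = 1, note = "all values tied"))
    }
    wt <- suppressWarnings(wilcox.test(a, b, exact = NULL, correct = TRUE))
    tibble::tibble(feature = col, median_a = median(a), median_b = median(b),
                   statistic = unname(wt$statistic), p_value = wt$p.value,
                   note = "")
  })
}
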