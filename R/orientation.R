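#' Bundle orientation from a binary projection
#'
#' Estimates the planar-cell-polarity orientation of a V-shaped bundle from
#' its binary z-projection. Two endpoint strategies are provided:
#'
#' * `"height_only"`: on each side of the centroid's x, take the lowest
#'   foreground pixel (maximal y; ties broken by the larger horizontal
#'   distance from the centroid). Works well for clean V shapes but can pick
#'   a non-wing pixel on atypical shapes.
#' * `"height_distance"`: on each side, restrict to pixels within
#'   `tolerance_px` of that side's lowest y, then take the pixel farthest
#'   (Euclidean) from the peak. More robust for irregular, curved bundles.
#'
#' The peak is the topmost pixel (minimal y, ties to minimal x). Three angles
#' are derived via [angles_from_points()]. If one side of the centroid has no
#' pixels under `"height_only"`, the result is flagged and the
#' `"height_distance"` rule is used as fallback.
#'
#' @param proj logical (y, x) matrix, e.g. from [project_z()].
#' @param method `"height_only"` or `"height_distance"`.
#' @param tolerance_px y-band half-width for `"height_distance"`, px.
#' @param bundle_id optional ID carried into the result.
#' @return A one-row tibble: endpoint coordinates (`left_x/y`, `right_x/y`,
#'   `peak_x/y`), `baseline_angle_deg`, `axis_angle_deg`, `apex_angle_deg`,
#'   `method`, `degenerate`.
#' @export
bundle_orientation <- function(proj, method = c("height_only",
                                                "height_distance"),
                               tolerance_px = 2, bundle_id = NA_integer_) {
  method <- match.arg(method)
  pix <- which(proj, arr.ind = TRUE)  # (y, x)
  if (nrow(pix) == 0) stop("empty projection", call. = FALSE)
  cx <- mean(pix[, 2])
  ypk <- min(pix[, 1])
  pk_x <- min(pix[pix[, 1] == ypk, 2]); pk_y <- ypk

  left <- pix[pix[, 2] < cx, , drop = FALSE]
  right <- pix[pix[, 2] > cx, , drop = FALSE]
  degenerate <- nrow(left) == 0 || nrow(right) == 0
  if (degenerate && method == "height_only") method <- "height_distance"
  if (degenerate) {
    # split at the peak instead of the centroid
    left <- pix[pix[, 2] <= pk_x, , drop = FALSE]
    right <- pix[pix[, 2] >= pk_x, , drop = FALSE]
  }

  pick <- function(side, sign) {
    if (method == "height_only") {
      ymax <- max(side[, 1])
      cand <- side[side[, 1] == ymax, , drop = FALSE]
      cand[which.max(abs(cand[, 2] - cx)), ]
    } else {
      ymax <- max(side[, 1])
      cand <- side[side[, 1] >= ymax - tolerance_px, , drop = FALSE]
      d2 <- (cand[, 2] - pk_x)^2 + (cand[, 1] - pk_y)^2
      best <- which(d2 == max(d2))
      if (length(best) > 1) {  # tie: lower then outermost
        cand <- cand[best, , drop = FALSE]
        best <- order(-cand[, 1], sign * -cand[, 2])[1]
        cand[best, ]
      } else cand[best, ]
    }
  }
  lp <- unname(pick(left, -1)); rp <- unname(pick(right, +1))

  ang <- angles_from_points(c(lp[2], lp[1]), c(rp[2], rp[1]), c(pk_x, pk_y))
  tibble::tibble(
    bundle_id = bundle_id,
    left_x = lp[2], left_y = lp[1],
    right_x = rp[2], right_y = rp[1],
    peak_x = pk_x, peak_y = pk_y,
    baseline_angle_deg = unname(ang["baseline"]),
    axis_angle_deg = unname(ang["axis"]),
    apex_angle_deg = unname(ang["apex"]),
    method = method, degenerate = degenerate
  )
}

#' Angles from V endpoints
#'
#' Given the left and right base points and the peak of a V (image
#' coordinates, y down), returns:
#' * `baseline`: direction of the left→right base line, `atan2(dy, dx)`
#'   mapped to `[0, 180)` degrees;
#' * `axis`: direction from the base midpoint to the peak, mapped to
#'   `[0, 180)`; a symmetric upright V gives exactly 90;
#' * `apex`: opening angle at the peak between the two wings, in `(0, 180)`.
#'
#' @param left,right,peak numeric `(x, y)` pairs.
#' @return Named numeric vector `baseline`, `axis`, `apex` (degrees); all
#'   `NA` with a warning if points coincide.
#' @examples
#' angles_from_points(c(30, 40), c(70, 40), c(50, 10))
#' @export
angles_from_points <- function(left, right, peak) {
  if (all(left == right)) {
    warning("left and right points coincide; angles undefined", call. = FALSE)
    return(c(baseline = NA_real_, axis = NA_real_, apex = NA_real_))
  }
  deg <- function(x) x * 180 / pi
  baseline <- deg(atan2(right[2] - left[2], right[1] - left[1])) %% 180
  mid <- (left + right) / 2
  axis <- deg(atan2(peak[2] - mid[2], peak[1] - mid[1])) %% 180
  v1 <- left - peak; v2 <- right - peak
  apex <- deg(acos(pmin(1, pmax(-1, sum(v1 * v2) /
                                  (sqrt(sum(v1^2)) * sqrt(sum(v2^2)))))))
  c(baseline = unname(baseline), axis = unname(axis), apex = unname(apex))
}

#' Orientation of every bundle in a volume
#'
#' @param vol a [label_volume()].
#' @param method,tolerance_px see [bundle_orientation()].
#' @return A tibble with one row per bundle.
#' @export
measure_orientations <- function(vol, method = "height_distance",
                                 tolerance_px = 2) {
  stopifnot(inherits(vol, "label_volume"))
  purrr::map_dfr(label_ids(vol), function(id) {
    bundle_orientation(project_z(vol, id), method = method,
                       tolerance_px = tolerance_px, bundle_id = id)
  })
}
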