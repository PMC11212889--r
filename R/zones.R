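#' Macro-averaged classification metrics from a confusion matrix
#'
#' Derives per-class one-vs-rest TP, FP, FN, TN and macro-averages accuracy
#' `(TP+TN)/(TP+TN+FP+FN)`, precision, recall, specificity and F1 across
#' classes; the error rate is the off-diagonal sum over the grand total.
#' Metrics with a zero denominator for some class are returned as `NA`
#' rather than 0.
#'
#' @param cm square matrix of non-negative integer counts; rows = truth,
#'   columns = prediction.
#' @return A one-row tibble: `accuracy`, `precision`, `recall`,
#'   `specificity`, `f1`, `error_rate`.
#' @examples
#' confusion_metrics(matrix(c(8, 1, 2, 9), 2))
#' @export
confusion_metrics <- function(cm) {
  cm <- as.matrix(cm)
  if (nrow(cm) != ncol(cm) || any(cm < 0) || sum(cm) == 0) {
    stop("`cm` must be a square count matrix with a positive total",
         call. = FALSE)
  }
  n <- sum(cm)
  per <- purrr::map_dfr(seq_len(nrow(cm)), function(c) {
    tp <- cm[c, c]
    fn <- sum(cm[c, ]) - tp
    fp <- sum(cm[, c]) - tp
    tn <- n - tp - fn - fp
    safe <- function(num, den) if (den > 0) num / den else NA_real_
    tibble::tibble(
      accuracy = (tp + tn) / n,
      precision = safe(tp, tp + fp),
      recall = safe(tp, tp + fn),
      specificity = safe(tn, tn + fp)
    ) |>
      dplyr::mutate(f1 = 2 * .data$precision * .data$recall /
                      (.data$precision + .data$recall))
  })
  dplyr::summarise(per, dplyr::across(dplyr::everything(),
                                      ~ mean(.x, na.rm = FALSE))) |>
    dplyr::mutate(error_rate = (n - sum(diag(cm))) / n)
}

#' Count prediction switches in a zone-label sequence
#'
#' A clean z-stack runs monotonically through pre-cellular (0), cellular
#' clarity (1) and noise-saturation (2) zones. A "switch" is any transition
#' that breaks that pattern: a decreasing step, or a forward step repeating a
#' transition already used (which implies the sequence went back in
#' between). Monotone non-decreasing sequences score 0.
#'
#' @param labels integer vector of per-frame classes in `{0, 1, 2}`.
#' @return Integer switch count.
#' @examples
#' count_switches(c(0, 0, 1, 1, 2))   # 0
#' count_switches(c(0, 1, 0, 1, 2))   # 2
#' @export
count_switches <- function(labels) {
  if (!all(labels %in% 0:2)) stop("labels must be 0, 1 or 2", call. = FALSE)
  if (length(labels) < 2) return(0L)
  used <- character()
  switches <- 0L
  for (i in 2:length(labels)) {
    a <- labels[i - 1]; b <- labels[i]
    if (b == a) next
    if (b < a) {
      switches <- switches + 1L
    } else {
      key <- paste(a, b)
      if (key %in% used) switches <- switches + 1L
      used <- c(used, key)
    }
  }
  switches
}

#' Cellular-clarity frame range
#'
#' The longest contiguous run of CCZ frames (class 1); with several runs of
#' maximal length, the first. Only these frames proceed to segmentation and
#' quantification.
#'
#' @param labels integer vector of per-frame classes in `{0, 1, 2}`.
#' @return Integer `(first, last)` 1-based frame indices, or `NULL` if no
#'   frame is CCZ.
#' @export
ccz_range <- function(labels) {
  if (!all(labels %in% 0:2)) stop("labels must be 0, 1 or 2", call. = FALSE)
  r <- rle(labels == 1L)
  if (!any(r$values)) return(NULL)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  best <- runs[which.max(r$lengths[runs])]
  c(first = starts[best], last = ends[best])
}

#' Aggregate per-frame rotation scores into one stack angle
#'
#' Per-frame class scores over 72 rotation classes (class c = `c * 5`
#' degrees, c = 0..71) are averaged across all frames of the stack; the
#' class with the highest mean score gives the predicted orientation and
#' the stack is to be rotated by `360 - predicted` degrees (mod 360) to
#' align it. Ties go to the lowest class.
#'
#' @param scores numeric matrix, one row per frame, 72 columns.
#' @return A list with `predicted_angle_deg` and `correction_deg`.
#' @export
aggregate_rotation <- function(scores) {
  scores <- as.matrix(scores)
  if (nrow(scores) == 0 || ncol(scores) != 72 || any(!is.finite(scores))) {
    stop("`scores` must be a finite matrix with 72 columns and >= 1 row",
         call. = FALSE)
  }
  avg <- colMeans(scores)
  cls <- which.max(avg) - 1L  # which.max takes the first (lowest) on ties
  pred <- 5 * cls
  list(predicted_angle_deg = pred, correction_deg = (360 - pred) %% 360)
}

#' Rotate a frame and crop the largest padding-free rectangle
#'
#' Rotates a 2D frame about its center, then crops the maximum-area
#' axis-aligned rectangle guaranteed to lie inside the rotated footprint of
#' the original frame (closed form for a rotated W x H rectangle), so the
#' output contains no padding pixels. Used to build rotation-augmented
#' training frames and to apply a predicted alignment correction.
#'
#' @param frame numeric matrix (y, x).
#' @param angle_deg rotation angle in degrees (positive = clockwise on
#'   screen, y pointing down).
#' @param interp `"nearest"` or `"bilinear"`.
#' @return The cropped rotated matrix.
#' @export
rotate_and_crop_max_rect <- function(frame, angle_deg,
                                     interp = c("nearest", "bilinear")) {
  interp <- match.arg(interp)
  H <- nrow(frame); W <- ncol(frame)
  a <- angle_deg %% 360
  if (a %% 90 == 0) {
    k <- (a / 90) %% 4
    out <- frame
    if (k >= 1) for (i in seq_len(k)) out <- t(apply(out, 2, rev))
    return(out)
  }
  rot <- rotate2d(frame, angle_deg, fill = NA_real_, interp = interp)
  wh <- largest_inscribed_rect(W, H, angle_deg)
  cw <- max(1L, floor(wh[1])); ch <- max(1L, floor(wh[2]))
  y0 <- floor((H - ch) / 2); x0 <- floor((W - cw) / 2)
  out <- rot[(y0 + 1):(y0 + ch), (x0 + 1):(x0 + cw), drop = FALSE]
  stopifnot(!anyNA(out))
  out
}

# closed-form largest axis-aligned rectangle inside a W x H rectangle
# rotated by `angle` degrees (Wikipedia "rotated rectangle" result)
largest_inscribed_rect <- function(W, H, angle) {
  a <- abs(angle %% 180)
  if (a > 90) a <- 180 - a
  a <- a * pi / 180
  if (a == 0) return(c(W, H))
  s <- sin(a); co <- cos(a)
  long <- max(W, H); short <- min(W, H)
  if (short <= 2 * s * co * long) {
    x <- 0.5 * short
    wh <- if (W >= H) c(x / s, x / co) else c(x / co, x / s)
  } else {
    cos2a <- co^2 - s^2
    wh <- c((W * co - H * s) / cos2a, (H * co - W * s) / cos2a)
  }
  wh
}

# rotate a matrix about its center by angle_deg (y-down image frame,
# positive angle = clockwise on screen) via inverse mapping
rotate2d <- function(mat, angle_deg, fill = 0, interp = "nearest") {
  H <- nrow(mat); W <- ncol(mat)
  a <- angle_deg * pi / 180
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  xg <- matrix(rep(seq_len(W), each = H), H, W) - cx
  yg <- matrix(rep(seq_len(H), W), H, W) - cy
  # inverse rotation: source coords for each output pixel
  sx <- cos(a) * xg - sin(a) * yg + cx
  sy <- sin(a) * xg + cos(a) * yg + cy
  out <- matrix(fill, H, W)
  if (interp == "nearest") {
    ix <- round(sx); iy <- round(sy)
    ok <- ix >= 1 & ix <= W & iy >= 1 & iy <= H
    out[ok] <- mat[cbind(iy[ok], ix[ok])]
  } else {
    x0 <- floor(sx); y0 <- floor(sy)
    fx <- sx - x0; fy <- sy - y0
    ok <- x0 >= 1 & x0 + 1 <= W & y0 >= 1 & y0 + 1 <= H
    g <- function(yy, xx) mat[cbind(yy[ok], xx[ok])]
    out[ok] <- (1 - fy[ok]) * ((1 - fx[ok]) * g(y0, x0) + fx[ok] * g(y0, x0 + 1)) +
      fy[ok] * ((1 - fx[ok]) * g(y0 + 1, x0) + fx[ok] * g(y0 + 1, x0 + 1))
  }
  out
}

#' Tonotopic region by windowed majority vote
#'
#' Classifies a stack as BASE, MIDDLE or APEX from per-frame predictions:
#' votes are counted over a window of `window` frames starting at the median
#' frame (index `floor((F - 1) / 2)`, 0-based) and clipped at the stack end.
#' Ties go to the label with the highest summed score when per-frame scores
#' are supplied, otherwise to the earlier label in `levels`.
#'
#' @param frame_labels character vector of per-frame predictions.
#' @param scores optional numeric vector of per-frame confidence scores.
#' @param window vote window length in frames.
#' @param levels label ordering used for tie-breaks.
#' @return A single label.
#' @export
tonotopic_vote <- function(frame_labels, scores = NULL, window = 13L,
                           levels = c("BASE", "MIDDLE", "APEX")) {
  f <- length(frame_labels)
  stopifnot(f >= 1)
  m <- floor((f - 1) / 2)                      # 0-based median frame
  idx <- (m + 1):min(f, m + window)            # 1-based, clipped
  votes <- table(factor(frame_labels[idx], levels = levels))
  top <- names(votes)[votes == max(votes)]
  if (length(top) == 1) return(top)
  if (!is.null(scores)) {
    ssum <- tapply(scores[idx], factor(frame_labels[idx], levels = levels),
                   sum)
    ssum <- ssum[top]
    return(names(ssum)[which.max(ssum)])
  }
  top[1]
}
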