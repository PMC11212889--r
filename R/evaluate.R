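#' 3D intersection-over-union of two voxel supports
#'
#' @param a,b logical arrays of identical shape.
#' @return `|a intersect b| / |a union b|`; `NA` if both supports are empty.
#' @export
iou3d <- function(a, b) {
  if (!identical(dim(a), dim(b))) stop("shapes differ", call. = FALSE)
  un <- sum(a | b)
  if (un == 0) return(NA_real_)
  sum(a & b) / un
}

#' Match predicted to ground-truth instances at one IoU threshold
#'
#' Iterates over the instance labels of both volumes (background excluded),
#' computes pairwise IoU for every overlapping (GT, prediction) pair, and
#' matches greedily by descending IoU so that each GT instance gets at most
#' one prediction and vice versa — the GT instance keeps the prediction with
#' the largest overlap, and a second prediction on the same GT instance
#' becomes a false positive. Matched pairs with IoU at or above the
#' threshold are true positives; unmatched predictions are false positives,
#' unmatched GT instances false negatives. True negatives are not counted
#' (background dominates them). `method = "optimal"` replaces the greedy
#' rule with the assignment maximizing total matched IoU (exhaustive; small
#' volumes only).
#'
#' @param gt,pred [label_volume()]s of identical shape.
#' @param iou_threshold threshold in `(0, 1]`.
#' @param method `"greedy"` (default) or `"optimal"`.
#' @return A one-row tibble: `iou_threshold`, `tp`, `fp`, `fn`, `precision`,
#'   `recall`, `f1`, `detection_accuracy` (= TP / (TP + FP + FN)), plus the
#'   matched pairs in attribute `"pairs"`.
#' @export
match_instances <- function(gt, pred, iou_threshold = 0.5,
                            method = c("greedy", "optimal")) {
  method <- match.arg(method)
  stopifnot(inherits(gt, "label_volume"), inherits(pred, "label_volume"))
  if (!identical(dim(gt$labels), dim(pred$labels))) {
    stop("volume shapes differ", call. = FALSE)
  }
  if (iou_threshold <= 0 || iou_threshold > 1) {
    stop("iou_threshold must be in (0, 1]", call. = FALSE)
  }
  pairs <- overlap_pairs(gt$labels, pred$labels)
  gt_ids <- label_ids(gt); pred_ids <- label_ids(pred)

  matched <- if (nrow(pairs) == 0) {
    pairs
  } else if (method == "greedy") {
    pairs <- pairs[order(-pairs$iou, pairs$gt_id, pairs$pred_id), ]
    keep <- logical(nrow(pairs))
    used_g <- integer(); used_p <- integer()
    for (i in seq_len(nrow(pairs))) {
      if (!(pairs$gt_id[i] %in% used_g) && !(pairs$pred_id[i] %in% used_p)) {
        keep[i] <- TRUE
        used_g <- c(used_g, pairs$gt_id[i])
        used_p <- c(used_p, pairs$pred_id[i])
      }
    }
    pairs[keep, ]
  } else {
    optimal_assignment(pairs)
  }

  tp <- sum(matched$iou >= iou_threshold)
  fp <- length(pred_ids) - tp
  fn <- length(gt_ids) - tp
  res <- tibble::tibble(
    iou_threshold = iou_threshold, tp = tp, fp = fp, fn = fn,
    precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    f1 = if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else NA_real_,
    detection_accuracy = if (tp + fp + fn > 0) tp / (tp + fp + fn)
    else NA_real_
  )
  attr(res, "pairs") <- matched
  res
}

# all overlapping (gt, pred) label pairs with sizes and IoU
overlap_pairs <- function(glabs, plabs) {
  both <- glabs > 0L & plabs > 0L
  if (!any(both)) {
    return(tibble::tibble(gt_id = integer(), pred_id = integer(),
                          inter = integer(), iou = numeric()))
  }
  tab <- table(gt = glabs[both], pred = plabs[both])
  gsz <- table(glabs[glabs > 0L]); psz <- table(plabs[plabs > 0L])
  df <- as.data.frame(tab, stringsAsFactors = FALSE)
  df <- df[df$Freq > 0, ]
  gt_id <- as.integer(df$gt); pred_id <- as.integer(df$pred)
  inter <- df$Freq
  union <- as.integer(gsz[as.character(gt_id)]) +
    as.integer(psz[as.character(pred_id)]) - inter
  tibble::tibble(gt_id = gt_id, pred_id = pred_id, inter = inter,
                 iou = inter / union)
}

# exhaustive one-to-one assignment maximizing total IoU (small inputs)
optimal_assignment <- function(pairs) {
  gts <- unique(pairs$gt_id)
  if (length(gts) > 10) {
    stop("optimal matching is exhaustive; use <= 10 GT instances",
         call. = FALSE)
  }
  best <- list(score = -1, rows = integer())
  recurse <- function(gi, used_p, rows, score) {
    if (gi > length(gts)) {
      if (score > best$score) best <<- list(score = score, rows = rows)
      return()
    }
    cand <- which(pairs$gt_id == gts[gi] & !(pairs$pred_id %in% used_p))
    recurse(gi + 1, used_p, rows, score)  # leave this GT unmatched
    for (i in cand) {
      recurse(gi + 1, c(used_p, pairs$pred_id[i]), c(rows, i),
              score + pairs$iou[i])
    }
  }
  recurse(1, integer(), integer(), 0)
  pairs[best$rows, ]
}

#' Detection metrics across the standard IoU threshold sweep
#'
#' Evaluates [match_instances()] at thresholds 0.10, 0.15, ..., 1.00
#' (19 values). TP is non-increasing and FP/FN non-decreasing in the
#' threshold.
#'
#' @param gt,pred [label_volume()]s of identical shape.
#' @param thresholds threshold vector (default the 19-step sweep).
#' @param method passed to [match_instances()].
#' @return A tibble with one row per threshold, of class `iou_sweep`.
#' @export
sweep_thresholds <- function(gt, pred,
                             thresholds = seq(0.10, 1.00, by = 0.05),
                             method = "greedy") {
  res <- purrr::map_dfr(thresholds, function(th) {
    match_instances(gt, pred, iou_threshold = th, method = method)
  })
  class(res) <- c("iou_sweep", class(res))
  res
}

#' Descriptive statistics
#'
#' Arithmetic mean, median, and standard deviation. The default s.d. uses
#' population normalization (divisor n); `normalization = "sample"` gives
#' the usual n-1 divisor.
#'
#' @param values numeric vector, n >= 1.
#' @param normalization `"population"` or `"sample"`.
#' @return A one-row tibble: `n`, `mean`, `median`, `std`.
#' @examples
#' descriptives(c(1, 2, 3, 4))
#' @export
descriptives <- function(values, normalization = c("population", "sample")) {
  normalization <- match.arg(normalization)
  values <- values[!is.na(values)]
  if (length(values) == 0) stop("no values", call. = FALSE)
  n <- length(values)
  s <- if (n == 1) 0 else if (normalization == "population") {
    sqrt(mean((values - mean(values))^2))
  } else sd(values)
  tibble::tibble(n = n, mean = mean(values), median = median(values),
                 std = s)
}

#' Agreement statistics between two paired measurement series
#'
#' Runs any subset of: Pearson correlation, paired t-test (df = n-1),
#' Wilcoxon signed-rank (zero differences dropped, exact for n <= 25
#' without ties), and (unpaired) Mann-Whitney U — the protocol used to
#' compare automated bundle heights with human observers. All p-values are
#' two-sided.
#'
#' @param x,y numeric vectors; equal length for the paired tests; n >= 3.
#' @param tests character subset of `c("pearson", "paired_t", "wilcoxon",
#'   "mannwhitney")`.
#' @return An `agreement` object; see [tidy()] for the per-test table and
#'   [glance()] for a one-row summary.
#' @examples
#' agreement(1:10, 1:10 + rnorm(10, 0, 0.1))
#' @export
agreement <- function(x, y, tests = c("pearson", "paired_t", "wilcoxon")) {
  tests <- match.arg(tests, c("pearson", "paired_t", "wilcoxon",
                              "mannwhitney"), several.ok = TRUE)
  if (length(x) < 3 || length(y) < 3) stop("need n >= 3", call. = FALSE)
  paired_tests <- intersect(tests, c("pearson", "paired_t", "wilcoxon"))
  if (length(paired_tests) > 0 && length(x) != length(y)) {
    stop("paired tests need equal lengths", call. = FALSE)
  }
  out <- list()
  if ("pearson" %in% tests) {
    if (sd(x) == 0 || sd(y) == 0) {
      out$pearson <- list(estimate = NA_real_, p.value = NA_real_,
                          note = "zero variance")
    } else {
      ct <- cor.test(x, y, method = "pearson")
      out$pearson <- list(estimate = unname(ct$estimate),
                          p.value = ct$p.value, note = "")
    }
  }
  if ("paired_t" %in% tests) {
    d <- x - y
    if (sd(d) < 1e-10 * max(1, abs(mean(d)))) {
      # identical series (or constant shift of zero spread): t is 0 or +-Inf
      out$paired_t <- list(
        statistic = if (mean(d) == 0) 0 else sign(mean(d)) * Inf,
        p.value = if (mean(d) == 0) 1 else 0,
        df = length(d) - 1, note = "constant differences")
    } else {
      tt <- t.test(x, y, paired = TRUE)
      out$paired_t <- list(statistic = unname(tt$statistic),
                           p.value = tt$p.value,
                           df = unname(tt$parameter), note = "")
    }
  }
  if ("wilcoxon" %in% tests) {
    wt <- suppressWarnings(wilcox.test(x, y, paired = TRUE))
    out$wilcoxon <- list(statistic = unname(wt$statistic),
                         p.value = wt$p.value, note = "zeros dropped")
  }
  if ("mannwhitney" %in% tests) {
    wt <- suppressWarnings(wilcox.test(x, y))
    out$mannwhitney <- list(statistic = unname(wt$statistic),
                            p.value = wt$p.value, note = "")
  }
  structure(list(tests = out, n = length(x),
                 descriptives_x = descriptives(x),
                 descriptives_y = descriptives(y)),
            class = "agreement")
}

#' @export
print.agreement <- function(x, ...) {
  cat(sprintf("<agreement> n = %d\n", x$n))
  print(tidy(x))
  invisible(x)
}

#' Tidy the per-test agreement results
#'
#' @param x an `agreement` object.
#' @param ... unused.
#' @return A tibble with one row per test: `test`, `estimate`, `statistic`,
#'   `df`, `p_value`.
#' @method tidy agreement
#' @export
tidy.agreement <- function(x, ...) {
  purrr::imap_dfr(x$tests, function(t, nm) {
    tibble::tibble(
      test = nm,
      estimate = t$estimate %||% NA_real_,
      statistic = t$statistic %||% NA_real_,
      df = t$df %||% NA_real_,
      p_value = t$p.value
    )
  })
}

#' One-row agreement summary
#'
#' @param x an `agreement` object.
#' @param ... unused.
#' @return A one-row tibble: `n`, `mean_x`, `mean_y`, and the headline
#'   Pearson r / paired t when computed.
#' @method glance agreement
#' @export
glance.agreement <- function(x, ...) {
  tibble::tibble(
    n = x$n,
    mean_x = x$descriptives_x$mean,
    mean_y = x$descriptives_y$mean,
    pearson_r = x$tests$pearson$estimate %||% NA_real_,
    paired_t = x$tests$paired_t$statistic %||% NA_real_
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Bundle-height agreement benchmark table
#'
#' The 18-bundle validation set used to compare automated tip-to-base height
#' measurements against two human expert observers: 18 cells from four
#' datasets (two wildtype, two Eps8-KO with AAV rescue), heights in µm.
#'
#' @return A tibble: `sample`, `id`, `vascilia`, `observer1`, `observer2`.
#' @export
height_agreement_data <- function() {
  path <- system.file("extdata", "height_agreement_study.csv",
                      package = "bundlekit3d", mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE)
}
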