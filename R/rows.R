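#' Assign bundles to hair-cell rows
#'
#' Clusters bundle base-point y coordinates into `k` groups and names them by
#' vertical position: the cluster with the largest mean y (bottom-most after
#' PCP alignment) is IHC, then OHC1, OHC2, OHC3 upward. Two backends:
#'
#' * `"kmeans"` — [stats::kmeans()] with `nstart` restarts under a fixed
#'   seed;
#' * `"gmm"` — a Gaussian mixture on y ([mclust::Mclust()], unequal-variance
#'   1-D model), useful when rows have different spreads;
#' * `"external"` — pass-through of labels supplied in `points$row`.
#'
#' By default only y is used (rows are horizontal bands); `features = "xy"`
#' clusters on (x, y) jointly.
#'
#' @param points tibble with `bundle_id` and base coordinates `x2`, `y2`
#'   (e.g. from [measure_heights()]); for `"external"`, a `row` column.
#' @param method `"kmeans"`, `"gmm"` or `"external"`.
#' @param k number of rows (default 4).
#' @param seed integer seed (both backends are deterministic given it).
#' @param features `"y"` (default) or `"xy"`.
#' @return A `row_assignment`: tibble `bundle_id`, `row` (factor IHC, OHC1,
#'   OHC2, OHC3), `cluster`, with the method and ordered cluster means in
#'   attributes.
#' @export
row_assign <- function(points, method = c("kmeans", "gmm", "external"),
                       k = 4L, seed = 1L, features = c("y", "xy")) {
  method <- match.arg(method)
  features <- match.arg(features)
  stopifnot(is.data.frame(points), "bundle_id" %in% names(points))
  if (method == "external") {
    stopifnot("row" %in% names(points))
    out <- tibble::tibble(bundle_id = points$bundle_id,
                          row = factor(points$row, levels = row_labels()),
                          cluster = as.integer(factor(points$row)))
    return(structure(out, class = c("row_assignment", class(out)),
                     method = method, means = NULL))
  }
  stopifnot(all(c("x2", "y2") %in% names(points)))
  if (nrow(points) < k) {
    stop(sprintf("%d bundles but k = %d clusters; use k <= %d",
                 nrow(points), k, nrow(points)), call. = FALSE)
  }
  y <- points$y2
  feat <- if (features == "y") matrix(y, ncol = 1) else cbind(points$x2, y)

  set.seed(as.integer(seed))
  cluster <- if (nrow(points) == k) {
    seq_len(k)  # one bundle per row; kmeans requires n > k
  } else {
    switch(method,
      kmeans = stats::kmeans(feat, centers = k, nstart = 10L)$cluster,
      gmm = {
        # Mclust resolves mclustBIC in the caller's frame; alias it locally
        mclustBIC <- mclust::mclustBIC
        mn <- if (features == "y") c("V", "E") else c("VVV", "EII")
        fit <- NULL
        for (m in mn) {  # unequal variances first, pooled as fallback
          fit <- mclust::Mclust(feat, G = k, modelNames = m, verbose = FALSE)
          if (!is.null(fit)) break
        }
        if (is.null(fit)) stop("GMM fit failed", call. = FALSE)
        fit$classification
      }
    )
  }
  means <- tapply(y, cluster, mean)
  mapping <- order_clusters(means)
  out <- tibble::tibble(
    bundle_id = points$bundle_id,
    row = factor(unname(mapping[as.character(cluster)]),
                 levels = row_labels()),
    cluster = as.integer(cluster)
  )
  structure(out, class = c("row_assignment", class(out)),
            method = method, means = sort(means, decreasing = TRUE))
}

#' Map ordered cluster means to row labels
#'
#' Clusters are named by strictly descending mean y: the bottom-most cluster
#' (largest y) is IHC, then OHC1, OHC2, OHC3. The mapping is invariant to
#' cluster index permutation.
#'
#' @param means named numeric vector of per-cluster mean y values (names =
#'   cluster indices).
#' @return Named character vector: cluster index -> row label.
#' @examples
#' order_clusters(c(`1` = 200, `2` = 140, `3` = 100, `4` = 60))
#' @export
order_clusters <- function(means) {
  if (is.null(names(means))) names(means) <- seq_along(means)
  if (anyDuplicated(means)) {
    stop("tied cluster means: degenerate clustering", call. = FALSE)
  }
  k <- length(means)
  labs <- row_labels()[seq_len(min(k, 4))]
  if (k > 4) labs <- c(labs, paste0("OHC", 3 + seq_len(k - 4)))
  ord <- order(unlist(means), decreasing = TRUE)
  setNames(labs, names(means)[ord])
}
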