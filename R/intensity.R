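#' Per-layer fluorescence sums for each bundle
#'
#' Superimposes the 3D instance masks onto the fluorescence stack and sums
#' intensities per bundle and z-plane. With `subtract_background = TRUE`,
#' each layer sum is reduced by (mean intensity of that plane's voxels
#' outside every mask) × (bundle voxel count in that plane), clamped at 0 —
#' a simple ambient-noise correction.
#'
#' @param vol a [label_volume()].
#' @param stack a [zstack()] of identical shape carrying the fluorescence
#'   channel to quantify.
#' @param subtract_background logical.
#' @return A tibble with one row per bundle per occupied plane: `bundle_id`,
#'   `z`, `n_voxels`, `raw_sum`, `background_mean`, `sum` (corrected if
#'   requested).
#' @export
per_layer_intensity <- function(vol, stack, subtract_background = FALSE) {
  stopifnot(inherits(vol, "label_volume"), inherits(stack, "zstack"))
  if (!identical(dim(vol$labels), dim(stack$frames))) {
    stop("label volume and stack shapes differ", call. = FALSE)
  }
  d <- dim(vol$labels)
  out <- vector("list", d[1])
  for (z in seq_len(d[1])) {
    lab <- vol$labels[z, , ]
    img <- stack$frames[z, , ]
    fg <- lab > 0L
    bg_mean <- if (all(fg)) 0 else mean(img[!fg])
    if (!any(fg)) next
    sums <- tapply(img[fg], lab[fg], sum)
    cnts <- tapply(img[fg], lab[fg], length)
    out[[z]] <- tibble::tibble(
      bundle_id = as.integer(names(sums)), z = z,
      n_voxels = as.integer(cnts),
      raw_sum = as.numeric(sums),
      background_mean = bg_mean
    )
  }
  tbl <- dplyr::bind_rows(out)
  if (nrow(tbl) == 0) {
    return(tibble::tibble(bundle_id = integer(), z = integer(),
                          n_voxels = integer(), raw_sum = numeric(),
                          background_mean = numeric(), sum = numeric()))
  }
  tbl |>
    dplyr::mutate(sum = if (subtract_background) {
      pmax(.data$raw_sum - .data$background_mean * .data$n_voxels, 0)
    } else .data$raw_sum) |>
    dplyr::arrange(.data$bundle_id, .data$z)
}

#' Depth-aware per-bundle intensity totals
#'
#' Aggregates per-layer sums into one total per bundle under three modes
#' that differ in how unequal segmentation depths are handled across the
#' comparison set (all bundles in `layers`):
#'
#' * mode 1 — sum over all detected layers of the bundle;
#' * mode 2 — sum over exactly `n` layers per bundle, `n` = the largest
#'   depth shared by all bundles (the minimum depth in the set); by default
#'   the `n` layers counted from the bundle's shallowest plane (tip side),
#'   or the `n` brightest layers with `top_rule = "brightest"`;
#' * mode 3 — pad shallower bundles up to `n_max` (the maximum depth in the
#'   set) by repeating the bundle's weakest-layer value, then sum.
#'
#' For non-negative intensities mode2 <= mode1 <= mode3, with equality when
#' all depths match.
#'
#' @param layers per-layer table from [per_layer_intensity()].
#' @param mode 1, 2 or 3.
#' @param top_rule which `n` layers mode 2 keeps: `"tip"` (shallowest-first,
#'   default) or `"brightest"`.
#' @return A tibble: `bundle_id`, `depth_layers`, `total`, `mean_intensity`
#'   (mode-1 total / bundle voxel count), `mode`.
#' @export
aggregate_intensity <- function(layers, mode = 1, top_rule = c("tip",
                                                               "brightest")) {
  top_rule <- match.arg(top_rule)
  if (!mode %in% 1:3) stop("mode must be 1, 2 or 3", call. = FALSE)
  if (nrow(layers) == 0) stop("empty per-layer table", call. = FALSE)
  depths <- layers |>
    dplyr::summarise(depth_layers = dplyr::n(), .by = "bundle_id")
  n_common <- min(depths$depth_layers)
  n_max <- max(depths$depth_layers)

  layers |>
    dplyr::arrange(.data$bundle_id, .data$z) |>
    dplyr::summarise(
      depth_layers = dplyr::n(),
      total = switch(as.character(mode),
        "1" = sum(.data$sum),
        "2" = if (top_rule == "tip") sum(.data$sum[seq_len(n_common)])
              else sum(sort(.data$sum, decreasing = TRUE)[seq_len(n_common)]),
        "3" = sum(.data$sum) + (n_max - dplyr::n()) * min(.data$sum)
      ),
      mean_intensity = sum(.data$sum) / sum(.data$n_voxels),
      .by = "bundle_id"
    ) |>
    dplyr::mutate(mode = as.integer(mode))
}

#' Max normalization within groups
#'
#' Divides `values` by the maximum of their group, mapping the group maximum
#' to 1 and keeping all values in `[0, 1]` for non-negative input.
#'
#' @param values numeric vector (group max must be > 0).
#' @param group optional grouping vector (default: one global group).
#' @return Numeric vector of normalized values.
#' @examples
#' normalize_max(c(2, 4, 8))
#' @export
normalize_max <- function(values, group = NULL) {
  if (is.null(group)) group <- rep(1L, length(values))
  split_vals <- split(values, group)
  if (any(vapply(split_vals, function(v) max(v) <= 0, logical(1)))) {
    stop("group maximum must be > 0 for max normalization", call. = FALSE)
  }
  unsplit(lapply(split_vals, function(v) v / max(v)), group)
}

#' Export per-cell-type intensity tables and histograms
#'
#' Writes, for each cell type (IHC, all OHC combined, OHC1, OHC2, OHC3), one
#' CSV and one histogram for the mean and the total intensity — 10 CSVs and
#' 10 plots per stack. Without a row assignment, everything goes into a
#' single "all" group with a warning.
#'
#' @param totals table from [aggregate_intensity()].
#' @param rows optional row-assignment tibble (`bundle_id`, `row`), e.g.
#'   from [row_assign()].
#' @param dir output directory.
#' @return Invisibly, a tibble listing the files written.
#' @export
export_group_tables <- function(totals, rows = NULL, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (nrow(totals) == 0) {
    warning("no bundles to export", call. = FALSE)
    return(invisible(tibble::tibble(file = character())))
  }
  if (is.null(rows)) {
    warning("no row assignment; exporting a single 'all' group",
            call. = FALSE)
    totals$row <- "all"
    groups <- list(all = totals)
  } else {
    totals <- dplyr::left_join(totals, rows[c("bundle_id", "row")],
                               by = "bundle_id")
    groups <- list(
      IHC = dplyr::filter(totals, .data$row == "IHC"),
      OHC = dplyr::filter(totals, .data$row %in% c("OHC1", "OHC2", "OHC3")),
      OHC1 = dplyr::filter(totals, .data$row == "OHC1"),
      OHC2 = dplyr::filter(totals, .data$row == "OHC2"),
      OHC3 = dplyr::filter(totals, .data$row == "OHC3")
    )
  }
  files <- character()
  for (g in names(groups)) {
    for (what in c("mean", "total")) {
      tab <- groups[[g]]
      col <- if (what == "mean") "mean_intensity" else "total"
      csv <- file.path(dir, sprintf("%s_%s_intensity.csv", g, what))
      readr::write_csv(tab[c("bundle_id", "row", col)], csv)
      png <- file.path(dir, sprintf("%s_%s_intensity.png", g, what))
      p <- ggplot2::ggplot(tab, ggplot2::aes(x = .data[[col]])) +
        ggplot2::geom_histogram(bins = 20, fill = "grey35") +
        ggplot2::labs(title = sprintf("%s %s intensity", g, what),
                      x = col, y = "bundles") +
        ggplot2::theme_minimal()
      ggplot2::ggsave(png, p, width = 4, height = 3, dpi = 96)
      files <- c(files, csv, png)
    }
  }
  invisible(tibble::tibble(file = files))
}
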