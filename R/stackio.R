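#' Z-stack container
#'
#' A `zstack` wraps a 3D voxel array of non-negative intensities indexed
#' `(z, y, x)` together with the physical voxel size. Index conventions used
#' throughout the package: z = 1 is the first acquired plane (top of the
#' stack), y increases downward as in raster images, all indices are 1-based.
#'
#' @param frames 3D numeric array indexed `(z, y, x)`.
#' @param voxel_size numeric length-3, physical size of one voxel in µm per
#'   axis, ordered `(z, y, x)`. All components must be strictly positive.
#' @return An object of class `zstack`: a list with elements `frames` and
#'   `voxel_size`.
#' @examples
#' zs <- zstack(array(0, dim = c(3, 8, 8)), voxel_size = c(0.110, 0.043, 0.043))
#' dim(zs$frames)
#' @export
zstack <- function(frames, voxel_size = c(1, 1, 1)) {
  frames <- as_frames_array(frames)
  voxel_size <- check_voxel_size(voxel_size)
  if (any(frames < 0, na.rm = TRUE)) {
    stop("zstack intensities must be non-negative", call. = FALSE)
  }
  structure(list(frames = frames, voxel_size = voxel_size), class = "zstack")
}

as_frames_array <- function(frames) {
  if (is.list(frames)) {
    shp <- unique(lapply(frames, dim))
    if (length(shp) != 1) {
      stop("all frames must share the same (y, x) shape", call. = FALSE)
    }
    frames <- aperm(
      array(unlist(frames), dim = c(shp[[1]], length(frames))),
      c(3, 1, 2)
    )
  }
  if (!is.array(frames) || length(dim(frames)) != 3) {
    stop("`frames` must be a 3D array indexed (z, y, x)", call. = FALSE)
  }
  frames
}

check_voxel_size <- function(voxel_size) {
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3 || any(!is.finite(voxel_size)) ||
      any(voxel_size <= 0)) {
    stop("`voxel_size` must be 3 strictly positive numbers (z, y, x) in um",
         call. = FALSE)
  }
  voxel_size
}

#' @export
print.zstack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf(
    "<zstack> %d planes of %d x %d (y x x); voxel %.4g x %.4g x %.4g um (z,y,x)\n",
    d[1], d[2], d[3], x$voxel_size[1], x$voxel_size[2], x$voxel_size[3]
  ))
  invisible(x)
}

#' Label volume container
#'
#' A `label_volume` is a 3D integer voxel grid with 0 reserved for background
#' and positive integers identifying bundle instances. The set of IDs present
#' is available via [label_ids()].
#'
#' @param labels 3D integer array indexed `(z, y, x)`; values must be
#'   non-negative integers.
#' @param voxel_size physical voxel size `(z, y, x)` in µm (optional; used by
#'   physical measurements downstream).
#' @return An object of class `label_volume`.
#' @examples
#' lv <- label_volume(array(0L, dim = c(2, 4, 4)))
#' label_ids(lv)
#' @export
label_volume <- function(labels, voxel_size = c(1, 1, 1)) {
  if (!is.array(labels) || length(dim(labels)) != 3) {
    stop("`labels` must be a 3D array indexed (z, y, x)", call. = FALSE)
  }
  if (any(labels < 0) || any(labels != round(labels))) {
    stop("labels must be non-negative integers (0 = background)", call. = FALSE)
  }
  storage.mode(labels) <- "integer"
  structure(
    list(labels = labels, voxel_size = check_voxel_size(voxel_size)),
    class = "label_volume"
  )
}

#' IDs present in a label volume
#' @param vol a [label_volume()].
#' @return Sorted integer vector of the positive IDs present.
#' @export
label_ids <- function(vol) {
  stopifnot(inherits(vol, "label_volume"))
  ids <- sort(unique(as.integer(vol$labels)))
  ids[ids > 0L]
}

#' @export
print.label_volume <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("<label_volume> %d x %d x %d (z,y,x); %d instance(s)\n",
              d[1], d[2], d[3], length(label_ids(x))))
  invisible(x)
}

#' Per-frame 2D instance mask series
#'
#' Holds one 2D integer label image per z-plane, with frame-local IDs that
#' carry no meaning across frames: [assign_tracks()] turns them into global
#' 3D instance IDs.
#'
#' @param masks list of 2D integer matrices (0 = background), all the same
#'   shape.
#' @param frame_index integer vector of 1-based z positions, strictly
#'   increasing; defaults to `seq_along(masks)`.
#' @return An object of class `frame_masks`.
#' @export
frame_masks <- function(masks, frame_index = seq_along(masks)) {
  if (!is.list(masks) || length(masks) == 0) {
    stop("`masks` must be a non-empty list of 2D label matrices", call. = FALSE)
  }
  shp <- unique(lapply(masks, dim))
  if (length(shp) != 1) {
    stop("all frame masks must share the same (y, x) shape", call. = FALSE)
  }
  frame_index <- as.integer(frame_index)
  if (length(frame_index) != length(masks) ||
      any(diff(frame_index) <= 0) || any(frame_index < 1)) {
    stop("`frame_index` must be strictly increasing 1-based z positions",
         call. = FALSE)
  }
  masks <- lapply(masks, function(m) { storage.mode(m) <- "integer"; m })
  structure(list(masks = masks, frame_index = frame_index),
            class = "frame_masks")
}

#' @export
print.frame_masks <- function(x, ...) {
  cat(sprintf("<frame_masks> %d frame(s), %d x %d each\n",
              length(x$masks), nrow(x$masks[[1]]), ncol(x$masks[[1]])))
  invisible(x)
}

# ---- TIFF I/O ---------------------------------------------------------------

#' Read a multi-page TIFF into a z-stack
#'
#' Pages become z-planes in page order. Voxel sizes are not reliably stored in
#' plain TIFF tags, so they are supplied explicitly.
#'
#' @param path path to a multi-page TIFF, or a directory of per-plane TIFFs
#'   (read in lexicographic order).
#' @param voxel_size physical voxel size `(z, y, x)` in µm. If `NULL`, voxel
#'   units are assumed (1, 1, 1) and a warning is emitted, so downstream
#'   physical outputs are in voxel units.
#' @return A [zstack()].
#' @export
read_stack <- function(path, voxel_size = NULL) {
  if (is.null(voxel_size)) {
    warning("no voxel_size supplied; using voxel units (1, 1, 1)",
            call. = FALSE)
    voxel_size <- c(1, 1, 1)
  }
  pages <- read_tiff_pages(path)
  zstack(pages, voxel_size = voxel_size)
}

read_tiff_pages <- function(path) {
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  paths <- path
  if (dir.exists(path)) {
    paths <- sort(list.files(path, pattern = "\\.tiff?$", full.names = TRUE,
                             ignore.case = TRUE))
    if (length(paths) == 0) stop("no TIFF files in ", path, call. = FALSE)
  }
  pages <- unlist(lapply(paths, function(p) {
    pg <- tiff::readTIFF(p, all = TRUE, as.is = TRUE)
    if (!is.list(pg)) pg <- list(pg)
    pg
  }), recursive = FALSE)
  pages <- lapply(pages, function(m) {
    if (length(dim(m)) == 3) m <- m[, , 1]  # first channel of RGB pages
    m
  })
  shp <- unique(lapply(pages, dim))
  if (length(shp) != 1) {
    stop("inconsistent page shapes in ", path, call. = FALSE)
  }
  pages
}

#' Write a z-stack to a multi-page TIFF
#'
#' @param stack a [zstack()].
#' @param path output path.
#' @param bits bits per sample (8 or 16).
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path, bits = 16L) {
  stopifnot(inherits(stack, "zstack"))
  write_tiff_planes(stack$frames, path, bits)
}

write_tiff_planes <- function(arr, path, bits) {
  bits <- as.integer(bits)
  if (!bits %in% c(8L, 16L)) stop("bits must be 8 or 16", call. = FALSE)
  maxval <- 2^bits - 1
  top <- max(arr)
  if (top > maxval) {
    stop(sprintf("values up to %s exceed %d-bit range", format(top), bits),
         call. = FALSE)
  }
  planes <- lapply(seq_len(dim(arr)[1]), function(z) arr[z, , ] / maxval)
  tiff::writeTIFF(planes, path, bits.per.sample = bits)
  invisible(path)
}

#' Read / write label volumes as multi-page TIFFs
#'
#' Labels are stored as unsigned integers of the requested bit depth; the
#' write→read round trip is the identity on labels.
#'
#' @param vol a [label_volume()].
#' @param path TIFF path.
#' @param bits bits per sample (8 or 16); writing errors if any ID exceeds
#'   the representable range.
#' @param voxel_size voxel size to attach on read.
#' @return `write_label_volume()` returns `path` invisibly;
#'   `read_label_volume()` returns a [label_volume()].
#' @export
write_label_volume <- function(vol, path, bits = 16L) {
  stopifnot(inherits(vol, "label_volume"))
  write_tiff_planes(vol$labels, path, bits)
}

#' @rdname write_label_volume
#' @export
read_label_volume <- function(path, voxel_size = c(1, 1, 1)) {
  pages <- read_tiff_pages(path)
  arr <- aperm(array(unlist(pages), dim = c(dim(pages[[1]]), length(pages))),
               c(3, 1, 2))
  label_volume(arr, voxel_size = voxel_size)
}

#' Write / read per-frame mask series as per-plane TIFFs
#'
#' One 16-bit label TIFF per frame, named `frame_0001.tif`, ... in a
#' directory.
#'
#' @param series a [frame_masks()].
#' @param dir output directory (created if missing).
#' @return `write_frame_masks()` returns `dir` invisibly; `read_frame_masks()`
#'   returns a [frame_masks()].
#' @export
write_frame_masks <- function(series, dir) {
  stopifnot(inherits(series, "frame_masks"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(series$masks)) {
    p <- file.path(dir, sprintf("frame_%04d.tif", series$frame_index[i]))
    tiff::writeTIFF(series$masks[[i]] / 65535, p, bits.per.sample = 16L)
  }
  invisible(dir)
}

#' @rdname write_frame_masks
#' @export
read_frame_masks <- function(dir) {
  paths <- sort(list.files(dir, pattern = "^frame_\\d+\\.tiff?$",
                           full.names = TRUE))
  if (length(paths) == 0) stop("no frame_NNNN.tif files in ", dir,
                               call. = FALSE)
  idx <- as.integer(sub("^frame_(\\d+)\\..*$", "\\1", basename(paths)))
  masks <- lapply(paths, function(p) {
    m <- tiff::readTIFF(p, as.is = TRUE)
    storage.mode(m) <- "integer"
    m
  })
  frame_masks(masks[order(idx)], frame_index = sort(idx))
}
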