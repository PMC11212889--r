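#' Overlap area between two 2D binary supports
#'
#' @param mask_a,mask_b logical or 0/1 matrices of identical shape.
#' @return Integer count of shared foreground pixels; symmetric, bounded by
#'   the smaller support.
#' @examples
#' a <- matrix(0L, 3, 3); a[1:2, ] <- 1L
#' b <- matrix(0L, 3, 3); b[2:3, ] <- 1L
#' overlap_area(a, b)
#' @export
overlap_area <- function(mask_a, mask_b) {
  if (!identical(dim(mask_a), dim(mask_b))) {
    stop("mask shapes differ", call. = FALSE)
  }
  sum(mask_a != 0 & mask_b != 0)
}

#' Reconstruct 3D tracks from per-frame 2D detections
#'
#' Greedy overlap tracking: every detection in the first frame seeds a track.
#' In each later frame, each detection is compared against the last stored
#' mask of every eligible track and claims the track with the largest pixel
#' overlap, provided that overlap reaches `min_overlap`; otherwise it seeds a
#' new track. When several detections claim the same track, the detection
#' with the largest overlap wins and the losers seed new tracks. A track
#' stays eligible while the gap since its last entry is at most `max_gap`
#' frames (`max_gap = 0`: previous frame only, the default, since bundles
#' are z-contiguous). Ties on equal largest overlap go to the lower track ID
#' (for a detection choosing among tracks) and to the larger detection area,
#' then lower frame-local ID (for a track choosing among detections); the
#' outcome is independent of detection processing order. Every detection
#' ends up in exactly one track.
#'
#' @param series a [frame_masks()].
#' @param min_overlap minimum pixel overlap (>= 1) counted as significant.
#' @param max_gap eligibility window in skipped frames (>= 0).
#' @return A `track_set`: list with `tracks` (each a list with `track_id` and
#'   `entries` tibble of `frame`, `local_id`, `area`) and `frame_count`.
#' @export
assign_tracks <- function(series, min_overlap = 1L, max_gap = 0L) {
  stopifnot(inherits(series, "frame_masks"), min_overlap >= 1, max_gap >= 0)
  tracks <- list()       # per track: entries data, last_mask, last_frame
  n_frames <- length(series$masks)

  for (fi in seq_len(n_frames)) {
    frame_z <- series$frame_index[fi]
    plane <- series$masks[[fi]]
    det_ids <- sort(unique(as.integer(plane)))
    det_ids <- det_ids[det_ids > 0L]
    if (length(det_ids) == 0) next
    det_masks <- lapply(det_ids, function(id) plane == id)
    det_area <- vapply(det_masks, sum, numeric(1))

    eligible <- which(vapply(tracks, function(tr) {
      frame_z - tr$last_frame <= max_gap + 1L
    }, logical(1)))

    # each detection's claimed track (largest overlap >= min_overlap)
    claim <- rep(NA_integer_, length(det_ids))
    claim_ov <- rep(0, length(det_ids))
    if (length(eligible)) {
      for (di in seq_along(det_ids)) {
        ov <- vapply(eligible, function(ti) {
          overlap_area(det_masks[[di]], tracks[[ti]]$last_mask)
        }, numeric(1))
        best <- which(ov == max(ov))[1]  # tie -> lower track id (creation order)
        if (ov[best] >= min_overlap) {
          claim[di] <- eligible[best]
          claim_ov[di] <- ov[best]
        }
      }
    }

    # contested tracks: largest overlap wins, then larger area, lower local id
    winners <- rep(FALSE, length(det_ids))
    for (ti in unique(claim[!is.na(claim)])) {
      cand <- which(!is.na(claim) & claim == ti)
      ord <- order(-claim_ov[cand], -det_area[cand], det_ids[cand])
      winners[cand[ord[1]]] <- TRUE
    }

    for (di in seq_along(det_ids)) {
      if (winners[di]) {
        ti <- claim[di]
        tracks[[ti]]$entries <- rbind(
          tracks[[ti]]$entries,
          data.frame(frame = frame_z, local_id = det_ids[di],
                     area = det_area[di])
        )
        tracks[[ti]]$last_mask <- det_masks[[di]]
        tracks[[ti]]$last_frame <- frame_z
      } else {
        tracks[[length(tracks) + 1L]] <- list(
          track_id = length(tracks) + 1L,
          entries = data.frame(frame = frame_z, local_id = det_ids[di],
                               area = det_area[di]),
          last_mask = det_masks[[di]], last_frame = frame_z
        )
      }
    }
  }

  structure(list(tracks = tracks, frame_count = n_frames,
                 frame_index = series$frame_index,
                 shape_yx = dim(series$masks[[1]])),
            class = "track_set")
}

#' @export
print.track_set <- function(x, ...) {
  cat(sprintf("<track_set> %d track(s) over %d frame(s)\n",
              length(x$tracks), x$frame_count))
  invisible(x)
}

#' Summarise a track set as a tibble
#'
#' @param x a `track_set` from [assign_tracks()].
#' @param ... unused.
#' @return A tibble with one row per track entry: `track_id`, `frame`,
#'   `local_id`, `area`.
#' @method tidy track_set
#' @export
tidy.track_set <- function(x, ...) {
  out <- purrr::map_dfr(x$tracks, function(tr) {
    tibble::as_tibble(tr$entries) |>
      dplyr::mutate(track_id = tr$track_id, .before = 1)
  })
  if (nrow(out) == 0) {
    out <- tibble::tibble(track_id = integer(), frame = integer(),
                          local_id = integer(), area = numeric())
  }
  out
}

#' Paint a track set into a 3D label volume
#'
#' Each voxel covered by a track entry receives the track's ID; IDs follow
#' track creation order. Valid frame-mask input guarantees no two tracks
#' claim a voxel.
#'
#' @param tracks a `track_set`.
#' @param series the [frame_masks()] the tracks were built from.
#' @param n_frames total z-depth of the output volume (defaults to the last
#'   frame index).
#' @param voxel_size voxel size attached to the result.
#' @return A [label_volume()].
#' @export
tracks_to_label_volume <- function(tracks, series,
                                   n_frames = max(series$frame_index),
                                   voxel_size = c(1, 1, 1)) {
  stopifnot(inherits(tracks, "track_set"), inherits(series, "frame_masks"))
  d <- dim(series$masks[[1]])
  vol <- array(0L, dim = c(n_frames, d[1], d[2]))
  for (tr in tracks$tracks) {
    for (k in seq_len(nrow(tr$entries))) {
      fz <- tr$entries$frame[k]
      fi <- match(fz, series$frame_index)
      sel <- series$masks[[fi]] == tr$entries$local_id[k]
      plane <- vol[fz, , ]
      stopifnot(all(plane[sel] == 0L))  # one track per voxel by construction
      plane[sel] <- tr$track_id
      vol[fz, , ] <- plane
    }
  }
  label_volume(vol, voxel_size = voxel_size)
}

#' Remove small reconstructed components
#'
#' Drops instance IDs whose z-extent is below `min_frames` or whose voxel
#' count is below `min_voxels`; survivors keep their IDs. Defaults suit the
#' phantom scale and are exposed on the command line.
#'
#' @param vol a [label_volume()].
#' @param min_frames minimum z-extent in planes.
#' @param min_voxels minimum voxel count.
#' @return A filtered [label_volume()].
#' @export
filter_components <- function(vol, min_frames = 2L, min_voxels = 20L) {
  stopifnot(inherits(vol, "label_volume"), min_frames >= 0, min_voxels >= 0)
  labs <- vol$labels
  ids <- label_ids(vol)
  if (length(ids) == 0) return(vol)
  keep <- vapply(ids, function(id) {
    w <- which(labs == id, arr.ind = TRUE)
    (max(w[, 1]) - min(w[, 1]) + 1L) >= min_frames && nrow(w) >= min_voxels
  }, logical(1))
  drop <- ids[!keep]
  if (length(drop)) labs[labs %in% drop] <- 0L
  label_volume(labs, voxel_size = vol$voxel_size)
}
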