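# Shared fixtures and independent oracles used across test files.

# A compact phantom that keeps every wedge well inside an 8 x 120 x 140
# canvas; 2 bundles per row, 8 bundles total.
small_config <- function(..., depth_layers = 4L, noise_sd = 4, seed = 1L) {
  phantom_config(
    shape = c(8L, 120L, 140L),
    rows_y = c(100, 76, 52, 28),
    bundles_per_row = 2L,
    wing_length_px = 20,
    z_start = 2L,
    depth_layers = depth_layers,
    noise_sd = noise_sd,
    seed = seed,
    ...
  )
}

# Independent re-statement of the greedy track-assignment rule, written
# matrix-first rather than incrementally: per frame, compute the full
# detection x track overlap matrix by explicit pixel loops, give each
# detection its argmax track, resolve each track to its best claimant, and
# spill everyone else into new tracks. Returns, per frame, a map
# local_id -> global track id.
oracle_assign <- function(series, min_overlap = 1, max_gap = 0) {
  last_mask <- list()   # per global track id
  last_frame <- integer()
  out <- list()
  next_id <- 0L
  for (fi in seq_along(series$masks)) {
    fz <- series$frame_index[fi]
    plane <- series$masks[[fi]]
    ids <- sort(setdiff(unique(as.integer(plane)), 0L))
    assign <- setNames(integer(length(ids)), ids)
    if (length(ids)) {
      elig <- which(fz - last_frame <= max_gap + 1)
      ov <- matrix(0, length(ids), length(elig))
      if (length(elig)) {
        for (i in seq_along(ids)) {
          mi <- plane == ids[i]
          for (j in seq_along(elig)) {
            ov[i, j] <- sum(mi & last_mask[[elig[j]]])
          }
        }
      }
      pref <- rep(NA_integer_, length(ids))
      for (i in seq_along(ids)) {
        if (length(elig) && max(ov[i, ]) >= min_overlap) {
          pref[i] <- elig[which.max(ov[i, ])]
        }
      }
      area <- vapply(ids, function(id) sum(plane == id), numeric(1))
      for (i in seq_along(ids)) {
        ti <- pref[i]
        keep <- !is.na(ti)
        if (keep) {
          rivals <- which(!is.na(pref) & pref == ti)
          best <- rivals[order(-ov[cbind(rivals, match(ti, elig))],
                               -area[rivals], ids[rivals])][1]
          keep <- best == i
        }
        if (keep) {
          assign[i] <- ti
        } else {
          next_id <- next_id + 1L
          assign[i] <- next_id
          last_mask[[next_id]] <- matrix(FALSE, nrow(plane), ncol(plane))
          last_frame[next_id] <- -1L
        }
      }
      for (i in seq_along(ids)) {
        last_mask[[assign[i]]] <- plane == ids[i]
        last_frame[assign[i]] <- fz
      }
      # renumber so new tracks appear in the same creation order as the
      # package: winners keep ids, losers/new get sequential ids already
    }
    out[[fi]] <- assign
  }
  out
}

# random tiny mask series for the oracle equivalence property
random_series <- function(n_frames = 3, max_objects = 4, shape = c(12, 12)) {
  masks <- lapply(seq_len(n_frames), function(f) {
    m <- matrix(0L, shape[1], shape[2])
    n_obj <- sample(0:max_objects, 1)
    for (k in seq_len(n_obj)) {
      cy <- sample(2:(shape[1] - 1), 1); cx <- sample(2:(shape[2] - 1), 1)
      h <- sample(1:3, 1); w <- sample(1:3, 1)
      ys <- max(1, cy - h):min(shape[1], cy + h)
      xs <- max(1, cx - w):min(shape[2], cx + w)
      m[ys, xs] <- k  # later objects overwrite earlier: keeps masks disjoint
    }
    m
  })
  frame_masks(masks)
}

# brute-force instance matcher: enumerate all one-to-one GT/pred assignments,
# take the one maximizing total matched IoU, then threshold.
brute_force_match <- function(gt, pred, threshold) {
  gl <- label_ids(gt); pl <- label_ids(pred)
  iou_of <- function(g, p) iou3d(gt$labels == g, pred$labels == p)
  n_g <- length(gl)
  best <- list(score = -1, tp = 0)
  assigns <- function(i, used, pairs) {
    if (i > n_g) {
      sc <- if (length(pairs)) sum(vapply(pairs, `[[`, numeric(1), "iou"))
      else 0
      if (sc > best$score) {
        ious <- vapply(pairs, `[[`, numeric(1), "iou")
        best <<- list(score = sc, tp = sum(ious >= threshold))
      }
      return()
    }
    assigns(i + 1, used, pairs)  # leave unmatched
    for (p in setdiff(pl, used)) {
      io <- iou_of(gl[i], p)
      if (io > 0) {
        assigns(i + 1, c(used, p),
                c(pairs, list(list(iou = io))))
      }
    }
  }
  assigns(1, integer(), list())
  tp <- best$tp
  list(tp = tp, fp = length(pl) - tp, fn = n_g - tp)
}

# per-pixel brute-force uniform LBP (P = 8, R = 1, >= comparison)
brute_force_lbp <- function(crop) {
  H <- nrow(crop); W <- ncol(crop)
  offs <- list(c(0, 1), c(-1, 1), c(-1, 0), c(-1, -1),
               c(0, -1), c(1, -1), c(1, 0), c(1, 1))
  counts <- numeric(10)
  for (y in 2:(H - 1)) {
    for (x in 2:(W - 1)) {
      bits <- vapply(offs, function(o) {
        crop[y + o[1], x + o[2]] >= crop[y, x]
      }, logical(1))
      trans <- sum(bits != c(bits[-1], bits[1]))
      bin <- if (trans <= 2) sum(bits) else 9
      counts[bin + 1] <- counts[bin + 1] + 1
    }
  }
  counts / sum(counts)
}
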