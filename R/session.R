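SESSION_FORMAT_VERSION <- "1.0"

#' Save / load a portable analysis session
#'
#' A session bundles the label volume with every result table produced so
#' far into a single self-describing tar archive: a JSON manifest (format
#' version, voxel sizes, provenance, seeds), the label volume as a 16-bit
#' multi-page TIFF, and each table as an RFC-4180 CSV. The load(save(x))
#' round trip reproduces every table and the label volume exactly, so
#' sessions can be archived, shared, and re-opened for review.
#'
#' @param state a named list with at least `labels` (a [label_volume()]);
#'   any element that is a data frame is archived as a CSV table; optional
#'   elements `seed` and `provenance` are recorded in the manifest.
#' @param path output archive path (conventionally `.tar`).
#' @return `save_session()` returns `path` invisibly; `load_session()`
#'   returns the state list with `labels` and all tables restored.
#' @export
save_session <- function(state, path) {
  if (!is.list(state) || !inherits(state$labels, "label_volume")) {
    stop("`state` must be a list containing a `labels` label_volume",
         call. = FALSE)
  }
  stage <- tempfile("session")
  dir.create(stage)
  on.exit(unlink(stage, recursive = TRUE), add = TRUE)

  tables <- Filter(is.data.frame, state)
  manifest <- list(
    format_version = SESSION_FORMAT_VERSION,
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
    voxel_size = state$labels$voxel_size,
    seed = state$seed,
    provenance = state$provenance,
    tables = names(tables)
  )
  jsonlite::write_json(manifest, file.path(stage, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  write_label_volume(state$labels, file.path(stage, "labels.tif"))
  for (nm in names(tables)) {
    readr::write_csv(tables[[nm]], file.path(stage, paste0(nm, ".csv")))
  }
  path <- normalizePath(path, mustWork = FALSE)
  old <- setwd(stage)
  on.exit(setwd(old), add = TRUE, after = FALSE)
  # internal tar implementation: no external tool needed
  utils::tar(path, files = list.files(stage), tar = "internal")
  invisible(path)
}

#' @rdname save_session
#' @export
load_session <- function(path) {
  if (!file.exists(path)) stop("session archive not found: ", path,
                               call. = FALSE)
  stage <- tempfile("session")
  dir.create(stage)
  on.exit(unlink(stage, recursive = TRUE), add = TRUE)
  utils::untar(path, exdir = stage, tar = "internal")

  mpath <- file.path(stage, "manifest.json")
  if (!file.exists(mpath)) {
    stop("archive is missing manifest.json", call. = FALSE)
  }
  manifest <- jsonlite::read_json(mpath, simplifyVector = TRUE)
  ver <- manifest$format_version
  if (!identical(ver, SESSION_FORMAT_VERSION)) {
    stop(sprintf("session format version %s is not supported (reader is %s)",
                 ver, SESSION_FORMAT_VERSION), call. = FALSE)
  }
  lpath <- file.path(stage, "labels.tif")
  if (!file.exists(lpath)) {
    stop("archive is missing members: labels.tif", call. = FALSE)
  }
  state <- list(
    labels = read_label_volume(lpath, voxel_size = manifest$voxel_size),
    seed = manifest$seed,
    provenance = manifest$provenance
  )
  for (nm in manifest$tables) {
    state[[nm]] <- readr::read_csv(file.path(stage, paste0(nm, ".csv")),
                                   show_col_types = FALSE)
  }
  state
}
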