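#' Read and write track sets as CSV
#'
#' The on-disk format is a flat UTF-8 CSV with header
#' `time_min,track_id,kind,x_um,y_um,z_um,radius_um` (an empty `z_um` means
#' 2D data), plus an optional JSON sidecar `<path>.meta.json` carrying
#' `frame_interval`, `oocyte_radius`, `seed` and a content hash. The round
#' trip is lossless up to 9 significant digits of float formatting.
#'
#' @param path CSV file path.
#' @return `read_tracks()` returns a [track_set()]; `write_tracks()` returns
#'   `path` invisibly.
#' @export
read_tracks <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("NA", ""))
  needed <- c("time_min", "track_id", "kind", "x_um", "y_um", "radius_um")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols) > 0) {
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (!"z_um" %in% names(df)) df$z_um <- NA_real_
  df$z_um <- as.numeric(df$z_um)
  # descriptive per-track time checks with line numbers
  for (id in unique(df$track_id)) {
    rows <- which(df$track_id == id)
    tt <- df$time_min[rows]
    dup <- anyDuplicated(tt)
    if (dup > 0) {
      stop(sprintf("duplicate (time, track_id) for track '%s' at line %d",
                   id, rows[dup] + 1), call. = FALSE)
    }
    dec <- which(diff(tt) < 0)
    if (length(dec) > 0) {
      stop(sprintf("non-monotone time for track '%s' at line %d",
                   id, rows[dec[1] + 1] + 1), call. = FALSE)
    }
  }
  meta_path <- paste0(path, ".meta.json")
  meta <- if (file.exists(meta_path)) jsonlite::fromJSON(meta_path) else list()
  fi <- meta$frame_interval %||% {
    tt <- sort(unique(df$time_min))
    if (length(tt) > 1) min(diff(tt)) else 1
  }
  track_set(df, frame_interval = fi,
            oocyte_radius = meta$oocyte_radius %||% NA_real_,
            seed = meta$seed %||% NA_integer_,
            provenance = meta$provenance %||% sprintf("read from %s", path))
}

#' @rdname read_tracks
#' @param tracks A `track_set`.
#' @param sidecar Write the JSON metadata sidecar (default `TRUE`).
#' @param downsample_vesicles Keep every k-th vesicle track only (1 = all);
#'   object tracks are always kept.
#' @export
write_tracks <- function(tracks, path, sidecar = TRUE,
                         downsample_vesicles = 1L) {
  stopifnot(inherits(tracks, "track_set"))
  rec <- tracks$records
  if (downsample_vesicles > 1) {
    ves_ids <- unique(rec$track_id[rec$kind == "vesicle"])
    keep <- ves_ids[seq(1, length(ves_ids), by = downsample_vesicles)]
    rec <- rec[rec$kind != "vesicle" | rec$track_id %in% keep, ]
  }
  out <- rec
  for (col in c("time_min", "x_um", "y_um", "z_um", "radius_um")) {
    vals <- trimws(formatC(out[[col]], digits = 9, format = "g"))
    vals[vals == "NA"] <- ""
    out[[col]] <- vals
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  if (sidecar) {
    meta <- list(frame_interval = tracks$frame_interval,
                 oocyte_radius = tracks$oocyte_radius,
                 seed = tracks$seed,
                 provenance = tracks$provenance,
                 content_hash = file_hash(path))
    jsonlite::write_json(meta, paste0(path, ".meta.json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         na = "null")
  }
  invisible(path)
}

file_hash <- function(path) {
  unname(tools::md5sum(path))
}

#' Write a run manifest next to command outputs
#'
#' Every CLI invocation records its command line, resolved configuration,
#' seeds, input hashes, package version and a timestamp, so a run can be
#' reproduced bit-identically.
#'
#' @param out_dir Output directory.
#' @param command Subcommand name.
#' @param config Resolved configuration (list), if any.
#' @param seeds Named seeds used.
#' @param inputs Character vector of input file paths (hashed).
#' @return The manifest path, invisibly.
#' @export
write_manifest <- function(out_dir, command, config = NULL, seeds = NULL,
                           inputs = character(0)) {
  manifest <- list(
    command = command,
    config = config,
    seeds = seeds,
    input_hashes = if (length(inputs)) {
      setNames(vapply(inputs, file_hash, character(1)), inputs)
    } else NULL,
    package_version = as.character(utils::packageVersion("oocenter")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  path <- file.path(out_dir, paste0(command, ".manifest.json"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
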