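#' Construct a track set
#'
#' The `track_set` is the common currency between the simulator, the
#' synthetic generators and every analysis: a table of timestamped particle
#' positions plus the metadata needed to interpret them (frame interval,
#' cell radius, seed, provenance).
#'
#' @param records Data frame with columns `time_min`, `track_id`, `kind`,
#'   `x_um`, `y_um`, `z_um` (may be `NA` for 2D data) and `radius_um`.
#' @param frame_interval Time between consecutive frames (min).
#' @param oocyte_radius Cell radius (um), or `NA` when not applicable.
#' @param seed Seed that produced the data, or `NA`.
#' @param provenance Free-text description of the origin of the tracks.
#' @return A `track_set` object.
#' @export
track_set <- function(records, frame_interval, oocyte_radius = NA_real_,
                      seed = NA_integer_, provenance = "") {
  records <- as_tibble(records)
  needed <- c("time_min", "track_id", "kind", "x_um", "y_um", "z_um", "radius_um")
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols) > 0) {
    stop("records is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  records <- records[needed]
  ord <- order(records$track_id, records$time_min)
  records <- records[ord, ]
  for (id in unique(records$track_id)) {
    tt <- records$time_min[records$track_id == id]
    if (any(diff(tt) <= 0)) {
      stop(sprintf("track '%s' has non-increasing or duplicate times", id),
           call. = FALSE)
    }
  }
  structure(list(records = records,
                 frame_interval = frame_interval,
                 oocyte_radius = oocyte_radius,
                 seed = seed,
                 provenance = provenance),
            class = "track_set")
}

#' @export
print.track_set <- function(x, ...) {
  nt <- length(unique(x$records$track_id))
  cat(sprintf("<track_set> %d tracks, %d records, frame interval %g min\n",
              nt, nrow(x$records), x$frame_interval))
  if (is.finite(x$oocyte_radius)) {
    cat(sprintf("  oocyte radius %g um\n", x$oocyte_radius))
  }
  if (nzchar(x$provenance)) cat("  ", x$provenance, "\n", sep = "")
  invisible(x)
}

#' @export
format.track_set <- function(x, ...) {
  sprintf("track_set(%d records)", nrow(x$records))
}

#' Split a track set into per-track position matrices
#'
#' @param tracks A `track_set`.
#' @param kind Optional filter on the `kind` column.
#' @return Named list of data frames (one per `track_id`), each ordered by
#'   time with columns `time_min`, `x_um`, `y_um`, `z_um`, `radius_um`.
#' @export
split_tracks <- function(tracks, kind = NULL) {
  stopifnot(inherits(tracks, "track_set"))
  rec <- tracks$records
  if (!is.null(kind)) rec <- rec[rec$kind %in% kind, ]
  split(rec[c("time_min", "x_um", "y_um", "z_um", "radius_um")],
        rec$track_id, drop = TRUE)
}

#' Keep only tracks with more than a minimum number of points
#'
#' Short tracks are usually spurious detections; the default keeps tracks
#' with strictly more than 30 points.
#'
#' @param tracks A `track_set`.
#' @param min_points Tracks with `length > min_points` are kept (default 30).
#' @return A filtered `track_set`.
#' @export
#' @examples
#' ts <- gen_brownian(walk_spec(D = 0.1, duration = 2, frame_interval = 0.1,
#'                              n_tracks = 3, seed = 1))
#' filter_tracks(ts, min_points = 10)
filter_tracks <- function(tracks, min_points = 30) {
  stopifnot(inherits(tracks, "track_set"))
  counts <- table(tracks$records$track_id)
  keep <- names(counts)[counts > min_points]
  rec <- tracks$records[tracks$records$track_id %in% keep, ]
  out <- tracks
  out$records <- rec
  out
}

positions_matrix <- function(track_df, dims = 3) {
  m <- as.matrix(track_df[, c("x_um", "y_um", "z_um")[seq_len(dims)]])
  storage.mode(m) <- "double"
  m
}
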