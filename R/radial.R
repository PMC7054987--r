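#' Off-centering of a position
#'
#' Distance of a centroid to the cell center normalised by the cell radius:
#' 1 at the cortex, 0 at the center. An object is "centered" when its
#' off-centering drops below 0.2 (for the 35-um oocyte, within 7 um of the
#' center).
#'
#' @param position Numeric vector (length 2 or 3) or an n x 2/3 matrix of
#'   positions relative to the cell center (um).
#' @param oocyte_radius Cell radius (um), > 0.
#' @return Dimensionless off-centering value(s).
#' @export
off_centering <- function(position, oocyte_radius) {
  if (!(oocyte_radius > 0)) stop("oocyte_radius must be positive", call. = FALSE)
  if (is.matrix(position)) sqrt(rowSums(position^2)) / oocyte_radius
  else sqrt(sum(position^2)) / oocyte_radius
}

#' @rdname off_centering
#' @param threshold Centering threshold on the off-centering (default 0.2).
#' @export
is_centered <- function(position, oocyte_radius, threshold = 0.2) {
  off_centering(position, oocyte_radius) < threshold
}

track_distances <- function(track) {
  sqrt(track$x_um^2 + track$y_um^2 +
         ifelse(is.na(track$z_um), 0, track$z_um)^2)
}

#' First time a track is centered
#'
#' @param track Single-track data frame (`time_min`, `x_um`, `y_um`, `z_um`).
#' @param oocyte_radius Cell radius (um).
#' @param threshold Off-centering threshold (default 0.2).
#' @return First `time_min` at which off-centering < threshold, or `NA` if
#'   the track never centers.
#' @export
time_to_center <- function(track, oocyte_radius, threshold = 0.2) {
  d <- track_distances(track)
  hit <- which(d / oocyte_radius < threshold)
  if (length(hit) == 0) NA_real_ else track$time_min[hit[1]]
}

#' Radial components of track displacements
#'
#' For each displacement over `lag` frames, returns `d * cos(theta)` where
#' `theta` is the angle between the displacement and the inward radial
#' direction at the displacement's start point. Positive values point toward
#' the center, negative toward the cortex. Displacements starting at the
#' exact center are skipped with a warning (radial direction undefined).
#'
#' @param track Single-track data frame.
#' @param lag Displacement lag in frames (>= 1).
#' @param center Cell center; default the origin.
#' @param dimensionality 2 (x-y projection, default) or 3.
#' @return Numeric vector of radial components (um), one per displacement.
#' @export
radial_components <- function(track, lag = 1, center = c(0, 0, 0),
                              dimensionality = 2) {
  stopifnot(lag >= 1)
  pos <- positions_matrix(track, dims = dimensionality)
  pos <- sweep(pos, 2, center[seq_len(dimensionality)])
  n <- nrow(pos)
  if (n <= lag) return(numeric(0))
  start <- pos[1:(n - lag), , drop = FALSE]
  disp <- pos[(lag + 1):n, , drop = FALSE] - start
  rr <- sqrt(rowSums(start^2))
  at_center <- rr == 0
  if (any(at_center)) {
    warning(sum(at_center), " displacement(s) start at the exact center; skipped")
  }
  # inward unit radial direction is -start/||start||
  comp <- -rowSums(disp * start) / rr
  comp[!at_center]
}

#' Mean instantaneous radial velocity with a z-test against zero
#'
#' Pools the net radial displacement over `lag`-frame windows across tracks,
#' divides by the window duration, and tests the mean against a zero-centered
#' normal null with the sample's standard error (two-sided z-test). This is
#' the short-time-scale bias statistic used on bead aggregates and droplets
#' at 5 frames (2.5 s at 500-ms sampling). Windows are non-overlapping
#' (stride = `lag`), so for drift-free Brownian motion the pooled samples
#' are independent and the z-test is calibrated; overlapping windows would
#' overstate the effective sample size.
#'
#' @param tracks A `track_set` or a list of single-track data frames sharing
#'   one frame interval.
#' @param lag Window length in frames (default 5).
#' @param center Cell center (default origin).
#' @param dimensionality 2 or 3.
#' @return List: `mean_velocity` (um/min, positive toward the center),
#'   `sd_velocity`, `n`, `z_p` (two-sided p), `lag`, `components` (the pooled
#'   `d cos(theta)` values, um).
#' @export
mean_instantaneous_radial_velocity <- function(tracks, lag = 5,
                                               center = c(0, 0, 0),
                                               dimensionality = 2) {
  trl <- if (inherits(tracks, "track_set")) split_tracks(tracks) else tracks
  dt <- if (inherits(tracks, "track_set")) tracks$frame_interval
        else diff(trl[[1]]$time_min[1:2])
  comp <- unlist(lapply(trl, function(tr) {
    all_comp <- suppressWarnings(
      radial_components(tr, lag = lag, center = center,
                        dimensionality = dimensionality))
    all_comp[seq(1, length(all_comp), by = lag)]
  }))
  if (length(comp) < 10) {
    stop("fewer than 10 displacement windows; refusing to test", call. = FALSE)
  }
  window <- lag * dt
  vels <- comp / window
  m <- mean(vels)
  se <- sd(vels) / sqrt(length(vels))
  z <- m / se
  list(mean_velocity = m, sd_velocity = sd(vels), n = length(vels),
       z_p = 2 * pnorm(-abs(z)), lag = lag, components = comp)
}

#' Radial velocity profile across distance bins
#'
#' Assigns each single-frame (or `lag`-frame) displacement to the distance
#' bin of its start point and averages the inward radial velocity per bin.
#' Empty bins are absent from the output rather than reported as zero.
#'
#' @param tracks A `track_set` or list of single-track data frames.
#' @param distance_bins Bin edges (um) covering `[0, oocyte_radius]`;
#'   default 2-um bins. Edges are half-open `[lo, hi)`.
#' @param lag Displacement lag in frames.
#' @param dimensionality 2 or 3.
#' @return Tibble: `distance_um` (bin center), `v_radial_mean`,
#'   `v_radial_sd` (um/min, positive inward), `n`.
#' @export
radial_velocity_profile <- function(tracks, distance_bins = NULL, lag = 1,
                                    dimensionality = 2) {
  trl <- if (inherits(tracks, "track_set")) split_tracks(tracks) else tracks
  dt <- if (inherits(tracks, "track_set")) tracks$frame_interval
        else diff(trl[[1]]$time_min[1:2])
  R <- if (inherits(tracks, "track_set") && is.finite(tracks$oocyte_radius)) {
    tracks$oocyte_radius
  } else {
    max(unlist(lapply(trl, track_distances)))
  }
  if (is.null(distance_bins)) distance_bins <- seq(0, ceiling(R / 2) * 2, by = 2)
  starts <- vels <- numeric(0)
  for (tr in trl) {
    pos <- positions_matrix(tr, dims = dimensionality)
    n <- nrow(pos)
    if (n <= lag) next
    start <- pos[1:(n - lag), , drop = FALSE]
    disp <- pos[(lag + 1):n, , drop = FALSE] - start
    rr <- sqrt(rowSums(start^2))
    ok <- rr > 0
    starts <- c(starts, rr[ok])
    vels <- c(vels, (-rowSums(disp * start) / rr)[ok] / (lag * dt))
  }
  bin <- cut(starts, distance_bins, right = FALSE, include.lowest = FALSE)
  keep <- !is.na(bin)
  agg <- tapply(vels[keep], bin[keep], function(v) c(mean(v), sd(v), length(v)))
  agg <- agg[!vapply(agg, is.null, logical(1))]
  ctr <- (distance_bins[-length(distance_bins)] + distance_bins[-1]) / 2
  names(ctr) <- levels(bin)
  tibble(distance_um = unname(ctr[names(agg)]),
         v_radial_mean = vapply(agg, `[`, numeric(1), 1),
         v_radial_sd = vapply(agg, `[`, numeric(1), 2),
         n = vapply(agg, `[`, numeric(1), 3))
}

#' Squared-velocity profile of vesicles versus distance from the center
#'
#' For every displacement within the time window, the squared velocity
#' `|dx|^2 / interval^2` is assigned to the distance bin of the start point;
#' per-bin means are returned. This is the observable against which the
#' motility parameters are calibrated (simulation window 30-60 min).
#'
#' @param tracks A `track_set`; vesicle tracks are used when a `kind` column
#'   distinguishes them.
#' @param window Length-2 time window (min) within which displacements are
#'   taken.
#' @param sampling_interval Sampling interval (min); defaults to the frame
#'   interval of `tracks`. Must be a multiple of it.
#' @param distance_bins Bin edges (um); default 2-um bins up to the cell
#'   radius.
#' @param dimensionality 3 for the simulation output (default), 2 for
#'   projected data.
#' @return Tibble: `distance_um`, `v2_mean` (um^2/min^2), `n`.
#' @export
squared_velocity_profile <- function(tracks, window = c(30, 60),
                                     sampling_interval = NULL,
                                     distance_bins = NULL,
                                     dimensionality = 3) {
  stopifnot(inherits(tracks, "track_set"))
  rec <- tracks$records
  if ("vesicle" %in% rec$kind) rec <- rec[rec$kind == "vesicle", ]
  tspan <- range(rec$time_min)
  if (window[1] < tspan[1] - 1e-9 || window[2] > tspan[2] + 1e-9) {
    stop(sprintf("window [%g, %g] outside track span [%g, %g]",
                 window[1], window[2], tspan[1], tspan[2]), call. = FALSE)
  }
  dt <- tracks$frame_interval
  if (is.null(sampling_interval)) sampling_interval <- dt
  stride <- round(sampling_interval / dt)
  if (abs(stride * dt - sampling_interval) > 1e-9) {
    stop("sampling_interval must be a multiple of the frame interval",
         call. = FALSE)
  }
  R <- if (is.finite(tracks$oocyte_radius)) tracks$oocyte_radius else
    max(track_distances(rec))
  if (is.null(distance_bins)) distance_bins <- seq(0, ceiling(R / 2) * 2, by = 2)

  sub <- track_set(rec, tracks$frame_interval, tracks$oocyte_radius)
  trl <- split_tracks(sub)
  starts <- v2 <- numeric(0)
  for (tr in trl) {
    sel <- tr$time_min >= window[1] - 1e-9 & tr$time_min <= window[2] + 1e-9
    tr <- tr[sel, ]
    n <- nrow(tr)
    if (n <= stride) next
    pos <- positions_matrix(tr, dims = dimensionality)
    idx <- seq(1, n, by = stride)
    if (length(idx) < 2) next
    p <- pos[idx, , drop = FALSE]
    d <- diff(p)
    starts <- c(starts, sqrt(rowSums(p[-nrow(p), , drop = FALSE]^2)))
    v2 <- c(v2, rowSums(d^2) / sampling_interval^2)
  }
  bin <- cut(starts, distance_bins, right = FALSE)
  keep <- !is.na(bin)
  agg <- tapply(v2[keep], bin[keep], function(v) c(mean(v), length(v)))
  agg <- agg[!vapply(agg, is.null, logical(1))]
  ctr <- (distance_bins[-length(distance_bins)] + distance_bins[-1]) / 2
  names(ctr) <- levels(bin)
  tibble(distance_um = unname(ctr[names(agg)]),
         v2_mean = vapply(agg, `[`, numeric(1), 1),
         n = vapply(agg, `[`, numeric(1), 2))
}

#' Vesicle density map on the x-y projection
#'
#' Counts vesicle positions over time in square bins of the x-y plane,
#' optionally rotating every frame about the z-axis so the object centroid
#' lies on the +x axis (the alignment used when pooling simulations whose
#' object settles in different directions).
#'
#' @param tracks A `track_set` containing vesicle records (and an object
#'   track if `align_object_axis` is used).
#' @param bin Bin side (um), default 2.3.
#' @param align_object_axis Rotate each frame so the object lies along +x.
#' @param burn_in Discard frames before this time (min).
#' @return Tibble: `x_um`, `y_um` (bin centers), `count`.
#' @export
density_map <- function(tracks, bin = 2.3, align_object_axis = FALSE,
                        burn_in = 0) {
  stopifnot(inherits(tracks, "track_set"))
  rec <- tracks$records[tracks$records$time_min >= burn_in, ]
  ves <- rec[rec$kind == "vesicle", ]
  if (align_object_axis) {
    obj <- rec[rec$kind == "object", c("time_min", "x_um", "y_um")]
    if (nrow(obj) == 0) stop("no object track to align on", call. = FALSE)
    ang <- setNames(atan2(obj$y_um, obj$x_um), format(obj$time_min))
    th <- ang[format(ves$time_min)]
    x <- cos(-th) * ves$x_um - sin(-th) * ves$y_um
    y <- sin(-th) * ves$x_um + cos(-th) * ves$y_um
    ves$x_um <- x
    ves$y_um <- y
  }
  R <- if (is.finite(tracks$oocyte_radius)) tracks$oocyte_radius else
    max(abs(c(ves$x_um, ves$y_um)))
  edges <- seq(-ceiling(R / bin) * bin, ceiling(R / bin) * bin, by = bin)
  ix <- cut(ves$x_um, edges, right = FALSE)
  iy <- cut(ves$y_um, edges, right = FALSE)
  tab <- table(ix, iy)
  ctr <- (edges[-length(edges)] + edges[-1]) / 2
  grid <- expand.grid(x_um = ctr, y_um = ctr)
  grid$count <- as.vector(tab)
  as_tibble(grid)
}
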