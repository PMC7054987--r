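#' Time-averaged mean squared displacement of a track
#'
#' Overlapping all-pairs estimator: for lag `k` frames the MSD is the mean of
#' `|x(t + k dt) - x(t)|^2` over every start frame `t`. The ensemble variant
#' [ensemble_msd()] averages per-track curves without weighting.
#'
#' @param track A single-track data frame (as returned by [split_tracks()])
#'   with columns `time_min`, `x_um`, `y_um` and optionally `z_um`.
#' @param dimensionality 2 (x-y projection, default) or 3.
#' @param max_lag Largest lag in frames; default is all available lags.
#' @return An `msd_result`: tibble of `lag_min`, `msd_um2`, `n_pairs` with
#'   attributes `dimensionality` and `frame_interval`.
#' @export
#' @examples
#' tr <- data.frame(time_min = 0:9, x_um = 0:9, y_um = 0, z_um = 0)
#' msd(tr)  # ballistic: msd = lag^2
msd <- function(track, dimensionality = 2, max_lag = NULL) {
  stopifnot(dimensionality %in% c(2, 3))
  tt <- track$time_min
  if (length(tt) < 2) stop("track needs at least 2 points", call. = FALSE)
  dts <- diff(tt)
  dt <- dts[1]
  if (any(abs(dts - dt) > 1e-6 * dt)) {
    stop("non-uniform sampling: msd requires a constant frame interval",
         call. = FALSE)
  }
  pos <- positions_matrix(track, dims = dimensionality)
  n <- nrow(pos)
  lags <- seq_len(if (is.null(max_lag)) n - 1 else min(max_lag, n - 1))
  vals <- vapply(lags, function(k) {
    d <- pos[(k + 1):n, , drop = FALSE] - pos[1:(n - k), , drop = FALSE]
    mean(rowSums(d^2))
  }, numeric(1))
  out <- tibble(lag_min = lags * dt, msd_um2 = vals, n_pairs = n - lags)
  attr(out, "dimensionality") <- dimensionality
  attr(out, "frame_interval") <- dt
  class(out) <- c("msd_result", class(out))
  out
}

#' Ensemble-averaged MSD across tracks
#'
#' Computes the time-averaged MSD of every track and averages the curves
#' (unweighted) over tracks. Lags are limited to a quarter of the longest
#' track by default, where the time average is well sampled.
#'
#' @param tracks A `track_set`, or a list of single-track data frames.
#' @param dimensionality 2 or 3.
#' @param kind Optional `kind` filter when `tracks` is a `track_set`.
#' @param max_lag_frac Largest lag as a fraction of the track length.
#' @return An `msd_result` averaged over tracks (`n_pairs` sums pairs).
#' @export
ensemble_msd <- function(tracks, dimensionality = 2, kind = NULL,
                         max_lag_frac = 0.25) {
  trl <- if (inherits(tracks, "track_set")) split_tracks(tracks, kind) else tracks
  if (length(trl) == 0) stop("no tracks to average", call. = FALSE)
  curves <- lapply(trl, function(tr) {
    msd(tr, dimensionality,
        max_lag = max(1L, floor((nrow(tr) - 1) * max_lag_frac)))
  })
  all_lags <- sort(unique(unlist(lapply(curves, function(cv) cv$lag_min))))
  acc_v <- acc_n <- acc_p <- setNames(numeric(length(all_lags)),
                                      format(all_lags, digits = 12))
  for (cv in curves) {
    keys <- format(cv$lag_min, digits = 12)
    acc_v[keys] <- acc_v[keys] + cv$msd_um2
    acc_n[keys] <- acc_n[keys] + 1
    acc_p[keys] <- acc_p[keys] + cv$n_pairs
  }
  out <- tibble(lag_min = all_lags, msd_um2 = unname(acc_v / acc_n),
                n_pairs = unname(acc_p))
  attr(out, "dimensionality") <- dimensionality
  attr(out, "frame_interval") <- attr(curves[[1]], "frame_interval")
  class(out) <- c("msd_result", class(out))
  out
}

#' Diffusion coefficient from the initial slope of an MSD curve
#'
#' Least-squares line (with intercept) through the first `n_points` lags;
#' the slope equals `4 D` in 2D and `6 D` in 3D.
#'
#' @param msd An `msd_result` (or any data frame with `lag_min`, `msd_um2`).
#' @param n_points Number of initial points to fit (default 20).
#' @param dimensionality 2 or 3; defaults to the attribute carried by `msd`.
#' @return Diffusion coefficient D (um^2/min).
#' @export
#' @examples
#' curve <- data.frame(lag_min = 1:30, msd_um2 = 0.288 * (1:30))
#' fit_diffusion(curve)  # 0.072
fit_diffusion <- function(msd, n_points = 20, dimensionality = NULL) {
  if (is.null(dimensionality)) {
    dimensionality <- attr(msd, "dimensionality") %||% 2
  }
  stopifnot(dimensionality %in% c(2, 3))
  if (nrow(msd) < n_points) {
    stop(sprintf("MSD curve has %d lags; %d required for the fit",
                 nrow(msd), n_points), call. = FALSE)
  }
  w <- msd[seq_len(n_points), ]
  slope <- coef(lm(msd_um2 ~ lag_min, data = w))[["lag_min"]]
  slope / (2 * dimensionality)
}

#' Anomalous exponent from a log-log fit of the MSD
#'
#' `alpha` is the slope of `log(MSD)` versus `log(lag)` over the first
#' `n_points` lags: 1 for diffusive, 2 for ballistic, < 1 for confined
#' motion. Non-positive MSD values are dropped from the window with a
#' warning.
#'
#' @inheritParams fit_diffusion
#' @param n_points Number of initial lags (default 100).
#' @return List with `alpha` (log-log slope) and `D` (from
#'   `exp(intercept) / (2 * dimensionality)`, meaningful when `alpha ~ 1`).
#' @export
msd_loglog <- function(msd, n_points = 100, dimensionality = NULL) {
  if (is.null(dimensionality)) {
    dimensionality <- attr(msd, "dimensionality") %||% 2
  }
  w <- msd[seq_len(min(n_points, nrow(msd))), ]
  ok <- w$msd_um2 > 0 & w$lag_min > 0
  if (!all(ok)) {
    warning("non-positive MSD values dropped from the log-log window")
    w <- w[ok, ]
  }
  if (nrow(w) < 2) stop("fewer than 2 positive MSD points", call. = FALSE)
  fit <- lm(log(msd_um2) ~ log(lag_min), data = w)
  list(alpha = unname(coef(fit)[2]),
       D = exp(unname(coef(fit)[1])) / (2 * dimensionality))
}
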