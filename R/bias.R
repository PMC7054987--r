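#' Classify a displacement as toward the center, toward the cortex, or not
#' directional
#'
#' The angle `theta` is measured between the displacement and the inward
#' radial direction at its start point. Under the default `"equal"`
#' convention the three classes are equal-measure bins on `cos(theta)`
#' (toward the center when `cos(theta) > 1/2`, toward the cortex when
#' `cos(theta) < -1/2`), so an isotropic planar displacement lands in each
#' class with probability exactly 1/3. The `"literal"` convention uses the
#' angular bounds +/-30 degrees (center) and beyond +/-60 degrees (cortex)
#' on `|theta|`; its class probabilities under isotropy are 1/6, 1/3 and 1/2
#' in the plane, so it is kept only for fidelity experiments.
#'
#' @param displacement Displacement vector (length 2 or 3).
#' @param start Start position relative to the cell center (same length).
#' @param convention `"equal"` (default) or `"literal"`.
#' @return One of `"toward_center"`, `"toward_cortex"`, `"not_directional"`.
#'   Zero-length displacements are `"not_directional"`; a start at the exact
#'   center is an error (radial direction undefined).
#' @export
classify_displacement <- function(displacement, start,
                                  convention = c("equal", "literal")) {
  convention <- match.arg(convention)
  r <- sqrt(sum(start^2))
  if (r == 0) stop("displacement starts at the center: radial direction undefined",
                   call. = FALSE)
  dn <- sqrt(sum(displacement^2))
  if (dn == 0) return("not_directional")
  cth <- -sum(displacement * start) / (dn * r)   # cos angle to inward radial
  cth <- max(-1, min(1, cth))
  if (convention == "equal") {
    if (cth > 0.5) "toward_center"
    else if (cth < -0.5) "toward_cortex"
    else "not_directional"
  } else {
    th <- acos(cth) * 180 / pi                   # |theta| in degrees
    if (th < 30) "toward_center"
    else if (th > 60) "toward_cortex"
    else "not_directional"
  }
}

# vectorised classification over all displacements of a track set at a lag
classified_counts <- function(tracks, step_frames, convention,
                              dimensionality = 2, center = c(0, 0, 0)) {
  trl <- if (inherits(tracks, "track_set")) split_tracks(tracks) else tracks
  counts <- c(toward_center = 0, toward_cortex = 0, not_directional = 0)
  for (tr in trl) {
    pos <- positions_matrix(tr, dims = dimensionality)
    pos <- sweep(pos, 2, center[seq_len(dimensionality)])
    n <- nrow(pos)
    if (n <= step_frames) next
    start <- pos[1:(n - step_frames), , drop = FALSE]
    disp <- pos[(step_frames + 1):n, , drop = FALSE] - start
    rr <- sqrt(rowSums(start^2))
    dn <- sqrt(rowSums(disp^2))
    ok <- rr > 0
    cth <- rep(NA_real_, n - step_frames)
    nz <- ok & dn > 0
    cth[nz] <- pmax(-1, pmin(1, -rowSums(disp * start)[nz] / (dn[nz] * rr[nz])))
    if (convention == "equal") {
      ctr <- sum(cth > 0.5, na.rm = TRUE)
      cor_ <- sum(cth < -0.5, na.rm = TRUE)
    } else {
      th <- acos(cth) * 180 / pi
      ctr <- sum(th < 30, na.rm = TRUE)
      cor_ <- sum(th > 60, na.rm = TRUE)
    }
    tot <- sum(ok)
    counts <- counts + c(ctr, cor_, tot - ctr - cor_)
  }
  counts
}

#' Cumulative bias of a track set
#'
#' Fraction of displacements (at a given time step) classified as directed
#' toward the cell center (or cortex), pooled across every displacement of
#' every track. For isotropic motion the expected fraction is 1/3 per class
#' under the default convention.
#'
#' @param tracks A `track_set` or list of single-track data frames.
#' @param time_step Displacement time step; an integer multiple of the frame
#'   interval (same units).
#' @param direction `"toward_center"` (default) or `"toward_cortex"`.
#' @param convention See [classify_displacement()].
#' @param dimensionality 2 (default) or 3.
#' @return The fraction in `[0, 1]`, with attributes `n_displacements` and
#'   `counts`.
#' @export
cumulative_bias <- function(tracks, time_step = NULL,
                            direction = c("toward_center", "toward_cortex"),
                            convention = c("equal", "literal"),
                            dimensionality = 2) {
  direction <- match.arg(direction)
  convention <- match.arg(convention)
  fi <- if (inherits(tracks, "track_set")) tracks$frame_interval
        else diff(tracks[[1]]$time_min[1:2])
  if (is.null(time_step)) time_step <- fi
  k <- round(time_step / fi)
  if (k < 1 || abs(k * fi - time_step) > 1e-9 * max(1, time_step)) {
    stop("time_step must be a positive integer multiple of the frame interval",
         call. = FALSE)
  }
  counts <- classified_counts(tracks, k, convention, dimensionality)
  total <- sum(counts)
  if (total == 0) stop("no displacements at this time step", call. = FALSE)
  out <- unname(counts[direction] / total)
  attr(out, "n_displacements") <- total
  attr(out, "counts") <- counts
  out
}

#' Brownian null ensemble of cumulative-bias values
#'
#' Generates `n_sims` pure Brownian tracks matched to the tested objects
#' (diffusion coefficient, duration, frame cadence, start radius) and
#' computes the per-simulation cumulative bias toward each direction at each
#' requested time step. This ensemble is the raw material of the bootstrap
#' confidence interval.
#'
#' @param D Diffusion coefficient of the null walks (um^2/min), > 0.
#' @param duration,frame_interval Track length and cadence (min), matched to
#'   the experimental tracks.
#' @param time_steps Time steps (min) at which bias is evaluated; integer
#'   multiples of `frame_interval`.
#' @param start_radius Start distance from the center (um); displacements
#'   near the center have an ill-defined radial axis, so null walks start
#'   where the tested objects do.
#' @param object_size Object diameter (um), recorded in the metadata (size
#'   enters the null through the chosen `D`).
#' @param n_sims Number of null simulations (default 1000).
#' @param dimensionality 2 (default, matching projected data) or 3.
#' @param convention See [classify_displacement()].
#' @param seed Integer seed.
#' @return A `null_ensemble`: list with `bias` (array
#'   `n_sims x time_steps x direction`), `counts` (per-sim displacement
#'   counts, same shape), and the generator parameters.
#' @export
build_null <- function(D, duration, frame_interval, time_steps,
                       start_radius = 10, object_size = NA_real_,
                       n_sims = 1000, dimensionality = 2,
                       convention = "equal", seed = 1L) {
  stopifnot(D > 0, n_sims >= 1)
  dirs <- c("toward_center", "toward_cortex")
  ks <- round(time_steps / frame_interval)
  stopifnot(all(ks >= 1))
  bias <- array(NA_real_, c(n_sims, length(time_steps), 2),
                dimnames = list(NULL, format(time_steps), dirs))
  counts <- array(0L, dim(bias), dimnames = dimnames(bias))
  spec <- walk_spec("brownian", D = D, duration = duration,
                    frame_interval = frame_interval,
                    dimensionality = dimensionality,
                    start = c(start_radius, rep(0, dimensionality - 1)),
                    n_tracks = 1, seed = seed)
  set.seed(seed)
  sim_seeds <- sample.int(.Machine$integer.max, n_sims)
  for (s in seq_len(n_sims)) {
    spec$seed <- sim_seeds[s]
    ts1 <- gen_brownian(spec)
    for (j in seq_along(time_steps)) {
      cc <- classified_counts(ts1, ks[j], convention, dimensionality)
      tot <- sum(cc)
      if (tot > 0) {
        bias[s, j, 1] <- cc["toward_center"] / tot
        bias[s, j, 2] <- cc["toward_cortex"] / tot
        counts[s, j, ] <- c(cc["toward_center"], cc["toward_cortex"])
      }
    }
  }
  structure(list(bias = bias, counts = counts, D = D, duration = duration,
                 frame_interval = frame_interval, time_steps = time_steps,
                 start_radius = start_radius, object_size = object_size,
                 n_sims = n_sims, dimensionality = dimensionality,
                 convention = convention, seed = seed),
            class = "null_ensemble")
}

#' Bootstrap confidence interval of the null cumulative bias
#'
#' Draws `n_objects` simulations from the null ensemble (without replacement
#' by default), pools their classified displacements into one cumulative
#' bias, repeats `n_boot` times, and returns the lower and upper quantiles
#' (1% and 99% at the default level): the interval within which the bias of
#' that many truly Brownian objects falls with the nominal probability.
#'
#' @param null A [build_null()] ensemble.
#' @param n_objects Number of objects in the tested sample (`<= n_sims`).
#' @param time_step Which time step of the ensemble (value, min).
#' @param direction `"toward_center"` or `"toward_cortex"`.
#' @param n_boot Bootstrap draws (default 10000).
#' @param level Confidence level (default 0.99: quantiles 0.01 and 0.99).
#' @param replace Resample with replacement instead (default `FALSE`).
#' @param pool `"displacements"` (default: pooled counts within a draw) or
#'   `"objects"` (average the per-simulation biases).
#' @param seed Integer seed for the bootstrap resampling.
#' @return Named numeric `c(ci_low, ci_high)`.
#' @export
bootstrap_ci <- function(null, n_objects, time_step = null$time_steps[1],
                         direction = c("toward_center", "toward_cortex"),
                         n_boot = 10000, level = 0.99, replace = FALSE,
                         pool = c("displacements", "objects"), seed = 1L) {
  direction <- match.arg(direction)
  pool <- match.arg(pool)
  stopifnot(inherits(null, "null_ensemble"))
  if (!replace && n_objects > null$n_sims) {
    stop("n_objects exceeds the number of null simulations", call. = FALSE)
  }
  j <- match(format(time_step), dimnames(null$bias)[[2]])
  if (is.na(j)) stop("time_step not present in the null ensemble", call. = FALSE)
  b <- null$bias[, j, direction]
  cnt <- null$counts[, j, direction]
  tot <- round(ifelse(b > 0, cnt / b, NA))
  # per-sim total displacement counts; identical across sims by construction
  tot[is.na(tot)] <- round(median(tot, na.rm = TRUE))
  set.seed(seed)
  draws <- vapply(seq_len(n_boot), function(i) {
    idx <- sample.int(null$n_sims, n_objects, replace = replace)
    if (pool == "displacements") sum(cnt[idx]) / sum(tot[idx])
    else mean(b[idx])
  }, numeric(1))
  qs <- quantile(draws, c(1 - level, level), names = FALSE, na.rm = TRUE)
  c(ci_low = qs[1], ci_high = qs[2])
}

#' Cumulative-bias significance test against the Brownian null
#'
#' For each requested time step and direction, computes the observed
#' cumulative bias of `tracks`, the bootstrap null interval for the same
#' number of objects, and flags significance when the observed fraction
#' falls outside the interval.
#'
#' @param tracks A `track_set` of the tested objects.
#' @param time_steps Time steps (min), integer multiples of the frame
#'   interval.
#' @param directions Directions to test (default both).
#' @param null Optional precomputed [build_null()] ensemble; built from
#'   `null_args` when absent.
#' @param null_args List of arguments for [build_null()] (at least `D`;
#'   `duration`, `frame_interval` and `time_steps` default to those of
#'   `tracks`).
#' @param n_boot,level,convention,dimensionality See [bootstrap_ci()] and
#'   [cumulative_bias()].
#' @param seed Integer seed for null construction and bootstrap.
#' @return Tibble with one row per time step x direction: `direction`,
#'   `time_step`, `fraction`, `ci_low`, `ci_high`, `significant`, `n_tracks`,
#'   `n_displacements`.
#' @export
bias_test <- function(tracks, time_steps,
                      directions = c("toward_center", "toward_cortex"),
                      null = NULL, null_args = list(),
                      n_boot = 10000, level = 0.99,
                      convention = "equal", dimensionality = 2,
                      seed = 1L) {
  stopifnot(inherits(tracks, "track_set"))
  n_tracks <- length(unique(tracks$records$track_id))
  if (n_tracks == 0) stop("empty track set", call. = FALSE)
  if (is.null(null)) {
    args <- list(duration = max(tracks$records$time_min),
                 frame_interval = tracks$frame_interval,
                 time_steps = time_steps, dimensionality = dimensionality,
                 convention = convention, seed = seed)
    args[names(null_args)] <- null_args
    null <- do.call(build_null, args)
  }
  rows <- list()
  for (ts_ in time_steps) {
    for (dir_ in directions) {
      fr <- cumulative_bias(tracks, ts_, direction = dir_,
                            convention = convention,
                            dimensionality = dimensionality)
      ci <- bootstrap_ci(null, n_objects = n_tracks, time_step = ts_,
                         direction = dir_, n_boot = n_boot, level = level,
                         seed = seed)
      rows[[length(rows) + 1]] <- tibble(
        direction = dir_, time_step = ts_, fraction = as.numeric(fr),
        ci_low = ci[["ci_low"]], ci_high = ci[["ci_high"]],
        significant = fr < ci[["ci_low"]] | fr > ci[["ci_high"]],
        n_tracks = n_tracks,
        n_displacements = attr(fr, "n_displacements"))
    }
  }
  do.call(rbind, rows)
}
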