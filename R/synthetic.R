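#' Specification of a synthetic walk
#'
#' Collects the parameters of the synthetic track generators into one list.
#' These generators produce `track_set` objects with known statistical
#' structure: Brownian walks (the bootstrap null), inward-drifted walks
#' (positive control for bias statistics), constant-speed persistent walks
#' (the single-agent version of the simulator's motility) and noisy
#' exponential approach series (fixture for the centering fit).
#'
#' @param kind `"brownian"`, `"biased_radial"`, `"persistent"` or
#'   `"exponential_approach"`.
#' @param D Diffusion coefficient (um^2/min).
#' @param drift Inward radial drift speed (um/min), biased walk only.
#' @param v,tau Speed (um/min) and persistence time (min), persistent walk.
#' @param a,b,noise_sd Exponential approach `a * exp(b t)` plus Gaussian
#'   noise of sd `noise_sd` (um).
#' @param duration Total time (min).
#' @param frame_interval Frame interval (min).
#' @param dimensionality 2 (default) or 3.
#' @param start Start position (recycled per track); default the origin.
#' @param confinement_radius Reflecting spherical boundary (um) or `NA`.
#' @param n_tracks Number of tracks to generate.
#' @param radius_um Object radius recorded in the track metadata (um).
#' @param seed Integer seed.
#' @return A `walk_spec` list.
#' @export
walk_spec <- function(kind = c("brownian", "biased_radial", "persistent",
                               "exponential_approach"),
                      D = 0.072, drift = 0, v = 1, tau = 1,
                      a = 10, b = -0.01, noise_sd = 0,
                      duration = 4, frame_interval = 1 / 120,
                      dimensionality = 2, start = NULL,
                      confinement_radius = NA_real_, n_tracks = 1,
                      radius_um = 1, seed = 1L) {
  kind <- match.arg(kind)
  stopifnot(D >= 0, frame_interval > 0, duration >= frame_interval,
            dimensionality %in% c(2, 3), n_tracks >= 1)
  if (is.null(start)) start <- rep(0, dimensionality)
  structure(list(kind = kind, D = D, drift = drift, v = v, tau = tau,
                 a = a, b = b, noise_sd = noise_sd, duration = duration,
                 frame_interval = frame_interval,
                 dimensionality = dimensionality, start = start,
                 confinement_radius = confinement_radius,
                 n_tracks = as.integer(n_tracks), radius_um = radius_um,
                 seed = as.integer(seed)),
            class = "walk_spec")
}

walk_track_set <- function(spec, mats, kind_label) {
  nf <- nrow(mats[[1]])
  tt <- (seq_len(nf) - 1) * spec$frame_interval
  rec <- do.call(rbind, lapply(seq_along(mats), function(i) {
    m <- mats[[i]]
    data.frame(time_min = tt,
               track_id = sprintf("%s%d", substr(spec$kind, 1, 1), i),
               kind = kind_label,
               x_um = m[, 1], y_um = m[, 2],
               z_um = if (spec$dimensionality == 3) m[, 3] else NA_real_,
               radius_um = spec$radius_um)
  }))
  track_set(rec, frame_interval = spec$frame_interval,
            oocyte_radius = spec$confinement_radius,
            seed = spec$seed,
            provenance = sprintf("synthetic %s walk", spec$kind))
}

reflect_sphere <- function(p, R) {
  # mirror reflection across the sphere of radius R (applied once; steps are
  # small relative to R in all intended uses)
  r <- sqrt(sum(p^2))
  if (is.na(R) || r <= R) return(p)
  p * (2 * R - r) / r
}

#' Generate Brownian tracks
#'
#' Gaussian increments of variance `2 D dt` per axis; mirror-reflecting
#' spherical boundary when `confinement_radius` is set. Deterministic by
#' `spec$seed`.
#'
#' @param spec A [walk_spec()] (fields `D`, `duration`, `frame_interval`,
#'   `dimensionality`, `start`, `confinement_radius`, `n_tracks`, `seed`).
#' @return A `track_set`.
#' @export
#' @examples
#' ts <- gen_brownian(walk_spec(D = 0.072, duration = 200 / 120,
#'                              frame_interval = 1 / 120, n_tracks = 2,
#'                              seed = 7))
gen_brownian <- function(spec) {
  stopifnot(spec$kind %in% c("brownian", "biased_radial"))
  set.seed(spec$seed)
  nf <- floor(spec$duration / spec$frame_interval) + 1
  dd <- spec$dimensionality
  sdv <- sqrt(2 * spec$D * spec$frame_interval)
  drift <- if (spec$kind == "biased_radial") spec$drift else 0
  mats <- lapply(seq_len(spec$n_tracks), function(i) {
    m <- matrix(0, nf, dd)
    m[1, ] <- spec$start[seq_len(dd)]
    for (k in 2:nf) {
      p <- m[k - 1, ] + rnorm(dd, 0, sdv)
      if (drift > 0) {
        r <- sqrt(sum(m[k - 1, ]^2))
        step_in <- drift * spec$frame_interval
        if (r > 0) p <- p - m[k - 1, ] / r * min(step_in, r)  # stops at center
      }
      m[k, ] <- reflect_sphere(p, spec$confinement_radius)
    }
    m
  })
  walk_track_set(spec, mats, "object")
}

#' Generate inward-biased random walks
#'
#' Brownian increments plus a deterministic inward radial step of
#' `drift * frame_interval`, truncated at the center. With `drift = 0` this
#' is exactly [gen_brownian()].
#'
#' @param spec A [walk_spec()] with `kind = "biased_radial"` and `drift >= 0`.
#' @return A `track_set`.
#' @export
gen_biased_radial <- function(spec) {
  stopifnot(spec$drift >= 0)
  spec$kind <- "biased_radial"
  gen_brownian(spec)
}

#' Generate constant-speed persistent random walks
#'
#' The single-agent version of the simulator's motility: steps of length
#' `v * dt` along a heading redrawn with probability `min(1, dt/tau)` per
#' frame. The long-time MSD is linear with effective diffusion coefficient
#' `D_eff = v^2 tau / dimensionality`.
#'
#' @param spec A [walk_spec()] with `v > 0`, `tau > 0`.
#' @return A `track_set`.
#' @export
gen_persistent <- function(spec) {
  stopifnot(spec$v > 0, spec$tau > 0)
  set.seed(spec$seed)
  nf <- floor(spec$duration / spec$frame_interval) + 1
  dd <- spec$dimensionality
  dt <- spec$frame_interval
  p_redraw <- min(1, dt / spec$tau)
  draw_dir <- function() {
    if (dd == 3) random_unit_vector()
    else { th <- 2 * pi * runif(1); c(cos(th), sin(th)) }
  }
  mats <- lapply(seq_len(spec$n_tracks), function(i) {
    m <- matrix(0, nf, dd)
    m[1, ] <- spec$start[seq_len(dd)]
    dir <- draw_dir()
    for (k in 2:nf) {
      if (runif(1) < p_redraw) dir <- draw_dir()
      m[k, ] <- reflect_sphere(m[k - 1, ] + spec$v * dt * dir,
                               spec$confinement_radius)
    }
    m
  })
  walk_track_set(spec, mats, "object")
}

#' Generate a noisy exponential-approach distance series
#'
#' `d(t) = a exp(b t) + N(0, noise_sd)`, floored at zero: the fixture for
#' [centering_velocity()].
#'
#' @param spec A [walk_spec()] with `a > 0`.
#' @return Data frame with `time_min` and `distance_um`.
#' @export
gen_exponential_approach <- function(spec) {
  stopifnot(spec$a > 0)
  set.seed(spec$seed)
  tt <- seq(0, spec$duration, by = spec$frame_interval)
  d <- spec$a * exp(spec$b * tt)
  if (spec$noise_sd > 0) d <- d + rnorm(length(tt), 0, spec$noise_sd)
  data.frame(time_min = tt, distance_um = pmax(d, 0))
}
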