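#' Run one agent-based centering simulation
#'
#' Integrates the 3D off-lattice model defined by a [simulation_config()]:
#' vesicles self-propel with speed `v0` and a heading redrawn with
#' probability `dt/tau`, where `tau` increases from the center to the cortex;
#' all agents interact through linear hard-core repulsion and are confined by
#' the cortex force; positions follow the overdamped force balance integrated
#' with the two-step Adams-Bashforth scheme (Euler bootstrap on the first
#' step). The passive object starts tangent to the cortex along +x and only
#' moves through collisions.
#'
#' Vesicles are placed uniformly at random in the cell, rejecting initial
#' overlap with the object and the cortex. The run is fully deterministic
#' given `config$seed`. When `config$auto_dt` is set, the integration is
#' repeated with a halved `dt` if any per-step displacement exceeded 10% of
#' the smallest agent radius.
#'
#' @param config A `simulation_config`.
#' @param record Either `"all"` (default) or `"object"`: which agents to keep
#'   in the returned records. The integration always simulates everything;
#'   `"object"` merely drops vesicle rows on output, which keeps memory down
#'   in ensemble sweeps.
#' @return A [track_set()] with one track per agent, positions every
#'   `record_interval` minutes (including t = 0). The object's track id is
#'   `"object"`; vesicles are `"v1" ... "vN"`.
#' @export
#' @examples
#' cfg <- simulation_config(n_vesicles = 30, duration = 20, seed = 42,
#'                          record_interval = 5)
#' ts <- run_simulation(cfg)
#' ts
run_simulation <- function(config, record = c("all", "object")) {
  validate_config(config)
  record <- match.arg(record)
  set.seed(config$seed)

  n_ves <- config$n_vesicles
  has_object <- config$object_radius > 0

  # vesicle radii: truncated normal, strictly positive
  radii_v <- numeric(0)
  if (n_ves > 0) {
    radii_v <- rnorm(n_ves, config$vesicle_radius_mean, config$vesicle_radius_sd)
    bad <- which(radii_v < config$vesicle_radius_floor)
    while (length(bad) > 0) {
      radii_v[bad] <- rnorm(length(bad), config$vesicle_radius_mean,
                            config$vesicle_radius_sd)
      bad <- which(radii_v < config$vesicle_radius_floor)
    }
  }

  obj_pos <- c(config$object_initial_distance, 0, 0)

  # uniform placement in the allowed volume, rejecting overlap with the
  # cortex, the object and already-placed vesicles (overlap-free start)
  n <- n_ves + as.integer(has_object)
  pos0 <- matrix(0, n, 3)
  radii <- numeric(n)
  kind <- integer(n)                    # 0 = object, 1 = vesicle
  if (has_object) {
    pos0[1, ] <- obj_pos
    radii[1] <- config$object_radius
    kind[1] <- 0L
  }
  n_placed <- as.integer(has_object)
  for (k in seq_len(n_ves)) {
    i <- k + as.integer(has_object)
    r <- radii_v[k]
    repeat {
      p <- runif(3, -1, 1) * config$oocyte_radius
      if (sum(p^2) > (config$oocyte_radius - r)^2) next
      prev <- seq_len(n_placed)
      d2 <- rowSums(sweep(pos0[prev, , drop = FALSE], 2, p)^2)
      if (any(d2 < (radii[prev] + r)^2)) next
      break
    }
    radii[i] <- r
    kind[i] <- 1L
    pos0[i, ] <- p
    n_placed <- i
  }

  dir0 <- t(vapply(seq_len(n), function(i) random_unit_vector(), numeric(3)))

  dt <- config$dt
  rng_state <- .Random.seed             # state after the initial-condition draws
  repeat {
    assign(".Random.seed", rng_state, envir = globalenv())
    n_steps <- round(config$duration / dt)
    rec_every <- max(1L, round(config$record_interval / dt))
    par <- list(
      oocyte_radius = config$oocyte_radius, v0 = config$v0,
      tau0 = config$tau0, tau_r = config$tau_r,
      gradient_form = if (config$gradient_form == "additive") 0L else 1L,
      gradient_on = config$gradient_on, tau_const = config$tau_const,
      c_r = config$c_r, c_c = config$c_c,
      confinement_exponent = config$confinement_exponent,
      gamma = config$gamma, dt = dt, n_steps = as.integer(n_steps),
      record_every = as.integer(rec_every),
      prob_model = if (config$redraw_model == "linear") 0L else 1L,
      object_motile = config$object_motile
    )
    res <- .sim_run_cpp(pos0, dir0, radii, kind, par)
    limit <- 0.1 * min(radii[radii > 0], config$oocyte_radius)
    if (!config$auto_dt || res$max_step_disp <= limit) break
    dt <- dt / 2
    warning(sprintf(
      "per-step displacement %.3g um exceeded 10%% of the smallest radius; dt halved to %g min",
      res$max_step_disp, dt))
  }

  ids <- character(n)
  if (has_object) ids[1] <- "object"
  ids[kind == 1L] <- paste0("v", seq_len(n_ves))
  kinds <- ifelse(kind == 0L, "object", "vesicle")

  n_rec <- length(res$time)
  pos <- res$pos                         # dim: 3 x n x n_rec
  keep <- if (record == "object" && has_object) 1L else seq_len(n)
  records <- tibble(
    time_min = rep(res$time, each = length(keep)),
    track_id = rep(ids[keep], times = n_rec),
    kind = rep(kinds[keep], times = n_rec),
    x_um = as.vector(pos[1, keep, ]),
    y_um = as.vector(pos[2, keep, ]),
    z_um = as.vector(pos[3, keep, ]),
    radius_um = rep(radii[keep], times = n_rec)
  )
  track_set(records,
            frame_interval = config$record_interval,
            oocyte_radius = config$oocyte_radius,
            seed = config$seed,
            provenance = sprintf(
              "oocenter simulation: %d vesicles, object r=%g um, gradient %s (%s), v0=%g, dt=%g, seed=%d",
              n_ves, config$object_radius,
              if (config$gradient_on) "on" else "off",
              config$gradient_form, config$v0, dt, config$seed))
}

#' Run replicate simulations with distinct seeds
#'
#' @param config A `simulation_config` (its `seed` field seeds replicate 1).
#' @param n_replicates Number of replicates.
#' @param record Passed to [run_simulation()].
#' @param .progress Print a dot per finished replicate to stderr.
#' @return List of `track_set`, one per replicate; replicate `k` uses seed
#'   `config$seed + k - 1`.
#' @export
run_ensemble <- function(config, n_replicates, record = "all",
                         .progress = FALSE) {
  lapply(seq_len(n_replicates), function(k) {
    cfg <- config
    cfg$seed <- config$seed + k - 1L
    out <- run_simulation(cfg, record = record)
    if (.progress) message(".", appendLF = FALSE)
    out
  })
}

#' Calibrate the intrinsic vesicle speed against a squared-velocity profile
#'
#' The simulated vesicles' squared velocity as a function of distance from
#' the center (measured at `sampling_interval` within the 30-60 min window,
#' as in [squared_velocity_profile()]) scales with `v0^2`. Given a target
#' profile, the calibration runs short simulations over a bracket of speeds
#' and returns the `v0` minimising the summed squared error between the
#' simulated and target per-bin values.
#'
#' @param config Base configuration (its `v0` is overridden during search).
#'   For speed, calibration runs usually use a reduced `duration` (>= 60 min)
#'   and can drop the object.
#' @param target_profile Data frame with columns `distance_um` and
#'   `v2_um2_min2`: target mean squared velocity per distance bin.
#' @param sampling_interval Sampling interval for the measured profile (min).
#' @param bracket Length-2 numeric search interval for `v0` (um/min).
#' @param tol Relative tolerance of the one-dimensional search.
#' @return List with `v0` (the optimum), `objective`, and the search trace.
#' @export
calibrate_speed <- function(config, target_profile,
                            sampling_interval = config$record_interval,
                            bracket = c(0.2, 6), tol = 0.02) {
  stopifnot(is.data.frame(target_profile), nrow(target_profile) > 0,
            all(c("distance_um", "v2_um2_min2") %in% names(target_profile)))
  if (sampling_interval < config$dt) {
    stop("sampling_interval must be >= dt", call. = FALSE)
  }
  if (all(target_profile$v2_um2_min2 == 0)) {
    warning("target profile is all zeros; returning the lower search bound")
    return(list(v0 = bracket[1], objective = NA_real_, trace = NULL))
  }
  edges <- profile_edges_from_target(target_profile, config$oocyte_radius)
  trace <- list()
  obj <- function(v0) {
    cfg <- config
    cfg$v0 <- v0
    cfg$record_interval <- sampling_interval
    if (cfg$duration > 80) cfg$duration <- 80   # window 30-60 min suffices
    ts <- run_simulation(cfg)
    prof <- squared_velocity_profile(ts, window = c(30, 60),
                                     distance_bins = edges)
    merged <- merge(prof, target_profile, by = "distance_um")
    err <- sum((merged$v2_mean - merged$v2_um2_min2)^2)
    trace[[length(trace) + 1]] <<- c(v0 = v0, err = err)
    err
  }
  fit <- optimize(obj, interval = bracket, tol = tol * diff(bracket))
  list(v0 = fit$minimum, objective = fit$objective,
       trace = do.call(rbind, trace))
}

# reconstruct bin edges from target bin centers (uniform spacing assumed)
profile_edges_from_target <- function(target, oocyte_radius) {
  ctr <- sort(unique(target$distance_um))
  if (length(ctr) == 1) {
    w <- oocyte_radius / 2
    return(c(max(0, ctr - w / 2), min(oocyte_radius, ctr + w / 2)))
  }
  w <- median(diff(ctr))
  c(ctr - w / 2, ctr[length(ctr)] + w / 2)
}

#' Closed-form squared-velocity profile of the persistent-walk model
#'
#' Mean-field prediction used as a synthetic calibration target: a vesicle
#' with speed `v0` and local persistence `tau(r)` sampled at interval `dt_s`
#' shows a measured squared velocity `MSD(dt_s)/dt_s^2` with the 3D
#' persistent-random-walk closed form
#' `MSD(t) = 2 v0^2 tau [t - tau (1 - exp(-t/tau))]`.
#'
#' This is a smooth idealisation of the simulated profile (it neglects
#' collisions and confinement); it is labelled synthetic wherever it stands
#' in for an experimentally measured profile.
#'
#' @param distance_um Distances from the center (um).
#' @param v0 Intrinsic speed (um/min).
#' @param tau0,tau_r,form Persistence gradient parameters, see
#'   [persistence_time()].
#' @param dt_s Sampling interval (min).
#' @return Tibble with `distance_um` and `v2_um2_min2`.
#' @export
reference_velocity_profile <- function(distance_um, v0, tau0 = 0.001,
                                       tau_r = 0.25, form = "additive",
                                       dt_s = 5) {
  tau <- persistence_time(distance_um, tau0, tau_r, form)
  msd <- 2 * v0^2 * tau * (dt_s - tau * (1 - exp(-dt_s / tau)))
  tibble(distance_um = distance_um, v2_um2_min2 = msd / dt_s^2)
}
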