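#' Stokes friction coefficient of a sphere
#'
#' `eta = 6 * pi * radius * gamma`. Friction grows linearly with the agent
#' radius, so at equal force a large object moves more slowly than a vesicle.
#'
#' @param radius Sphere radius (um), > 0.
#' @param gamma Medium viscosity (pN.min/um^2), > 0.
#' @return Friction coefficient (pN.min/um).
#' @export
#' @examples
#' stokes_friction(0.5, 1)  # 3 * pi
stokes_friction <- function(radius, gamma) {
  if (any(!is.finite(radius)) || any(radius <= 0)) {
    stop("radius must be positive", call. = FALSE)
  }
  if (!is.finite(gamma) || gamma <= 0) stop("gamma must be positive", call. = FALSE)
  6 * pi * radius * gamma
}

#' Persistence time at a given distance from the cell center
#'
#' The spatial gradient of motion persistence: `tau` equals `tau0` at the
#' center and increases toward the cortex with slope `tau_r`. The additive
#' form is `tau0 + tau_r * r`; the multiplicative form `tau0 * (1 + tau_r * r)`.
#'
#' @param radial_distance Distance from the cell center (um), >= 0. Vectorised.
#' @param tau0 Minimal persistence time (min).
#' @param tau_r Gradient slope (min/um).
#' @param form `"additive"` (default) or `"multiplicative"`.
#' @return Persistence time(s) in minutes.
#' @export
persistence_time <- function(radial_distance, tau0, tau_r,
                             form = c("additive", "multiplicative")) {
  form <- match.arg(form)
  if (any(radial_distance < 0)) stop("radial_distance must be >= 0", call. = FALSE)
  if (form == "additive") tau0 + tau_r * radial_distance
  else tau0 * (1 + tau_r * radial_distance)
}

#' Hard-core repulsion between two overlapping spheres
#'
#' Zero until the spheres overlap; once they do, a linear restoring force of
#' magnitude `c_r * (1 - d / d_eq)` pushes them apart along the center-center
#' axis, where `d_eq` is the sum of the radii. The two returned forces are
#' equal and opposite.
#'
#' @param center_i,center_j Sphere centers (length-3 numeric).
#' @param radius_i,radius_j Sphere radii (um).
#' @param c_r Repulsion coefficient (pN).
#' @return List with `force_i`, `force_j` (pN vectors, `force_i = -force_j`).
#' @export
pair_repulsion <- function(center_i, center_j, radius_i, radius_j, c_r) {
  d <- center_j - center_i
  dist <- sqrt(sum(d^2))
  if (dist == 0) stop("coincident centers: repulsion direction undefined",
                      call. = FALSE)
  d_eq <- radius_i + radius_j
  if (dist >= d_eq) {
    z <- c(0, 0, 0)
    return(list(force_i = z, force_j = z))
  }
  mag <- c_r * (1 - dist / d_eq)
  u <- d / dist
  list(force_i = -mag * u, force_j = mag * u)
}

#' Confinement force at the cell cortex
#'
#' The cortex acts on an agent as soon as its sphere touches the boundary,
#' i.e. when the gap between the agent center and the cortex surface drops
#' below the agent radius. The force is directed radially inward with
#' magnitude `c_c * (1 - gap / radius)^exponent`.
#'
#' @param center Agent center (length-3, um), origin at the cell center.
#' @param radius Agent radius (um).
#' @param oocyte_radius Cell radius (um).
#' @param c_c Confinement coefficient (pN).
#' @param exponent Force-law exponent (default 2).
#' @param outside `"error"` (default) or `"clamp"`: what to do when the agent
#'   center lies outside the cell. Clamping keeps the (large) inward force
#'   given by the same law with a negative gap and emits a warning.
#' @return Force vector (pN).
#' @export
cortex_confinement <- function(center, radius, oocyte_radius, c_c,
                               exponent = 2, outside = c("error", "clamp")) {
  outside <- match.arg(outside)
  dist <- sqrt(sum(center^2))
  gap <- oocyte_radius - dist
  if (gap < 0) {
    if (outside == "error") {
      stop("agent center outside the oocyte sphere", call. = FALSE)
    }
    warning("agent center outside the oocyte sphere; confinement force clamped")
  }
  if (gap >= radius || dist == 0) return(c(0, 0, 0))
  mag <- c_c * (1 - gap / radius)^exponent
  -mag * center / dist
}

#' Redraw a motility heading with probability dt/tau
#'
#' At each step a self-propelled agent keeps its heading, or redraws it
#' uniformly on the unit sphere with probability `min(1, dt/tau)` (linear
#' model) or `1 - exp(-dt/tau)` (exponential model). Redraws form a geometric
#' process whose mean waiting time approaches `tau` for `dt << tau`.
#'
#' @param direction Current unit heading (length-3).
#' @param tau Persistence time (min), > 0 (may be `Inf`).
#' @param dt Time step (min), > 0.
#' @param model `"linear"` or `"exponential"`.
#' @return A unit vector: either `direction` unchanged or a fresh draw.
#' @export
maybe_redraw_direction <- function(direction, tau, dt,
                                   model = c("linear", "exponential")) {
  model <- match.arg(model)
  if (!(tau > 0)) stop("tau must be positive", call. = FALSE)
  if (!(dt > 0)) stop("dt must be positive", call. = FALSE)
  p <- if (model == "linear") min(1, dt / tau) else 1 - exp(-dt / tau)
  if (runif(1) < p) random_unit_vector() else direction
}

#' Uniform random direction on the unit sphere
#'
#' Consumes exactly two uniform draws (`z = 2u1 - 1`, `phi = 2 pi u2`),
#' matching the draw order of the compiled simulation loop.
#'
#' @return Length-3 unit vector.
#' @export
random_unit_vector <- function() {
  z <- 2 * runif(1) - 1
  phi <- 2 * pi * runif(1)
  s <- sqrt(max(0, 1 - z^2))
  c(s * cos(phi), s * sin(phi), z)
}

#' Overdamped velocity from the force balance
#'
#' `v = F / eta + v0 * heading` for motile agents; passive objects receive
#' the force term only. `eta` is the Stokes friction of the agent.
#'
#' @param total_force Net force on the agent (pN, length-3).
#' @param radius Agent radius (um).
#' @param gamma Viscosity (pN.min/um^2).
#' @param v0 Intrinsic speed (um/min); ignored for passive agents.
#' @param direction Unit heading (length-3).
#' @param motile Logical: does the agent self-propel?
#' @return Velocity vector (um/min).
#' @export
compute_velocity <- function(total_force, radius, gamma, v0 = 0,
                             direction = c(1, 0, 0), motile = TRUE) {
  v <- total_force / stokes_friction(radius, gamma)
  if (motile) v <- v + v0 * direction
  v
}

#' One position update of the two-step Adams-Bashforth scheme
#'
#' `x + dt * (3/2 v_now - 1/2 v_prev)`; the first step of a trajectory, which
#' has no previous velocity, uses the explicit Euler form `x + dt * v_now`
#' (pass `v_prev = NULL`).
#'
#' @param position Current position.
#' @param v_now Velocity at the current step.
#' @param v_prev Velocity at the previous step, or `NULL` on the first step.
#' @param dt Time step (min), > 0.
#' @return Updated position.
#' @export
ab2_step <- function(position, v_now, v_prev, dt) {
  if (!(dt > 0)) stop("dt must be positive", call. = FALSE)
  if (is.null(v_prev)) position + dt * v_now
  else position + dt * (1.5 * v_now - 0.5 * v_prev)
}

#' Candidate contact pairs from a uniform spatial grid
#'
#' Returns a superset of all truly overlapping agent pairs by binning agent
#' centers into cubic cells of side `interaction_range` and pairing agents in
#' neighbouring cells. Pairs farther apart than `interaction_range` are
#' filtered out.
#'
#' @param positions n x 3 matrix of agent centers.
#' @param interaction_range Cell size (um); must be at least twice the
#'   largest agent radius for the superset guarantee.
#' @return Two-column integer matrix of candidate pairs `(i, j)`, `i < j`.
#' @export
build_neighbor_index <- function(positions, interaction_range) {
  stopifnot(is.matrix(positions), ncol(positions) == 3, interaction_range > 0)
  n <- nrow(positions)
  if (n < 2) return(matrix(integer(0), ncol = 2,
                           dimnames = list(NULL, c("i", "j"))))
  h <- interaction_range
  idx <- floor(sweep(positions, 2, apply(positions, 2, min)) / h)
  key <- idx[, 1] + 1e4 * idx[, 2] + 1e8 * idx[, 3]
  cells <- split(seq_len(n), key)
  cell_idx <- do.call(rbind, lapply(cells, function(m) idx[m[1], , drop = TRUE]))
  pairs <- list()
  keys <- as.numeric(names(cells))
  for (a in seq_along(cells)) {
    ia <- cell_idx[a, ]
    for (b in a:length(cells)) {
      ib <- cell_idx[b, ]
      if (all(abs(ia - ib) <= 1)) {
        ma <- cells[[a]]; mb <- cells[[b]]
        if (a == b) {
          if (length(ma) > 1) pairs[[length(pairs) + 1]] <- t(utils::combn(ma, 2))
        } else {
          pairs[[length(pairs) + 1]] <- as.matrix(expand.grid(i = ma, j = mb))
        }
      }
    }
  }
  if (length(pairs) == 0) return(matrix(integer(0), ncol = 2,
                                        dimnames = list(NULL, c("i", "j"))))
  pr <- do.call(rbind, pairs)
  pr <- cbind(i = pmin(pr[, 1], pr[, 2]), j = pmax(pr[, 1], pr[, 2]))
  d2 <- rowSums((positions[pr[, 1], , drop = FALSE] -
                   positions[pr[, 2], , drop = FALSE])^2)
  pr <- pr[d2 <= interaction_range^2, , drop = FALSE]
  pr[order(pr[, 1], pr[, 2]), , drop = FALSE]
}
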