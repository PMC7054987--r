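# Independent oracles used across the test files.

# Pure-R reference integrator mirroring the compiled loop draw-for-draw.
# Pair forces are summed brute force; with at most one contact pair at a
# time (the configurations used in tests) floating-point summation order is
# identical to the compiled kernel, so trajectories must match bitwise.
ref_sim <- function(pos0, dir0, radii, kind, par) {
  n <- nrow(pos0)
  pos <- pos0
  dir <- dir0
  vprev <- matrix(0, n, 3)
  eta <- 6 * pi * radii * par$gamma
  motile <- ifelse(kind == 1L, TRUE, par$object_motile)
  n_rec <- par$n_steps %/% par$record_every + 1
  rec <- array(NA_real_, c(n, 3, n_rec))
  rec_time <- numeric(n_rec)
  rec[, , 1] <- pos
  slot <- 2

  tau_of <- function(d) {
    if (!par$gradient_on) return(par$tau_const)
    if (par$gradient_form == 0L) par$tau0 + par$tau_r * d
    else par$tau0 * (1 + par$tau_r * d)
  }

  for (step in seq_len(par$n_steps)) {
    frc <- matrix(0, n, 3)
    # all pair contacts (i < j), vesicle pairs first then object pairs to
    # mirror the kernel's accumulation order in one-contact scenarios
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        d <- pos[j, ] - pos[i, ]
        deq <- radii[i] + radii[j]
        dist2 <- sum(d^2)
        if (dist2 >= deq^2 || dist2 == 0) next
        dist <- sqrt(dist2)
        mag <- par$c_r * (1 - dist / deq) / dist
        frc[j, ] <- frc[j, ] + mag * d
        frc[i, ] <- frc[i, ] - mag * d
      }
    }
    for (i in seq_len(n)) {
      dist <- sqrt(sum(pos[i, ]^2))
      gap <- par$oocyte_radius - dist
      if (gap < radii[i] && dist > 0) {
        mag <- par$c_c * (1 - gap / radii[i])^par$confinement_exponent / dist
        frc[i, ] <- frc[i, ] - mag * pos[i, ]
      }
      if (motile[i]) {
        tau <- tau_of(dist)
        p <- if (par$prob_model == 0L) min(1, par$dt / tau)
             else 1 - exp(-par$dt / tau)
        if (runif(1) < p) {
          z <- 2 * runif(1) - 1
          phi <- 2 * pi * runif(1)
          s <- sqrt(max(0, 1 - z^2))
          dir[i, ] <- c(s * cos(phi), s * sin(phi), z)
        }
      }
      v <- frc[i, ] / eta[i]
      if (motile[i]) v <- v + par$v0 * dir[i, ]
      v_eff <- if (step == 1) v else 1.5 * v - 0.5 * vprev[i, ]
      dx <- par$dt * v_eff
      cap <- 0.45 * max(0.5, 4 * par$v0 * par$dt)   # bounded step, as compiled
      nrm <- sqrt(sum(dx^2))
      if (nrm > cap) dx <- dx * cap / nrm
      pos[i, ] <- pos[i, ] + dx
      vprev[i, ] <- v
    }
    if (step %% par$record_every == 0) {
      rec[, , slot] <- pos
      rec_time[slot] <- step * par$dt
      slot <- slot + 1
    }
  }
  list(time = rec_time, pos = rec)
}

# default kernel parameter list for direct .sim_run_cpp / ref_sim calls
ref_par <- function(...) {
  par <- list(oocyte_radius = 35, v0 = 0, tau0 = 0.001, tau_r = 0.25,
              gradient_form = 1L, gradient_on = TRUE, tau_const = 0.005,
              c_r = 100, c_c = 200, confinement_exponent = 2, gamma = 1 / 60,
              dt = 0.001, n_steps = 50L, record_every = 1L, prob_model = 1L,
              object_motile = FALSE)
  mods <- list(...)
  par[names(mods)] <- mods
  par
}

# brute-force time-averaged MSD (independent of the package implementation)
brute_msd <- function(pos, dt) {
  n <- nrow(pos)
  vapply(seq_len(n - 1), function(k) {
    s <- 0
    for (t in seq_len(n - k)) s <- s + sum((pos[t + k, ] - pos[t, ])^2)
    s / (n - k)
  }, numeric(1))
}

# single-track data frame from coordinates
make_track <- function(x, y, z = NA_real_, dt = 1, id = "t1",
                       kind = "object", radius = 1) {
  data.frame(time_min = (seq_along(x) - 1) * dt, track_id = id, kind = kind,
             x_um = x, y_um = y, z_um = z, radius_um = radius)
}

track_set_of <- function(..., frame_interval = 1, oocyte_radius = NA_real_) {
  track_set(do.call(rbind, list(...)), frame_interval = frame_interval,
            oocyte_radius = oocyte_radius)
}

dist3 <- function(tr) sqrt(tr$x_um^2 + tr$y_um^2 +
                             ifelse(is.na(tr$z_um), 0, tr$z_um)^2)
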