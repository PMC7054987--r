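test_that("identical configuration and seed reproduce tracks bitwise", {
  cfg <- simulation_config(n_vesicles = 40, duration = 10, seed = 99,
                           record_interval = 1)
  a <- run_simulation(cfg)
  b <- run_simulation(cfg)
  expect_identical(a$records, b$records)
  c2 <- run_simulation(simulation_config(n_vesicles = 40, duration = 10,
                                         seed = 100, record_interval = 1))
  expect_false(identical(a$records, c2$records))
})

test_that("with no vesicles a passive object never moves", {
  cfg <- simulation_config(n_vesicles = 0, duration = 20, seed = 1)
  ts <- run_simulation(cfg)
  obj <- split_tracks(ts, kind = "object")[[1]]
  expect_equal(unique(obj$x_um), 22.5)
  expect_equal(unique(obj$y_um), 0)
  expect_equal(unique(obj$z_um), 0)
})

test_that("recorded positions respect the soft confinement invariant", {
  cfg <- simulation_config(n_vesicles = 120, duration = 30, seed = 5)
  ts <- run_simulation(cfg)
  rec <- ts$records
  r <- sqrt(rec$x_um^2 + rec$y_um^2 + rec$z_um^2)
  # transient violations are allowed up to 20% of the agent radius
  expect_true(all(r + rec$radius_um <= 35 + 0.2 * rec$radius_um))
})

test_that("compiled kernel matches the pure-R reference integrator", {
  # contact-free: several motile vesicles far apart exercising the gradient,
  # redraw and two-step integration paths
  pos0 <- matrix(c(10, 0, 0, -8, 6, 2, 0, -12, 5, 3, 3, -15), 4, 3, byrow = TRUE)
  radii <- c(0.5, 0.6, 0.4, 0.5)
  kind <- rep(1L, 4)
  par <- ref_par(v0 = 3, n_steps = 200L, record_every = 10L, dt = 0.002,
                 tau0 = 0.002)
  set.seed(31)
  dir0 <- t(vapply(1:4, function(i) random_unit_vector(), numeric(3)))
  res_cpp <- oocenter:::.sim_run_cpp(pos0, dir0, radii, kind, par)
  set.seed(31)
  dir0b <- t(vapply(1:4, function(i) random_unit_vector(), numeric(3)))
  res_ref <- ref_sim(pos0, dir0b, radii, kind, par)
  expect_identical(dim(res_cpp$pos), c(3L, 4L, 21L))
  for (s in c(1, 5, 21)) {
    expect_identical(t(res_cpp$pos[, , s]), res_ref$pos[, , s])
  }

  # single contact pair plus a passive object: exercises repulsion and the
  # object brute-force path with an unambiguous summation order
  pos0 <- matrix(c(0, 0, 0, 5.8, 0, 0, 5.8, 0.7, 0), 3, 3, byrow = TRUE)
  radii <- c(5, 1, 0.8)
  kind <- c(0L, 1L, 1L)
  par <- ref_par(v0 = 1, n_steps = 100L, record_every = 5L, dt = 0.002,
                 gradient_on = FALSE, tau_const = 1e6)
  set.seed(8)
  dir0 <- matrix(rep(c(1, 0, 0), 3), 3, 3, byrow = TRUE)
  res_cpp <- oocenter:::.sim_run_cpp(pos0, dir0, radii, kind, par)
  set.seed(8)
  res_ref <- ref_sim(pos0, dir0, radii, kind, par)
  # force arithmetic may be contracted (FMA) by the compiler: agreement to
  # near machine precision rather than bit identity on the contact path
  expect_equal(t(res_cpp$pos[, , 21]), res_ref$pos[, , 21],
               tolerance = 1e-12)
})

test_that("contact forces are equal and opposite: friction-weighted recoil", {
  # two overlapping vesicles, no propulsion, no cortex contact: they relax
  # apart with eta_i dx_i = -eta_j dx_j at every recorded step
  pos0 <- matrix(c(-0.4, 0, 0, 0.4, 0, 0), 2, 3, byrow = TRUE)
  radii <- c(0.5, 1.0)
  par <- ref_par(v0 = 0, n_steps = 400L, record_every = 20L,
                 gradient_on = FALSE, tau_const = 1e6, c_r = 20)
  set.seed(2)
  dir0 <- matrix(c(1, 0, 0, -1, 0, 0), 2, 3, byrow = TRUE)
  res <- oocenter:::.sim_run_cpp(pos0, dir0, radii, c(1L, 1L), par)
  eta <- 6 * pi * radii * par$gamma
  x1 <- res$pos[1, 1, ]
  x2 <- res$pos[1, 2, ]
  expect_true(all(diff(x1) <= 0))  # pushed apart until contact is lost
  expect_true(all(diff(x2) >= 0))
  expect_lt(x1[3], x1[1])          # and they did move
  expect_equal(eta[1] * diff(x1), -eta[2] * diff(x2), tolerance = 1e-12)
  expect_equal(res$pos[2, , ], matrix(0, 2, 21))  # purely axial
})

test_that("doubling c_r halves the steady head-on compression overlap", {
  # two motile vesicles driven into each other with frozen headings
  overlap_at <- function(c_r) {
    pos0 <- matrix(c(-1, 0, 0, 1, 0, 0), 2, 3, byrow = TRUE)
    dir0 <- matrix(c(1, 0, 0, -1, 0, 0), 2, 3, byrow = TRUE)
    par <- ref_par(v0 = 5, n_steps = 2000L, record_every = 100L,
                   gradient_on = FALSE, tau_const = 1e9, c_r = c_r,
                   dt = 5e-4)
    set.seed(4)
    res <- oocenter:::.sim_run_cpp(pos0, dir0, c(0.5, 0.5), c(1L, 1L), par)
    gap <- res$pos[1, 2, 17:21] - res$pos[1, 1, 17:21]
    mean(1 - gap)  # steady overlap relative to d_eq = 1
  }
  o1 <- overlap_at(40)
  o2 <- overlap_at(80)
  expect_gt(o1, 0)
  expect_equal(o1 / o2, 2, tolerance = 0.05)
  # and the steady force balance is quantitative: overlap = eta v0 / c_r
  eta <- 6 * pi * 0.5 / 60
  expect_equal(o1, eta * 5 / 40, tolerance = 0.05)
})

test_that("free persistent vesicles reach the closed-form diffusivity", {
  # long-time MSD slope of a persistent random walk: 6 D t with
  # D = v0^2 tau / 3 in 3D, checked at three persistence times
  for (tau in c(0.5, 2, 8)) {
    n <- 24
    set.seed(1000 + tau * 10)
    pos0 <- matrix(runif(3 * n, -20, 20), n, 3)
    dir0 <- t(vapply(seq_len(n), function(i) random_unit_vector(), numeric(3)))
    par <- ref_par(v0 = 1, oocyte_radius = 500, gradient_on = FALSE,
                   tau_const = tau, dt = 0.01,
                   n_steps = as.integer(50 * tau / 0.01),
                   record_every = as.integer(tau / 0.01))
    res <- oocenter:::.sim_run_cpp(pos0, dir0, rep(0.5, n), rep(1L, n), par)
    curves <- lapply(seq_len(n), function(i) {
      tr <- data.frame(time_min = res$time, x_um = res$pos[1, i, ],
                       y_um = res$pos[2, i, ], z_um = res$pos[3, i, ])
      msd(tr, dimensionality = 3)
    })
    lags <- curves[[1]]$lag_min
    mean_msd <- rowMeans(vapply(curves, function(cv) cv$msd_um2,
                                numeric(length(lags))))
    sel <- lags >= 5 * tau & lags <= 25 * tau
    slope <- coef(lm(mean_msd[sel] ~ lags[sel]))[[2]]
    D_emp <- slope / 6
    expect_equal(D_emp, tau / 3, tolerance = 0.15)
  }
})

test_that("the automatic stability check halves dt on stiff contacts", {
  cfg <- simulation_config(n_vesicles = 60, oocyte_radius = 4,
                           object_radius = 0, duration = 2, v0 = 2,
                           c_r = 500, c_c = 500, dt = 0.01,
                           record_interval = 1, seed = 3, auto_dt = TRUE)
  expect_warning(ts <- run_simulation(cfg), "halved")
  r <- sqrt(ts$records$x_um^2 + ts$records$y_um^2 + ts$records$z_um^2)
  expect_true(all(r + ts$records$radius_um <= 4 + 0.2 * ts$records$radius_um))
})

test_that("speed calibration recovers a known v0 from its own profile", {
  base <- simulation_config(n_vesicles = 150, object_radius = 0,
                            duration = 80, seed = 17)
  truth <- base
  truth$v0 <- 20
  target_ts <- run_simulation(truth)
  prof <- squared_velocity_profile(target_ts, window = c(30, 60))
  target <- data.frame(distance_um = prof$distance_um,
                       v2_um2_min2 = prof$v2_mean)
  fit <- calibrate_speed(base, target, bracket = c(8, 32), tol = 0.02)
  expect_equal(fit$v0, 20, tolerance = 0.10)
  # degenerate target: lower bound with a warning
  expect_warning(z <- calibrate_speed(base,
      data.frame(distance_um = c(10, 20), v2_um2_min2 = c(0, 0)),
      bracket = c(8, 32)), "zero")
  expect_equal(z$v0, 8)
})

test_that("replicate runner derives distinct deterministic seeds", {
  cfg <- simulation_config(n_vesicles = 10, duration = 5, seed = 50)
  reps <- run_ensemble(cfg, 3, record = "object")
  expect_length(reps, 3)
  expect_equal(vapply(reps, function(x) x$seed, integer(1)), 50:52)
  again <- run_ensemble(cfg, 3, record = "object")
  expect_identical(reps[[2]]$records, again[[2]]$records)
})
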