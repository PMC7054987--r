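test_that("displacement classification is exact on the axes", {
  start <- c(10, 0)
  expect_equal(classify_displacement(c(-1, 0), start), "toward_center")
  expect_equal(classify_displacement(c(1, 0), start), "toward_cortex")
  expect_equal(classify_displacement(c(0, 1), start), "not_directional")
  expect_equal(classify_displacement(c(0, 0), start), "not_directional")
  expect_error(classify_displacement(c(1, 0), c(0, 0)), "center")
  # literal angular bounds remain available
  expect_equal(classify_displacement(c(-1, 0.1), start,
                                     convention = "literal"), "toward_center")
  expect_equal(classify_displacement(c(0.2, 1), start,
                                     convention = "literal"), "toward_cortex")
})

test_that("isotropic displacements fall in each class with probability 1/3", {
  # planar walk with isotropic steps taken far from the center, so the
  # radial axis is effectively constant across displacements
  set.seed(55)
  n <- 1e6
  th <- runif(n, 0, 2 * pi)
  x <- 1e7 + c(0, cumsum(cos(th)))
  y <- c(0, cumsum(sin(th)))
  tr <- make_track(x = x, y = y)
  f_ctr <- cumulative_bias(list(tr), time_step = 1)
  f_cor <- cumulative_bias(list(tr), time_step = 1,
                           direction = "toward_cortex")
  expect_equal(as.numeric(f_ctr), 1 / 3, tolerance = 0.002 * 3)
  expect_equal(as.numeric(f_cor), 1 / 3, tolerance = 0.002 * 3)
  expect_lt(abs(as.numeric(f_ctr) - 1 / 3), 0.002)
  expect_lt(abs(as.numeric(f_cor) - 1 / 3), 0.002)
  # the three fractions always sum to exactly one
  counts <- attr(f_ctr, "counts")
  expect_equal(sum(counts) , attr(f_ctr, "n_displacements"))
  expect_equal(sum(counts / sum(counts)), 1)

  # under the literal +/-30 / +/-60 degree bounds the same isotropic data
  # are NOT equiprobable (1/6 center, 2/3 cortex in the plane)
  f_lit_ctr <- cumulative_bias(list(tr), 1, convention = "literal")
  f_lit_cor <- cumulative_bias(list(tr), 1, direction = "toward_cortex",
                               convention = "literal")
  expect_equal(as.numeric(f_lit_ctr), 1 / 6, tolerance = 0.02)
  expect_equal(as.numeric(f_lit_cor), 2 / 3, tolerance = 0.02)
})

test_that("cumulative bias responds to drift in the expected direction", {
  tr <- make_track(x = seq(100, 50, by = -1), y = 0)
  expect_equal(as.numeric(cumulative_bias(list(tr), 1)), 1)
  # drifted walk: toward_center above 1/3, toward_cortex below
  spec <- walk_spec("biased_radial", D = 0.05, drift = 1.2, duration = 40,
                    frame_interval = 0.2, start = c(500, 0), n_tracks = 5,
                    seed = 10)
  ts <- gen_biased_radial(spec)
  f_ctr <- as.numeric(cumulative_bias(ts, 0.2))
  f_cor <- as.numeric(cumulative_bias(ts, 0.2, direction = "toward_cortex"))
  expect_gt(f_ctr, 1 / 3 + 0.1)
  expect_lt(f_cor, 1 / 3 - 0.1)
  expect_error(cumulative_bias(ts, 0.3), "multiple")
})

test_that("the Brownian null ensemble is reproducible and unbiased", {
  null <- build_null(D = 0.072, duration = 4, frame_interval = 1 / 120,
                     time_steps = c(1, 4) / 120, start_radius = 15,
                     n_sims = 150, seed = 3)
  null2 <- build_null(D = 0.072, duration = 4, frame_interval = 1 / 120,
                      time_steps = c(1, 4) / 120, start_radius = 15,
                      n_sims = 150, seed = 3)
  expect_identical(null$bias, null2$bias)
  expect_equal(dim(null$bias), c(150, 2, 2))
  # ensemble mean bias ~ 1/3 per class at every step
  for (j in 1:2) for (k in 1:2) {
    expect_equal(mean(null$bias[, j, k]), 1 / 3, tolerance = 0.05)
  }
  n1 <- build_null(D = 0.072, duration = 1, frame_interval = 1 / 120,
                   time_steps = 1 / 120, n_sims = 1, seed = 9)
  expect_equal(dim(n1$bias)[1], 1)
})

test_that("bootstrap CI behaves: degeneracy, width, containment of 1/3", {
  null <- build_null(D = 0.072, duration = 4, frame_interval = 1 / 120,
                     time_steps = 1 / 120, start_radius = 15,
                     n_sims = 300, seed = 5)
  # a wider sample narrows the interval
  ci5 <- bootstrap_ci(null, 5, n_boot = 2000, seed = 1)
  ci29 <- bootstrap_ci(null, 29, n_boot = 2000, seed = 1)
  expect_lt(diff(ci29), diff(ci5))
  # the null interval always contains the isotropic expectation
  expect_lt(ci29[["ci_low"]], 1 / 3)
  expect_gt(ci29[["ci_high"]], 1 / 3)
  expect_error(bootstrap_ci(null, 400), "exceeds")

  # degenerate ensemble: CI collapses onto the common value
  fake <- null
  fake$bias[, 1, "toward_center"] <- 0.4
  fake$counts[, 1, "toward_center"] <- 40          # of 100 displacements each
  ci <- bootstrap_ci(fake, 10, n_boot = 200, seed = 2)
  expect_equal(unname(ci), c(0.4, 0.4), tolerance = 1e-12)
})

test_that("null coverage: Brownian tracks rarely flagged as biased", {
  # replicate experiments of 8 Brownian objects tested against the null at
  # the 99% two-tail interval: the flag rate per direction stays small
  null <- build_null(D = 0.1, duration = 4, frame_interval = 1 / 120,
                     time_steps = 5 / 120, start_radius = 12,
                     n_sims = 250, seed = 17)
  flags <- 0L
  n_rep <- 60
  for (s in seq_len(n_rep)) {
    ts <- gen_brownian(walk_spec("brownian", D = 0.1, duration = 4,
                                 frame_interval = 1 / 120,
                                 start = c(12, 0), n_tracks = 8,
                                 seed = 7000 + s))
    f <- cumulative_bias(ts, 5 / 120)
    ci <- bootstrap_ci(null, 8, time_step = 5 / 120, n_boot = 400,
                       seed = s)
    flags <- flags + (f < ci[["ci_low"]] || f > ci[["ci_high"]])
  }
  # nominal 2% two-tail rate; allow binomial spread on 60 replicates
  expect_lte(flags, 6)
})

test_that("bias_test flags advected droplets but not Brownian ones", {
  drift_ts <- gen_biased_radial(walk_spec("biased_radial", D = 0.05,
                                          drift = 0.8, duration = 4,
                                          frame_interval = 1 / 120,
                                          start = c(20, 0), n_tracks = 10,
                                          seed = 12))
  rep_ <- bias_test(drift_ts, time_steps = c(2, 10) / 120,
                    null_args = list(D = 0.05, start_radius = 20,
                                     n_sims = 200),
                    n_boot = 1000, seed = 4)
  expect_equal(nrow(rep_), 4)
  ctr <- rep_[rep_$direction == "toward_center", ]
  cor_ <- rep_[rep_$direction == "toward_cortex", ]
  expect_true(all(ctr$significant))
  expect_true(all(ctr$fraction > ctr$ci_high))
  expect_true(all(!cor_$significant | cor_$fraction < cor_$ci_low))

  brown_ts <- gen_brownian(walk_spec("brownian", D = 0.05, duration = 4,
                                     frame_interval = 1 / 120,
                                     start = c(20, 0), n_tracks = 10,
                                     seed = 13))
  rep_b <- bias_test(brown_ts, time_steps = c(2, 10) / 120,
                     null_args = list(D = 0.05, start_radius = 20,
                                      n_sims = 200),
                     n_boot = 1000, seed = 4)
  expect_lte(sum(rep_b$significant), 1)
  expect_error(bias_test(track_set(drift_ts$records[0, ], 1 / 120), 1 / 120),
               "empty|nonempty|no tracks")
})

test_that("bias statistics are invariant under global rotation", {
  spec <- walk_spec("biased_radial", D = 0.05, drift = 0.5, duration = 4,
                    frame_interval = 1 / 120, start = c(15, 0), n_tracks = 4,
                    seed = 23)
  ts <- gen_biased_radial(spec)
  th <- 1.1
  rot <- ts
  x <- cos(th) * ts$records$x_um - sin(th) * ts$records$y_um
  y <- sin(th) * ts$records$x_um + cos(th) * ts$records$y_um
  rot$records$x_um <- x
  rot$records$y_um <- y
  f1 <- cumulative_bias(ts, 5 / 120)
  f2 <- cumulative_bias(rot, 5 / 120)
  expect_equal(as.numeric(f1), as.numeric(f2))
  expect_identical(attr(f1, "counts"), attr(f2, "counts"))
  # the radial-velocity statistic is rotation-invariant too
  m1 <- mean_instantaneous_radial_velocity(ts, lag = 5)
  m2 <- mean_instantaneous_radial_velocity(rot, lag = 5)
  expect_equal(m1$mean_velocity, m2$mean_velocity, tolerance = 1e-10)
})
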