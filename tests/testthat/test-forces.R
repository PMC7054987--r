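test_that("Stokes friction follows 6 pi r gamma and rejects bad input", {
  expect_equal(stokes_friction(0.5, 1), 3 * pi)
  expect_equal(stokes_friction(2, 0.5) / stokes_friction(1, 0.5), 2)
  expect_error(stokes_friction(0, 1), "radius")
  expect_error(stokes_friction(1, -1), "gamma")
})

test_that("persistence time matches both gradient forms and is monotone", {
  # tau at the center is the minimal persistence time in either form
  expect_equal(persistence_time(0, 0.001, 0.25, "additive"), 0.001)
  expect_equal(persistence_time(0, 0.001, 0.25, "multiplicative"), 0.001)
  expect_equal(persistence_time(35, 0.001, 0.25, "additive"), 8.751)
  expect_equal(persistence_time(35, 0.001, 0.25, "multiplicative"), 0.00975)
  r <- seq(0, 35, by = 0.5)
  for (form in c("additive", "multiplicative")) {
    expect_true(all(diff(persistence_time(r, 0.001, 0.25, form)) > 0))
  }
  expect_error(persistence_time(-1, 0.001, 0.25), ">= 0")
})

test_that("pair repulsion is linear in overlap, equal and opposite", {
  z <- c(0, 0, 0)
  # contact boundary and beyond: no force
  f <- pair_repulsion(z, c(2, 0, 0), 1, 1, c_r = 10)
  expect_equal(f$force_i, z)
  expect_equal(f$force_j, z)
  expect_equal(pair_repulsion(z, c(4, 0, 0), 1, 1, 10)$force_j, z)
  # half overlap: magnitude c_r / 2 on each, antiparallel along the axis
  f <- pair_repulsion(z, c(1, 0, 0), 1, 1, c_r = 10)
  expect_equal(f$force_j, c(5, 0, 0))
  expect_equal(f$force_i, -f$force_j)
  # off-axis direction
  f <- pair_repulsion(c(1, 1, 0), c(1 + sqrt(0.5), 1 + sqrt(0.5), 0), 1, 1, 10)
  expect_equal(sqrt(sum(f$force_j^2)), 5)
  expect_equal(f$force_j[1], f$force_j[2])
  expect_error(pair_repulsion(z, z, 1, 1, 10), "coincident")
})

test_that("cortex confinement activates at touch and points inward", {
  # gap equal to the radius: exactly zero
  expect_equal(cortex_confinement(c(34, 0, 0), 1, 35, 100), c(0, 0, 0))
  # gap = radius/2, exponent 2: magnitude c_c / 4
  f <- cortex_confinement(c(34.5, 0, 0), 1, 35, 100, exponent = 2)
  expect_equal(f, c(-25, 0, 0))
  # exponent 1 reduces to the pair-repulsion form: magnitude c_c / 2
  f <- cortex_confinement(c(34.5, 0, 0), 1, 35, 100, exponent = 1)
  expect_equal(f, c(-50, 0, 0))
  expect_error(cortex_confinement(c(36, 0, 0), 1, 35, 100), "outside")
  expect_warning(f <- cortex_confinement(c(36, 0, 0), 1, 35, 100,
                                         outside = "clamp"), "clamped")
  expect_true(f[1] < -100)  # deeper than full overlap: stronger than c_c
})

test_that("heading redraw has the right probability and limits", {
  set.seed(1)
  d0 <- c(1, 0, 0)
  # dt >= tau redraws every step under the linear model
  out <- replicate(20, maybe_redraw_direction(d0, tau = 0.01, dt = 1,
                                              model = "linear")[1])
  expect_false(any(out == 1))  # redrawn direction lands on x = 1 w.p. 0
  # infinite tau never redraws
  expect_identical(maybe_redraw_direction(d0, tau = Inf, dt = 1), d0)
  # empirical redraw frequency at p = dt/tau = 0.01
  set.seed(42)
  n <- 5e4
  hits <- sum(vapply(seq_len(n), function(i) {
    !identical(maybe_redraw_direction(d0, tau = 1, dt = 0.01), d0)
  }, logical(1)))
  p_hat <- hits / n
  expect_lt(abs(p_hat - 0.01), 3 * sqrt(0.01 * 0.99 / n))
  expect_error(maybe_redraw_direction(d0, tau = 0, dt = 1), "tau")
})

test_that("redrawn directions are uniform on the unit sphere", {
  set.seed(7)
  m <- t(replicate(4000, random_unit_vector()))
  expect_equal(rowSums(m^2), rep(1, 4000), tolerance = 1e-12)
  # each component has mean 0 and variance 1/3
  expect_lt(max(abs(colMeans(m))), 3 / sqrt(3 * 4000))
  expect_equal(unname(apply(m, 2, var)), rep(1 / 3, 3), tolerance = 0.05)
})

test_that("velocity balance divides force by friction and adds propulsion", {
  # free motile agent moves at exactly v0 along its heading
  v <- compute_velocity(c(0, 0, 0), radius = 0.5, gamma = 1 / 60, v0 = 2,
                        direction = c(0, 1, 0))
  expect_equal(v, c(0, 2, 0))
  # free passive object does not move
  expect_equal(compute_velocity(c(0, 0, 0), 12.5, 1 / 60, motile = FALSE),
               c(0, 0, 0))
  # same force, radii 1 and 2: force-term speeds in ratio 2:1
  f <- c(3, 0, 0)
  v1 <- compute_velocity(f, 1, 1 / 60, motile = FALSE)
  v2 <- compute_velocity(f, 2, 1 / 60, motile = FALSE)
  expect_equal(v1[1] / v2[1], 2)
})

test_that("two-step integrator is exact on constant velocity", {
  x <- c(1, 2, 3)
  v <- c(0.5, -1, 0)
  expect_equal(ab2_step(x, v, v, dt = 0.2), x + 0.2 * v)
  # first step falls back to Euler
  expect_equal(ab2_step(x, v, NULL, dt = 0.2), x + 0.2 * v)
  # v_prev = 0 weights the current velocity 3/2
  expect_equal(ab2_step(x, v, c(0, 0, 0), dt = 0.2), x + 0.3 * v)
  expect_equal(ab2_step(x, v, v, dt = 1e-12), x, tolerance = 1e-9)
  expect_error(ab2_step(x, v, v, dt = 0), "dt")
})

test_that("neighbor index is a superset of overlapping pairs", {
  set.seed(3)
  n <- 50
  pos <- matrix(runif(3 * n, -10, 10), n, 3)
  radii <- runif(n, 0.5, 1.2)
  rng <- 2 * max(radii)
  cand <- build_neighbor_index(pos, rng)
  # brute-force truth
  overlaps <- list()
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    if (sum((pos[i, ] - pos[j, ])^2) < (radii[i] + radii[j])^2) {
      overlaps[[length(overlaps) + 1]] <- c(i, j)
    }
  }
  ov <- do.call(rbind, overlaps)
  key <- function(m) paste(m[, 1], m[, 2])
  expect_gt(nrow(ov), 0)          # the fixture does contain contacts
  expect_true(all(key(ov) %in% key(cand)))
  # nothing farther than the interaction range is returned
  d2 <- rowSums((pos[cand[, 1], , drop = FALSE] -
                   pos[cand[, 2], , drop = FALSE])^2)
  expect_true(all(d2 <= rng^2 + 1e-12))
  # degenerate inputs
  expect_equal(nrow(build_neighbor_index(pos[1, , drop = FALSE], rng)), 0)
  far <- matrix(c(0, 0, 0, 100, 0, 0), 2, 3, byrow = TRUE)
  expect_equal(nrow(build_neighbor_index(far, rng)), 0)
})
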