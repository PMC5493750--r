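test_that("order parameter vanishes exactly on aligned states and is invariant", {
  lanes <- make_fixture("two_lane_perfect", N = 40)
  expect_equal(order_parameter(lanes), 0)
  p <- model_params(B = 2, Lx = 40, Ly = 20, seed = 3)
  st <- init_random(50, p)
  # hand value: mean sin^2 deviation from the preferred directions
  Th <- ifelse(st$species == "right", 0, pi)
  expect_equal(order_parameter(st), mean(sin(st$theta - Th)^2))
  expect_lte(order_parameter(st), 1)
  # invariance under global translation
  shift <- particle_state(st$x + 3.3, st$y + 1.2, st$theta, st$species,
                          st$radii, p)
  expect_equal(order_parameter(shift), order_parameter(st))
  # invariance under species exchange + rotation by pi
  flip <- particle_state(st$x, st$y, st$theta + pi,
                         ifelse(st$species == "right", "left", "right"),
                         st$radii, p)
  expect_equal(order_parameter(flip), order_parameter(st))
})

test_that("connected fluctuations subtract the plateau", {
  s <- observable_series(1:100, rep(0.3, 100), burn_in = 1)
  expect_equal(as.numeric(w_fluctuations(s, plateau = 0)), 0)
  set.seed(1)
  v <- rnorm(4000, 0, 0.2)
  s2 <- observable_series(1:4000, v, burn_in = 1)
  expect_equal(as.numeric(w_fluctuations(s2, plateau = 0.01)),
               var(v) - 0.01)
})

test_that("correlation time recovers known scales", {
  # white noise: of the order of the sampling interval
  set.seed(2)
  s <- observable_series(1:2000, rnorm(2000), burn_in = 1)
  expect_lt(correlation_time(s), 2)
  # exponentially correlated series, several realizations within 10%
  for (seed in 1:3) {
    est <- correlation_time(ou_series(5e5, tau = 50, seed = seed))
    expect_lt(abs(est - 50) / 50, 0.10)
  }
  expect_error(correlation_time(observable_series(1:100, rep(1, 100))),
               "constant")
  # non-stationary drift
  expect_error(correlation_time(observable_series(1:500, seq(0, 1,
                                                  length.out = 500))),
               "non-decaying|non-stationary")
})

test_that("density fields conserve mass and resolve lanes", {
  p <- model_params(B = 2, Lx = 48, Ly = 24, seed = 5)
  one <- make_fixture("single_right", params = p)
  f1 <- density_fields(one, bin = 6)
  expect_equal(sum(f1$drho > 0), 1)
  st <- init_random(400, p)
  f <- density_fields(st, bin = 6)
  expect_equal(sum(f$rho_right) * f$bin_x * f$bin_y, 200)
  expect_equal(sum(f$rho_left) * f$bin_x * f$bin_y, 200)
  lanes <- make_fixture("two_lane_perfect", N = 400, params = p)
  fl <- density_fields(lanes, bin = 6)
  expect_true(all(abs(fl$drho) > 0))
  expect_equal(as.character(laning_classifier(fl)), "lane")
  expect_equal(as.character(laning_classifier(f)), "mingled")
})

test_that("orientational diffusivity recovers a known rotational diffusion", {
  # synthetic free angular random walk, D_r = 0.15
  set.seed(8)
  n_part <- 150; n_fr <- 400; dtf <- 0.2; Dr <- 0.15
  th <- matrix(0, n_part, n_fr)
  for (f in 2:n_fr)
    th[, f] <- th[, f - 1] + rnorm(n_part, 0, sqrt(2 * Dr * dtf))
  traj <- list(times = (1:n_fr) * dtf, theta = th,
               species = rep(c("right", "left"), n_part / 2))
  class(traj) <- "lane_traj"
  est <- orientational_diffusivity(traj)
  expect_equal(as.numeric(est), Dr, tolerance = 0.15)
  # frozen orientations
  frozen <- traj; frozen$theta <- matrix(1, n_part, n_fr)
  expect_equal(as.numeric(orientational_diffusivity(frozen)), 0)
  # pinned, barely fluctuating orientations (laned state) are undefined
  pinned <- traj
  pinned$theta <- matrix(rnorm(n_part * n_fr, 0, 0.01), n_part, n_fr)
  expect_error(orientational_diffusivity(pinned), "barely decays")
})

test_that("displacement scaling is ballistic for a free mover", {
  p <- model_params(B = 2, Lx = 40, Ly = 20, seed = 3)
  # two non-interacting particles moving along their orientations
  st <- particle_state(x = c(5, 30), y = c(5, 15), theta = c(0, pi),
                       species = c("right", "left"), radii = c(1, 1),
                       params = p)
  tr <- run_simulation(st, steps = 4000, save_every = 40)
  ds <- displacement_scaling(tr)
  # deterministic straight lines: zero transverse spread, linear drift
  expect_true(all(ds$table$sd_y < 1e-10))
  expect_equal(ds$drift_speed, 1, tolerance = 1e-6)
})
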