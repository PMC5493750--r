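p_box <- model_params(B = 5, Lx = 40, Ly = 20, seed = 1)

test_that("pair torque matches its angular-energy definition", {
  # equilibrium: pointing exactly away from the partner
  expect_equal(pair_torque(0, c(3, 5), c(1, 5), 1, 1, p_box), 0)
  # out of range: zero regardless of angles
  expect_equal(pair_torque(1.1, c(10, 5), c(5, 5), 1, 1.4, p_box), 0)
  # value fixed by the derivative of the angular energy:
  # B = 5, a_i = a_j = 1, r = 1, theta - phi = pi/2 -> -5 * (1 - 1/2) * 1
  expect_equal(pair_torque(pi / 2, c(1, 0) + c(2, 3), c(2, 3), 1, 1, p_box),
               -2.5)
  # numeric-derivative oracle of U = -B(r) cos(theta - phi) at general angle
  th <- 0.7; r_i <- c(4, 6); r_j <- c(3.2, 5.1)
  U <- function(th) {
    d <- r_i - r_j; r <- sqrt(sum(d^2))
    -p_box$B * (1 - r / 2.4) * cos(th - atan2(d[2], d[1]))
  }
  h <- 1e-6
  expect_equal(pair_torque(th, r_i, r_j, 1, 1.4, p_box),
               -(U(th + h) - U(th - h)) / (2 * h), tolerance = 1e-8)
  # torque magnitude bounded by the kernel
  expect_lte(abs(pair_torque(2.2, r_i, r_j, 1, 1.4, p_box)),
             p_box$B * (1 - sqrt(sum((r_i - r_j)^2)) / 2.4))
  expect_error(pair_torque(0, c(1, 1), c(1, 1), 1, 1, p_box), "degenerate")
})

test_that("drive torque restores the preferred direction", {
  expect_equal(drive_torque(0, "right", p_box), 0)
  expect_equal(drive_torque(pi, "left", p_box), 0)
  expect_equal(drive_torque(pi / 2, "right", p_box), -1)
  # numeric derivative of the harmonic angular potential -H cos(theta - Theta)
  V <- function(th) -p_box$H * cos(th - pi)
  h <- 1e-6
  expect_equal(drive_torque(2.1, "left", p_box),
               -(V(2.1 + h) - V(2.1 - h)) / (2 * h), tolerance = 1e-8)
  # restoring sign
  expect_lt(drive_torque(0.3, "right", p_box), 0)
  expect_gt(drive_torque(-0.3, "right", p_box), 0)
})

test_that("sweep-and-prune equals the brute-force neighbour scan", {
  # wrap-around pair across the periodic seam
  st <- particle_state(x = c(0.1, 39.9), y = c(5, 5), theta = c(0, pi),
                       species = c("right", "left"), radii = c(1, 1.4),
                       params = p_box)
  expect_equal(nrow(neighbor_pairs(st)), 1)
  # distant pair
  st2 <- particle_state(x = c(5, 10), y = c(5, 5), theta = c(0, pi),
                        species = c("right", "left"), radii = c(1, 1.4),
                        params = p_box)
  expect_equal(nrow(neighbor_pairs(st2)), 0)
  # randomized configurations at several sizes and densities
  set.seed(42)
  for (rep in 1:25) {
    n <- sample(c(20, 100, 400), 1)
    Lx <- sample(c(12, 40, 80), 1)
    p <- model_params(B = 2, Lx = Lx, Ly = Lx / 2, seed = rep)
    st <- init_random(n, p)
    got <- neighbor_pairs(st)
    want <- brute_force_pairs(st$x, st$y, st$radii, p$Lx, p$Ly)
    expect_identical(got[order(got[, 1], got[, 2]), , drop = FALSE],
                     matrix(as.integer(want), ncol = 2),
                     label = sprintf("rep %d n %d Lx %d", rep, n, Lx))
  }
})

test_that("euler_step advances ballistically and matches a scalar oracle", {
  one <- make_fixture("single_right", params = p_box)
  new <- euler_step(one)
  expect_equal(new$x, one$x + p_box$v0 * p_box$dt)
  expect_equal(new$y, one$y)
  expect_equal(new$theta, 0)
  # two interacting particles against an independent scalar implementation
  st <- particle_state(x = c(5, 6.5), y = c(5, 5.8), theta = c(0.3, 2.5),
                       species = c("right", "left"), radii = c(1, 1.4),
                       params = p_box)
  new2 <- euler_step(st)
  x <- st$x; y <- st$y; th <- st$theta; Th <- c(0, pi); a <- st$radii
  Tq <- numeric(2)
  for (i in 1:2) {
    j <- 3 - i
    dx <- x[i] - x[j]; dx <- dx - 40 * round(dx / 40)
    dy <- y[i] - y[j]; dy <- dy - 20 * round(dy / 20)
    r <- sqrt(dx^2 + dy^2)
    if (r < a[i] + a[j])
      Tq[i] <- -p_box$B * (1 - r / (a[i] + a[j])) *
        sin(th[i] - atan2(dy, dx))
  }
  expect_equal(new2$x, (x + cos(th) * 0.01) %% 40)
  expect_equal(new2$y, (y + sin(th) * 0.01) %% 20)
  expect_equal(new2$theta, th + 0.01 * (-sin(th - Th) + Tq))
})

test_that("speeds stay exactly v0 and populations are conserved", {
  p <- model_params(B = 4, Lx = 30, Ly = 15, seed = 9)
  st <- init_random(60, p)
  tr <- run_simulation(st, steps = 50, save_every = 1)
  expect_equal(tr$state$species, st$species)
  # per-step displacement has modulus exactly v0 dt for every particle
  step_d <- sqrt(t(diff(t(tr$x_unwrapped)))^2 + t(diff(t(tr$y_unwrapped)))^2)
  expect_equal(as.vector(step_d), rep(p$v0 * p$dt, length(step_d)),
               tolerance = 1e-12)
  expect_true(all(tr$state$x >= 0 & tr$state$x < p$Lx))
  expect_true(all(tr$state$y >= 0 & tr$state$y < p$Ly))
})

test_that("trajectories respect the species-exchange point symmetry", {
  p <- model_params(B = 3, Lx = 40, Ly = 20, seed = 12)
  st <- init_random(100, p)
  tr1 <- run_simulation(st, steps = 500, w_every = 5)
  flip <- particle_state(x = (-st$x) %% p$Lx, y = (-st$y) %% p$Ly,
                         theta = st$theta + pi,
                         species = ifelse(st$species == "right",
                                          "left", "right"),
                         radii = st$radii, params = p)
  tr2 <- run_simulation(flip, steps = 500, w_every = 5)
  expect_equal(tr1$W$values, tr2$W$values, tolerance = 1e-10)
})

test_that("without repulsion all orientations relax monotonically to the drive", {
  p0 <- suppressWarnings(model_params(B = 0, Lx = 40, Ly = 20, seed = 2))
  st <- init_random(50, p0)
  dev <- abs(wrap_angle(st$theta - preferred_angle(st)))
  for (k in 1:40) {
    st <- euler_step(st)
    dev_new <- abs(wrap_angle(st$theta - preferred_angle(st)))
    expect_true(all(dev_new <= dev + 1e-12))
    dev <- dev_new
  }
  # after a few drive times the trivially laned limit is nearly reached
  relax <- run_simulation(st, steps = 1000)$state
  expect_lt(order_parameter(relax), 0.05)
})
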