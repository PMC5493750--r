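test_that("pair correlations are flat for uncorrelated configurations", {
  p <- model_params(B = 5, Lx = 60, Ly = 30, seed = 8)
  st <- init_random(2000, p)
  g <- pair_correlations(st, xmax = 10, ymax = 5, bin = 1)
  expect_true(all(abs(colMeans(g$all$values) - 1) < 0.05))
  expect_lt(abs(mean(g$all$values) - 1), 0.01)
  expect_true(all(g$all$values >= 0))
  # cross-species grids are mirror images by construction
  expect_equal(g$rl$values, g$lr$values[rev(seq_along(g$lr$x)),
                                        rev(seq_along(g$lr$y))])
})

test_that("the single-pair normalization matches the hand-computed factor", {
  p <- model_params(B = 5, Lx = 60, Ly = 30, seed = 8)
  st <- particle_state(x = c(10, 12.3), y = c(5, 5.4), theta = c(0, pi),
                       species = c("right", "left"), radii = c(1, 1.4),
                       params = p)
  g <- pair_correlations(st, xmax = 4, ymax = 4, bin = 1)
  # one displacement in one bin: g = A / (N_r * N_l * bin^2) * count
  expect_equal(sum(g$rl$values > 0), 1)
  expect_equal(max(g$rl$values), 60 * 30 / 1)
  expect_equal(sum(g$rr$counts), 0)
})

test_that("scaling collapse is exact for fields built with the scaling form", {
  xs <- seq(0.5, 40, by = 0.5); ys <- seq(-10, 9.5, by = 0.5)
  f <- function(u) exp(-u^2)
  vals <- 1 + outer(xs, ys, function(x, y) x^(-1.5) * f(y / sqrt(x)))
  grid <- correlation_grid(vals, xs, ys, pair = "synthetic")
  sc <- scaling_collapse(grid, x_slices = c(4, 8, 16, 32))
  expect_lt(sc$spread_relative, 0.02)
  # additive noise shows up as spread of the right order
  set.seed(3)
  noisy <- vals + matrix(rnorm(length(vals), 0, 1e-4), nrow(vals))
  gn <- correlation_grid(noisy, xs, ys, pair = "synthetic")
  scn <- scaling_collapse(gn, x_slices = c(4, 8, 16, 32))
  expect_gt(scn$spread, sc$spread)
  expect_lt(scn$spread, 50 * 1e-4 * 32^1.5)
  # a null rescaling collapses far worse
  null <- scaling_collapse(grid, x_slices = c(4, 8, 16, 32),
                           x_exponent = 1, y_exponent = 1)
  expect_gt(null$spread_relative, 5 * sc$spread_relative)
})

test_that("log-log slope fitting recovers planted exponents", {
  x <- seq(1, 100, by = 0.5)
  f <- fit_loglog_slope(x, 2.7 * x^(-1.5), x_range = c(2, 80))
  expect_equal(f$slope, -1.5, tolerance = 1e-10)
  expect_gt(f$r2, 0.999999)
})
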