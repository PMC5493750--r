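hp_coupled <- hydro_params(v = 1, Dx = 0.5, Dy = 0.5, Dtx = 0.2, Dty = 0.2,
                           kappa = 0.5, Tnoise = 1)

test_that("the structure factor has direction-dependent q -> 0 limits", {
  # closed-form axis limits from the Lyapunov solution
  eps <- 1e-5
  sfx <- structure_factor(hp_coupled, eps, 0)
  sfy <- structure_factor(hp_coupled, 0, eps)
  Sx <- sfx$S_rr[1, 1]; Sy <- sfy$S_rr[1, 1]
  expect_equal(Sx, sfx$a, tolerance = 1e-6)
  expect_equal(Sy, sfy$b, tolerance = 1e-6)
  # independent hand values of the two limits
  expect_equal(sfx$a, 1 * 1 / (0.5 * (1 - 0.5^2)), tolerance = 1e-12)
  expect_equal(sfy$b, 1 * 0.5 / (0.5^2 - 0.2^2), tolerance = 1e-12)
  expect_gt(abs(Sx - Sy), 0.1)  # finite gap between the two limits
  # with the coupling current off and isotropic diffusion the two
  # constants coincide and the spectrum is flat
  hp0 <- hydro_params(v = 1, Dx = 0.5, Dy = 0.5, Tnoise = 1)
  sf0 <- structure_factor(hp0, c(eps, 0.3, 1), c(0, 0.2, 0.7))
  expect_equal(sf0$a, sf0$b)
  vals <- sf0$S_rr[is.finite(sf0$S_rr)]
  expect_equal(vals, rep(2, length(vals)))  # T/D = 2 everywhere
})

test_that("auto-spectra are real, positive and inversion symmetric", {
  q <- seq(-1.5, 1.5, by = 0.25)
  sf <- structure_factor(hp_coupled, q, q)
  fin <- is.finite(sf$S_rr)
  expect_true(all(sf$S_rr[fin] > 0))
  expect_identical(sf$S_rr, sf$S_ll)
  # S(q) = S(-q)
  expect_equal(sf$S_rr, sf$S_rr[rev(seq_along(q)), rev(seq_along(q))])
  # destabilizing parameters are reported, naming the offending mode
  bad <- hydro_params(v = 0.1, Dx = 0.05, Dy = 0.05, Dtx = 0.3, Dty = 0.3,
                      kappa = 0.05)
  expect_error(structure_factor(bad, 0.5, 0.5), "unstable")
})

test_that("real-space correlations decay fast without coupling, slowly with", {
  hp0 <- hydro_params(v = 1, Dx = 0.5, Dy = 0.5, Tnoise = 1)
  g0 <- realspace_correlations(hp0, n = 256, L = 256)
  cut0 <- longitudinal_cut(g0)
  # flat (analytic) spectrum: no tail beyond transform ringing
  expect_true(all(abs(cut0$value[cut0$x >= 5] - 1) < 1e-4))
  g1 <- realspace_correlations(hp_coupled, n = 256, L = 256)
  cut1 <- longitudinal_cut(g1)
  expect_gt(max(abs(cut1$value[cut1$x >= 5 & cut1$x <= 40] - 1)), 1e-4)
})

test_that("kinetic closure rates scale linearly with the partner density", {
  p <- model_params(B = 5, Lx = 168)
  k0 <- kinetic_rates(p, 0)
  expect_equal(k0$collision_rate, 0)
  expect_equal(k0$nu_R, 0)
  expect_equal(k0$kappa, 0)   # coupling current vanishes with collisions
  expect_equal(k0$Dt, 0)
  expect_equal(k0$v, p$v0)    # free advection-relaxation only
  k1 <- kinetic_rates(p, 0.05); k2 <- kinetic_rates(p, 0.10)
  expect_equal(k2$collision_rate, 2 * k1$collision_rate)
  expect_equal(k2$nu_R, 2 * k1$nu_R)
  hp <- kinetic_coefficients(p, 0.07)
  expect_s3_class(hp, "hydro_params")
  comp <- attr(hp, "components")
  expect_named(comp, c("alignment", "pressure", "rotational_diffusivity"))
  expect_error(kinetic_coefficients(model_params(B = 0.8, Lx = 168), 0.07),
               "closure invalid")
  expect_error(kinetic_coefficients(p, 0.005), "laned-regime")
})
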