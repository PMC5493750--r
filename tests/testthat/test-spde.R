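test_that("the stochastic integrator conserves mass and is stable", {
  hp <- hydro_params(v = 0.6, Dx = 0.3, Dy = 0.3, Dtx = 0.1, Dty = 0.1,
                     kappa = 0.3, Tnoise = 1)
  res <- spde_integrate(hp, n = 16, L = 32, dt = 0.02, t_total = 40,
                        t_burn = 4, sample_every = 2L, seed = 2)
  # pinned q = 0 mode: global mass never fluctuates
  expect_equal(res$S_rr[1, 1], 0)
  expect_equal(res$S_ll[1, 1], 0)
  expect_true(all(is.finite(res$S_rr)))
  # noise-free relaxation from a random perturbation decays to nothing
  # (slowest mode rate Dx qmin^2 ~ 0.046, so t = 400 is ~18 decay times)
  hp0 <- hydro_params(v = 0.6, Dx = 0.3, Dy = 0.3, Dtx = 0.1, Dty = 0.1,
                      kappa = 0.3, Tnoise = 0)
  dec <- spde_integrate(hp0, n = 16, L = 16, dt = 0.02, t_total = 400,
                        t_burn = 0, sample_every = 10L, seed = 3,
                        init_amp = 1)
  expect_lt(dec$final_norm, 1e-4)
})

test_that("a decoupled anisotropic-diffusion species matches its closed form", {
  # independent oracle: conserved noise + pure anisotropic diffusion gives
  # S(q) = T q^2 / (Dx qx^2 + Dy qy^2)
  Tn <- 0.7; Dx <- 0.4; Dy <- 0.15
  hp <- hydro_params(v = 0, Dx = Dx, Dy = Dy, Tnoise = Tn)
  res <- spde_integrate(hp, n = 32, L = 32, dt = 0.01, t_total = 800,
                        t_burn = 100, sample_every = 5L, seed = 4)
  QX <- outer(res$qx, rep(1, 32)); QY <- outer(rep(1, 32), res$qy)
  Sref <- Tn * (QX^2 + QY^2) / (Dx * QX^2 + Dy * QY^2)
  live <- res$mask == 1
  z <- abs(res$S_rr - Sref) / res$se
  expect_lt(max(z[live]), 3)
  expect_lt(median(abs(res$S_rr / Sref - 1)[live]), 0.1)
})

test_that("anisotropic conserved noise changes amplitudes, not the scaling", {
  # on the scaling parabola qx ~ qy^2 the longitudinal noise component is
  # subleading, so the anisotropic-noise spectrum converges to the
  # isotropic one with T = Ty as qy -> 0: same non-analytic structure,
  # different amplitude elsewhere
  mk <- function(T_) hydro_params(v = 1, Dx = 0.5, Dy = 0.5, Dtx = 0.2,
                                  Dty = 0.2, kappa = 0.5, Tnoise = T_)
  hp_a <- mk(c(3, 0.5)); hp_i <- mk(0.5)
  dev_at <- function(qy) {
    qx <- seq(0.5, 3, by = 0.5) * qy^2
    Sa <- vapply(qx, function(q) structure_factor(hp_a, q, qy)$S_rr[1, 1],
                 numeric(1))
    Si <- vapply(qx, function(q) structure_factor(hp_i, q, qy)$S_rr[1, 1],
                 numeric(1))
    max(abs(Sa / Si - 1))
  }
  devs <- vapply(c(0.04, 0.02, 0.01), dev_at, numeric(1))
  expect_lt(devs[3], 0.005)
  expect_true(all(diff(devs) < 0))  # converging as qy -> 0
  # away from the parabola the amplitudes genuinely differ
  expect_gt(abs(structure_factor(hp_a, 0.5, 0)$S_rr[1, 1] /
                  structure_factor(hp_i, 0.5, 0)$S_rr[1, 1] - 1), 1)
})
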