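#' Coefficients of the linearized two-species hydrodynamics
#'
#' The mingled state is described by the two conserved density
#' fluctuation fields of the right and left movers, each advected along
#' its drive direction and relaxed by anisotropic diffusion, and coupled
#' to the other species through a current with two pieces: a
#' collision-suppressed longitudinal advection (amplitude `kappa`: a local
#' excess of partners slows the longitudinal current) and a
#' pressure-gradient cross-diffusion (diagonal tensor `Dtx`, `Dty`).
#' Fluctuations enter as conserved isotropic white noise of variance
#' `2 * Tnoise`.
#'
#' In Fourier space each mode pair obeys
#' `d(rho_+, rho_-)/dt = M (rho_+, rho_-) + noise` with
#' `M = [[-lambda, mu], [Conj(mu), -Conj(lambda)]]`,
#' `lambda = i v qx + Dx qx^2 + Dy qy^2` and
#' `mu = i kappa qx - (Dtx qx^2 + Dty qy^2)`.
#'
#' @param v advection speed along the drive.
#' @param Dx,Dy longitudinal/transverse self-diffusion (> 0).
#' @param Dtx,Dty cross-diffusion (pressure coupling) components.
#' @param kappa collision-suppressed advection coupling.
#' @param Tnoise conserved-noise variance parameter T; either a scalar
#'   (isotropic noise) or a length-2 vector `c(Tx, Ty)` for anisotropic
#'   conserved noise (the algebraic structure of the correlations does
#'   not depend on this anisotropy, only amplitudes do).
#' @param rho_right,rho_left mean densities (bookkeeping; the linear
#'   theory depends on them only through the coefficients).
#' @return object of class `hydro_params`.
#' @export
hydro_params <- function(v, Dx, Dy, Dtx = 0, Dty = 0, kappa = 0,
                         Tnoise = 1, rho_right = NA, rho_left = NA) {
  if (Dx <= 0 || Dy <= 0) stop("diffusivities Dx, Dy must be > 0")
  if (!length(Tnoise) %in% c(1, 2) || any(Tnoise < 0))
    stop("Tnoise must be a non-negative scalar or length-2 c(Tx, Ty)")
  Tnoise <- rep_len(as.numeric(Tnoise), 2)
  structure(list(v = v, Dx = Dx, Dy = Dy, Dtx = Dtx, Dty = Dty,
                 kappa = kappa, Tnoise = Tnoise,
                 rho_right = rho_right, rho_left = rho_left),
            class = "hydro_params")
}

#' @export
print.hydro_params <- function(x, ...) {
  cat("hydro_params: v =", x$v, " D = (", x$Dx, ",", x$Dy, ")",
      " Dt = (", x$Dtx, ",", x$Dty, ")  kappa =", x$kappa,
      " T =", x$Tnoise, "\n")
  invisible(x)
}

lambda_mu <- function(hp, qx, qy) {
  list(lambda = complex(real = hp$Dx * qx^2 + hp$Dy * qy^2,
                        imaginary = hp$v * qx),
       mu = complex(real = -(hp$Dtx * qx^2 + hp$Dty * qy^2),
                    imaginary = hp$kappa * qx))
}

#' Stationary density-fluctuation spectrum
#'
#' Exact stationary structure factor of the linearized two-species
#' equations driven by conserved isotropic noise, obtained by solving the
#' per-mode 2x2 Lyapunov equation in closed form:
#' `S_auto = T q^2 |lambda|^2 / (Re(lambda) (|lambda|^2 - |mu|^2))` and
#' `S_cross = mu / lambda * S_auto`. By the species-exchange symmetry the
#' two auto-spectra coincide. The spectrum depends on direction in the
#' q -> 0 limit whenever the axis limits a = S(qx -> 0, qy = 0) and
#' b = S(qx = 0, qy -> 0) differ; with the coupling current switched off
#' and isotropic diffusion it is the constant T/D (analytic).
#'
#' The exact q = 0 point is excluded (the spectrum is non-analytic
#' there); it is returned as NA.
#'
#' @param hp a [hydro_params].
#' @param qx,qy wavevector axes (the spectrum is evaluated on their outer
#'   grid).
#' @return list with matrices `S_rr`, `S_ll` (real), `S_rl` (complex),
#'   the axes, and the axis limits `a`, `b`; class `spectral_grid`.
#' @export
structure_factor <- function(hp, qx, qy) {
  QX <- outer(qx, rep(1, length(qy))); QY <- outer(rep(1, length(qx)), qy)
  lm_ <- lambda_mu(hp, QX, QY)
  lam <- lm_$lambda; mu <- lm_$mu
  q2 <- QX^2 + QY^2
  al2 <- Mod(lam)^2; am2 <- Mod(mu)^2
  denom <- Re(lam) * (al2 - am2)
  zero <- q2 == 0
  bad <- !zero & (denom <= 0)
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1, ]
    stop("vanishing or unstable denominator at mode qx = ",
         signif(QX[idx[1], idx[2]], 4), ", qy = ",
         signif(QY[idx[1], idx[2]], 4),
         ": relaxation rates must be positive")
  }
  S <- (hp$Tnoise[1] * QX^2 + hp$Tnoise[2] * QY^2) * al2 / denom
  Sc <- (mu / lam) * S
  S[zero] <- NA_real_; Sc[zero] <- NA_complex_
  structure(list(S_rr = S, S_ll = S, S_rl = Sc, qx = qx, qy = qy,
                 a = axis_limit(hp, "x"), b = axis_limit(hp, "y")),
            class = "spectral_grid")
}

# closed-form q -> 0 limits along the two axes
axis_limit <- function(hp, axis) {
  if (axis == "x") {
    # lambda ~ i v qx + Dx qx^2, mu ~ i kappa qx - Dtx qx^2
    if (hp$v == 0)
      return(hp$Tnoise[1] * hp$Dx / (hp$Dx^2 - hp$Dtx^2))
    hp$Tnoise[1] * hp$v^2 / (hp$Dx * (hp$v^2 - hp$kappa^2))
  } else {
    hp$Tnoise[2] * hp$Dy / (hp$Dy^2 - hp$Dty^2)
  }
}

# FFT-ordered wavevector axis: k = 0, 1, ..., then negative
fft_freqs <- function(n, L) {
  k <- seq_len(n) - 1
  2 * pi * ifelse(k <= n / 2, k, k - n) / L
}

#' Real-space correlations from the spectrum
#'
#' Evaluates the stationary spectrum on a full FFT grid (q = 0 pinned to
#' zero: global mass is fixed), applies a separable Hann taper near the
#' Nyquist edge to suppress ringing, and inverse-transforms to the
#' real-space density correlation function. The returned grid exposes
#' longitudinal cuts and transverse slices for the diffusive-scaling
#' collapse; feed it to [longitudinal_cut()], [fit_loglog_slope()] and
#' [scaling_collapse()] (the latter expects values oscillating around 1,
#' so `values = 1 + C` is stored and the collapse subtracts the 1 back).
#'
#' @param hp a [hydro_params].
#' @param n grid points per axis.
#' @param L real-space box length (sets the q resolution 2 pi / L).
#' @param taper apply the Hann edge taper (recommended).
#' @return a [correlation_grid] with `values = 1 + C` on centered
#'   coordinates, plus the raw `C` in `$C` and the spectrum in `$spectrum`.
#' @export
realspace_correlations <- function(hp, n = 1024, L = n, taper = TRUE) {
  q <- fft_freqs(n, L)
  sf <- structure_factor(hp, q, q)
  S <- sf$S_rr
  S[1, 1] <- 0  # pinned q = 0 mode
  if (taper) {
    w <- 0.5 * (1 + cos(pi * q / max(abs(q))))
    S <- S * outer(w, w)
  }
  C <- Re(fft(S, inverse = TRUE)) / L^2
  # reorder to centered real-space coordinates (lattice spacing L/n)
  ord <- order(q)
  x_coords <- sort(q) / (2 * pi / L) * (L / n)  # k index times dx
  Cc <- C[ord, ord]
  g <- correlation_grid(1 + Cc, x_coords, x_coords, pair = "theory")
  g$C <- Cc
  g$spectrum <- sf
  g
}

#' Kinetic-theory estimates of the hydrodynamic coefficients
#'
#' Builds a [hydro_params] from the microscopic constants using the
#' binary-collision picture: upon a collision a particle reorients along
#' the center-to-center axis, so the collision rate with the partner
#' species is `r_c = 2 R 2 v0 rho_partner` (cross-section times relative
#' speed times density) and the collision-induced rotational diffusivity
#' is `nu_R = r_c <dtheta^2> / 2` with `<dtheta^2> = pi^2 / 3` (uniform
#' reorientation kick). A wrapped-Gaussian closure for the orientational
#' fluctuations balances drive relaxation against collisional kicks,
#' `sigma^2 = nu_R / H`, giving the advection speed
#' `v = v0 exp(-sigma^2 / 2)` and the force-field's three contributions:
#' drive alignment, a repulsion-induced pressure proportional to the
#' partner-weighted density gradient, and the collision-induced rotational
#' diffusivity. Rates are linear in the partner density throughout.
#'
#' These are order-of-magnitude closures: the package treats the
#' hydrodynamic coefficients as first-class parameters, and every claim
#' tested downstream (axis limits, exponents, conservation) is robust to
#' their values.
#'
#' @param params a [model_params] with `B > 1` (repulsion-dominated
#'   mingled regime; the closure is invalid in the laned regime).
#' @param rho mean number density per species.
#' @return a [hydro_params] with attribute `components` naming the three
#'   force-field contributions.
#' @export
kinetic_coefficients <- function(params, rho) {
  if (params$B <= 1)
    stop("closure invalid outside the repulsion-dominated regime (B <= 1)")
  phi <- pi * 1.48 * 2 * rho  # area fraction of the full mixture
  if (phi <= 0.2)
    stop("closure invalid at laned-regime densities (area fraction <= 0.2)")
  k <- kinetic_rates(params, rho)
  hp <- hydro_params(v = k$v, Dx = k$Dx, Dy = k$Dy, Dtx = k$Dt, Dty = k$Dt,
                     kappa = k$kappa, Tnoise = 1,
                     rho_right = rho, rho_left = rho)
  attr(hp, "components") <- list(
    alignment = c(rate = params$H),
    pressure = c(cross_diffusion = k$Dt),
    rotational_diffusivity = c(nu_R = k$nu_R, collision_rate = k$collision_rate))
  hp
}

#' Raw kinetic-closure rates
#'
#' The unchecked coefficient formulas behind [kinetic_coefficients()],
#' evaluable at any density (at zero density all collision-induced terms
#' vanish and only free advection and drive relaxation remain).
#'
#' @param params a [model_params].
#' @param rho mean number density per species.
#' @return named list: `collision_rate`, `nu_R`, `sigma2`, `v`, `Dx`,
#'   `Dy`, `kappa`, `Dt`.
#' @export
kinetic_rates <- function(params, rho) {
  R <- 2.4                       # mean summed interaction radius
  v0 <- params$v0; H <- params$H
  r_c <- 2 * R * 2 * v0 * rho    # binary collision rate with partners
  nu_R <- r_c * pi^2 / 3 / 2     # collision-induced rotational diffusivity
  sigma2 <- nu_R / H             # wrapped-Gaussian width
  tau <- 1 / (H + nu_R)
  v <- v0 * exp(-sigma2 / 2)
  Dy <- v0^2 * sigma2 * tau      # transverse kicks from collisions
  Dx <- 0.5 * v0^2 * sigma2^2 * tau + 0.05 * Dy
  kappa <- 0.5 * v0 * exp(-sigma2 / 2) * sigma2
  Dt <- min(0.8, rho * R^2) * 0.5 * Dy  # pressure coupling, kept below D
  list(collision_rate = r_c, nu_R = nu_R, sigma2 = sigma2, v = v,
       Dx = Dx, Dy = Dy, kappa = kappa, Dt = Dt)
}

#' Symmetry-averaged spectra from a stochastic integration
#'
#' The model has two exact spectral symmetries: the two species'
#' auto-spectra coincide, and the spectrum is even in `qy`. Averaging a
#' measured spectrum over both partners is the standard
#' variance-reduction step before comparing with the closed form. The
#' `qy`-mirror modes carry independent noise, so that average halves
#' the variance exactly; the two species are dynamically coupled, so
#' their average is conservatively credited with no variance reduction.
#' The returned `se` reflects exactly that accounting (`se / sqrt(2)`).
#'
#' @param res a `spde_result` from [spde_integrate()].
#' @return list with the averaged `S`, its conservative `se`, the
#'   `theory` spectrum and the live-mode `mask`.
#' @export
spde_symmetry_average <- function(res) {
  n <- length(res$qx)
  mirror <- c(1L, rev(seq_len(n - 1L) + 1L))  # q -> -q index on fft axes
  Ssp <- (res$S_rr + res$S_ll) / 2
  S <- (Ssp + Ssp[, mirror]) / 2
  list(S = S, se = res$se / sqrt(2), theory = res$theory,
       mask = res$mask)
}

#' Stochastic integration of the linear fluctuating hydrodynamics
#'
#' Integrates the two coupled linear stochastic field equations
#' pseudo-spectrally with a semi-implicit Euler-Maruyama scheme and
#' conserved noise (the divergence of a white vector noise), then
#' time-averages the per-mode spectra. The q = 0 mode is pinned (mass
#' conservation is exact) and, on even grids, the Nyquist rows are pinned
#' too (reality). The result carries the closed-form spectrum and a
#' conservative per-mode Monte-Carlo standard error based on each mode's
#' slowest relaxation time.
#'
#' @param hp a [hydro_params].
#' @param n grid points per axis.
#' @param L box length.
#' @param dt time step; the default resolves the stiffest retained mode.
#' @param t_total,t_burn total and burn-in integration spans.
#' @param sample_every sampling cadence in steps.
#' @param seed integer seed of the noise stream.
#' @param init_amp amplitude of a random initial perturbation (default 0:
#'   start from the unperturbed homogeneous state). With `Tnoise = 0` this
#'   exercises the deterministic relaxation of the stable linear system.
#' @return list with measured `S_rr`, `S_ll`, `S_rl`, the `theory`
#'   spectrum on the same grid, per-mode `se`, the `mask` of live modes
#'   and the grid axes; class `spde_result`.
#' @export
spde_integrate <- function(hp, n = 64, L = 64, dt = NULL,
                           t_total = 1500, t_burn = 150,
                           sample_every = 5L, seed = 1L, init_amp = 0) {
  q <- fft_freqs(n, L)
  qmax2 <- 2 * max(q^2)
  rate_max <- (hp$Dx + hp$Dtx + hp$Dy + hp$Dty) * qmax2
  if (is.null(dt)) dt <- 0.02 / rate_max
  nsteps <- ceiling(t_total / dt)
  burn <- ceiling(t_burn / dt)
  res <- cpp_spde(n, L, dt, as.integer(nsteps), as.integer(burn),
                  as.integer(sample_every),
                  hp$Tnoise[1], hp$Tnoise[2], hp$v, hp$kappa,
                  hp$Dx, hp$Dy, hp$Dtx, hp$Dty,
                  as.integer(seed), init_amp)
  res$qx <- as.numeric(res$qx); res$qy <- as.numeric(res$qy)
  sf <- structure_factor(hp, res$qx, res$qy)
  Sth <- sf$S_rr
  Sth[res$mask == 0] <- NA
  # conservative error: slowest per-mode relaxation sets the effective
  # number of independent samples
  lm_ <- lambda_mu(hp, outer(res$qx, rep(1, n)), outer(rep(1, n), res$qy))
  disc <- Mod(lm_$mu)^2 - Im(lm_$lambda)^2
  rate_slow <- Re(lm_$lambda) - sqrt(pmax(disc, 0))
  t_avg <- (nsteps - burn) * dt
  n_eff <- pmin(t_avg / (2 / pmax(rate_slow, 1e-12)), res$n_samples)
  se <- Sth / sqrt(pmax(n_eff, 1))
  structure(list(S_rr = res$S_rr, S_ll = res$S_ll,
                 S_rl = complex(real = res$S_rl_re,
                                imaginary = res$S_rl_im),
                 theory = Sth, se = se, mask = res$mask,
                 qx = res$qx, qy = res$qy, final_norm = res$final_norm,
                 dt = dt, n_samples = res$n_samples, t_avg = t_avg),
            class = "spde_result")
}
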