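#' Particle state container
#'
#' Positions, orientations, species labels and interaction radii of N
#' particles in the periodic box of `params`. Positions are wrapped into
#' `[0, Lx) x [0, Ly)`; orientation angles are stored unwrapped internally
#' and wrapped to `(-pi, pi]` on output by [wrap_angle()]. Species are
#' "right" (preferred direction 0) and "left" (preferred direction pi), in
#' equal numbers.
#'
#' @param x,y,theta numeric vectors of positions and orientations (radians).
#' @param species character vector of "right"/"left".
#' @param radii interaction radii, one per particle.
#' @param params a [model_params] object.
#' @param time current time.
#' @param check_balance enforce the equal-population invariant (default);
#'   internal propagation of already-validated or deliberately special
#'   states (e.g. the single-particle fixture) disables it.
#' @return object of class `particle_state`.
#' @export
particle_state <- function(x, y, theta, species, radii, params, time = 0,
                           check_balance = TRUE) {
  n <- length(x)
  stopifnot(length(y) == n, length(theta) == n, length(species) == n,
            length(radii) == n)
  if (!all(species %in% c("right", "left")))
    stop("species must be 'right' or 'left'")
  if (check_balance && sum(species == "right") != sum(species == "left"))
    stop("populations must have equal size (N/2 per species)")
  structure(list(
    x = x %% params$Lx, y = y %% params$Ly, theta = theta,
    species = species, radii = radii, time = time, params = params),
    class = "particle_state")
}

#' Preferred direction of each particle
#' @param state a [particle_state].
#' @return numeric vector, 0 for right movers and pi for left movers.
#' @export
preferred_angle <- function(state) ifelse(state$species == "right", 0, pi)

#' Wrap angles to (-pi, pi]
#'
#' Ties at -pi map to +pi.
#' @param theta angles in radians.
#' @export
wrap_angle <- function(theta) {
  w <- theta - 2 * pi * floor(theta / (2 * pi) + 0.5)
  w[w <= -pi] <- pi
  w
}

#' @export
print.particle_state <- function(x, ...) {
  cat("particle_state:", length(x$x), "particles at t =", x$time, "in",
      x$params$Lx, "x", x$params$Ly, "box\n")
  invisible(x)
}

#' Random initial condition
#'
#' Uniform positions and orientations, equal-size populations, alternating
#' interaction radii (1, 1.4, 1, 1.4, ...). The draw is reproducible: the
#' seed in `params` is applied before sampling, and positions are drawn
#' before orientations.
#'
#' @param N even particle count.
#' @param params a [model_params].
#' @return a [particle_state].
#' @export
init_random <- function(N, params) {
  if (N %% 2 != 0) stop("N must be even: equal-size populations required")
  set.seed(params$seed)
  x <- runif(N, 0, params$Lx)
  y <- runif(N, 0, params$Ly)
  theta <- runif(N, -pi, pi)
  # species split half/half, radii alternating so each species carries both
  species <- rep(c("right", "left"), each = N / 2)
  particle_state(x, y, theta, species, alternating_radii(N), params)
}

#' Named deterministic fixture configurations
#'
#' Small states used in tests and examples: `"two_lane_perfect"` (two
#' species-pure stripes, everyone aligned with its drive),
#' `"mingled_random"` (uniform random mixture), `"colliding_pair"` (the
#' two-body scattering geometry, see [scatter_setup()]) and
#' `"single_right"` (one right mover plus its left partner far away,
#' keeping populations balanced is not possible with one particle so this
#' fixture holds exactly one particle and relaxes the balance invariant).
#'
#' @param name fixture name.
#' @param params a [model_params]; defaults to a small box.
#' @param N particle count for the random fixtures (even).
#' @param y_in impact parameter for `"colliding_pair"`.
#' @return a [particle_state].
#' @export
make_fixture <- function(name, params = NULL, N = 64, y_in = 0.5) {
  if (is.null(params))
    params <- model_params(B = 5, Lx = 48, Ly = 24, seed = 42L)
  switch(name,
    two_lane_perfect = {
      if (N %% 2 != 0) stop("N must be even")
      half <- N / 2
      # quasi-uniform fill of each half-box: right movers below, left above
      g1 <- (sqrt(5) - 1) / 2; g2 <- sqrt(2) - 1
      xs <- ((seq_len(half) * g1) %% 1) * params$Lx
      ys <- ((seq_len(half) * g2) %% 1) * params$Ly / 2
      x <- rep(xs, 2)
      y <- c(ys, ys + params$Ly / 2)
      theta <- c(rep(0, half), rep(pi, half))
      species <- rep(c("right", "left"), each = half)
      particle_state(x, y, theta, species, alternating_radii(N), params)
    },
    mingled_random = {
      p <- params
      init_random(N, p)
    },
    colliding_pair = {
      setup <- scatter_setup(B = params$B, y_in = y_in)
      pos <- scatter_positions(setup)
      st <- particle_state(
        x = pos$x - min(pos$x) + params$Lx / 2,
        y = pos$y - min(pos$y) + params$Ly / 2,
        theta = pos$theta, species = c("right", "left"),
        radii = c(setup$a_r, setup$a_l), params = params)
      st
    },
    single_right = {
      structure(list(x = params$Lx / 2, y = params$Ly / 2, theta = 0,
                     species = "right", radii = 1, time = 0, params = params),
                class = "particle_state")
    },
    stop("unknown fixture: ", name))
}
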