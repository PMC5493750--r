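# Shared generators and independent oracles for the test suite.

# O(N^2) minimum-image all-pairs scan (vectorized), the brute-force
# oracle for the sweep-and-prune implementation.
brute_force_pairs <- function(x, y, radii, Lx, Ly) {
  dx <- outer(x, x, "-"); dx <- dx - Lx * round(dx / Lx)
  dy <- outer(y, y, "-"); dy <- dy - Ly * round(dy / Ly)
  hit <- (dx^2 + dy^2 < outer(radii, radii, "+")^2) & upper.tri(dx)
  idx <- which(hit, arr.ind = TRUE)
  m <- cbind(idx[, 1], idx[, 2])
  m[order(m[, 1], m[, 2]), , drop = FALSE]
}

# Exponentially correlated (AR(1)) series with decay time tau.
ou_series <- function(n, tau, dt = 1, seed = 1) {
  set.seed(seed)
  a <- exp(-dt / tau)
  v <- as.numeric(stats::filter(sqrt(1 - a^2) * rnorm(n), a,
                                method = "recursive"))
  observable_series((1:n) * dt, v, burn_in = 1)
}

# Synthetic critical sweep with known B_c and exponents.
synthetic_sweep <- function(Bc = 2, beta = 0.35, gamma = 0.64, znu = 1.2,
                            noise = 0.03, floor_W = 0.01, dB = 0.05) {
  B <- seq(Bc - 0.5, Bc + 1.0, by = dB)
  W_true <- ifelse(B > Bc, (B - Bc)^beta, 0)
  W <- sqrt((W_true * (1 + rnorm(length(B), 0, noise)))^2 + floor_W^2)
  var_true <- ifelse(B > Bc, 0.1 * abs(B - Bc)^(-gamma),
                     0.1 * 0.5^(-gamma))
  Wv <- var_true * (1 + rnorm(length(B), 0, noise)) + 1e-4
  tau <- ifelse(abs(B - Bc) > 1e-3, abs(B - Bc)^(-znu), 1e3) *
    (1 + rnorm(length(B), 0, noise))
  data.frame(B = B, W_mean = W, W_var = Wv, tau = tau)
}

# Relaxed mingled-state trajectory at number density `dens`, reused by
# several observable tests.
mingled_traj <- function(N = 480, dens = 0.15, B = 5, seed = 21,
                         burn_steps = 10000, run_steps = 15000,
                         save_every = 25) {
  Ly <- sqrt(N / dens / 2)
  p <- model_params(B = B, Lx = 2 * Ly, Ly = Ly, seed = seed)
  st <- init_random(N, p)
  b <- run_simulation(st, steps = burn_steps, w_every = 1e9L)
  run_simulation(b$state, steps = run_steps, save_every = save_every,
                 w_every = 50L)
}
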