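#' Sweep the repulsion strength across the laning transition
#'
#' For each repulsion amplitude B (and replicate) the sweep initializes a
#' random state at the requested number density, discards a burn-in
#' stretch, then measures the order parameter W: its time average, its
#' connected variance and its correlation time, with two-standard-deviation
#' errors from block averages. Seeds are derived from `seed_base` and the
#' value of B (not its position in `B_list`), so results are invariant
#' under reordering and bit-reproducible.
#'
#' @param B_list repulsion amplitudes.
#' @param density number density N / (Lx * Ly).
#' @param N particle count (even).
#' @param replicates independent runs per B.
#' @param t_burn,t_run burn-in and measurement spans (time units).
#' @param seed_base base RNG seed.
#' @param w_every order-parameter cadence in steps.
#' @param dt Euler time step.
#' @return a `sweep_result`: data.frame with one row per B (columns
#'   `B, W_mean, W_err, W_var, W_var_err, tau, tau_err`) and metadata
#'   attributes, plus all per-run series in attribute `series`.
#' @export
run_sweep <- function(B_list, density, N, replicates = 1,
                      t_burn = 200, t_run = 400, seed_base = 1L,
                      w_every = 10L, dt = 1e-2) {
  Ly <- sqrt(N / density / 2); Lx <- 2 * Ly
  rows <- list(); all_series <- list()
  for (B in sort(B_list)) {
    per_rep <- lapply(seq_len(replicates), function(r) {
      seed <- (seed_base + 7919L * r + round(1000 * B)) %% .Machine$integer.max
      p <- model_params(B = B, Lx = Lx, Ly = Ly, dt = dt, seed = seed)
      st <- init_random(N, p)
      burn <- run_simulation(st, steps = round(t_burn / dt), w_every = 1e9L)
      run_simulation(burn$state, steps = round(t_run / dt),
                     w_every = w_every)$W
    })
    vals <- lapply(per_rep, stationary_values)
    pooled <- unlist(vals)
    # block errors: 8 blocks across the pooled stationary data
    blocks <- split(pooled, cut(seq_along(pooled), 8, labels = FALSE))
    bm <- vapply(blocks, mean, numeric(1))
    bv <- vapply(blocks, var, numeric(1))
    taus <- vapply(per_rep, function(s)
      tryCatch(correlation_time(s), error = function(e) NA_real_), numeric(1))
    rows[[length(rows) + 1]] <- data.frame(
      B = B,
      W_mean = mean(pooled), W_err = 2 * sd(bm) / sqrt(length(bm)),
      W_var = var(pooled), W_var_err = 2 * sd(bv) / sqrt(length(bv)),
      tau = mean(taus, na.rm = TRUE),
      tau_err = 2 * sd(taus) / sqrt(max(1, sum(is.finite(taus)))))
    all_series[[sprintf("B%.3f", B)]] <- per_rep
  }
  out <- do.call(rbind, rows)
  attr(out, "N") <- N; attr(out, "density") <- density
  attr(out, "box") <- c(Lx = Lx, Ly = Ly)
  attr(out, "seed_base") <- seed_base
  attr(out, "series") <- all_series
  class(out) <- c("sweep_result", "data.frame")
  out
}

#' Fit the critical point and exponents of the laning transition
#'
#' Estimates `B_c` by scanning candidates on a fine grid and, for each,
#' fitting `log(W_eff)` linearly in `log(B - B_c)` over the points above
#' the candidate; the candidate minimizing the residual sum of squares
#' wins. The order-parameter exponent `beta` is that fit's slope. The
#' fluctuation exponent `gamma` and dynamic exponent `znu` come from
#' log-log fits of the connected fluctuations and the correlation time
#' against `B - B_c` above the transition. The noise floor of the
#' symmetric phase (`floor`, default: mean W over the two smallest-B
#' points) is removed in quadrature before fitting. One-standard-deviation
#' errors come from the fit covariances; the `B_c` error from the
#' curvature of the RSS profile.
#'
#' @param sweep a `sweep_result` or a data.frame with columns
#'   `B, W_mean, W_var, tau` (errors optional).
#' @param floor_W noise floor of `<W>`; `NULL` for the default estimate.
#' @param floor_var fluctuation plateau to subtract; `NULL` for the
#'   smallest observed variance.
#' @param Bc_grid candidate grid; `NULL` for an automatic grid between the
#'   second and second-to-last sweep points.
#' @return list with `B_c, beta, gamma, znu`, their `*_err` standard
#'   errors, and the per-quantity fit details.
#' @export
fit_critical <- function(sweep, floor_W = NULL, floor_var = NULL,
                         Bc_grid = NULL, min_above = 6) {
  d <- as.data.frame(sweep)[order(sweep$B), ]
  if (is.null(floor_W)) floor_W <- mean(head(d$W_mean, 2))
  if (is.null(floor_var)) floor_var <- min(d$W_var)
  W_eff_all <- sqrt(pmax(d$W_mean^2 - floor_W^2, 0))
  if (all(W_eff_all > 0) || all(W_eff_all == 0))
    stop("transition not bracketed: <W> does not cross its noise floor ",
         "within the sweep")
  if (is.null(Bc_grid))
    Bc_grid <- seq(d$B[2], d$B[length(d$B) - min_above],
                   length.out = 201)
  # fast least squares of y ~ x
  lsq <- function(x, y) {
    n <- length(x); mx <- mean(x); my <- mean(y)
    sxx <- sum((x - mx)^2); b <- sum((x - mx) * (y - my)) / sxx
    res <- y - my - b * (x - mx)
    list(slope = b, rss = sum(res^2), n = n,
         se = sqrt(sum(res^2) / (n - 2) / sxx))
  }
  estimate <- function(sub) {
    W_eff <- sqrt(pmax(sub$W_mean^2 - floor_W^2, 0))
    # profile over candidate B_c: amplitude and exponent from the log-log
    # fit above the candidate, residuals scored on EVERY sweep point (the
    # laned side must sit at the floor), so overshooting candidates pay
    # for the rising points they exclude
    score <- vapply(Bc_grid, function(bc) {
      keep <- sub$B > bc & W_eff > 0
      if (sum(keep) < min_above) return(NA_real_)
      f <- lsq(log(sub$B[keep] - bc), log(W_eff[keep]))
      amp <- exp(mean(log(W_eff[keep])) -
                   f$slope * mean(log(sub$B[keep] - bc)))
      pred <- ifelse(sub$B > bc, amp * pmax(sub$B - bc, 0)^f$slope, 0)
      w_pred <- sqrt(floor_W^2 + pred^2)
      mean((sub$W_mean - w_pred)^2)
    }, numeric(1))
    if (all(is.na(score))) return(NULL)
    B_c <- Bc_grid[which.min(score)]
    keep <- sub$B > B_c & W_eff > 0
    fb <- lsq(log(sub$B[keep] - B_c), log(W_eff[keep]))
    pow <- function(y) {
      k <- sub$B > B_c & is.finite(y) & y > 0
      if (sum(k) < 3) return(list(slope = NA_real_, se = NA_real_))
      lsq(log(sub$B[k] - B_c), log(y[k]))
    }
    g <- pow(sub$W_var - floor_var)
    z <- pow(sub$tau)
    list(B_c = B_c, beta = fb$slope, beta_se = fb$se,
         gamma = -g$slope, gamma_se = g$se,
         znu = -z$slope, znu_se = z$se, n_above = sum(keep))
  }
  full <- estimate(d)
  if (is.null(full)) stop("no candidate B_c admits a power-law fit")
  # jackknife over sweep points for the full pipeline (candidate scan
  # included), so the B_c uncertainty propagates into every exponent
  jk <- lapply(seq_len(nrow(d)), function(i) estimate(d[-i, ]))
  jk <- jk[!vapply(jk, is.null, logical(1))]
  jse <- function(field) {
    v <- vapply(jk, function(e) e[[field]], numeric(1))
    v <- v[is.finite(v)]
    if (length(v) < 3) return(NA_real_)
    sqrt((length(v) - 1) / length(v) * sum((v - mean(v))^2))
  }
  grid_step <- median(diff(Bc_grid))
  list(B_c = full$B_c, B_c_err = max(jse("B_c"), grid_step),
       beta = full$beta, beta_err = max(jse("beta"), full$beta_se,
                                        na.rm = TRUE),
       gamma = full$gamma, gamma_err = max(jse("gamma"), full$gamma_se,
                                           na.rm = TRUE),
       znu = full$znu, znu_err = max(jse("znu"), full$znu_se, na.rm = TRUE),
       floor_W = floor_W, floor_var = floor_var,
       n_points_above = full$n_above)
}

#' Locate the onset of the mingled state in a coarse sweep
#'
#' Returns the smallest B whose mean order parameter exceeds
#' `factor` times the laned-side floor, bracketing the critical point at
#' the sweep's resolution.
#'
#' @param sweep a `sweep_result`.
#' @param factor detection threshold relative to the floor.
#' @return list with `B_onset`, `B_below` (the largest laned B) and the
#'   floor used.
#' @export
sweep_onset <- function(sweep, factor = 3) {
  d <- as.data.frame(sweep)[order(sweep$B), ]
  floor_W <- mean(head(d$W_mean, 2))
  above <- d$W_mean > factor * max(floor_W, 1e-6)
  if (!any(above) || all(above))
    stop("transition not bracketed by the sweep")
  i <- which(above)[1]
  list(B_onset = d$B[i], B_below = d$B[max(1, i - 1)], floor_W = floor_W)
}

#' Map the lane/mingled phase diagram
#'
#' Runs a short simulation at each (B, density) grid point and labels the
#' final stretch with [laning_classifier()]. The expected monotone
#' structure (mingled for all B above the smallest mingled B at fixed
#' density) is checked; deviations are reported in the attribute
#' `monotone_violations`, never silently fixed.
#'
#' @param B_grid,density_grid grids of repulsion amplitudes and number
#'   densities.
#' @param N particle count per run.
#' @param t_relax,t_measure relaxation and measurement spans.
#' @param seed_base base seed.
#' @param n_fields number of snapshots fed to the classifier.
#' @return data.frame with columns `B`, `density`, `label`.
#' @export
phase_diagram <- function(B_grid, density_grid, N = 493,
                          t_relax = 300, t_measure = 100,
                          seed_base = 1L, n_fields = 5) {
  rows <- list()
  for (dens in density_grid) for (B in B_grid) {
    Ly <- sqrt(N / dens / 2); Lx <- 2 * Ly
    seed <- (seed_base + round(1000 * B) + round(1e5 * dens)) %%
      .Machine$integer.max
    p <- model_params(B = B, Lx = Lx, Ly = Ly, seed = seed)
    st <- init_random(N, p)
    relax <- run_simulation(st, steps = round(t_relax / p$dt), w_every = 1e9L)
    meas <- run_simulation(relax$state, steps = round(t_measure / p$dt),
                           save_every = round(t_measure / p$dt / n_fields),
                           w_every = 1e9L)
    fields <- lapply(seq_along(meas$times), function(f)
      density_fields(traj_frame(meas, f)))
    rows[[length(rows) + 1]] <- data.frame(
      B = B, density = dens, label = as.character(laning_classifier(fields)))
  }
  out <- do.call(rbind, rows)
  viol <- list()
  for (dens in density_grid) {
    sub <- out[out$density == dens, ]
    sub <- sub[order(sub$B), ]
    first_m <- which(sub$label == "mingled")[1]
    if (!is.na(first_m) && first_m < nrow(sub)) {
      bad <- which(sub$label[seq(first_m, nrow(sub))] == "lane")
      if (length(bad) > 0)
        viol[[length(viol) + 1]] <- sub[first_m + bad - 1, ]
    }
  }
  attr(out, "monotone_violations") <-
    if (length(viol) > 0) do.call(rbind, viol) else NULL
  out
}
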