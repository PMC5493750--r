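#' Scalar observable time series
#'
#' @param times strictly increasing sample times.
#' @param values one scalar per time.
#' @param name observable name.
#' @param burn_in index of the first sample regarded as stationary
#'   (default: half the series, the standard burn-in convention here).
#' @return object of class `observable_series`.
#' @export
observable_series <- function(times, values, name = "obs", burn_in = NULL) {
  stopifnot(length(times) == length(values))
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (is.null(burn_in)) burn_in <- floor(length(values) / 2) + 1
  if (burn_in >= length(values)) burn_in <- max(1L, length(values) - 1L)
  structure(list(times = times, values = values, name = name,
                 burn_in = as.integer(burn_in)),
            class = "observable_series")
}

#' @export
print.observable_series <- function(x, ...) {
  cat("observable_series '", x$name, "': ", length(x$values),
      " samples, burn-in at ", x$burn_in, "\n", sep = "")
  invisible(x)
}

stationary_values <- function(series) {
  series$values[seq(series$burn_in, length(series$values))]
}

#' Orientational order parameter W
#'
#' `W = mean_i sin^2(theta_i - Theta_i)`: zero exactly when every particle
#' points along its preferred direction, bounded by 1, and invariant under
#' the species-exchange symmetry (swap labels and rotate all orientations
#' by pi). Its time average is statistically zero in the lane phase and
#' finite in the mingled phase.
#'
#' @param state a [particle_state].
#' @return scalar in `[0, 1]`.
#' @export
order_parameter <- function(state) {
  mean(sin(state$theta - preferred_angle(state))^2)
}

#' Connected order-parameter fluctuations
#'
#' Variance of W over the stationary segment, minus the finite-size
#' plateau measured deep in the homogeneous phase (large B), where the
#' connected variance saturates at a value of order 1/N. If the series is
#' shorter than ~10 correlation times the result carries the attribute
#' `short_series = TRUE`.
#'
#' @param series an [observable_series] of W.
#' @param plateau large-B reference plateau to subtract.
#' @return connected variance minus plateau (can be negative for series at
#'   or below the plateau).
#' @export
w_fluctuations <- function(series, plateau = 0) {
  v <- stationary_values(series)
  out <- var(v) - plateau
  tau <- tryCatch(correlation_time(series), error = function(e) NA_real_)
  span <- diff(range(series$times[seq(series$burn_in, length(series$times))]))
  if (is.finite(tau) && span < 10 * tau) attr(out, "short_series") <- TRUE
  out
}

#' Correlation time of an observable
#'
#' Integrated autocorrelation time of the stationary segment,
#' `tau = dt * (1/2 + sum_k C(k)/C(0))`, with the sum truncated at a
#' self-consistent window `k* >= window_factor * tau(k*)` (the standard
#' windowing rule that balances truncation bias against the noise
#' accumulated by summing empirical autocorrelations). For an
#' exponentially correlated series this recovers the decay time; for
#' white noise it is half the sampling interval.
#'
#' @param series an [observable_series].
#' @param window_factor self-consistent window size in units of tau.
#' @return correlation time, in the series' time units.
#' @export
correlation_time <- function(series, window_factor = 6) {
  v <- stationary_values(series)
  if (length(v) < 8) stop("series too short for a correlation time")
  if (var(v) == 0) stop("constant series: correlation time undefined")
  dt <- median(diff(series$times))
  n <- length(v)
  M <- min(n - 2, 200L)
  tau_samples <- NA_real_
  repeat {
    a <- acf(v, lag.max = M, plot = FALSE, demean = TRUE)$acf[, 1, 1]
    tau_k <- 0.5 + cumsum(a[-1])
    kstar <- which(seq_along(tau_k) >= window_factor * tau_k)[1]
    if (!is.na(kstar)) { tau_samples <- tau_k[kstar]; break }
    if (M >= n - 2)
      stop("non-decaying autocorrelation (no self-consistent window): ",
           "input looks non-stationary or far shorter than its ",
           "correlation time")
    M <- min(n - 2, 2L * M)
  }
  # stationarity guard: a deterministic trend decorrelates and would
  # still yield a number, so compare the fitted linear drift over the
  # window with the fluctuation scale implied by tau
  idx <- seq_len(n)
  fit <- lm(v ~ idx)
  drift <- abs(coef(fit)[2]) * (n - 1)
  sd_drift <- sd(fit$residuals) *
    sqrt(24 * max(tau_samples, 0.5) / n)
  if (drift > 6 * max(sd_drift, .Machine$double.eps))
    stop("non-stationary input: fitted drift ", signif(drift, 3),
         " exceeds the stationary noise scale ", signif(sd_drift, 3))
  dt * tau_samples
}

#' Coarse-grained per-species density fields
#'
#' Counts particles of each species on a square grid and normalizes to
#' densities; the difference field `drho = rho_right - rho_left` is the
#' basic diagnostic of lane formation. The requested bin size is adjusted
#' to divide the box evenly.
#'
#' @param state a [particle_state].
#' @param bin requested bin side (default 9.6, about four interaction
#'   radii, so a bin holds many particles and the histogram probes the
#'   distribution shape, not shot noise).
#' @return object of class `density_field` with matrices `rho_right`,
#'   `rho_left`, `drho` and the realized bin sizes.
#' @export
density_fields <- function(state, bin = 9.6) {
  p <- state$params
  nx <- max(1L, round(p$Lx / bin)); ny <- max(1L, round(p$Ly / bin))
  bx <- p$Lx / nx; by <- p$Ly / ny
  ix <- pmin(nx, floor(state$x / bx) + 1)
  iy <- pmin(ny, floor(state$y / by) + 1)
  count <- function(keep) {
    m <- matrix(0, nx, ny)
    t <- table(factor(ix[keep], levels = 1:nx), factor(iy[keep], levels = 1:ny))
    m + as.matrix(t)
  }
  area <- bx * by
  rr <- count(state$species == "right") / area
  rl <- count(state$species == "left") / area
  structure(list(rho_right = rr, rho_left = rl, drho = rr - rl,
                 bin_x = bx, bin_y = by, Lx = p$Lx, Ly = p$Ly),
            class = "density_field")
}

#' Classify lane versus mingled states from density-difference histograms
#'
#' Pools the `drho` values of the supplied fields and fits one- and
#' two-component Gaussian mixtures. The state is labelled `"lane"` when
#' the two-component fit is preferred by BIC *and* the component means are
#' separated by more than the mean component width (operationalizing
#' "strongly bimodal" versus "Gaussian fluctuations"); otherwise
#' `"mingled"`.
#'
#' @param field_samples a `density_field` or list of them.
#' @return `"lane"` or `"mingled"`, with the fitted mixture summary in the
#'   attribute `"mixture"`.
#' @importFrom mclust Mclust mclustBIC
#' @export
laning_classifier <- function(field_samples) {
  if (inherits(field_samples, "density_field"))
    field_samples <- list(field_samples)
  vals <- unlist(lapply(field_samples, function(f) as.vector(f$drho)))
  fit <- mclust::Mclust(vals, G = 1:2, modelNames = "V", verbose = FALSE)
  lab <- "mingled"
  if (fit$G == 2) {
    mu <- fit$parameters$mean
    sg <- sqrt(fit$parameters$variance$sigmasq)
    if (abs(diff(mu)) > mean(sg)) lab <- "lane"
  }
  structure(lab, mixture = list(G = fit$G, mean = fit$parameters$mean,
                                sd = sqrt(fit$parameters$variance$sigmasq),
                                bic = fit$BIC))
}

#' Orientational diffusivity from the short-time decorrelation
#'
#' Computes the orientation autocorrelation
#' `C(t) = <cos(theta(t0 + t) - theta(t0))>` averaged over particles and
#' time origins. The drive pins each orientation to its preferred
#' direction, so C eventually saturates at a finite plateau; at short
#' time it decays exponentially and the orientational diffusivity `nu_R`
#' is the decay rate of `log C` fitted over the first half of that decay
#' (no plateau subtraction: the short-time rate measures the collisional
#' rotational diffusion, which vanishes with the collision rate at low
#' density). Exactly frozen orientations give 0; a barely fluctuating or
#' clearly non-exponential correlation (the laned state) raises an
#' error, as the measurement is undefined there.
#'
#' @param traj a `lane_traj` with snapshots.
#' @param min_r2 minimal R^2 of the log-linear fit.
#' @param min_contrast minimal connected amplitude `1 - C_inf` below
#'   which the decorrelation is deemed unmeasurable.
#' @return `nu_R` (1/time) with attributes `fit_r2`, `lags_used` and
#'   `plateau`.
#' @export
orientational_diffusivity <- function(traj, min_r2 = 0.9,
                                      min_contrast = 0.02) {
  if (is.null(traj$theta)) stop("trajectory carries no snapshots")
  th <- traj$theta
  nf <- ncol(th)
  if (nf < 12) stop("need at least 12 frames")
  dtf <- median(diff(traj$times))
  max_lag <- nf - 2
  C <- vapply(0:max_lag, function(l) {
    if (l == 0) return(1)
    mean(cos(th[, seq_len(nf - l), drop = FALSE] -
               th[, seq_len(nf - l) + l, drop = FALSE]))
  }, numeric(1))
  if (max(abs(C - 1)) < 1e-12)
    return(structure(0, fit_r2 = NA, lags_used = 0L, plateau = 1))
  # plateau from the late half of the window
  C_inf <- mean(C[seq(floor(length(C) / 2), length(C))])
  if (1 - C_inf < min_contrast)
    stop("orientation autocorrelation barely decays: ",
         "measurement undefined (laned or non-ergodic trajectory)")
  # initial window: first half of the decay toward the plateau
  conn <- (C - C_inf) / (1 - C_inf)
  below <- which(conn <= 0.5)[1]
  keep <- seq_len(if (is.na(below)) length(conn) else max(3, below - 1))
  keep <- keep[C[keep] > 0]
  if (length(keep) < 3)
    stop("decorrelation faster than the frame cadence: reduce save_every")
  tt <- (keep - 1) * dtf
  fit <- lm(log(C[keep]) ~ tt)
  r2 <- summary(fit)$r.squared
  if (is.na(r2) || r2 < min_r2)
    stop("short-time orientation decorrelation is not exponential (R^2 = ",
         signif(r2, 3), ")")
  structure(-unname(coef(fit)[2]), fit_r2 = r2, lags_used = length(keep),
            plateau = C_inf)
}

`%||%` <- function(a, b) if (is.null(a) || is.na(a[1])) b else a

#' Longitudinal drift and transverse spreading of particle displacements
#'
#' From unwrapped trajectory snapshots, measures for a set of lag times the
#' mean longitudinal displacement per species (expected linear in t: the
#' populations drift at their advection speed) and the standard deviation
#' of the transverse displacement (expected diffusive, sd ~ t^(1/2), in
#' the mingled state where frontal collisions randomize the transverse
#' motion).
#'
#' @param traj a `lane_traj` with snapshots.
#' @param lag_min,lag_max fit window in time units (defaults: from a few
#'   collision times to a quarter of the span).
#' @return list with the lag table and the fitted transverse exponent
#'   (`y_exponent`, with standard error) and longitudinal linear-fit R^2.
#' @export
displacement_scaling <- function(traj, lag_min = NULL, lag_max = NULL) {
  if (is.null(traj$y_unwrapped)) stop("trajectory carries no snapshots")
  dtf <- median(diff(traj$times))
  nf <- length(traj$times)
  span <- (nf - 1) * dtf
  if (is.null(lag_min)) lag_min <- max(2 * dtf, span / 50)
  if (is.null(lag_max)) lag_max <- span / 4
  lags <- unique(round(exp(seq(log(lag_min / dtf), log(lag_max / dtf),
                               length.out = 12))))
  lags <- lags[lags >= 1 & lags < nf]
  right <- traj$species == "right"
  tab <- do.call(rbind, lapply(lags, function(l) {
    o <- seq_len(nf - l)
    dy <- traj$y_unwrapped[, o + l, drop = FALSE] -
      traj$y_unwrapped[, o, drop = FALSE]
    dx <- traj$x_unwrapped[, o + l, drop = FALSE] -
      traj$x_unwrapped[, o, drop = FALSE]
    data.frame(lag = l * dtf, sd_y = sd(as.vector(dy)),
               drift_right = mean(dx[right, ]),
               drift_left = mean(dx[!right, ]))
  }))
  lin <- lm(drift_right ~ lag, data = tab)
  if (all(tab$sd_y < 1e-10)) {
    yexp <- NA_real_; yse <- NA_real_  # deterministic straight trajectories
  } else {
    fit <- lm(log(sd_y) ~ log(lag), data = tab)
    yexp <- unname(coef(fit)[2])
    yse <- summary(fit)$coefficients[2, 2]
  }
  list(table = tab,
       y_exponent = yexp,
       y_exponent_se = yse,
       drift_linear_r2 = summary(lin)$r.squared,
       drift_speed = unname(coef(lin)[2]))
}
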