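#' Correlation grid container
#'
#' A 2D array over displacement (or position) bins, x along the drive and
#' y transverse to it, with the species-pair label and per-bin sample
#' counts when it comes from particle data.
#'
#' @param values matrix of values, rows indexed by x, columns by y.
#' @param x,y bin-center coordinates.
#' @param pair label, e.g. "rr", "rl", "lr", "ll", "all", or "theory".
#' @param counts optional matrix of raw pair counts.
#' @export
correlation_grid <- function(values, x, y, pair = "all", counts = NULL) {
  stopifnot(nrow(values) == length(x), ncol(values) == length(y))
  structure(list(values = values, x = x, y = y, pair = pair,
                 counts = counts),
            class = "correlation_grid")
}

#' @export
print.correlation_grid <- function(x, ...) {
  cat("correlation_grid '", x$pair, "': ", length(x$x), " x ",
      length(x$y), " bins\n", sep = "")
  invisible(x)
}

#' Species-resolved pair correlation functions
#'
#' Accumulates minimum-image pair displacements over trajectory frames into
#' square bins and normalizes by the ideal-gas expectation, so an
#' uncorrelated homogeneous system gives g = 1 in every bin. Displacements
#' point from the first species of the pair label to the second, so
#' `g_rl(x, y) = g_lr(-x, -y)` holds by construction.
#'
#' @param traj a `lane_traj` with snapshots, or a [particle_state].
#' @param xmax,ymax half-widths of the displacement window.
#' @param bin square bin side (default 0.5, the interaction-radius scale).
#' @param frames frame indices to use (default: post burn-in half).
#' @return named list of [correlation_grid] objects `rr`, `rl`, `lr`,
#'   `ll`, and `all` (the overall g).
#' @export
pair_correlations <- function(traj, xmax = 20, ymax = 10, bin = 0.5,
                              frames = NULL) {
  if (inherits(traj, "particle_state")) {
    st <- traj
    traj <- list(times = st$time, x = matrix(st$x), y = matrix(st$y),
                 theta = matrix(st$theta), species = st$species,
                 radii = st$radii, params = st$params)
  }
  if (is.null(traj$x)) stop("trajectory carries no snapshots")
  p <- traj$params
  nf_all <- ncol(traj$x)
  if (is.null(frames)) frames <- seq(floor(nf_all / 2) + 1, nf_all)
  if (nf_all == 1) frames <- 1L
  spec <- as.integer(traj$species == "left")  # 0 right, 1 left
  nx <- round(2 * xmax / bin); ny <- round(2 * ymax / bin)
  acc <- list(rr = matrix(0, nx, ny), rl = matrix(0, nx, ny),
              lr = matrix(0, nx, ny), ll = matrix(0, nx, ny))
  for (f in frames) {
    h <- cpp_pair_hist(traj$x[, f], traj$y[, f], spec,
                       p$Lx, p$Ly, xmax, ymax, bin)
    for (k in names(acc)) acc[[k]] <- acc[[k]] + h[[k]]
  }
  xc <- -xmax + bin * (seq_len(nx) - 0.5)
  yc <- -ymax + bin * (seq_len(ny) - 0.5)
  A <- p$Lx * p$Ly
  n_r <- sum(spec == 0); n_l <- sum(spec == 1)
  norm <- function(counts, na, nb, same) {
    expected <- na * (nb - as.integer(same)) / A * bin^2 * length(frames)
    counts / expected
  }
  out <- list(
    rr = correlation_grid(norm(acc$rr, n_r, n_r, TRUE), xc, yc, "rr", acc$rr),
    rl = correlation_grid(norm(acc$rl, n_r, n_l, FALSE), xc, yc, "rl", acc$rl),
    lr = correlation_grid(norm(acc$lr, n_l, n_r, FALSE), xc, yc, "lr", acc$lr),
    ll = correlation_grid(norm(acc$ll, n_l, n_l, TRUE), xc, yc, "ll", acc$ll))
  tot <- acc$rr + acc$rl + acc$lr + acc$ll
  n <- n_r + n_l
  out$all <- correlation_grid(norm(tot, n, n, TRUE), xc, yc, "all", tot)
  out
}

#' Longitudinal cut of a correlation grid
#'
#' Values along y = 0 (the bin row closest to it) for x > 0.
#' @param grid a [correlation_grid].
#' @return data.frame with `x` and `value`.
#' @export
longitudinal_cut <- function(grid) {
  jy <- which.min(abs(grid$y))
  keep <- grid$x > 0
  data.frame(x = grid$x[keep], value = grid$values[keep, jy])
}

#' Diffusive scaling collapse of correlation slices
#'
#' For each selected longitudinal distance x, rescales the transverse
#' profile as `(g - 1) * x^x_exponent` against `u = y / x^y_exponent` and
#' interpolates onto a common u grid. With the exponents of the
#' advective-diffusive scaling (3/2 and 1/2) the slices of a mingled-state
#' correlation function collapse onto a single master curve; the returned
#' `spread` (mean over u of the across-slice standard deviation, relative
#' to the master curve's scale) scores the collapse quality.
#'
#' @param grid a [correlation_grid] (particle g or theory correlations).
#' @param x_slices longitudinal distances (defaults to geometrically
#'   spaced values over the grid's positive-x range).
#' @param x_exponent,y_exponent rescaling exponents (3/2 and 1/2 by
#'   default; pass others to score null rescalings).
#' @param n_u number of points of the common u grid.
#' @param u_max half-range of the common u grid; by default the largest
#'   range covered by every slice, capped at 5 (the master curve of the
#'   advective-diffusive scaling decays on u of order one).
#' @return list with `u`, `profiles` (one column per slice), `x_slices`,
#'   `spread` and `spread_relative`.
#' @export
scaling_collapse <- function(grid, x_slices = NULL,
                             x_exponent = 1.5, y_exponent = 0.5,
                             n_u = 41, u_max = NULL) {
  xs <- grid$x[grid$x > 0]
  if (is.null(x_slices)) {
    lo <- max(min(xs), 0.05 * max(xs)); hi <- 0.9 * max(xs)
    x_slices <- exp(seq(log(lo), log(hi), length.out = 5))
  }
  x_slices <- vapply(x_slices, function(v) xs[which.min(abs(xs - v))],
                     numeric(1))
  x_slices <- unique(x_slices)
  umax <- min(vapply(x_slices, function(xv) max(grid$y) / xv^y_exponent,
                     numeric(1)))
  if (is.null(u_max)) u_max <- min(umax, 5)
  u <- seq(-u_max, u_max, length.out = n_u)
  prof <- vapply(x_slices, function(xv) {
    ix <- which.min(abs(grid$x - xv))
    h <- (grid$values[ix, ] - 1) * xv^x_exponent
    approx(grid$y / xv^y_exponent, h, xout = u, rule = 2)$y
  }, numeric(n_u))
  spread <- mean(apply(prof, 1, sd))
  scale <- mean(abs(prof))
  list(u = u, profiles = prof, x_slices = x_slices, spread = spread,
       spread_relative = spread / max(scale, .Machine$double.eps))
}

#' Log-log slope of an algebraic decay
#'
#' Utility fitting `log |value|` against `log x` over a window, used for
#' the x^(-3/2) tails of correlation cuts.
#'
#' @param x,value positive distances and values.
#' @param x_range length-2 window.
#' @return list with `slope`, `se`, `r2`, `n`.
#' @export
fit_loglog_slope <- function(x, value, x_range = range(x[x > 0])) {
  keep <- x >= x_range[1] & x <= x_range[2] & is.finite(value) & value != 0
  if (sum(keep) < 4) stop("too few points in the fit window")
  fit <- lm(log(abs(value[keep])) ~ log(x[keep]))
  s <- summary(fit)
  list(slope = unname(coef(fit)[2]), se = s$coefficients[2, 2],
       r2 = s$r.squared, n = sum(keep))
}
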