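#' Two-body scattering setup
#'
#' The canonical collision experiment: a right mover with orientation
#' `theta_r` and a left mover with `theta_l` are placed at vertical
#' positions +y_in and -y_in; their horizontal separation is chosen so the
#' pair is exactly at interaction range at t = 0 ("contact"), with the
#' contact point at the origin. Interactions and the alignment drive act
#' only from contact on, so the incoming legs are straight lines. When
#' `2 * y_in` exceeds the interaction range no contact geometry exists and
#' the collision is a no-op.
#'
#' @param B repulsion amplitude.
#' @param y_in impact parameter (half the initial transverse separation).
#' @param theta_r,theta_l initial orientations (defaults 0 and
#'   `pi - pi/10`, the slightly inclined head-on geometry).
#' @param a_r,a_l interaction radii (equal by default, making the
#'   mirror symmetry of the deflection exact).
#' @return object of class `scatter_setup`.
#' @export
scatter_setup <- function(B, y_in, theta_r = 0, theta_l = pi - pi / 10,
                          a_r = 1, a_l = 1) {
  structure(list(B = B, y_in = y_in, theta_r = theta_r, theta_l = theta_l,
                 a_r = a_r, a_l = a_l, range = a_r + a_l),
            class = "scatter_setup")
}

#' Initial positions for a scattering setup
#' @param setup a [scatter_setup].
#' @return list with `x`, `y`, `theta` for (right, left), or NULL when no
#'   contact geometry exists.
#' @export
scatter_positions <- function(setup) {
  R <- setup$range
  if (2 * abs(setup$y_in) >= R) return(NULL)
  dx0 <- sqrt(R^2 - (2 * setup$y_in)^2)
  list(x = c(-dx0 / 2, dx0 / 2),
       y = c(setup$y_in, -setup$y_in),
       theta = c(setup$theta_r, setup$theta_l))
}

#' Integrate one two-body collision
#'
#' Deterministic forward-Euler integration on the unbounded plane from the
#' contact configuration. The collision ends when the pair separation
#' exceeds twice the interaction range and the right mover has realigned
#' with its drive to within `align_tol` (its final vertical position is
#' then `y_out`, signed, relative to the contact point), or when the
#' bound-pair criterion fires: the separation never exceeded the
#' interaction range while the pair's centre travelled `bound_travel`
#' along the transverse direction.
#'
#' With `check_convergence = TRUE` the integration is repeated at `dt / 2`
#' and an error (carrying both estimates) is raised if `y_out` moved by
#' more than `tol`.
#'
#' @param setup a [scatter_setup].
#' @param H,v0 drive amplitude and speed.
#' @param dt time step; two-body runs default to 1e-3, finer than bulk
#'   simulation, since deflection curves demand accuracy.
#' @param tmax maximum integration time.
#' @param align_tol realignment tolerance (radians).
#' @param bound_travel transverse centre displacement declaring a bound
#'   pair (default 20 interaction ranges).
#' @param record_every trajectory recording cadence in steps (0 = none).
#' @param check_convergence verify y_out under dt halving.
#' @param tol allowed |y_out(dt) - y_out(dt/2)|.
#' @param init optional explicit initial condition, a list with `x`, `y`,
#'   `theta` (length 2, right mover first) overriding the contact
#'   geometry. Used e.g. to start from a transversely propelling bound
#'   configuration, which exists wherever the pair torque can balance the
#'   drive (`B(r) = H`).
#' @return list with `y_out`, `bound`, `status`
#'   ("scattered"/"bound"/"timeout"/"no_contact"), `t_end` and `traj`.
#' @export
scatter <- function(setup, H = 1, v0 = 1, dt = 1e-3, tmax = 400,
                    align_tol = 1e-3, bound_travel = NULL,
                    record_every = 0L, check_convergence = FALSE,
                    tol = 0.01, init = NULL) {
  pos <- if (is.null(init)) scatter_positions(setup) else init
  if (is.null(pos))
    return(list(y_out = setup$y_in, bound = FALSE, status = "no_contact",
                t_end = 0, traj = NULL))
  if (is.null(bound_travel)) bound_travel <- 20 * setup$range
  run1 <- function(step) cpp_scatter(
    pos$x[1], pos$y[1], pos$theta[1],
    pos$x[2], pos$y[2], pos$theta[2],
    setup$a_r, setup$a_l, setup$B, H, v0, step,
    tmax, align_tol, bound_travel, as.integer(record_every))
  res <- run1(dt)
  if (check_convergence) {
    res2 <- run1(dt / 2)
    if (res$status == "scattered" && res2$status == "scattered" &&
        abs(res$y_out - res2$y_out) > tol)
      stop("scattering integration not converged: y_out(dt) = ",
           signif(res$y_out, 6), ", y_out(dt/2) = ", signif(res2$y_out, 6))
  }
  list(y_out = res$y_out, bound = identical(res$status, "bound"),
       status = res$status, t_end = res$t_end,
       theta_out = res$theta_out,
       traj = if (record_every > 0) res$traj else NULL)
}

#' Deflection curves y_out(y_in; B)
#'
#' Runs [scatter()] over a grid of impact parameters for each repulsion
#' amplitude and tabulates the signed transverse displacement and the
#' bound-pair flag.
#'
#' @param B_list repulsion amplitudes.
#' @param y_in_grid impact parameters.
#' @param ... passed to [scatter()].
#' @return data.frame with columns `B, y_in, y_out, bound, status`.
#' @export
deflection_curve <- function(B_list, y_in_grid, ...) {
  do.call(rbind, lapply(B_list, function(B) {
    do.call(rbind, lapply(y_in_grid, function(yi) {
      r <- scatter(scatter_setup(B = B, y_in = yi), ...)
      data.frame(B = B, y_in = yi, y_out = r$y_out, bound = r$bound,
                 status = r$status)
    }))
  }))
}
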