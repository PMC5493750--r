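## Torque-definition seam (R side).
##
## The model's two torques are defined here and mirrored by the inline
## functions at the top of src/core.cpp; the two must be kept in sync.
## Forms:
##   drive:  T_d = -H * sin(theta - Theta)
##   pair:   U_ij = -B(r_ij) * cos(theta_i - phi_ij),  T_ij = -dU/dtheta_i
##           B(r) = B * (1 - r/(a_i + a_j)) for r < a_i + a_j, else 0
## phi_ij is the angle of r_i - r_j (minimum image), so the pair torque
## rotates particle i toward pointing away from particle j.

#' Pairwise repulsive torque on particle i from particle j
#'
#' The interaction derives from the angular energy
#' `U_ij = -B(r_ij) * cos(theta_i - phi_ij)` with the linearly decaying
#' kernel `B(r) = B * (1 - r / (a_i + a_j))` cut off at the summed radii,
#' and `phi_ij` the direction of the minimum-image center-to-center vector
#' `r_i - r_j`. The torque `-dU/dtheta_i` vanishes when particle i points
#' exactly away from j and whenever the pair is out of range; its magnitude
#' never exceeds `B(r_ij)`.
#'
#' @param theta_i orientation of particle i (radians).
#' @param r_i,r_j length-2 position vectors.
#' @param a_i,a_j interaction radii.
#' @param params a [model_params] (supplies B and the periodic box).
#' @return torque (1/time units).
#' @export
pair_torque <- function(theta_i, r_i, r_j, a_i, a_j, params) {
  d <- r_i - r_j
  d[1] <- d[1] - params$Lx * round(d[1] / params$Lx)
  d[2] <- d[2] - params$Ly * round(d[2] / params$Ly)
  r <- sqrt(sum(d^2))
  if (r == 0) stop("degenerate pair: coincident positions after minimum image")
  asum <- a_i + a_j
  if (r >= asum) return(0)
  kern <- params$B * (1 - r / asum)
  phi <- atan2(d[2], d[1])
  -kern * sin(theta_i - phi)
}

#' Harmonic drive torque
#'
#' Restores the orientation toward the species' preferred direction
#' (0 for right movers, pi for left movers): `-H * sin(theta - Theta)`.
#' Zero exactly at the preferred direction (mod 2 pi).
#'
#' @param theta orientation (radians).
#' @param species "right" or "left".
#' @param params a [model_params].
#' @export
drive_torque <- function(theta, species, params) {
  Theta <- if (identical(species, "right")) 0 else pi
  -params$H * sin(theta - Theta)
}

#' Interacting pairs by sweep-and-prune
#'
#' Returns every unordered pair whose minimum-image distance is below the
#' summed interaction radii, found by sorting x coordinates and pruning on
#' interval overlap (with a dedicated pass across the periodic seam).
#'
#' @param state a [particle_state].
#' @param params optional [model_params] override (defaults to the state's).
#' @return two-column integer matrix of particle indices, i < j.
#' @export
neighbor_pairs <- function(state, params = state$params) {
  cpp_neighbor_pairs(state$x, state$y, state$radii, params$Lx, params$Ly)
}

#' Advance the state by one forward-Euler step
#'
#' Positions move ballistically along the current orientations at speed
#' `v0`; orientations pick up `dt` times the sum of the drive torque and
#' all pairwise torques. Speeds are exactly `v0` at all times: the model
#' has no positional forces.
#'
#' @param state a [particle_state].
#' @param params optional [model_params] override.
#' @return the updated [particle_state].
#' @export
euler_step <- function(state, params = state$params) {
  res <- cpp_run(state$x, state$y, state$theta,
                 preferred_angle(state), state$radii,
                 params$B, params$H, params$v0, params$dt,
                 params$Lx, params$Ly,
                 nsteps = 1L, save_every = 0L, w_every = 1L)
  particle_state(res$x, res$y, res$theta, state$species, state$radii,
                 params, time = state$time + params$dt,
                 check_balance = FALSE)
}

#' Run the microscopic dynamics
#'
#' Integrates the torque-coupled equations of motion for `steps` forward-
#' Euler steps, recording the orientational order parameter every
#' `w_every` steps and (optionally) full snapshots every `save_every`
#' steps. Unwrapped positions are carried along for displacement
#' statistics.
#'
#' @param state initial [particle_state].
#' @param steps number of Euler steps.
#' @param save_every snapshot cadence in steps (0 = no snapshots).
#' @param w_every order-parameter cadence in steps.
#' @param params optional [model_params] override.
#' @return a `lane_traj` object: final `state`, the order-parameter series
#'   `W` (an [observable_series]), and when snapshots were requested the
#'   frame times plus N x frames matrices `x`, `y`, `x_unwrapped`,
#'   `y_unwrapped`, `theta`.
#' @export
run_simulation <- function(state, steps, save_every = 0L, w_every = 10L,
                           params = state$params) {
  res <- cpp_run(state$x, state$y, state$theta,
                 preferred_angle(state), state$radii,
                 params$B, params$H, params$v0, params$dt,
                 params$Lx, params$Ly,
                 nsteps = as.integer(steps),
                 save_every = as.integer(save_every),
                 w_every = as.integer(w_every))
  final <- particle_state(res$x, res$y, res$theta, state$species,
                          state$radii, params,
                          time = state$time + steps * params$dt,
                          check_balance = FALSE)
  out <- list(
    state = final,
    W = observable_series(state$time + res$w_times, res$w_values,
                          name = "W"),
    species = state$species, radii = state$radii, params = params)
  if (save_every > 0) {
    out$times <- state$time + res$frame_times
    out$x <- res$frames_x; out$y <- res$frames_y
    out$x_unwrapped <- res$frames_x_unwrapped
    out$y_unwrapped <- res$frames_y_unwrapped
    out$theta <- res$frames_theta
  }
  class(out) <- "lane_traj"
  out
}

#' @export
print.lane_traj <- function(x, ...) {
  cat("lane_traj:", length(x$species), "particles,",
      if (!is.null(x$times)) paste(length(x$times), "frames,") else "",
      "final t =", x$state$time, "\n")
  invisible(x)
}

#' Extract one frame of a trajectory as a particle_state
#' @param traj a `lane_traj` with snapshots.
#' @param frame frame index (1-based).
#' @export
traj_frame <- function(traj, frame) {
  if (is.null(traj$times)) stop("trajectory carries no snapshots")
  particle_state(traj$x[, frame], traj$y[, frame], traj$theta[, frame],
                 traj$species, traj$radii, traj$params,
                 time = traj$times[frame], check_balance = FALSE)
}
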