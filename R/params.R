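#' Microscopic model parameters
#'
#' Bundles the constants of the torque-coupled active-mixture model: the
#' repulsion amplitude `B`, the harmonic drive amplitude `H`, the
#' self-propulsion speed `v0`, the Euler time step `dt`, the periodic box
#' `Lx` by `Ly` (aspect ratio 2:1 by default) and the RNG seed. Interaction
#' radii alternate between 1 and 1.4 (one particle in every two) to frustrate
#' crystallization; this is fixed by `radii_scheme = "alternating"`.
#'
#' All quantities are in the model's natural units: lengths in units of the
#' smaller interaction radius, times in units of the inverse drive rate.
#'
#' @param B repulsive torque amplitude (dimensionless, >= 0; the laning
#'   transition lives at B of order 2 for the default density, and B = 0 is
#'   the trivially laning limit).
#' @param H amplitude of the harmonic angular drive toward each species'
#'   preferred direction. Default 1.
#' @param v0 self-propulsion speed. Default 1.
#' @param dt forward-Euler time step. Default 1e-2.
#' @param Lx,Ly periodic box lengths. Default geometry is `Lx = 2 * Ly`;
#'   set `allow_any_box = TRUE` to override.
#' @param seed integer RNG seed driving all stochastic operations.
#' @param allow_any_box logical; permit `Lx != 2 * Ly`.
#' @return an object of class `model_params`.
#' @export
model_params <- function(B, H = 1, v0 = 1, dt = 1e-2,
                         Lx = 168, Ly = Lx / 2, seed = 1L,
                         allow_any_box = FALSE) {
  stopifnot(is.numeric(B), length(B) == 1, is.finite(B))
  if (B < 0) stop("B must be >= 0")
  if (B == 0) warning("B = 0: repulsion disabled, dynamics lanes trivially")
  if (H <= 0) stop("H must be > 0")
  if (v0 < 0) stop("v0 must be >= 0")
  if (dt <= 0) stop("dt must be > 0")
  if (Lx <= 0 || Ly <= 0) stop("box lengths must be > 0")
  if (!allow_any_box && abs(Lx - 2 * Ly) > 1e-9 * Lx)
    stop("default geometry requires Lx = 2 * Ly; ",
         "pass allow_any_box = TRUE to override")
  structure(list(B = B, H = H, v0 = v0, dt = dt, Lx = Lx, Ly = Ly,
                 radii_scheme = "alternating", seed = as.integer(seed)),
            class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat("model_params: B =", x$B, " H =", x$H, " v0 =", x$v0,
      " dt =", x$dt, "\n  box", x$Lx, "x", x$Ly,
      " radii", x$radii_scheme, " seed", x$seed, "\n")
  invisible(x)
}

#' Area fraction and number density
#'
#' The particle area fraction is computed from the torque-interaction disks,
#' `pi * sum(a_i^2) / (Lx * Ly)`; with the alternating radii 1 and 1.4 this
#' is `pi * 1.48 * N / (Lx * Ly)`. The bare number density `N / (Lx * Ly)`
#' is reported alongside since both conventions are common.
#'
#' @param N particle count.
#' @param params a [model_params] object.
#' @return named list with `area_fraction` and `number_density`.
#' @export
packing_measures <- function(N, params) {
  radii <- alternating_radii(N)
  A <- params$Lx * params$Ly
  list(area_fraction = pi * sum(radii^2) / A, number_density = N / A)
}

#' @rdname packing_measures
#' @export
alternating_radii <- function(N) rep_len(c(1, 1.4), N)

#' Read a simulation configuration file
#'
#' YAML file with keys exactly `B, H, v0, dt, Lx, Ly, N, seed, steps,
#' save_every` (plus the optional flag `allow_any_box`). Unknown keys are
#' rejected; missing optional keys get the model defaults (`H = 1`,
#' `v0 = 1`, `dt = 1e-2`, `Ly = Lx / 2`).
#'
#' @param path config file path.
#' @return list with `params` ([model_params]), `N`, `steps`, `save_every`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  # YAML 1.1 resolves a bare key "N" to a boolean; quote it before parsing
  txt <- sub("^(\\s*)N(\\s*):", '\\1"N"\\2:', readLines(path))
  cfg <- yaml::yaml.load(paste(txt, collapse = "\n"))
  known <- c("B", "H", "v0", "dt", "Lx", "Ly", "N", "seed", "steps",
             "save_every", "allow_any_box")
  extra <- setdiff(names(cfg), known)
  if (length(extra) > 0)
    stop("unknown config key(s): ", paste(extra, collapse = ", "))
  req <- c("B", "N", "Lx", "steps")
  miss <- setdiff(req, names(cfg))
  if (length(miss) > 0)
    stop("missing required config key(s): ", paste(miss, collapse = ", "))
  defaults <- list(H = 1, v0 = 1, dt = 1e-2, seed = 1L, save_every = 0L,
                   allow_any_box = FALSE)
  cfg <- modifyList(defaults, cfg)
  if (is.null(cfg$Ly)) cfg$Ly <- cfg$Lx / 2
  params <- model_params(B = cfg$B, H = cfg$H, v0 = cfg$v0, dt = cfg$dt,
                         Lx = cfg$Lx, Ly = cfg$Ly, seed = cfg$seed,
                         allow_any_box = isTRUE(cfg$allow_any_box))
  if (cfg$N %% 2 != 0) stop("config key N: equal-size populations require even N")
  list(params = params, N = as.integer(cfg$N), steps = as.integer(cfg$steps),
       save_every = as.integer(cfg$save_every))
}
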