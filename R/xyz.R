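#' Write a trajectory as extended-XYZ
#'
#' One frame per stored snapshot. Each frame's comment line records the
#' box (as a `Lattice` entry), the column layout (`Properties`), the time
#' and the model constants B, H, v0. Per-particle rows carry the species
#' symbol (`R`/`L`), position, orientation angle (radians) and interaction
#' radius, at full double precision so round trips are exact.
#'
#' @param traj a `lane_traj` with snapshots, or a [particle_state]
#'   (written as a single frame).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_frames <- function(traj, path) {
  if (inherits(traj, "particle_state")) {
    st <- traj
    traj <- list(times = st$time, x = matrix(st$x), y = matrix(st$y),
                 theta = matrix(st$theta), species = st$species,
                 radii = st$radii, params = st$params)
  }
  p <- traj$params
  con <- file(path, "w")
  on.exit(close(con))
  n <- length(traj$species)
  sym <- ifelse(traj$species == "right", "R", "L")
  for (f in seq_along(traj$times)) {
    writeLines(as.character(n), con)
    writeLines(sprintf(
      paste0('Lattice="%.17g 0 0 0 %.17g 0 0 0 1" ',
             'Properties=species:S:1:pos:R:2:theta:R:1:radius:R:1 ',
             'Time=%.17g B=%.17g H=%.17g v0=%.17g angle_unit=radian'),
      p$Lx, p$Ly, traj$times[f], p$B, p$H, p$v0), con)
    writeLines(sprintf("%s %.17g %.17g %.17g %.17g",
                       sym, traj$x[, f], traj$y[, f], traj$theta[, f],
                       traj$radii), con)
  }
  invisible(path)
}

#' Read an extended-XYZ trajectory
#'
#' Inverse of [write_frames()]: returns a `lane_traj` whose wrapped
#' positions, angles, species and radii reproduce the written values
#' exactly. Frames with unequal species counts violate the equal-
#' population invariant and raise an error naming the frame.
#'
#' @param path file written by [write_frames()].
#' @return a `lane_traj` (without unwrapped positions or W series).
#' @export
read_frames <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0) {
    out <- list(times = numeric(0), x = NULL, y = NULL, theta = NULL,
                species = character(0), radii = numeric(0), params = NULL)
    class(out) <- "lane_traj"
    return(out)
  }
  pos <- 1L; frames <- list(); times <- numeric(0)
  meta <- NULL
  fidx <- 0L
  while (pos <= length(lines)) {
    if (!nzchar(trimws(lines[pos]))) { pos <- pos + 1L; next }
    n <- as.integer(lines[pos]); fidx <- fidx + 1L
    comment <- lines[pos + 1L]
    grab <- function(key) {
      m <- regmatches(comment,
                      regexpr(paste0(key, "=[-+0-9.eE]+"), comment))
      if (length(m) == 0) return(NA_real_)
      as.numeric(sub(paste0(key, "="), "", m))
    }
    lat <- regmatches(comment, regexpr('Lattice="[^"]*"', comment))
    latv <- as.numeric(strsplit(gsub('Lattice="|"', "", lat), "\\s+")[[1]])
    body <- lines[pos + 1L + seq_len(n)]
    parts <- strsplit(trimws(body), "\\s+")
    sym <- vapply(parts, `[[`, character(1), 1)
    num <- t(vapply(parts, function(v) as.numeric(v[2:5]), numeric(4)))
    species <- ifelse(sym == "R", "right", "left")
    if (sum(species == "right") != sum(species == "left"))
      stop("frame ", fidx, ": unequal species counts violate the ",
           "equal-population invariant")
    frames[[fidx]] <- list(x = num[, 1], y = num[, 2], theta = num[, 3],
                           radii = num[, 4], species = species)
    times <- c(times, grab("Time"))
    if (is.null(meta))
      meta <- list(Lx = latv[1], Ly = latv[5], B = grab("B"), H = grab("H"),
                   v0 = grab("v0"))
    pos <- pos + 2L + n
  }
  params <- model_params(B = meta$B, H = meta$H, v0 = meta$v0,
                         Lx = meta$Lx, Ly = meta$Ly, allow_any_box = TRUE)
  out <- list(
    times = times,
    x = vapply(frames, `[[`, numeric(length(frames[[1]]$x)), "x"),
    y = vapply(frames, `[[`, numeric(length(frames[[1]]$x)), "y"),
    theta = vapply(frames, `[[`, numeric(length(frames[[1]]$x)), "theta"),
    species = frames[[1]]$species, radii = frames[[1]]$radii,
    params = params)
  if (length(frames[[1]]$x) == 1) {  # keep matrix shape for N = 1
    out$x <- matrix(out$x, 1); out$y <- matrix(out$y, 1)
    out$theta <- matrix(out$theta, 1)
  }
  class(out) <- "lane_traj"
  out
}

#' Write a run manifest
#'
#' Every command-line run drops a `manifest.json` snapshotting the
#' configuration, seed, package version and output paths, so results
#' regenerate from the manifest alone.
#'
#' @param dir output directory.
#' @param config named list of configuration values.
#' @param outputs character vector of produced files.
#' @return manifest path, invisibly.
#' @export
write_manifest <- function(dir, config, outputs = character(0)) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    config = config,
    outputs = outputs,
    package_version = as.character(utils::packageVersion("lanesim")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
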