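# Synthetic observable distributions and bead-model cage/guest trajectories.

#' Draw from a Gaussian-mixture observable emulator
#'
#' Statistical emulation of structural-observable histograms (SASA, contact
#' counts, solvent contacts): draws from a mixture of normals.
#'
#' @param components data.frame (or list coercible to one) with columns
#'   `weight`, `mean`, `sd`. Weights must be non-negative and sum to 1;
#'   `sd = 0` gives a point mass.
#' @param n Number of draws.
#' @param seed Integer seed; draws are bit-reproducible for a fixed seed.
#' @return Numeric vector of length `n`.
#' @export
sample_observable_distribution <- function(components, n, seed) {
  components <- as.data.frame(components)
  stopifnot(all(c("weight", "mean", "sd") %in% names(components)), n >= 1)
  if (any(components$weight < 0)) stop("negative mixture weights")
  if (any(components$sd < 0)) stop("negative mixture variances")
  if (abs(sum(components$weight) - 1) > 1e-8)
    stop("mixture weights must sum to 1")
  set.seed(seed)
  idx <- sample.int(nrow(components), n, replace = TRUE,
                    prob = components$weight)
  rnorm(n, mean = components$mean[idx], sd = components$sd[idx])
}

# quasi-uniform points on the unit sphere (golden-spiral lattice);
# deterministic, no seed
golden_spiral_points <- function(n) {
  k <- seq_len(n)
  z <- 1 - (2 * k - 1) / n
  phi <- k * pi * (3 - sqrt(5))
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(x = r * cos(phi), y = r * sin(phi), z = z)
}

#' Generate a bead-model cage/guest trajectory
#'
#' Test substrate for the structural observables: `n_cage_beads` fixed beads
#' on a spherical shell (golden-spiral lattice) and a single guest bead
#' performing an overdamped random walk in an isotropic harmonic confining
#' potential centred on the cage centre, so its stationary coordinates are
#' Boltzmann-distributed, Normal(0, sqrt(kT/kappa)) per axis (reduced units,
#' kT = 1).
#'
#' @param shell_radius Cage shell radius (reduced length), > 0.
#' @param n_cage_beads Number of cage beads (>= 1).
#' @param guest_mobility Diffusion coefficient D of the guest random walk.
#' @param frames Number of stored frames (>= 1).
#' @param seed Integer seed.
#' @param kappa Spring constant of the confining potential (kT per length^2);
#'   default gives a thermal width of `shell_radius / 3`.
#' @param dt Integration time step; one frame is stored per step.
#' @param bead_radius Radius assigned to every bead.
#' @param guest_start Initial guest position (length-3), default the centre.
#' @return An object of class `bead_system`: fixed `cage` coordinates,
#'   `guest` frames (frames x 3 matrix), `radii`, `box`, `times`, and the
#'   generation parameters.
#' @export
generate_bead_system <- function(shell_radius, n_cage_beads, guest_mobility,
                                 frames, seed,
                                 kappa = 9 / shell_radius^2, dt = 0.05,
                                 bead_radius = 0.2 * shell_radius,
                                 guest_start = c(0, 0, 0)) {
  if (shell_radius <= 0) stop("shell_radius must be positive")
  stopifnot(n_cage_beads >= 1, frames >= 1, guest_mobility >= 0)
  set.seed(seed)
  cage <- shell_radius * golden_spiral_points(n_cage_beads)
  guest <- matrix(NA_real_, frames, 3,
                  dimnames = list(NULL, c("x", "y", "z")))
  x <- as.numeric(guest_start)
  sig <- sqrt(2 * guest_mobility * dt)
  for (f in seq_len(frames)) {
    x <- x - guest_mobility * kappa * x * dt + sig * rnorm(3)
    guest[f, ] <- x
  }
  structure(
    list(cage = cage, guest = guest,
         radii = rep(bead_radius, n_cage_beads + 1),
         box = c(-2, 2) * shell_radius,
         times = dt * seq_len(frames),
         params = list(shell_radius = shell_radius, kappa = kappa,
                       guest_mobility = guest_mobility, dt = dt,
                       seed = seed)),
    class = "bead_system")
}

#' @export
print.bead_system <- function(x, ...) {
  cat(sprintf("<bead_system: %d cage beads on shell r=%g, %d frames>\n",
              nrow(x$cage), x$params$shell_radius, nrow(x$guest)))
  invisible(x)
}

#' Read / write bead frames as XYZ text
#'
#' Standard multi-frame XYZ: cage beads (element `C`) plus the guest bead
#' (element `G`) per frame; cage coordinates are repeated in every frame.
#'
#' @param bs A `bead_system`.
#' @param path Output/input file path.
#' @return `read_xyz()` returns a list with `cage` (coordinates of the first
#'   frame's `C` beads) and `guest` (frames x 3 matrix of `G` positions).
#' @export
write_xyz <- function(bs, path) {
  stopifnot(inherits(bs, "bead_system"))
  con <- file(path, "w")
  on.exit(close(con))
  nat <- nrow(bs$cage) + 1
  for (f in seq_len(nrow(bs$guest))) {
    writeLines(c(as.character(nat), sprintf("frame %d", f)), con)
    xyz <- rbind(bs$cage, bs$guest[f, , drop = FALSE])
    el <- c(rep("C", nrow(bs$cage)), "G")
    writeLines(sprintf("%s %.10g %.10g %.10g",
                       el, xyz[, 1], xyz[, 2], xyz[, 3]), con)
  }
  invisible(path)
}

#' @rdname write_xyz
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  i <- 1; cage <- NULL; guest <- list()
  while (i <= length(lines)) {
    nat <- as.integer(lines[i])
    if (is.na(nat)) stop(sprintf("malformed XYZ atom count at line %d", i))
    block <- lines[(i + 2):(i + 1 + nat)]
    parts <- do.call(rbind, strsplit(trimws(block), "\\s+"))
    xyz <- matrix(as.numeric(parts[, 2:4]), ncol = 3)
    el <- parts[, 1]
    if (is.null(cage)) cage <- xyz[el == "C", , drop = FALSE]
    guest[[length(guest) + 1]] <- xyz[el == "G", , drop = FALSE]
    i <- i + 2 + nat
  }
  list(cage = cage, guest = do.call(rbind, guest))
}
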