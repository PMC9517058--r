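# Free-energy-surface estimation and basin thermodynamics.

new_free_energy_profile <- function(grid, F, temperature, periodic, basins,
                                    source = "unknown") {
  stopifnot(length(grid) == length(F), all(diff(grid) > 0))
  F <- F - min(F, na.rm = TRUE)
  structure(list(grid = grid, F = F, temperature = temperature,
                 periodic = periodic, basins = basins, source = source),
            class = "free_energy_profile")
}

#' @export
print.free_energy_profile <- function(x, ...) {
  cat(sprintf(
    "<free_energy_profile: %d points, T = %g K, %d undefined bins (%s)>\n",
    length(x$grid), x$temperature, sum(is.na(x$F)), x$source))
  invisible(x)
}

#' Free-energy profile from a hills log
#'
#' Standard well-tempered estimator: F(s) = -(gamma/(gamma-1)) V(s, t_final),
#' min-shifted to zero.
#'
#' @param hills A `hills_log` from [run_wtmetad()] (or [read_hills()]).
#' @param grid CV grid (default 512 points over the hills domain).
#' @param basins Basin annotation; defaults to the generating potential's
#'   basins when the log carries them.
#' @return A `free_energy_profile`.
#' @export
fes_from_hills <- function(hills, grid = NULL, basins = NULL) {
  stopifnot(inherits(hills, "hills_log"))
  if (nrow(hills) == 0) stop("empty hills log")
  lo <- attr(hills, "lo"); hi <- attr(hills, "hi")
  if (is.null(grid))
    grid <- seq(lo, hi - if (attr(hills, "periodic")) (hi - lo) / 512 else 0,
                length.out = 512)
  gam <- attr(hills, "bias_factor")
  fac <- if (is.finite(gam)) gam / (gam - 1) else 1
  V <- evaluate_bias(hills, grid)
  pot <- attr(hills, "potential")
  if (is.null(basins) && !is.null(pot)) basins <- pot$basins
  new_free_energy_profile(grid, -fac * V, attr(hills, "temperature"),
                          attr(hills, "periodic"), basins,
                          source = "hills")
}

#' Final-bias reweighting weights for a metadynamics trajectory
#'
#' w_i proportional to exp(V(s_i, t_final)/kT), normalized to sum 1.
#'
#' @param traj A `trajectory` from [run_wtmetad()].
#' @param hills The matching `hills_log` (run ids must agree).
#' @return Numeric weights, one per saved frame.
#' @export
reweight_trajectory <- function(traj, hills) {
  stopifnot(inherits(traj, "trajectory"), inherits(hills, "hills_log"))
  if (!is.null(traj$run_id) && !is.null(attr(hills, "run_id")) &&
      !identical(traj$run_id, attr(hills, "run_id")))
    stop("trajectory and hills log come from different runs")
  kT <- kT_of(traj$params$temperature)
  V <- evaluate_bias(hills, traj$cv)
  w <- exp((V - max(V)) / kT)
  w / sum(w)
}

#' Free-energy profile from (weighted) samples
#'
#' F = -kT log(weighted histogram density), min-shifted. Empty bins are
#' undefined (NA), never clipped to a cap.
#'
#' @param samples CV samples.
#' @param weights Optional weights (default uniform).
#' @param grid Bin-center grid (equally spaced).
#' @param temperature Temperature in K.
#' @param periodic,basins Profile annotation.
#' @return A `free_energy_profile`.
#' @export
fes_from_samples <- function(samples, weights = NULL, grid,
                             temperature = default_temperature,
                             periodic = FALSE, basins = NULL) {
  n <- length(samples)
  if (n < length(grid)) stop("need at least as many samples as grid bins")
  if (is.null(weights)) weights <- rep(1 / n, n)
  stopifnot(length(weights) == n)
  h <- grid[2] - grid[1]
  edges <- c(grid - h / 2, grid[length(grid)] + h / 2)
  idx <- findInterval(samples, edges, rightmost.closed = TRUE)
  keep <- idx >= 1 & idx <= length(grid)
  dens <- rep(0, length(grid))
  agg <- tapply(weights[keep], idx[keep], sum)
  dens[as.integer(names(agg))] <- agg
  if (all(dens == 0)) stop("all histogram bins are empty")
  F <- ifelse(dens > 0, -kT_of(temperature) * log(dens), NA_real_)
  new_free_energy_profile(grid, F, temperature, periodic, basins,
                          source = "samples")
}

# indices of the grid falling in a (possibly wrapped) basin interval,
# ordered along the path through the basin (wrapped basins cross the seam)
basin_index <- function(fes, interval) {
  g <- fes$grid
  if (fes$periodic) {
    p <- diff(range(g)) + (g[2] - g[1])
    lo0 <- min(g)
    a <- (interval[1] - lo0) %% p + lo0
    b <- (interval[2] - lo0) %% p + lo0
    if (a <= b) which(g >= a & g <= b)
    else c(which(g >= a), which(g <= b))
  } else {
    which(g >= interval[1] & g <= interval[2])
  }
}

basin_partition_function <- function(fes, basin) {
  interval <- if (is.character(basin)) fes$basins[[basin]] else basin
  if (is.null(interval)) stop(sprintf("basin '%s' not declared", basin))
  idx <- basin_index(fes, interval)
  if (length(idx) < 2) stop("basin covers fewer than 2 grid points")
  if (anyNA(fes$F[idx]))
    stop(sprintf("undefined (unsampled) bins inside basin at grid = %s",
                 paste(signif(fes$grid[idx][is.na(fes$F[idx])], 4),
                       collapse = ", ")))
  kT <- kT_of(fes$temperature)
  w <- exp(-fes$F[idx] / kT)
  h <- fes$grid[2] - fes$grid[1]
  # trapezoid over the (contiguous-in-circle) basin: treat as ordered run
  sum(w) * h - (w[1] + w[length(w)]) * h / 2
}

#' Basin free-energy difference
#'
#' Default ("basin") convention: Boltzmann-integrated populations,
#' dG = -kT log(Z_B / Z_A) with Z the trapezoidal quadrature of exp(-F/kT)
#' over the basin interval. The "point" convention uses the profile values
#' at the basin minima instead.
#'
#' @param fes A `free_energy_profile` with declared, fully sampled basins.
#' @param basinA,basinB Basin names (or explicit intervals).
#' @param convention `"basin"` (default) or `"point"`.
#' @return dG(A->B) in kcal/mol.
#' @export
basin_free_energy_difference <- function(fes, basinA, basinB,
                                         convention = c("basin", "point")) {
  convention <- match.arg(convention)
  if (convention == "basin") {
    ZA <- basin_partition_function(fes, basinA)
    ZB <- basin_partition_function(fes, basinB)
    -kT_of(fes$temperature) * log(ZB / ZA)
  } else {
    fa <- min(fes$F[basin_index(fes, resolve_basin(fes, basinA))], na.rm = TRUE)
    fb <- min(fes$F[basin_index(fes, resolve_basin(fes, basinB))], na.rm = TRUE)
    fb - fa
  }
}

resolve_basin <- function(fes, basin) {
  if (is.character(basin)) {
    interval <- fes$basins[[basin]]
    if (is.null(interval)) stop(sprintf("basin '%s' not declared", basin))
    interval
  } else basin
}

#' Barrier height between two basins
#'
#' Maximum of F on the grid path between the basin minima, minus F at the
#' source minimum. On periodic profiles both directions are considered and
#' the lower-barrier path is taken. Undefined bins invalidate a path; an
#' error is raised if no defined path remains.
#'
#' @inheritParams basin_free_energy_difference
#' @param source_basin,target_basin Basin names or intervals.
#' @return Barrier in kcal/mol from the source minimum.
#' @export
barrier_height <- function(fes, source_basin, target_basin) {
  iS <- basin_index(fes, resolve_basin(fes, source_basin))
  iT <- basin_index(fes, resolve_basin(fes, target_basin))
  if (anyNA(fes$F[iS]) || all(is.na(fes$F[iT])))
    stop("undefined bins in basin regions")
  s <- iS[which.min(fes$F[iS])]
  t <- iT[which.min(fes$F[iT])]
  n <- length(fes$grid)
  path_max <- function(idx) {
    f <- fes$F[idx]
    if (anyNA(f)) NA_real_ else max(f)
  }
  lo <- min(s, t); hi <- max(s, t)
  m1 <- path_max(lo:hi)
  if (fes$periodic) {
    m2 <- path_max(c(hi:n, 1:lo))
    m <- suppressWarnings(min(m1, m2, na.rm = TRUE))
    if (!is.finite(m)) stop("undefined bins on both paths between basins")
  } else {
    if (is.na(m1)) stop("undefined bins on the path between basins")
    m <- m1
  }
  m - fes$F[s]
}

#' Equilibrium constant from a free-energy difference
#'
#' K = exp(-dG / (kB T)).
#'
#' @param dG Free-energy difference in kcal/mol.
#' @param temperature Temperature in K.
#' @return Dimensionless equilibrium constant.
#' @export
equilibrium_constant <- function(dG, temperature = default_temperature) {
  stopifnot(is.finite(dG))
  exp(-dG / kT_of(temperature))
}

#' In-cage partition probability
#'
#' P_in = K_enc / (1 + K_enc): the probability of finding the guest inside
#' the cavity at equilibrium.
#'
#' @param K_enc Encapsulation equilibrium constant (>= 0).
#' @return P_in in (0, 1) (0 at K = 0).
#' @export
partition_probability <- function(K_enc) {
  if (any(K_enc < 0)) stop("K_enc must be non-negative")
  K_enc / (1 + K_enc)
}

#' Relative conformer probabilities from a free-energy profile
#'
#' Point convention: P(omega) = exp(-(F(omega) - F(ref))/kT) per grid point.
#' Basin convention: per declared basin, the ratio of Boltzmann-integrated
#' basin populations to the reference basin's.
#'
#' @param fes A `free_energy_profile`.
#' @param reference Reference omega value (point convention) — must fall in
#'   a defined bin; for the basin convention the basin containing it is the
#'   reference.
#' @param convention `"point"` or `"basin"`.
#' @return A `conformer_table` data.frame: `omega` (or basin name), `dG`
#'   relative to the reference, and `pconf`; the convention is recorded as
#'   an attribute.
#' @export
conformer_probability_profile <- function(fes, reference = pi,
                                          convention = c("point", "basin")) {
  convention <- match.arg(convention)
  kT <- kT_of(fes$temperature)
  if (fes$periodic) {
    p <- diff(range(fes$grid)) + (fes$grid[2] - fes$grid[1])
    reference <- min(fes$grid) + ((reference - min(fes$grid)) %% p)
  }
  if (convention == "point") {
    i <- which.min(abs(fes$grid - reference))
    if (is.na(fes$F[i])) stop("reference omega falls in an undefined bin")
    dG <- fes$F - fes$F[i]
    out <- data.frame(omega = fes$grid, dG = dG, pconf = exp(-dG / kT))
  } else {
    if (is.null(fes$basins) || length(fes$basins) == 0)
      stop("basin convention requires declared basins")
    h <- fes$grid[2] - fes$grid[1]
    refb <- NULL
    for (nm in names(fes$basins)) {
      idx <- basin_index(fes, fes$basins[[nm]])
      if (length(idx) &&
          min(abs(fes$grid[idx] - reference)) <= h + 1e-12)
        refb <- nm
    }
    if (is.null(refb)) stop("reference omega is not inside any basin")
    Zr <- basin_partition_function(fes, refb)
    rows <- lapply(names(fes$basins), function(nm) {
      Z <- basin_partition_function(fes, nm)
      data.frame(omega = nm, dG = -kT * log(Z / Zr), pconf = Z / Zr)
    })
    out <- do.call(rbind, rows)
  }
  structure(out, class = c("conformer_table", "data.frame"),
            convention = convention, reference = reference,
            temperature = fes$temperature)
}

#' Root-mean-square deviation between two free-energy profiles
#'
#' Profiles are defined up to an additive constant, so the offset is removed
#' (mean alignment by default) before comparing; only bins defined in both
#' profiles enter.
#'
#' @param fes_a,fes_b `free_energy_profile`s on the same grid.
#' @param align `"mean"` (default) or `"none"`.
#' @return RMSD in kcal/mol.
#' @export
fes_rmsd <- function(fes_a, fes_b, align = c("mean", "none")) {
  align <- match.arg(align)
  stopifnot(length(fes_a$grid) == length(fes_b$grid),
            max(abs(fes_a$grid - fes_b$grid)) < 1e-9)
  ok <- !is.na(fes_a$F) & !is.na(fes_b$F)
  if (!any(ok)) stop("no commonly defined bins")
  d <- fes_a$F[ok] - fes_b$F[ok]
  if (align == "mean") d <- d - mean(d)
  sqrt(mean(d^2))
}

#' Export a free-energy profile as TSV
#'
#' Two columns (`cv`, `F`) preceded by a `#`-comment metadata header
#' (temperature, source, periodicity).
#'
#' @param fes A `free_energy_profile`.
#' @param path Output path.
#' @export
write_fes_tsv <- function(fes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# temperature_K\t%g", fes$temperature),
               sprintf("# source\t%s", fes$source),
               sprintf("# periodic\t%s", fes$periodic),
               "cv\tF_kcal_mol"), con)
  writeLines(sprintf("%.10g\t%.10g", fes$grid, fes$F), con)
  invisible(path)
}
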