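# Analytic 1-D model free-energy landscapes.
#
# Every potential is a constant plus a cosine series plus Gaussian terms,
# F(s) = c0 + sum_k a_k cos(k s) + sum_i h_i exp(-(s - c_i)^2 / (2 w_i^2)),
# evaluated (with wrapped Gaussian images for periodic coordinates) by the
# compiled kernel shared with the sampler. Construction calibrates the
# Gaussian heights numerically so that the requested basin free-energy
# difference and barrier are reproduced essentially exactly.

new_potential_spec <- function(kind, lo, hi, periodic, c0, cos_a, gauss,
                               basins, meta = list()) {
  stopifnot(hi > lo, is.matrix(gauss) || nrow(gauss) == 0)
  structure(
    list(kind = kind, lo = lo, hi = hi, periodic = periodic,
         c0 = c0, cos_a = cos_a, gauss = gauss, basins = basins,
         meta = meta),
    class = "potential_spec")
}

#' Evaluate a model potential
#'
#' @param spec A `potential_spec`.
#' @param s Numeric vector of collective-variable values (periodic
#'   coordinates are wrapped into the domain first).
#' @return Free energy in kcal/mol at each `s`.
#' @export
eval_potential <- function(spec, s) {
  stopifnot(inherits(spec, "potential_spec"))
  s <- wrap_cv(spec, s)
  eval_potential_cpp(unclass(spec), as.numeric(s))
}

#' @rdname eval_potential
#' @return `potential_deriv` returns dF/ds in kcal/mol per CV unit.
#' @export
potential_deriv <- function(spec, s) {
  stopifnot(inherits(spec, "potential_spec"))
  s <- wrap_cv(spec, s)
  eval_potential_deriv_cpp(unclass(spec), as.numeric(s))
}

wrap_cv <- function(spec, s) {
  if (!spec$periodic) return(s)
  p <- spec$hi - spec$lo
  spec$lo + ((s - spec$lo) %% p)
}

#' @export
print.potential_spec <- function(x, ...) {
  cat(sprintf("<potential_spec: %s>\n", x$kind))
  cat(sprintf("  domain [%g, %g] %s\n", x$lo, x$hi,
              if (x$periodic) "(periodic)" else "(reflecting)"))
  for (nm in names(x$basins))
    cat(sprintf("  basin %-6s [%g, %g]\n", nm, x$basins[[nm]][1],
                x$basins[[nm]][2]))
  invisible(x)
}

# Locate the refined minimum of F inside an interval (which may extend past
# the periodic domain; evaluation wraps).
refine_extremum <- function(spec, interval, maximum = FALSE, n_scan = 512) {
  xs <- seq(interval[1], interval[2], length.out = n_scan)
  fs <- eval_potential(spec, xs)
  i <- if (maximum) which.max(fs) else which.min(fs)
  lo <- xs[max(1, i - 2)]; hi <- xs[min(n_scan, i + 2)]
  op <- optimize(function(z) eval_potential(spec, z),
                 lower = lo, upper = hi, maximum = maximum, tol = 1e-12)
  if (maximum) c(x = op$maximum, f = op$objective)
  else c(x = op$minimum, f = op$objective)
}

# Achieved (dG, barrier) of a two-well spec: dG = F(minB) - F(minA),
# barrier = max on the path between minima - F(minA).
achieved_two_well <- function(spec, basinA, basinB, path_interval) {
  mA <- refine_extremum(spec, spec$basins[[basinA]])
  mB <- refine_extremum(spec, spec$basins[[basinB]])
  M <- refine_extremum(spec, path_interval, maximum = TRUE)
  c(dG = unname(mB["f"] - mA["f"]), barrier = unname(M["f"] - mA["f"]),
    fA = unname(mA["f"]))
}

# Newton iteration on the two Gaussian-well heights so the achieved
# (dG, barrier) hit the targets. `make` builds a spec from heights c(hA, hB)
# (hA: well of the reference/source basin). Returns the calibrated spec.
calibrate_two_well <- function(make, h0, targets, basinA, basinB,
                               path_interval, tol = 1e-9, max_iter = 30) {
  h <- h0
  for (it in seq_len(max_iter)) {
    spec <- make(h)
    a <- achieved_two_well(spec, basinA, basinB, path_interval)
    r <- c(a["dG"] - targets["dG"], a["barrier"] - targets["barrier"])
    if (max(abs(r)) < tol) break
    eps <- 1e-6
    J <- matrix(0, 2, 2)
    for (j in 1:2) {
      hp <- h; hp[j] <- hp[j] + eps
      ap <- achieved_two_well(make(hp), basinA, basinB, path_interval)
      J[, j] <- (c(ap["dG"], ap["barrier"]) - c(a["dG"], a["barrier"])) / eps
    }
    h <- h - solve(J, r)
  }
  spec <- make(h)
  # shift so the reference-basin minimum sits at zero
  a <- achieved_two_well(spec, basinA, basinB, path_interval)
  spec$c0 <- spec$c0 - a["fA"]
  names(spec$c0) <- NULL
  spec
}

#' Periodic dihedral double-well potential
#'
#' Builds the model free-energy profile of amide omega isomerization on
#' \eqn{[-\pi, \pi)}: a cis well at \eqn{\omega = 0} and a trans well at
#' \eqn{\omega = \pi}, as Gaussian wells sunk into a plateau, calibrated so
#' that \eqn{F(cis) - F(trans)} equals `dG` and the maximum between the
#' minima sits `barrier` above the trans minimum.
#'
#' @param dG Trans-to-cis free-energy difference, kcal/mol (cis higher when
#'   positive).
#' @param barrier Barrier from the trans minimum, kcal/mol; must exceed
#'   `max(0, dG)`.
#' @param widths Gaussian widths (standard deviations, rad) of the trans and
#'   cis wells.
#' @param equalize_curvature If TRUE (default), rescale the cis width so
#'   both wells have equal stiffness; the basin-integrated free-energy
#'   difference then coincides with the point `dG` (up to small anharmonic
#'   corrections) instead of carrying a kT/2 log-curvature offset.
#' @return A `potential_spec` with basins `"trans"` (around \eqn{\pi},
#'   wrapped) and `"cis"` (around 0) partitioning the circle at
#'   \eqn{\pm\pi/2}.
#' @export
make_dihedral_potential <- function(dG, barrier, widths = c(0.35, 0.35),
                                    equalize_curvature = TRUE) {
  if (!(barrier > max(0, dG)))
    stop("infeasible landscape: barrier must exceed max(0, dG)")
  if (any(widths <= 0)) stop("widths must be positive")
  basins <- list(trans = c(pi / 2, 3 * pi / 2), cis = c(-pi / 2, pi / 2))
  fit <- function(widths) {
    make <- function(h) {
      new_potential_spec(
        kind = "dihedral", lo = -pi, hi = pi, periodic = TRUE,
        c0 = barrier, cos_a = numeric(0),
        gauss = rbind(c(-h[1], pi, widths[1]), c(-h[2], 0, widths[2])),
        basins = basins,
        meta = list(dG = dG, barrier = barrier, widths = widths))
    }
    calibrate_two_well(make, h0 = c(barrier, barrier - dG),
                       targets = c(dG = dG, barrier = barrier),
                       basinA = "trans", basinB = "cis",
                       path_interval = c(0.05, pi - 0.05))
  }
  spec <- fit(widths)
  if (equalize_curvature) {
    for (it in 1:3) {
      H <- -spec$gauss[, 1]   # trans, cis well depths
      widths[2] <- widths[1] * sqrt(H[2] / H[1])
      spec <- fit(widths)
    }
  }
  spec
}

#' Radial encapsulation double-well potential
#'
#' Bounded non-periodic profile on `[0, r_max]` for guest encapsulation:
#' a bound ("in") well inside the cage, an exit barrier at the portal
#' `r_cage`, and a flat unbound ("out") region at zero. The declared "out"
#' basin interval has length equal to the thermal width of the bound well at
#' 300 K, the standard-state convention under which the basin-integrated
#' binding free energy equals the point `dG_enc`.
#'
#' @param dG_enc Binding free energy, kcal/mol; must be negative.
#' @param barrier_off Expulsion barrier from the bound well, kcal/mol; must
#'   exceed `-dG_enc`.
#' @param r_cage Portal position (reduced length).
#' @param r_max Domain end.
#' @param widths Gaussian widths of the bound well and the portal barrier.
#' @return A `potential_spec` with basins `"in"` and `"out"`.
#' @export
make_encapsulation_potential <- function(dG_enc, barrier_off, r_cage = 1,
                                         r_max = 3,
                                         widths = c(r_cage / 6, r_cage / 6)) {
  if (dG_enc >= 0) stop("dG_enc must be negative (favorable binding)")
  if (barrier_off <= 0) stop("barrier_off must be positive")
  if (barrier_off < -dG_enc)
    stop("infeasible landscape: no barrier from outside (barrier_off < -dG_enc)")
  if (!(r_cage > 0 && r_cage < r_max)) stop("need 0 < r_cage < r_max")
  r_in <- r_cage / 2
  basins_of <- function(spec) spec$basins
  make <- function(h) {
    new_potential_spec(
      kind = "encapsulation", lo = 0, hi = r_max, periodic = FALSE,
      c0 = 0, cos_a = numeric(0),
      gauss = rbind(c(-h[1], r_in, widths[1]),
                    c(h[2], r_cage, widths[2])),
      basins = list("in" = c(0, r_cage), out = c(r_cage, r_max)),
      meta = list(dG_enc = dG_enc, barrier_off = barrier_off,
                  r_cage = r_cage, r_in = r_in, widths = widths))
  }
  spec <- calibrate_two_well(make, h0 = c(-dG_enc, barrier_off + dG_enc),
                             targets = c(dG = -dG_enc, barrier = barrier_off),
                             basinA = "in", basinB = "out",
                             path_interval = c(r_in + widths[1],
                                               r_cage + 3 * widths[2]))
  # the flat out region sits at 0 but calibrate_two_well shifted F(in)=0;
  # re-anchor to the out plateau so F(out)=0, F(in)=dG_enc
  spec$c0 <- spec$c0 - eval_potential(spec, r_max)
  # out "basin" interval: thermal width of the bound well, placed clear of
  # the portal barrier
  kT <- kT_of(default_temperature)
  kappa <- abs(spec$gauss[1, 1]) / widths[1]^2
  L_out <- sqrt(2 * pi * kT / kappa)
  o0 <- min(r_cage + 4 * widths[2], r_max - L_out)
  spec$basins$out <- c(o0, o0 + L_out)
  spec
}

#' Two-basin reaction profile for hydroxide attack
#'
#' Model free-energy profile along the nucleophilic-attack coordinate with a
#' reactant basin "R" and a tetrahedral-intermediate basin "TI".
#'
#' @param dG_reac `F(TI) - F(R)` in kcal/mol (negative when the intermediate
#'   is more stable, i.e. `K_reac > 1`).
#' @param barrier_fwd Forward (attack) barrier from R, kcal/mol.
#' @param widths Gaussian widths of the R and TI wells.
#' @return A `potential_spec` on `[0, 3]` with basins `"R"` and `"TI"`.
#' @export
make_reaction_profile <- function(dG_reac, barrier_fwd,
                                  widths = c(0.25, 0.25)) {
  if (!(barrier_fwd > max(0, dG_reac)))
    stop("infeasible landscape: barrier_fwd must exceed max(0, dG_reac)")
  sR <- 0.75; sTI <- 2.25
  make <- function(h) {
    new_potential_spec(
      kind = "reaction", lo = 0, hi = 3, periodic = FALSE,
      c0 = barrier_fwd, cos_a = numeric(0),
      gauss = rbind(c(-h[1], sR, widths[1]), c(-h[2], sTI, widths[2])),
      basins = list(R = c(0, 1.5), TI = c(1.5, 3)),
      meta = list(dG_reac = dG_reac, barrier_fwd = barrier_fwd,
                  widths = widths))
  }
  calibrate_two_well(make, h0 = c(barrier_fwd, barrier_fwd - dG_reac),
                     targets = c(dG = dG_reac, barrier = barrier_fwd),
                     basinA = "R", basinB = "TI",
                     path_interval = c(sR + widths[1], sTI - widths[2]))
}

#' Serialize / restore a potential spec
#'
#' Potential specs round-trip through plain lists (and hence YAML config
#' files) losslessly.
#'
#' @param spec A `potential_spec`.
#' @param x A list previously produced by `potential_to_list()` (or read
#'   from YAML).
#' @param path File path for the YAML variants.
#' @return `potential_to_list()` a plain list; `potential_from_list()` a
#'   `potential_spec`.
#' @export
potential_to_list <- function(spec) {
  stopifnot(inherits(spec, "potential_spec"))
  out <- unclass(spec)
  out$gauss <- lapply(seq_len(nrow(spec$gauss)), function(i)
    as.list(setNames(spec$gauss[i, ], c("height", "center", "width"))))
  out
}

#' @rdname potential_to_list
#' @export
potential_from_list <- function(x) {
  g <- if (length(x$gauss))
    do.call(rbind, lapply(x$gauss, function(r)
      c(r$height, r$center, r$width)))
  else matrix(numeric(0), 0, 3)
  basins <- lapply(x$basins, as.numeric)
  new_potential_spec(x$kind, x$lo, x$hi, x$periodic, x$c0,
                     as.numeric(x$cos_a), g, basins,
                     meta = x$meta)
}

#' @rdname potential_to_list
#' @export
write_potential_yaml <- function(spec, path) {
  writeLines(yaml::as.yaml(potential_to_list(spec), precision = 15), path)
  invisible(path)
}

#' @rdname potential_to_list
#' @export
read_potential_yaml <- function(path) {
  potential_from_list(yaml::read_yaml(path))
}
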