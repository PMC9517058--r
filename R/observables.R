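# Structural observables on bead coordinates: switching-function contacts,
# center distances, Shrake-Rupley SASA and histogram free-energy surfaces.

#' Switching-function contact count
#'
#' Coordination number between two bead groups with the rational switching
#' function s(r) = (1 - (r/r0)^n) / (1 - (r/r0)^m); the removable
#' singularity at r = r0 evaluates to n/m.
#'
#' @param coords Numeric matrix (beads x 3).
#' @param group_a,group_b Row-index vectors of the two groups (pairs with
#'   identical indices are skipped).
#' @param r0 Switching radius (> 0).
#' @param n,m Exponents, 0 < n < m (defaults 6 and 12).
#' @return Total (fractional) contact count.
#' @export
switching_contacts <- function(coords, group_a, group_b, r0, n = 6, m = 12) {
  if (length(group_a) == 0 || length(group_b) == 0)
    stop("empty bead groups")
  stopifnot(r0 > 0, n > 0, n < m)
  A <- coords[group_a, , drop = FALSE]
  B <- coords[group_b, , drop = FALSE]
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
  r <- sqrt(pmax(d2, 0))
  x <- r / r0
  s <- ifelse(abs(x - 1) < 1e-9, n / m, (1 - x^n) / (1 - x^m))
  same <- outer(group_a, group_b, "==")
  sum(s[!same])
}

#' Distance between group geometric centers
#'
#' Euclidean distance between the unweighted geometric centers of two bead
#' selections (e.g. cage centre vs guest centre).
#'
#' @inheritParams switching_contacts
#' @param cage_selection,guest_selection Row-index vectors.
#' @return Distance (reduced length).
#' @export
center_distance <- function(coords, cage_selection, guest_selection) {
  if (length(cage_selection) == 0 || length(guest_selection) == 0)
    stop("empty selection")
  ca <- colMeans(coords[cage_selection, , drop = FALSE])
  cb <- colMeans(coords[guest_selection, , drop = FALSE])
  sqrt(sum((ca - cb)^2))
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Quasi-uniform test points (deterministic golden-spiral lattice) on each
#' sphere inflated by the probe radius; points inside any other inflated
#' sphere are occluded. Exact duplicate spheres are merged first so
#' coincident beads are not double-counted.
#'
#' @param centers Numeric matrix (spheres x 3); zero rows give area 0.
#' @param radii Per-sphere radii (> 0).
#' @param probe_radius Probe radius (>= 0).
#' @param n_points Test points per sphere (>= 32).
#' @return Total exposed area.
#' @export
shrake_rupley_sasa <- function(centers, radii, probe_radius = 0,
                               n_points = 960) {
  if (is.null(centers) || nrow(centers) == 0) return(0)
  stopifnot(n_points >= 32, all(radii > 0), probe_radius >= 0)
  key <- paste(centers[, 1], centers[, 2], centers[, 3], radii)
  keep <- !duplicated(key)
  centers <- centers[keep, , drop = FALSE]
  radii <- radii[keep]
  ns <- nrow(centers)
  pts <- golden_spiral_points(n_points)
  R <- radii + probe_radius
  total <- 0
  for (i in seq_len(ns)) {
    p <- sweep(pts * R[i], 2, centers[i, ], "+")
    exposed <- rep(TRUE, n_points)
    for (j in seq_len(ns)) {
      if (j == i) next
      d2 <- (p[, 1] - centers[j, 1])^2 + (p[, 2] - centers[j, 2])^2 +
        (p[, 3] - centers[j, 3])^2
      exposed <- exposed & d2 > R[j]^2
      if (!any(exposed)) break
    }
    total <- total + mean(exposed) * 4 * pi * R[i]^2
  }
  total
}

#' Observable series over bead-system frames
#'
#' Applies one of the per-frame observables to every frame of a
#' `bead_system`.
#'
#' @param bs A `bead_system`.
#' @param observable `"center_distance"`, `"contacts"` (guest vs cage,
#'   switching function) or `"sasa"` (guest + cage SASA of the guest bead).
#' @param r0,n,m Switching parameters for `"contacts"`.
#' @param probe_radius,n_points SASA parameters.
#' @return An `observable_series` data.frame with `time` and `value`.
#' @export
observable_series <- function(bs, observable = c("center_distance",
                                                 "contacts", "sasa"),
                              r0 = bs$params$shell_radius / 2, n = 6, m = 12,
                              probe_radius = 0, n_points = 256) {
  observable <- match.arg(observable)
  stopifnot(inherits(bs, "bead_system"))
  ncage <- nrow(bs$cage)
  vals <- vapply(seq_len(nrow(bs$guest)), function(f) {
    coords <- rbind(bs$cage, bs$guest[f, ])
    switch(observable,
      center_distance = center_distance(coords, seq_len(ncage), ncage + 1),
      contacts = switching_contacts(coords, ncage + 1, seq_len(ncage), r0,
                                    n, m),
      sasa = {
        pts <- sweep(golden_spiral_points(n_points) *
                       (bs$radii[ncage + 1] + probe_radius), 2,
                     bs$guest[f, ], "+")
        # exposed fraction of the guest sphere against the cage beads
        expo <- rep(TRUE, n_points)
        for (j in seq_len(ncage)) {
          d2 <- rowSums(sweep(pts, 2, bs$cage[j, ])^2)
          expo <- expo & d2 > (bs$radii[j] + probe_radius)^2
        }
        mean(expo) * 4 * pi * (bs$radii[ncage + 1] + probe_radius)^2
      })
  }, numeric(1))
  structure(data.frame(time = bs$times, value = vals),
            class = c("observable_series", "data.frame"),
            observable = observable)
}

#' Two-dimensional histogram free-energy surface
#'
#' F(x, y) = -kT log(bin density), min-shifted; empty bins are NA.
#'
#' @param x,y Equal-length coordinate series.
#' @param bins Bins per axis (single number or length-2; >= 2).
#' @param temperature Temperature in K.
#' @return List with `xmid`, `ymid` (bin centers) and matrix `F`.
#' @export
histogram_fes2d <- function(x, y, bins = 32,
                            temperature = default_temperature) {
  stopifnot(length(x) == length(y))
  bins <- rep(bins, length.out = 2)
  if (any(bins < 2)) stop("need at least 2 bins per axis")
  xe <- seq(min(x), max(x), length.out = bins[1] + 1)
  ye <- seq(min(y), max(y), length.out = bins[2] + 1)
  ix <- pmin(findInterval(x, xe, rightmost.closed = TRUE), bins[1])
  iy <- pmin(findInterval(y, ye, rightmost.closed = TRUE), bins[2])
  cnt <- matrix(0, bins[1], bins[2])
  t2 <- table(factor(ix, levels = seq_len(bins[1])),
              factor(iy, levels = seq_len(bins[2])))
  cnt[] <- as.numeric(t2)
  if (all(cnt == 0)) stop("all histogram bins are empty")
  F <- ifelse(cnt > 0, -kT_of(temperature) * log(cnt / sum(cnt)), NA_real_)
  F <- F - min(F, na.rm = TRUE)
  list(xmid = (xe[-1] + xe[-length(xe)]) / 2,
       ymid = (ye[-1] + ye[-length(ye)]) / 2, F = F)
}
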