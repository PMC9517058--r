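# Shared oracles and fixtures for the test suite.

kT300 <- cagekin::kB_kcal * 300

# Boltzmann-weighted basin integral of an analytic potential by adaptive
# quadrature, independent of the package's grid-based estimators.
quad_Z <- function(pot, interval, temperature = 300) {
  integrate(function(s) exp(-eval_potential(pot, s) / (kB_kcal * temperature)),
            interval[1], interval[2], rel.tol = 1e-10)$value
}

# Basin free-energy difference A -> B by quadrature (the oracle for the
# grid-trapezoid implementation).
quad_dG <- function(pot, basinA, basinB, temperature = 300) {
  -kB_kcal * temperature *
    log(quad_Z(pot, pot$basins[[basinB]], temperature) /
          quad_Z(pot, pot$basins[[basinA]], temperature))
}

# Brute-force unbiased mean first-passage time (oracle for infrequent
# metadynamics): an ensemble with effectively no bias deposition.
brute_force_mfpt <- function(pot, source, target, n_replicas = 30,
                             seed = 1, max_steps = 2e7) {
  mp <- metad_params(hill_height0 = 1e-12, hill_sigma = 0.25,
                     deposit_stride = 1e9, bias_factor = 5)
  ev <- run_infrequent_ensemble(pot, run_params(seed = seed), mp,
                                source, target, n_replicas,
                                max_steps = max_steps)
  mean(ev$physical_time[!ev$censored])
}

# Dense free-energy grid for a potential (periodic grids drop the duplicate
# endpoint).
fes_grid <- function(pot, n = 256) {
  if (pot$periodic) seq(pot$lo, pot$hi - (pot$hi - pot$lo) / n,
                        length.out = n)
  else seq(pot$lo, pot$hi, length.out = n)
}

# exact FES of an analytic potential, as a free_energy_profile
true_fes <- function(pot, n = 256, temperature = 300) {
  g <- fes_grid(pot, n)
  cagekin:::new_free_energy_profile(g, eval_potential(pot, g), temperature,
                                    pot$periodic, pot$basins,
                                    source = "analytic")
}

# Brute-force pairwise switching-function loop (oracle for the vectorized
# implementation).
brute_contacts <- function(coords, ga, gb, r0, n = 6, m = 12) {
  tot <- 0
  for (i in ga) for (j in gb) {
    if (i == j) next
    r <- sqrt(sum((coords[i, ] - coords[j, ])^2))
    x <- r / r0
    tot <- tot + if (abs(x - 1) < 1e-9) n / m else (1 - x^n) / (1 - x^m)
  }
  tot
}

rotation_matrix <- function(theta, axis = c(0, 0, 1)) {
  a <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -a[3], a[2], a[3], 0, -a[1], -a[2], a[1], 0), 3, 3)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * K %*% K
}

# reactivity inputs for hand-checkable three-term arithmetic
simple_input <- function(chi, pconf, nw, pin = NULL, label = "x") {
  reactivity_input(chi = chi, pconf = pconf, nw = nw, pin = pin,
                   label = label)
}
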