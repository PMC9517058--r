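# FES estimation, basin thermodynamics and equilibrium quantities.

test_that("single-hill FES follows the well-tempered prefactor", {
  h <- cagekin:::new_hills_log(
    data.frame(time = 1, center = 0, sigma = 0.35, height = 1),
    bias_factor = 10, hill_height0 = 1, periodic = TRUE, lo = -pi, hi = pi)
  fes <- fes_from_hills(h, grid = seq(-pi, pi - 2 * pi / 256,
                                      length.out = 256))
  # depth of the dip at the hill center relative to far field
  far <- fes$F[which.min(abs(fes$grid + pi))]
  ctr <- fes$F[which.min(abs(fes$grid))]
  expect_equal(far - ctr, -(10 / 9) * (-1), tolerance = 1e-3)
  empty <- cagekin:::new_hills_log(
    data.frame(time = numeric(0), center = numeric(0),
               sigma = numeric(0), height = numeric(0)),
    bias_factor = 10, hill_height0 = Inf, periodic = TRUE, lo = -pi, hi = pi)
  expect_error(fes_from_hills(empty), "empty")
})

test_that("converged FES on a symmetric well is symmetric", {
  pot <- make_dihedral_potential(0, 3)
  run <- run_wtmetad(pot, run_params(n_steps = 2e6, seed = 21,
                                     save_stride = 40),
                     metad_params(hill_height0 = 0.3, hill_sigma = 0.3,
                                  deposit_stride = 500, bias_factor = 8))
  fes <- fes_from_hills(run$hills)
  expect_lt(abs(basin_free_energy_difference(fes, "trans", "cis")), 0.2)
})

test_that("hills-based FES matches the generating landscape", {
  pot <- make_dihedral_potential(1.5, 5)
  run <- run_wtmetad(pot, run_params(n_steps = 4e6, seed = 22,
                                     save_stride = 40),
                     metad_params(hill_height0 = 0.3, hill_sigma = 0.3,
                                  deposit_stride = 500, bias_factor = 10))
  fes <- fes_from_hills(run$hills)
  expect_lt(fes_rmsd(fes, true_fes(pot, n = 512)), 0.3)
})

test_that("reweighting weights are normalized and uniform at zero bias", {
  pot <- make_dihedral_potential(1, 3)
  tr <- run_langevin(pot, run_params(n_steps = 1e4, seed = 2,
                                     save_stride = 100))
  empty <- cagekin:::new_hills_log(
    data.frame(time = numeric(0), center = numeric(0),
               sigma = numeric(0), height = numeric(0)),
    bias_factor = 10, hill_height0 = Inf, periodic = TRUE, lo = -pi,
    hi = pi, run_id = tr$run_id)
  w <- reweight_trajectory(tr, empty)
  expect_equal(sum(w), 1, tolerance = 1e-12)
  expect_lt(diff(range(w)), 1e-15)
  # mismatched runs are rejected
  run <- run_wtmetad(pot, run_params(n_steps = 1e5, seed = 3),
                     metad_params(hill_height0 = 0.3, hill_sigma = 0.3,
                                  deposit_stride = 500, bias_factor = 8))
  expect_error(reweight_trajectory(tr, run$hills), "different runs")
})

test_that("hills and reweighted-histogram estimators agree", {
  pot <- make_dihedral_potential(1.5, 6)
  run <- run_wtmetad(pot, run_params(n_steps = 4e6, seed = 23,
                                     save_stride = 40),
                     metad_params(hill_height0 = 0.3, hill_sigma = 0.3,
                                  deposit_stride = 500, bias_factor = 10))
  fes_h <- fes_from_hills(run$hills,
                          grid = fes_grid(pot, 128))
  tr <- run$trajectory
  half <- (length(tr$cv) %/% 2 + 1):length(tr$cv)
  tr2 <- tr; tr2$cv <- tr$cv[half]
  w <- reweight_trajectory(tr2, run$hills)
  fes_s <- fes_from_samples(tr2$cv, w, grid = fes_grid(pot, 128),
                            periodic = TRUE, basins = pot$basins)
  expect_lt(fes_rmsd(fes_h, fes_s), 0.3)
})

test_that("sample-based FES has Boltzmann curvature and flags empty bins", {
  set.seed(31)
  sig <- 0.4
  x <- rnorm(2e5, sd = sig)
  g <- seq(-1, 1, length.out = 41)
  fes <- fes_from_samples(x, grid = g)
  # quadratic fit of curvature kT/sigma^2
  fit <- lm(fes$F ~ I(g^2))
  expect_lt(abs(coef(fit)[2] - kT300 / (2 * sig^2)) /
              (kT300 / (2 * sig^2)), 0.1)
  # far-out empty bins are NA, not clipped
  g2 <- seq(-10, 10, length.out = 81)
  fes2 <- fes_from_samples(x, grid = g2)
  expect_true(anyNA(fes2$F))
  expect_error(fes_from_samples(x[1:10], grid = g), "samples")
})

test_that("uniform samples give a flat profile", {
  set.seed(5)
  x <- runif(2e5, -1, 1)
  fes <- fes_from_samples(x, grid = seq(-0.9, 0.9, length.out = 31))
  expect_lt(diff(range(fes$F)), 0.05)
})

test_that("Boltzmann samples of a landscape recover its basin dG", {
  pot <- make_dihedral_potential(1, 2.5)
  tr <- run_langevin(pot, run_params(n_steps = 4e6, seed = 25,
                                     save_stride = 20), s0 = pi)
  fes <- fes_from_samples(tr$cv, grid = fes_grid(pot, 72),
                          periodic = TRUE, basins = pot$basins)
  expect_lt(abs(basin_free_energy_difference(fes, "trans", "cis") - 1), 0.2)
})

test_that("basin dG quadrature matches a high-resolution oracle", {
  pot <- make_dihedral_potential(2.2, 8)
  fes <- true_fes(pot, n = 4096)
  dg <- basin_free_energy_difference(fes, "trans", "cis")
  expect_lt(abs(dg - quad_dG(pot, "trans", "cis")), 1e-3)
  # symmetric profile gives 0
  pot0 <- make_dihedral_potential(0, 5)
  expect_lt(abs(basin_free_energy_difference(true_fes(pot0, 2048),
                                             "trans", "cis")), 1e-6)
  # antisymmetry: K(A->B) * K(B->A) = 1
  KAB <- equilibrium_constant(dg)
  KBA <- equilibrium_constant(
    basin_free_energy_difference(fes, "cis", "trans"))
  expect_equal(KAB * KBA, 1, tolerance = 1e-10)
})

test_that("point convention reads minima directly", {
  pot <- make_dihedral_potential(2.2, 8)
  fes <- true_fes(pot, n = 4096)
  expect_lt(abs(basin_free_energy_difference(fes, "trans", "cis",
                                             convention = "point") - 2.2),
            1e-3)
})

test_that("undefined bins inside a basin abort basin integration", {
  g <- seq(-pi, pi - 2 * pi / 64, length.out = 64)
  F <- rep(1, 64); F[30] <- NA
  fes <- cagekin:::new_free_energy_profile(
    g, F, 300, TRUE, list(cis = c(-pi / 2, pi / 2),
                          trans = c(pi / 2, 3 * pi / 2)))
  expect_error(basin_free_energy_difference(fes, "trans", "cis"),
               "undefined")
})

test_that("barrier_height reads path maxima with periodic shortcuts", {
  pot <- make_dihedral_potential(2.2, 8)
  fes <- true_fes(pot, n = 2048)
  expect_lt(abs(barrier_height(fes, "trans", "cis") - 8), 0.01)
  expect_lt(abs(barrier_height(fes, "cis", "trans") - (8 - 2.2)), 0.01)
  # monotone two-level profile: barrier equals the level difference
  g <- seq(0, 1, length.out = 50)
  F2 <- c(rep(0, 25), rep(2, 25))
  fes2 <- cagekin:::new_free_energy_profile(
    g, F2, 300, FALSE, list(a = c(0, 0.4), b = c(0.6, 1)))
  expect_equal(barrier_height(fes2, "a", "b"), 2)
})

test_that("equilibrium constants reproduce the printed K_conf pairs", {
  expect_equal(equilibrium_constant(6.5, 300), 1.8e-5, tolerance = 0.03)
  expect_equal(equilibrium_constant(2.7, 300), 1.1e-2, tolerance = 0.03)
  expect_identical(equilibrium_constant(0), 1)
})

test_that("partition probability is monotone and bounded", {
  expect_identical(partition_probability(0), 0)
  expect_equal(partition_probability(1), 0.5)
  expect_equal(partition_probability(1.5e3), 0.99933, tolerance = 1e-4)
  K <- 10^seq(-3, 8, length.out = 40)
  p <- partition_probability(K)
  expect_true(all(diff(p) > 0))
  expect_true(all(p > 0 & p < 1))
  expect_error(partition_probability(-1), "non-negative")
})

test_that("conformer probability profiles honor both conventions", {
  pot <- make_dihedral_potential(2.7, 19.8)
  fes <- true_fes(pot, n = 2048)
  ct <- conformer_probability_profile(fes, reference = pi,
                                      convention = "point")
  i_ref <- which.min(abs(ct$omega - pi + 2 * pi / 2048))
  expect_equal(max(ct$pconf), 1, tolerance = 1e-9)
  cb <- conformer_probability_profile(fes, reference = pi,
                                      convention = "basin")
  p_cis <- cb$pconf[cb$omega == "cis"]
  expect_equal(p_cis, 1.1e-2, tolerance = 0.05)
  expect_equal(cb$pconf[cb$omega == "trans"], 1)
  # flat profile: all point probabilities 1
  flat <- cagekin:::new_free_energy_profile(
    seq(-pi, pi - 2 * pi / 32, length.out = 32), rep(0, 32), 300, TRUE,
    NULL)
  cf <- conformer_probability_profile(flat, reference = 0)
  expect_true(all(abs(cf$pconf - 1) < 1e-12))
})

test_that("FES TSV export carries metadata and data", {
  pot <- make_dihedral_potential(1, 3)
  fes <- true_fes(pot, 64)
  path <- tempfile(fileext = ".tsv")
  write_fes_tsv(fes, path)
  lines <- readLines(path)
  expect_match(lines[1], "temperature_K")
  tab <- read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  expect_equal(nrow(tab), 64)
})
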