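# Langevin / metadynamics sampler and PLUMED-dialect I/O.

flat_potential <- function() {
  cagekin:::new_potential_spec(
    "flat", -pi, pi, TRUE, 0, numeric(0),
    matrix(numeric(0), 0, 3), list(all = c(-pi, pi)))
}

test_that("free diffusion has MSD ~ 2 D t", {
  pot <- flat_potential()
  msds <- sapply(1:20, function(k) {
    tr <- run_langevin(pot, run_params(n_steps = 2000, seed = 40 + k,
                                       save_stride = 2000), s0 = 0)
    tr$cv[1]^2
  })
  Dt2 <- 2 * 0.02 * 2000 * 0.005
  expect_lt(abs(mean(msds) - Dt2) / Dt2, 1)  # 20 replicas, chi2 spread
})

test_that("harmonic well sampling has Boltzmann variance", {
  # deep narrow Gaussian well ~ harmonic with kappa = depth / width^2
  pot <- cagekin:::new_potential_spec(
    "well", -pi, pi, TRUE, 0, numeric(0),
    rbind(c(-30, 0, 0.6)), list(well = c(-1, 1)))
  tr <- run_langevin(pot, run_params(n_steps = 6e5, seed = 8,
                                     save_stride = 5), s0 = 0)
  expect_lt(abs(var(tr$cv) - kT300 / (30 / 0.36)) / (kT300 / (30 / 0.36)),
            0.05)
})

test_that("trajectories are bit-reproducible under a fixed seed", {
  pot <- make_dihedral_potential(1, 3)
  t1 <- run_langevin(pot, run_params(n_steps = 5e4, seed = 5))
  t2 <- run_langevin(pot, run_params(n_steps = 5e4, seed = 5))
  expect_identical(t1$cv, t2$cv)
})

test_that("unbiased sampling matches exp(-F/kT) on two-basin landscapes", {
  # chi-square goodness of fit on a 50-bin histogram, barrier <= 4 kT,
  # with the effective sample size from the integrated autocorrelation
  pot <- make_dihedral_potential(0.5, 2.5 * kT300)
  tr <- run_langevin(pot, run_params(n_steps = 4e6, seed = 17,
                                     save_stride = 100), s0 = pi)
  x <- tr$cv; n <- length(x)
  rho <- acf(cos(x), lag.max = 400, plot = FALSE)$acf[-1]
  tau_int <- 1 + 2 * sum(rho[cumsum(rho < 0.05) == 0])
  neff <- n / (2 * tau_int)
  edges <- seq(-pi, pi, length.out = 51)
  obs <- as.numeric(table(cut(x, edges)))
  mids <- (edges[-1] + edges[-51]) / 2
  p <- exp(-eval_potential(pot, mids) / kT300)
  p <- p / sum(p)
  chi2 <- sum((obs / n - p)^2 / p) * neff
  expect_gt(pchisq(chi2, df = 49, lower.tail = FALSE), 0.01)
})

test_that("oversized steps raise a step-size error", {
  pot <- make_dihedral_potential(1, 20, widths = c(0.05, 0.05))
  expect_error(
    run_langevin(pot, run_params(dt = 5, diffusion = 10, n_steps = 1000,
                                 seed = 1)),
    "step-size")
})

test_that("hill heights temper with accumulated bias", {
  pot <- make_dihedral_potential(0.5, 2)
  run <- run_wtmetad(pot, run_params(n_steps = 4e5, seed = 2),
                     metad_params(hill_height0 = 0.5, hill_sigma = 0.3,
                                  deposit_stride = 200, bias_factor = 5))
  h <- run$hills
  expect_true(all(h$height <= 0.5 + 1e-12))
  expect_lt(mean(tail(h$height, 50)), mean(head(h$height, 50)))
  # deposited height equals h0 exp(-V(s,t-)/( (gamma-1) kT ))
  i <- nrow(h)
  V_before <- evaluate_bias(h, h$center[i], t = h$time[i] - 1e-9)
  # grid interpolation inside the engine allows a small discrepancy
  expect_lt(abs(h$height[i] - 0.5 * exp(-V_before / (4 * kT300))), 1e-3)
})

test_that("infinite bias factor gives constant hill heights", {
  pot <- make_dihedral_potential(0.5, 2)
  run <- run_wtmetad(pot, run_params(n_steps = 1e5, seed = 3),
                     metad_params(hill_height0 = 0.05, hill_sigma = 0.3,
                                  deposit_stride = 300, bias_factor = Inf))
  expect_true(all(abs(run$hills$height - 0.05) < 1e-12))
})

test_that("WT-MetaD recovers a 1 kcal/mol basin difference over 3 seeds", {
  pot <- make_dihedral_potential(1, 4)
  rec <- sapply(1:3, function(k) {
    run <- run_wtmetad(pot, run_params(n_steps = 4e6, seed = 30 + k,
                                       save_stride = 40),
                       metad_params(hill_height0 = 0.3, hill_sigma = 0.3,
                                    deposit_stride = 500, bias_factor = 8))
    basin_free_energy_difference(fes_from_hills(run$hills), "trans", "cis")
  })
  expect_lt(abs(mean(rec) - 1), 0.2)
})

test_that("evaluate_bias obeys its Gaussian and periodic contracts", {
  h <- cagekin:::new_hills_log(
    data.frame(time = 1, center = 0, sigma = 0.35, height = 1),
    bias_factor = 10, hill_height0 = 1, periodic = TRUE, lo = -pi, hi = pi)
  expect_equal(evaluate_bias(h, 0), 1, tolerance = 1e-12)
  empty <- cagekin:::new_hills_log(
    data.frame(time = numeric(0), center = numeric(0),
               sigma = numeric(0), height = numeric(0)),
    bias_factor = 10, hill_height0 = Inf, periodic = TRUE, lo = -pi, hi = pi)
  expect_identical(evaluate_bias(empty, c(0, 1)), c(0, 0))
  # wrap-around: hill near +pi seen from near -pi
  h2 <- cagekin:::new_hills_log(
    data.frame(time = 1, center = pi - 0.1, sigma = 0.35, height = 1),
    bias_factor = 10, hill_height0 = 1, periodic = TRUE, lo = -pi, hi = pi)
  expect_equal(evaluate_bias(h2, -pi + 0.1),
               exp(-0.5 * 0.2^2 / 0.35^2), tolerance = 1e-9)
  # time cutoff
  h3 <- cagekin:::new_hills_log(
    data.frame(time = c(1, 2), center = c(0, 0), sigma = 0.35,
               height = c(1, 1)),
    bias_factor = 10, hill_height0 = 1, periodic = TRUE, lo = -pi, hi = pi)
  expect_equal(evaluate_bias(h3, 0, t = 1.5), 1, tolerance = 1e-12)
})

test_that("infrequent ensembles obey their contracts on a tiny barrier", {
  pot <- make_dihedral_potential(0, 0.3)  # ~0.5 kT barrier
  # deposition far slower than the transit time: no hill lands before exit
  mp <- metad_params(hill_height0 = 0.2, hill_sigma = 0.25,
                     deposit_stride = 1e6, bias_factor = 5)
  ev <- run_infrequent_ensemble(pot, run_params(seed = 6), mp,
                                "trans", "cis", n_replicas = 8)
  expect_false(any(ev$censored))
  # transitions happen before any hill: rescaled == physical time
  expect_lt(max(abs(ev$rescaled_time - ev$physical_time) /
                  ev$physical_time), 1e-9)
  expect_true(all(ev$rescaled_time >=
                    ev$physical_time * (1 - 1e-9)))
  ev2 <- run_infrequent_ensemble(pot, run_params(seed = 6), mp,
                                 "trans", "cis", n_replicas = 8)
  expect_identical(ev$rescaled_time, ev2$rescaled_time)
  expect_error(run_infrequent_ensemble(pot, run_params(seed = 1), mp,
                                       "trans", "trans", 4), "differ")
  expect_error(
    run_infrequent_ensemble(pot, run_params(seed = 1),
                            metad_params(deposit_stride = 10), "trans",
                            "cis", 4),
    "floor")
})

test_that("infrequent rescaled times track the unbiased MFPT at 6 kT", {
  pot <- make_dihedral_potential(1, 6 * kT300)
  bf <- brute_force_mfpt(pot, "trans", "cis", n_replicas = 30, seed = 55)
  mp <- metad_params(hill_height0 = 0.12, hill_sigma = 0.25,
                     deposit_stride = 4000, bias_factor = 6)
  ev <- run_infrequent_ensemble(pot, run_params(seed = 77), mp,
                                "trans", "cis", n_replicas = 20,
                                max_steps = 3e7)
  ratio <- mean(ev$rescaled_time[!ev$censored]) / bf
  expect_gt(ratio, 0.5)
  expect_lt(ratio, 2)
})

test_that("HILLS files round-trip losslessly and reject bad input", {
  pot <- make_dihedral_potential(0.5, 2)
  run <- run_wtmetad(pot, run_params(n_steps = 1e5, seed = 9),
                     metad_params(hill_height0 = 0.4, hill_sigma = 0.3,
                                  deposit_stride = 250, bias_factor = 6))
  path <- tempfile(fileext = ".hills")
  write_hills(run$hills, path)
  expect_match(readLines(path, n = 1),
               "^#! FIELDS time dihedral sigma_dihedral height biasf$")
  back <- read_hills(path)
  expect_equal(back$center, run$hills$center, tolerance = 1e-11)
  expect_equal(back$height, run$hills$height, tolerance = 1e-11)
  expect_equal(attr(back, "bias_factor"), 6)
  # interleaved comments are skipped
  lines <- readLines(path)
  withr::with_tempfile("p2", {
    writeLines(c(lines[1], "# a comment", lines[-1], "# trailing"), p2)
    back2 <- read_hills(p2)
    expect_equal(nrow(back2), nrow(run$hills))
  })
  # malformed header and ragged rows fail with a line number
  withr::with_tempfile("p3", {
    writeLines(c("#! FIELDS time x sigma_y height biasf", "1 2 3 4 5"), p3)
    expect_error(read_hills(p3), "malformed HILLS header")
  })
  withr::with_tempfile("p4", {
    writeLines(c(lines[1], "1 2 3", lines[-1]), p4)
    expect_error(read_hills(p4), "line 2")
  })
})

test_that("COLVAR files round-trip the CV trace", {
  pot <- make_dihedral_potential(0.5, 2)
  tr <- run_langevin(pot, run_params(n_steps = 1e4, seed = 12,
                                     save_stride = 100))
  path <- tempfile(fileext = ".colvar")
  write_colvar(tr, path)
  back <- read_colvar(path)
  expect_equal(back$dihedral, tr$cv, tolerance = 1e-11)
  expect_equal(back$time, tr$times, tolerance = 1e-11)
})
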