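# Overdamped-Langevin dynamics with well-tempered / infrequent metadynamics.
#
# Dynamics are Brownian (Euler-Maruyama): ds = -beta D F'(s) dt
# + sqrt(2 D dt) xi. Times are reduced units; mapping to seconds is out of
# scope. The per-step kernels are compiled (src/metad.cpp) and draw from R's
# RNG, so runs are bit-reproducible under set.seed().

#' Sampler run parameters
#'
#' @param dt Time step (reduced units).
#' @param diffusion Diffusion coefficient D (reduced units).
#' @param temperature Temperature in K.
#' @param n_steps Number of integration steps.
#' @param seed Integer seed.
#' @param boundary `"periodic"` or `"reflecting"`; defaults to the
#'   potential's own periodicity at run time.
#' @param save_stride Store the CV every this many steps.
#' @return A `run_params` list.
#' @export
run_params <- function(dt = 0.005, diffusion = 0.02,
                       temperature = default_temperature,
                       n_steps = 1e5, seed = 1, boundary = NULL,
                       save_stride = 10) {
  stopifnot(dt > 0, diffusion > 0, n_steps >= 1, save_stride >= 1)
  structure(list(dt = dt, diffusion = diffusion, temperature = temperature,
                 n_steps = n_steps, seed = as.integer(seed),
                 boundary = boundary, save_stride = as.integer(save_stride)),
            class = "run_params")
}

#' Well-tempered metadynamics parameters
#'
#' @param hill_height0 Initial hill height h0, kcal/mol.
#' @param hill_sigma Hill width, CV units.
#' @param deposit_stride Steps between hill depositions.
#' @param bias_factor Well-tempering factor gamma > 1 (`Inf` for the
#'   non-tempered limit of constant hill heights).
#' @return A `metad_params` list.
#' @export
metad_params <- function(hill_height0 = 1.2, hill_sigma = 0.35,
                         deposit_stride = 500, bias_factor = 15) {
  stopifnot(hill_height0 > 0, hill_sigma > 0, deposit_stride >= 1,
            bias_factor > 1)
  structure(list(hill_height0 = hill_height0, hill_sigma = hill_sigma,
                 deposit_stride = as.integer(deposit_stride),
                 bias_factor = bias_factor),
            class = "metad_params")
}

default_start <- function(potential, basin = NULL) {
  b <- if (is.null(basin)) potential$basins[[1]] else potential$basins[[basin]]
  unname(refine_extremum(potential, b)["x"])
}

new_trajectory <- function(times, cv, bias, params, potential, run_id) {
  structure(list(times = times, cv = cv, bias = bias, params = params,
                 potential = potential, run_id = run_id),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory: %d frames over t = %g (seed %d)>\n",
              length(x$cv), max(x$times), x$params$seed))
  invisible(x)
}

#' Unbiased overdamped-Langevin run
#'
#' @param potential A `potential_spec`.
#' @param params A `run_params`.
#' @param s0 Starting CV value (default: the minimum of the potential's
#'   first declared basin).
#' @return A `trajectory` (times, CV values, bias — zero here — and the run
#'   parameters). Stationary sampling follows exp(-F/kT).
#' @export
run_langevin <- function(potential, params, s0 = NULL) {
  stopifnot(inherits(potential, "potential_spec"),
            inherits(params, "run_params"))
  if (is.null(s0)) s0 <- default_start(potential)
  set.seed(params$seed)
  cv <- run_langevin_cpp(unclass(potential), params$dt, params$diffusion,
                         kT_of(params$temperature), params$n_steps,
                         params$save_stride, s0)
  times <- params$dt * params$save_stride * seq_along(cv)
  new_trajectory(times, cv, rep(0, length(cv)), params, potential,
                 run_id = sprintf("langevin-%d", params$seed))
}

#' Well-tempered metadynamics run
#'
#' Deposits Gaussian hills every `deposit_stride` steps with tempered
#' heights h = h0 exp(-V(s,t) / ((gamma - 1) kT)).
#'
#' @inheritParams run_langevin
#' @param metad A `metad_params`.
#' @param n_grid Resolution of the internal bias grid.
#' @return List with `trajectory` (CV and instantaneous bias per saved
#'   frame) and `hills` (a `hills_log`).
#' @export
run_wtmetad <- function(potential, params, metad, s0 = NULL, n_grid = 1024) {
  stopifnot(inherits(potential, "potential_spec"),
            inherits(params, "run_params"),
            inherits(metad, "metad_params"))
  if (is.null(s0)) s0 <- default_start(potential)
  set.seed(params$seed)
  gam <- if (is.finite(metad$bias_factor)) metad$bias_factor else -1
  res <- run_wtmetad_cpp(unclass(potential), params$dt, params$diffusion,
                         kT_of(params$temperature), params$n_steps,
                         params$save_stride, s0,
                         metad$hill_height0, metad$hill_sigma,
                         metad$deposit_stride, gam, n_grid)
  run_id <- sprintf("wtmetad-%d", params$seed)
  times <- params$dt * params$save_stride * seq_along(res$cv)
  traj <- new_trajectory(times, res$cv, res$bias_at, params, potential,
                         run_id)
  hills <- new_hills_log(
    data.frame(time = res$hill_time, center = res$hill_center,
               sigma = metad$hill_sigma, height = res$hill_height),
    bias_factor = metad$bias_factor, hill_height0 = metad$hill_height0,
    periodic = potential$periodic, lo = potential$lo, hi = potential$hi,
    cv_name = potential$kind, potential = potential,
    temperature = params$temperature, run_id = run_id)
  list(trajectory = traj, hills = hills)
}

#' Infrequent-metadynamics transition-event ensemble
#'
#' Runs `n_replicas` independent infrequent WT-MetaD replicas from the
#' source-basin minimum, each stopped at its first commitment to the target
#' basin (first entry beyond the basin's inner edge by `commit_margin`).
#' The unbiased (rescaled) transition time is accumulated per step as
#' sum dt * exp(V(s,t)/kT); hills are never deposited after the transition.
#' Replica seeds are `params$seed + replica - 1`.
#'
#' @inheritParams run_wtmetad
#' @param source_basin,target_basin Basin names declared on the potential.
#' @param n_replicas Number of replicas.
#' @param commit_margin How far past the target basin's inner edge the CV
#'   must travel to count as committed (CV units).
#' @param max_steps Per-replica step cap; replicas hitting it are flagged
#'   censored.
#' @param min_stride Floor on `deposit_stride` enforced for infrequent runs
#'   (deposition must be slow relative to basin relaxation).
#' @return A `transition_events` data.frame (`replica`, `physical_steps`,
#'   `physical_time`, `rescaled_time`, `censored`) with the run setup in
#'   attributes.
#' @export
run_infrequent_ensemble <- function(potential, params, metad,
                                    source_basin, target_basin,
                                    n_replicas, commit_margin = 0.1,
                                    max_steps = 5e6, min_stride = 100,
                                    n_grid = 1024) {
  stopifnot(inherits(potential, "potential_spec"))
  if (!all(c(source_basin, target_basin) %in% names(potential$basins)))
    stop("source/target basins must be declared on the potential")
  if (source_basin == target_basin) stop("basins must differ")
  if (metad$deposit_stride < min_stride)
    stop(sprintf("deposit_stride %d below the infrequent floor %d",
                 metad$deposit_stride, min_stride))
  s0 <- default_start(potential, source_basin)
  ci <- commit_interval(potential, source_basin, target_basin, commit_margin)
  gam <- if (is.finite(metad$bias_factor)) metad$bias_factor else -1
  rows <- lapply(seq_len(n_replicas), function(r) {
    set.seed(params$seed + r - 1L)
    res <- run_infrequent_cpp(unclass(potential), params$dt,
                              params$diffusion, kT_of(params$temperature),
                              max_steps, s0,
                              metad$hill_height0, metad$hill_sigma,
                              metad$deposit_stride, gam, n_grid,
                              ci[1], ci[2])
    data.frame(replica = r, physical_steps = res$physical_steps,
               physical_time = res$physical_steps * params$dt,
               rescaled_time = res$rescaled_time,
               censored = !res$committed)
  })
  ev <- do.call(rbind, rows)
  structure(ev, class = c("transition_events", "data.frame"),
            source_basin = source_basin, target_basin = target_basin,
            params = params, metad = metad, commit_margin = commit_margin)
}

# Commitment window: the target-basin interval with both edges pushed
# inward by the margin (any edge can face the source on a periodic
# coordinate; crossing the window is required to reach the far side
# otherwise). Returned in wrapped coordinates; lo > hi encodes a window
# wrapping the domain edge.
commit_interval <- function(potential, source_basin, target_basin, margin) {
  tgt <- potential$basins[[target_basin]]
  if (tgt[2] - tgt[1] <= 2 * margin)
    stop("commit_margin too large for the target basin")
  win <- c(tgt[1] + margin, tgt[2] - margin)
  if (potential$periodic) {
    p <- potential$hi - potential$lo
    win <- potential$lo + ((win - potential$lo) %% p)
  } else {
    win <- pmin(pmax(win, potential$lo), potential$hi)
  }
  win
}

#' Evaluate the deposited metadynamics bias
#'
#' Sum of the Gaussian hills deposited up to time `t`, with periodic images
#' for periodic CVs.
#'
#' @param hills A `hills_log`.
#' @param s CV values at which to evaluate.
#' @param t Upper time cutoff (default: all hills).
#' @param method `"exact"` sums every Gaussian analytically; `"grid"`
#'   evaluates exactly on a dense grid and interpolates linearly (for long
#'   trajectories against large logs); `"auto"` switches on workload.
#' @return Bias V(s, t) in kcal/mol.
#' @export
evaluate_bias <- function(hills, s, t = Inf,
                          method = c("auto", "exact", "grid")) {
  method <- match.arg(method)
  stopifnot(inherits(hills, "hills_log"))
  h <- hills[hills$time <= t, , drop = FALSE]
  if (nrow(h) == 0) return(rep(0, length(s)))
  pseudo <- list(periodic = attr(hills, "periodic"),
                 lo = attr(hills, "lo"), hi = attr(hills, "hi"),
                 c0 = 0, cos_a = numeric(0),
                 gauss = cbind(h$height, h$center, h$sigma))
  per <- pseudo$periodic
  p <- pseudo$hi - pseudo$lo
  if (per) s <- pseudo$lo + ((s - pseudo$lo) %% p)
  if (method == "auto")
    method <- if (length(s) * nrow(h) > 2e7) "grid" else "exact"
  if (method == "exact")
    return(eval_potential_cpp(pseudo, as.numeric(s)))
  g <- seq(pseudo$lo, pseudo$hi, length.out = 2049)
  Vg <- eval_potential_cpp(pseudo, g)
  stats::approx(g, Vg, xout = as.numeric(s), rule = 2)$y
}
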