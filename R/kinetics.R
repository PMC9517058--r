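# Rate reconstruction from transition-time ensembles.
#
# Infrequent-metadynamics rescaled transition times are, when the bias was
# deposited slowly enough, i.i.d. exponential; tau is their MLE mean, the
# uncertainty a seeded percentile bootstrap, and reliability is checked by a
# Kolmogorov-Smirnov test against the fitted exponential.

#' Kolmogorov-Smirnov exponentiality test
#'
#' Two-sided KS statistic of `times` against the exponential CDF
#' 1 - exp(-t/tau), with the asymptotic p-value.
#'
#' @param times Transition times (> 0), n >= 5.
#' @param tau Exponential mean.
#' @return List with `statistic` and `p`.
#' @export
ks_exponentiality <- function(times, tau) {
  if (tau <= 0) stop("tau must be positive")
  if (length(times) < 5) stop("need at least 5 transition times")
  kt <- suppressWarnings(
    ks.test(times, "pexp", rate = 1 / tau, exact = FALSE))
  list(statistic = unname(kt$statistic), p = unname(kt$p.value))
}

#' Exponential rate estimate from transition times
#'
#' tau is the maximum-likelihood mean of the uncensored times, k = 1/tau.
#' A seeded percentile bootstrap (default 2000 resamples) gives the 95%
#' interval, and the KS exponentiality check is attached: a small `ks_p`
#' flags an unreliable (non-Poissonian) ensemble.
#'
#' @param times Transition times (rescaled times from an infrequent
#'   ensemble, or any positive times), or a `transition_events` object.
#' @param censored Logical flags; censored events are excluded from the MLE
#'   by default.
#' @param include_censored If TRUE, use the censored-MLE
#'   tau = sum(all times)/n_uncensored instead of dropping censored events.
#' @param n_boot Bootstrap resamples.
#' @param conf Confidence level.
#' @param min_events Floor on the number of uncensored events.
#' @param seed Seed for the bootstrap resampling.
#' @return A `rate_estimate`: `tau`, `k`, `ci_low`, `ci_high`, `ks_stat`,
#'   `ks_p`, `n_events`, `n_censored`.
#' @export
fit_exponential_rate <- function(times, censored = NULL,
                                 include_censored = FALSE,
                                 n_boot = 2000, conf = 0.95,
                                 min_events = 5, seed = 1) {
  if (inherits(times, "transition_events")) {
    censored <- times$censored
    times <- times$rescaled_time
  }
  if (is.null(censored)) censored <- rep(FALSE, length(times))
  stopifnot(length(censored) == length(times))
  unc <- times[!censored]
  if (length(unc) == 0) stop("all events censored")
  if (length(unc) < min_events)
    stop(sprintf("only %d uncensored events (need >= %d)",
                 length(unc), min_events))
  tau <- if (include_censored) sum(times) / length(unc) else mean(unc)
  set.seed(seed)
  boots <- vapply(seq_len(n_boot), function(b) {
    i <- sample.int(length(unc), replace = TRUE)
    if (include_censored) {
      # resample the full event set, keep the censoring structure
      j <- sample.int(length(times), replace = TRUE)
      s <- sum(times[j]); nu <- sum(!censored[j])
      if (nu == 0) NA_real_ else s / nu
    } else mean(unc[i])
  }, numeric(1))
  qs <- quantile(boots, c((1 - conf) / 2, 1 - (1 - conf) / 2), na.rm = TRUE)
  ks <- ks_exponentiality(unc, tau)
  structure(list(tau = tau, k = 1 / tau,
                 ci_low = unname(qs[1]), ci_high = unname(qs[2]),
                 ks_stat = ks$statistic, ks_p = ks$p,
                 n_events = length(unc), n_censored = sum(censored),
                 include_censored = include_censored, conf = conf),
            class = "rate_estimate")
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat(sprintf(
    "<rate_estimate: tau = %.4g [%.4g, %.4g], k = %.4g (n = %d, %d censored)>\n",
    x$tau, x$ci_low, x$ci_high, x$k, x$n_events, x$n_censored))
  cat(sprintf("  KS exponentiality: D = %.3f, p = %.3g%s\n", x$ks_stat,
              x$ks_p, if (x$ks_p < 0.05) "  [flagged unreliable]" else ""))
  invisible(x)
}

#' Concentration-scaled attack rate
#'
#' The constrained-reactant setup keeps a hydroxide ion permanently at
#' solvation distance from the amide, equivalent to an OH- concentration
#' equal to that of water in pure water, 55.6 M. Pseudo-first-order scaling
#' to any other concentration: k_on(c) = (1/tau_on) (c / 55.6).
#'
#' @param tau_on Characteristic attack time at the 55.6 M reference state.
#' @param concentration OH- concentration, mol/L.
#' @param reference Reference concentration (55.6 M).
#' @return k_on in 1/time.
#' @export
concentration_scaled_kon <- function(tau_on, concentration,
                                     reference = 55.6) {
  if (tau_on <= 0 || any(concentration <= 0))
    stop("tau_on and concentration must be positive")
  (1 / tau_on) * (concentration / reference)
}

#' Reaction equilibrium from attack/release rates
#'
#' K_reac = k_on / k_off for hydroxide attack (R <-> TI formation);
#' K_reac > 1 means the tetrahedral intermediate is the more stable state.
#'
#' @param k_on,k_off Attack and release rate constants (> 0).
#' @return A `reaction_equilibrium` list: `k_on`, `k_off`, `K_reac`.
#' @export
reaction_equilibrium <- function(k_on, k_off) {
  if (k_on <= 0 || k_off <= 0) stop("rates must be positive")
  structure(list(k_on = k_on, k_off = k_off, K_reac = k_on / k_off),
            class = "reaction_equilibrium")
}

#' Write a rate estimate as JSON
#'
#' @param estimate A `rate_estimate`.
#' @param path Output path.
#' @export
write_rate_json <- function(estimate, path) {
  stopifnot(inherits(estimate, "rate_estimate"))
  jsonlite::write_json(unclass(estimate), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write / read transition-time ensembles as TSV
#'
#' Columns: replica, physical_steps, rescaled_time, censored.
#'
#' @param events A `transition_events` data.frame.
#' @param path File path.
#' @return `read_transition_events()` returns a `transition_events`.
#' @export
write_transition_events <- function(events, path) {
  write.table(as.data.frame(events)[, c("replica", "physical_steps",
                                        "rescaled_time", "censored")],
              path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_transition_events
#' @export
read_transition_events <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t")
  structure(df, class = c("transition_events", "data.frame"))
}
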