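# Combination framework: conformer reactivity scores, global reaction
# constants in and out of the cage, and the confinement acceleration index.
#
# For one environment, the global reaction constant sums over the discrete
# conformer set:  K = sum_omega chi_omega P^conf_omega P^in_omega NW_omega,
# with P^in = 1 for the free solution. The acceleration index is
# a = K(cage) / K(sol).

#' Relative conformer reactivity scores
#'
#' chi_omega = K_reac(omega) / max(K_reac): reaction constants normalized to
#' the most reactive conformer (set to 1).
#'
#' @param K_reac Named positive vector of per-conformer reaction constants
#'   (k_on/k_off).
#' @return A `reactivity_table` data.frame: `omega`, `K_reac`, `chi`.
#' @export
chi_scores <- function(K_reac) {
  if (length(K_reac) < 1) stop("need at least one conformer")
  if (any(K_reac <= 0)) stop("K_reac values must be positive")
  structure(
    data.frame(omega = if (is.null(names(K_reac)))
                 as.character(seq_along(K_reac)) else names(K_reac),
               K_reac = unname(K_reac),
               chi = unname(K_reac / max(K_reac))),
    class = c("reactivity_table", "data.frame"))
}

#' Per-environment reactivity input
#'
#' One row per conformer omega with the four factors of the global reaction
#' constant. For a solution environment leave `pin` unset: it is forced to
#' 1 (the guest is by definition outside any cage).
#'
#' @param chi Named reactivity scores (max 1 by convention).
#' @param pconf Named relative conformer probabilities (trans = 1 reference
#'   when present).
#' @param nw Named mean solvent-contact counts (>= 0).
#' @param pin Named in-cage probabilities in (0, 1]; NULL for solution.
#' @param label Environment label.
#' @return A `reactivity_input` data.frame.
#' @export
reactivity_input <- function(chi, pconf, nw, pin = NULL, label = "") {
  omega <- names(chi)
  if (is.null(omega)) stop("conformer factors must be named")
  if (!setequal(omega, names(pconf)) || !setequal(omega, names(nw)))
    stop("mismatched conformer sets across chi / pconf / nw")
  solution <- is.null(pin)
  if (solution) pin <- setNames(rep(1, length(omega)), omega)
  if (!setequal(omega, names(pin))) stop("mismatched conformer set in pin")
  if (any(pin <= 0 | pin > 1)) stop("pin must lie in (0, 1]")
  if (any(nw[omega] < 0)) stop("NW must be non-negative")
  if ("trans" %in% omega && abs(pconf[["trans"]] - 1) > 1e-12)
    stop("pconf is relative to trans: pconf['trans'] must be 1")
  structure(
    data.frame(omega = omega, chi = unname(chi[omega]),
               pconf = unname(pconf[omega]), pin = unname(pin[omega]),
               nw = unname(nw[omega])),
    class = c("reactivity_input", "data.frame"),
    label = label, solution = solution)
}

#' Global reaction constant of one environment
#'
#' K = sum over conformers of chi * P^conf * P^in * NW, with the per-term
#' breakdown.
#'
#' @param input A `reactivity_input`.
#' @return List with `K` and `breakdown` (the input with a `term` column).
#' @export
global_reaction_constant <- function(input) {
  stopifnot(inherits(input, "reactivity_input"))
  term <- input$chi * input$pconf * input$pin * input$nw
  breakdown <- cbind(as.data.frame(input), term = term)
  list(K = sum(term), breakdown = breakdown)
}

#' Confinement acceleration index
#'
#' a = K(cage) / K(sol): how much faster the reaction proceeds with the
#' cage present in the system than with the guest free in solution.
#'
#' @param K_cage,K_sol Global reaction constants (K_sol > 0).
#' @param route Which in-cage-probability route produced `K_cage`:
#'   `"pin1"` (the P^in ~ 1 simplification) or `"explicit"`.
#' @param breakdown_cage,breakdown_sol Optional per-term breakdowns to carry
#'   along.
#' @param truncation Optional truncation report to carry along.
#' @return An `acceleration_result`: `a`, `K_cage`, `K_sol`, `route`, plus
#'   any breakdowns.
#' @export
acceleration_index <- function(K_cage, K_sol, route = "explicit",
                               breakdown_cage = NULL, breakdown_sol = NULL,
                               truncation = NULL) {
  if (!is.finite(K_sol) || K_sol <= 0)
    stop("K_sol must be positive")
  structure(list(a = K_cage / K_sol, K_cage = K_cage, K_sol = K_sol,
                 route = route, breakdown_cage = breakdown_cage,
                 breakdown_sol = breakdown_sol, truncation = truncation),
            class = "acceleration_result")
}

#' @export
print.acceleration_result <- function(x, ...) {
  cat(sprintf("<acceleration_result: a = %.4g (K_cage = %.4g, K_sol = %.4g, %s route)>\n",
              x$a, x$K_cage, x$K_sol, x$route))
  if (!is.null(x$truncation) && nrow(x$truncation) > 0)
    cat(sprintf("  truncated terms: %s\n",
                paste(x$truncation$omega, collapse = ", ")))
  invisible(x)
}

#' Full-framework acceleration for a cage/solution pair
#'
#' Computes both global reaction constants and their ratio. With
#' `pin_route = "pin1"` the in-cage probability is set to 1 for every
#' conformer (justified whenever the encapsulation constants are large);
#' `"explicit"` uses the P^in values carried by the cage input. Conformer
#' terms whose chi * P^conf falls below `truncate_below` are dropped from
#' both sums and reported.
#'
#' @param input_cage,input_sol `reactivity_input` objects over the same
#'   conformer set.
#' @param pin_route `"pin1"` or `"explicit"`.
#' @param truncate_below Drop threshold on chi * P^conf (0 disables).
#' @return An `acceleration_result`.
#' @export
accelerate_pair <- function(input_cage, input_sol,
                            pin_route = c("pin1", "explicit"),
                            truncate_below = 1e-12) {
  pin_route <- match.arg(pin_route)
  stopifnot(inherits(input_cage, "reactivity_input"),
            inherits(input_sol, "reactivity_input"))
  if (!setequal(input_cage$omega, input_sol$omega))
    stop("cage and solution inputs cover different conformer sets")
  if (pin_route == "pin1") input_cage$pin <- rep(1, nrow(input_cage))
  dropped <- unique(c(
    input_cage$omega[input_cage$chi * input_cage$pconf < truncate_below],
    input_sol$omega[input_sol$chi * input_sol$pconf < truncate_below]))
  # only terms negligible in BOTH environments may be dropped
  dropped <- dropped[
    input_cage$chi[match(dropped, input_cage$omega)] *
      input_cage$pconf[match(dropped, input_cage$omega)] < truncate_below &
    input_sol$chi[match(dropped, input_sol$omega)] *
      input_sol$pconf[match(dropped, input_sol$omega)] < truncate_below]
  keep_c <- !input_cage$omega %in% dropped
  keep_s <- !input_sol$omega %in% dropped
  gc <- global_reaction_constant(input_cage[keep_c, , drop = FALSE])
  gs <- global_reaction_constant(input_sol[keep_s, , drop = FALSE])
  trunc_report <- input_cage[!keep_c, c("omega", "chi", "pconf"),
                             drop = FALSE]
  acceleration_index(gc$K, gs$K,
                     route = if (pin_route == "pin1") "pin1" else "explicit",
                     breakdown_cage = gc$breakdown,
                     breakdown_sol = gs$breakdown,
                     truncation = trunc_report)
}

#' Write / read per-environment reactivity inputs as TSV
#'
#' Columns omega, chi, pconf, pin, nw; the environment label and whether it
#' is a solution environment are stored as header comments.
#'
#' @param input A `reactivity_input`.
#' @param path File path.
#' @return `read_reactivity_tsv()` returns a `reactivity_input`.
#' @export
write_reactivity_tsv <- function(input, path) {
  stopifnot(inherits(input, "reactivity_input"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# label\t%s", attr(input, "label")),
               sprintf("# solution\t%s", attr(input, "solution"))), con)
  write.table(as.data.frame(input), con, sep = "\t", row.names = FALSE,
              quote = FALSE)
  invisible(path)
}

#' @rdname write_reactivity_tsv
#' @export
read_reactivity_tsv <- function(path) {
  hdr <- readLines(path, n = 2)
  solution <- identical(sub("^# solution\t", "", hdr[2]), "TRUE")
  label <- sub("^# label\t", "", hdr[1])
  df <- read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  v <- function(col) setNames(df[[col]], df$omega)
  reactivity_input(chi = v("chi"), pconf = v("pconf"), nw = v("nw"),
                   pin = if (solution) NULL else v("pin"), label = label)
}

#' Monte-Carlo uncertainty propagation for the acceleration index
#'
#' Draws every input factor (log-normal for chi and P^conf and P^in — they
#' are positive multiplicative quantities — truncated normal at zero for
#' NW), recomputes a per draw, and summarizes the distribution.
#'
#' @param input_cage,input_sol `reactivity_input` objects.
#' @param rel_sd Named list of relative uncertainties for any of `chi`,
#'   `pconf`, `pin`, `nw` (defaults 0).
#' @param n_draws Number of Monte-Carlo draws (>= 100).
#' @param seed Seed.
#' @param pin_route Passed to [accelerate_pair()].
#' @return List with `draws` (vector of a values), `median`, `q16`, `q84`.
#' @export
propagate_uncertainty <- function(input_cage, input_sol,
                                  rel_sd = list(), n_draws = 1000, seed = 1,
                                  pin_route = "pin1") {
  if (n_draws < 100) stop("need at least 100 draws")
  rs <- function(nm) if (is.null(rel_sd[[nm]])) 0 else rel_sd[[nm]]
  if (any(vapply(c("chi", "pconf", "pin", "nw"), rs, numeric(1)) < 0))
    stop("uncertainties must be non-negative")
  set.seed(seed)
  perturb <- function(input) {
    out <- input
    ln <- function(x, r) if (r > 0)
      x * exp(rnorm(length(x), -0.5 * log(1 + r^2), sqrt(log(1 + r^2))))
      else x
    out$chi <- ln(input$chi, rs("chi"))
    out$pconf <- ln(input$pconf, rs("pconf"))
    if (!attr(input, "solution") && rs("pin") > 0)
      out$pin <- pmin(1, ln(input$pin, rs("pin")))
    r <- rs("nw")
    if (r > 0) {
      # truncated normal at zero by rejection
      nw <- rnorm(length(input$nw), input$nw, r * input$nw)
      while (any(nw <= 0))
        nw[nw <= 0] <- rnorm(sum(nw <= 0), input$nw[nw <= 0],
                             r * input$nw[nw <= 0])
      out$nw <- nw
    }
    out
  }
  draws <- vapply(seq_len(n_draws), function(d) {
    accelerate_pair(perturb(input_cage), perturb(input_sol),
                    pin_route = pin_route)$a
  }, numeric(1))
  list(draws = draws, median = median(draws),
       q16 = unname(quantile(draws, 0.16)),
       q84 = unname(quantile(draws, 0.84)))
}
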