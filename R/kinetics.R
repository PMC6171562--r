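# Label-incorporation kinetics: the enrichment a labeling strategy can
# reach, and first-order well-mixed pool-turnover simulation of labeled
# fraction through linear or cyclic pathway chains. The labeled fraction
# L_i of pool i obeys
#   dL_i/dt = (F / P_i) * (L_{i-1}^h - L_i),
# with L_0 the precursor (input) enrichment, F the pathway flux, P_i the
# pool size, and h a cooperativity exponent on the donor fraction
# (h = 1 plain first order, h > 1 positive, h < 1 negative
# cooperativity). A cyclic topology feeds the terminal pool back into
# the first with a mixing fraction.

#' Initial precursor enrichment of a labeling strategy
#'
#' The label fraction of the feeding pool immediately after label
#' addition — the plateau that bounds downstream labeled fractions.
#' Three designs are supported: \code{spike_in} (label added on top of
#' unlabeled medium precursor and any unlabeled internal pool),
#' \code{medium_swap} (medium replaced by fully labeled medium; only an
#' unlabeled internal pool dilutes), and \code{conditioning} (growth on
#' a half-strength medium, the other half then added as label — the
#' minimally perturbing design, reaching ~50% initial enrichment with
#' equal halves and no internal pool).
#'
#' @param strategy One of \code{"spike_in"}, \code{"medium_swap"},
#'   \code{"conditioning"}.
#' @param labeled Amount of labeled precursor added (>= 0).
#' @param unlabeled_medium Unlabeled precursor in the medium; must be 0
#'   for \code{medium_swap} (the medium was replaced).
#' @param internal_pool Unlabeled internal (cellular) precursor pool.
#' @return The initial enrichment fraction in [0, 1].
#' @export
#' @examples
#' precursor_enrichment("conditioning", labeled = 0.5,
#'                      unlabeled_medium = 0.5)      # 0.5
#' precursor_enrichment("medium_swap", labeled = 1)  # 1
precursor_enrichment <- function(strategy = c("spike_in", "medium_swap",
                                              "conditioning"),
                                 labeled, unlabeled_medium = 0,
                                 internal_pool = 0) {
  strategy <- match.arg(strategy)
  stopifnot(labeled >= 0, unlabeled_medium >= 0, internal_pool >= 0)
  if (strategy == "medium_swap" && unlabeled_medium > 0) {
    stop("medium_swap replaces the medium; unlabeled_medium must be 0")
  }
  total <- labeled + unlabeled_medium + internal_pool
  if (total <= 0) stop("all amounts are zero")
  labeled / total
}

#' Define a pool-chain labeling model
#'
#' @param pool_sizes Positive pool sizes P_i (amount units), one per pool
#'   in pathway order; the last pool is the detected metabolite.
#' @param flux Pathway flux F (amount / time), > 0.
#' @param topology \code{"linear"} or \code{"cyclic"} (terminal pool
#'   recycled into the first).
#' @param cooperativity Exponent h > 0 on the donor labeled fraction.
#' @param input Precursor enrichment: a constant in [0, 1] or a function
#'   of time returning values in [0, 1].
#' @param recycle_fraction For cyclic topology: fraction of the first
#'   pool's inflow drawn from the terminal pool rather than the
#'   precursor (in [0, 1)).
#' @return An object of class \code{"pool_chain_model"}.
#' @export
pool_chain_model <- function(pool_sizes, flux, topology = c("linear", "cyclic"),
                             cooperativity = 1, input = 1,
                             recycle_fraction = 0) {
  topology <- match.arg(topology)
  stopifnot(length(pool_sizes) >= 1L, all(pool_sizes > 0), flux > 0,
            cooperativity > 0,
            recycle_fraction >= 0, recycle_fraction < 1)
  if (topology == "linear" && recycle_fraction > 0) {
    stop("recycle_fraction applies only to cyclic topology")
  }
  input_fun <- if (is.function(input)) input else {
    stopifnot(input >= 0, input <= 1)
    function(t) rep(input, length(t))
  }
  structure(list(pool_sizes = pool_sizes, flux = flux, topology = topology,
                 cooperativity = cooperativity, input = input_fun,
                 recycle_fraction = recycle_fraction),
            class = "pool_chain_model")
}

#' @export
print.pool_chain_model <- function(x, ...) {
  cat("<pool_chain_model> ", length(x$pool_sizes), " pool(s), ", x$topology,
      ", flux ", x$flux, ", h = ", x$cooperativity,
      if (x$topology == "cyclic") paste0(", recycle ", x$recycle_fraction),
      "\n", sep = "")
  invisible(x)
}

#' Simulate label incorporation through a pool chain
#'
#' Integrates the first-order pool-turnover system with \code{deSolve}
#' (lsoda, rtol 1e-8) from unlabeled initial conditions. For h = 1 linear
#' chains under constant input the trajectories are monotone
#' non-decreasing and bounded by the input enrichment, which every pool
#' approaches at steady state.
#'
#' @param model A \code{\link{pool_chain_model}}.
#' @param times Increasing time vector starting at 0 (user's units —
#'   hours by convention in growth experiments).
#' @return A data frame: \code{time}, then one labeled-fraction column
#'   per pool (\code{pool_1} ... ; the last pool is the readout).
#' @export
#' @examples
#' m <- pool_chain_model(pool_sizes = 1, flux = 0.5, input = 0.5)
#' simulate_chain(m, times = seq(0, 10, 0.5))
simulate_chain <- function(model, times) {
  stopifnot(inherits(model, "pool_chain_model"),
            length(times) >= 2L, times[1] == 0, all(diff(times) > 0))
  np <- length(model$pool_sizes)
  rates <- model$flux / model$pool_sizes
  h <- model$cooperativity
  rho <- model$recycle_fraction
  deriv <- function(t, L, parms) {
    inp <- model$input(t)
    donor0 <- if (model$topology == "cyclic" && np >= 1L) {
      (1 - rho) * inp + rho * L[np]
    } else inp
    donors <- c(donor0, L[-np])
    list(rates * (pmax(donors, 0)^h - L))
  }
  sol <- deSolve::ode(y = rep(0, np), times = times, func = deriv,
                      parms = NULL, method = "lsoda",
                      rtol = 1e-8, atol = 1e-10)
  if (any(!is.finite(sol))) stop("ODE integration failed (non-finite solution)")
  out <- as.data.frame(sol)
  names(out) <- c("time", paste0("pool_", seq_len(np)))
  out
}

#' Combine independent moiety labeling into an isotopologue trajectory
#'
#' A metabolite assembled from several moieties, each supplied by its own
#' pathway, has an isotopologue distribution given (under independence)
#' by the convolution of per-moiety binomials: moiety m with n_m
#' labelable atoms at labeled fraction L_m(t) contributes
#' Binomial(n_m, L_m(t)). The fully labeled species fraction is the
#' product of the per-moiety terms.
#'
#' @param trajectories A matrix or data frame of per-moiety labeled
#'   fractions in [0, 1]: rows are time points, columns moieties.
#' @param n_atoms Integer vector of labelable atoms per moiety (same
#'   length as the number of columns).
#' @return A list: \code{distribution} (rows = time points, columns
#'   M+0..M+n for n = sum(n_atoms)) and \code{fully_labeled} (its last
#'   column).
#' @export
#' @examples
#' simulate_multi_input(cbind(0.5, 0.5), n_atoms = c(1, 1))$fully_labeled
simulate_multi_input <- function(trajectories, n_atoms) {
  trajectories <- as.matrix(trajectories)
  stopifnot(ncol(trajectories) == length(n_atoms), all(n_atoms >= 1),
            all(trajectories >= 0 & trajectories <= 1))
  n_atoms <- as.integer(n_atoms)
  n_tot <- sum(n_atoms)
  dist <- t(apply(trajectories, 1L, function(p) {
    d <- 1
    for (m in seq_along(n_atoms)) {
      d <- stats::convolve(d, rev(stats::dbinom(0:n_atoms[m], n_atoms[m], p[m])),
                           type = "open")
    }
    pmax(d, 0)
  }))
  colnames(dist) <- paste0("M", 0:n_tot)
  list(distribution = dist, fully_labeled = unname(dist[, n_tot + 1L]))
}

#' Time to half the labeling plateau
#'
#' @param fit A \code{\link{fit_labeling_curve}} result, or a list with a
#'   \code{predict}-able curve.
#' @return Time at which the fitted curve first reaches half its plateau.
#' @export
half_time <- function(fit) {
  stopifnot(inherits(fit, "labeling_fit"))
  if (fit$degenerate) return(NA_real_)
  A <- fit$plateau
  f <- function(t) predict(fit, t) - A / 2
  upper <- max(fit$times) * 10
  if (f(upper) < 0) return(Inf)
  stats::uniroot(f, lower = 0, upper = upper, tol = 1e-10)$root
}
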