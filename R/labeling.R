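# Isotopologue-distribution analysis: normalized mass-isotopomer
# distributions (MIDs), the summary statistics used to present label
# incorporation, binomial natural-abundance correction, and
# moiety-resolved labeled fractions from the full (k, j) channel grid.

#' Normalize isotopologue intensities to a fractional distribution
#'
#' @param intensities Non-negative M+0..M+n intensities (named or not).
#' @return Fractions summing to one.
#' @export
#' @examples
#' fractional_distribution(c(90, 10, 0, 0, 0, 0))
fractional_distribution <- function(intensities) {
  stopifnot(is.numeric(intensities), all(is.finite(intensities)),
            all(intensities >= 0))
  s <- sum(intensities)
  if (s <= 0) stop("all-zero intensity vector cannot be normalized")
  intensities / s
}

.check_fractions <- function(f, tol = 1e-6) {
  stopifnot(is.numeric(f), all(is.finite(f)), all(f >= -tol))
  if (abs(sum(f) - 1) > tol) {
    stop("fractions must be normalized (sum to 1); got sum = ", sum(f))
  }
  invisible(f)
}

#' Percent label incorporation
#'
#' The labeled-molecule percentage, 100 x (1 - f_0): the share of the
#' pool carrying at least one label. This is the molecule-level "overall
#' label incorporation" readout; \code{\link{mean_enrichment}} is the
#' atom-weighted companion.
#'
#' @param f Normalized M+0..M+n fractions.
#' @return Percent in [0, 100].
#' @export
percent_label_incorporation <- function(f) {
  .check_fractions(f)
  100 * sum(f[-1])
}

#' Mean atom enrichment
#'
#' Atom-weighted labeling, sum(i * f_i) / n: the fraction of labelable
#' atoms carrying the heavy isotope.
#'
#' @param f Normalized M+0..M+n fractions (length n + 1).
#' @param n Number of labelable atoms; must equal \code{length(f) - 1}.
#' @return Fraction in [0, 1].
#' @export
mean_enrichment <- function(f, n = length(f) - 1L) {
  .check_fractions(f)
  if (n != length(f) - 1L) {
    stop("n (", n, ") does not match distribution length (", length(f), ")")
  }
  if (n < 1L) stop("need n >= 1")
  sum((seq_along(f) - 1L) * f) / n
}

#' Natural-abundance correction matrix
#'
#' Builds the lower-triangular matrix M with M[i, j] = P(i - j natural
#' heavy shifts | j tracer labels), the binomial probability of i - j
#' naturally occurring heavy isotopes among the n_atoms - j positions of
#' the tracer element not carrying tracer label. Observed intensities
#' are the convolution I = M x of the true distribution x; correction
#' deconvolves it.
#'
#' @param n Highest tracer label count (matrix is (n+1) x (n+1)).
#' @param n_atoms Total atoms of the tracer element in the (derivatized)
#'   molecule; for derivatized analytes this includes tag atoms, which
#'   contribute natural abundance like any others. Must be >= n.
#' @param abundance Natural heavy-isotope abundance of the tracer element
#'   (default: the packaged value for \code{element}).
#' @param element Tracer element, used only to look up the default
#'   abundance.
#' @return An (n+1) x (n+1) lower-triangular matrix.
#' @export
na_correction_matrix <- function(n, n_atoms, abundance = NULL,
                                 element = c("C", "N")) {
  element <- match.arg(element)
  if (is.null(abundance)) {
    tab <- element_masses()
    abundance <- tab$heavy_abundance[tab$element == element]
  }
  stopifnot(n >= 0, n_atoms >= n, abundance >= 0, abundance <= 1)
  M <- matrix(0, n + 1L, n + 1L)
  for (j in 0:n) {
    shifts <- 0:(n - j)
    M[j + 1L + shifts, j + 1L] <- stats::dbinom(shifts, n_atoms - j, abundance)
  }
  M
}

#' Correct isotopologue intensities for natural isotope abundance
#'
#' Solves the convolution I = M x for the tracer-only distribution x by
#' non-negative least squares (robust to noise, unlike direct matrix
#' inversion), then normalizes. A solution whose residual exceeds
#' \code{tol} relative to the total signal is flagged, not hidden.
#'
#' @param intensities Observed M+0..M+n intensities.
#' @inheritParams na_correction_matrix
#' @param tol Relative residual above which the fit is flagged
#'   (default 1e-3).
#' @return A list: \code{fractions} (corrected, normalized),
#'   \code{raw_fractions} (uncorrected, for comparison),
#'   \code{residual} (relative), and logical \code{flagged}.
#' @export
#' @examples
#' # with abundance 0 the correction is the identity
#' correct_natural_abundance(c(80, 20, 0), n_atoms = 6, abundance = 0)
correct_natural_abundance <- function(intensities, n_atoms, abundance = NULL,
                                      element = c("C", "N"), tol = 1e-3) {
  raw <- fractional_distribution(intensities)
  n <- length(raw) - 1L
  M <- na_correction_matrix(n, n_atoms, abundance, element)
  fit <- pracma::lsqnonneg(M, raw)
  x <- pmax(fit$x, 0)
  if (sum(x) <= 0) stop("correction produced an all-zero distribution")
  residual <- sqrt(sum((M %*% x - raw)^2)) / sqrt(sum(raw^2))
  list(fractions = x / sum(x), raw_fractions = raw,
       residual = residual, flagged = residual > tol)
}

#' Convolve a tracer distribution with natural abundance
#'
#' The forward operation that \code{\link{correct_natural_abundance}}
#' inverts: predicts observed fractions from a tracer-only distribution.
#'
#' @param fractions Tracer-only M+0..M+n fractions.
#' @inheritParams na_correction_matrix
#' @return Observed-scale fractions (renormalized over the M+0..M+n
#'   window).
#' @export
convolve_natural_abundance <- function(fractions, n_atoms, abundance = NULL,
                                       element = c("C", "N")) {
  .check_fractions(fractions)
  n <- length(fractions) - 1L
  M <- na_correction_matrix(n, n_atoms, abundance, element)
  obs <- as.numeric(M %*% fractions)
  obs / sum(obs)
}

#' Moiety-resolved labeled fractions from a (k, j) channel grid
#'
#' From areas measured on the full isotopologue grid — k labels in the
#' precursor, j of them in the fragment — computes the fraction of
#' molecules labeled in the fragment moiety (j >= 1) and in the
#' remainder moiety (k - j >= 1). For AMP monitored by base release,
#' "fragment" is the nitrogen base and "remainder" the ribose phosphate,
#' so these two numbers are the base-labeled and ribose-labeled molecule
#' fractions whose kinetics separate the two biosynthetic inputs.
#'
#' @param areas Data frame with columns \code{k}, \code{j}, \code{area}
#'   (one row per measured channel, areas >= 0).
#' @param scheme Optional \code{\link{label_scheme}}; when given, grid
#'   coverage is checked against the feasible ladder and incomplete grids
#'   are flagged (computed over available channels).
#' @return A list: \code{fragment_labeled}, \code{remainder_labeled}
#'   (fractions in [0, 1]), \code{coverage} (measured / feasible channel
#'   count, NA without a scheme), \code{complete}.
#' @export
moiety_labeling <- function(areas, scheme = NULL) {
  stopifnot(is.data.frame(areas),
            all(c("k", "j", "area") %in% names(areas)),
            all(areas$area >= 0), all(areas$j <= areas$k), all(areas$j >= 0))
  if (anyDuplicated(areas[c("k", "j")])) stop("duplicate (k, j) channels")
  total <- sum(areas$area)
  if (total <= 0) stop("all-zero channel areas")
  coverage <- NA_real_
  complete <- NA
  if (!is.null(scheme)) {
    feasible <- sum(vapply(0:scheme$n_total, function(k) {
      length(.feasible_j(k, scheme$n_total, scheme$n_frag))
    }, integer(1)))
    bad <- areas$j > pmin(areas$k, scheme$n_frag) |
      areas$j < pmax(0L, areas$k - (scheme$n_total - scheme$n_frag))
    if (any(bad)) stop("channels outside the feasible grid: ",
                       paste(sprintf("(%d,%d)", areas$k[bad], areas$j[bad]),
                             collapse = ", "))
    coverage <- nrow(areas) / feasible
    complete <- nrow(areas) == feasible
    if (!complete) {
      warning("channel grid incomplete (", nrow(areas), "/", feasible,
              " channels); moiety fractions computed over available channels")
    }
  }
  list(fragment_labeled = sum(areas$area[areas$j >= 1]) / total,
       remainder_labeled = sum(areas$area[areas$k - areas$j >= 1]) / total,
       coverage = coverage, complete = complete)
}
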