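#' Element mass and natural-abundance table
#'
#' Returns the packaged table of per-element nominal (integer) masses,
#' monoisotopic masses, and the natural abundance of the single-neutron
#' heavy isotope (13C, 15N, 2H, 17O, 33S). The table covers the CHNOPS
#' elements that make up every analyte in the transition library; it is
#' shipped as a plain CSV under \code{inst/extdata} so the numbers are
#' inspectable and citable.
#'
#' @return A data frame with columns \code{element}, \code{nominal_mass},
#'   \code{monoisotopic_mass}, \code{heavy_abundance}.
#' @export
#' @examples
#' element_masses()
element_masses <- function() {
  if (is.null(.mrmflux_cache$elements)) {
    path <- system.file("extdata", "element_masses.csv", package = "mrmflux",
                        mustWork = TRUE)
    tab <- utils::read.csv(path, stringsAsFactors = FALSE)
    stopifnot(all(tab$nominal_mass == round(tab$nominal_mass)),
              all(tab$heavy_abundance >= 0 & tab$heavy_abundance <= 1))
    .mrmflux_cache$elements <- tab
  }
  .mrmflux_cache$elements
}

.mrmflux_cache <- new.env(parent = emptyenv())

# monoisotopic mass of the proton; nominal-mode ion math uses exactly 1
PROTON_MASS <- 1.007276467

.element_vector <- function(column) {
  tab <- element_masses()
  stats::setNames(tab[[column]], tab$element)
}

#' Parse a Hill-notation molecular formula
#'
#' Parses strings such as \code{"C10H14N5O7P"} into a named integer vector
#' of element counts (class \code{"chem_formula"}). An omitted count means
#' one atom. Only elements present in \code{\link{element_masses}} are
#' accepted; an unknown symbol or malformed count is an error.
#'
#' @param text A formula string, e.g. \code{"C6H12O6"}. The empty string
#'   yields the empty formula (mass zero).
#' @return A \code{chem_formula}: named integer vector of atom counts.
#' @export
#' @examples
#' parse_formula("C10H14N5O7P")
#' nominal_mass(parse_formula("H2O"))
parse_formula <- function(text) {
  stopifnot(is.character(text), length(text) == 1L, !is.na(text))
  text <- trimws(text)
  known <- element_masses()$element
  counts <- stats::setNames(integer(length(known)), known)
  if (nzchar(text)) {
    m <- gregexpr("([A-Z][a-z]?)([0-9]*)", text, perl = TRUE)[[1]]
    tokens <- regmatches(text, list(m))[[1]]
    if (sum(attr(m, "match.length")) != nchar(text)) {
      stop("malformed formula string: '", text, "'")
    }
    for (tok in tokens) {
      sym <- sub("[0-9]*$", "", tok)
      num <- sub("^[A-Za-z]+", "", tok)
      n <- if (nzchar(num)) as.integer(num) else 1L
      if (!sym %in% known) {
        stop("unknown element symbol '", sym, "' in formula '", text, "'")
      }
      counts[sym] <- counts[sym] + n
    }
  }
  new_chem_formula(counts)
}

new_chem_formula <- function(counts) {
  counts <- counts[counts > 0L]
  storage.mode(counts) <- "integer"
  if (any(counts < 0L)) stop("negative atom count")
  structure(counts, class = "chem_formula")
}

#' @export
format.chem_formula <- function(x, ...) {
  if (length(x) == 0L) return("")
  # Hill order: C, H, then alphabetical
  nm <- names(x)
  ord <- order(match(nm, c("C", "H"), nomatch = 3L), nm)
  paste0(nm[ord], ifelse(x[ord] == 1L, "", x[ord]), collapse = "")
}

#' @export
print.chem_formula <- function(x, ...) {
  cat("<chem_formula> ", format(x), "  (nominal ", nominal_mass(x), " Da)\n",
      sep = "")
  invisible(x)
}

#' @export
`+.chem_formula` <- function(e1, e2) {
  els <- union(names(e1), names(e2))
  out <- stats::setNames(integer(length(els)), els)
  out[names(e1)] <- out[names(e1)] + unclass(e1)
  out[names(e2)] <- out[names(e2)] + unclass(e2)
  new_chem_formula(out)
}

#' @export
`-.chem_formula` <- function(e1, e2) {
  if (missing(e2)) stop("unary minus is undefined for formulas")
  els <- union(names(e1), names(e2))
  out <- stats::setNames(integer(length(els)), els)
  out[names(e1)] <- out[names(e1)] + unclass(e1)
  out[names(e2)] <- out[names(e2)] - unclass(e2)
  if (any(out < 0L)) {
    stop("formula subtraction would yield a negative count for: ",
         paste(els[out < 0L], collapse = ", "))
  }
  new_chem_formula(out)
}

.as_formula <- function(f) {
  if (inherits(f, "chem_formula")) f else parse_formula(f)
}

#' Nominal (integer) molecular mass
#'
#' Sum of per-element nominal masses times atom counts. This is the mass
#' scale on which unit-resolution triple-quadrupole Q1/Q3 settings are
#' printed, so it is the package default for transition prediction.
#'
#' @param f A \code{chem_formula} or a formula string.
#' @return Integer mass in Da.
#' @export
#' @examples
#' nominal_mass("C10H14N5O7P")  # 347
nominal_mass <- function(f) {
  f <- .as_formula(f)
  if (length(f) == 0L) return(0L)
  masses <- .element_vector("nominal_mass")
  as.integer(sum(masses[names(f)] * unclass(f)))
}

#' Monoisotopic molecular mass
#'
#' Sum of lightest-isotope exact masses times atom counts; provided for
#' high-resolution use alongside the nominal default.
#'
#' @inheritParams nominal_mass
#' @return Mass in Da (double).
#' @export
monoisotopic_mass <- function(f) {
  f <- .as_formula(f)
  if (length(f) == 0L) return(0)
  masses <- .element_vector("monoisotopic_mass")
  sum(masses[names(f)] * unclass(f))
}

#' Ion specification for m/z computation
#'
#' The two ionization modes the method suite uses: positive polarity pairs
#' with proton gain ([M+H]+) and negative polarity with proton loss
#' ([M-H]-). Any other pairing is rejected.
#'
#' @param polarity "positive" or "negative".
#' @param charge Positive integer charge state (default 1).
#' @param adduct "proton-gain" or "proton-loss"; defaults to the one the
#'   polarity implies.
#' @return An object of class \code{"ion_spec"}.
#' @export
ion_spec <- function(polarity = c("positive", "negative"), charge = 1L,
                     adduct = NULL) {
  polarity <- match.arg(polarity)
  charge <- as.integer(charge)
  stopifnot(charge >= 1L)
  if (is.null(adduct)) {
    adduct <- if (polarity == "positive") "proton-gain" else "proton-loss"
  }
  adduct <- match.arg(adduct, c("proton-gain", "proton-loss"))
  ok <- (polarity == "positive" && adduct == "proton-gain") ||
    (polarity == "negative" && adduct == "proton-loss")
  if (!ok) stop("polarity '", polarity, "' is incompatible with adduct '",
                adduct, "'")
  structure(list(polarity = polarity, charge = charge, adduct = adduct),
            class = "ion_spec")
}

#' Compute the m/z of a protonated or deprotonated ion
#'
#' In nominal mode the proton counts as exactly 1 Da so that predicted
#' values reproduce printed unit-resolution Q1/Q3 settings bit-exactly; in
#' monoisotopic mode the exact proton mass is used.
#'
#' @inheritParams nominal_mass
#' @param ion An \code{\link{ion_spec}}, or a polarity string as shorthand.
#' @param mode "nominal" (default) or "monoisotopic".
#' @return m/z (integer in nominal mode for singly charged ions).
#' @export
#' @examples
#' ion_mz("C10H14N5O7P", "positive")            # 348, AMP [M+H]+
#' ion_mz("C6H13O9P", "negative")               # 259, G6P [M-H]-
ion_mz <- function(f, ion, mode = c("nominal", "monoisotopic")) {
  mode <- match.arg(mode)
  if (is.character(ion)) ion <- ion_spec(ion)
  stopifnot(inherits(ion, "ion_spec"))
  m <- if (mode == "nominal") nominal_mass(f) else monoisotopic_mass(f)
  pm <- if (mode == "nominal") 1 else PROTON_MASS
  sign <- if (ion$adduct == "proton-gain") 1 else -1
  mz <- (m + sign * ion$charge * pm) / ion$charge
  if (mz <= 0) stop("non-positive m/z for formula of mass ", m)
  if (mode == "nominal" && ion$charge == 1L) mz <- as.integer(mz)
  mz
}

# net formula change per OBHA condensation site:
# OBHA (C7H9NO) attacks a carbonyl/activated carboxyl and water leaves,
# so the analyte gains C7H9NO - H2O = C7H7N, i.e. +105 Da nominal.
OBHA_NET <- c(C = 7L, H = 7L, N = 1L)

#' Apply O-benzylhydroxylamine (OBHA) derivatization stoichiometry
#'
#' Each derivatized carbonyl/carboxyl site condenses with OBHA and
#' releases water, a net gain of C7H7N (+105 Da nominal) per site. The
#' number of sites is a curated per-analyte attribute in the transition
#' library, never inferred from the formula: glutamate, for example, is
#' mono-derivatized on this method despite carrying two carboxyls.
#'
#' @inheritParams nominal_mass
#' @param n_sites Non-negative integer number of derivatized sites.
#' @return The derivatized \code{chem_formula}.
#' @export
#' @examples
#' ion_mz(derivatize_obha("C3H4O3", 2), "positive")  # 299, bis-OBHA pyruvate
derivatize_obha <- function(f, n_sites) {
  f <- .as_formula(f)
  n_sites <- as.integer(n_sites)
  if (is.na(n_sites) || n_sites < 0L) stop("n_sites must be >= 0")
  if (n_sites == 0L) return(f)
  f + new_chem_formula(OBHA_NET * n_sites)
}
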