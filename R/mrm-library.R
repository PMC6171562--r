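#' Load the packaged MRM transition library
#'
#' The library reproduces, verbatim, the printed acquisition parameters of
#' the single-column method suite: analyte name and abbreviation, molecular
#' formula, polarity, OBHA derivatization state with the curated number of
#' derivatized sites, precursor (Q1) and product (Q3) m/z, collision energy
#' (CE, volts), retention time (RT, minutes), and the method/gradient each
#' analyte is acquired under. Printed Q1/Q3 values are authoritative for
#' acquisition; \code{\link{predict_transition}} recomputes them from the
#' formulas to validate the library and extend it to new analytes.
#'
#' Several metabolites appear under more than one method (e.g. aspartate
#' underivatized in both polarities and OBHA-derivatized), so rows are
#' keyed by \code{entry_id} and uniqueness is enforced on
#' (abbreviation, method_tag).
#'
#' @param path Optional path to a library CSV in the packaged dialect;
#'   defaults to the packaged resource.
#' @return A data frame with one row per analyte entry and list columns
#'   \code{q3} (numeric product m/z), \code{ce} (volts) and
#'   \code{fragment} (per-product fragment spec, each \code{"none"} or
#'   \code{"product:<formula>"} / \code{"loss:<formula>"}).
#' @export
#' @examples
#' lib <- load_mrm_library()
#' subset(lib, abbreviation == "AMP")[, c("q1", "rt")]
load_mrm_library <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "mrm_library.csv", package = "mrmflux",
                        mustWork = TRUE)
  }
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(q1 = "numeric", rt = "numeric",
                                        n_obha_sites = "integer"))
  required <- c("entry_id", "abbreviation", "name", "formula", "polarity",
                "derivatization", "n_obha_sites", "q1", "q3_list", "ce_list",
                "fragment_list", "rt", "method_tag", "gradient")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    stop("library file is missing columns: ", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(raw[c("abbreviation", "method_tag")])) {
    stop("duplicate (abbreviation, method_tag) in library")
  }
  raw$q3 <- lapply(strsplit(raw$q3_list, ";", fixed = TRUE), as.numeric)
  raw$ce <- lapply(strsplit(raw$ce_list, ";", fixed = TRUE), as.numeric)
  raw$fragment <- strsplit(raw$fragment_list, ";", fixed = TRUE)
  n_q3 <- lengths(raw$q3)
  if (any(lengths(raw$ce) != n_q3) || any(lengths(raw$fragment) != n_q3)) {
    stop("q3_list, ce_list and fragment_list must have matching lengths")
  }
  # sanity on printed values
  stopifnot(all(raw$q1 > 0), all(raw$rt >= 0),
            all(unlist(raw$q3) < rep(raw$q1, n_q3)))
  for (i in seq_len(nrow(raw))) {
    parse_formula(raw$formula[i])  # errors on a malformed formula
    for (fr in raw$fragment[[i]]) .parse_fragment(fr)
  }
  raw$q3_list <- raw$ce_list <- raw$fragment_list <- NULL
  class(raw) <- c("mrm_library", "data.frame")
  raw
}

.parse_fragment <- function(spec) {
  if (is.na(spec) || spec == "" || spec == "none") {
    return(list(kind = "none"))
  }
  parts <- strsplit(spec, ":", fixed = TRUE)[[1]]
  if (length(parts) != 2L || !parts[1] %in% c("product", "loss")) {
    stop("malformed fragment spec '", spec, "'")
  }
  list(kind = parts[1], formula = parse_formula(parts[2]))
}

#' Load the packaged HPLC gradient programs
#'
#' @param path Optional path to a gradients YAML file; defaults to the
#'   packaged resource.
#' @return A named list of gradient programs, each with buffers, column
#'   temperature, flow rate and a timetable data frame (minutes, %B).
#' @export
load_gradients <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "gradients.yml", package = "mrmflux",
                        mustWork = TRUE)
  }
  raw <- yaml::read_yaml(path)
  lapply(raw, function(g) {
    tt <- do.call(rbind, lapply(g$timetable, as.data.frame))
    if (any(diff(tt$time_min) <= 0)) stop("gradient times must strictly increase")
    if (any(tt$percent_b < 0 | tt$percent_b > 100)) stop("%B must lie in [0, 100]")
    g$timetable <- tt
    g
  })
}

#' Predict Q1/Q3 of a library entry from first principles
#'
#' Q1 is the (de)protonated m/z of the analyte formula after applying the
#' curated OBHA derivatization stoichiometry. Each Q3 is computed from the
#' entry's fragment spec: a \code{product} fragment is ionized in the same
#' polarity as the precursor; a \code{loss} fragment subtracts the neutral
#' mass from Q1. Products whose fragmentation is not curated are returned
#' as \code{NA} (prediction is then limited to Q1).
#'
#' @param entry One row of \code{\link{load_mrm_library}} (or a one-row
#'   data frame in the same dialect).
#' @param mode "nominal" (default, unit resolution) or "monoisotopic".
#' @return List with \code{q1} and numeric vector \code{q3} (NA where not
#'   predictable).
#' @export
#' @examples
#' lib <- load_mrm_library()
#' predict_transition(lib[lib$entry_id == "AMP.pos", ])  # 348 / 136
predict_transition <- function(entry, mode = c("nominal", "monoisotopic")) {
  mode <- match.arg(mode)
  stopifnot(is.data.frame(entry), nrow(entry) == 1L)
  f <- parse_formula(entry$formula)
  if (identical(entry$derivatization, "OBHA")) {
    f <- derivatize_obha(f, entry$n_obha_sites)
  }
  ion <- ion_spec(entry$polarity)
  q1 <- ion_mz(f, ion, mode)
  frags <- entry$fragment[[1]]
  q3 <- vapply(frags, function(spec) {
    fr <- .parse_fragment(spec)
    switch(fr$kind,
           none = NA_real_,
           product = as.numeric(ion_mz(fr$formula, ion, mode)),
           loss = {
             loss_mass <- if (mode == "nominal") nominal_mass(fr$formula)
                          else monoisotopic_mass(fr$formula)
             as.numeric(q1 - loss_mass)
           })
  }, numeric(1))
  list(q1 = as.numeric(q1), q3 = q3)
}

#' Validate the transition library against formula-based predictions
#'
#' Recomputes every predictable Q1 and Q3 in nominal mode and classifies
#' each entry as \code{"exact-match"} (all predictable values reproduce
#' the printed ones after rounding to unit resolution), \code{"off-by-k"}
#' (some predictable value deviates; the maximum absolute integer
#' deviation is reported) or \code{"not-predictable"} (no curated
#' fragment and no checkable Q1 — never the case for this library, where
#' Q1 is always predictable). Known anomalies (the glutamine-OBHA printed
#' Q1) carry their curated annotation rather than being silently absorbed.
#'
#' @param lib A library from \code{\link{load_mrm_library}}.
#' @return A data frame with one row per entry: predicted/printed Q1, the
#'   per-entry status, maximum deviation, and the anomaly annotation.
#' @export
validate_library <- function(lib = load_mrm_library()) {
  rows <- lapply(seq_len(nrow(lib)), function(i) {
    entry <- lib[i, ]
    pred <- predict_transition(entry, mode = "nominal")
    printed <- c(entry$q1, entry$q3[[1]])
    predicted <- c(pred$q1, pred$q3)
    comparable <- !is.na(predicted)
    dev <- predicted[comparable] - round(printed[comparable])
    status <- if (!any(comparable)) "not-predictable"
              else if (all(dev == 0)) "exact-match"
              else "off-by-k"
    data.frame(entry_id = entry$entry_id,
               abbreviation = entry$abbreviation,
               method_tag = entry$method_tag,
               q1_printed = entry$q1,
               q1_predicted = pred$q1,
               n_q3_predictable = sum(!is.na(pred$q3)),
               n_q3 = length(pred$q3),
               status = status,
               max_abs_deviation = if (length(dev)) max(abs(dev)) else NA_integer_,
               anomaly = entry$anomaly,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Resolve isobaric transitions by retention time
#'
#' Amino-acid pairs such as isoleucine/leucine and lysine/glutamine share
#' identical Q1/Q3 and are distinguished only chromatographically. Given an
#' observed (Q1, Q3, RT), this returns the library entry sharing that
#' transition whose RT is nearest the observation, within \code{tolerance}
#' minutes. An exact RT tie between two candidates is an error, never a
#' silent choice.
#'
#' @param q1,q3 Observed transition m/z (matched to printed values within
#'   \code{mz_tolerance}).
#' @param rt Observed retention time, minutes.
#' @param tolerance RT matching window, minutes (> 0).
#' @param lib Library data frame.
#' @param mz_tolerance m/z matching window for printed values (default 0.5,
#'   unit resolution).
#' @return The matching library row (one-row data frame).
#' @export
#' @examples
#' resolve_isobars(132.0, 86.0, rt = 6.5)$name  # "Isoleucine"
resolve_isobars <- function(q1, q3, rt, tolerance = 0.5,
                            lib = load_mrm_library(), mz_tolerance = 0.5) {
  stopifnot(tolerance > 0, mz_tolerance > 0)
  hit <- vapply(seq_len(nrow(lib)), function(i) {
    abs(lib$q1[i] - q1) <= mz_tolerance &&
      any(abs(lib$q3[[i]] - q3) <= mz_tolerance)
  }, logical(1))
  cand <- lib[hit, , drop = FALSE]
  if (nrow(cand) == 0L) {
    stop("no library transition matches Q1/Q3 ", q1, "/", q3)
  }
  drt <- abs(cand$rt - rt)
  cand <- cand[drt <= tolerance, , drop = FALSE]
  drt <- drt[drt <= tolerance]
  if (nrow(cand) == 0L) {
    stop("no candidate within ", tolerance, " min of RT ", rt)
  }
  best <- which(drt == min(drt))
  if (length(best) > 1L) {
    stop("RT tie between ", paste(cand$entry_id[best], collapse = ", "),
         " at RT ", rt)
  }
  cand[best, , drop = FALSE]
}
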