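# 13C/15N isotopologue MRM ladder design with fragment-aware label
# partitioning. For an MRM transition whose product ion retains n_frag of
# the n_total labelable atoms, a precursor carrying k labels can place
# j of them in the fragment, where
#   max(0, k - (n_total - n_frag)) <= j <= min(k, n_frag),
# giving the channel (Q1 + k, Q3 + j). The independent Q1 and Q3 shifts
# are what resolve moieties (e.g. AMP's ribose vs its nitrogen base).

#' Define a labeling scheme for one tracer element
#'
#' @param element "C" or "N" — the traced element.
#' @param n_total Labelable atoms of that element in the precursor ion.
#' @param n_frag Labelable atoms retained in the product ion
#'   (0 <= n_frag <= n_total).
#' @param mass_shift Mass shift per label: 1 (unit/nominal, default) or
#'   the exact heavy-minus-light isotope mass difference for
#'   high-resolution work (1.00336 for 13C, 0.99703 for 15N).
#' @return An object of class \code{"label_scheme"}.
#' @export
#' @examples
#' label_scheme("N", n_total = 5, n_frag = 5)   # 15N in AMP: base keeps all N
#' label_scheme("C", n_total = 10, n_frag = 5)  # 13C in AMP: base keeps 5 C
label_scheme <- function(element = c("C", "N"), n_total, n_frag = n_total,
                         mass_shift = 1) {
  element <- match.arg(element)
  n_total <- as.integer(n_total)
  n_frag <- as.integer(n_frag)
  if (n_total < 0L || n_frag < 0L || n_frag > n_total) {
    stop("need 0 <= n_frag <= n_total")
  }
  stopifnot(mass_shift > 0)
  structure(list(element = element, n_total = n_total, n_frag = n_frag,
                 mass_shift = mass_shift),
            class = "label_scheme")
}

#' @export
print.label_scheme <- function(x, ...) {
  cat("<label_scheme> ", x$element, ": ", x$n_total, " labelable atoms (",
      x$n_frag, " in fragment), shift ", x$mass_shift, " per label\n", sep = "")
  invisible(x)
}

.feasible_j <- function(k, n_total, n_frag) {
  lo <- max(0L, k - (n_total - n_frag))
  hi <- min(k, n_frag)
  if (lo > hi) integer(0) else lo:hi
}

#' Generate the complete isotopologue MRM ladder for an analyte
#'
#' Enumerates every feasible (k, j) channel — k labels in the precursor,
#' j of them in the fragment — for the given scheme, with Q1 = base Q1 +
#' k * shift and Q3 = base Q3 + j * shift. Channel names follow the
#' \code{<element>_<abbrev>_<k>} pattern, with a moiety suffix when more
#' than one j exists for the same k. Collision energy is inherited from
#' the base (unlabeled) transition: labeled channels fragment identically.
#'
#' @param entry A one-row library entry (see \code{\link{load_mrm_library}});
#'   the first printed Q3/CE pair is used as the base transition.
#' @param scheme A \code{\link{label_scheme}}; its \code{n_total} must not
#'   exceed the analyte's atom count for that element.
#' @return A data frame of channels: \code{name, k, j, q1, q3, ce,
#'   moiety_tag} with tags \code{unlabeled} (k = 0),
#'   \code{fragment-labeled} (j = k), \code{remainder-labeled} (j = 0,
#'   k > 0) and \code{mixed}.
#' @export
#' @examples
#' lib <- load_mrm_library()
#' amp <- lib[lib$entry_id == "AMP.pos", ]
#' generate_ladder(amp, label_scheme("N", 5, 5))  # 348/136 ... 353/141
generate_ladder <- function(entry, scheme) {
  stopifnot(inherits(scheme, "label_scheme"),
            is.data.frame(entry), nrow(entry) == 1L)
  f <- parse_formula(entry$formula)
  n_atoms <- if (scheme$element %in% names(f)) f[[scheme$element]] else 0L
  if (scheme$n_total > n_atoms) {
    stop("scheme has n_total = ", scheme$n_total, " but ", entry$abbreviation,
         " contains only ", n_atoms, " ", scheme$element, " atoms")
  }
  base_q1 <- entry$q1
  base_q3 <- entry$q3[[1]][1]
  base_ce <- entry$ce[[1]][1]
  rows <- list()
  for (k in 0:scheme$n_total) {
    js <- .feasible_j(k, scheme$n_total, scheme$n_frag)
    # the channel published tables name without a suffix: all labels in
    # the fragment while they fit, remainder saturated beyond that
    series_j <- if (k <= scheme$n_frag) k
                else k - (scheme$n_total - scheme$n_frag)
    for (j in js) {
      tag <- if (k == 0L) "unlabeled"
             else if (j == k) "fragment-labeled"
             else if (j == 0L) "remainder-labeled"
             else "mixed"
      name <- paste0(if (scheme$element == "C") "13C" else "15N", "_",
                     entry$abbreviation, "_", k)
      if (j != series_j) {
        name <- paste0(name, "_", if (j == 0L) "remainder" else paste0("j", j))
      }
      rows[[length(rows) + 1L]] <-
        data.frame(name = name, k = k, j = j,
                   q1 = base_q1 + k * scheme$mass_shift,
                   q3 = base_q3 + j * scheme$mass_shift,
                   ce = base_ce, moiety_tag = tag,
                   stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  expected <- sum(vapply(0:scheme$n_total, function(k) {
    length(.feasible_j(k, scheme$n_total, scheme$n_frag))
  }, integer(1)))
  stopifnot(nrow(out) == expected, !anyDuplicated(out[c("q1", "q3")]))
  out
}

#' Select an acquisition subset of an isotopologue ladder
#'
#' Published labeled-transition tables typically list only a subset of the
#' feasible grid: the channels where Q3 tracks the fragment (maximal j per
#' k, the default readout) plus, for moiety work, the fragment-unlabeled
#' channels (j = 0, label confined to the remainder moiety — e.g. the
#' all-ribose 13C AMP channel 353/136).
#'
#' @param ladder Output of \code{\link{generate_ladder}}.
#' @param policy \code{"q3-tracks-fragment"}: one channel per k, with all
#'   labels in the fragment while they fit (j = k for k <= n_frag) and the
#'   remainder moiety saturated beyond that (j = k - n_remainder) — the
#'   series published tables print; \code{"fragment-unlabeled"}: the j = 0
#'   channels (label confined to the remainder moiety); or
#'   \code{"full-grid"}.
#' @return The subset, same columns as the ladder.
#' @export
select_channels <- function(ladder,
                            policy = c("q3-tracks-fragment",
                                       "fragment-unlabeled", "full-grid")) {
  policy <- match.arg(policy)
  n_total <- max(ladder$k)
  n_frag <- max(ladder$j)
  switch(policy,
         "full-grid" = ladder,
         "fragment-unlabeled" = ladder[ladder$j == 0L, , drop = FALSE],
         "q3-tracks-fragment" = {
           target_j <- ifelse(ladder$k <= n_frag, ladder$k,
                              ladder$k - (n_total - n_frag))
           ladder[ladder$j == target_j, , drop = FALSE]
         })
}

#' Partition an analyte's atoms into fragment and remainder moieties
#'
#' For entries whose fragment spec is a product-ion formula, counts the
#' atoms of each element in the product (the fragment moiety) and in what
#' the precursor loses (the remainder moiety). For AMP this recovers the
#' nitrogen base (5 C, 5 N) versus the ribose-phosphate remainder
#' (5 C, 0 N) that underlies moiety-resolved label tracing.
#'
#' @param entry A one-row library entry with a \code{product:} fragment.
#' @return A data frame: \code{element, precursor, fragment, remainder}.
#' @export
moiety_atoms <- function(entry) {
  stopifnot(is.data.frame(entry), nrow(entry) == 1L)
  specs <- lapply(entry$fragment[[1]], .parse_fragment)
  kinds <- vapply(specs, `[[`, "", "kind")
  ip <- which(kinds == "product")
  if (length(ip) == 0L) {
    stop("entry ", entry$entry_id, " has no product-ion fragment formula")
  }
  prec <- parse_formula(entry$formula)
  if (identical(entry$derivatization, "OBHA")) {
    prec <- derivatize_obha(prec, entry$n_obha_sites)
  }
  frag <- specs[[ip[1]]]$formula
  els <- names(prec)
  fr <- vapply(els, function(e) {
    if (e %in% names(frag)) frag[[e]] else 0L
  }, integer(1))
  if (any(fr > unclass(prec))) {
    stop("fragment atoms exceed precursor atoms for ", entry$entry_id)
  }
  data.frame(element = els, precursor = as.integer(prec), fragment = fr,
             remainder = as.integer(prec) - fr, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Write an isotopologue ladder as a CSV acquisition list
#'
#' @param ladder Output of \code{\link{generate_ladder}} (or a subset).
#' @param path Output CSV path.
#' @return Invisibly, the exported data frame (name, Q1, Q3, CE).
#' @export
write_acquisition_list <- function(ladder, path) {
  out <- ladder[, c("name", "q1", "q3", "ce")]
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(out)
}
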