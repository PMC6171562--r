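# Shared fixtures and independent oracles, all built in code.

library_entry <- function(id, lib = load_mrm_library()) {
  lib[lib$entry_id == id, , drop = FALSE]
}

# regex-free formula tokenizer: character-by-character scan
oracle_parse_formula <- function(text) {
  chars <- strsplit(text, "")[[1]]
  counts <- integer(0)
  sym <- ""
  num <- ""
  flush <- function(counts, sym, num) {
    if (sym == "") return(counts)
    n <- if (num == "") 1L else as.integer(num)
    counts[sym] <- (if (sym %in% names(counts)) counts[[sym]] else 0L) + n
    counts
  }
  for (ch in chars) {
    if (ch %in% LETTERS) {
      counts <- flush(counts, sym, num)
      sym <- ch
      num <- ""
    } else if (ch %in% letters) {
      sym <- paste0(sym, ch)
    } else if (ch %in% as.character(0:9)) {
      num <- paste0(num, ch)
    } else stop("bad char")
  }
  counts <- flush(counts, sym, num)
  counts[counts > 0]
}

# random CHNOPS formula string for property tests
random_formula_string <- function() {
  els <- c("C", "H", "N", "O", "P", "S")
  n <- sample(2:5, 1)
  pick <- sample(els, n)
  paste0(pick, sample(1:20, n, replace = TRUE), collapse = "")
}

# brute-force (k, j) grid oracle: double loop with the feasibility test
oracle_grid <- function(n_total, n_frag) {
  out <- NULL
  for (k in 0:n_total) {
    for (j in 0:n_total) {
      if (j <= k && j <= n_frag && (k - j) <= (n_total - n_frag)) {
        out <- rbind(out, c(k = k, j = j))
      }
    }
  }
  as.data.frame(out)
}

# one-row synthetic library-style entry (for ladder/moiety tests that
# should not depend on the packaged file)
synthetic_entry <- function(formula = "C3H7NO2", q1 = 90, q3 = 44, ce = 11,
                            fragment = "none", polarity = "positive",
                            rt = 1, abbreviation = "SYN") {
  data.frame(entry_id = paste0(abbreviation, ".syn"),
             abbreviation = abbreviation, name = "synthetic",
             formula = formula, polarity = polarity, derivatization = "none",
             n_obha_sites = 0L, q1 = q1, rt = rt, method_tag = "syn",
             gradient = "syn", anomaly = "", comment = "",
             q3 = I(list(q3)), ce = I(list(ce)),
             fragment = I(list(fragment)),
             stringsAsFactors = FALSE)
}

gaussian_area <- function(height, width) height * width * sqrt(2 * pi)
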