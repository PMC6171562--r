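# CSV interchange: long-format chromatograms and isotopologue channel
# intensity tables, with validating readers that name the offending row.

#' Read an isotopologue channel intensity table
#'
#' Expected columns: \code{analyte}, \code{time}, \code{k}, \code{j},
#' \code{area}. Validation errors name the offending file row.
#'
#' @param path CSV path.
#' @return The validated data frame (with integer \code{k}, \code{j}).
#' @export
read_intensity_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("analyte", "time", "k", "j", "area")
  missing <- setdiff(required, names(tab))
  if (length(missing) > 0) {
    stop("missing column(s): ", paste(missing, collapse = ", "))
  }
  # data row i is file line i + 1 (header)
  bad <- which(!is.finite(tab$area) | tab$area < 0)
  if (length(bad) > 0) {
    stop("negative or non-numeric area at file row ", bad[1] + 1L)
  }
  bad <- which(tab$k < 0 | tab$j < 0 | tab$j > tab$k)
  if (length(bad) > 0) {
    stop("invalid (k, j) channel at file row ", bad[1] + 1L)
  }
  dup <- which(duplicated(tab[c("analyte", "time", "k", "j")]))
  if (length(dup) > 0) {
    stop("duplicate (analyte, time, k, j) at file row ", dup[1] + 1L)
  }
  tab$k <- as.integer(tab$k)
  tab$j <- as.integer(tab$j)
  tab
}

#' Write an isotopologue channel intensity table
#'
#' @param tab Data frame in the \code{\link{read_intensity_table}}
#'   dialect.
#' @param path Output CSV path.
#' @return Invisibly, \code{path}.
#' @export
write_intensity_table <- function(tab, path) {
  stopifnot(all(c("analyte", "time", "k", "j", "area") %in% names(tab)))
  utils::write.csv(tab[, c("analyte", "time", "k", "j", "area")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a long-format chromatogram table
#'
#' Expected columns: \code{transition_id}, \code{time_min},
#' \code{intensity}.
#'
#' @param path CSV path.
#' @return The validated data frame.
#' @export
read_chromatogram_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("transition_id", "time_min", "intensity")
  missing <- setdiff(required, names(tab))
  if (length(missing) > 0) {
    stop("missing column(s): ", paste(missing, collapse = ", "))
  }
  bad <- which(!is.finite(tab$intensity) | tab$intensity < 0)
  if (length(bad) > 0) {
    stop("negative or non-numeric intensity at file row ", bad[1] + 1L)
  }
  tab
}

#' Write a long-format chromatogram table
#'
#' @param tab Data frame with \code{transition_id}, \code{time_min},
#'   \code{intensity}.
#' @param path Output CSV path.
#' @return Invisibly, \code{path}.
#' @export
write_chromatogram_table <- function(tab, path) {
  stopifnot(all(c("transition_id", "time_min", "intensity") %in% names(tab)))
  utils::write.csv(tab[, c("transition_id", "time_min", "intensity")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}
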