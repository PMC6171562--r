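# Transparent chromatographic peak detection and integration, replacing
# the vendor quantitation step, plus a synthetic-chromatogram generator
# used throughout the test suite.

#' Simulate MRM chromatograms
#'
#' Generates long-format chromatograms as Gaussian peaks at specified
#' retention times on a uniform time grid, plus i.i.d. Gaussian baseline
#' noise, clipped at zero. Deterministic given the seed.
#'
#' @param peaks A data frame with columns \code{transition_id},
#'   \code{rt} (minutes), \code{height} (counts) and \code{width}
#'   (Gaussian sigma, minutes; > 0). Several rows may share a
#'   transition_id (co-eluting peaks on one trace).
#' @param t_range Time window in minutes, default \code{c(0, 21)} (the
#'   method run length).
#' @param dt Grid spacing, minutes (default 0.01, ~ 1.7 Hz dwell).
#' @param noise_sd Baseline noise standard deviation, counts.
#' @param seed Integer RNG seed; required so fixtures are reproducible.
#' @return A data frame \code{(transition_id, time_min, intensity)}.
#' @export
#' @examples
#' sim <- simulate_chromatogram(
#'   data.frame(transition_id = "132.0/86.0", rt = 6.53,
#'              height = 1e5, width = 0.05),
#'   noise_sd = 0, seed = 1)
simulate_chromatogram <- function(peaks, t_range = c(0, 21), dt = 0.01,
                                  noise_sd = 0, seed) {
  stopifnot(is.data.frame(peaks),
            all(c("transition_id", "rt", "height", "width") %in% names(peaks)),
            all(peaks$width > 0), all(peaks$height >= 0),
            length(t_range) == 2L, t_range[2] > t_range[1], dt > 0,
            noise_sd >= 0)
  if (!missing(seed)) set.seed(as.integer(seed))
  tt <- seq(t_range[1], t_range[2], by = dt)
  out <- lapply(split(peaks, peaks$transition_id), function(pk) {
    y <- rep(0, length(tt))
    for (i in seq_len(nrow(pk))) {
      y <- y + pk$height[i] * exp(-0.5 * ((tt - pk$rt[i]) / pk$width[i])^2)
    }
    if (noise_sd > 0) y <- y + stats::rnorm(length(tt), 0, noise_sd)
    data.frame(transition_id = pk$transition_id[1], time_min = tt,
               intensity = pmax(y, 0), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

.one_trace <- function(chrom) {
  stopifnot(is.data.frame(chrom),
            all(c("time_min", "intensity") %in% names(chrom)))
  if (length(unique(chrom$transition_id)) > 1L) {
    stop("detect/integrate operate on a single transition; split first")
  }
  if (nrow(chrom) < 8L) stop("chromatogram too short (< 8 points)")
  if (any(diff(chrom$time_min) <= 0)) stop("time must strictly increase")
  if (any(chrom$intensity < 0)) stop("negative intensities")
  chrom
}

#' Detect peaks in one chromatogram
#'
#' Boxcar-smooths the trace, finds local maxima, walks outward from each
#' apex to the flanking valley or baseline return, and estimates
#' signal-to-noise from the median absolute deviation of the trace's
#' first differences (robust to the peaks themselves). Maxima below the
#' SNR or width thresholds are dropped.
#'
#' @param chrom One-transition data frame \code{(time_min, intensity)}.
#' @param min_snr Minimum apex signal-to-noise (default 5).
#' @param min_width Minimum peak base width, minutes (default 0.02).
#' @param smooth Boxcar window in points, odd (default 5).
#' @return A data frame of peaks: \code{apex_rt, left, right, height,
#'   area, snr}, ordered by retention time; zero rows when nothing
#'   qualifies.
#' @export
detect_peaks <- function(chrom, min_snr = 5, min_width = 0.02, smooth = 5L) {
  chrom <- .one_trace(chrom)
  stopifnot(min_snr > 0, min_width > 0, smooth >= 1L)
  y_raw <- chrom$intensity
  tt <- chrom$time_min
  n <- length(y_raw)
  if (smooth > 1L) {
    k <- rep(1 / smooth, smooth)
    y <- as.numeric(stats::filter(y_raw, k, sides = 2))
    y[is.na(y)] <- y_raw[is.na(y)]
  } else y <- y_raw
  # robust noise level: MAD of successive differences, scaled for the
  # difference operator; floored at a tiny positive value for clean traces
  noise <- stats::mad(diff(y_raw)) / sqrt(2)
  baseline <- stats::median(y)
  if (all(y_raw == 0)) return(.empty_peaks())
  is_max <- c(FALSE, y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n],
              FALSE)
  apex_idx <- which(is_max)
  # walk down a flank, tolerating noise-scale bumps; stops at a genuine
  # valley (rise above the running minimum beyond noise) or at baseline
  # return, and reports which
  walk <- function(a, dir, floor_lvl, tol_rise) {
    i <- a
    run_min <- y[a]
    reason <- "end"
    while (i + dir >= 1L && i + dir <= n) {
      nxt <- y[i + dir]
      if (nxt > run_min + tol_rise) {
        reason <- "valley"
        break
      }
      i <- i + dir
      run_min <- min(run_min, y[i])
      if (y[i] <= floor_lvl) {
        reason <- "floor"
        break
      }
    }
    list(idx = i, reason = reason)
  }
  # Gaussian-equivalent sigma from the half-height width around an apex
  sigma_est <- function(a) {
    half <- baseline + (y[a] - baseline) / 2
    il <- a; while (il > 1L && y[il] > half) il <- il - 1L
    ir <- a; while (ir < n && y[ir] > half) ir <- ir + 1L
    hw <- min(tt[a] - tt[il], tt[ir] - tt[a])
    if (hw <= 0) return(NA_real_)
    hw / sqrt(2 * log(2))
  }
  rows <- list()
  for (a in apex_idx) {
    snr <- if (noise > 0) (y[a] - baseline) / noise else Inf
    if (snr < min_snr) next
    floor_lvl <- baseline + 0.5 * noise
    tol_rise <- 3 * noise
    wl <- walk(a, -1L, floor_lvl, tol_rise)
    wr <- walk(a, +1L, floor_lvl, tol_rise)
    l <- wl$idx
    r <- wr$idx
    if (l == a || r == a) next
    # a bound that reached baseline (not a valley) extends to apex +/- 4
    # sigma so the tails enter the integral
    sg <- sigma_est(a)
    if (is.finite(sg)) {
      if (wl$reason != "valley") {
        l <- min(l, max(1L, findInterval(tt[a] - 4 * sg, tt)))
      }
      if (wr$reason != "valley") {
        ri <- findInterval(tt[a] + 4 * sg, tt) + 1L
        r <- max(r, min(n, ri))
      }
    }
    if (tt[r] - tt[l] < min_width) next
    rows[[length(rows) + 1L]] <- data.frame(
      apex_rt = tt[a], left = tt[l], right = tt[r],
      height = y_raw[a], snr = snr)
  }
  if (length(rows) == 0L) return(.empty_peaks())
  pk <- do.call(rbind, rows)
  pk <- pk[order(pk$apex_rt), , drop = FALSE]
  pk$area <- vapply(seq_len(nrow(pk)), function(i) {
    integrate_peak(chrom, pk[i, ])
  }, numeric(1))
  rownames(pk) <- NULL
  pk[, c("apex_rt", "left", "right", "height", "area", "snr")]
}

.empty_peaks <- function() {
  data.frame(apex_rt = numeric(0), left = numeric(0), right = numeric(0),
             height = numeric(0), area = numeric(0), snr = numeric(0))
}

#' Integrate one peak by the trapezoid rule above a local linear baseline
#'
#' The baseline is the straight line joining the trace at the peak's left
#' and right bounds; the area is the trapezoidal integral of the trace
#' minus that line, floored at zero. This mirrors what vendor defaults
#' compute, in auditable form.
#'
#' @param chrom One-transition chromatogram data frame.
#' @param peak A one-row peak (needs \code{left} and \code{right},
#'   minutes), e.g. one row of \code{\link{detect_peaks}} output.
#' @return Area in intensity x minutes.
#' @export
integrate_peak <- function(chrom, peak) {
  chrom <- .one_trace(chrom)
  stopifnot(nrow(peak) == 1L)
  if (peak$left >= peak$right) stop("inverted peak bounds")
  if (peak$left < min(chrom$time_min) || peak$right > max(chrom$time_min)) {
    stop("peak bounds outside the chromatogram time range")
  }
  idx <- chrom$time_min >= peak$left & chrom$time_min <= peak$right
  tt <- chrom$time_min[idx]
  yy <- chrom$intensity[idx]
  if (length(tt) < 2L) return(0)
  # baseline endpoints as local medians so a single noisy sample at a
  # bound does not tilt the whole baseline
  m <- length(yy)
  k <- max(3L, min(11L, m %/% 8L))
  y_l <- stats::median(yy[seq_len(k)])
  y_r <- stats::median(yy[seq.int(m - k + 1L, m)])
  base <- y_l + (y_r - y_l) * (tt - tt[1]) / (tt[m] - tt[1])
  h <- yy - base
  max(sum(diff(tt) * (h[-m] + h[-1]) / 2), 0)
}

#' Assign detected peaks to library analytes by transition and RT
#'
#' Each peak (observed on a known Q1/Q3 transition) is matched to the
#' library entry sharing that transition whose retention time is nearest
#' within \code{rt_tolerance}; peaks with no candidate are reported
#' unassigned rather than dropped.
#'
#' @param peaks Data frame with columns \code{q1}, \code{q3},
#'   \code{apex_rt} (one row per detected peak).
#' @param lib Library from \code{\link{load_mrm_library}}.
#' @param rt_tolerance Minutes (default 0.5).
#' @return \code{peaks} with added columns \code{entry_id}, \code{name}
#'   (NA when unassigned) and \code{assigned}.
#' @export
assign_peaks <- function(peaks, lib = load_mrm_library(), rt_tolerance = 0.5) {
  stopifnot(all(c("q1", "q3", "apex_rt") %in% names(peaks)),
            rt_tolerance > 0)
  peaks$entry_id <- NA_character_
  peaks$name <- NA_character_
  for (i in seq_len(nrow(peaks))) {
    hit <- tryCatch(
      resolve_isobars(peaks$q1[i], peaks$q3[i], peaks$apex_rt[i],
                      tolerance = rt_tolerance, lib = lib),
      error = function(e) NULL)
    if (!is.null(hit)) {
      peaks$entry_id[i] <- hit$entry_id
      peaks$name[i] <- hit$name
    }
  }
  peaks$assigned <- !is.na(peaks$entry_id)
  peaks
}
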