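#' Optical-tweezers trace
#'
#' Uniformly sampled extension/force recording (default 2500 Hz).
#'
#' @param time Time (s), uniformly spaced.
#' @param extension Tether extension (nm).
#' @param force Tension (pN, >= 0).
#' @return Object of class `"tweezers_trace"` with attribute `fs` (Hz).
#' @export
tweezers_trace <- function(time, extension, force) {
  n <- length(time)
  if (length(extension) != n || length(force) != n)
    stop_recbcd("invalid_argument", "time, extension and force lengths differ")
  dt <- diff(time)
  if (any(dt <= 0) || (n > 2 && stats::sd(dt) > 1e-6 * mean(dt)))
    stop_recbcd("invalid_argument", "time must be uniformly increasing")
  if (any(force < 0))
    stop_recbcd("invalid_argument", "force must be >= 0")
  structure(list(time = time, extension = extension, force = force),
            class = "tweezers_trace", fs = 1 / mean(dt))
}

## Extensible worm-like chain in the high-force (Odijk) limit:
##   x = Lc (1 - (1/2) sqrt(kT/(F P)) + F/S)
## valid above a few pN; analytically invertible for Lc.
wlc_extension <- function(contour_nm, force_pN, persistence_nm = 50,
                          stretch_pN = 1200, kT = 4.114) {
  contour_nm * (1 - 0.5 * sqrt(kT / (force_pN * persistence_nm)) +
                  force_pN / stretch_pN)
}

#' Convert extension to contour length via the worm-like chain
#'
#' Inverts the extensible worm-like chain force-extension relation (Odijk
#' high-force form) sample by sample, then converts contour nanometres to
#' base pairs with the helix rise.  Samples with force below `force_floor`
#' (where the inversion is unstable) are flagged and linearly interpolated
#' from their neighbours.
#'
#' @param trace A [tweezers_trace()].
#' @param persistence_nm dsDNA persistence length (default 50 nm).
#' @param rise_nm_per_bp Helix rise (default 0.34 nm/bp).
#' @param stretch_pN Stretch modulus (default 1200 pN).
#' @param force_floor Minimum usable force (default 0.1 pN).
#' @param kT Thermal energy (pN nm), default 4.114 (25 C).
#' @return Object of class `"contour_trace"`: `time`, `contour_bp`, `force`,
#'   logical `flagged` for interpolated samples; attribute `fs`.
#' @export
extension_to_contour <- function(trace, persistence_nm = 50,
                                 rise_nm_per_bp = 0.34, stretch_pN = 1200,
                                 force_floor = 0.1, kT = 4.114) {
  stopifnot(inherits(trace, "tweezers_trace"))
  bad <- trace$force <= force_floor
  f <- pmax(trace$force, force_floor)
  denom <- 1 - 0.5 * sqrt(kT / (f * persistence_nm)) + f / stretch_pN
  contour_nm <- trace$extension / denom
  contour_bp <- contour_nm / rise_nm_per_bp
  if (any(bad)) {
    if (all(bad))
      stop_recbcd("numerical_error", "all samples below the force floor")
    good <- which(!bad)
    contour_bp[bad] <- stats::approx(trace$time[good], contour_bp[good],
                                     xout = trace$time[bad], rule = 2)$y
  }
  structure(list(time = trace$time, contour_bp = contour_bp,
                 force = trace$force, flagged = bad),
            class = "contour_trace", fs = attr(trace, "fs"))
}

## Running mean of the previous `k` samples (exclusive of the current one),
## truncated near the edges; `forward = FALSE` averages the next `k`.  Where
## the window is empty (first/last sample) the sample itself is used.
running_mean <- function(x, k, forward = TRUE) {
  n <- length(x)
  cs <- cumsum(c(0, x))
  i <- seq_len(n)
  if (forward) {
    lo <- pmax(i - 1 - k, 0)
    cnt <- i - 1 - lo
    out <- (cs[i] - cs[lo + 1]) / pmax(cnt, 1)
  } else {
    hi <- pmin(i + k, n)
    cnt <- hi - i
    out <- (cs[hi + 1] - cs[i + 1]) / pmax(cnt, 1)
  }
  out[cnt == 0] <- x[cnt == 0]
  out
}

#' Chung-Kennedy edge-preserving filter
#'
#' Nonlinear adaptive filter for piecewise-constant signals in noise: at
#' each sample the mean of a *past* window and the mean of a *future* window
#' are combined with weights proportional to the inverse of the local
#' predictor variance raised to the exponent `p`, so the window that does
#' not straddle a step dominates and edges are preserved.  The filter is run
#' for each window length and the outputs are averaged with the given
#' weights (equal by default).
#'
#' @param signal Numeric vector, longer than the largest window.
#' @param windows Window lengths in samples (default `c(25, 50, 100)`).
#' @param weights Per-window combination weights (default equal).
#' @param p Variance-weighting exponent (default 2).
#' @param eps Variance floor (default 1e-12) to keep weights finite on
#'   noise-free segments.
#' @return Filtered signal, same length as the input.
#' @export
chung_kennedy <- function(signal, windows = c(25, 50, 100),
                          weights = rep(1, length(windows)), p = 2,
                          eps = 1e-12) {
  n <- length(signal)
  if (n <= max(windows))
    stop_recbcd("invalid_argument",
                "signal must be longer than the largest window (%d)", max(windows))
  if (length(weights) != length(windows) || any(weights < 0) || sum(weights) == 0)
    stop_recbcd("invalid_argument", "bad window weights")
  weights <- weights / sum(weights)
  out <- numeric(n)
  for (j in seq_along(windows)) {
    k <- windows[j]
    mf <- running_mean(signal, k, forward = TRUE)    # past-window predictor
    mb <- running_mean(signal, k, forward = FALSE)   # future-window predictor
    ef <- running_mean((signal - mf)^2, k, forward = TRUE)   # local MSEs
    eb <- running_mean((signal - mb)^2, k, forward = FALSE)
    wf <- (ef + eps)^(-p)
    wb <- (eb + eps)^(-p)
    out <- out + weights[j] * (wf * mf + wb * mb) / (wf + wb)
  }
  out
}

#' Detect pauses in a filtered contour trace
#'
#' Histogram-based threshold algorithm: the filtered contour values are
#' binned (`bin_bp` wide); histogram peaks holding more than
#' `min_hist_points` samples mark candidate dwell positions; contiguous runs
#' of samples within a peak's bins define candidate pause intervals.
#' Adjacent candidates separated by less than `min_transloc_s` *and* less
#' than `min_contour_bp` are merged (they are one dwell split by noise);
#' candidates shorter than `min_pause_s` are then discarded, as is the later
#' of two consecutive pauses violating the minimum translocation time or
#' minimum contour change between pauses.
#'
#' @param contour A [extension_to_contour()] result (already
#'   Chung-Kennedy-filtered contour values may be supplied via `filtered`).
#' @param filtered Optional pre-filtered contour values; when `NULL` the
#'   contour is filtered with [chung_kennedy()] defaults.
#' @param min_pause_s Minimal pause duration (s), default 0.002.
#' @param min_transloc_s Minimal translocation time between pauses (s),
#'   default 0.001.
#' @param min_contour_bp Minimal contour change between pauses (bp),
#'   default 5.
#' @param min_hist_points Minimal samples in a histogram peak, default 50.
#' @param bin_bp Histogram bin width (bp), default 2.
#' @return Data frame of class `"pause_table"`: `start_s`, `end_s`,
#'   `duration_s`, `position_bp` (possibly zero rows).
#' @export
detect_pauses <- function(contour, filtered = NULL, min_pause_s = 0.002,
                          min_transloc_s = 0.001, min_contour_bp = 5,
                          min_hist_points = 50, bin_bp = 2) {
  stopifnot(inherits(contour, "contour_trace"))
  x <- if (is.null(filtered)) chung_kennedy(contour$contour_bp) else filtered
  t <- contour$time
  empty <- data.frame(start_s = numeric(0), end_s = numeric(0),
                      duration_s = numeric(0), position_bp = numeric(0))
  class(empty) <- c("pause_table", "data.frame")
  brk <- seq(floor(min(x)) - bin_bp, ceiling(max(x)) + bin_bp, by = bin_bp)
  counts <- graphics::hist(x, breaks = brk, plot = FALSE)$counts
  ## histogram peaks: local maxima above the occupancy threshold
  nb <- length(counts)
  is_peak <- counts > min_hist_points &
    counts >= c(-Inf, counts[-nb]) & counts >= c(counts[-1], -Inf)
  peaks <- which(is_peak)
  if (!length(peaks)) return(empty)
  intervals <- NULL
  for (pk in peaks) {
    lo <- brk[pk]; hi <- brk[pk + 1]
    inside <- x >= lo - bin_bp / 2 & x < hi + bin_bp / 2
    r <- rle(inside)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (i in which(r$values)) {
      intervals <- rbind(intervals,
                         c(start = t[starts[i]], end = t[ends[i]],
                           pos = mean(x[starts[i]:ends[i]])))
    }
  }
  intervals <- as.data.frame(intervals)
  intervals <- intervals[order(intervals$start), , drop = FALSE]
  ## merge candidates split by noise: tiny gap and tiny contour change
  merged <- intervals[1, , drop = FALSE]
  for (i in seq_len(nrow(intervals))[-1]) {
    last <- nrow(merged)
    gap <- intervals$start[i] - merged$end[last]
    dpos <- abs(intervals$pos[i] - merged$pos[last])
    if (gap < min_transloc_s && dpos < min_contour_bp) {
      merged$end[last] <- max(merged$end[last], intervals$end[i])
      merged$pos[last] <- (merged$pos[last] + intervals$pos[i]) / 2
    } else {
      merged <- rbind(merged, intervals[i, ])
    }
  }
  merged$dur <- merged$end - merged$start
  merged <- merged[merged$dur >= min_pause_s, , drop = FALSE]
  if (nrow(merged) > 1) {
    keep <- rep(TRUE, nrow(merged))
    last_kept <- 1
    for (i in seq_len(nrow(merged))[-1]) {
      gap <- merged$start[i] - merged$end[last_kept]
      dpos <- abs(merged$pos[i] - merged$pos[last_kept])
      if (gap < min_transloc_s || dpos < min_contour_bp) keep[i] <- FALSE
      else last_kept <- i
    }
    merged <- merged[keep, , drop = FALSE]
  }
  if (!nrow(merged)) return(empty)
  out <- data.frame(start_s = merged$start, end_s = merged$end,
                    duration_s = merged$dur, position_bp = merged$pos)
  class(out) <- c("pause_table", "data.frame")
  out
}

#' Segment velocities in a force window
#'
#' Smooths the contour with a `smooth_points` moving average, restricts to
#' samples whose force lies inside `force_window`, slices each contiguous
#' in-window stretch into segments of `segment_s` seconds, and returns the
#' slope of a linear fit per segment (bp/s).  Segments with fewer than 80%
#' of their expected samples are dropped.
#'
#' @param contour A [extension_to_contour()] result.
#' @param force_window Length-2 numeric, default `c(10, 15)` pN.
#' @param segment_s Segment duration (s), default 0.25.
#' @param smooth_points Moving-average length, default 100.
#' @return Numeric vector of segment velocities (possibly empty).
#' @export
segment_velocities <- function(contour, force_window = c(10, 15),
                               segment_s = 0.25, smooth_points = 100) {
  stopifnot(inherits(contour, "contour_trace"))
  fs <- attr(contour, "fs")
  sm <- as.numeric(stats::filter(contour$contour_bp,
                                 rep(1 / smooth_points, smooth_points),
                                 sides = 2))
  ok <- contour$force >= force_window[1] & contour$force <= force_window[2] &
    !is.na(sm)
  if (!any(ok)) return(numeric(0))
  per_seg <- max(2, round(segment_s * fs))
  runs <- rle(ok)
  ends <- cumsum(runs$lengths); starts <- ends - runs$lengths + 1
  vels <- numeric(0)
  for (i in which(runs$values)) {
    idx <- starts[i]:ends[i]
    n_seg <- length(idx) %/% per_seg
    for (s in seq_len(n_seg)) {
      seg <- idx[((s - 1) * per_seg + 1):(s * per_seg)]
      if (length(seg) < 0.8 * per_seg) next
      vels <- c(vels, unname(stats::coef(
        stats::lm(sm[seg] ~ contour$time[seg]))[2]))
    }
  }
  vels
}

#' Pause density with a confidence interval
#'
#' Density of pauses per translocated base pair, `tp / tc`, with a 95%
#' half-width in one of two forms: `"as_printed"` reproduces the published
#' formula `1.96 * sqrt(tp / tc)`; `"poisson_count"` is the standard Poisson
#' counting error on `tp`, `1.96 * sqrt(tp) / tc`, and is the recommended
#' default for new analyses (the printed formula is dimensionally
#' inconsistent with a count-based error; both are retained, and the
#' reproduction default is `"as_printed"`).
#'
#' @param tp Total pauses (count, >= 0).
#' @param tc Total translocated base pairs (> 0).
#' @param formula `"as_printed"` or `"poisson_count"`.
#' @return Object of class `"pause_summary"`: `tp`, `tc`, `density`,
#'   `ci_half_width`, `formula`.
#' @export
#' @examples
#' pause_density(25, 10000)                     # printed-formula half-width
#' pause_density(25, 10000, "poisson_count")    # counting-error half-width
pause_density <- function(tp, tc, formula = c("as_printed", "poisson_count")) {
  formula <- match.arg(formula)
  if (tc <= 0) stop_recbcd("invalid_argument", "tc must be > 0")
  if (tp < 0) stop_recbcd("invalid_argument", "tp must be >= 0")
  hw <- switch(formula,
               as_printed = 1.96 * sqrt(tp / tc),
               poisson_count = 1.96 * sqrt(tp) / tc)
  structure(list(tp = tp, tc = tc, density = tp / tc,
                 ci_half_width = hw, formula = formula),
            class = "pause_summary")
}

#' @export
print.pause_summary <- function(x, ...) {
  cat(sprintf("Pause density: %d pauses / %g bp = %.4g +/- %.3g per bp (95%%, %s)\n",
              x$tp, x$tc, x$density, x$ci_half_width, x$formula))
  invisible(x)
}

#' Read / write tweezers and contour traces, and pause tables, as CSV
#'
#' Trace columns: `time_s`, `extension_nm`, `force_pN`; contour columns:
#' `time_s`, `contour_bp`, `force_pN`; pause columns: `start_s`, `end_s`,
#' `position_bp`.
#'
#' @param x The object to write.
#' @param path CSV path.
#' @return The path (write) or the object (read).
#' @export
write_tweezers_csv <- function(x, path) {
  stopifnot(inherits(x, "tweezers_trace"))
  utils::write.csv(data.frame(time_s = x$time, extension_nm = x$extension,
                              force_pN = x$force), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tweezers_csv
#' @export
read_tweezers_csv <- function(path) {
  df <- utils::read.csv(path)
  tweezers_trace(df$time_s, df$extension_nm, df$force_pN)
}

#' @rdname write_tweezers_csv
#' @export
write_pauses_csv <- function(x, path) {
  utils::write.csv(data.frame(start_s = x$start_s, end_s = x$end_s,
                              position_bp = x$position_bp),
                   path, row.names = FALSE)
  invisible(path)
}
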