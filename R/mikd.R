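#' Sliding-window specification for the kurtosis detector
#'
#' Windows are `win_s` seconds long (`M = round(win_s * fs)` samples).
#' Extraction uses contiguous non-overlapping windows (`step = M`), which is
#' what makes a 60 s record at 4000 Hz decompose into exactly 1200 segments;
#' an overlapping analysis stride can be requested via `step` but plays no
#' part in extraction.
#'
#' @param fs Sampling rate in Hz.
#' @param win_s Window length in seconds (default 0.05).
#' @param step Hop in samples; defaults to the window length `M`.
#' @return An object of class `window_spec` with fields `M`, `step`, `win_s`,
#'   `fs`.
#' @export
window_spec <- function(fs, win_s = 0.05, step = NULL) {
  check_positive(fs, "fs")
  check_positive(win_s, "win_s")
  M <- round(win_s * fs)
  if (M < 4L) stop("window must contain at least 4 samples", call. = FALSE)
  if (is.null(step)) step <- M
  if (step < 1L || step > M) stop("step must be in [1, M]", call. = FALSE)
  structure(list(M = as.integer(M), step = as.integer(step), win_s = win_s,
                 fs = fs),
            class = "window_spec")
}

#' Segment a recording into analysis windows
#'
#' Returns the 1-based, half-open sample intervals `[start, end)` of the
#' windows. A trailing partial window is dropped; a record shorter than one
#' window is an error.
#'
#' @param x A [recording()] or numeric vector.
#' @param spec A [window_spec()].
#' @return A two-column integer matrix (`start`, `end`), one row per window.
#' @export
segment_windows <- function(x, spec) {
  stopifnot(inherits(spec, "window_spec"))
  n <- if (inherits(x, "recording")) length(x$samples) else length(x)
  if (n < spec$M) {
    stop(sprintf("record (%d samples) shorter than one window (%d samples)",
                 n, spec$M), call. = FALSE)
  }
  starts <- seq.int(1L, n - spec$M + 1L, by = spec$step)
  cbind(start = starts, end = starts + spec$M)
}

#' Windowed excess kurtosis series
#'
#' For each window computes
#' `K_j = sum((x - m)^4) / ((M - 1) * s^4) - 3`, with `m` and `s` the window
#' sample mean and sample standard deviation (denominator `M - 1`). Near-zero
#' for Gaussian background windows and positive for windows containing a
#' transient burst. Windows with zero variance are degenerate: their `K` is
#' defined as 0 and they are flagged so downstream steps can exclude them.
#'
#' @inheritParams segment_windows
#' @return A list of class `kurtosis_series`: `k` (numeric per window),
#'   `degenerate` (logical per window), `windows` (the interval matrix).
#' @export
kurtosis_series <- function(x, spec) {
  if (inherits(x, "recording")) x <- x$samples
  win <- segment_windows(x, spec)
  M <- spec$M
  if (spec$step == M) {
    # non-overlapping windows: one reshape, column-wise moments
    nw <- nrow(win)
    mat <- matrix(x[seq_len(nw * M)], nrow = M)
    m <- colMeans(mat)
    cen <- mat - rep(m, each = M)
    s2 <- colSums(cen^2) / (M - 1)
    s4 <- s2^2
    degen <- s4 <= .Machine$double.xmin
    k <- numeric(nw)
    ok <- !degen
    k[ok] <- colSums(cen[, ok, drop = FALSE]^4) / ((M - 1) * s4[ok]) - 3
  } else {
    k <- numeric(nrow(win))
    degen <- logical(nrow(win))
    for (j in seq_len(nrow(win))) {
      w <- x[win[j, 1L]:(win[j, 2L] - 1L)]
      cen <- w - mean(w)
      s2 <- sum(cen^2) / (M - 1)
      if (s2^2 <= .Machine$double.xmin) {
        degen[j] <- TRUE
      } else {
        k[j] <- sum(cen^4) / ((M - 1) * s2^2) - 3
      }
    }
  }
  structure(list(k = k, degenerate = degen, windows = win),
            class = "kurtosis_series")
}

#' Adaptive kurtosis threshold from the cumulative-count rule
#'
#' Histograms the kurtosis values into `n_bins` equal-width intervals over
#' their range, accumulates counts from the lowest interval upwards until the
#' running total exceeds `coverage` of all values, and sets the threshold to
#' `factor` times the upper edge of that crossing interval (`mode = "edge"`,
#' the default) or `factor` times the interval width (`mode = "width"`).
#' All-equal input is degenerate: the threshold is `factor` times that value.
#'
#' @param k Numeric vector of (finite) kurtosis values.
#' @param coverage Cumulative-count fraction, in (0, 1); default 0.9.
#' @param factor Threshold multiplier; default 2.
#' @param n_bins Number of histogram bins; default
#'   `ceiling(sqrt(length(k)))` clamped to \[10, 100\].
#' @param mode `"edge"` or `"width"` (see above).
#' @return A single numeric threshold.
#' @export
estimate_threshold <- function(k, coverage = 0.9, factor = 2, n_bins = NULL,
                               mode = c("edge", "width")) {
  mode <- match.arg(mode)
  k <- k[is.finite(k)]
  if (length(k) == 0L) stop("no finite kurtosis values", call. = FALSE)
  stopifnot(coverage > 0, coverage < 1, factor > 0)
  rng <- range(k)
  if (rng[1] == rng[2]) {
    return(factor * rng[1])
  }
  if (is.null(n_bins)) {
    n_bins <- min(100L, max(10L, ceiling(sqrt(length(k)))))
  }
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  bin <- findInterval(k, breaks, rightmost.closed = TRUE, all.inside = TRUE)
  counts <- tabulate(bin, nbins = n_bins)
  cum <- cumsum(counts)
  j <- which(cum > coverage * length(k))[1L]
  if (mode == "edge") factor * breaks[j + 1L] else factor * diff(breaks)[1L]
}

#' Run the iterative kurtosis-based bowel-sound detector
#'
#' Splits a recording into a burst (BS) channel and a background (BGS)
#' channel by iterating: compute the windowed excess kurtosis of the current
#' background, estimate the adaptive threshold from its distribution, and
#' move every window whose kurtosis meets the threshold verbatim from the
#' background to the burst channel (the window becomes zero in the
#' background). Iteration stops when the mean power of the newly extracted
#' samples drops below `stop_power_ratio` times the mean power of the
#' original record, when no window is flagged, or after `max_iter`
#' iterations. Because windows are moved and never transformed,
#' `bs + bgs` reconstructs the input exactly at every iteration.
#'
#' @param rec A [recording()] or numeric vector.
#' @param spec A [window_spec()]; defaults to 0.05 s non-overlapping windows.
#' @param coverage,threshold_factor,n_bins,threshold_mode Passed to
#'   [estimate_threshold()].
#' @param stop_power_ratio Stopping level relative to the original record's
#'   mean power (default 0.01).
#' @param max_iter Iteration cap (default 10).
#' @return An object of class `mikd_result`: `bs`, `bgs` (numeric, same
#'   length as input), `masks` (list of per-iteration logical window masks of
#'   newly flagged windows), `thresholds` (per iteration), `flagged` (final
#'   logical window mask), `windows`, `n_iter`, `fs`.
#' @export
run_mikd <- function(rec, spec = NULL,
                     coverage = 0.9, threshold_factor = 2, n_bins = NULL,
                     threshold_mode = c("edge", "width"),
                     stop_power_ratio = 0.01, max_iter = 10L) {
  threshold_mode <- match.arg(threshold_mode)
  if (inherits(rec, "recording")) {
    x <- rec$samples
    fs <- rec$fs
  } else {
    x <- as.numeric(rec)
    fs <- NA_real_
  }
  if (is.null(spec)) {
    if (is.na(fs)) stop("`spec` required for plain numeric input",
                        call. = FALSE)
    spec <- window_spec(fs)
  }
  stopifnot(max_iter >= 1L)
  win <- segment_windows(x, spec)
  nw <- nrow(win)
  bgs <- x
  bs <- numeric(length(x))
  flagged <- logical(nw)
  masks <- list()
  thresholds <- numeric(0)
  p0 <- mean(x^2)

  for (it in seq_len(max_iter)) {
    ks <- kurtosis_series(bgs, spec)
    valid <- !ks$degenerate & !flagged
    if (!any(valid)) {
      masks[[it]] <- logical(nw)
      thresholds[it] <- NA_real_
      break
    }
    thr <- estimate_threshold(ks$k[valid], coverage = coverage,
                              factor = threshold_factor, n_bins = n_bins,
                              mode = threshold_mode)
    thresholds[it] <- thr
    if (thr <= 0) {
      # bursts have positive excess kurtosis; a non-positive threshold means
      # the remaining background carries no burst evidence
      masks[[it]] <- logical(nw)
      break
    }
    newly <- valid & ks$k >= thr
    masks[[it]] <- newly
    if (!any(newly)) break
    idx <- unlist(lapply(which(newly),
                         function(j) win[j, 1L]:(win[j, 2L] - 1L)))
    bs[idx] <- bgs[idx]
    bgs[idx] <- 0
    flagged <- flagged | newly
    new_power <- mean(bs[idx]^2)
    bs_log("mIKD iteration %d: %d window(s) flagged, threshold %.4g",
           it, sum(newly), thr)
    if (new_power < stop_power_ratio * p0) break
  }

  structure(list(bs = bs, bgs = bgs, masks = masks, thresholds = thresholds,
                 flagged = flagged, windows = win,
                 n_iter = length(masks), fs = fs),
            class = "mikd_result")
}

#' @export
print.mikd_result <- function(x, ...) {
  cat(sprintf(
    "mIKD result: %d iteration(s), %d/%d window(s) flagged as bowel sound\n",
    x$n_iter, sum(x$flagged), nrow(x$windows)))
  invisible(x)
}

#' Flagged window intervals of a detection result
#'
#' @param det A `mikd_result`.
#' @param zero_based Return 0-based half-open intervals (the on-disk CSV
#'   convention) instead of 1-based.
#' @return A `data.frame` with `start_sample`, `end_sample`, `iteration`.
#' @export
flagged_intervals <- function(det, zero_based = TRUE) {
  stopifnot(inherits(det, "mikd_result"))
  rows <- do.call(rbind, lapply(seq_along(det$masks), function(it) {
    j <- which(det$masks[[it]])
    if (length(j) == 0L) return(NULL)
    data.frame(start_sample = det$windows[j, 1L],
               end_sample = det$windows[j, 2L],
               iteration = it)
  }))
  if (is.null(rows)) {
    rows <- data.frame(start_sample = integer(0), end_sample = integer(0),
                       iteration = integer(0))
  }
  if (zero_based) {
    rows$start_sample <- rows$start_sample - 1L
    rows$end_sample <- rows$end_sample - 1L
  }
  rows
}

#' Window-level detector performance against ground-truth events
#'
#' Labels each analysis window by its overlap with the ground-truth burst
#' intervals: windows whose samples are covered by events for at least
#' `min_overlap` of the window length are burst windows; windows with zero
#' overlap are background windows (partial-overlap windows below the cutoff
#' are ignored in both rates). Recall is the fraction of burst windows
#' flagged; the false-flag rate is the fraction of background windows
#' flagged.
#'
#' @param det A `mikd_result`.
#' @param events Two-column matrix of half-open 1-based event intervals
#'   (`labeled_recording$events`).
#' @param min_overlap Minimum covered fraction of a window to count it as a
#'   burst window (default 0.25).
#' @return List: `recall`, `false_flag_rate`, `n_burst_windows`,
#'   `n_background_windows`.
#' @export
detection_performance <- function(det, events, min_overlap = 0.25) {
  stopifnot(inherits(det, "mikd_result"))
  win <- det$windows
  M <- win[1L, 2L] - win[1L, 1L]
  overlap <- numeric(nrow(win))
  if (!is.null(events) && nrow(events) > 0L) {
    for (e in seq_len(nrow(events))) {
      ov <- pmin(win[, 2L], events[e, 2L]) - pmax(win[, 1L], events[e, 1L])
      overlap <- overlap + pmax(0, ov)
    }
  }
  frac <- overlap / M
  is_burst <- frac >= min_overlap
  is_bg <- frac == 0
  list(recall = if (any(is_burst)) mean(det$flagged[is_burst]) else NA_real_,
       false_flag_rate = if (any(is_bg)) mean(det$flagged[is_bg]) else NA_real_,
       n_burst_windows = sum(is_burst),
       n_background_windows = sum(is_bg))
}
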