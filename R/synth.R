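#' Parameters for the synthetic bowel-sound generator
#'
#' Bundles the knobs of the synthetic auscultation model. A record is the sum
#' of three components: (i) a regular physiological background — low-pass
#' filtered Gaussian noise confined below `bgs_band[2]` plus sinusoidal breath
#' and heartbeat components — whose excess kurtosis is near zero; (ii) sparse
#' short bowel-sound bursts, Hann-windowed linear chirps confined to
#' `bs_band`, arriving as a Poisson process whose rate and amplitude depend on
#' the class label; and (iii) additive white measurement noise. Bursts are
#' kept short (default 10--40 ms) relative to the 50 ms detector window:
#' single peristaltic events are brief clicks, and it is their transience
#' within a window that makes them kurtotic and hence detectable.
#'
#' The defaults reproduce the nominal recording protocol: 60 s mono records at
#' 4000 Hz (240,000 samples), background energy below 100 Hz, burst energy in
#' 200--1000 Hz. Class 1 ("defecation intention") records carry more frequent
#' and slightly stronger bursts than class 0.
#'
#' @param fs Sampling rate in Hz.
#' @param duration Record length in seconds.
#' @param bgs_band Background frequency band in Hz, `c(low, high)`.
#' @param bs_band Burst frequency band in Hz; must lie strictly above
#'   `bgs_band`.
#' @param breath_rate,heart_rate Breathing and heartbeat frequencies in Hz.
#' @param breath_amp,heart_amp Amplitudes of the sinusoidal breath/heart
#'   components (unitless, audio normalised to roughly \[-1, 1\]).
#' @param bg_sigma Standard deviation of the Gaussian noise that is low-pass
#'   filtered into the background.
#' @param burst_rate_by_class Mean number of bursts per record for class 0 and
#'   class 1 (`burst_rate_by_class[2] >= burst_rate_by_class[1]`).
#' @param burst_len_range Burst duration bounds in seconds.
#' @param burst_amp_by_class Burst amplitude scale for class 0 and class 1.
#' @param noise_sigma Standard deviation of the additive white noise.
#' @param seed Default integer seed used when generator functions are called
#'   without one.
#' @return An object of class `synth_params`.
#' @examples
#' p <- synth_params(duration = 2)
#' rec <- make_record(p, label = 1, seed = 1)
#' length(rec$samples)
#' @export
synth_params <- function(fs = 4000,
                         duration = 60,
                         bgs_band = c(0, 100),
                         bs_band = c(200, 1000),
                         breath_rate = 0.25,
                         heart_rate = 1.2,
                         breath_amp = 0.05,
                         heart_amp = 0.05,
                         bg_sigma = 0.1,
                         burst_rate_by_class = c(8, 16),
                         burst_len_range = c(0.01, 0.04),
                         burst_amp_by_class = c(0.4, 0.6),
                         noise_sigma = 0.01,
                         seed = NULL) {
  check_positive(fs, "fs")
  check_positive(duration, "duration")
  stopifnot(length(bgs_band) == 2L, length(bs_band) == 2L)
  if (bs_band[1] <= bgs_band[2]) {
    stop("`bs_band` must lie strictly above `bgs_band`", call. = FALSE)
  }
  if (bs_band[2] > fs / 2) {
    stop("`bs_band` upper edge exceeds the Nyquist frequency", call. = FALSE)
  }
  if (any(burst_rate_by_class < 0)) {
    stop("burst rates must be non-negative", call. = FALSE)
  }
  if (burst_rate_by_class[2] < burst_rate_by_class[1]) {
    stop("class-1 burst rate must be >= class-0 burst rate", call. = FALSE)
  }
  stopifnot(length(burst_len_range) == 2L,
            burst_len_range[1] > 0,
            burst_len_range[1] <= burst_len_range[2],
            burst_len_range[2] < duration)
  stopifnot(bg_sigma >= 0, noise_sigma >= 0,
            breath_amp >= 0, heart_amp >= 0,
            all(burst_amp_by_class >= 0))
  structure(
    list(fs = fs, duration = duration,
         bgs_band = bgs_band, bs_band = bs_band,
         breath_rate = breath_rate, heart_rate = heart_rate,
         breath_amp = breath_amp, heart_amp = heart_amp,
         bg_sigma = bg_sigma,
         burst_rate_by_class = burst_rate_by_class,
         burst_len_range = burst_len_range,
         burst_amp_by_class = burst_amp_by_class,
         noise_sigma = noise_sigma,
         seed = seed),
    class = "synth_params"
  )
}

#' @export
print.synth_params <- function(x, ...) {
  cat(sprintf(
    "Synthetic bowel-sound parameters: %.0f Hz, %.3g s (%d samples/record)\n",
    x$fs, x$duration, round(x$fs * x$duration)))
  cat(sprintf("  background: <= %g Hz, sigma %g; bursts: %g-%g Hz\n",
              x$bgs_band[2], x$bg_sigma, x$bs_band[1], x$bs_band[2]))
  cat(sprintf("  burst rate/record (class 0, 1): %g, %g; amplitude: %g, %g\n",
              x$burst_rate_by_class[1], x$burst_rate_by_class[2],
              x$burst_amp_by_class[1], x$burst_amp_by_class[2]))
  invisible(x)
}

#' Generate the regular physiological background
#'
#' Low-pass filtered Gaussian noise (4th-order Butterworth, zero-phase via
#' forward-backward filtering, cutoff at the upper edge of `bgs_band`) plus
#' sinusoidal breath and heartbeat components. The result emulates the
#' near-Gaussian, low-frequency background against which bowel-sound bursts
#' must be detected; its excess kurtosis is close to zero.
#'
#' @param params A [synth_params()] object.
#' @param seed Integer seed; falls back to `params$seed`.
#' @return A [recording()] with `round(fs * duration)` samples.
#' @export
make_background <- function(params, seed = params$seed) {
  stopifnot(inherits(params, "synth_params"))
  n <- round(params$fs * params$duration)
  x <- with_seed(seed, {
    base <- numeric(n)
    if (params$bg_sigma > 0) {
      w <- stats::rnorm(n, sd = params$bg_sigma)
      bf <- signal::butter(4, params$bgs_band[2] / (params$fs / 2),
                           type = "low")
      base <- as.numeric(signal::filtfilt(bf, w))
    }
    t <- (seq_len(n) - 1) / params$fs
    base +
      params$breath_amp * sin(2 * pi * params$breath_rate * t) +
      params$heart_amp * sin(2 * pi * params$heart_rate * t)
  })
  recording(x, params$fs)
}

# One Hann-windowed linear chirp of n_samp samples sweeping f0 -> f1 Hz.
hann_chirp <- function(n_samp, f0, f1, fs, amp) {
  tau <- (seq_len(n_samp) - 1) / fs
  len <- n_samp / fs
  phase <- 2 * pi * (f0 * tau + (f1 - f0) / (2 * len) * tau^2)
  win <- 0.5 * (1 - cos(2 * pi * (seq_len(n_samp) - 1) / (n_samp - 1)))
  amp * win * sin(phase)
}

# Merge sorted half-open intervals [start, end); returns a 2-column matrix.
merge_intervals <- function(ints) {
  if (nrow(ints) == 0L) return(ints)
  ints <- ints[order(ints[, 1L]), , drop = FALSE]
  out <- ints[1L, , drop = FALSE]
  for (i in seq_len(nrow(ints))[-1L]) {
    k <- nrow(out)
    if (ints[i, 1L] <= out[k, 2L]) {
      out[k, 2L] <- max(out[k, 2L], ints[i, 2L])
    } else {
      out <- rbind(out, ints[i, , drop = FALSE])
    }
  }
  out
}

#' Generate the sparse bowel-sound burst channel
#'
#' Draws a Poisson number of bursts (mean `burst_rate_by_class[label + 1]`),
#' places them uniformly in time, and renders each as a Hann-windowed linear
#' chirp sweeping a random sub-interval of `bs_band`. Burst amplitude is the
#' class amplitude scale jittered by +/-20%. Overlapping ground-truth
#' intervals are merged so the returned events are disjoint.
#'
#' @param params A [synth_params()] object.
#' @param label Class label, 0 (no defecation intention) or 1 (intention).
#' @param seed Integer seed; falls back to `params$seed`.
#' @return A list with `signal` (numeric vector, zero outside bursts) and
#'   `events` (two-column matrix of half-open 1-based sample intervals
#'   `[start, end)`, sorted and disjoint).
#' @export
make_bursts <- function(params, label, seed = params$seed) {
  stopifnot(inherits(params, "synth_params"), label %in% c(0, 1))
  n <- round(params$fs * params$duration)
  rate <- params$burst_rate_by_class[label + 1L]
  amp0 <- params$burst_amp_by_class[label + 1L]
  with_seed(seed, {
    sig <- numeric(n)
    k <- stats::rpois(1L, rate)
    empty <- matrix(numeric(0), ncol = 2L,
                    dimnames = list(NULL, c("start", "end")))
    if (k == 0L || amp0 == 0) {
      list(signal = sig, events = empty)
    } else {
      ev <- matrix(0, nrow = k, ncol = 2L,
                   dimnames = list(NULL, c("start", "end")))
      for (i in seq_len(k)) {
        len_s <- stats::runif(1L, params$burst_len_range[1],
                              params$burst_len_range[2])
        n_samp <- max(8L, round(len_s * params$fs))
        start <- 1L + floor(stats::runif(1L) * (n - n_samp))
        f <- sort(stats::runif(2L, params$bs_band[1], params$bs_band[2]))
        # keep a minimal sweep so the chirp stays broadband inside the band
        if (diff(f) < 50) f[2] <- min(f[1] + 50, params$bs_band[2])
        amp <- amp0 * stats::runif(1L, 0.8, 1.2)
        idx <- start:(start + n_samp - 1L)
        sig[idx] <- sig[idx] + hann_chirp(n_samp, f[1], f[2], params$fs, amp)
        ev[i, ] <- c(start, start + n_samp)
      }
      list(signal = sig, events = merge_intervals(ev))
    }
  })
}

#' Generate one labelled synthetic auscultation record
#'
#' Additively combines background, burst channel and white measurement noise:
#' the record is the sum of the bowel-sound component and the background
#' component, which is exactly the decomposition the detector tries to
#' recover. Sub-seeds for the three components are derived deterministically
#' from `seed`.
#'
#' @inheritParams make_bursts
#' @return An object of class `labeled_recording`: a [recording()] with extra
#'   fields `label`, `events` (ground-truth burst intervals) and `seed`.
#' @export
make_record <- function(params, label, seed = params$seed) {
  stopifnot(inherits(params, "synth_params"), label %in% c(0, 1))
  n <- round(params$fs * params$duration)
  bg <- make_background(params, seed = if (is.null(seed)) NULL else seed)
  bu <- make_bursts(params, label,
                    seed = if (is.null(seed)) NULL else seed + 1L)
  noise <- with_seed(if (is.null(seed)) NULL else seed + 2L, {
    if (params$noise_sigma > 0) stats::rnorm(n, sd = params$noise_sigma)
    else numeric(n)
  })
  rec <- recording(bg$samples + bu$signal + noise, params$fs)
  rec$label <- as.integer(label)
  rec$events <- bu$events
  rec$seed <- seed
  class(rec) <- c("labeled_recording", class(rec))
  rec
}

#' @export
print.labeled_recording <- function(x, ...) {
  cat(sprintf(
    "Labelled synthetic record: %d samples @ %g Hz, class %d, %d burst event(s)\n",
    length(x$samples), x$fs, x$label, nrow(x$events)))
  invisible(x)
}

#' Simulate a labelled dataset in memory
#'
#' Generates `n_records` records with `round(n_records * class_balance)` in
#' class 1 and the rest in class 0, each with a record-specific seed derived
#' from `seed`.
#'
#' @param params A [synth_params()] object.
#' @param n_records Number of records (>= 2).
#' @param class_balance Fraction of class-1 records, in (0, 1).
#' @param seed Master integer seed.
#' @return A list of `labeled_recording` objects.
#' @export
simulate_records <- function(params, n_records, class_balance = 0.5,
                             seed = 1L) {
  stopifnot(n_records >= 2, class_balance > 0, class_balance < 1)
  n1 <- round(n_records * class_balance)
  labels <- c(rep(1L, n1), rep(0L, n_records - n1))
  lapply(seq_len(n_records), function(i) {
    make_record(params, labels[i], seed = seed * 1000L + i * 3L)
  })
}

#' Write a synthetic dataset to disk
#'
#' Generates records with [simulate_records()], writes each as a 16-bit PCM
#' mono WAV (peak-normalised to 0.9 full scale; the applied scale factor is
#' recorded in the manifest), writes a JSON sidecar with the ground-truth
#' burst intervals, and returns the manifest, also written as
#' `manifest.csv` in `out_dir`.
#'
#' @inheritParams simulate_records
#' @param out_dir Output directory (created if needed).
#' @return The manifest `data.frame` with columns `path`, `label`, `seed`,
#'   `n_events`, `scale`, invisibly also written to disk.
#' @export
make_dataset <- function(params, n_records, class_balance = 0.5, seed = 1L,
                         out_dir) {
  stopifnot(is.character(out_dir), length(out_dir) == 1L)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) {
    stop(sprintf("cannot create output directory '%s'", out_dir),
         call. = FALSE)
  }
  recs <- simulate_records(params, n_records, class_balance, seed)
  rows <- lapply(seq_along(recs), function(i) {
    rec <- recs[[i]]
    path <- file.path(out_dir, sprintf("record_%04d.wav", i))
    peak <- max(abs(rec$samples))
    scale <- if (peak > 0) 0.9 / peak else 1
    write_wav(recording(rec$samples * scale, rec$fs), path)
    jsonlite::write_json(
      list(label = rec$label, seed = rec$seed, scale = scale,
           events = unname(apply(rec$events, 1, as.integer, simplify = FALSE))),
      sub("\\.wav$", ".json", path), auto_unbox = TRUE, digits = NA)
    data.frame(path = path, label = rec$label, seed = rec$seed,
               n_events = nrow(rec$events), scale = scale,
               stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  write_manifest(manifest, file.path(out_dir, "manifest.csv"))
  manifest
}
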