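#' Time-domain features TF1--TF8
#'
#' Summary statistics of the processed bowel-sound series: mean (TF1),
#' population variance with the 1/N normalisation (TF2), maximum and minimum
#' (TF3, TF4), square-root amplitude `((1/N) * sum(sqrt(|x|)))^2` (TF5),
#' absolute mean (TF6), and the raw third and fourth moments
#' `(1/N) * sum(x^3)` and `(1/N) * sum(x^4)` (TF7, TF8). TF7/TF8 are kept as
#' raw moments rather than standardised skewness/kurtosis, which makes them
#' scale-covariant (degree 3 and 4). `literal_tf5 = TRUE` switches TF5 to the
#' variant without the square root inside the sum, `((1/N) * sum(|x|))^2`.
#'
#' @param x Non-empty finite numeric vector.
#' @param literal_tf5 Use the no-inner-square-root TF5 variant.
#' @return Named numeric vector `tf1`..`tf8`.
#' @export
time_domain_features <- function(x, literal_tf5 = FALSE) {
  stopifnot(length(x) >= 1L, all(is.finite(x)))
  n <- length(x)
  m <- mean(x)
  tf5 <- if (literal_tf5) mean(abs(x))^2 else mean(sqrt(abs(x)))^2
  c(tf1 = m,
    tf2 = sum((x - m)^2) / n,
    tf3 = max(x),
    tf4 = min(x),
    tf5 = tf5,
    tf6 = mean(abs(x)),
    tf7 = mean(x^3),
    tf8 = mean(x^4))
}

#' Frequency-domain features TF9--TF11
#'
#' DC component (TF9, the signal mean), mean normalised DFT magnitude within
#' the bowel-sound band (TF10, default 200--1000 Hz, where burst energy
#' concentrates), and total spectral power `sum(|F(x)|^2) / N` (TF11), which
#' by Parseval's identity equals `sum(x^2)`.
#'
#' @param x Non-empty finite numeric vector.
#' @param fs Sampling rate in Hz.
#' @param band Frequency band for TF10, `c(low, high)` in Hz.
#' @return Named numeric vector `tf9`..`tf11`.
#' @export
frequency_domain_features <- function(x, fs, band = c(200, 1000)) {
  stopifnot(length(x) >= 1L, all(is.finite(x)))
  check_positive(fs, "fs")
  n <- length(x)
  X <- stats::fft(x)
  freq <- (seq_len(n) - 1) * fs / n
  idx <- freq >= band[1] & freq <= min(band[2], fs / 2)
  tf10 <- if (any(idx)) mean(Mod(X[idx])) / n else 0
  c(tf9 = mean(x),
    tf10 = tf10,
    tf11 = sum(Mod(X)^2) / n)
}

#' Multilevel Haar decomposition
#'
#' Recursive pairwise averaging and differencing with the 1/2 (not
#' orthonormal 1/sqrt(2)) normalisation: at each level the current
#' approximation is split into even-index (`a0, a2, ...`) and odd-index
#' (`a1, a3, ...`) samples, the next approximation is `(even + odd) / 2` and
#' the detail is `(even - odd) / 2`. Input is zero-padded to the next power
#' of two (the original length is recorded); `levels` may not exceed
#' `log2(padded length)`.
#'
#' @param x Numeric vector.
#' @param levels Number of decomposition levels (>= 1); default
#'   `min(6, log2(padded length))`.
#' @return An object of class `haar_decomp`: `approx` (the level-`levels`
#'   approximation), `details` (list; `details[[j]]` is the level-`j`
#'   detail), `levels`, `n_original`, `n_padded`.
#' @examples
#' d <- haar_forward(c(1, 3, 5, 7), levels = 2)
#' d$approx            # 4
#' d$details[[2]]      # -2
#' d$details[[1]]      # -1 -1
#' @export
haar_forward <- function(x, levels = NULL) {
  stopifnot(length(x) >= 1L, all(is.finite(x)))
  np <- next_pow2(max(2L, length(x)))
  max_levels <- as.integer(round(log2(np)))
  if (is.null(levels)) levels <- min(6L, max_levels)
  stopifnot(levels >= 1L)
  if (levels > max_levels) {
    stop(sprintf("levels (%d) exceeds log2 of padded length (%d)",
                 levels, max_levels), call. = FALSE)
  }
  a <- c(x, numeric(np - length(x)))
  details <- vector("list", levels)
  for (j in seq_len(levels)) {
    even <- a[seq.int(1L, length(a), by = 2L)]
    odd <- a[seq.int(2L, length(a), by = 2L)]
    details[[j]] <- (even - odd) / 2
    a <- (even + odd) / 2
  }
  structure(list(approx = a, details = details, levels = levels,
                 n_original = length(x), n_padded = np),
            class = "haar_decomp")
}

#' Invert a Haar decomposition
#'
#' Exact inverse of [haar_forward()] (even = approx + detail,
#' odd = approx - detail, interleave), truncated back to the original length.
#'
#' @param dec A `haar_decomp`.
#' @return Numeric vector of length `dec$n_original`.
#' @export
haar_inverse <- function(dec) {
  stopifnot(inherits(dec, "haar_decomp"))
  a <- dec$approx
  for (j in rev(seq_len(dec$levels))) {
    d <- dec$details[[j]]
    if (length(d) != length(a)) {
      stop("inconsistent coefficient lengths in decomposition", call. = FALSE)
    }
    out <- numeric(2L * length(a))
    out[seq.int(1L, length(out), by = 2L)] <- a + d
    out[seq.int(2L, length(out), by = 2L)] <- a - d
    a <- out
  }
  a[seq_len(dec$n_original)]
}

#' Per-subband wavelet energies
#'
#' Reduces the variable-length Haar coefficient set to a fixed-length
#' summary: the mean square (energy) of the final approximation and of each
#' detail subband, ordered coarse to fine
#' `[E(A_L), E(D_L), ..., E(D_1)]`.
#'
#' @param dec A `haar_decomp`.
#' @return Named numeric vector of length `levels + 1`.
#' @export
wavelet_features <- function(dec) {
  stopifnot(inherits(dec, "haar_decomp"))
  L <- dec$levels
  e <- c(mean(dec$approx^2),
         vapply(rev(seq_len(L)), function(j) mean(dec$details[[j]]^2),
                numeric(1)))
  names(e) <- c(sprintf("wA%d", L), sprintf("wD%d", rev(seq_len(L))))
  e
}

#' Assemble the fixed-length feature vector of a record
#'
#' Concatenates TF1--TF8 (time domain), TF9--TF11 (frequency domain) and the
#' `levels + 1` Haar subband energies, for a total dimension of
#' `11 + levels + 1` (18 with the default 6 levels).
#'
#' @param x A [recording()] or numeric vector (typically the denoised BS
#'   channel).
#' @param fs Sampling rate in Hz (taken from the recording when omitted).
#' @param levels Haar decomposition depth; default 6.
#' @param band TF10 band in Hz.
#' @param literal_tf5 Passed to [time_domain_features()].
#' @return Named numeric vector.
#' @export
build_feature_vector <- function(x, fs = NULL, levels = 6L,
                                 band = c(200, 1000), literal_tf5 = FALSE) {
  if (inherits(x, "recording")) {
    if (is.null(fs)) fs <- x$fs
    x <- x$samples
  }
  if (is.null(fs)) stop("`fs` required for plain numeric input", call. = FALSE)
  c(time_domain_features(x, literal_tf5 = literal_tf5),
    frequency_domain_features(x, fs, band = band),
    wavelet_features(haar_forward(x, levels = levels)))
}
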