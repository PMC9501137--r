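# Independent brute-force oracles and small fixtures used across tests.
# These deliberately re-derive results straight from the defining formulas,
# independent of the package implementation they check.

# Excess kurtosis of one window, straight from the defining sum.
kurtosis_oracle <- function(w) {
  M <- length(w)
  m <- sum(w) / M
  s <- sqrt(sum((w - m)^2) / (M - 1))
  sum((w - m)^4) / ((M - 1) * s^4) - 3
}

# Cumulative-count threshold rule, re-derived with hist().
threshold_oracle <- function(k, coverage = 0.9, factor = 2, n_bins = 10) {
  h <- hist(k, breaks = seq(min(k), max(k), length.out = n_bins + 1),
            plot = FALSE)
  j <- which(cumsum(h$counts) > coverage * length(k))[1]
  list(threshold = factor * h$breaks[j + 1], crossing_bin = j)
}

# Recursive pairwise averaging/differencing Haar transform (1/2 scaling).
haar_oracle <- function(x, levels) {
  np <- 2^ceiling(log2(max(2, length(x))))
  a <- c(x, numeric(np - length(x)))
  details <- vector("list", levels)
  for (j in seq_len(levels)) {
    even <- a[seq(1, length(a), by = 2)]
    odd <- a[seq(2, length(a), by = 2)]
    details[[j]] <- (even - odd) / 2
    a <- (even + odd) / 2
  }
  list(approx = a, details = details)
}

# Textbook linear-Gaussian Kalman filter in plain matrix algebra.
kalman_oracle <- function(z, A, H, Q, R, s0, P0) {
  s <- matrix(s0, ncol = 1)
  P <- P0
  n <- length(z)
  p_out <- numeric(n)
  I <- diag(nrow(A))
  for (t in seq_len(n)) {
    s <- A %*% s
    P <- A %*% P %*% t(A) + Q
    S <- as.numeric(H %*% P %*% t(H)) + R
    K <- P %*% t(H) / S
    s <- s + K %*% (z[t] - as.numeric(H %*% s))
    P <- (I - K %*% H) %*% P
    p_out[t] <- s[1, 1]
  }
  p_out
}

# Norm-based relative gradient error against central finite differences.
gradient_check <- function(params, X, y, eps = 1e-5) {
  ana <- bowelsound:::bp_gradient(params, X, y)
  fd_block <- function(get, set) {
    vals <- get(params)
    num <- vals * 0
    for (i in seq_along(vals)) {
      pp <- set(params, replace(vals, i, vals[i] + eps))
      pm <- set(params, replace(vals, i, vals[i] - eps))
      num[i] <- (bp_loss(bp_forward(pp, X)$output, y) -
                 bp_loss(bp_forward(pm, X)$output, y)) / (2 * eps)
    }
    num
  }
  num <- c(
    fd_block(function(p) p$W1, function(p, v) {p$W1[] <- v; p}),
    fd_block(function(p) p$theta1, function(p, v) {p$theta1 <- v; p}),
    fd_block(function(p) p$w2, function(p, v) {p$w2 <- v; p}),
    fd_block(function(p) p$theta2, function(p, v) {p$theta2 <- v; p}))
  analytic <- c(ana$dW1, ana$dtheta1, ana$dw2, ana$dtheta2)
  sqrt(sum((num - analytic)^2)) /
    (sqrt(sum(num^2)) + sqrt(sum(analytic^2)))
}

# Short-record generator parameters for fast tests.
tiny_params <- function(duration = 5, ...) {
  synth_params(duration = duration, ...)
}

# Parameters with no class effect (identical burst statistics per class).
null_params <- function(...) {
  synth_params(burst_rate_by_class = c(8, 8),
               burst_amp_by_class = c(0.4, 0.4), ...)
}

# High-SNR parameters for detector-power tests: burst amplitude 1 against
# background sd 0.1 gives within-burst SNR well above 10.
high_snr_params <- function(duration = 10) {
  synth_params(duration = duration,
               burst_rate_by_class = c(8, 8),
               burst_amp_by_class = c(1, 1))
}

# Fast classifier settings for protocol tests on tiny feature tables.
fast_train_config <- function() {
  cfg <- default_config()
  cfg$hidden <- 20L
  cfg$max_iter <- 2000L
  cfg$n_rounds <- 3L
  cfg
}
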