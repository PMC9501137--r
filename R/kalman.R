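#' Build the constant-acceleration Kalman model
#'
#' The burst channel is modelled as a smooth trend plus noise: the state
#' `s(t) = (p, v, a)` holds the signal value and its first two derivatives,
#' propagated by the second-order Taylor transition
#' `A = [[1, h, h^2/2], [0, 1, h], [0, 0, 1]]` and observed through
#' `H = [1, 0, 0]`. The environmental input term is omitted. The process
#' noise is `q_scale` times the discrete white-noise-acceleration structure
#' `[[h^4/4, h^3/2, h^2/2], [h^3/2, h^2, h], [h^2/2, h, 1]]`; the
#' measurement-noise variance is `r`.
#'
#' @param h Time step in seconds (`1/fs` for audio).
#' @param q_scale Process-noise scale (>= 0); default `1e-4`.
#' @param r Measurement-noise variance (> 0); default `1e-2`.
#' @return An object of class `kalman_model` with fields `A`, `H`, `Q`, `R`,
#'   `h`.
#' @examples
#' m <- build_model(h = 1)
#' m$A
#' @export
build_model <- function(h, q_scale = 1e-4, r = 1e-2) {
  check_positive(h, "h")
  check_positive(r, "r")
  stopifnot(q_scale >= 0)
  A <- matrix(c(1, h, h^2 / 2,
                0, 1, h,
                0, 0, 1), nrow = 3, byrow = TRUE)
  H <- matrix(c(1, 0, 0), nrow = 1)
  G <- c(h^2 / 2, h, 1)
  Q <- q_scale * (G %o% G)
  structure(list(A = A, H = H, Q = Q, R = r, h = h, q_scale = q_scale),
            class = "kalman_model")
}

#' @export
print.kalman_model <- function(x, ...) {
  cat(sprintf("Constant-acceleration Kalman model: h = %g, q_scale = %g, R = %g\n",
              x$h, x$q_scale, x$R))
  invisible(x)
}

#' Kalman-denoise a time series
#'
#' Standard predict/update recursion returning the position component of the
#' state as the denoised signal. With `lag_n > 0` the update at step `t` uses
#' a measurement drawn uniformly at random (seeded) from steps
#' `max(1, t - lag_n) ... t`, a smoothing trick that trades responsiveness
#' for noise rejection; the default `lag_n = 0` is the plain filter.
#'
#' @param series Numeric vector of finite measurements.
#' @param model A [build_model()] object.
#' @param init_state Initial state `(p, v, a)`; default
#'   `c(series[1], 0, 0)`.
#' @param init_cov Initial 3x3 error covariance; default `diag(3)`.
#' @param lag_n Random-lag depth (>= 0); default 0.
#' @param seed Seed for the lag resampling (ignored when `lag_n = 0`).
#' @param keep_trajectory Also return per-step states and covariances.
#' @return A list: `p` (denoised series) and, when requested, `states`
#'   (n x 3) and `covariances` (n x 9, row-major flattened 3x3).
#' @export
kalman_denoise <- function(series, model, init_state = NULL,
                           init_cov = diag(3), lag_n = 0L, seed = NULL,
                           keep_trajectory = FALSE) {
  stopifnot(inherits(model, "kalman_model"), length(series) >= 1L)
  if (!all(is.finite(series))) {
    stop("series must be finite", call. = FALSE)
  }
  stopifnot(lag_n >= 0)
  if (is.null(init_state)) init_state <- c(series[1], 0, 0)
  z <- series
  if (lag_n > 0L) {
    idx <- with_seed(seed, {
      t <- seq_along(series)
      lo <- pmax(1L, t - as.integer(lag_n))
      lo + floor(stats::runif(length(t)) * (t - lo + 1))
    })
    z <- series[idx]
  }
  out <- kalman_filter_cpp(z, model$h, model$Q, model$R,
                           as.numeric(init_state), init_cov,
                           keep_trajectory)
  out$p <- as.numeric(out$p)
  out
}

#' Denoise the burst channel of a detection result
#'
#' Applies [kalman_denoise()] to the extracted bowel-sound (BS) channel of a
#' detector result; the background channel is untouched. The time step is
#' `1/fs` unless a prebuilt model is supplied.
#'
#' @param det A `mikd_result` from [run_mikd()].
#' @param model Optional [build_model()]; built from `q_scale`/`r` otherwise.
#' @param q_scale,r Model parameters used when `model` is `NULL`.
#' @param lag_n,seed Passed to [kalman_denoise()].
#' @return A [recording()] holding the denoised BS channel.
#' @export
denoise_record <- function(det, model = NULL, q_scale = 1e-4, r = 1e-2,
                           lag_n = 0L, seed = NULL) {
  stopifnot(inherits(det, "mikd_result"))
  fs <- det$fs
  if (is.null(model)) {
    if (is.na(fs)) stop("detection result carries no sampling rate; pass `model`",
                        call. = FALSE)
    model <- build_model(h = 1 / fs, q_scale = q_scale, r = r)
  }
  den <- kalman_denoise(det$bs, model, lag_n = lag_n, seed = seed)
  recording(den$p, if (is.na(fs)) 1 / model$h else fs)
}
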