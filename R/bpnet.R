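sigmoid <- function(z) 1 / (1 + exp(-z))

#' Initialise network parameters
#'
#' One hidden layer of logistic units and a single logistic output.
#' Weights are drawn from `Uniform(-1/sqrt(fan_in), +1/sqrt(fan_in))`;
#' unit thresholds start at zero.
#'
#' @param input_dim Number of input features (>= 1).
#' @param hidden_dim Number of hidden units (default 200).
#' @param seed Integer seed for reproducible initialisation.
#' @return An object of class `bp_params`: `W1` (hidden x input), `theta1`
#'   (hidden thresholds), `w2` (output weights), `theta2` (output
#'   threshold).
#' @export
bp_init <- function(input_dim, hidden_dim = 200L, seed = NULL) {
  stopifnot(input_dim >= 1L, hidden_dim >= 1L)
  with_seed(seed, {
    lim1 <- 1 / sqrt(input_dim)
    lim2 <- 1 / sqrt(hidden_dim)
    structure(
      list(W1 = matrix(stats::runif(hidden_dim * input_dim, -lim1, lim1),
                       nrow = hidden_dim),
           theta1 = numeric(hidden_dim),
           w2 = stats::runif(hidden_dim, -lim2, lim2),
           theta2 = 0,
           input_dim = as.integer(input_dim),
           hidden_dim = as.integer(hidden_dim)),
      class = "bp_params")
  })
}

#' Forward pass
#'
#' Each hidden unit computes the logistic function of its weighted input
#' minus its threshold, `y = f(W1 x - theta1)`; the output unit does the
#' same on the hidden activations, giving a value strictly in (0, 1).
#'
#' @param params A `bp_params` object.
#' @param X Feature matrix (n x input_dim) or a single feature vector.
#' @return List with `output` (length n), `hidden` (n x hidden_dim).
#' @export
bp_forward <- function(params, X) {
  stopifnot(inherits(params, "bp_params"))
  if (is.null(dim(X))) X <- matrix(X, nrow = 1L)
  if (ncol(X) != params$input_dim) {
    stop(sprintf("feature dimension %d does not match network input %d",
                 ncol(X), params$input_dim), call. = FALSE)
  }
  H <- sigmoid(X %*% t(params$W1) -
                 matrix(params$theta1, nrow(X), params$hidden_dim,
                        byrow = TRUE))
  out <- sigmoid(as.numeric(H %*% params$w2) - params$theta2)
  list(output = out, hidden = H)
}

#' Squared-error loss
#'
#' `E = (1/2) * sum((output - target)^2)`.
#'
#' @param outputs,targets Equal-length numeric vectors.
#' @return Non-negative scalar.
#' @export
bp_loss <- function(outputs, targets) {
  if (length(outputs) != length(targets)) {
    stop("outputs and targets differ in length", call. = FALSE)
  }
  0.5 * sum((outputs - targets)^2)
}

# Analytic gradients of bp_loss summed over the batch.
# Returns list(dW1, dtheta1, dw2, dtheta2).
bp_gradient <- function(params, X, y) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1L)
  fw <- bp_forward(params, X)
  out <- fw$output
  H <- fw$hidden
  delta2 <- (out - y) * out * (1 - out)            # n
  dw2 <- as.numeric(crossprod(H, delta2))          # hidden
  dtheta2 <- -sum(delta2)
  delta1 <- (delta2 %o% params$w2) * H * (1 - H)   # n x hidden
  dW1 <- crossprod(delta1, X)                      # hidden x input
  dtheta1 <- -colSums(delta1)
  list(dW1 = dW1, dtheta1 = dtheta1, dw2 = dw2, dtheta2 = dtheta2)
}

#' Train the network by backpropagation with momentum
#'
#' Mini-batch gradient descent on the squared-error loss: each weight update
#' is `v <- momentum * v - lr * gradient; w <- w + v` (classical momentum).
#' Samples are reshuffled every epoch (seeded). After each epoch the loss
#' over the full training set is recorded; training stops when it changes by
#' less than `convergence_tol` between consecutive epochs, or after
#' `max_iter` weight updates.
#'
#' @param params A `bp_params` starting point (see [bp_init()]).
#' @param X Feature matrix (n x input_dim), already standardised.
#' @param y Binary targets (0/1), length n.
#' @param learning_rate Step size (default 0.01).
#' @param momentum Momentum coefficient in \[0, 1) (default 0.9).
#' @param batch_size Mini-batch size (default 10).
#' @param max_iter Maximum number of weight updates (default 50,000).
#' @param convergence_tol Absolute epoch-loss difference below which training
#'   is declared converged (default 0.01; 0 disables).
#' @param seed Seed for the per-epoch shuffling.
#' @return List: `params` (trained), `trace` (per-epoch losses),
#'   `converged`, `iterations` (weight updates used).
#' @export
bp_train <- function(params, X, y, learning_rate = 0.01, momentum = 0.9,
                     batch_size = 10L, max_iter = 50000L,
                     convergence_tol = 0.01, seed = NULL) {
  stopifnot(inherits(params, "bp_params"))
  if (is.null(dim(X))) X <- matrix(X, nrow = 1L)
  n <- nrow(X)
  stopifnot(length(y) == n, all(y %in% c(0, 1)))
  stopifnot(learning_rate >= 0, momentum >= 0, momentum < 1,
            batch_size >= 1L, max_iter >= 1L, convergence_tol >= 0)
  if (!all(0:1 %in% y)) {
    stop("training data must contain both classes", call. = FALSE)
  }
  v <- list(dW1 = params$W1 * 0, dtheta1 = params$theta1 * 0,
            dw2 = params$w2 * 0, dtheta2 = 0)
  trace <- numeric(0)
  iter <- 0L
  converged <- FALSE
  prev_loss <- NA_real_

  with_seed(seed, {
    repeat {
      ord <- sample.int(n)
      for (b_start in seq.int(1L, n, by = batch_size)) {
        if (iter >= max_iter) break
        idx <- ord[b_start:min(b_start + batch_size - 1L, n)]
        g <- bp_gradient(params, X[idx, , drop = FALSE], y[idx])
        v$dW1 <- momentum * v$dW1 - learning_rate * g$dW1
        v$dtheta1 <- momentum * v$dtheta1 - learning_rate * g$dtheta1
        v$dw2 <- momentum * v$dw2 - learning_rate * g$dw2
        v$dtheta2 <- momentum * v$dtheta2 - learning_rate * g$dtheta2
        params$W1 <- params$W1 + v$dW1
        params$theta1 <- params$theta1 + v$dtheta1
        params$w2 <- params$w2 + v$dw2
        params$theta2 <- params$theta2 + v$dtheta2
        iter <- iter + 1L
      }
      ep_loss <- bp_loss(bp_forward(params, X)$output, y)
      if (!is.finite(ep_loss)) {
        stop(sprintf(
          "training diverged (non-finite loss); reduce learning_rate (%g)",
          learning_rate), call. = FALSE)
      }
      trace <- c(trace, ep_loss)
      if (convergence_tol > 0 && !is.na(prev_loss) &&
          abs(ep_loss - prev_loss) < convergence_tol) {
        converged <- TRUE
        break
      }
      prev_loss <- ep_loss
      if (iter >= max_iter) break
    }
  })
  list(params = params, trace = trace, converged = converged,
       iterations = iter)
}

#' Predict binary labels
#'
#' @param params A trained `bp_params`.
#' @param X Feature matrix or vector.
#' @param threshold Decision threshold on the output unit (default 0.5);
#'   label 1 iff output >= threshold.
#' @return Integer vector of 0/1 labels.
#' @export
bp_predict <- function(params, X, threshold = 0.5) {
  as.integer(bp_forward(params, X)$output >= threshold)
}

#' Fit a classifier on a feature table
#'
#' Convenience wrapper: z-scores the features using training-set statistics
#' (constant features get unit scale), initialises and trains the network,
#' and returns a model object that carries the scaler so prediction applies
#' the same transformation.
#'
#' @param X Raw (unstandardised) feature matrix.
#' @param y Binary labels.
#' @param hidden_dim Hidden-layer width (default 200).
#' @param learning_rate,momentum,batch_size,max_iter,convergence_tol Passed
#'   to [bp_train()].
#' @param seed Seed covering initialisation and shuffling.
#' @return An object of class `bp_model`.
#' @export
bp_fit <- function(X, y, hidden_dim = 200L, learning_rate = 0.01,
                   momentum = 0.9, batch_size = 10L, max_iter = 50000L,
                   convergence_tol = 0.01, seed = NULL) {
  X <- as.matrix(X)
  center <- colMeans(X)
  scale <- apply(X, 2L, stats::sd)
  scale[!is.finite(scale) | scale == 0] <- 1
  Xs <- sweep(sweep(X, 2L, center), 2L, scale, "/")
  params <- bp_init(ncol(X), hidden_dim,
                    seed = if (is.null(seed)) NULL else seed)
  fit <- bp_train(params, Xs, y, learning_rate = learning_rate,
                  momentum = momentum, batch_size = batch_size,
                  max_iter = max_iter, convergence_tol = convergence_tol,
                  seed = if (is.null(seed)) NULL else seed + 1L)
  structure(list(params = fit$params, center = center, scale = scale,
                 trace = fit$trace, converged = fit$converged,
                 iterations = fit$iterations),
            class = "bp_model")
}

#' @export
print.bp_model <- function(x, ...) {
  cat(sprintf(
    "BP classifier: %d -> %d -> 1, %d update(s), %sconverged (final loss %.4g)\n",
    x$params$input_dim, x$params$hidden_dim, x$iterations,
    if (x$converged) "" else "not ", utils::tail(x$trace, 1L)))
  invisible(x)
}

#' @param object A `bp_model`.
#' @param newdata Raw feature matrix.
#' @param threshold Decision threshold (default 0.5).
#' @param ... Unused.
#' @rdname bp_fit
#' @export
predict.bp_model <- function(object, newdata, threshold = 0.5, ...) {
  X <- as.matrix(newdata)
  Xs <- sweep(sweep(X, 2L, object$center), 2L, object$scale, "/")
  bp_predict(object$params, Xs, threshold = threshold)
}
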