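#' Confusion matrix of binary predictions
#'
#' Conventional cell definitions: TP = (true 1, predicted 1), FP = (true 0,
#' predicted 1), FN = (true 1, predicted 0), TN = (true 0, predicted 0).
#'
#' @param y_true,y_pred Equal-length 0/1 vectors.
#' @return An object of class `bs_confusion` with fields `tp`, `fp`, `fn`,
#'   `tn`.
#' @export
confusion_matrix <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) {
    stop("y_true and y_pred differ in length", call. = FALSE)
  }
  if (!all(y_true %in% c(0, 1)) || !all(y_pred %in% c(0, 1))) {
    stop("labels must be 0 or 1", call. = FALSE)
  }
  structure(list(tp = sum(y_true == 1 & y_pred == 1),
                 fp = sum(y_true == 0 & y_pred == 1),
                 fn = sum(y_true == 1 & y_pred == 0),
                 tn = sum(y_true == 0 & y_pred == 0)),
            class = "bs_confusion")
}

#' @export
print.bs_confusion <- function(x, ...) {
  cat(sprintf("Confusion: TP=%d FP=%d FN=%d TN=%d (n=%d)\n",
              x$tp, x$fp, x$fn, x$tn, x$tp + x$fp + x$fn + x$tn))
  invisible(x)
}

#' Accuracy, sensitivity and specificity
#'
#' `accuracy = (TP+TN)/(TP+TN+FP+FN)`, `sensitivity = TP/(TP+FN)`,
#' `specificity = TN/(TN+FP)`. `convention = "literal"` instead computes
#' specificity as `TN/(TP+FP)`, a printed variant retained for comparison;
#' the conventional definitions are the default because they are the ones
#' mutually consistent with an integer confusion matrix. A zero denominator
#' yields `NaN` with a warning.
#'
#' @param cm A [confusion_matrix()] result.
#' @param convention `"standard"` (default) or `"literal"`.
#' @return Named numeric vector `accuracy`, `sensitivity`, `specificity`.
#' @export
compute_metrics <- function(cm, convention = c("standard", "literal")) {
  convention <- match.arg(convention)
  stopifnot(inherits(cm, "bs_confusion"))
  n <- cm$tp + cm$tn + cm$fp + cm$fn
  if (n == 0L) stop("empty confusion matrix", call. = FALSE)
  sens_den <- cm$tp + cm$fn
  spec_den <- if (convention == "standard") cm$tn + cm$fp else cm$tp + cm$fp
  if (sens_den == 0L || spec_den == 0L) {
    warning("degenerate confusion matrix: some metrics are undefined (NaN)",
            call. = FALSE)
  }
  c(accuracy = (cm$tp + cm$tn) / n,
    sensitivity = if (sens_den == 0L) NaN else cm$tp / sens_den,
    specificity = if (spec_den == 0L) NaN else
      (if (convention == "standard") cm$tn else cm$tn) / spec_den)
}

#' Stratified random train/test split
#'
#' Splits indices so that the training set holds `round(train_frac * n)`
#' records overall while each class contributes its proportional share
#' (within one record). Deterministic given `seed`; train and test are
#' disjoint and exhaust the input.
#'
#' @param labels 0/1 label vector (or a manifest `data.frame` with a `label`
#'   column).
#' @param train_frac Training fraction, default 0.7.
#' @param seed Integer seed.
#' @return List with integer index vectors `train` and `test`.
#' @export
split_train_test <- function(labels, train_frac = 0.7, seed = NULL) {
  if (is.data.frame(labels)) labels <- labels$label
  stopifnot(train_frac > 0, train_frac < 1, all(labels %in% c(0, 1)))
  if (!all(0:1 %in% labels)) {
    stop("both classes must be present to split", call. = FALSE)
  }
  n <- length(labels)
  target <- round(train_frac * n)
  classes <- sort(unique(labels), decreasing = TRUE)  # class 1 first on ties
  base <- vapply(classes, function(cl) floor(train_frac * sum(labels == cl)),
                 numeric(1))
  rem <- vapply(classes, function(cl) train_frac * sum(labels == cl),
                numeric(1)) - base
  extra <- target - sum(base)
  if (extra > 0) {
    give <- order(rem, decreasing = TRUE)[seq_len(extra)]
    base[give] <- base[give] + 1
  }
  with_seed(seed, {
    train <- integer(0)
    for (i in seq_along(classes)) {
      idx <- which(labels == classes[i])
      train <- c(train, sample(idx, base[i]))
    }
    list(train = sort(train), test = setdiff(seq_len(n), train))
  })
}

#' Repeated-round evaluation protocol
#'
#' For each round: a fresh stratified 7:3 split with a round-derived seed,
#' training of the BP classifier on the training features, and accuracy on
#' the held-out records. Reports per-round accuracies, their mean/min/max,
#' and the confusion matrix pooled over all rounds' test predictions.
#'
#' @param features Raw feature matrix (one row per record).
#' @param labels 0/1 record labels.
#' @param n_rounds Number of rounds (default 20).
#' @param config Pipeline configuration ([default_config()]).
#' @param seed Master seed; round `r` uses `seed + 100 * r` for the split and
#'   training.
#' @return An object of class `bs_round_report`: `accuracy` (per round),
#'   `mean_accuracy`, `min_accuracy`, `max_accuracy`, `seeds`, `confusion`
#'   (pooled), `metrics` (on the pooled confusion).
#' @export
run_rounds <- function(features, labels, n_rounds = 20L,
                       config = default_config(), seed = 1L) {
  features <- as.matrix(features)
  stopifnot(nrow(features) == length(labels), n_rounds >= 1L)
  acc <- numeric(n_rounds)
  seeds <- seed + 100L * seq_len(n_rounds)
  y_true_all <- integer(0)
  y_pred_all <- integer(0)
  for (r in seq_len(n_rounds)) {
    sp <- split_train_test(labels, train_frac = config$train_frac,
                           seed = seeds[r])
    model <- bp_fit(features[sp$train, , drop = FALSE], labels[sp$train],
                    hidden_dim = config$hidden,
                    learning_rate = config$learning_rate,
                    momentum = config$momentum,
                    batch_size = config$batch,
                    max_iter = config$max_iter,
                    convergence_tol = config$convergence_tol,
                    seed = seeds[r] + 1L)
    pred <- predict(model, features[sp$test, , drop = FALSE])
    acc[r] <- mean(pred == labels[sp$test])
    y_true_all <- c(y_true_all, labels[sp$test])
    y_pred_all <- c(y_pred_all, pred)
    bs_log("round %d/%d: accuracy %.4f", r, n_rounds, acc[r])
  }
  cm <- confusion_matrix(y_true_all, y_pred_all)
  structure(list(accuracy = acc,
                 mean_accuracy = mean(acc),
                 min_accuracy = min(acc),
                 max_accuracy = max(acc),
                 seeds = seeds,
                 confusion = cm,
                 metrics = compute_metrics(cm)),
            class = "bs_round_report")
}

#' @export
print.bs_round_report <- function(x, ...) {
  cat(sprintf(
    "Evaluation over %d round(s): mean accuracy %.4f (min %.4f, max %.4f)\n",
    length(x$accuracy), x$mean_accuracy, x$min_accuracy, x$max_accuracy))
  cat(sprintf("  pooled: accuracy %.4f, sensitivity %.4f, specificity %.4f\n",
              x$metrics["accuracy"], x$metrics["sensitivity"],
              x$metrics["specificity"]))
  invisible(x)
}
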