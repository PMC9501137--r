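test_that("confusion matrices use the conventional cell definitions", {
  cm <- confusion_matrix(c(1, 1, 0, 0), c(1, 1, 0, 0))
  expect_identical(unlist(cm[c("tp", "fp", "fn", "tn")]),
                   c(tp = 2L, fp = 0L, fn = 0L, tn = 2L))
  cm <- confusion_matrix(c(1, 0), c(1, 1))
  expect_identical(unlist(cm[c("tp", "fp", "fn", "tn")]),
                   c(tp = 1L, fp = 1L, fn = 0L, tn = 0L))
  expect_error(confusion_matrix(c(1, 2), c(0, 1)), "0 or 1")
  expect_error(confusion_matrix(1, c(0, 1)), "length")

  # counts always partition the records
  set.seed(3)
  for (i in 1:10) {
    n <- sample(5:50, 1)
    yt <- sample(0:1, n, replace = TRUE)
    yp <- sample(0:1, n, replace = TRUE)
    cm <- confusion_matrix(yt, yp)
    expect_identical(cm$tp + cm$fp + cm$fn + cm$tn, n)
    expect_identical(cm$tp, sum(yt == 1 & yp == 1))
  }
})

test_that("metrics reproduce known confusion matrices", {
  # the n = 70 matrix whose metrics print as 0.914286/0.921053/0.90625
  cm <- structure(list(tp = 35L, fp = 3L, fn = 3L, tn = 29L),
                  class = "bs_confusion")
  m <- compute_metrics(cm)
  expect_equal(unname(m["accuracy"]), 0.914286, tolerance = 1e-6)
  expect_equal(unname(m["sensitivity"]), 0.921053, tolerance = 1e-6)
  expect_equal(unname(m["specificity"]), 0.90625, tolerance = 1e-6)

  ones <- structure(list(tp = 1L, fp = 1L, fn = 1L, tn = 1L),
                    class = "bs_confusion")
  expect_equal(unname(compute_metrics(ones)), rep(0.5, 3))

  perfect <- structure(list(tp = 4L, fp = 0L, fn = 0L, tn = 6L),
                       class = "bs_confusion")
  expect_equal(unname(compute_metrics(perfect)), rep(1, 3))

  # the literal variant divides TN by TP + FP
  lit <- compute_metrics(cm, convention = "literal")
  expect_equal(unname(lit["specificity"]), 29 / 38, tolerance = 1e-12)

  degenerate <- structure(list(tp = 0L, fp = 0L, fn = 0L, tn = 5L),
                          class = "bs_confusion")
  expect_warning(md <- compute_metrics(degenerate), "undefined")
  expect_true(is.nan(md["sensitivity"]))
})

test_that("metric identities hold on random confusion matrices", {
  set.seed(9)
  for (i in 1:20) {
    cm <- structure(as.list(stats::setNames(sample(1:40, 4),
                                            c("tp", "fp", "fn", "tn"))),
                    class = "bs_confusion")
    m <- compute_metrics(cm)
    P <- cm$tp + cm$fn; N <- cm$tn + cm$fp
    expect_equal(unname(m["accuracy"]),
                 (m[["sensitivity"]] * P + m[["specificity"]] * N) / (P + N),
                 tolerance = 1e-12)
  }
})

test_that("splits are stratified, disjoint and reproducible", {
  labels <- rep(0:1, each = 5)
  sp <- split_train_test(labels, seed = 1)
  expect_length(sp$train, 7L)
  expect_length(sp$test, 3L)
  expect_identical(sort(c(sp$train, sp$test)), 1:10)
  expect_identical(split_train_test(labels, seed = 1), sp)
  expect_false(identical(split_train_test(labels, seed = 2)$train, sp$train))
  expect_error(split_train_test(rep(1, 6)), "both classes")

  # stratification: each class within one record of its proportional share
  set.seed(4)
  for (i in 1:20) {
    n <- sample(8:40, 1)
    labels <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    sp <- split_train_test(labels, seed = i)
    expect_length(sp$train, round(0.7 * n))
    for (cl in 0:1) {
      got <- sum(labels[sp$train] == cl)
      expect_lte(abs(got - 0.7 * sum(labels == cl)), 1)
    }
  }
})

test_that("repeated rounds report per-round accuracy deterministically", {
  set.seed(10)
  n <- 30
  X <- cbind(stats::rnorm(n, rep(c(0, 2), each = n / 2)), stats::rnorm(n))
  y <- rep(0:1, each = n / 2)
  cfg <- fast_train_config()
  rep1 <- run_rounds(X, y, n_rounds = 4, config = cfg, seed = 3)
  expect_length(rep1$accuracy, 4L)
  expect_equal(rep1$mean_accuracy, mean(rep1$accuracy), tolerance = 1e-12)
  expect_gte(rep1$mean_accuracy, rep1$min_accuracy)
  expect_lte(rep1$mean_accuracy, rep1$max_accuracy)
  rep2 <- run_rounds(X, y, n_rounds = 4, config = cfg, seed = 3)
  expect_identical(rep1$accuracy, rep2$accuracy)
  # pooled confusion covers every test prediction
  n_test <- as.integer(4 * (n - round(0.7 * n)))
  cmt <- rep1$confusion
  expect_identical(cmt$tp + cmt$fp + cmt$fn + cmt$tn, n_test)
})

test_that("the end-to-end pipeline runs, reproduces, and writes artifacts", {
  p <- tiny_params(duration = 1)
  cfg <- fast_train_config()
  out_dir <- file.path(tempdir(), "bs_pipe")
  rep1 <- run_pipeline(params = p, n_records = 12, config = cfg, seed = 2,
                       out_dir = out_dir)
  expect_s3_class(rep1, "bs_round_report")
  expect_true(all(is.finite(rep1$metrics)))
  expect_true(file.exists(file.path(out_dir, "features.csv")))
  mj <- jsonlite::read_json(file.path(out_dir, "metrics.json"))
  expect_length(mj$per_round, 3L)
  expect_true(all(c("accuracy", "sensitivity", "specificity") %in%
                    names(mj$metrics)))

  rep2 <- run_pipeline(params = p, n_records = 12, config = cfg, seed = 2)
  expect_identical(rep1$accuracy, rep2$accuracy)
  unlink(out_dir, recursive = TRUE)
})

test_that("manifest-driven evaluation matches in-memory generation", {
  p <- tiny_params(duration = 1)
  ds <- file.path(tempdir(), "bs_mani")
  manifest <- make_dataset(p, 8, class_balance = 0.5, seed = 6, out_dir = ds)
  cfg <- fast_train_config()
  ft <- featurize_dataset(manifest, cfg)
  expect_identical(dim(ft$features), c(8L, 18L))
  expect_identical(ft$labels, manifest$label)
  unlink(ds, recursive = TRUE)
})
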