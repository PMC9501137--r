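test_that("time-domain statistics match closed forms", {
  # constant signal
  td <- time_domain_features(rep(2, 4))
  expect_equal(unname(td), c(2, 0, 2, 2, 2, 2, 8, 16))
  # alternating +/-1
  td <- time_domain_features(c(1, -1, 1, -1))
  expect_equal(unname(td), c(0, 1, 1, -1, 1, 1, 0, 1))
  # square-root amplitude on a constant 4: ((1/4) * 4 * sqrt(4))^2 = 4
  expect_equal(unname(time_domain_features(rep(4, 4))["tf5"]), 4)
  # literal variant drops the inner square root
  expect_equal(unname(time_domain_features(rep(4, 4),
                                           literal_tf5 = TRUE)["tf5"]), 16)
  expect_error(time_domain_features(numeric(0)))
})

test_that("time-domain statistics scale covariantly", {
  set.seed(7)
  x <- stats::rnorm(256)
  s <- 2.5
  a <- time_domain_features(x)
  b <- time_domain_features(s * x)
  expect_equal(b["tf1"], s * a["tf1"])
  expect_equal(b["tf2"], s^2 * a["tf2"])
  expect_equal(b["tf3"], s * a["tf3"])
  expect_equal(b["tf4"], s * a["tf4"])
  expect_equal(b["tf6"], s * a["tf6"])
  expect_equal(b["tf7"], s^3 * a["tf7"])
  expect_equal(b["tf8"], s^4 * a["tf8"])
})

test_that("frequency-domain features obey Parseval and band placement", {
  # constant: DC only
  fd <- frequency_domain_features(rep(3, 100), fs = 4000)
  expect_equal(unname(fd["tf9"]), 3)
  expect_equal(unname(fd["tf10"]), 0)

  # unit 50 Hz sine over 1 s: total power N/2
  t <- (0:3999) / 4000
  s50 <- sin(2 * pi * 50 * t)
  fd <- frequency_domain_features(s50, fs = 4000)
  expect_equal(unname(fd["tf11"]), 0.5 * 4000, tolerance = 1e-6)

  # in-band tone beats out-of-band tone on TF10
  s500 <- sin(2 * pi * 500 * t)
  expect_gt(frequency_domain_features(s500, 4000)["tf10"],
            frequency_domain_features(s50, 4000)["tf10"])

  # Parseval identity on random signals, relative 1e-9
  set.seed(3)
  for (n in c(64, 100, 1000)) {
    x <- stats::rnorm(n)
    tf11 <- frequency_domain_features(x, 4000)["tf11"]
    expect_lt(abs(tf11 - sum(x^2)) / sum(x^2), 1e-9)
  }
})

test_that("Haar analysis matches hand computation and a recursive oracle", {
  d <- haar_forward(c(1, 3, 5, 7), levels = 2)
  expect_equal(d$approx, 4)
  expect_equal(d$details[[2]], -2)
  expect_equal(d$details[[1]], c(-1, -1))

  # constant signal: all details vanish
  dc <- haar_forward(rep(5, 16), levels = 4)
  expect_true(all(vapply(dc$details, function(v) all(v == 0), logical(1))))
  expect_equal(dc$approx, 5)

  # random signals, including non-power-of-two lengths, against the oracle
  set.seed(5)
  for (n in c(8, 13, 64, 100)) {
    x <- stats::rnorm(n)
    L <- 3
    got <- haar_forward(x, levels = L)
    want <- haar_oracle(x, levels = L)
    expect_equal(got$approx, want$approx, tolerance = 1e-14)
    for (j in 1:L) expect_equal(got$details[[j]], want$details[[j]],
                                tolerance = 1e-14)
  }
  expect_error(haar_forward(1:8, levels = 4), "levels")
})

test_that("Haar transform is exactly invertible and linear", {
  expect_equal(haar_inverse(haar_forward(c(1, 3, 5, 7), 2)), c(1, 3, 5, 7))

  set.seed(6)
  for (i in 1:20) {
    n <- sample(5:200, 1)
    x <- stats::rnorm(n)
    L <- sample.int(floor(log2(2^ceiling(log2(max(2, n))))), 1)
    expect_lt(max(abs(haar_inverse(haar_forward(x, L)) - x)), 1e-12)
  }

  # linearity of the analysis operator
  x <- stats::rnorm(32); y <- stats::rnorm(32)
  fa <- haar_forward(2 * x + 3 * y, 3)
  fx <- haar_forward(x, 3); fy <- haar_forward(y, 3)
  expect_equal(fa$approx, 2 * fx$approx + 3 * fy$approx, tolerance = 1e-12)
  expect_equal(fa$details[[2]], 2 * fx$details[[2]] + 3 * fy$details[[2]],
               tolerance = 1e-12)

  # zero coefficients reconstruct to zero
  z <- haar_forward(numeric(8), 3)
  expect_identical(haar_inverse(z), numeric(8))
})

test_that("subband energies summarise the decomposition coarse to fine", {
  e <- wavelet_features(haar_forward(c(1, 3, 5, 7), 2))
  expect_equal(unname(e), c(16, 4, 1))
  expect_identical(names(e), c("wA2", "wD2", "wD1"))

  # adding a fine-scale transient shifts energy into D1
  set.seed(8)
  base <- sin(2 * pi * (0:255) / 64)
  spike <- base; spike[100:101] <- spike[100:101] + c(2, -2)
  e0 <- wavelet_features(haar_forward(base, 4))
  e1 <- wavelet_features(haar_forward(spike, 4))
  expect_gt(e1["wD1"], e0["wD1"])
})

test_that("the assembled feature vector has fixed dimension and is deterministic", {
  p <- tiny_params(duration = 2)
  rec <- make_record(p, 1, seed = 9)
  v1 <- build_feature_vector(rec, levels = 6)
  expect_length(v1, 18L)
  expect_identical(v1, build_feature_vector(rec, levels = 6))
  expect_length(build_feature_vector(rec, levels = 3), 15L)

  # burst-rich records have a larger fourth moment than the bare background
  bg <- make_background(p, seed = 9)
  vb <- build_feature_vector(bg, levels = 6)
  expect_gt(v1["tf8"], vb["tf8"])
})
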