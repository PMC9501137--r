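test_that("parameter validation rejects inconsistent settings", {
  expect_error(synth_params(fs = -1), "fs")
  expect_error(synth_params(duration = 0), "duration")
  expect_error(synth_params(bgs_band = c(0, 300), bs_band = c(200, 1000)),
               "above")
  expect_error(synth_params(burst_rate_by_class = c(10, 5)), "rate")
  expect_error(synth_params(burst_len_range = c(0.5, 80), duration = 60))
})

test_that("background has the nominal length, is seeded, and is silent without sources", {
  p <- synth_params()  # 60 s at 4000 Hz
  bg <- make_background(p, seed = 1)
  expect_length(bg$samples, 240000L)

  p2 <- tiny_params(duration = 2)
  b1 <- make_background(p2, seed = 7)
  b2 <- make_background(p2, seed = 7)
  expect_identical(b1$samples, b2$samples)
  b3 <- make_background(p2, seed = 8)
  expect_false(identical(b1$samples, b3$samples))

  silent <- tiny_params(duration = 1, bg_sigma = 0, breath_amp = 0,
                        heart_amp = 0, noise_sigma = 0)
  expect_identical(make_background(silent, seed = 1)$samples, numeric(4000))
})

test_that("background power is concentrated below the band edge", {
  p <- tiny_params(duration = 10)
  bg <- make_background(p, seed = 3)$samples
  pow <- Mod(stats::fft(bg))^2
  fr <- (seq_along(bg) - 1) * p$fs / length(bg)
  fr <- pmin(fr, p$fs - fr)
  expect_gt(sum(pow[fr <= p$bgs_band[2]]) / sum(pow), 0.9)
})

test_that("burst channel is sparse, Poisson-counted and band-limited", {
  p <- tiny_params(duration = 5)
  none <- make_bursts(synth_params(duration = 5,
                                   burst_rate_by_class = c(0, 0)),
                      label = 0, seed = 1)
  expect_identical(none$signal, numeric(20000))
  expect_identical(nrow(none$events), 0L)

  # Monte-Carlo event count vs the Poisson mean
  rate <- p$burst_rate_by_class[2]
  counts <- vapply(1:60, function(i) nrow(make_bursts(p, 1, seed = i)$events),
                   numeric(1))
  expect_lt(abs(mean(counts) - rate), 3 * sqrt(rate) / sqrt(60) + 0.5)

  # FFT oracle: burst energy stays in the burst band
  for (s in 1:5) {
    b <- make_bursts(p, 1, seed = s)
    pow <- Mod(stats::fft(b$signal))^2
    fr <- (seq_along(b$signal) - 1) * p$fs / length(b$signal)
    fr <- pmin(fr, p$fs - fr)
    inband <- sum(pow[fr >= p$bs_band[1] & fr <= p$bs_band[2]]) / sum(pow)
    expect_gt(inband, 0.95)
  }

  # zero outside events; events sorted and disjoint
  b <- make_bursts(p, 1, seed = 11)
  mask <- logical(20000)
  for (e in seq_len(nrow(b$events))) {
    mask[b$events[e, 1]:(b$events[e, 2] - 1)] <- TRUE
  }
  expect_identical(b$signal[!mask], rep(0, sum(!mask)))
  if (nrow(b$events) > 1) {
    expect_true(all(diff(b$events[, 1]) > 0))
    expect_true(all(b$events[-nrow(b$events), 2] <= b$events[-1, 1]))
  }
})

test_that("records decompose into background + bursts + white noise", {
  p <- tiny_params(duration = 10)
  rec <- make_record(p, 1, seed = 5)
  bg <- make_background(p, seed = 5)
  bu <- make_bursts(p, 1, seed = 6)
  resid <- rec$samples - bg$samples - bu$signal
  expect_lt(abs(stats::var(resid) - p$noise_sigma^2) / p$noise_sigma^2, 0.1)

  # bursts raise the global excess kurtosis above the background's
  expect_gt(kurtosis_oracle(rec$samples), kurtosis_oracle(bg$samples))

  # label and events stored; noise/burst-free record equals its background
  expect_identical(rec$label, 1L)
  expect_identical(rec$events, bu$events)
  clean <- synth_params(duration = 2, noise_sigma = 0,
                        burst_rate_by_class = c(0, 0))
  expect_identical(make_record(clean, 0, seed = 2)$samples,
                   make_background(clean, seed = 2)$samples)
})

test_that("class 1 records carry more bursts than class 0 on average", {
  p <- tiny_params(duration = 2)
  n0 <- vapply(1:50, function(i) nrow(make_bursts(p, 0, seed = i)$events),
               numeric(1))
  n1 <- vapply(1:50, function(i) nrow(make_bursts(p, 1, seed = i)$events),
               numeric(1))
  expect_gt(mean(n1), mean(n0))
})

test_that("datasets are written with a valid manifest and rebuild byte-identically", {
  p <- tiny_params(duration = 0.5)
  d1 <- file.path(tempdir(), "bs_ds1")
  d2 <- file.path(tempdir(), "bs_ds2")
  m1 <- make_dataset(p, 10, class_balance = 0.5, seed = 3, out_dir = d1)
  m2 <- make_dataset(p, 10, class_balance = 0.5, seed = 3, out_dir = d2)
  expect_identical(nrow(m1), 10L)
  expect_identical(sum(m1$label == 1), 5L)
  expect_identical(sum(m1$label == 0), 5L)
  expect_identical(unname(tools::md5sum(m1$path)), unname(tools::md5sum(m2$path)))

  # round-trips through the manifest reader
  m <- read_manifest(file.path(d1, "manifest.csv"))
  expect_identical(m$label, m1$label)

  # a 232-record manifest has 232 rows (short records keep this cheap)
  d3 <- file.path(tempdir(), "bs_ds3")
  p3 <- tiny_params(duration = 0.1)
  m3 <- make_dataset(p3, 232, class_balance = 0.5, seed = 1, out_dir = d3)
  expect_identical(nrow(m3), 232L)
  unlink(c(d1, d2, d3), recursive = TRUE)
})
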