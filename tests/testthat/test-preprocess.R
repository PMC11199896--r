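## analytic magnitude response of the zero-phase (forward-backward)
## Butterworth bandpass: |H(f)|^2 of the one-pass filter
butter_zerophase_gain <- function(f, fs, low = 1, high = 10, order = 4) {
  bf <- signal::butter(order, c(low, high) / (fs / 2), type = "pass")
  w <- 2 * pi * f / fs
  H <- sum(bf$b * exp(-1i * w * (seq_along(bf$b) - 1))) /
    sum(bf$a * exp(-1i * w * (seq_along(bf$a) - 1)))
  Mod(H)^2
}

test_that("bandpass defaults and degenerate inputs behave", {
  spec <- filter_spec()
  expect_equal(spec$low_hz, 1)
  expect_equal(spec$high_hz, 10)
  expect_equal(spec$order, 4)
  z <- bandpass_filter(matrix(0, 2, 1024), 512)
  expect_equal(z, matrix(0, 2, 1024))
  expect_error(filter_spec(low_hz = 0), "0 < low")
  expect_error(bandpass_filter(matrix(1, 1, 100), 512,
                               filter_spec(high_hz = 300)), "too low")
  expect_error(bandpass_filter(matrix(NA_real_, 1, 100), 512), "non-finite")
  expect_error(bandpass_filter(matrix(1, 1, 100), 15), "too low")
})

test_that("filter response matches the analytic zero-phase oracle", {
  fs <- 512
  t <- seq(0, 6, by = 1 / fs)
  mid <- seq(round(length(t) * 0.3), round(length(t) * 0.7))
  for (freq in c(5, 40)) {
    y <- bandpass_filter(rbind(sin(2 * pi * freq * t)), fs)
    measured <- max(abs(y[1, mid]))
    expected <- butter_zerophase_gain(freq, fs)
    expect_lt(abs(measured - expected), 0.01) # within 1% of full scale
  }
  ## passband essentially transparent, stopband crushed
  y5 <- bandpass_filter(rbind(sin(2 * pi * 5 * t)), fs)
  y40 <- bandpass_filter(rbind(sin(2 * pi * 40 * t)), fs)
  expect_gte(max(abs(y5[1, mid])), 0.9)
  expect_lte(max(abs(y40[1, mid])), 0.05)
})

test_that("filtering is linear", {
  set.seed(5)
  x <- matrix(rnorm(2 * 2048), 2, 2048)
  y <- matrix(rnorm(2 * 2048), 2, 2048)
  lhs <- bandpass_filter(3 * x - 2 * y, 512)
  rhs <- 3 * bandpass_filter(x, 512) - 2 * bandpass_filter(y, 512)
  expect_equal(lhs, rhs, tolerance = 1e-9)
})

test_that("epoch extraction is event-locked, ordered and bounds-checked", {
  fs <- 512
  sig <- matrix(seq_len(2 * 3 * fs), 2, 3 * fs, byrow = TRUE)
  ev <- tibble::tibble(onset = c(0L, 512L, 700L), label = c(1L, 0L, 1L))
  es <- extract_epochs(sig, fs, ev, epoch_window(1))
  expect_equal(dim(es$data), c(3, 2, 512))
  expect_equal(es$info$label, c(1L, 0L, 1L))
  ## half-open [onset, onset + duration): first sample is the onset sample
  expect_equal(es$data[2, 1, 1], sig[1, 513])
  expect_equal(es$data[2, 1, 512], sig[1, 1024])

  empty <- extract_epochs(sig, fs, ev[0, ], epoch_window(1))
  expect_equal(n_epochs(empty), 0)
  expect_error(extract_epochs(sig, fs, tibble::tibble(onset = 3 * fs - 10, label = 0L),
                              epoch_window(1)), "event 1")
})

test_that("downsampling hits the canonical sample counts", {
  x1 <- matrix(rnorm(2 * 512), 2, 512)
  d1 <- downsample(x1, fs_out = 64, fs_in = 512)
  expect_equal(ncol(d1), 64)
  expect_equal(d1[, 2], x1[, 9]) # decimation keeps every 8th sample

  x2 <- matrix(rnorm(2 * 128), 2, 128)
  d2 <- downsample(x2, fs_out = 128, fs_in = 256)
  expect_equal(ncol(d2), 64)

  expect_identical(downsample(x1, fs_out = 512, fs_in = 512), x1)
  expect_error(downsample(x1, fs_out = 1024, fs_in = 512), "must not exceed")

  ## non-integer ratio goes through polyphase resampling, preserving duration
  x3 <- matrix(rnorm(2 * 96), 2, 96) # 1 s at 96 Hz
  d3 <- downsample(x3, fs_out = 64, fs_in = 96)
  expect_equal(ncol(d3), 64)
})

test_that("channel selection honours order and substitutions", {
  es <- small_set(n_subjects = 1, n = 4)
  es$channel_names <- c("FCz", "Cz")
  same <- select_channels(es, c("FCz", "Cz"))
  expect_identical(same$data, es$data)

  swapped <- select_channels(es, c("Cz", "FCz"))
  expect_identical(swapped$data[, 1, ], es$data[, 2, ])
  expect_identical(swapped$channel_names, c("Cz", "FCz"))

  lsc <- es
  lsc$channel_names <- c("Fz", "Cz")
  expect_message(out <- select_channels(lsc, c("FCz", "Cz"),
                                        substitution = c(FCz = "Fz")),
                 "using Fz")
  expect_identical(out$channel_names, c("Fz", "Cz"))
  expect_error(select_channels(lsc, c("FCz", "Cz")), "no substitution")
})

test_that("amplitude scaling is exact and validated", {
  es <- small_set(n_subjects = 1, n = 4)
  sc <- scale_amplitude(es, 1000)
  nz <- es$data != 0
  expect_true(all(abs(sc$data[nz] / es$data[nz] - 1000) < 1e-9))
  expect_identical(scale_amplitude(es[1], 5)$data[es[1]$data == 0],
                   numeric(sum(es[1]$data == 0)))
  expect_error(scale_amplitude(es, -1), "positive")
})

test_that("the pipeline emits canonical epochs and composes its stages", {
  set.seed(11)
  fs <- 512
  sig <- matrix(rnorm(2 * 6 * fs) * 1e-5, 2, 6 * fs)
  ev <- tibble::tibble(onset = c(100L, 1500L, 2500L), label = c(1L, 0L, 0L))
  rr <- raw_recording(sig, fs, c("FCz", "Cz"), ev)
  out <- run_pipeline(rr, profile_bnci_cursor())
  expect_true(is_canonical(out))
  expect_equal(out$sampling_rate, 64)
  expect_equal(out$info$label, ev$label)

  ## composition: identical to manually chained stages
  manual <- bandpass_filter(sig, fs) |>
    extract_epochs(fs, ev, epoch_window(1), channel_names = c("FCz", "Cz")) |>
    downsample(64) |>
    select_channels(c("FCz", "Cz")) |>
    scale_amplitude(1000)
  expect_equal(out$data, manual$data)

  ## pre-epoched 0.5 s / 256 Hz input: no filtering, downsample to 128 Hz
  pre <- epoch_set(array(rnorm(3 * 2 * 128) * 1e-5, c(3, 2, 128)),
                   tibble::tibble(label = c(1L, 0L, 0L), subject = "s01",
                                  session = "session1", task = "gaze"),
                   channel_names = c("FCz", "Cz"), sampling_rate = 256)
  gout <- run_pipeline(pre, profile_gaze_speller())
  expect_true(is_canonical(gout))
  expect_equal(gout$sampling_rate, 128)
  ## filtering skipped: decimated samples are exact input values
  expect_equal(gout$data[1, 1, 3], pre$data[1, 1, 5] * 1000)
})

test_that("preprocessing never permutes labels", {
  es <- small_set(n_subjects = 2, n = 10)
  labs <- es$info$label
  out <- es |>
    downsample(32) |>
    select_channels(c("FCz", "Cz")) |>
    scale_amplitude(2)
  expect_identical(out$info$label, labs)
})
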