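make_epochs <- function(data, fs = 128, labels = NULL, phase = NULL) {
  nt <- dim(data)[1]
  eeg_epochs(
    data = data,
    labels = labels %||% rep(c(1L, 2L), length.out = nt),
    sampling_rate = fs,
    phase = phase
  )
}

test_that("common average reference annihilates a signal shared by every channel", {
  fs <- 128
  x <- sin(2 * pi * 7 * seq(0, 1, length.out = fs)) + rnorm(fs)
  data <- array(0, dim = c(2, 4, fs))
  for (ch in 1:4) data[1, ch, ] <- x
  for (ch in 1:4) data[2, ch, ] <- 2 * x
  eeg <- make_epochs(data)
  out <- preprocess(eeg, notch_hz = NULL)
  expect_equal(max(abs(out$data)), 0)
})

test_that("the notch filter attenuates the line frequency by at least 40 dB", {
  fs <- 256
  tt <- seq(0, 2 - 1 / fs, by = 1 / fs)
  tone <- sin(2 * pi * 50 * tt)
  data <- array(0, dim = c(1, 2, length(tt)))
  data[1, 1, ] <- tone
  data[1, 2, ] <- -tone # CAR of (x, -x) leaves both untouched
  eeg <- make_epochs(data, fs = fs, labels = 1L, phase = "offline")
  out <- preprocess(eeg, notch_hz = 50)
  band_power <- function(x) {
    sp <- Mod(stats::fft(x))^2
    f <- (seq_along(x) - 1) * fs / length(x)
    sum(sp[f >= 49 & f <= 51])
  }
  # steady-state response: discard the zero-phase filter's edge transients
  mid <- seq(length(tt) / 4, 3 * length(tt) / 4)
  atten_db <- 10 * log10(band_power(data[1, 1, mid]) /
                           band_power(out$data[1, 1, mid]))
  expect_gt(atten_db, 40)
})

test_that("channel exclusion is honoured and validated", {
  data <- array(rnorm(2 * 4 * 64), dim = c(2, 4, 64))
  eeg <- make_epochs(data)
  expect_equal(dim(preprocess(eeg, notch_hz = NULL)$data)[2], 4L)
  kept <- preprocess(eeg, notch_hz = NULL, exclude_channels = c("ch01", "ch03"))
  expect_identical(kept$channel_names, c("ch02", "ch04"))
  expect_error(preprocess(eeg, exclude_channels = "nope"), "unknown channels")
  expect_error(preprocess(eeg, exclude_channels = sprintf("ch%02d", 1:4)),
               "excluding all channels")
  expect_error(preprocess(eeg, notch_hz = 70), "Nyquist")
})

test_that("window and feature counts follow the sliding-window arithmetic", {
  fs <- 256
  data <- array(rnorm(2 * 3 * fs * 5), dim = c(2, 3, fs * 5))
  eeg <- make_epochs(data, fs = fs)
  fm <- extract_psd_features(eeg, window_len = 0.5, window_step = 0.05,
                             band = c(1, 70), bin_width = 2)
  # floor((5 - 0.5) / 0.05) + 1 = 91 windows per trial
  expect_equal(sum(fm$window_trial == 1L), 91)
  # ceiling((70 - 1) / 2) = 35 bins per channel
  expect_equal(ncol(fm$X), 35 * 3)
  expect_equal(nrow(fm$freq_bins), 35)
  expect_error(extract_psd_features(eeg, window_len = 6), "window")
  # a bin narrower than the spectral resolution must be refused
  expect_error(
    extract_psd_features(eeg, window_len = 0.5, band = c(1, 10), bin_width = 1),
    "no spectral line"
  )
})

test_that("amplitude scaling shifts every log-power feature by exactly 2 log c", {
  fs <- 128
  data <- array(rnorm(2 * 2 * fs), dim = c(2, 2, fs))
  eeg1 <- make_epochs(data, fs = fs)
  eeg2 <- make_epochs(data * 3, fs = fs)
  f1 <- extract_psd_features(eeg1, window_step = 0.1, band = c(2, 30), bin_width = 4)
  f2 <- extract_psd_features(eeg2, window_step = 0.1, band = c(2, 30), bin_width = 4)
  expect_equal(f2$X - f1$X,
               matrix(2 * log(3), nrow(f1$X), ncol(f1$X)),
               tolerance = 1e-10, ignore_attr = TRUE)
  # and the linear-power variant scales by c^2
  l1 <- extract_psd_features(eeg1, window_step = 0.1, band = c(2, 30),
                             bin_width = 4, log_power = FALSE)
  l2 <- extract_psd_features(eeg2, window_step = 0.1, band = c(2, 30),
                             bin_width = 4, log_power = FALSE)
  expect_equal(l2$X, 9 * l1$X, tolerance = 1e-10)
})

test_that("white noise yields an approximately flat log-power profile", {
  fs <- 128
  withr::with_seed(99, {
    data <- array(rnorm(6 * 1 * fs * 2), dim = c(6, 1, fs * 2))
  })
  eeg <- make_epochs(data, fs = fs)
  fm <- extract_psd_features(eeg, window_step = 0.05, band = c(4, 28), bin_width = 4)
  bin_means <- colMeans(fm$X)
  bin_sds <- apply(fm$X, 2, sd)
  expect_lt(max(bin_means) - min(bin_means), 3 * mean(bin_sds))
})

test_that("window bookkeeping is exact and extraction deterministic", {
  eeg <- generate_dataset(tiny_config(seed = 8))
  fm <- extract_psd_features(eeg, window_step = 0.1, band = c(2, 30), bin_width = 4)
  fm2 <- extract_psd_features(eeg, window_step = 0.1, band = c(2, 30), bin_width = 4)
  expect_identical(fm$X, fm2$X)
  # every window maps to exactly one trial; per-trial concatenation rebuilds X
  expect_equal(length(fm$window_trial), nrow(fm$X))
  rebuilt <- do.call(rbind, lapply(sort(unique(fm$window_trial)), function(tr) {
    fm$X[fm$window_trial == tr, , drop = FALSE]
  }))
  expect_identical(rebuilt, fm$X)
  # window labels agree with the parent trial labels
  expect_identical(fm$window_label, eeg$labels[fm$window_trial])
})
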