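make_rec <- function(x, fs = 250, channels = NULL) {
  if (is.vector(x)) x <- matrix(x, nrow = 1)
  if (is.null(channels)) channels <- paste0("ch", seq_len(nrow(x)))
  eeg_recording(x, fs, channels)
}

test_that("band-pass response matches the filter oracles", {
  fs <- 250
  t <- seq_len(60 * fs) / fs
  mid <- (20 * fs):(40 * fs)
  # DC sits far into the high-pass stop band
  rec <- make_rec(rep(1, length(t)), fs)
  out <- eeg_bandpass(rec, 0.15, 30)
  expect_lt(max(abs(out$data[1, mid])), 0.01)
  # 10 Hz is mid pass band
  rec <- make_rec(sin(2 * pi * 10 * t), fs)
  out <- eeg_bandpass(rec, 0.15, 30)
  expect_lt(abs(max(abs(out$data[1, mid])) - 1), 0.05)
  # 50 Hz is past the low-pass corner
  rec <- make_rec(sin(2 * pi * 50 * t), fs)
  out <- eeg_bandpass(rec, 0.15, 30)
  expect_lt(max(abs(out$data[1, mid])), 0.10)
  # shape preserved, Nyquist guarded
  expect_equal(dim(out$data), c(1, length(t)))
  expect_error(eeg_bandpass(rec, 0.15, 125), "Nyquist")
})

test_that("segmentation follows the window arithmetic", {
  w <- segment_windows(rnorm(1000), 250, win_ms = 650, overlap = 0.5)
  expect_equal(nrow(w), 162)          # floor(0.65 * 250)
  expect_equal(ncol(w), 11)           # floor((1000 - 162) / 81) + 1
  one <- segment_windows(rnorm(162), 250)
  expect_equal(ncol(one), 1)
  expect_error(segment_windows(rnorm(100), 250), "shorter than one")
  # windows tile the signal with hop 81
  x <- seq_len(500)
  w <- segment_windows(x, 250)
  expect_equal(w[, 2], x[82:243])
})

test_that("Welch estimates obey self-spectrum and Parseval identities", {
  set.seed(1)
  x <- segment_windows(rnorm(5000), 250)
  est <- spectral_estimates(x, x, 250)
  expect_equal(Re(est$Pxy), est$Pxx, tolerance = 1e-12)
  expect_lt(max(abs(Im(est$Pxy))), 1e-12)
  expect_true(all(est$Pxx >= 0))
  # integral of the density recovers the tapered-signal power within 2 %
  df <- diff(est$freqs[1:2])
  hn <- 0.5 - 0.5 * cos(2 * pi * (0:161) / 161)
  xd <- sweep(x, 2, colMeans(x))
  power <- mean(colSums((xd * hn)^2)) / sum(hn^2)
  expect_lt(abs(sum(est$Pxx) * df - power) / power, 0.02)
  # Cauchy-Schwarz after averaging
  y <- segment_windows(rnorm(5000), 250)
  est2 <- spectral_estimates(x, y, 250)
  expect_true(all(Mod(est2$Pxy)^2 <= est2$Pxx * est2$Pyy * (1 + 1e-12)))
  expect_error(spectral_estimates(x, y[, 1:3], 250), "identical dimensions")
})

test_that("a pure tone peaks at its own frequency bin", {
  fs <- 250
  x <- sin(2 * pi * 10.8 * seq_len(162) / fs)  # bin 8 of a 162-point grid
  est <- spectral_estimates(matrix(x), matrix(x), fs)
  expect_equal(which.max(est$Pxx), which.min(abs(est$freqs - 10.8)))
})

test_that("MSC is 1 for identical signals and 1/L for independent noise", {
  set.seed(2)
  x <- segment_windows(rnorm(2000), 250)
  cs <- magnitude_squared_coherence(spectral_estimates(x, x, 250))
  expect_true(all(abs(cs$msc - 1) < 1e-9))
  # independent white noise, L non-overlapping segments: E[msc] ~ 1/L
  L <- 8
  m <- replicate(150, {
    a <- matrix(rnorm(64 * L), 64, L)
    b <- matrix(rnorm(64 * L), 64, L)
    mean(magnitude_squared_coherence(spectral_estimates(a, b, 250))$msc)
  })
  expect_lt(abs(mean(m) - 1 / L), 0.03)
})

test_that("a pure delay preserves coherence", {
  set.seed(3)
  x <- rnorm(4000)
  d <- 5
  y <- c(rep(0, d), x[1:(4000 - d)])
  wx <- segment_windows(x, 250)
  wy <- segment_windows(y, 250)
  cs <- magnitude_squared_coherence(spectral_estimates(wx, wy, 250))
  inb <- cs$freqs > 5 & cs$freqs < 100
  expect_gt(mean(cs$msc[inb]), 0.95)
})

test_that("MSC is symmetric, bounded, and guarded against 1 segment", {
  set.seed(4)
  for (i in 1:10) {
    n <- sample(600:2000, 1)
    x <- switch(1 + i %% 3, rnorm(n),
                sin(2 * pi * runif(1, 1, 40) * seq_len(n) / 250) + rnorm(n, 0, .1),
                cumsum(rnorm(n)))
    y <- switch(1 + (i + 1) %% 3, rnorm(n), rep(0, n), x + rnorm(n))
    wx <- segment_windows(x, 250); wy <- segment_windows(y, 250)
    a <- magnitude_squared_coherence(spectral_estimates(wx, wy, 250))
    b <- magnitude_squared_coherence(spectral_estimates(wy, wx, 250))
    expect_true(all(a$msc >= 0 & a$msc <= 1))
    expect_equal(a$msc, b$msc, tolerance = 1e-12)
  }
  one <- matrix(rnorm(64), 64, 1)
  expect_error(magnitude_squared_coherence(spectral_estimates(one, one, 250)),
               "at least 2 segments")
})

test_that("band averaging is the arithmetic mean over in-band bins", {
  cs <- structure(list(freqs = c(7, 9, 10, 12, 14),
                       msc = c(0.9, 0.2, 0.4, 0.6, 0.9)),
                  class = "coherence_spectrum")
  alpha <- band_definition("alpha", 8, 13)
  expect_equal(band_coherence(cs, alpha), 0.4)
  cs$msc <- rep(0.7, 5)
  expect_equal(band_coherence(cs, alpha), 0.7)
  expect_error(band_coherence(cs, band_definition("x", 20, 30)), "no frequency")
})

test_that("Fisher-Z follows the square-root convention", {
  expect_equal(fisher_z(0), 0)
  expect_equal(fisher_z(0.64), atanh(0.8), tolerance = 1e-12)
  expect_lt(fisher_z(0.3), fisher_z(0.5))
  expect_error(fisher_z(1), "below 1")
  expect_equal(fisher_z(1, clamp = TRUE), atanh(sqrt(1 - 1e-10)))
  expect_equal(fisher_z(0.64, convention = "direct"), atanh(0.64))
})

test_that("feature matrix has the montage grid and is scale-free", {
  spec <- cohort_spec(n_per_class = c(1, 1), duration_s = 10, seed = 6)
  cohort <- generate_cohort(spec)
  feats <- build_feature_matrix(cohort)
  expect_equal(ncol(feats$values), 48)
  expect_equal(colnames(feats$values)[1:3],
               c("F3-C3_delta", "F3-C3_theta", "F3-C3_alpha"))
  expect_false(anyNA(feats$values))
  # duplicated recording gives identical rows
  twin <- build_feature_matrix(list(cohort[[1]], cohort[[1]]))
  expect_identical(twin$values[1, ], twin$values[2, ])
  # coherence ignores per-channel gain
  scaled <- cohort[[1]]
  scaled$data <- scaled$data * runif(19, 0.2, 5)
  pair <- build_feature_matrix(list(cohort[[1]], scaled))
  expect_equal(pair$values[1, ], pair$values[2, ], tolerance = 1e-8)
  # missing electrode is reported by name
  cut <- cohort[[1]]
  keep <- setdiff(rownames(cut$data), "T5")
  cut$data <- cut$data[keep, ]
  cut$channels <- keep
  expect_error(build_feature_matrix(list(cut)), "T5")
})

test_that("a planted alpha effect lands in its feature at the target level", {
  spec <- one_effect_spec(0.25, seed = 8)
  feats <- build_feature_matrix(list(synthesize_recording(spec, "BD", 8)))
  z <- feats$values[1, "F3-C3_alpha"]
  expect_lt(abs(tanh(z)^2 - 0.25), 0.05)
})
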