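#' Zero-phase band-pass filter an EEG recording
#'
#' Applies a zero-phase Butterworth band-pass per channel: a 2nd-order
#' high-pass at `lo` cascaded with a 4th-order low-pass at `hi`, each run
#' forward and backward (so the effective attenuation is doubled and phase is
#' zero). The cascade is used instead of a single band-pass section because
#' the clinical lower edge (0.15 Hz) sits at a tiny normalized frequency
#' where a high-order band-pass design is numerically fragile.
#'
#' @param rec An [eeg_recording()].
#' @param lo,hi Pass-band edges in Hz; `hi` must be below Nyquist.
#' @return A filtered [eeg_recording()] of identical shape.
#' @export
eeg_bandpass <- function(rec, lo = 0.15, hi = 30) {
  stopifnot(inherits(rec, "eeg_recording"))
  nyq <- rec$fs / 2
  if (!(lo >= 0 && lo < hi)) stop("need 0 <= lo < hi")
  if (hi >= nyq) stop("hi must be below the Nyquist frequency")
  x <- t(rec$data)
  if (lo > 0) {
    hp <- signal::butter(2, lo / nyq, type = "high")
    x <- .cpp_filtfilt(hp$b, hp$a, x, padlen = min(nrow(x) - 1L, 1000L))
  }
  lp <- signal::butter(4, hi / nyq, type = "low")
  x <- .cpp_filtfilt(lp$b, lp$a, x, padlen = min(nrow(x) - 1L, 1000L))
  out <- rec
  out$data <- t(x)
  rownames(out$data) <- rec$channels
  out
}

#' Split a signal into overlapping analysis windows
#'
#' Window length is `floor(win_ms * fs / 1000)` samples (162 at the default
#' 650 ms and 250 Hz) and the hop is `floor(length * (1 - overlap))`. Only
#' full-length windows are kept; the trailing remainder is discarded.
#'
#' @param x Numeric sample vector.
#' @param fs Sampling rate in Hz.
#' @param win_ms Window length in milliseconds.
#' @param overlap Fractional overlap between consecutive windows.
#' @return A `win x n_windows` numeric matrix of window columns.
#' @export
segment_windows <- function(x, fs, win_ms = 650, overlap = 0.5) {
  win <- floor(win_ms * fs / 1000)
  hop <- max(1L, floor(win * (1 - overlap)))
  if (length(x) < win)
    stop("signal shorter than one analysis window")
  l <- floor((length(x) - win) / hop) + 1L
  idx <- outer(seq_len(win), (seq_len(l) - 1L) * hop, "+")
  matrix(x[idx], nrow = win)
}

#' Welch auto- and cross-spectral estimates
#'
#' Each window is mean-detrended, tapered with a Hanning window, Fourier
#' transformed, and the one-sided auto/cross periodograms are averaged over
#' windows. Mean removal per window suppresses DC leakage, which matters
#' because the band-pass lower edge lies below the frequency resolution of a
#' 650 ms window. Densities are scaled so that the integral of `Pxx` over
#' frequency matches the signal power.
#'
#' @param x,y Window matrices from [segment_windows()] (same dimensions).
#' @param fs Sampling rate in Hz.
#' @return A `spectral_estimate` with `freqs`, `Pxx`, `Pyy` (real),
#'   `Pxy` (complex), and `n_segments`.
#' @export
spectral_estimates <- function(x, y, fs) {
  if (!is.matrix(x) || !is.matrix(y) || !all(dim(x) == dim(y)))
    stop("x and y must be window matrices with identical dimensions")
  win <- nrow(x)
  Fx <- .windowed_fft(x)
  Fy <- if (identical(x, y)) Fx else .windowed_fft(y)
  half <- seq_len(floor(win / 2) + 1L)
  w <- .hann(win)
  scale <- 2 / (fs * sum(w^2))
  Pxx <- rowMeans(Mod(Fx[half, , drop = FALSE])^2) * scale
  Pyy <- rowMeans(Mod(Fy[half, , drop = FALSE])^2) * scale
  Pxy <- rowMeans(Fx[half, , drop = FALSE] * Conj(Fy[half, , drop = FALSE])) * scale
  # DC (and Nyquist for even lengths) bins are not doubled in one-sided form
  Pxx[1] <- Pxx[1] / 2; Pyy[1] <- Pyy[1] / 2; Pxy[1] <- Pxy[1] / 2
  if (win %% 2 == 0) {
    k <- length(half)
    Pxx[k] <- Pxx[k] / 2; Pyy[k] <- Pyy[k] / 2; Pxy[k] <- Pxy[k] / 2
  }
  structure(list(freqs = (half - 1) * fs / win,
                 Pxx = Pxx, Pyy = Pyy, Pxy = Pxy,
                 n_segments = ncol(x), fs = fs),
            class = "spectral_estimate")
}

.hann <- function(n) 0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / (n - 1))

.windowed_fft <- function(x) {
  x <- sweep(x, 2, colMeans(x))
  mvfft(x * .hann(nrow(x)))
}

#' Magnitude-squared coherence spectrum
#'
#' `msc(f) = |Pxy(f)|^2 / (Pxx(f) * Pyy(f))`, clipped to `[0, 1]` against
#' floating-point overshoot. Bins with zero power are defined as 0. A
#' single-segment estimate is identically 1 regardless of the signals, so at
#' least two averaged segments are required.
#'
#' @param est A [spectral_estimates()] result.
#' @return A `coherence_spectrum` with `freqs` and `msc`.
#' @export
magnitude_squared_coherence <- function(est) {
  stopifnot(inherits(est, "spectral_estimate"))
  if (est$n_segments < 2)
    stop("MSC from a single segment is degenerate (identically 1); ",
         "at least 2 segments are required")
  denom <- est$Pxx * est$Pyy
  msc <- ifelse(denom > 0, Mod(est$Pxy)^2 / denom, 0)
  msc <- pmin(pmax(msc, 0), 1)
  structure(list(freqs = est$freqs, msc = msc), class = "coherence_spectrum")
}

#' Average coherence over a frequency band
#'
#' Arithmetic mean of the MSC over bins with `lo <= f <= hi`.
#'
#' @param cs A [magnitude_squared_coherence()] result.
#' @param band A [band_definition()].
#' @return Scalar band coherence in `[0, 1]`.
#' @export
band_coherence <- function(cs, band) {
  stopifnot(inherits(cs, "coherence_spectrum"), inherits(band, "band_definition"))
  inb <- cs$freqs >= band$lo & cs$freqs <= band$hi
  if (!any(inb)) stop(sprintf("no frequency bins inside band %s", band$name))
  mean(cs$msc[inb])
}

#' Fisher-Z transform for magnitude-squared coherence
#'
#' Variance-stabilizing transform `z = atanh(sqrt(c))`, the standard
#' convention for squared coherence (the square root maps MSC back to the
#' coherency-magnitude scale on which atanh stabilizes variance). The direct
#' convention `z = atanh(c)` is available via `convention = "direct"`.
#'
#' @param c Coherence value(s) in `[0, 1)`.
#' @param convention `"sqrt"` (default) or `"direct"`.
#' @param clamp If `TRUE`, values at or above 1 are clamped to `1 - 1e-10`
#'   instead of raising an error.
#' @return Transformed value(s), `>= 0`, monotone increasing in `c`.
#' @export
fisher_z <- function(c, convention = c("sqrt", "direct"), clamp = FALSE) {
  convention <- match.arg(convention)
  if (any(c < 0)) stop("coherence must be non-negative")
  if (any(c >= 1)) {
    if (!clamp) stop("coherence must be below 1 (or set clamp = TRUE)")
    c <- pmin(c, 1 - 1e-10)
  }
  if (convention == "sqrt") atanh(sqrt(c)) else atanh(c)
}
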