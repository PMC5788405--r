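#' Short-time complex spectrogram
#'
#' Splits a mono waveform into frames, applies a window, zero-pads and takes
#' the one-sided DFT of each frame. The default analysis geometry is a frame
#' length of 2048 samples with a hop of 1024 at a 24 kHz working rate; the
#' sinusoid-detection front-end additionally zero-pads each frame with 2048
#' zeros, giving a 4096-point DFT (bin spacing 5.86 Hz).
#'
#' @param wave Numeric sample vector (mono).
#' @param sample_rate Sample rate in Hz.
#' @param window `"rectangular"` or `"hann"`.
#' @param frame_length Frame length N in samples.
#' @param hop Frame shift L in samples.
#' @param zero_pad Zeros appended to each frame before the DFT.
#' @return An object of class `alarm_spectrogram`: a list with `values`
#'   (complex matrix, bins x frames, bin k of the matrix holding DFT index
#'   k-1), `sample_rate`, `frame_length`, `hop`, `dft_size`, `window` and
#'   `frame_times` (frame start times, seconds).
#' @export
compute_spectrogram <- function(wave, sample_rate,
                                window = c("rectangular", "hann"),
                                frame_length = 2048L, hop = 1024L,
                                zero_pad = 0L) {
  window <- match.arg(window)
  if (is.matrix(wave) && ncol(wave) > 1) stop("mono required")
  wave <- as.numeric(wave)
  frame_length <- as.integer(frame_length)
  hop <- as.integer(hop)
  zero_pad <- as.integer(zero_pad)
  stopifnot(hop > 0L, frame_length > 0L, zero_pad >= 0L)
  if (length(wave) < frame_length) stop("input too short")
  dft_size <- frame_length + zero_pad
  n_frames <- (length(wave) - frame_length) %/% hop + 1L
  n_bins <- dft_size %/% 2L + 1L
  win <- switch(window,
    rectangular = rep(1, frame_length),
    # periodic Hann, the DFT-analysis convention
    hann = 0.5 - 0.5 * cos(2 * pi * (0:(frame_length - 1L)) / frame_length))
  starts <- (seq_len(n_frames) - 1L) * hop
  values <- matrix(0i, nrow = n_bins, ncol = n_frames)
  chunk <- max(1L, min(n_frames, as.integer(2^22 / dft_size)))
  idx_frame <- seq_len(frame_length)
  for (c0 in seq(1L, n_frames, by = chunk)) {
    cols <- c0:min(n_frames, c0 + chunk - 1L)
    fr <- matrix(0, nrow = dft_size, ncol = length(cols))
    fr[idx_frame, ] <- wave[outer(idx_frame, starts[cols], `+`)] * win
    sp <- stats::mvfft(fr)
    values[, cols] <- sp[seq_len(n_bins), , drop = FALSE]
  }
  structure(list(values = values, sample_rate = sample_rate,
                 frame_length = frame_length, hop = hop,
                 dft_size = dft_size, window = window,
                 frame_times = starts / sample_rate),
            class = "alarm_spectrogram")
}

#' @export
print.alarm_spectrogram <- function(x, ...) {
  cat(sprintf(
    "<alarm_spectrogram> %d bins x %d frames | fs=%g Hz N=%d L=%d dft=%d (%s)\n",
    nrow(x$values), ncol(x$values), x$sample_rate, x$frame_length, x$hop,
    x$dft_size, x$window))
  invisible(x)
}

n_frames <- function(spec) ncol(spec$values)
n_bins <- function(spec) nrow(spec$values)

#' Frequency-bin centres of a spectrogram
#'
#' @param spec An `alarm_spectrogram`.
#' @return Centre frequency in Hz of each one-sided bin (bin k at
#'   (k-1) * sample_rate / dft_size).
#' @export
bin_frequencies <- function(spec) {
  (seq_len(n_bins(spec)) - 1L) * spec$sample_rate / spec$dft_size
}

#' Bins covering an alarm-specific frequency region
#'
#' Returns the contiguous range of spectrogram bins whose centre frequencies
#' lie within `center_freq` +/- `tolerance` (the +/- delta = 20 Hz regions in
#' which all alarm-specific processing takes place). The range is never
#' empty: with a tolerance smaller than half a bin the single nearest bin is
#' returned.
#'
#' @param center_freq Region centre in Hz; must lie in (0, Nyquist).
#' @param tolerance One-sided tolerance delta in Hz (default 20).
#' @param spec An `alarm_spectrogram` supplying the bin geometry.
#' @return Integer vector of (1-based) bin indices into `spec$values`.
#' @export
region_bins <- function(center_freq, tolerance = 20, spec) {
  if (center_freq <= 0 || center_freq >= spec$sample_rate / 2)
    stop("frequency out of band")
  freqs <- bin_frequencies(spec)
  ks <- which(freqs >= center_freq - tolerance & freqs <= center_freq + tolerance)
  if (length(ks) == 0L) ks <- which.min(abs(freqs - center_freq))
  as.integer(ks)
}

#' Frequency-filtered log filter-bank energy features (baseline)
#'
#' The generic baseline features: per frame, Mel-scaled triangular band-pass
#' energies of the power spectrum are logged, then frequency-filtered by
#' taking the difference between the log energies of the following and the
#' preceding filter (one-sided differences at the two edge filters), and
#' finally appended with first-order temporal derivatives. With the default
#' 18 filters the feature dimension is 36.
#'
#' @param spec An `alarm_spectrogram` (any window).
#' @param n_filters Number of Mel filters (>= 3; default 18).
#' @return An `alarm_features` object: list with `vectors` (frames x dim),
#'   `frame_times`, `feature_kind = "ff_lfbe"`.
#' @export
compute_ff_lfbe <- function(spec, n_filters = 18L) {
  stopifnot(n_filters >= 3L)
  fb <- mel_filterbank(n_filters, n_bins(spec), spec$sample_rate, spec$dft_size)
  pow <- Mod(spec$values)^2
  e <- fb %*% pow                          # n_filters x frames
  loge <- log(pmax(e, 1e-12))              # floor keeps silence finite
  nf <- n_filters
  ff <- rbind(loge[2L, , drop = FALSE] - loge[1L, , drop = FALSE],
              loge[3:nf, , drop = FALSE] - loge[1:(nf - 2L), , drop = FALSE],
              loge[nf, , drop = FALSE] - loge[nf - 1L, , drop = FALSE])
  static <- t(ff)                          # frames x n_filters
  delta <- temporal_delta(static)
  new_features(cbind(static, delta), spec$frame_times, "ff_lfbe")
}

# +/-1-frame symmetric difference, zero at the sequence edges.
temporal_delta <- function(x) {
  T <- nrow(x)
  d <- matrix(0, T, ncol(x))
  if (T >= 3L) d[2:(T - 1L), ] <- (x[3:T, , drop = FALSE] - x[1:(T - 2L), , drop = FALSE]) / 2
  d
}

# Triangular Mel filterbank spanning 0 Hz .. Nyquist with 50% overlap.
mel_filterbank <- function(n_filters, nbins, sample_rate, dft_size) {
  hz2mel <- function(f) 2595 * log10(1 + f / 700)
  mel2hz <- function(m) 700 * (10^(m / 2595) - 1)
  edges <- mel2hz(seq(hz2mel(0), hz2mel(sample_rate / 2), length.out = n_filters + 2L))
  freqs <- (seq_len(nbins) - 1L) * sample_rate / dft_size
  fb <- matrix(0, n_filters, nbins)
  for (j in seq_len(n_filters)) {
    lo <- edges[j]; ce <- edges[j + 1L]; hi <- edges[j + 2L]
    up <- (freqs - lo) / (ce - lo)
    dn <- (hi - freqs) / (hi - ce)
    fb[j, ] <- pmax(0, pmin(up, dn))
  }
  fb
}

new_features <- function(vectors, frame_times, kind) {
  stopifnot(nrow(vectors) == length(frame_times))
  if (any(!is.finite(vectors))) stop("non-finite feature values")
  structure(list(vectors = vectors, frame_times = frame_times,
                 feature_kind = kind),
            class = "alarm_features")
}

#' @export
print.alarm_features <- function(x, ...) {
  cat(sprintf("<alarm_features:%s> %d frames x %d dims\n", x$feature_kind,
              nrow(x$vectors), ncol(x$vectors)))
  invisible(x)
}
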