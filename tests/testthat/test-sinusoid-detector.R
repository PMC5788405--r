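fs <- 24000

test_that("peak features self-normalise and cancel the phase advance of a
           stationary bin-centred tone", {
  f0 <- 200 * fs / 4096
  w <- sin(2 * pi * f0 * (0:(fs - 1)) / fs)
  sp <- compute_spectrogram(w, fs, "rectangular", 2048, 1024, 2048)
  pf <- extract_peak_features(sp, 5, context = 6)
  expect_true(all(abs(pf$features[, 7] - 1) == 0))     # y1 centre element
  expect_true(all(pf$features[, 1:13] >= 0))
  i <- which(pf$bin == 201L)
  expect_lt(abs(pf$features[i, 13 + 7]), 1e-10)        # y2 centre ~ 0
  y2 <- pf$features[, 14:26]
  expect_true(all(y2 > -pi & y2 <= pi))
  expect_error(extract_peak_features(sp, 1), "no previous frame")
})

test_that("phase-continuity features disperse on noise peaks and
           concentrate on sinusoid peaks", {
  set.seed(21)
  w <- stats::rnorm(fs)
  sp <- compute_spectrogram(w, fs, "rectangular", 2048, 1024, 2048)
  pf <- do.call(rbind, lapply(2:22, function(l)
    extract_peak_features(sp, l)$features))
  y2n <- as.vector(pf[, 14:26])
  expect_gt(length(y2n), 1e4)
  # pooled over the context, noise phase differences are near-uniform on
  # (-pi, pi]: sd within a few percent of sqrt(pi^2/3). Exact uniformity
  # cannot hold at the peak bin itself: with 50% frame overlap the shared
  # samples correlate successive phases and pull the centre element
  # towards zero even for noise.
  expect_lt(abs(stats::sd(y2n) - pi / sqrt(3)), 0.06)
  # centre-element dispersion is still several times that of true
  # sinusoid peaks from the training corpus
  co <- synth_sinusoid_corpus(60, snr_db = -7, seed = 5)
  y2s <- c()
  for (ex in co$examples[vapply(co$examples, `[[`, logical(1), "is_sinusoid")]) {
    sps <- compute_spectrogram(ex$wave, fs, "rectangular", 2048, 1024, 2048)
    tb <- round(ex$freq * 4096 / fs) + 1L
    pt <- extract_peak_features(sps, 3)
    i <- which(abs(pt$bin - tb) <= 1L)
    if (length(i)) y2s <- c(y2s, pt$features[i, 13 + 7])
  }
  expect_gte(stats::var(pf[, 13 + 7]) / stats::var(y2s), 3)
})

test_that("trained peak models have the documented shape and separate
           held-out sinusoid peaks from noise", {
  pm <- get_peak_models()
  expect_equal(ncol(pm$lambda_s$means), 26L)           # 2*(2*6+1)
  expect_equal(length(pm$lambda_s$weights), 32L)
  expect_equal(sum(pm$lambda_s$weights), 1, tolerance = 1e-9)
  expect_equal(sum(pm$lambda_n$weights), 1, tolerance = 1e-9)
  co <- synth_sinusoid_corpus(30, snr_db = -7, seed = 555)
  lls <- c(); lln <- c()
  for (ex in co$examples[sapply(co$examples, `[[`, "is_sinusoid")]) {
    sp <- compute_spectrogram(ex$wave, fs, "rectangular", 2048, 1024, 2048)
    tb <- round(ex$freq * 4096 / fs) + 1L
    cp <- classify_peaks(sp, pm, bins = max(8, tb - 3):min(2042, tb + 3))
    lls <- c(lls, cp$llh_s); lln <- c(lln, cp$llh_n)
  }
  expect_gt(mean(lls), mean(lln))
})

test_that("peak scoring matches the closed-form Gaussian log-density and is
           order-independent", {
  g <- structure(list(weights = 1, means = matrix(0, 1, 26),
                      vars = matrix(1, 1, 26)), class = "diag_gmm")
  toy <- structure(list(lambda_s = g, lambda_n = g, M = 6L), class = "peak_models")
  s <- score_peak(matrix(0, 1, 26), toy)
  expect_equal(s$llh_s, -26 / 2 * log(2 * pi), tolerance = 1e-10)
  pm <- get_peak_models()
  set.seed(3)
  x <- cbind(matrix(abs(stats::rnorm(5 * 13)), 5), matrix(stats::runif(5 * 13, -3, 3), 5))
  batch <- score_peak(x, pm)
  single <- vapply(1:5, function(i) score_peak(x[i, , drop = FALSE], pm)$llh_s,
                   numeric(1))
  expect_equal(batch$llh_s, single, tolerance = 1e-12)
  expect_error(score_peak(matrix(0, 1, 10), pm), "dimension mismatch")
})

test_that("track detection finds one track per clean tone and applies the
           duration and energy filters", {
  pm <- get_peak_models()
  set.seed(2)
  n <- round(fs * 2.2)
  tone <- sin(2 * pi * 1000 * (0:(n - 1)) / fs)
  sp <- compute_spectrogram(tone + stats::rnorm(n) * 0.01, fs,
                            "rectangular", 2048, 1024, 2048)
  tr <- detect_sinusoid_tracks(sp, pm)
  expect_length(tr, 1L)
  expect_gte(tr[[1]]$offset - tr[[1]]$onset + 1L, 48L)
  expect_equal(stats::median(tr[[1]]$bins), 1000 * 4096 / fs + 1, tolerance = 1)
  # a 2-frame blip is removed by the 3-frame duration filter
  blip <- c(numeric(fs %/% 4), sin(2 * pi * 800 * (0:3071) / fs), numeric(fs %/% 4))
  spb <- compute_spectrogram(blip + stats::rnorm(length(blip)) * 0.01, fs,
                             "rectangular", 2048, 1024, 2048)
  expect_length(detect_sinusoid_tracks(spb, pm, min_frames = 3), 0L)
  # a tone 30 dB weaker (still clear of the strong tone's sidelobes) is
  # kept by a 40 dB energy floor and removed by a 20 dB one
  t2 <- sin(2 * pi * 2500 * (0:(n - 1)) / fs) * 10^(-30 / 20)
  sp2 <- compute_spectrogram(tone + t2 + stats::rnorm(n) * 1e-4, fs,
                             "rectangular", 2048, 1024, 2048)
  tr40 <- detect_sinusoid_tracks(sp2, pm, energy_floor_db = 40)
  expect_length(tr40, 2L)
  tr20 <- detect_sinusoid_tracks(sp2, pm, energy_floor_db = 20)
  expect_length(tr20, 1L)
  expect_equal(stats::median(tr20[[1]]$bins), 1000 * 4096 / fs + 1, tolerance = 1)
})

test_that("SD feature dimensions follow the mode and the normalised
           magnitudes sum to one", {
  pm <- get_peak_models()
  reg <- default_registry()
  cls <- reg[["a1"]]                                   # two frequencies
  set.seed(6)
  al <- synth_alarm(cls, 1, 3, fs)
  w <- al$wave + stats::rnorm(length(al$wave)) * 0.01
  sp <- compute_spectrogram(w, fs, "rectangular", 2048, 1024, 2048)
  expect_equal(ncol(extract_sd_features(sp, pm, cls, "ratio")$vectors), 2L)
  expect_equal(ncol(extract_sd_features(sp, pm, cls, "llh")$vectors), 4L)
  fa <- extract_sd_features(sp, pm, cls, "llh_amp")
  expect_equal(ncol(fa$vectors), 6L)
  amps <- fa$vectors[, 5:6]
  expect_equal(rowSums(amps), rep(1, nrow(amps)), tolerance = 1e-9)
  # doubling the waveform leaves the normalised magnitudes unchanged
  sp2 <- compute_spectrogram(2 * w, fs, "rectangular", 2048, 1024, 2048)
  fa2 <- extract_sd_features(sp2, pm, cls, "llh_amp")
  expect_lt(max(abs(fa2$vectors[, 5:6] - amps)), 1e-6)
})

test_that("single-tone frames concentrate the normalised magnitude in the
           tone's own region", {
  pm <- get_peak_models()
  cls <- alarm_class_spec("toy", list(list(
    tones = list(list(freqs = c(1000, 2000), duration = 1.0)), L_sil = 0.5)))
  set.seed(8)
  n <- fs
  w <- sin(2 * pi * 1000 * (0:(n - 1)) / fs) + stats::rnorm(n) * 0.01
  sp <- compute_spectrogram(w, fs, "rectangular", 2048, 1024, 2048)
  fa <- extract_sd_features(sp, pm, cls, "llh_amp")
  a1 <- mean(fa$vectors[3:20, 5])                      # region of 1000 Hz
  expect_gt(a1, 0.95)
})
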