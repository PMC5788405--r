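# Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

# The reference sinusoid/noise peak models (32 components, M = 6, -7 dB
# training SNR). Trained once; reused by detector and acceptance tests.
get_peak_models <- function() {
  if (is.null(.fixtures$pm))
    .fixtures$pm <- train_peak_models(rng_seed = 1L, n_examples = 400L)
  .fixtures$pm
}

# Event table for a synthetic soundscape: bursts of the three fixture
# classes, staggered in time, cycling through the given local SNRs.
fixture_events <- function(snrs, duration, gap = 40,
                           classes = c("a1", "a7", "a10"),
                           n_periods = 8L) {
  do.call(rbind, lapply(seq_along(classes), function(i) {
    st <- seq(2 + (i - 1) * 6, duration - 20, by = gap)
    data.frame(class_id = classes[i], version = 1L, start = st,
               n_periods = n_periods, snr_db = rep(snrs, length.out = length(st)))
  }))
}

fixture_scene <- function(snrs, duration, seed, background = "white", ...) {
  reg <- default_registry()
  sc <- render_scene(scene_spec(duration, fixture_events(snrs, duration, ...),
                                seed = seed,
                                background = list(kind = background,
                                                  level = 0.05)),
                     reg)
  list(outside = sc$outside, inside = sc$inside,
       annotations = sc$annotations, sample_rate = sc$sample_rate)
}

# A stationary tone in white noise at a given broadband SNR.
tone_in_noise <- function(freq, snr_db, n_samples, fs = 24000, amp = 1) {
  sigma <- amp / sqrt(2 * 10^(snr_db / 10))
  t <- (seq_len(n_samples) - 1) / fs
  amp * sin(2 * pi * freq * t) + stats::rnorm(n_samples, sd = sigma)
}

# Minimal hand-built spectrogram with constant per-bin magnitudes: used to
# test band-power arithmetic without audio in the way.
flat_spectrogram <- function(mag_by_bin, n_frames = 4, sample_rate = 24000,
                             dft_size = 4096) {
  structure(list(values = matrix(complex(modulus = mag_by_bin, argument = 0),
                                 nrow = length(mag_by_bin), ncol = n_frames),
                 sample_rate = sample_rate, frame_length = dft_size / 2,
                 hop = dft_size / 4, dft_size = dft_size,
                 window = "rectangular",
                 frame_times = (seq_len(n_frames) - 1) * (dft_size / 4) / sample_rate),
            class = "alarm_spectrogram")
}
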