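# Synthetic alarm registry, waveforms, and annotated soundscapes.
#
# Periodic equipment alarms are tone(s)-then-silence cycles: each period
# holds one signal interval (one or more consecutive stationary tones, each
# a sum of sinusoids) followed by a silence interval. Different device
# units play slightly shifted versions of the same class. The generator
# reproduces this structure, mixes alarms over broadband backgrounds at a
# requested per-alarm local SNR, and writes reference annotations, so the
# detection pipeline can be trained and scored without clinical recordings.

#' Construct an alarm class specification
#'
#' @param class_id Class identifier string (e.g. `"a1"`).
#' @param versions List of versions; each version is a list with `tones`
#'   (list of `list(freqs = <Hz vector>, duration = <s>)` played
#'   consecutively) and `L_sil` (silence interval, s). `L_sig` is the sum
#'   of tone durations and the period is `L_sig + L_sil`.
#' @return An `alarm_class_spec`.
#' @export
alarm_class_spec <- function(class_id, versions) {
  versions <- lapply(versions, function(v) {
    v$L_sig <- sum(vapply(v$tones, `[[`, numeric(1), "duration"))
    v$period <- v$L_sig + v$L_sil
    for (tn in v$tones) stopifnot(all(tn$freqs > 0))
    v
  })
  structure(list(class_id = class_id, versions = versions),
            class = "alarm_class_spec")
}

#' @export
print.alarm_class_spec <- function(x, ...) {
  v1 <- x$versions[[1L]]
  cat(sprintf("<alarm_class_spec %s> %d version(s), %d tone(s), f = {%s} Hz, period %.3g s\n",
              x$class_id, length(x$versions), length(v1$tones),
              paste(alarm_frequencies(x), collapse = ", "), v1$period))
  invisible(x)
}

#' Alarm-specific frequencies of a class
#'
#' @param cls An `alarm_class_spec`.
#' @param version Version index (default 1, the canonical version that
#'   defines the detection bands).
#' @return Sorted unique frequency vector in Hz.
#' @export
alarm_frequencies <- function(cls, version = 1L) {
  sort(unique(unlist(lapply(cls$versions[[version]]$tones, `[[`, "freqs"))))
}

version_shift <- function(v, df = 15, dd = 0.05) {
  v$tones <- lapply(v$tones, function(tn) {
    tn$freqs <- tn$freqs + df
    tn$duration <- tn$duration * (1 + dd)
    tn
  })
  v$L_sil <- v$L_sil * (1 + dd)
  v
}

#' Default synthetic alarm-class registry
#'
#' Seven classes (`a1, a3, a6, a7, a8, a10, a16`) with documented synthetic
#' placeholder frequencies and durations that encode the structural facts
#' of the alarm family: all classes are simple tone-silence except `a3`,
#' which plays two consecutive tones; `a16` has a single frequency that it
#' shares with `a1` and `a8`; `a6` has a short period; `a1`, `a3`, `a7`
#' and `a10` come in two device versions (+15 Hz, +5% durations). All
#' frequencies lie in 300-4000 Hz and distinct frequencies are at least
#' 100 Hz apart except for the deliberate shared one.
#'
#' @param config_file Optional YAML-free CSV/JSON override is not needed:
#'   pass a JSON file produced by [registry_to_json()] to replace the
#'   defaults entirely.
#' @return Named list of `alarm_class_spec` objects.
#' @export
default_registry <- function(config_file = NULL) {
  if (!is.null(config_file)) return(registry_from_json(config_file))
  base <- function(freqs, dur, sil)
    list(tones = list(list(freqs = freqs, duration = dur)), L_sil = sil)
  reg <- list(
    a1 = alarm_class_spec("a1", {
      v <- base(c(960, 1440), 0.5, 0.5); list(v, version_shift(v))
    }),
    a3 = alarm_class_spec("a3", {
      v <- list(tones = list(list(freqs = c(520, 780), duration = 0.25),
                             list(freqs = c(640, 1080), duration = 0.25)),
                L_sil = 1.0)
      list(v, version_shift(v))
    }),
    a6 = alarm_class_spec("a6", list(base(2800, 0.2, 0.3))),
    a7 = alarm_class_spec("a7", {
      v <- base(c(1800, 2250), 0.4, 0.8); list(v, version_shift(v))
    }),
    a8 = alarm_class_spec("a8", list(base(c(960, 1680), 0.3, 1.2))),
    a10 = alarm_class_spec("a10", {
      v <- base(3300, 0.6, 1.4); list(v, version_shift(v))
    }),
    a16 = alarm_class_spec("a16", list(base(960, 0.3, 0.7)))
  )
  reg
}

#' Serialise / load a registry as JSON
#'
#' @param registry Named list of `alarm_class_spec`s.
#' @param path JSON file path.
#' @export
registry_to_json <- function(registry, path) {
  plain <- lapply(registry, function(cls) {
    list(class_id = cls$class_id,
         versions = lapply(cls$versions, function(v)
           list(tones = lapply(v$tones, function(tn)
                  list(freqs = tn$freqs, duration = tn$duration)),
                L_sil = v$L_sil)))
  })
  jsonlite::write_json(plain, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname registry_to_json
#' @export
registry_from_json <- function(path) {
  plain <- jsonlite::read_json(path, simplifyVector = FALSE)
  reg <- lapply(plain, function(p) {
    alarm_class_spec(p$class_id, lapply(p$versions, function(v)
      list(tones = lapply(v$tones, function(tn)
             list(freqs = unlist(tn$freqs), duration = tn$duration)),
           L_sil = v$L_sil)))
  })
  names(reg) <- vapply(reg, `[[`, character(1), "class_id")
  reg
}

raised_cosine_ramp <- function(n_tone, n_ramp) {
  env <- rep(1, n_tone)
  if (n_ramp > 0L && n_tone >= 2L * n_ramp) {
    r <- 0.5 - 0.5 * cos(pi * seq_len(n_ramp) / n_ramp)
    env[seq_len(n_ramp)] <- r
    env[(n_tone - n_ramp + 1L):n_tone] <- rev(r)
  }
  env
}

#' Synthesise an alarm waveform
#'
#' Concatenates `n_periods` of the class's signal interval (each tone an
#' equal-phase sum of sinusoids with 10 ms raised-cosine onset/offset
#' ramps) followed by exact-zero silence.
#'
#' @param cls An `alarm_class_spec`.
#' @param version Version index.
#' @param n_periods Number of periods (>= 1).
#' @param sample_rate Sample rate in Hz.
#' @return List with `wave` (peak amplitude 1), `onsets_sec` (period-start
#'   timestamps), `signal_intervals` (`data.frame(onset_sec, offset_sec)`,
#'   one row per period) and the version's durations.
#' @export
synth_alarm <- function(cls, version = 1L, n_periods = 1L, sample_rate = 24000) {
  stopifnot(n_periods >= 1L, version >= 1L, version <= length(cls$versions))
  v <- cls$versions[[version]]
  nyq <- sample_rate / 2
  for (tn in v$tones) if (any(tn$freqs >= nyq)) stop("frequency out of band")
  n_ramp <- round(0.010 * sample_rate)
  tone_waves <- lapply(v$tones, function(tn) {
    n <- round(tn$duration * sample_rate)
    t <- (seq_len(n) - 1L) / sample_rate
    w <- rowSums(vapply(tn$freqs, function(f) sin(2 * pi * f * t),
                        numeric(n))) / length(tn$freqs)
    w * raised_cosine_ramp(n, n_ramp)
  })
  sig <- unlist(tone_waves)
  per <- c(sig, numeric(round(v$L_sil * sample_rate)))
  wave <- rep(per, n_periods)
  onsets <- (seq_len(n_periods) - 1L) * length(per) / sample_rate
  list(wave = wave, onsets_sec = onsets,
       signal_intervals = data.frame(onset_sec = onsets,
                                     offset_sec = onsets + length(sig) / sample_rate),
       L_sig = v$L_sig, L_sil = v$L_sil, period = v$period)
}

#' Scene specification
#'
#' @param duration Scene length in seconds.
#' @param events `data.frame` with columns `class_id`, `version`, `start`
#'   (s), `n_periods`, `snr_db` (target local SNR on the inside channel).
#' @param background List `kind` (`"white"`, `"pink"` or `"mixture"`) and
#'   `level` (waveform standard deviation).
#' @param seed Mandatory integer seed.
#' @param sample_rate Sample rate in Hz (default 24000).
#' @param channels Inside-channel model: `gain` and first-order low-pass
#'   cutoff `lowpass_hz` emulating incubator attenuation.
#' @return A `scene_spec` list.
#' @export
scene_spec <- function(duration, events, seed,
                       background = list(kind = "white", level = 0.05),
                       sample_rate = 24000,
                       channels = list(gain = 0.5, lowpass_hz = 2000)) {
  stopifnot(!missing(seed), is.finite(seed))
  stopifnot(all(events$start + 0 <= duration))
  structure(list(duration = duration, events = events, seed = as.integer(seed),
                 background = background, sample_rate = sample_rate,
                 channels = channels),
            class = "scene_spec")
}

pink_noise <- function(n) {
  x <- stats::rnorm(n)
  X <- stats::fft(x)
  f <- c(1, seq_len(n - 1L))
  f <- pmin(f, n - f + 1)           # symmetric for real output
  X <- X / sqrt(f)
  y <- Re(stats::fft(X, inverse = TRUE)) / n
  y / stats::sd(y)
}

synth_background <- function(kind, level, n, sample_rate) {
  w <- switch(kind,
    white = stats::rnorm(n),
    pink = pink_noise(n),
    mixture = {
      base <- 0.7 * pink_noise(n) + 0.7 * stats::rnorm(n)
      # occasional broadband transients to stress false-alarm behaviour
      n_tr <- max(1L, round(n / sample_rate / 10))
      for (i in seq_len(n_tr)) {
        at <- sample.int(n - sample_rate %/% 10, 1L)
        len <- sample_rate %/% 20
        burst <- stats::rnorm(len) * exp(-6 * seq_len(len) / len)
        base[at:(at + len - 1L)] <- base[at:(at + len - 1L)] + 3 * burst
      }
      # non-target tonal interference: short beeps at random frequencies,
      # emulating the many other tonal devices of a multisource clinical
      # soundscape (these defeat generic spectral features but not
      # band-restricted, class-specific ones)
      n_bp <- max(1L, round(n / sample_rate / 4))
      for (i in seq_len(n_bp)) {
        len <- round(stats::runif(1, 0.1, 0.5) * sample_rate)
        if (len + 1L >= n) next
        at <- sample.int(n - len, 1L)
        f0 <- stats::runif(1, 300, 4000)
        tt <- (seq_len(len) - 1L) / sample_rate
        beep <- sin(2 * pi * f0 * tt) * raised_cosine_ramp(len, round(0.01 * sample_rate))
        base[at:(at + len - 1L)] <- base[at:(at + len - 1L)] +
          stats::runif(1, 2, 6) * beep
      }
      base
    },
    stop("unknown background kind"))
  w * level / stats::sd(w)
}

inside_channel <- function(wave, channels, sample_rate) {
  bf <- signal::butter(1, channels$lowpass_hz / (sample_rate / 2), "low")
  channels$gain * as.numeric(signal::filter(bf, wave))
}

# Mean per-bin band power of a waveform over given bins, restricted (like
# the local-SNR measure) to frames whose start time falls inside one of the
# given [onset, offset) intervals.
band_power <- function(wave, sample_rate, bins, intervals = NULL,
                       window = "hann") {
  sp <- compute_spectrogram(wave, sample_rate, window, 2048L, 1024L, 2048L)
  frames <- seq_len(n_frames(sp))
  if (!is.null(intervals)) {
    tf <- sp$frame_times
    keep <- rep(FALSE, length(tf))
    for (i in seq_len(nrow(intervals)))
      keep <- keep | (tf >= intervals[i, 1] & tf < intervals[i, 2])
    if (any(keep)) frames <- which(keep)
  }
  mean(Mod(sp$values[bins, frames, drop = FALSE])^2)
}

#' Render a synthetic alarm scene
#'
#' Synthesises the background, scales every alarm event so that its local
#' SNR on the inside channel matches the requested target (closed-form
#' gain from the additive band powers of the filtered alarm and
#' background), mixes linearly, derives the inside-incubator channel
#' (gain + first-order low-pass), and emits per-signal-interval
#' annotations. Deterministic under the scene seed.
#'
#' @param spec A `scene_spec`.
#' @param registry Alarm-class registry (see [default_registry()]).
#' @return List with `outside`, `inside` (numeric waveforms),
#'   `sample_rate`, `annotations` (`data.frame`), and `manifest` (seed,
#'   per-event gains and predicted local SNRs).
#' @export
render_scene <- function(spec, registry) {
  fs <- spec$sample_rate
  n <- round(spec$duration * fs)
  with_rng(spec$seed, {
    bg <- synth_background(spec$background$kind, spec$background$level, n, fs)
    if (stats::sd(bg) == 0) stop("unsatisfiable SNR: zero background")
    bg_in <- inside_channel(bg, spec$channels, fs)
    outside <- bg
    ann <- list(); man <- list()
    for (i in seq_len(nrow(spec$events))) {
      ev <- spec$events[i, ]
      cls <- registry[[ev$class_id]]
      if (is.null(cls)) stop("unknown class: ", ev$class_id)
      al <- synth_alarm(cls, ev$version, ev$n_periods, fs)
      # snap onsets to the hop grid so annotation intervals align with frames
      at <- round(ev$start * fs / 1024) * 1024L
      ev$start <- at / fs
      len <- min(length(al$wave), n - at)
      if (len <= 0) next
      src <- numeric(n)
      src[at + seq_len(len)] <- al$wave[seq_len(len)]
      src_in <- inside_channel(src, spec$channels, fs)
      sig_spec0 <- compute_spectrogram(bg_in[1:min(n, fs)], fs, "hann",
                                       2048L, 1024L, 2048L)
      freqs_c <- alarm_frequencies(cls, ev$version)
      sig_bins <- sort(unique(unlist(lapply(freqs_c, region_bins,
                                            tolerance = 20, spec = sig_spec0))))
      bf <- bin_frequencies(sig_spec0)
      noise_bins <- integer(0)
      for (f in freqs_c)
        noise_bins <- c(noise_bins, which((bf >= f - 120 & bf < f - 20) |
                                          (bf > f + 20 & bf <= f + 120)))
      noise_bins <- setdiff(sort(unique(noise_bins)), sig_bins)
      seg <- (at + 1L):min(n, at + len)
      ivals <- as.matrix(al$signal_intervals)
      B <- band_power(bg_in[seg], fs, sig_bins, ivals)
      C <- band_power(bg_in[seg], fs, noise_bins, ivals)
      # inside-channel alarm band power and its leakage into the noise bands
      A_in <- band_power(src_in[seg], fs, sig_bins, ivals)
      D_in <- band_power(src_in[seg], fs, noise_bins, ivals)
      rho <- db_to_pow(ev$snr_db)
      denom <- A_in - rho * D_in
      if (denom <= 0)
        stop("unsatisfiable local SNR target for class ", ev$class_id,
             " (alarm leakage into the flanking noise bands dominates)")
      g2 <- (rho * C - B) / denom
      g <- sqrt(max(g2, 1e-12))
      outside <- outside + g * src
      pred <- pow_to_db((max(g2, 0) * A_in + B) / (C + max(g2, 0) * D_in))
      ann[[i]] <- data.frame(
        onset_sec = ev$start + al$signal_intervals$onset_sec,
        offset_sec = ev$start + al$signal_intervals$offset_sec,
        class_id = ev$class_id, version = ev$version)
      man[[i]] <- data.frame(class_id = ev$class_id, version = ev$version,
                             start = ev$start, target_snr_db = ev$snr_db,
                             gain = g, predicted_snr_db = pred,
                             inside_band_power = g^2 * A_in)
    }
    inside <- inside_channel(outside, spec$channels, fs)
    annotations <- if (length(ann)) do.call(rbind, ann) else
      data.frame(onset_sec = numeric(0), offset_sec = numeric(0),
                 class_id = character(0), version = integer(0))
    annotations <- annotations[annotations$onset_sec < spec$duration, , drop = FALSE]
    list(outside = outside, inside = inside, sample_rate = fs,
         annotations = annotations,
         manifest = list(seed = spec$seed,
                         background = spec$background,
                         events = if (length(man)) do.call(rbind, man) else NULL))
  })
}

#' Synthesise a sinusoid-detection training corpus
#'
#' Random-frequency stationary sinusoids in white noise at a fixed
#' broadband SNR (positive examples) and noise-only segments (negative
#' examples). Frequencies are drawn log-uniformly in (80 Hz, 11 kHz),
#' amplitudes uniformly in [0.1, 1].
#'
#' @param n_examples Total number of examples (half sinusoid, half noise).
#' @param snr_db Broadband SNR of the sinusoid examples (default -7 dB).
#' @param sample_rate Sample rate in Hz.
#' @param seed Integer seed.
#' @param frame_length,hop Analysis geometry used to size each example.
#' @param example_frames Frames per example (default 10).
#' @return List with `examples` (each `list(wave, freq, amp, is_sinusoid)`;
#'   `freq` is `NA` for noise examples), and the generation parameters.
#' @export
synth_sinusoid_corpus <- function(n_examples, snr_db = -7, sample_rate = 24000,
                                  seed = 1L, frame_length = 2048L, hop = 1024L,
                                  example_frames = 10L) {
  stopifnot(n_examples >= 1L)
  n_samp <- (example_frames - 1L) * hop + frame_length
  n_sin <- ceiling(n_examples / 2)
  with_rng(seed, {
    examples <- vector("list", n_examples)
    for (i in seq_len(n_examples)) {
      is_sin <- i <= n_sin
      amp <- stats::runif(1, 0.1, 1)
      sigma <- amp / sqrt(2 * db_to_pow(snr_db))
      noise <- stats::rnorm(n_samp, sd = sigma)
      if (is_sin) {
        freq <- exp(stats::runif(1, log(80), log(11000)))
        ph <- stats::runif(1, 0, 2 * pi)
        t <- (seq_len(n_samp) - 1L) / sample_rate
        wave <- amp * sin(2 * pi * freq * t + ph) + noise
      } else {
        freq <- NA_real_
        wave <- noise
      }
      examples[[i]] <- list(wave = wave, freq = freq, amp = amp,
                            is_sinusoid = is_sin)
    }
    list(examples = examples, snr_db = snr_db, sample_rate = sample_rate,
         frame_length = frame_length, hop = hop, seed = seed)
  })
}
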