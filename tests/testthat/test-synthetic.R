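fs <- 24000

test_that("the default registry encodes the alarm family's structure", {
  reg <- default_registry()
  expect_setequal(names(reg), c("a1", "a3", "a6", "a7", "a8", "a10", "a16"))
  # only a3 has several consecutive tones
  n_tones <- vapply(reg, function(c) length(c$versions[[1]]$tones), integer(1))
  expect_equal(n_tones[["a3"]], 2L)
  expect_true(all(n_tones[setdiff(names(reg), "a3")] == 1L))
  # a16's single frequency is shared with a1 and a8
  f16 <- alarm_frequencies(reg$a16)
  expect_length(f16, 1L)
  expect_true(f16 %in% alarm_frequencies(reg$a1))
  expect_true(f16 %in% alarm_frequencies(reg$a8))
  # a6 has the shortest period
  periods <- vapply(reg, function(c) c$versions[[1]]$period, numeric(1))
  expect_equal(names(which.min(periods)), "a6")
  # structural invariants on every version
  for (cls in reg) for (v in cls$versions) {
    expect_equal(v$L_sig + v$L_sil, v$period, tolerance = 1e-3)
    expect_equal(v$L_sig, sum(vapply(v$tones, `[[`, numeric(1), "duration")))
    for (tn in v$tones) expect_true(all(tn$freqs > 0 & tn$freqs < 12000))
  }
  # versioned classes
  n_ver <- vapply(reg, function(c) length(c$versions), integer(1))
  expect_true(all(n_ver[c("a1", "a3", "a7", "a10")] == 2L))
})

test_that("registry JSON round-trips", {
  reg <- default_registry()
  f <- tempfile(fileext = ".json")
  registry_to_json(reg, f)
  back <- default_registry(config_file = f)
  expect_setequal(names(back), names(reg))
  expect_equal(alarm_frequencies(back$a3), alarm_frequencies(reg$a3))
  expect_equal(back$a6$versions[[1]]$period, reg$a6$versions[[1]]$period)
})

test_that("synthesised alarms have exact period structure and silence", {
  reg <- default_registry()
  al <- synth_alarm(reg$a7, 1, 3, fs)
  expect_length(al$onsets_sec, 3L)
  expect_equal(diff(al$onsets_sec), rep(reg$a7$versions[[1]]$period, 2),
               tolerance = 1e-6)
  # silence intervals are exactly zero
  sil_start <- round((al$onsets_sec[1] + al$L_sig) * fs) + 1
  sil_end <- round(al$onsets_sec[2] * fs)
  expect_true(all(al$wave[sil_start:sil_end] == 0))
  expect_lte(max(abs(al$wave)), 1)
  expect_error(synth_alarm(alarm_class_spec("bad", list(list(
    tones = list(list(freqs = 13000, duration = 0.2)), L_sil = 0.3))), 1, 1, fs),
    "frequency out of band")
})

test_that("alarm energy concentrates in the class's frequency bands", {
  reg <- default_registry()
  al <- synth_alarm(reg$a1, 1, 2, fs)
  sp <- compute_spectrogram(al$wave, fs, "hann", 2048, 1024, 0)
  fr <- 3:8                                        # interior tone frames
  pow <- Mod(sp$values[, fr])^2
  bins <- unlist(lapply(alarm_frequencies(reg$a1), region_bins,
                        tolerance = 20, spec = sp))
  expect_gte(sum(pow[bins, ]) / sum(pow), 0.99)
})

test_that("the sinusoid corpus hits its broadband SNR and label contract", {
  co <- synth_sinusoid_corpus(40, snr_db = -7, seed = 5)
  is_sin <- vapply(co$examples, `[[`, logical(1), "is_sinusoid")
  expect_true(any(is_sin) && any(!is_sin))
  for (ex in co$examples[is_sin][1:10]) {
    t <- (seq_along(ex$wave) - 1) / fs
    tone <- ex$amp * sin(2 * pi * ex$freq * t)     # reconstruct numerator
    noise <- ex$wave - tone
    snr <- 10 * log10(mean(tone^2) / mean(noise^2))
    expect_equal(snr, -7, tolerance = 0.5)
    expect_gt(ex$freq, 80); expect_lt(ex$freq, 11000)
  }
  expect_true(all(is.na(vapply(co$examples[!is_sin], `[[`, numeric(1), "freq"))))
})

test_that("rendered scenes hit the requested local SNR within a dB and are
           deterministic", {
  reg <- default_registry()
  ev <- data.frame(class_id = c("a1", "a7"), version = 1L,
                   start = c(2, 10), n_periods = c(6L, 5L), snr_db = c(10, 18))
  sc <- render_scene(scene_spec(22, ev, seed = 77), reg)
  spi <- compute_spectrogram(sc$inside, fs, "hann", 2048, 1024, 2048)
  for (cid in c("a1", "a7")) {
    rows <- sc$annotations[sc$annotations$class_id == cid, ]
    snrs <- apply(rows, 1, function(r)
      local_snr(spi, as.numeric(r[1:2]), reg[[cid]]))
    expect_equal(mean(snrs), ev$snr_db[ev$class_id == cid], tolerance = 1)
  }
  sc2 <- render_scene(scene_spec(22, ev, seed = 77), reg)
  expect_identical(sc$outside, sc2$outside)
  expect_identical(sc$inside, sc2$inside)
  expect_identical(sc$annotations, sc2$annotations)
})

test_that("overlapping alarms mix linearly and are all annotated", {
  reg <- default_registry()
  e1 <- data.frame(class_id = "a1", version = 1L, start = 2, n_periods = 4L,
                   snr_db = 15)
  e2 <- data.frame(class_id = "a7", version = 1L, start = 3, n_periods = 3L,
                   snr_db = 15)
  s0 <- render_scene(scene_spec(12, e1[0, ], seed = 9), reg)   # background only
  s1 <- render_scene(scene_spec(12, e1, seed = 9), reg)
  s2 <- render_scene(scene_spec(12, e2, seed = 9), reg)
  s12 <- render_scene(scene_spec(12, rbind(e1, e2), seed = 9), reg)
  expect_setequal(unique(s12$annotations$class_id), c("a1", "a7"))
  expect_equal(s12$outside, s1$outside + s2$outside - s0$outside,
               tolerance = 1e-12)
})

test_that("WAV files round-trip scenes", {
  set.seed(10)
  w <- stats::runif(2000, -0.9, 0.9)         # inside the PCM16 full scale
  f <- tempfile(fileext = ".wav")
  write_wav(w, f, fs, bits = 16L)
  back <- read_wav(f)
  expect_equal(attr(back, "sample_rate"), fs)
  expect_lt(max(abs(as.numeric(back) - w)), 1e-4)    # 16-bit quantisation
  write_wav(w, f, fs, bits = 32L)
  expect_lt(max(abs(as.numeric(read_wav(f)) - w)), 1e-6)
  expect_warning(read_wav(f, sample_rate = 16000), "resampling")
})
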