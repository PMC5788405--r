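test_that("frame metrics are exact count ratios with degenerate cases", {
  r <- c(1, 1, 0, 0); h <- r
  m <- frame_metrics(r, h)
  expect_equal(m$mr, 0); expect_equal(m$far, 0)
  m2 <- frame_metrics(r, rep(1, 4))
  expect_equal(m2$mr, 0); expect_equal(m2$far, 1)
  ref <- c(rep(1, 100), rep(0, 900))
  hyp <- c(rep(1, 90), rep(0, 10), rep(1, 9), rep(0, 891))
  m3 <- frame_metrics(ref, hyp)
  expect_equal(m3$mr, 0.10)
  expect_equal(m3$far, 0.01)
  expect_equal(m3$counts, list(n_alarm = 100L, n_nonalarm = 900L,
                               n_miss = 10L, n_false_alarm = 9L))
  expect_true(is.na(frame_metrics(rep(0, 5), rep(0, 5))$mr))
  expect_error(frame_metrics(1:3 * 0, 1:4 * 0), "length mismatch")
})

test_that("the DET curve equals brute-force per-threshold counting and has
           monotone error rates", {
  set.seed(1)
  sc <- stats::rnorm(1000); y <- rep(c(1, 0), 500)
  sc[y == 1] <- sc[y == 1] + 1
  dc <- det_curve(sc, y)
  for (i in sample(nrow(dc), 20)) {
    t <- dc$threshold[i]
    expect_equal(dc$mr[i], mean(sc[y == 1] <= t))
    expect_equal(dc$far[i], mean(sc[y == 0] > t))
  }
  expect_true(all(diff(dc$mr) >= 0))
  expect_true(all(diff(dc$far) <= 0))
  expect_equal(sum(dc$eer_point), 1L)
  expect_equal(dc$mr[1], 0); expect_equal(dc$far[1], 1)   # below min score
  expect_equal(dc$mr[nrow(dc)], 1); expect_equal(dc$far[nrow(dc)], 0)
  # perfectly separated scores reach (0, 0)
  dp <- det_curve(c(1, 1, 0, 0), c(1, 1, 0, 0))
  expect_true(any(dp$mr == 0 & dp$far == 0))
  expect_error(det_curve(1:4, rep(1, 4)), "single class")
})

test_that("PB-ERR follows the F1 complement with one-to-one matching", {
  expect_equal(pb_err(c(5L, 20L), c(5L, 20L), 3, 15)$pb_err, 0)
  expect_equal(pb_err(c(5L, 20L, 40L), c(6L, 21L, 60L), 3, 15)$pb_err,
               1 - 4 / 6, tolerance = 1e-12)          # Nc=2, Nm=1, Nfa=1
  expect_equal(pb_err(c(5L, 20L), integer(0), 3, 15)$pb_err, 1)
  expect_equal(pb_err(integer(0), integer(0), 3, 15)$pb_err, 0)
  expect_error(pb_err(1L, 1L, 8, 15), "half-period constraint")
  # with T_tol < period/2 a hypothesis never serves two references
  set.seed(2)
  for (i in 1:10) {
    period <- sample(10:30, 1); tol <- sample.int(floor(period / 2) - 1, 1)
    ref <- sort(sample.int(200, 8)) * 1L
    hyp <- sort(sample.int(200, 8)) * 1L
    ct <- pb_err(ref, hyp, tol, period)$counts
    expect_lte(ct$n_correct, min(length(ref), length(hyp)))
    expect_equal(ct$n_correct + ct$n_miss, length(ref))
    expect_equal(ct$n_correct + ct$n_false_alarm, length(hyp))
  }
})

test_that("PB-ERR is non-increasing in the matching tolerance", {
  set.seed(3)
  ref <- cumsum(sample(15:25, 10, replace = TRUE))
  hyp <- ref + sample(-6:6, 10, replace = TRUE)
  errs <- vapply(1:7, function(tol) pb_err(ref, hyp, tol, 16)$pb_err, numeric(1))
  expect_true(all(diff(errs) <= 0))
})

test_that("local SNR reproduces known band-power ratios", {
  cls <- alarm_class_spec("toy", list(list(
    tones = list(list(freqs = 1000, duration = 0.5)), L_sil = 0.5)))
  nb <- 2049
  mag <- rep(2, nb)                                # flat noise floor
  sp0 <- flat_spectrogram(mag)
  expect_equal(local_snr(sp0, c(0, 0.2), cls), 0, tolerance = 1e-9)
  sig_bins <- region_bins(1000, 20, sp0)
  mag10 <- mag; mag10[sig_bins] <- 2 * sqrt(10)    # 10x the power
  expect_equal(local_snr(flat_spectrogram(mag10), c(0, 0.2), cls), 10,
               tolerance = 1e-9)
  magz <- 0 * mag; magz[sig_bins] <- 1
  expect_warning(s <- local_snr(flat_spectrogram(magz), c(0, 0.2), cls),
                 "zero noise power")
  expect_equal(s, 120)
})

test_that("annotations round-trip through CSV to the millisecond", {
  ann <- data.frame(onset_sec = c(1.2345, 7.89), offset_sec = c(1.7345, 8.49),
                    class_id = c("a1", "a7"), version = c(1L, 2L))
  f <- tempfile(fileext = ".csv")
  write_annotations(ann, f)
  back <- read_annotations(f)
  expect_equal(back$onset_sec, ann$onset_sec, tolerance = 1e-3)
  expect_equal(back$offset_sec, ann$offset_sec, tolerance = 1e-3)
  expect_equal(back$class_id, ann$class_id)
})

test_that("frame labels and reference events derive from annotations at hop
           resolution", {
  ann <- data.frame(onset_sec = 1024 * 5 / 24000, offset_sec = 1024 * 8 / 24000,
                    class_id = "a1", version = 1L)
  y <- annotation_frame_labels(ann, "a1", 12, 1024, 24000)
  expect_equal(which(y == 1L), 6:8)                # frames starting inside
  ev <- annotation_events(ann, "a1", 1024, 24000)
  expect_equal(ev$timestamps, 6L)
  expect_equal(ev$kind, "reference")
})
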