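# Frame-level and period-level evaluation, local SNR, annotations.

#' Frame-level missing and false-alarm rates
#'
#' `MR = N_M / N_A` (missed alarm frames over alarm frames) and
#' `FAR = N_FA / N_NA` (false-alarm frames over non-alarm frames). A rate
#' whose denominator is zero is reported as `NA`.
#'
#' @param ref,hyp Binary per-frame label vectors of equal length (1 = alarm).
#' @return List with `mr`, `far` and `counts`
#'   (`n_alarm`, `n_nonalarm`, `n_miss`, `n_false_alarm`).
#' @export
frame_metrics <- function(ref, hyp) {
  r <- as.integer(ref); h <- as.integer(hyp)
  if (length(r) != length(h)) stop("ref and hyp length mismatch")
  n_a <- sum(r == 1L); n_na <- sum(r == 0L)
  n_m <- sum(r == 1L & h == 0L); n_fa <- sum(r == 0L & h == 1L)
  list(mr = if (n_a > 0L) n_m / n_a else NA_real_,
       far = if (n_na > 0L) n_fa / n_na else NA_real_,
       counts = list(n_alarm = n_a, n_nonalarm = n_na,
                     n_miss = n_m, n_false_alarm = n_fa))
}

#' Detection error tradeoff curve
#'
#' One operating point per distinct score (thresholds at midpoints between
#' consecutive distinct scores plus one beyond each extreme); frames scoring
#' strictly above the threshold are called alarms. The point closest to
#' equal error (`|MR - FAR|` minimal) is flagged.
#'
#' @param scores Numeric per-frame scores (larger = more alarm-like).
#' @param ref Binary reference labels.
#' @return `data.frame` with columns `threshold`, `mr`, `far`, `eer_point`.
#' @export
det_curve <- function(scores, ref) {
  y <- as.integer(ref)
  if (length(unique(y)) < 2L) stop("cannot compute DET curve for a single class")
  s <- sort(unique(scores))
  cand <- if (length(s) == 1L) c(s - 1, s + 1)
          else c(s[1L] - 1, (s[-1L] + s[-length(s)]) / 2, s[length(s)] + 1)
  sa <- sort(scores[y == 1L]); sn <- sort(scores[y == 0L])
  mr <- findInterval(cand, sa) / length(sa)
  far <- 1 - findInterval(cand, sn) / length(sn)
  d <- abs(mr - far)
  data.frame(threshold = cand, mr = mr, far = far,
             eer_point = seq_along(cand) == which.min(d))
}

#' Period-based error rate (PB-ERR)
#'
#' `PB-ERR = 1 - F1 = 1 - 2 N_C / (2 N_C + N_FA + N_M)` over alarm-period
#' events. References are scanned chronologically and each is matched
#' one-to-one to the earliest unmatched hypothesis within
#' `[T_ref - T_tol, T_ref + T_tol]`. `T_tol` must be smaller than half the
#' alarm period, which guarantees no hypothesis can serve two references.
#'
#' @param ref,hyp `event_set`s (or sorted timestamp vectors), reference and
#'   hypothesis period starts in frames.
#' @param T_tol Matching tolerance in frames.
#' @param period_frames Alarm period duration in frames.
#' @return List with `pb_err` and `counts`
#'   (`n_correct`, `n_miss`, `n_false_alarm`, `t_tol`).
#' @export
pb_err <- function(ref, hyp, T_tol, period_frames) {
  if (T_tol >= period_frames / 2) stop("tolerance violates half-period constraint")
  r <- event_times(ref); h <- event_times(hyp)
  matched <- rep(FALSE, length(h))
  n_c <- 0L
  for (t in r) {
    ok <- which(!matched & abs(h - t) <= T_tol)
    if (length(ok) > 0L) {
      matched[ok[1L]] <- TRUE
      n_c <- n_c + 1L
    }
  }
  n_m <- length(r) - n_c
  n_fa <- length(h) - n_c
  err <- if (n_c + n_m + n_fa == 0L) 0 else 1 - 2 * n_c / (2 * n_c + n_fa + n_m)
  list(pb_err = err,
       counts = list(n_correct = n_c, n_miss = n_m, n_false_alarm = n_fa,
                     t_tol = T_tol))
}

#' Local signal-to-noise ratio of an annotated alarm interval
#'
#' Signal power is the mean per-bin power over the class's alarm-specific
#' bands (every `f_b +/- delta`) across the interval's frames; noise power
#' is the mean per-bin power over the 100 Hz bands flanking each signal
#' band (signal bins of any band of the class are excluded from noise
#' bands). `SNR = 10 log10(P_signal / P_noise)` in dB.
#'
#' @param spec An `alarm_spectrogram` (inside-incubator channel when
#'   available). A Hann-windowed spectrogram is recommended: the
#'   rectangular window's sidelobes leak alarm power into the flanking
#'   noise bands and bias the measure low.
#' @param interval Numeric `c(onset_sec, offset_sec)` of one alarm signal
#'   interval.
#' @param cls An `alarm_class_spec`.
#' @param delta Signal-band half width in Hz (default 20).
#' @param noise_width Width of each flanking noise band in Hz (default 100).
#' @return Local SNR in dB (capped at +120 when the noise power is zero).
#' @export
local_snr <- function(spec, interval, cls, delta = 20, noise_width = 100) {
  freqs_c <- alarm_frequencies(cls)
  bf <- bin_frequencies(spec)
  sig_bins <- sort(unique(unlist(lapply(freqs_c, region_bins, tolerance = delta,
                                        spec = spec))))
  noise_bins <- integer(0)
  for (f in freqs_c) {
    lo1 <- f - delta - noise_width; hi1 <- f - delta
    lo2 <- f + delta; hi2 <- f + delta + noise_width
    noise_bins <- c(noise_bins,
                    which(bf >= lo1 & bf < hi1), which(bf > lo2 & bf <= hi2))
  }
  noise_bins <- setdiff(sort(unique(noise_bins)), sig_bins)
  if (length(sig_bins) == 0L || length(noise_bins) == 0L)
    stop("empty signal or noise band")
  tf <- spec$frame_times
  fr <- which(tf >= interval[1] & tf < interval[2])
  if (length(fr) == 0L) fr <- which.min(abs(tf - interval[1]))
  pow <- Mod(spec$values[, fr, drop = FALSE])^2
  p_sig <- mean(pow[sig_bins, ])
  p_noise <- mean(pow[noise_bins, ])
  if (p_noise <= 0) {
    warning("zero noise power; SNR capped at +120 dB")
    return(120)
  }
  min(pow_to_db(p_sig / p_noise), 120)
}

#' Read / write alarm annotations
#'
#' Annotations are CSV label files with one row per alarm signal interval
#' and columns `onset_sec`, `offset_sec`, `class_id`, `version`.
#'
#' @param path CSV file path.
#' @return `read_annotations`: a `data.frame` with the four columns.
#' @export
read_annotations <- function(path) {
  ann <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("onset_sec", "offset_sec", "class_id", "version")
  if (!all(need %in% names(ann))) stop("annotation file missing columns")
  ann[need]
}

#' @rdname read_annotations
#' @param ann Annotation `data.frame`.
#' @export
write_annotations <- function(ann, path) {
  utils::write.csv(ann, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Frame labels and reference events from annotations
#'
#' Frame `l` (start time `(l-1) * hop / fs`) is labelled alarm when its
#' start time falls in a half-open annotated interval `[onset, offset)` of
#' the class. Reference period timestamps are the annotated signal-interval
#' onsets rounded to the nearest frame.
#'
#' @param ann Annotation `data.frame` (see [read_annotations()]).
#' @param class_id Alarm class to extract.
#' @param n_frames Total number of frames.
#' @param hop,sample_rate Frame hop (samples) and sample rate (Hz).
#' @return `annotation_frame_labels`: binary vector of length `n_frames`.
#' @export
annotation_frame_labels <- function(ann, class_id, n_frames, hop, sample_rate) {
  t0 <- (seq_len(n_frames) - 1L) * hop / sample_rate
  y <- integer(n_frames)
  rows <- ann[ann$class_id == class_id, , drop = FALSE]
  for (i in seq_len(nrow(rows)))
    y[t0 >= rows$onset_sec[i] & t0 < rows$offset_sec[i]] <- 1L
  y
}

#' @rdname annotation_frame_labels
#' @return `annotation_events`: a reference `event_set` of period-start
#'   frames.
#' @export
annotation_events <- function(ann, class_id, hop, sample_rate) {
  rows <- ann[ann$class_id == class_id, , drop = FALSE]
  ts <- sort(unique(as.integer(round(rows$onset_sec * sample_rate / hop)) + 1L))
  new_event_set(ts, class_id, "reference")
}
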