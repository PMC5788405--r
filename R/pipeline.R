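# Orchestration: one independent detector per alarm class, run in parallel
# over the same audio; training, detection, evaluation and experiment grids.

#' Pipeline run configuration
#'
#' @param feature One of `"sd_llh_amp"`, `"sd_llh"`, `"sd_ratio"`,
#'   `"ff_lfbe"`, `"nmf"`.
#' @param classifier `"gmm"` or `"nn"`.
#' @param post Post-processing: `"none"`, `"smooth"`, `"temporal"` or
#'   `"smooth+temporal"`.
#' @param sample_rate Working rate, Hz.
#' @param frame_length,hop Analysis frame length and hop in samples.
#' @param zero_pad Zero-padding for the sinusoid-detection DFT.
#' @param delta Alarm-band tolerance in Hz.
#' @param n_mel Mel filters for the baseline features.
#' @param nmf List of NMF settings (`R_alarm`, `R_nonalarm`, `beta`,
#'   `n_iters`).
#' @param nn_hp Neural-net hyperparameters ([nn_hyperparameters()]).
#' @param t_tol_frac Period-matching tolerance as a fraction of the period
#'   (default 0.49).
#' @param seed Integer seed for all stochastic stages.
#' @return An `alarm_config` list.
#' @export
alarm_config <- function(feature = c("sd_llh_amp", "sd_llh", "sd_ratio",
                                     "ff_lfbe", "nmf"),
                         classifier = c("gmm", "nn"),
                         post = c("smooth+temporal", "none", "smooth",
                                  "temporal"),
                         sample_rate = 24000, frame_length = 2048L,
                         hop = 1024L, zero_pad = 2048L, delta = 20,
                         n_mel = 18L,
                         nmf = list(R_alarm = 4L, R_nonalarm = 15L,
                                    beta = 1, n_iters = 20L),
                         nn_hp = nn_hyperparameters(),
                         t_tol_frac = 0.49, seed = 1L) {
  structure(list(feature = match.arg(feature),
                 classifier = match.arg(classifier), post = match.arg(post),
                 sample_rate = sample_rate, frame_length = frame_length,
                 hop = hop, zero_pad = zero_pad, delta = delta,
                 n_mel = n_mel, nmf = nmf, nn_hp = nn_hp,
                 t_tol_frac = t_tol_frac, seed = as.integer(seed)),
            class = "alarm_config")
}

uses_sd <- function(config) startsWith(config$feature, "sd_")

# Attach the spectrograms a config needs to a session (wave + annotations).
prepare_session <- function(session, config) {
  if (uses_sd(config) && is.null(session$spec_sd))
    session$spec_sd <- compute_spectrogram(session$outside, config$sample_rate,
                                           "rectangular", config$frame_length,
                                           config$hop, config$zero_pad)
  if (config$feature %in% c("ff_lfbe", "nmf") && is.null(session$spec_hann))
    session$spec_hann <- compute_spectrogram(session$outside, config$sample_rate,
                                             "hann", config$frame_length,
                                             config$hop, 0L)
  session
}

session_frames <- function(session, config) {
  sp <- session$spec_sd %||% session$spec_hann
  n_frames(sp)
}

class_period_frames <- function(cls, config) {
  v <- cls$versions[[1L]]
  fs <- config$sample_rate
  list(L_sig = max(1L, as.integer(round(v$L_sig * fs / config$hop))),
       L_sil = max(1L, as.integer(round(v$L_sil * fs / config$hop))),
       period = max(2L, as.integer(round(v$period * fs / config$hop))))
}

class_band_bins <- function(cls, spec, delta) {
  sort(unique(unlist(lapply(alarm_frequencies(cls), region_bins,
                            tolerance = delta, spec = spec))))
}

# Frame features of one class for one prepared session.
class_features <- function(session, config, cls, models) {
  switch(config$feature,
    ff_lfbe = compute_ff_lfbe(session$spec_hann, config$n_mel),
    nmf = {
      model <- models$nmf[[cls$class_id]]
      if (is.null(model)) stop("missing trained NMF bases for class ",
                               cls$class_id, "; run train_nmf_models() first")
      bands <- class_band_bins(cls, session$spec_hann, config$delta)
      acts <- infer_activations(Mod(session$spec_hann$values[bands, , drop = FALSE]),
                                model, rng_seed = config$seed)
      extract_nmf_features(acts, model, session$spec_hann$frame_times)
    },
    {
      if (is.null(models$peak)) stop("missing peak models; run train_peak_models() first")
      mode <- sub("^sd_", "", config$feature)
      extract_sd_features(session$spec_sd, models$peak, cls, mode = mode,
                          delta = config$delta)
    })
}

#' Train per-class NMF bases over training sessions
#'
#' Alarm bases are fitted on the class's annotated signal-interval frames,
#' non-alarm bases on frames free of any alarm, both restricted to the
#' class's frequency bands.
#'
#' @param sessions List of sessions (`list(outside, annotations, ...)`).
#' @param registry Alarm-class registry.
#' @param config An `alarm_config` with `feature = "nmf"`.
#' @param max_frames Cap on frames per training matrix.
#' @return Named list of `nmf_model`s, one per class.
#' @export
train_nmf_models <- function(sessions, registry, config, max_frames = 3000L) {
  sessions <- lapply(sessions, prepare_session,
                     config = utils::modifyList(config, list(feature = "nmf")))
  models <- list()
  for (cls in registry) {
    al <- list(); na <- list()
    bands <- NULL
    for (s in sessions) {
      sp <- s$spec_hann
      bands <- class_band_bins(cls, sp, config$delta)
      T <- n_frames(sp)
      y_cls <- annotation_frame_labels(s$annotations, cls$class_id, T,
                                       config$hop, config$sample_rate)
      y_any <- integer(T)
      for (cid in unique(s$annotations$class_id))
        y_any <- pmax(y_any, annotation_frame_labels(s$annotations, cid, T,
                                                     config$hop, config$sample_rate))
      mag <- Mod(sp$values[bands, , drop = FALSE])
      if (any(y_cls == 1L)) al[[length(al) + 1L]] <- mag[, y_cls == 1L, drop = FALSE]
      if (any(y_any == 0L)) na[[length(na) + 1L]] <- mag[, y_any == 0L, drop = FALSE]
    }
    A <- do.call(cbind, al); N <- do.call(cbind, na)
    if (is.null(A) || is.null(N)) {
      warning("class ", cls$class_id, " lacks training frames; skipped")
      next
    }
    cap <- function(m) if (ncol(m) > max_frames)
      m[, round(seq(1, ncol(m), length.out = max_frames)), drop = FALSE] else m
    models[[cls$class_id]] <- train_nmf_bases(
      cap(A), cap(N), R_alarm = config$nmf$R_alarm,
      R_nonalarm = config$nmf$R_nonalarm, beta = config$nmf$beta,
      n_iters = config$nmf$n_iters, rng_seed = config$seed,
      band_bins = bands)
  }
  models
}

#' Train the per-class alarm detectors
#'
#' For every registry class: extracts the configured features over all
#' training sessions, fits the configured frame classifier, selects the
#' frame decision threshold by the equal-error-rate criterion on training
#' scores and, when the temporal model is in use, sweeps the class-specific
#' period-curve threshold to minimise PB-ERR on the training sessions.
#'
#' @param sessions List of training sessions.
#' @param registry Alarm-class registry.
#' @param config An `alarm_config`.
#' @param models List with `peak` ([train_peak_models()]) and/or `nmf`
#'   ([train_nmf_models()]) as the feature mode requires.
#' @return An `alarm_detectors` object.
#' @export
train_detectors <- function(sessions, registry, config, models = list()) {
  sessions <- lapply(sessions, prepare_session, config = config)
  per_class <- list()
  for (cls in registry) {
    pf <- class_period_frames(cls, config)
    feats <- list(); labels <- list(); times <- list()
    for (s in sessions) {
      f <- class_features(s, config, cls, models)
      y <- annotation_frame_labels(s$annotations, cls$class_id, nrow(f$vectors),
                                   config$hop, config$sample_rate)
      feats[[length(feats) + 1L]] <- f$vectors
      labels[[length(labels) + 1L]] <- y
    }
    x <- do.call(rbind, feats); y <- unlist(labels)
    if (sum(y == 1L) < 2L) {
      warning("class ", cls$class_id, " absent from training; skipped")
      next
    }
    det <- if (config$classifier == "gmm")
      train_gmm_detector(x, y, class_id = cls$class_id)
    else
      train_nn_detector(x, y, hp = config$nn_hp, rng_seed = config$seed,
                        class_id = cls$class_id)
    scores <- detector_scores(det, x)
    eer_thr <- select_eer_threshold(scores, y)
    period_thr <- NA_real_
    if (config$post %in% c("temporal", "smooth+temporal")) {
      curves <- list(); refs <- list()
      for (j in seq_along(sessions)) {
        post <- frame_posteriors(det, feats[[j]])
        curves[[j]] <- period_probability(post, pf$L_sig, pf$L_sil)
        refs[[j]] <- annotation_events(sessions[[j]]$annotations, cls$class_id,
                                       config$hop, config$sample_rate)
      }
      period_thr <- sweep_period_threshold(curves, refs, pf, config$t_tol_frac)
    }
    per_class[[cls$class_id]] <- list(
      cls = cls, detector = det, eer_threshold = as.numeric(eer_thr),
      train_eer = attr(eer_thr, "eer"), period_threshold = period_thr,
      frames = pf)
  }
  structure(list(per_class = per_class, config = config, models = models),
            class = "alarm_detectors")
}

# Minimise training PB-ERR over candidate period-curve thresholds.
sweep_period_threshold <- function(curves, refs, pf, t_tol_frac) {
  vals <- unlist(lapply(curves, function(cv) cv$values[local_maxima(cv$values)]))
  if (length(vals) == 0L) return(0)
  cand <- unique(stats::quantile(vals, probs = seq(0.05, 0.99, length.out = 20),
                                 names = FALSE))
  t_tol <- floor(t_tol_frac * pf$period)
  errs <- vapply(cand, function(thr) {
    nc <- 0L; nm <- 0L; nfa <- 0L
    for (j in seq_along(curves)) {
      hyp <- pick_period_peaks(curves[[j]], thr, pf$period)
      pe <- pb_err(refs[[j]], hyp, t_tol, pf$period)
      nc <- nc + pe$counts$n_correct; nm <- nm + pe$counts$n_miss
      nfa <- nfa + pe$counts$n_false_alarm
    }
    if (nc + nm + nfa == 0L) 0 else 1 - 2 * nc / (2 * nc + nfa + nm)
  }, numeric(1))
  # The optimum is usually a plateau. Err towards its low edge (lower
  # quartile): a threshold that is too high irrecoverably misses periods,
  # while extra peaks from a slightly-too-low threshold are pruned by the
  # minimum-separation rule and, in the combined scheme, by method 1.
  best <- which(errs <= min(errs) + 1e-12)
  cand[best[max(1L, ceiling(length(best) / 4))]]
}

# Frame labels + period events from scores/posteriors under a post mode.
apply_decisions <- function(scores, posteriors, entry, config) {
  pf <- entry$frames
  raw <- as.integer(scores > entry$eer_threshold)
  min_sep <- 0.75 * pf$period
  smooth_win <- min(pf$L_sig, pf$L_sil)
  out <- switch(config$post,
    none = {
      lab <- raw
      list(labels = lab,
           events = labels_periods_convert(lab, min_sep = min_sep,
                                           class_id = entry$cls$class_id))
    },
    smooth = {
      lab <- majority_vote_smooth(raw, smooth_win)
      list(labels = lab,
           events = labels_periods_convert(lab, min_sep = min_sep,
                                           class_id = entry$cls$class_id))
    },
    temporal = {
      curve <- period_probability(posteriors, pf$L_sig, pf$L_sil)
      ev <- pick_period_peaks(curve, entry$period_threshold, pf$period,
                              entry$cls$class_id)
      list(labels = labels_periods_convert(ev, L_sig = pf$L_sig,
                                           direction = "to_labels",
                                           n_frames = length(scores)),
           events = ev)
    },
    `smooth+temporal` = {
      m1 <- majority_vote_smooth(raw, smooth_win)
      curve <- period_probability(posteriors, pf$L_sig, pf$L_sil)
      ev2 <- pick_period_peaks(curve, entry$period_threshold, pf$period,
                               entry$cls$class_id)
      lab <- combine_decisions(m1, ev2, pf$L_sig)
      ev <- labels_periods_convert(lab, min_sep = min_sep,
                                   class_id = entry$cls$class_id)
      # report the temporal model's timestamp where one coincides: the
      # period curve localises period starts more sharply than the onset
      # of a smoothed label run
      tol <- ceiling(pf$L_sig / 2)
      ts <- vapply(ev$timestamps, function(t) {
        if (length(ev2$timestamps) == 0L) return(t)
        j <- which.min(abs(ev2$timestamps - t))
        if (abs(ev2$timestamps[j] - t) <= tol) ev2$timestamps[j] else t
      }, integer(1))
      list(labels = lab,
           events = new_event_set(sort(unique(ts)), entry$cls$class_id,
                                  "hypothesis"))
    })
  out
}

#' Run detection on one session
#'
#' Executes every trained class detector independently over the session's
#' audio: feature extraction, frame posteriors, the configured
#' post-processing, and frame- plus period-level scoring against the
#' session's annotations.
#'
#' @param detectors An `alarm_detectors` object.
#' @param session List with `outside` (waveform), `annotations`
#'   (`data.frame`) and optionally `inside`.
#' @return List with `per_class` (`data.frame`: EER from the test DET
#'   curve, MR, FAR at the trained threshold, PB-ERR at the configured
#'   tolerance, counts), `overall` (unweighted class means), and per-class
#'   `labels`, `events`, `scores`, `reference`.
#' @export
run_detection <- function(detectors, session) {
  config <- detectors$config
  session <- prepare_session(session, config)
  rows <- list(); labels <- list(); events <- list()
  scores_l <- list(); refs <- list()
  for (entry in detectors$per_class) {
    cid <- entry$cls$class_id
    f <- class_features(session, config, entry$cls, detectors$models)
    T <- nrow(f$vectors)
    ref <- annotation_frame_labels(session$annotations, cid, T,
                                   config$hop, config$sample_rate)
    ref_ev <- annotation_events(session$annotations, cid,
                                config$hop, config$sample_rate)
    sc <- detector_scores(entry$detector, f)
    post <- frame_posteriors(entry$detector, f)
    dec <- apply_decisions(sc, post, entry, config)
    fm <- frame_metrics(ref, dec$labels)
    t_tol <- floor(config$t_tol_frac * entry$frames$period)
    pe <- pb_err(ref_ev, dec$events, t_tol, entry$frames$period)
    eer <- if (length(unique(ref)) == 2L) {
      dc <- det_curve(sc, ref)
      mean(unlist(dc[dc$eer_point, c("mr", "far")]))
    } else NA_real_
    rows[[cid]] <- data.frame(
      class_id = cid, eer = eer, mr = fm$mr, far = fm$far,
      pb_err = pe$pb_err,
      n_alarm = fm$counts$n_alarm, n_miss = fm$counts$n_miss,
      n_nonalarm = fm$counts$n_nonalarm, n_false_alarm = fm$counts$n_false_alarm,
      n_ref_periods = length(ref_ev$timestamps),
      n_correct_periods = pe$counts$n_correct,
      n_miss_periods = pe$counts$n_miss,
      n_fa_periods = pe$counts$n_false_alarm)
    labels[[cid]] <- dec$labels; events[[cid]] <- dec$events
    scores_l[[cid]] <- sc
    refs[[cid]] <- list(labels = ref, events = ref_ev)
  }
  per_class <- do.call(rbind, rows)
  rownames(per_class) <- NULL
  num <- c("eer", "mr", "far", "pb_err")
  overall <- colMeans(per_class[num], na.rm = TRUE)
  list(per_class = per_class, overall = overall, labels = labels,
       events = events, scores = scores_l, reference = refs,
       config = config)
}

#' Run a grid of configurations
#'
#' Trains and evaluates each configuration on the same train/test corpus
#' and returns one comparison row per configuration (class-averaged EER,
#' MR, FAR, PB-ERR). A failing configuration is marked failed; the others
#' proceed.
#'
#' @param corpus List with `train` and `test`, each a list of sessions.
#' @param grid List of `alarm_config`s.
#' @param registry Alarm-class registry.
#' @param models Shared trained feature models (`peak`, `nmf`).
#' @return `data.frame` with one row per configuration.
#' @export
run_experiment_grid <- function(corpus, grid, registry, models = list()) {
  stopifnot(length(grid) >= 1L)
  rows <- lapply(seq_along(grid), function(i) {
    config <- grid[[i]]
    res <- try({
      m <- models
      if (config$feature == "nmf" && is.null(m$nmf))
        m$nmf <- train_nmf_models(corpus$train, registry, config)
      dets <- train_detectors(corpus$train, registry, config, m)
      agg <- NULL
      for (s in corpus$test) {
        r <- run_detection(dets, s)
        agg <- if (is.null(agg)) r$per_class else {
          cnt <- c("n_alarm", "n_miss", "n_nonalarm", "n_false_alarm",
                   "n_ref_periods", "n_correct_periods", "n_miss_periods",
                   "n_fa_periods")
          agg[cnt] <- agg[cnt] + r$per_class[cnt]
          agg$eer <- (agg$eer + r$per_class$eer) / 2
          agg
        }
      }
      agg$mr <- agg$n_miss / agg$n_alarm
      agg$far <- agg$n_false_alarm / agg$n_nonalarm
      agg$pb_err <- 1 - 2 * agg$n_correct_periods /
        pmax(2 * agg$n_correct_periods + agg$n_fa_periods + agg$n_miss_periods, 1)
      data.frame(feature = config$feature, classifier = config$classifier,
                 post = config$post, failed = FALSE,
                 eer = mean(agg$eer, na.rm = TRUE), mr = mean(agg$mr),
                 far = mean(agg$far), pb_err = mean(agg$pb_err))
    }, silent = TRUE)
    if (inherits(res, "try-error"))
      data.frame(feature = grid[[i]]$feature, classifier = grid[[i]]$classifier,
                 post = grid[[i]]$post, failed = TRUE, eer = NA_real_,
                 mr = NA_real_, far = NA_real_, pb_err = NA_real_)
    else res
  })
  do.call(rbind, rows)
}

#' Session-wise cross-validation
#'
#' Leave-one-session-out: for each fold the detectors are trained on the
#' remaining sessions and run on the held-out one; per class, frame and
#' period counts are accumulated over folds before rates are computed, and
#' the overall score is the unweighted mean over classes. Optionally the
#' annotated alarm intervals of the test folds are stratified into 5 dB
#' local-SNR bins (inside channel when present) and the per-bin missing
#' rate is reported, together with a sweep that discards intervals below
#' an SNR cutoff.
#'
#' @param corpus List of >= 2 sessions.
#' @param config An `alarm_config`.
#' @param registry Alarm-class registry.
#' @param models Shared feature models (`peak`, `nmf`).
#' @param snr_stratify If `TRUE`, compute the SNR-stratified report.
#' @param snr_bin_width Bin width in dB (default 5).
#' @return List with `per_class`, `overall`, and optionally `snr`
#'   (`bins` and `sweep` data frames).
#' @export
cross_validate <- function(corpus, config, registry, models = list(),
                           snr_stratify = FALSE, snr_bin_width = 5) {
  stopifnot(length(corpus) >= 2L)
  acc <- list()
  strat <- list()
  for (k in seq_along(corpus)) {
    train <- corpus[-k]
    m <- models
    if (config$feature == "nmf")
      m$nmf <- train_nmf_models(train, registry, config)
    dets <- train_detectors(train, registry, config, m)
    res <- run_detection(dets, corpus[[k]])
    for (i in seq_len(nrow(res$per_class))) {
      row <- res$per_class[i, ]
      cid <- row$class_id
      if (is.null(acc[[cid]])) acc[[cid]] <- row else {
        cnt <- c("n_alarm", "n_miss", "n_nonalarm", "n_false_alarm",
                 "n_ref_periods", "n_correct_periods", "n_miss_periods",
                 "n_fa_periods")
        acc[[cid]][cnt] <- acc[[cid]][cnt] + row[cnt]
      }
    }
    if (snr_stratify)
      strat[[k]] <- snr_interval_table(corpus[[k]], res, dets, config, registry)
  }
  per_class <- do.call(rbind, acc)
  per_class$mr <- per_class$n_miss / per_class$n_alarm
  per_class$far <- per_class$n_false_alarm / per_class$n_nonalarm
  per_class$pb_err <- 1 - 2 * per_class$n_correct_periods /
    pmax(2 * per_class$n_correct_periods + per_class$n_fa_periods +
           per_class$n_miss_periods, 1)
  per_class$eer <- NULL
  rownames(per_class) <- NULL
  overall <- colMeans(per_class[c("mr", "far", "pb_err")], na.rm = TRUE)
  out <- list(per_class = per_class, overall = overall)
  if (snr_stratify) {
    tab <- do.call(rbind, strat)
    bin_lo <- floor(tab$snr_db / snr_bin_width) * snr_bin_width
    bins <- stats::aggregate(cbind(n_frames, n_miss) ~ bin,
                             data = cbind(tab, bin = bin_lo), FUN = sum)
    bins$mr <- bins$n_miss / bins$n_frames
    cutoffs <- sort(unique(bin_lo))
    sweep <- do.call(rbind, lapply(cutoffs, function(cut) {
      keep <- tab$snr_db >= cut
      data.frame(snr_cutoff_db = cut,
                 mr = sum(tab$n_miss[keep]) / max(sum(tab$n_frames[keep]), 1),
                 n_intervals = sum(keep))
    }))
    out$snr <- list(bins = bins, sweep = sweep)
  }
  out
}

# Per-interval local SNR and miss counts for one evaluated session.
snr_interval_table <- function(session, res, dets, config, registry) {
  wave <- session$inside
  if (is.null(wave)) {
    warning("no inside channel; local SNR measured on the outside channel")
    wave <- session$outside
  }
  sp <- compute_spectrogram(wave, config$sample_rate, "rectangular",
                            config$frame_length, config$hop, config$zero_pad)
  ann <- session$annotations
  rows <- list()
  for (i in seq_len(nrow(ann))) {
    cid <- ann$class_id[i]
    if (is.null(res$labels[[cid]])) next
    snr <- local_snr(sp, c(ann$onset_sec[i], ann$offset_sec[i]),
                     registry[[cid]], delta = config$delta)
    T <- length(res$labels[[cid]])
    t0 <- (seq_len(T) - 1L) * config$hop / config$sample_rate
    fr <- which(t0 >= ann$onset_sec[i] & t0 < ann$offset_sec[i])
    rows[[i]] <- data.frame(class_id = cid, snr_db = snr,
                            n_frames = length(fr),
                            n_miss = sum(res$labels[[cid]][fr] == 0L))
  }
  do.call(rbind, rows)
}
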