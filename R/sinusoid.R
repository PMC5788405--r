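# Statistical sinusoid detection on spectral peaks.
#
# Every local maximum of the short-time magnitude spectrum is a candidate
# sinusoidal component. A peak at bin k_p in frame l is described by
#   y1(j) = |S_l(k_p+j)| / |S_l(k_p)|,            j = -M..M  (magnitude shape)
#   y2(j) = wrap(phi_l(k_p+j) - phi_{l-1}(k_p+j) - 2*pi*k_p*L/Ndft)
# i.e. the shape of the magnitude spectrum around the peak, self-normalised,
# and the frame-to-frame phase difference with the expected phase advance of
# a stationary sinusoid at the peak bin removed. Two Gaussian mixture models
# (lambda_s for sinusoid peaks, lambda_n for noise peaks) are trained on a
# synthetic corpus and a peak is scored by its log-likelihood under each.

# Internal: locate peaks and assemble feature matrices for many frames at
# once. Peaks are strict local maxima; on a plateau the lowest bin index is
# taken. Peaks closer than M bins to either spectrum edge, zero-magnitude
# peaks, and frame 1 (no previous frame for the phase difference) are
# skipped. `bins`, if given, restricts peak *locations* (neighbours still
# come from the full spectrum).
peak_feature_table <- function(spec, M, frames = NULL, bins = NULL) {
  mag <- Mod(spec$values); pha <- Arg(spec$values)
  K <- nrow(mag); T <- ncol(mag)
  if (is.null(frames)) frames <- seq_len(T)
  frames <- frames[frames >= 2L & frames <= T]
  is_peak <- matrix(FALSE, K, T)
  if (K >= 3L)
    is_peak[2:(K - 1L), ] <- mag[2:(K - 1L), ] > mag[1:(K - 2L), ] &
      mag[2:(K - 1L), ] >= mag[3:K, ] & mag[2:(K - 1L), ] > 0
  keep_rows <- rep(FALSE, K)
  lo <- M + 2L; hi <- K - M  # 1-based; ensures context fits and k >= 2
  if (lo <= hi) keep_rows[lo:hi] <- TRUE
  if (!is.null(bins)) {
    sel <- rep(FALSE, K); sel[bins] <- TRUE
    keep_rows <- keep_rows & sel
  }
  is_peak[!keep_rows, ] <- FALSE
  keep_cols <- rep(FALSE, T); keep_cols[frames] <- TRUE
  is_peak[, !keep_cols] <- FALSE
  w <- which(is_peak)
  if (length(w) == 0L)
    return(list(features = matrix(0, 0L, 2L * (2L * M + 1L)),
                bin = integer(0), frame = integer(0)))
  b <- ((w - 1L) %% K) + 1L
  f <- ((w - 1L) %/% K) + 1L
  offs <- (-M):M
  ctx <- outer(w, offs, `+`)                       # linear indices, same frame
  y1 <- mag[ctx] / mag[w]
  dphi <- pha[ctx] - pha[ctx - K] -
    2 * pi * (b - 1) * spec$hop / spec$dft_size
  y2 <- wrap_angle(dphi)
  dim(y1) <- dim(ctx); dim(y2) <- dim(ctx)
  list(features = cbind(y1, y2), bin = b, frame = f)
}

#' Extract spectral-peak features from one frame
#'
#' @param spec An `alarm_spectrogram` (rectangular window and zero-padding
#'   recommended; the reference setup is N = 2048, hop 1024, 2048 padding
#'   zeros).
#' @param frame Frame index (1-based). Must be >= 2: the phase-continuity
#'   features need the previous frame.
#' @param context Half-width M of the spectral context in bins (default 6).
#' @return A `peak_features` object: list with `features` (one row per
#'   detected peak, `2*(2M+1)` columns: magnitude shape then wrapped phase
#'   differences), `bin` (1-based peak bin indices) and `frame`.
#' @export
extract_peak_features <- function(spec, frame, context = 6L) {
  stopifnot(context >= 1L)
  if (frame < 2L) stop("no previous frame")
  if (frame > n_frames(spec)) stop("frame out of range")
  res <- peak_feature_table(spec, as.integer(context), frames = frame)
  structure(res, class = "peak_features", M = as.integer(context))
}

#' Train sinusoid / noise peak models
#'
#' Synthesises a corpus of random-frequency stationary sinusoids in white
#' noise (broadband SNR `training_snr_db`, default -7 dB) plus noise-only
#' segments, extracts peak features, and fits one diagonal-covariance GMM to
#' peaks at the sinusoid's own bin (`lambda_s`) and one to noise peaks
#' (`lambda_n`). With the defaults (32 components, M = 6) both models live
#' in 26 dimensions.
#'
#' @param n_components Mixture components per model (default 32).
#' @param M Spectral context half-width in bins (default 6).
#' @param training_snr_db Broadband SNR of the training sinusoids (default -7).
#' @param rng_seed Integer seed controlling corpus synthesis and EM init.
#' @param n_examples Corpus size passed to [synth_sinusoid_corpus()].
#' @param sample_rate,frame_length,hop,zero_pad Analysis geometry.
#' @param max_noise_peaks Cap on noise peaks used to fit `lambda_n`.
#' @return A `peak_models` object.
#' @export
train_peak_models <- function(n_components = 32L, M = 6L,
                              training_snr_db = -7, rng_seed = 1L,
                              n_examples = 400L, sample_rate = 24000,
                              frame_length = 2048L, hop = 1024L,
                              zero_pad = 2048L, max_noise_peaks = 12000L) {
  stopifnot(n_components >= 1L)
  corpus <- synth_sinusoid_corpus(n_examples, snr_db = training_snr_db,
                                  sample_rate = sample_rate, seed = rng_seed,
                                  frame_length = frame_length, hop = hop)
  sin_feats <- list(); noise_feats <- list()
  for (ex in corpus$examples) {
    sp <- compute_spectrogram(ex$wave, sample_rate, "rectangular",
                              frame_length, hop, zero_pad)
    pt <- peak_feature_table(sp, M)
    if (length(pt$bin) == 0L) next
    if (ex$is_sinusoid) {
      true_bin <- round(ex$freq * sp$dft_size / sample_rate) + 1L
      keep <- abs(pt$bin - true_bin) <= 3L
      if (any(keep)) sin_feats[[length(sin_feats) + 1L]] <- pt$features[keep, , drop = FALSE]
    } else {
      noise_feats[[length(noise_feats) + 1L]] <- pt$features
    }
  }
  xs <- do.call(rbind, sin_feats)
  xn <- do.call(rbind, noise_feats)
  if (is.null(xs) || nrow(xs) < 10L * n_components)
    stop("too few sinusoid peaks in training corpus; increase n_examples")
  if (nrow(xn) > max_noise_peaks)
    xn <- with_rng(rng_seed + 1L,
                   xn[sample.int(nrow(xn), max_noise_peaks), , drop = FALSE])
  lambda_s <- fit_diag_gmm(xs, n_components, rng_seed = rng_seed)
  lambda_n <- fit_diag_gmm(xn, n_components, rng_seed = rng_seed)
  structure(list(lambda_s = lambda_s, lambda_n = lambda_n, M = as.integer(M),
                 training_snr_db = training_snr_db,
                 n_sin_peaks = nrow(xs), n_noise_peaks = nrow(xn),
                 sample_rate = sample_rate, frame_length = frame_length,
                 hop = hop, zero_pad = zero_pad, rng_seed = rng_seed),
            class = "peak_models")
}

#' @export
print.peak_models <- function(x, ...) {
  cat(sprintf(
    "<peak_models> M=%d dim=%d | %d comps | trained at %g dB (%d sin / %d noise peaks)\n",
    x$M, 2L * (2L * x$M + 1L), length(x$lambda_s$weights),
    x$training_snr_db, x$n_sin_peaks, x$n_noise_peaks))
  invisible(x)
}

#' Score spectral peaks under the sinusoid and noise models
#'
#' @param pf A `peak_features` object or a numeric feature matrix
#'   (rows = peaks).
#' @param models A `peak_models` object.
#' @return List with numeric vectors `llh_s` and `llh_n`, one log-density
#'   per peak.
#' @export
score_peak <- function(pf, models) {
  x <- if (is.matrix(pf)) pf else pf$features
  if (ncol(x) != ncol(models$lambda_s$means))
    stop("feature/model dimension mismatch")
  list(llh_s = gmm_logdens(models$lambda_s, x),
       llh_n = gmm_logdens(models$lambda_n, x))
}

#' Classify all spectral peaks of a spectrogram
#'
#' Convenience wrapper: locates peaks (optionally restricted to `bins` /
#' `frames`), scores each under both peak models, and returns one row per
#' peak.
#'
#' @inheritParams detect_sinusoid_tracks
#' @param bins,frames Optional restrictions (1-based indices).
#' @return `data.frame` with columns `frame`, `bin`, `llh_s`, `llh_n`,
#'   `sinusoidal` (`llh_s > llh_n`).
#' @export
classify_peaks <- function(spec, models, bins = NULL, frames = NULL) {
  pt <- peak_feature_table(spec, models$M, frames = frames, bins = bins)
  if (length(pt$bin) == 0L)
    return(data.frame(frame = integer(0), bin = integer(0),
                      llh_s = numeric(0), llh_n = numeric(0),
                      sinusoidal = logical(0)))
  sc <- score_peak(pt$features, models)
  data.frame(frame = pt$frame, bin = pt$bin, llh_s = sc$llh_s,
             llh_n = sc$llh_n, sinusoidal = sc$llh_s > sc$llh_n)
}

#' Detect temporal tracks of sinusoidal components
#'
#' Peaks classified as sinusoidal (`llh_s > llh_n`) are linked across
#' consecutive frames when their bin indices differ by at most one. Within
#' each frame, marks within `M` bins of a stronger mark are suppressed
#' first: the sidelobes of a strong off-grid sinusoid are themselves
#' phase-coherent and would otherwise spawn duplicate tracks. Tracks
#' shorter than `min_frames` (default 3) are discarded, as are tracks whose
#' mean energy lies more than `energy_floor_db` (default 40 dB) below the
#' loudest track's mean energy in the file.
#'
#' @param spec An `alarm_spectrogram`.
#' @param models A `peak_models` object.
#' @param min_frames Minimum track duration in frames.
#' @param energy_floor_db Relative energy floor in dB.
#' @return List of tracks, each a list with `frames`, `bins` (parallel
#'   integer vectors), `onset`, `offset` (frame indices) and `energy_db`
#'   (mean per-frame energy at the track's bins, dB).
#' @export
detect_sinusoid_tracks <- function(spec, models, min_frames = 3L,
                                   energy_floor_db = 40) {
  stopifnot(min_frames >= 1L)
  if (n_frames(spec) == 0L) return(list())
  marks <- classify_peaks(spec, models)
  marks <- marks[marks$sinusoidal, , drop = FALSE]
  mag2 <- Mod(spec$values)^2
  if (nrow(marks) > 0L) {
    marks$mag <- mag2[cbind(marks$bin, marks$frame)]
    keep <- unlist(lapply(split(seq_len(nrow(marks)), marks$frame), function(ix) {
      ord <- ix[order(-marks$mag[ix])]
      kept <- integer(0)
      for (i in ord)
        if (!length(kept) || all(abs(marks$bin[i] - marks$bin[kept]) > models$M))
          kept <- c(kept, i)
      kept
    }))
    marks <- marks[sort(keep), , drop = FALSE]
  }
  open <- list(); done <- list()
  by_frame <- split(marks$bin, marks$frame)
  for (f in seq_len(n_frames(spec))) {
    bins_f <- by_frame[[as.character(f)]] %||% integer(0)
    used <- rep(FALSE, length(bins_f))
    keep <- logical(length(open))
    for (i in seq_along(open)) {
      tr <- open[[i]]
      cand <- which(!used & abs(bins_f - tr$last_bin) <= 1L)
      if (length(cand) > 0L && tr$last_frame == f - 1L) {
        j <- cand[which.min(abs(bins_f[cand] - tr$last_bin))]
        used[j] <- TRUE
        tr$frames <- c(tr$frames, f); tr$bins <- c(tr$bins, bins_f[j])
        tr$last_bin <- bins_f[j]; tr$last_frame <- f
        open[[i]] <- tr; keep[i] <- TRUE
      } else {
        done[[length(done) + 1L]] <- tr; keep[i] <- FALSE
      }
    }
    open <- open[keep]
    for (j in which(!used)) {
      open[[length(open) + 1L]] <- list(frames = f, bins = bins_f[j],
                                        last_bin = bins_f[j], last_frame = f)
    }
  }
  done <- c(done, open)
  done <- Filter(function(tr) length(tr$frames) >= min_frames, done)
  if (length(done) == 0L) return(list())
  tracks <- lapply(done, function(tr) {
    e <- mean(mag2[cbind(tr$bins, tr$frames)])
    list(frames = tr$frames, bins = tr$bins,
         onset = tr$frames[1L], offset = tr$frames[length(tr$frames)],
         energy_db = pow_to_db(e))
  })
  emax <- max(vapply(tracks, `[[`, numeric(1), "energy_db"))
  Filter(function(tr) tr$energy_db >= emax - energy_floor_db, tracks)
}

#' Sinusoid-detection features for one alarm class
#'
#' For every frame and every alarm-specific frequency region (f_b +/- delta)
#' the peak maximising the sinusoid-model log-likelihood is selected.
#' Depending on `mode` the per-frame feature vector contains, per region:
#' the log-likelihood ratio (`"ratio"`, dimension N_f), the pair of
#' log-likelihoods (`"llh"`, 2*N_f), or the pairs plus the region magnitudes
#' normalised to sum to one across regions (`"llh_amp"`, 3*N_f). Regions
#' with no peak receive the floor log-likelihood `floor_llh` and the
#' magnitude of the region's strongest bin; the first frame, which has no
#' phase reference, is treated the same way. Observed log-likelihoods are
#' also clipped from below at the floor, so the features are bounded and,
#' critically, on the same scale in every recording (a file-relative floor
#' would make the detector's operating point file-dependent).
#'
#' @param spec An `alarm_spectrogram` (rectangular window, zero-padded).
#' @param models A `peak_models` object.
#' @param cls An `alarm_class_spec` (see [default_registry()]).
#' @param mode `"ratio"`, `"llh"` or `"llh_amp"`.
#' @param delta Frequency tolerance in Hz (default 20).
#' @param floor_llh Absolute floor (nats) assigned to peakless regions and
#'   used to clip observed log-likelihoods from below (default -300, below
#'   the 1st percentile of matched-peak log-likelihoods at the reference
#'   settings).
#' @return An `alarm_features` object.
#' @export
extract_sd_features <- function(spec, models, cls,
                                mode = c("llh_amp", "llh", "ratio"),
                                delta = 20, floor_llh = -300) {
  mode <- match.arg(mode)
  freqs <- alarm_frequencies(cls)
  stopifnot(length(freqs) >= 1L)
  T <- n_frames(spec); R <- length(freqs)
  mag <- Mod(spec$values)
  LLS <- matrix(NA_real_, T, R); LLN <- matrix(NA_real_, T, R)
  AMP <- matrix(0, T, R)
  for (r in seq_len(R)) {
    bins <- region_bins(freqs[r], delta, spec)
    AMP[, r] <- apply(mag[bins, , drop = FALSE], 2L, max)
    cp <- classify_peaks(spec, models, bins = bins)
    if (nrow(cp) > 0L) {
      cp <- cp[order(cp$frame, -cp$llh_s), , drop = FALSE]
      best <- cp[!duplicated(cp$frame), , drop = FALSE]
      LLS[best$frame, r] <- best$llh_s
      LLN[best$frame, r] <- best$llh_n
      AMP[cbind(best$frame, r)] <- mag[cbind(best$bin, best$frame)]
    }
  }
  LLS[is.na(LLS)] <- floor_llh
  LLN[is.na(LLN)] <- floor_llh
  LLS <- pmax(LLS, floor_llh)
  LLN <- pmax(LLN, floor_llh)
  vec <- switch(mode,
    ratio = LLS - LLN,
    llh = cbind(LLS, LLN),
    llh_amp = {
      tot <- rowSums(AMP)
      ampn <- AMP / ifelse(tot > 0, tot, 1)
      ampn[tot <= 0, ] <- 1 / R
      cbind(LLS, LLN, ampn)
    })
  kind <- switch(mode, ratio = "sd_ratio", llh = "sd_llh", llh_amp = "sd_llh_amp")
  new_features(vec, spec$frame_times, kind)
}
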