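# Supervised non-negative matrix factorisation features.
#
# Magnitude spectra restricted to the alarm-specific frequency bands are
# approximated as S ~ W H with W, H >= 0, minimising the Kullback-Leibler
# divergence D_KL(S || WH) plus a sparsity penalty beta * |H|_1, by the
# classical multiplicative updates. Alarm bases W_A are trained on alarm
# signal-interval spectra, non-alarm bases W_NA on alarm-free spectra;
# at feature-extraction time W = [W_A, W_NA] is held fixed, only H is
# estimated, each activation column is normalised to sum to one and the
# alarm rows H_A are the features.

EPS_NMF <- 1e-12

kl_objective <- function(s, wh, h, beta) {
  # 0*log(0) = 0 convention; eps floor inside the log
  t1 <- sum(ifelse(s > 0, s * log(pmax(s, EPS_NMF) / pmax(wh, EPS_NMF)), 0))
  t1 - sum(s) + sum(wh) + beta * sum(h)
}

nmf_update_h <- function(s, w, h, beta) {
  wh <- pmax(w %*% h, EPS_NMF)
  h * (crossprod(w, s / wh)) / (matrix(colSums(w), nrow(h), ncol(h)) + beta)
}

nmf_update_w <- function(s, w, h) {
  wh <- pmax(w %*% h, EPS_NMF)
  w * ((s / wh) %*% t(h)) / pmax(matrix(rowSums(h), nrow(w), ncol(w), byrow = TRUE), EPS_NMF)
}

run_nmf <- function(s, r, beta, n_iters, rng_seed, w = NULL, tol = 1e-6) {
  nb <- nrow(s); T <- ncol(s)
  fixed_w <- !is.null(w)
  with_rng(rng_seed, {
    if (!fixed_w) w <- matrix(stats::runif(nb * r, 0.1, 1), nb, r)
    h <- matrix(stats::runif(r * T, 0.1, 1), r, T)
    obj <- numeric(0)
    prev <- Inf
    for (it in seq_len(n_iters)) {
      h <- nmf_update_h(s, w, h, beta)
      if (!fixed_w) w <- nmf_update_w(s, w, h)
      wh <- w %*% h
      o <- kl_objective(s, wh, h, beta)
      obj <- c(obj, o)
      if (is.finite(prev) && abs(prev - o) < tol * max(abs(prev), 1)) break
      prev <- o
    }
    list(w = w, h = h, objective = obj)
  })
}

#' Train supervised NMF bases for one alarm class
#'
#' Fits `R_alarm` bases on alarm signal-interval spectra and `R_nonalarm`
#' bases on alarm-free spectra (default 4 and 15), each by multiplicative
#' KL + sparsity updates (`beta` defaults to 1, up to 20 iterations with an
#' early stop on relative objective change < 1e-6), then concatenates them.
#' Basis columns are L1-normalised once after the final update, which
#' removes the W/H scale ambiguity without disturbing the monotone descent
#' of the penalised objective during the iterations.
#'
#' @param alarm_spectra,nonalarm_spectra Non-negative magnitude matrices
#'   (band bins x frames) over the same band-bin rows.
#' @param R_alarm,R_nonalarm Number of alarm / non-alarm bases.
#' @param beta Sparsity weight on `|H|_1`.
#' @param n_iters Maximum multiplicative updates.
#' @param rng_seed Integer seed for the positive random initialisation.
#' @param band_bins Optional integer vector recording which spectrogram bins
#'   the rows correspond to (stored for later consistency checks).
#' @return An `nmf_model` object with fields `W`, `alarm_cols`,
#'   `nonalarm_cols`, `beta`, `band_bins`, `n_iters`, and the training
#'   objective traces.
#' @export
train_nmf_bases <- function(alarm_spectra, nonalarm_spectra,
                            R_alarm = 4L, R_nonalarm = 15L, beta = 1,
                            n_iters = 20L, rng_seed = 1L, band_bins = NULL) {
  alarm_spectra <- as.matrix(alarm_spectra)
  nonalarm_spectra <- as.matrix(nonalarm_spectra)
  if (any(alarm_spectra < 0) || any(nonalarm_spectra < 0))
    stop("non-negative input required")
  if (sum(alarm_spectra) == 0 || sum(nonalarm_spectra) == 0)
    stop("degenerate training matrix")
  if (nrow(alarm_spectra) != nrow(nonalarm_spectra))
    stop("band mismatch between alarm and non-alarm spectra")
  fa <- run_nmf(alarm_spectra, R_alarm, beta, n_iters, rng_seed)
  fn <- run_nmf(nonalarm_spectra, R_nonalarm, beta, n_iters, rng_seed + 1L)
  w <- cbind(fa$w, fn$w)
  norms <- pmax(colSums(w), EPS_NMF)
  w <- sweep(w, 2L, norms, `/`)
  structure(list(W = w, alarm_cols = seq_len(R_alarm),
                 nonalarm_cols = R_alarm + seq_len(R_nonalarm),
                 beta = beta, band_bins = band_bins, n_iters = n_iters,
                 rng_seed = rng_seed,
                 objective_alarm = fa$objective,
                 objective_nonalarm = fn$objective),
            class = "nmf_model")
}

#' @export
print.nmf_model <- function(x, ...) {
  cat(sprintf("<nmf_model> %d bands, %d alarm + %d non-alarm bases, beta=%g\n",
              nrow(x$W), length(x$alarm_cols), length(x$nonalarm_cols), x$beta))
  invisible(x)
}

#' Infer NMF activations with fixed bases
#'
#' @param spec_bands Non-negative magnitude matrix (band bins x frames) over
#'   the same band rows the model was trained on.
#' @param model An `nmf_model`.
#' @param rng_seed Seed for the positive random initialisation of H.
#' @return An `nmf_activations` object: list with `H` (bases x frames),
#'   `alarm_rows` and the inference `objective` trace.
#' @export
infer_activations <- function(spec_bands, model, rng_seed = 1L) {
  spec_bands <- as.matrix(spec_bands)
  if (nrow(spec_bands) != nrow(model$W))
    stop("band mismatch with trained model")
  if (any(spec_bands < 0)) stop("non-negative input required")
  fit <- run_nmf(spec_bands, ncol(model$W), model$beta, model$n_iters,
                 rng_seed, w = model$W)
  structure(list(H = fit$h, alarm_rows = model$alarm_cols,
                 objective = fit$objective),
            class = "nmf_activations")
}

#' Alarm-activation features
#'
#' Each activation column is normalised to sum to one over all bases; only
#' the alarm rows are returned, giving `R_alarm`-dimensional frame features
#' that are invariant to the overall signal scale. All-zero activation
#' columns fall back to the uniform value `1/R_total`.
#'
#' @param acts An `nmf_activations` from [infer_activations()].
#' @param model The `nmf_model` the activations were inferred with.
#' @param frame_times Optional frame times for the returned feature object.
#' @return An `alarm_features` object of kind `"nmf_act"`.
#' @export
extract_nmf_features <- function(acts, model, frame_times = NULL) {
  h <- acts$H
  tot <- colSums(h)
  r_total <- nrow(h)
  hn <- sweep(h, 2L, ifelse(tot > EPS_NMF, tot, 1), `/`)
  hn[, tot <= EPS_NMF] <- 1 / r_total
  feats <- t(hn[model$alarm_cols, , drop = FALSE])
  if (is.null(frame_times)) frame_times <- seq_len(ncol(h)) - 1
  new_features(feats, frame_times, "nmf_act")
}
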