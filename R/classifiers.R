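# Per-class frame classifiers: alarm vs non-alarm.
#
# The generative detector models each class with a single Gaussian with
# diagonal covariance. The discriminative detector is a one-hidden-layer
# neural network (32 logistic hidden units, 1 logistic output) whose hidden
# layer is pretrained as a Gaussian-Bernoulli RBM with CD-1 before
# supervised backpropagation on the cross-entropy loss.

#' Train a single-Gaussian alarm/non-alarm detector
#'
#' Maximum-likelihood fit of one diagonal Gaussian per class (sample mean,
#' sample variance floored at 1e-6).
#'
#' @param features An `alarm_features` object or numeric matrix (frames x dim).
#' @param frame_labels Binary per-frame labels (1 = alarm).
#' @param class_id Optional alarm-class identifier stored in the model.
#' @return A `gmm_detector` object.
#' @export
train_gmm_detector <- function(features, frame_labels, class_id = NULL) {
  x <- if (is.matrix(features)) features else features$vectors
  y <- as.integer(frame_labels)
  stopifnot(nrow(x) == length(y))
  if (sum(y == 1L) < 2L || sum(y == 0L) < 2L) stop("insufficient class data")
  fit1 <- function(m) {
    list(mean = colMeans(m),
         var = pmax(apply(m, 2L, stats::var), 1e-6))
  }
  structure(list(alarm = fit1(x[y == 1L, , drop = FALSE]),
                 nonalarm = fit1(x[y == 0L, , drop = FALSE]),
                 feature_kind = if (is.matrix(features)) NA_character_
                                else features$feature_kind,
                 class_id = class_id, dim = ncol(x)),
            class = "gmm_detector")
}

diag_gauss_logdens <- function(x, g) {
  gmm_component_logdens(x, matrix(g$mean, 1L), matrix(g$var, 1L))[, 1L]
}

#' Default neural-network training hyperparameters
#'
#' Unsupervised (RBM) stage: learning rate 0.001, 80 epochs, momentum 0.9,
#' weight decay 2e-7. Supervised stage: learning rate 0.001, 50 epochs,
#' momentum 0.9, weight decay 1.2e-4. Minibatch size 10, 32 hidden units.
#'
#' @param ... Overrides for any of the fields.
#' @return Named list of hyperparameters.
#' @export
nn_hyperparameters <- function(...) {
  hp <- list(hidden = 32L, batch_size = 10L,
             unsup = list(lr = 0.001, epochs = 80L, momentum = 0.9, decay = 2e-7),
             sup = list(lr = 0.001, epochs = 50L, momentum = 0.9, decay = 1.2e-4))
  utils::modifyList(hp, list(...))
}

sigmoid <- function(z) 1 / (1 + exp(-z))

#' Train an RBM-pretrained neural-network detector
#'
#' Pipeline: class balancing by seeded down-sampling of the majority class;
#' mean-variance normalisation statistics computed on the balanced set;
#' Gaussian-Bernoulli RBM pretraining of the hidden layer by one-step
#' contrastive divergence; a logistic output unit is added and the whole
#' network trained by backpropagation (cross-entropy) with momentum and
#' weight decay, minibatch size 10, inputs reshuffled into minibatches each
#' epoch.
#'
#' @param features An `alarm_features` object or numeric matrix.
#' @param frame_labels Binary per-frame labels (1 = alarm).
#' @param hp Hyperparameters from [nn_hyperparameters()].
#' @param rng_seed Integer seed (balancing, weight init, shuffling).
#' @param class_id Optional class identifier.
#' @return An `nn_detector` object.
#' @export
train_nn_detector <- function(features, frame_labels,
                              hp = nn_hyperparameters(), rng_seed = 1L,
                              class_id = NULL) {
  x <- if (is.matrix(features)) features else features$vectors
  y <- as.integer(frame_labels)
  stopifnot(nrow(x) == length(y))
  if (sum(y == 1L) < 2L || sum(y == 0L) < 2L) stop("insufficient class data")
  with_rng(rng_seed, {
    i1 <- which(y == 1L); i0 <- which(y == 0L)
    n <- min(length(i1), length(i0))
    keep <- c(if (length(i1) > n) sample(i1, n) else i1,
              if (length(i0) > n) sample(i0, n) else i0)
    xb <- x[keep, , drop = FALSE]; yb <- y[keep]
    mu <- colMeans(xb)
    sd <- apply(xb, 2L, stats::sd); sd[sd < 1e-8] <- 1
    xs <- sweep(sweep(xb, 2L, mu), 2L, sd, `/`)
    d <- ncol(xs); h <- hp$hidden; bs <- hp$batch_size
    W <- matrix(stats::runif(d * h, -0.01, 0.01), d, h)
    bh <- rep(0, h); bv <- rep(0, d)
    # --- RBM pretraining (CD-1, Gaussian visible units of unit variance)
    vW <- W * 0; vbh <- bh * 0; vbv <- bv * 0
    up <- hp$unsup
    nb <- nrow(xs)
    rbm_err <- numeric(up$epochs)
    for (ep in seq_len(up$epochs)) {
      ord <- sample.int(nb)
      err <- 0
      for (s0 in seq(1L, nb, by = bs)) {
        idx <- ord[s0:min(nb, s0 + bs - 1L)]
        v0 <- xs[idx, , drop = FALSE]
        ph0 <- sigmoid(sweep(v0 %*% W, 2L, bh, `+`))
        hs <- matrix(stats::runif(length(ph0)) < ph0, nrow(ph0), ncol(ph0)) * 1
        v1 <- sweep(hs %*% t(W), 2L, bv, `+`)
        ph1 <- sigmoid(sweep(v1 %*% W, 2L, bh, `+`))
        m <- length(idx)
        gW <- (crossprod(v0, ph0) - crossprod(v1, ph1)) / m - up$decay * W
        vW <- up$momentum * vW + up$lr * gW
        vbh <- up$momentum * vbh + up$lr * (colMeans(ph0) - colMeans(ph1))
        vbv <- up$momentum * vbv + up$lr * (colMeans(v0) - colMeans(v1))
        W <- W + vW; bh <- bh + vbh; bv <- bv + vbv
        err <- err + sum((v0 - v1)^2)
      }
      rbm_err[ep] <- err / nb
      if (!all(is.finite(W))) stop("training diverged; reduce learning rate")
    }
    # --- supervised backpropagation
    w2 <- matrix(stats::runif(h, -0.01, 0.01), h, 1L); b2 <- 0
    vW <- W * 0; vbh <- bh * 0; vw2 <- w2 * 0; vb2 <- 0
    sp <- hp$sup
    losses <- numeric(sp$epochs)
    for (ep in seq_len(sp$epochs)) {
      ord <- sample.int(nb)
      tot <- 0
      for (s0 in seq(1L, nb, by = bs)) {
        idx <- ord[s0:min(nb, s0 + bs - 1L)]
        xm <- xs[idx, , drop = FALSE]; ym <- yb[idx]
        a1 <- sigmoid(sweep(xm %*% W, 2L, bh, `+`))
        out <- as.numeric(sigmoid(a1 %*% w2 + b2))
        p <- pmin(pmax(out, 1e-12), 1 - 1e-12)
        tot <- tot - sum(ym * log(p) + (1 - ym) * log(1 - p))
        m <- length(idx)
        dout <- matrix(out - ym, m, 1L)                  # dL/dz2
        gw2 <- crossprod(a1, dout) / m + sp$decay * w2
        gb2 <- mean(dout)
        d1 <- (dout %*% t(w2)) * a1 * (1 - a1)
        gW <- crossprod(xm, d1) / m + sp$decay * W
        gbh <- colMeans(d1)
        vw2 <- sp$momentum * vw2 - sp$lr * gw2
        vb2 <- sp$momentum * vb2 - sp$lr * gb2
        vW <- sp$momentum * vW - sp$lr * gW
        vbh <- sp$momentum * vbh - sp$lr * gbh
        w2 <- w2 + vw2; b2 <- b2 + vb2; W <- W + vW; bh <- bh + vbh
      }
      losses[ep] <- tot / nb
      if (!is.finite(losses[ep])) stop("training diverged; reduce learning rate")
    }
    structure(list(W1 = W, b1 = bh, w2 = w2, b2 = b2,
                   norm_mean = mu, norm_sd = sd, dim = d,
                   feature_kind = if (is.matrix(features)) NA_character_
                                  else features$feature_kind,
                   class_id = class_id,
                   training_log = list(rbm_reconstruction_error = rbm_err,
                                       supervised_loss = losses,
                                       n_per_class = n)),
              class = "nn_detector")
  })
}

nn_forward <- function(det, x) {
  xs <- sweep(sweep(x, 2L, det$norm_mean), 2L, det$norm_sd, `/`)
  a1 <- sigmoid(sweep(xs %*% det$W1, 2L, det$b1, `+`))
  as.numeric(sigmoid(a1 %*% det$w2 + det$b2))
}

#' Per-frame alarm / non-alarm log-posteriors
#'
#' For the Gaussian detector, the two class likelihoods are combined with
#' equal priors and normalised to sum to one; for the neural network the
#' output unit is read as the alarm probability. Posteriors are floored at
#' `floor` (and renormalised), which bounds the per-frame log-posterior
#' contrast to about `2*log(1/floor)` nats: unbounded Gaussian
#' log-likelihood ratios would otherwise make downstream period-curve
#' heights scale with signal level rather than with the alarm's time
#' structure.
#'
#' @param detector A `gmm_detector` or `nn_detector`.
#' @param features An `alarm_features` object or numeric matrix.
#' @param floor Posterior probability floor (default 1e-6).
#' @return A `frame_posteriors` object: list with `log_alarm` (P_A) and
#'   `log_nonalarm` (P_NA), both per frame and `<= 0`, with
#'   `exp(P_A) + exp(P_NA) = 1`.
#' @export
frame_posteriors <- function(detector, features, floor = 1e-6) {
  x <- if (is.matrix(features)) features else features$vectors
  if (ncol(x) != detector$dim) stop("feature/model dimension mismatch")
  if (inherits(detector, "gmm_detector")) {
    la <- diag_gauss_logdens(x, detector$alarm) + log(0.5)
    ln <- diag_gauss_logdens(x, detector$nonalarm) + log(0.5)
    norm <- logsumexp_rows(cbind(la, ln))
    pa <- la - norm; pn <- ln - norm
  } else if (inherits(detector, "nn_detector")) {
    p <- nn_forward(detector, x)
    pa <- log(pmax(p, 1e-300)); pn <- log(pmax(1 - p, 1e-300))
    norm <- logsumexp_rows(cbind(pa, pn))
    pa <- pa - norm; pn <- pn - norm
  } else stop("unknown detector type")
  if (floor > 0) {
    qa <- pmax(exp(pa), floor); qn <- pmax(exp(pn), floor)
    pa <- log(qa / (qa + qn)); pn <- log(qn / (qa + qn))
  }
  structure(list(log_alarm = pa, log_nonalarm = pn),
            class = "frame_posteriors")
}

#' Frame decision scores
#'
#' The score thresholded for frame-level decisions: the log-likelihood
#' ratio `P_A - P_NA` for the Gaussian detector, the network output for the
#' neural network.
#'
#' The raw (unfloored) ratio is used so threshold sweeps and DET curves
#' keep full resolution; the posterior floor only applies to the temporal
#' aggregation path.
#'
#' @inheritParams frame_posteriors
#' @return Numeric score per frame (larger = more alarm-like).
#' @export
detector_scores <- function(detector, features) {
  x <- if (is.matrix(features)) features else features$vectors
  if (inherits(detector, "nn_detector")) {
    nn_forward(detector, x)
  } else {
    if (ncol(x) != detector$dim) stop("feature/model dimension mismatch")
    diag_gauss_logdens(x, detector$alarm) -
      diag_gauss_logdens(x, detector$nonalarm)
  }
}

#' Select a decision threshold by the equal-error-rate criterion
#'
#' Sweeps thresholds at the midpoints between consecutive distinct score
#' values (plus one beyond each extreme) and returns the threshold
#' minimising `|MR - FAR|`, where frames scoring strictly above the
#' threshold are called alarms. Ties take the lower threshold.
#'
#' @param scores Numeric per-frame decision scores.
#' @param frame_labels Binary reference labels (1 = alarm).
#' @return The threshold, with attributes `mr`, `far` and `eer`
#'   (`(MR + FAR)/2` at the threshold).
#' @export
select_eer_threshold <- function(scores, frame_labels) {
  y <- as.integer(frame_labels)
  if (length(unique(y)) < 2L) stop("cannot compute EER")
  s <- sort(unique(scores))
  cand <- if (length(s) == 1L) c(s - 1, s + 1)
          else c(s[1L] - 1, (s[-1L] + s[-length(s)]) / 2, s[length(s)] + 1)
  sa <- sort(scores[y == 1L]); sn <- sort(scores[y == 0L])
  mr <- findInterval(cand, sa) / length(sa)        # alarm scores <= t: missed
  far <- 1 - findInterval(cand, sn) / length(sn)   # non-alarm scores > t
  i <- which.min(abs(mr - far))
  structure(cand[i], mr = mr[i], far = far[i], eer = (mr[i] + far[i]) / 2)
}
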