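# Diagonal-covariance Gaussian mixture models fitted by EM.
#
# Used for the sinusoid-peak models (lambda_s / lambda_n, 32 components over
# the 2*(2M+1)-dimensional peak features). Initialisation is a seeded
# k-means partition (stats::kmeans); a variance floor keeps components from
# collapsing; EM stops when the mean log-likelihood improves by less than
# `tol` or after `max_iter` iterations.

fit_diag_gmm <- function(x, n_components, rng_seed = 1L,
                         max_iter = 200L, tol = 1e-4, var_floor = 1e-6) {
  x <- as.matrix(x)
  n <- nrow(x); d <- ncol(x)
  stopifnot(n_components >= 1L, n >= n_components)
  with_rng(rng_seed, {
    if (n_components == 1L) {
      cl <- rep(1L, n)
    } else {
      km <- suppressWarnings(stats::kmeans(x, centers = n_components,
                                           nstart = 1L, iter.max = 30L))
      cl <- km$cluster
    }
    w <- tabulate(cl, n_components) / n
    mu <- matrix(0, n_components, d)
    vr <- matrix(1, n_components, d)
    gv <- apply(x, 2L, stats::var); gv[!is.finite(gv) | gv <= 0] <- 1
    for (k in seq_len(n_components)) {
      xk <- x[cl == k, , drop = FALSE]
      if (nrow(xk) >= 1L) mu[k, ] <- colMeans(xk)
      if (nrow(xk) >= 2L) {
        vk <- apply(xk, 2L, stats::var)
        vr[k, ] <- pmax(ifelse(is.finite(vk), vk, gv), var_floor)
      } else vr[k, ] <- pmax(gv, var_floor)
    }
    w <- pmax(w, 1e-10); w <- w / sum(w)
    prev <- -Inf; trace <- numeric(0)
    for (it in seq_len(max_iter)) {
      lp <- gmm_component_logdens(x, mu, vr) +
        matrix(log(w), n, n_components, byrow = TRUE)
      lse <- logsumexp_rows(lp)
      ll <- mean(lse)
      trace <- c(trace, ll)
      r <- exp(lp - lse)
      nk <- colSums(r)
      low <- nk < 1e-8
      nk[low] <- 1e-8
      w <- nk / sum(nk)
      mu <- (t(r) %*% x) / nk
      ex2 <- (t(r) %*% (x^2)) / nk
      vr <- pmax(ex2 - mu^2, var_floor)
      if (any(vr <= var_floor + 1e-15))
        ad_log("variance floor applied in EM iteration ", it)
      if (is.finite(prev) && ll - prev < tol) break
      prev <- ll
    }
    structure(list(weights = w, means = mu, vars = vr,
                   loglik_trace = trace, var_floor = var_floor),
              class = "diag_gmm")
  })
}

# n x K matrix of per-component Gaussian log-densities.
gmm_component_logdens <- function(x, mu, vr) {
  d <- ncol(x)
  cst <- -0.5 * d * log(2 * pi) - 0.5 * rowSums(log(vr))  # per component
  q <- x^2 %*% t(1 / vr) - 2 * (x %*% t(mu / vr)) +
    matrix(rowSums(mu^2 / vr), nrow(x), nrow(mu), byrow = TRUE)
  sweep(-0.5 * q, 2L, cst, `+`)
}

# Mixture log-density of each row of x.
gmm_logdens <- function(model, x) {
  x <- as.matrix(x)
  if (ncol(x) != ncol(model$means)) stop("feature/model dimension mismatch")
  lp <- gmm_component_logdens(x, model$means, model$vars) +
    matrix(log(model$weights), nrow(x), length(model$weights), byrow = TRUE)
  logsumexp_rows(lp)
}
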