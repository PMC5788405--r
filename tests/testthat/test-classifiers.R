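test_that("the Gaussian detector recovers known class parameters and is a
           closed-form (repeatable) estimator", {
  set.seed(1)
  mu1 <- c(2, -1, 0.5); mu0 <- c(-2, 1, 0)
  s1 <- c(1, 2, 0.5); s0 <- c(2, 1, 1)
  n <- 10000
  x <- rbind(sweep(sweep(matrix(stats::rnorm(3 * n), n), 2, s1, `*`), 2, mu1, `+`),
             sweep(sweep(matrix(stats::rnorm(3 * n), n), 2, s0, `*`), 2, mu0, `+`))
  y <- rep(c(1, 0), each = n)
  d <- train_gmm_detector(x, y)
  se1 <- s1 / sqrt(n); se0 <- s0 / sqrt(n)
  expect_true(all(abs(d$alarm$mean - mu1) < 3 * se1))
  expect_true(all(abs(d$nonalarm$mean - mu0) < 3 * se0))
  expect_equal(d$alarm$var, unname(s1^2), tolerance = 0.1)
  d2 <- train_gmm_detector(x, y)
  expect_identical(d, d2)
})

test_that("a degenerate constant class hits the variance floor", {
  x <- rbind(matrix(1, 5, 2), matrix(0, 5, 2))
  y <- rep(c(1, 0), each = 5)
  d <- train_gmm_detector(x, y)
  expect_equal(unname(d$alarm$mean), c(1, 1))
  expect_equal(unname(d$alarm$var), c(1e-6, 1e-6))
  expect_error(train_gmm_detector(x[c(1, 6:10), ], c(1, rep(0, 5))),
               "insufficient class data")
})

test_that("frame posteriors are normalised and reproduce likelihood
           ratios", {
  d <- structure(list(alarm = list(mean = 0, var = 1),
                      nonalarm = list(mean = 1, var = 1), dim = 1L),
                 class = "gmm_detector")
  # equal likelihoods at the midpoint
  p <- frame_posteriors(d, matrix(0.5))
  expect_equal(p$log_alarm, log(0.5), tolerance = 1e-12)
  expect_equal(p$log_nonalarm, log(0.5), tolerance = 1e-12)
  # a 9:1 likelihood ratio gives posterior 0.9
  x9 <- (1 - 2 * log(9)) / 2
  p9 <- frame_posteriors(d, matrix(x9))
  expect_equal(exp(p9$log_alarm), 0.9, tolerance = 1e-9)
  set.seed(2)
  pr <- frame_posteriors(d, matrix(stats::rnorm(100)))
  expect_true(all(abs(exp(pr$log_alarm) + exp(pr$log_nonalarm) - 1) < 1e-9))
  expect_true(all(pr$log_alarm <= 0 & pr$log_nonalarm <= 0))
  expect_error(frame_posteriors(d, matrix(0, 2, 3)), "dimension mismatch")
})

test_that("the neural detector balances classes, learns separable data and
           is bit-reproducible under a fixed seed", {
  set.seed(3)
  x <- rbind(matrix(stats::rnorm(800, 3), ncol = 2),
             matrix(stats::rnorm(1200, -3), ncol = 2))
  y <- c(rep(1, 400), rep(0, 600))
  hp <- nn_hyperparameters(
    unsup = list(lr = 0.001, epochs = 10, momentum = 0.9, decay = 2e-7),
    sup = list(lr = 0.01, epochs = 20, momentum = 0.9, decay = 1.2e-4))
  d <- train_nn_detector(x, y, hp, rng_seed = 4)
  expect_equal(d$training_log$n_per_class, 400L)   # majority down-sampled
  acc <- mean((detector_scores(d, x) > 0.5) == y)
  expect_gte(acc, 0.99)
  d2 <- train_nn_detector(x, y, hp, rng_seed = 4)
  expect_identical(d$W1, d2$W1)
  expect_identical(d$w2, d2$w2)
  p <- frame_posteriors(d, x)
  expect_true(all(abs(exp(p$log_alarm) + exp(p$log_nonalarm) - 1) < 1e-9))
})

test_that("EER threshold selection matches the Gaussian closed form and is
           symmetric", {
  thr <- select_eer_threshold(c(1, 1, 1, 0, 0, 0), c(1, 1, 1, 0, 0, 0))
  expect_equal(as.numeric(thr), 0.5)
  expect_equal(attr(thr, "mr"), 0)
  expect_equal(attr(thr, "far"), 0)
  set.seed(5)
  sc <- c(stats::rnorm(1e5, 1), stats::rnorm(1e5, -1))
  y <- rep(c(1, 0), each = 1e5)
  t2 <- select_eer_threshold(sc, y)
  expect_lt(abs(as.numeric(t2)), 0.05)
  expect_equal(attr(t2, "eer"), stats::pnorm(-1), tolerance = 0.01)
  expect_lte(abs(attr(t2, "mr") - attr(t2, "far")), 0.01)
  # swapping labels and negating scores negates the threshold
  set.seed(6)
  sc3 <- stats::rnorm(500); y3 <- rep(c(0, 1), 250)
  ta <- select_eer_threshold(sc3, y3)
  tb <- select_eer_threshold(-sc3, 1 - y3)
  expect_equal(as.numeric(tb), -as.numeric(ta), tolerance = 1e-9)
  expect_error(select_eer_threshold(1:5, rep(1, 5)), "cannot compute EER")
})

test_that("the selected threshold generalises: held-out |MR - FAR| stays
           within a percentage point", {
  set.seed(7)
  gen <- function(n) list(s = c(stats::rnorm(n, 1), stats::rnorm(n, -1)),
                          y = rep(c(1, 0), each = n))
  tr <- gen(5e4); te <- gen(5e4)
  thr <- select_eer_threshold(tr$s, tr$y)
  mr <- mean(te$s[te$y == 1] <= thr)
  far <- mean(te$s[te$y == 0] > thr)
  expect_lte(abs(mr - far), 0.01)
})
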