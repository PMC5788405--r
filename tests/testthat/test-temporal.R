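# Brute-force oracle for the period-probability double sum.
period_prob_brute <- function(d, L_sig, L_sil) {
  T <- length(d); Lp <- L_sig + L_sil
  vapply(seq_len(T - Lp + 1L), function(t) {
    sum(d[t:(t + L_sig - 1L)]) - sum(d[(t + L_sig):(t + Lp - 1L)])
  }, numeric(1))
}

test_that("the period curve reproduces ideal-posterior arithmetic", {
  d <- rep(c(1, 1, -1, -1), 5)                  # L_sig = L_sil = 2
  cv <- period_probability(d, 2, 2)
  expect_equal(cv$values[1], 4)                  # aligned: L_sig + L_sil
  expect_equal(cv$values[2], 0)                  # quarter-period offset
  expect_equal(cv$values[3], -4)                 # half period: anti-aligned
  expect_equal(length(cv$values), length(d) - 4 + 1)
  expect_error(period_probability(c(1, -1), 2, 2), "shorter than one alarm period")
})

test_that("the cumulative-sum implementation equals the brute-force double
           sum on random posteriors", {
  set.seed(1)
  for (i in 1:25) {
    L_sig <- sample(1:9, 1); L_sil <- sample(1:9, 1)
    T <- L_sig + L_sil + sample(5:40, 1)
    d <- stats::rnorm(T)
    cv <- period_probability(d, L_sig, L_sil)
    expect_equal(cv$values, period_prob_brute(d, L_sig, L_sil),
                 tolerance = 1e-9)
  }
})

test_that("period-peak picking thresholds, separates and orders peaks", {
  cv <- structure(list(values = c(0, 1, 0, 2, 0), start_frames = 1:5,
                       L_sig = 1L, L_sil = 1L, n_frames = 5L),
                  class = "period_curve")
  expect_length(pick_period_peaks(cv, 5, 4)$timestamps, 0L)
  # two equal peaks half a period apart: only the earlier survives
  cv2 <- structure(list(values = c(0, 3, 0, 3, 0), start_frames = 1:5,
                        L_sig = 1L, L_sil = 1L, n_frames = 5L),
                   class = "period_curve")
  ev <- pick_period_peaks(cv2, 1, period_frames = 4)
  expect_equal(ev$timestamps, 2L)
  # a synthetic 3-period ideal sequence yields 3 timestamps at the starts
  d <- rep(c(rep(1, 3), rep(-1, 4)), 3)
  cv3 <- period_probability(d, 3, 4)
  ev3 <- pick_period_peaks(cv3, 3, period_frames = 7)
  expect_length(ev3$timestamps, 3L)
  expect_true(all(abs(ev3$timestamps - c(1, 8, 15)) <= 1))
})

test_that("majority voting matches a brute-force windowed majority", {
  expect_equal(majority_vote_smooth(rep(1L, 10), 3), rep(1L, 10))
  expect_equal(majority_vote_smooth(c(0, 0, 1, 0, 0), 3), rep(0L, 5))
  brute <- function(y, w) {
    h <- (w - 1) %/% 2
    vapply(seq_along(y), function(i) {
      win <- y[max(1, i - h):min(length(y), i + h)]
      if (2 * sum(win) > length(win)) 1L
      else if (2 * sum(win) < length(win)) 0L else y[i]
    }, integer(1))
  }
  set.seed(2)
  for (i in 1:10) {
    y <- sample(0:1, 30, replace = TRUE)
    w <- sample(c(3, 5, 7), 1)
    expect_equal(majority_vote_smooth(y, w), brute(y, w))
  }
  # an even window is forced odd
  expect_equal(majority_vote_smooth(c(0, 1, 1, 1, 0), 4),
               majority_vote_smooth(c(0, 1, 1, 1, 0), 5))
  # smoothing never flips a label that agrees with its neighbourhood
  set.seed(3)
  for (i in 1:10) {
    y <- sample(0:1, 40, replace = TRUE)
    s <- majority_vote_smooth(y, 5)
    agree <- brute(y, 5) == y
    expect_true(all(s[agree] == y[agree]))
  }
})

test_that("labels and period events convert both ways and round-trip", {
  y <- c(0, 0, 1, 1, 1, 0, 0, 1, 1, 1)
  ev <- labels_periods_convert(y, min_sep = 1)
  expect_equal(ev$timestamps, c(3L, 8L))
  y2 <- labels_periods_convert(ev, L_sig = 3, direction = "to_labels",
                               n_frames = 10)
  expect_equal(y2, y)
  # a run starting too close to the previous event is not emitted
  ev2 <- labels_periods_convert(y, min_sep = 6)
  expect_equal(ev2$timestamps, 3L)
  # round trip with sufficient separation
  ev3 <- new_event_set(c(2L, 9L, 17L))
  lab <- labels_periods_convert(ev3, L_sig = 4, direction = "to_labels",
                                n_frames = 22)
  back <- labels_periods_convert(lab, min_sep = 4)
  expect_equal(back$timestamps, ev3$timestamps)
})

test_that("the combined decision keeps only runs that coincide with a
           temporal-model period", {
  y <- c(0, 1, 1, 0, 0, 0, 1, 1, 0, 0)
  expect_equal(combine_decisions(y, integer(0), L_sig = 4), rep(0L, 10))
  expect_equal(combine_decisions(y, c(2L), L_sig = 4), c(0, 1, 1, rep(0, 7)))
  # boundary: onset within ceiling(L_sig/2) kept, beyond removed
  L <- 4
  run <- c(rep(0, 9), 1, 1, rep(0, 9))           # onset at frame 10
  expect_equal(combine_decisions(run, 10L - L / 2, L), run)
  expect_equal(combine_decisions(run, 10L - (L / 2 + 1), L), rep(0L, 20))
})
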