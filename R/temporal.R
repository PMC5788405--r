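# Temporal structure: period-probability aggregation, peak picking,
# majority-vote smoothing, and the three decision methods.

#' Create an event set
#'
#' Alarm-period timestamps (1-based frame indices of period starts),
#' reference or hypothesised.
#'
#' @param timestamps Strictly increasing integer frame indices.
#' @param class_id Optional alarm-class id.
#' @param kind `"reference"` or `"hypothesis"`.
#' @param scores Optional per-event scores (e.g. period-curve values).
#' @return An `event_set` object.
#' @export
new_event_set <- function(timestamps, class_id = NULL,
                          kind = c("hypothesis", "reference"),
                          scores = NULL) {
  kind <- match.arg(kind)
  timestamps <- as.integer(timestamps)
  if (is.unsorted(timestamps, strictly = TRUE)) stop("timestamps must be strictly increasing")
  structure(list(timestamps = timestamps, class_id = class_id, kind = kind,
                 scores = scores),
            class = "event_set")
}

#' @export
print.event_set <- function(x, ...) {
  cat(sprintf("<event_set:%s%s> %d events\n", x$kind,
              if (is.null(x$class_id)) "" else paste0(" ", x$class_id),
              length(x$timestamps)))
  invisible(x)
}

event_times <- function(x) if (inherits(x, "event_set")) x$timestamps else as.integer(x)

#' Period-probability curve
#'
#' Aggregates the per-frame log-posterior contrast `d(t) = P_A - P_NA` over
#' one alarm period: at each candidate start frame `t`,
#' `P_period(t) = sum(d over the L_sig signal frames) - sum(d over the
#' following L_sil silence frames)`, so the curve peaks where a full
#' signal-then-silence period begins. Computed with cumulative sums; equal
#' to the direct double sum to numerical precision.
#'
#' @param post A `frame_posteriors` object (or numeric vector already equal
#'   to `P_A - P_NA`).
#' @param L_sig,L_sil Signal and silence interval lengths in frames (>= 1).
#' @return A `period_curve` object: list with `values`, `start_frames`
#'   (1-based candidate start frames), `L_sig`, `L_sil`, `n_frames`.
#' @export
period_probability <- function(post, L_sig, L_sil) {
  d <- if (inherits(post, "frame_posteriors")) post$log_alarm - post$log_nonalarm
       else as.numeric(post)
  L_sig <- as.integer(L_sig); L_sil <- as.integer(L_sil)
  stopifnot(L_sig >= 1L, L_sil >= 1L)
  T <- length(d); Lp <- L_sig + L_sil
  if (T < Lp) stop("sequence shorter than one alarm period")
  cs <- c(0, cumsum(d))
  t <- seq_len(T - Lp + 1L)
  sig <- cs[t + L_sig] - cs[t]
  sil <- cs[t + Lp] - cs[t + L_sig]
  structure(list(values = sig - sil, start_frames = t,
                 L_sig = L_sig, L_sil = L_sil, n_frames = T),
            class = "period_curve")
}

# Strict local maxima of a numeric vector; plateaus take the lowest index;
# the two boundary points count when they exceed their single neighbour.
local_maxima <- function(v) {
  n <- length(v)
  if (n == 1L) return(1L)
  left_ok <- c(TRUE, v[-1L] > v[-n])
  right_ok <- c(v[-n] >= v[-1L], TRUE)
  which(left_ok & right_ok)
}

#' Pick alarm-period starts from a period curve
#'
#' Local maxima of the curve above a class-specific threshold are accepted
#' greedily in descending curve value (ties to the earlier frame); a
#' candidate closer than 75% of the alarm period to an already accepted
#' peak is discarded.
#'
#' @param curve A `period_curve`.
#' @param threshold Class-specific threshold on the curve value.
#' @param period_frames Alarm period duration in frames (>= 1).
#' @param class_id Optional class id for the returned events.
#' @return A hypothesis `event_set` (timestamps in curve frame indices).
#' @export
pick_period_peaks <- function(curve, threshold, period_frames,
                              class_id = NULL) {
  stopifnot(period_frames >= 1)
  min_sep <- 0.75 * period_frames
  cand <- local_maxima(curve$values)
  cand <- cand[curve$values[cand] > threshold]
  if (length(cand) == 0L)
    return(new_event_set(integer(0), class_id, "hypothesis"))
  ord <- cand[order(-curve$values[cand], cand)]
  acc <- integer(0)
  for (t in ord) if (all(abs(t - acc) >= min_sep)) acc <- c(acc, t)
  acc <- sort(acc)
  new_event_set(curve$start_frames[acc], class_id, "hypothesis",
                scores = curve$values[acc])
}

#' Majority-vote smoothing of binary frame labels
#'
#' Each output label is the majority over a centred window (forced up to
#' the nearest odd length); windows are truncated at the sequence edges,
#' where a tie keeps the input label.
#'
#' @param labels Binary vector (0/1).
#' @param window Window length in frames (>= 1); even values are increased
#'   by one.
#' @return Smoothed binary vector of the same length.
#' @export
majority_vote_smooth <- function(labels, window) {
  stopifnot(window >= 1)
  w <- as.integer(window)
  if (w %% 2L == 0L) w <- w + 1L
  h <- (w - 1L) %/% 2L
  y <- as.integer(labels)
  T <- length(y)
  if (T == 0L || h == 0L) return(y)
  cs <- c(0L, cumsum(y))
  a <- pmax(seq_len(T) - h, 1L)
  b <- pmin(seq_len(T) + h, T)
  ones <- cs[b + 1L] - cs[a]
  n <- b - a + 1L
  ifelse(2L * ones > n, 1L, ifelse(2L * ones < n, 0L, y))
}

#' Convert between frame labels and period events
#'
#' `direction = "to_events"`: the onset of each maximal run of 1s becomes a
#' period timestamp; a run starting closer than `min_sep` frames to the
#' previously accepted timestamp is not emitted. `direction = "to_labels"`:
#' the `L_sig` frames from each timestamp onward are set to 1 (clipped at
#' the sequence end).
#'
#' @param x Binary labels (for `"to_events"`) or an `event_set` /
#'   timestamp vector (for `"to_labels"`).
#' @param L_sig Signal-interval length in frames (used by `"to_labels"`).
#' @param min_sep Minimum separation between emitted events in frames.
#' @param direction `"to_events"` or `"to_labels"`.
#' @param n_frames Total sequence length (required for `"to_labels"`).
#' @param class_id Optional class id for emitted events.
#' @return An `event_set` or a binary label vector.
#' @export
labels_periods_convert <- function(x, L_sig = NULL, min_sep = 1L,
                                   direction = c("to_events", "to_labels"),
                                   n_frames = NULL, class_id = NULL) {
  direction <- match.arg(direction)
  if (direction == "to_events") {
    y <- as.integer(x)
    onsets <- which(diff(c(0L, y)) == 1L)
    acc <- integer(0)
    for (o in onsets) {
      if (length(acc) == 0L || o - acc[length(acc)] >= min_sep)
        acc <- c(acc, o)
    }
    new_event_set(acc, class_id, "hypothesis")
  } else {
    stopifnot(!is.null(L_sig), !is.null(n_frames))
    ts <- event_times(x)
    y <- integer(n_frames)
    for (t in ts) {
      if (t > n_frames) next
      y[t:min(n_frames, t + L_sig - 1L)] <- 1L
    }
    y
  }
}

#' Combine frame-level and period-level decisions
#'
#' Third decision method: every maximal run of alarm labels (method 1)
#' whose onset has no period timestamp from the temporal model (method 2)
#' within `+/- ceil(L_sig/2)` frames is reassigned to the non-alarm class;
#' all other frames are left unchanged.
#'
#' @param method1_labels Binary frame labels from thresholding + smoothing.
#' @param method2_events An `event_set` (or timestamp vector) from
#'   [pick_period_peaks()].
#' @param L_sig Signal-interval length in frames.
#' @return Binary label vector.
#' @export
combine_decisions <- function(method1_labels, method2_events, L_sig) {
  y <- as.integer(method1_labels)
  ts <- event_times(method2_events)
  tol <- ceiling(L_sig / 2)
  d <- diff(c(0L, y))
  onsets <- which(d == 1L)
  ends <- which(diff(c(y, 0L)) == -1L)
  for (i in seq_along(onsets)) {
    if (length(ts) == 0L || min(abs(onsets[i] - ts)) > tol)
      y[onsets[i]:ends[i]] <- 0L
  }
  y
}
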