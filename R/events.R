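#' Decode daily probabilities into discrete predicted events
#'
#' A predicted event is each maximal run of at least `min_run_days`
#' consecutive days with probability above `threshold`; its start is the
#' run's first day and `peak_prob` the run's maximum.
#'
#' @param probs numeric vector of daily probabilities in \[0, 1\].
#' @param threshold decision threshold in (0, 1); default 0.5.
#' @param min_run_days minimum run length (default 1).
#' @return A data frame with columns `start` (0-based day), `end`
#'   (0-based last day of the run) and `peak_prob`.
#' @export
probabilities_to_events <- function(probs, threshold = 0.5,
                                    min_run_days = 1L) {
  if (threshold <= 0 || threshold >= 1)
    stop("threshold must lie in (0, 1)")
  r <- rle(probs > threshold)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_run_days
  data.frame(
    start = starts[keep] - 1L,
    end = ends[keep] - 1L,
    peak_prob = vapply(which(keep), function(i)
      max(probs[starts[i]:ends[i]]), numeric(1)))
}

#' Match predicted to actual event starts with a -3/+6-day tolerance
#'
#' Actual events are processed in order; each actual start `a` opens the
#' window `[a - early_tolerance, a + late_tolerance]`. The earliest
#' not-yet-consumed predicted start inside the window is a true positive
#' (only the first prediction in a window counts); every further
#' prediction in that window, and any prediction matching no window, is
#' a false positive. Unmatched actual events are false negatives. A
#' field-season with neither actual nor predicted events contributes one
#' true negative.
#'
#' @param predicted,actual sorted integer vectors of start days.
#' @param early_tolerance days a prediction may precede the actual start
#'   (default 3).
#' @param late_tolerance days it may follow it (default 6).
#' @return A list with counts `TP`, `TN`, `FP`, `FN`.
#' @export
match_events <- function(predicted, actual, early_tolerance = 3L,
                         late_tolerance = 6L) {
  if (is.unsorted(predicted) || is.unsorted(actual))
    stop("start lists must be sorted")
  used <- logical(length(predicted))
  tp <- fn <- 0L
  for (a in actual) {
    inwin <- which(!used & predicted >= a - early_tolerance &
                     predicted <= a + late_tolerance)
    if (length(inwin)) {
      used[inwin[1]] <- TRUE  # earliest unconsumed prediction is the TP
      tp <- tp + 1L
    } else fn <- fn + 1L
  }
  # every further prediction in a window, and any prediction matching no
  # window, ends up unconsumed and counts as an FP
  fp <- sum(!used)
  tn <- if (!length(actual) && !length(predicted)) 1L else 0L
  list(TP = tp, TN = tn, FP = fp, FN = fn)
}

#' Event-level binary accuracy
#'
#' `acc = (TP + TN) / (TP + TN + FP + FN)` over event-level counts
#' pooled across fields.
#'
#' @param counts a list with `TP`, `TN`, `FP`, `FN`.
#' @return Accuracy in \[0, 1\].
#' @export
event_accuracy <- function(counts) {
  total <- counts$TP + counts$TN + counts$FP + counts$FN
  if (total == 0) stop("no events counted")
  (counts$TP + counts$TN) / total
}

# pool match counts over fields
sum_counts <- function(counts_list) {
  Reduce(function(a, b) list(TP = a$TP + b$TP, TN = a$TN + b$TN,
                             FP = a$FP + b$FP, FN = a$FN + b$FN),
         counts_list, list(TP = 0L, TN = 0L, FP = 0L, FN = 0L))
}

#' Season-level mowing score per field
#'
#' Probability that at least one mowing event occurred during the
#' season. The default treats days as independent detections
#' (`noisy_or`: `1 - prod(1 - p_d)`); `"max"` uses the season's maximum
#' daily probability instead.
#'
#' @param probs fields x days probability matrix.
#' @param method `"noisy_or"` or `"max"`.
#' @return Numeric vector of season scores, one per field.
#' @export
season_scores <- function(probs, method = c("noisy_or", "max")) {
  method <- match.arg(method)
  switch(method,
         noisy_or = 1 - apply(1 - probs, 1L, prod),
         max = apply(probs, 1L, max))
}

#' End-of-season accuracy
#'
#' A field is predicted mown when its season score exceeds `threshold`
#' (more than 50% by default); the accuracy is the fraction of fields
#' whose predicted status matches the label.
#'
#' @param scores season scores (one per field, aligned with `mown`).
#' @param mown logical vector of true mown status.
#' @param threshold decision threshold (default 0.5).
#' @return Accuracy in \[0, 1\].
#' @export
eos_accuracy <- function(scores, mown, threshold = 0.5) {
  if (length(scores) != length(mown))
    stop("scores and mown flags are misaligned")
  mean((scores > threshold) == mown)
}

#' Rank-based ROC AUC
#'
#' Normalized Mann-Whitney U statistic: the probability that a random
#' mown field scores above a random non-mown field, with ties counting
#' one half.
#'
#' @param scores numeric season scores.
#' @param flags logical (or 0/1) class labels; both classes required.
#' @return AUC in \[0, 1\].
#' @export
auc_roc <- function(scores, flags) {
  flags <- as.logical(flags)
  n_pos <- sum(flags); n_neg <- sum(!flags)
  if (n_pos == 0 || n_neg == 0)
    stop("both classes must be present to compute AUC")
  r <- rank(scores)  # midranks give the tie = 1/2 convention
  (sum(r[flags]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Calibration curve over equal-width probability bins
#'
#' @param scores predicted probabilities in \[0, 1\].
#' @param flags observed binary outcomes.
#' @param n_bins number of equal-width bins on \[0, 1\] (>= 2).
#' @return A data frame with one row per bin: `bin_low`, `bin_high`,
#'   `mean_predicted`, `observed_fraction`, `count` (empty bins have
#'   count 0 and `NA` means).
#' @export
calibration_curve <- function(scores, flags, n_bins = 10L) {
  if (!length(scores)) stop("empty input")
  if (length(scores) != length(flags))
    stop("scores and flags are misaligned")
  if (any(scores < 0 | scores > 1)) stop("scores must lie in [0, 1]")
  n_bins <- as.integer(n_bins)
  if (n_bins < 2L) stop("n_bins must be >= 2")
  edges <- seq(0, 1, length.out = n_bins + 1L)
  bin <- pmin(findInterval(scores, edges, rightmost.closed = TRUE),
              n_bins)
  flags <- as.numeric(as.logical(flags))
  out <- data.frame(bin_low = edges[-(n_bins + 1L)], bin_high = edges[-1])
  out$mean_predicted <- out$observed_fraction <- NA_real_
  out$count <- 0L
  for (b in seq_len(n_bins)) {
    i <- bin == b
    if (any(i)) {
      out$mean_predicted[b] <- mean(scores[i])
      out$observed_fraction[b] <- mean(flags[i])
      out$count[b] <- sum(i)
    }
  }
  out
}

#' Evaluate daily probabilities against a labelled feature matrix
#'
#' Decodes events per field, matches them with the -3/+6-day window,
#' and computes event accuracy, end-of-season accuracy, season-score
#' AUC and the calibration table.
#'
#' @param probs fields x days probability matrix (rows aligned with
#'   `fm$field_ids`).
#' @param fm a `feature_matrix` carrying true starts and labels.
#' @param eval_cfg list with `threshold`, `min_run_days`,
#'   `early_tolerance`, `late_tolerance`, `season_score` (see
#'   [load_config()]).
#' @return A list with `counts`, `event_accuracy`, `eos_accuracy`,
#'   `auc`, `scores`, `mown`, `calibration`, `events` (decoded predicted
#'   starts per field).
#' @export
evaluate_predictions <- function(probs, fm,
                                 eval_cfg = default_config()$eval) {
  n <- nrow(probs)
  if (n != length(fm$field_ids)) stop("probability rows do not match fields")
  events <- vector("list", n)
  counts <- vector("list", n)
  for (i in seq_len(n)) {
    ev <- probabilities_to_events(probs[i, ], eval_cfg$threshold,
                                  eval_cfg$min_run_days)
    events[[i]] <- ev$start
    counts[[i]] <- match_events(ev$start, fm$starts[[i]],
                                eval_cfg$early_tolerance,
                                eval_cfg$late_tolerance)
  }
  total <- sum_counts(counts)
  mown <- vapply(fm$starts, function(s) length(s) > 0L, logical(1))
  scores <- season_scores(probs, eval_cfg$season_score)
  list(counts = total,
       event_accuracy = event_accuracy(total),
       eos_accuracy = eos_accuracy(scores, mown, eval_cfg$threshold),
       auc = if (any(mown) && !all(mown)) auc_roc(scores, mown)
             else NA_real_,
       scores = scores, mown = mown,
       calibration = calibration_curve(pmin(pmax(scores, 0), 1), mown),
       events = setNames(events, fm$field_ids))
}
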