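#' Fit the abstention interval from validation scores
#'
#' Chooses the reject region `(t_low, t_upper)` over season-level
#' scores so that the requested rates are met on the validation set:
#' `t_upper` is the `k`-th positive score in descending order with
#' `k = ceiling(desired_tpr * n_pos)`, so at least `k` positives score
#' `>= t_upper` and are decided mown; `t_low` is the `m`-th negative
#' score in ascending order with `m = ceiling(desired_tnr * n_neg)`, so
#' at least `m` negatives score `<= t_low` and are decided not mown.
#' Scores strictly inside the interval are abstained; if `t_low >=
#' t_upper` the interval is empty and nothing is rejected (reported via
#' a warning).
#'
#' @param scores validation season scores in \[0, 1\].
#' @param flags logical mown status; both classes must be present.
#' @param desired_tpr,desired_tnr requested true-positive and
#'   true-negative rates in (0, 1\].
#' @return A list of class `reject_interval` with `t_low`, `t_upper`,
#'   `desired_tpr`, `desired_tnr`, `empty`.
#' @export
fit_reject_interval <- function(scores, flags, desired_tpr = 0.97,
                                desired_tnr = 0.75) {
  flags <- as.logical(flags)
  if (length(scores) != length(flags))
    stop("scores and flags are misaligned")
  if (!any(flags) || all(flags))
    stop("both classes must be present in the validation set")
  for (r in c(desired_tpr, desired_tnr))
    if (r <= 0 || r > 1) stop("desired rates must lie in (0, 1]")
  pos <- sort(scores[flags], decreasing = TRUE)
  neg <- sort(scores[!flags])
  k <- ceiling(desired_tpr * length(pos))
  m <- ceiling(desired_tnr * length(neg))
  t_upper <- pos[k]
  t_low <- neg[m]
  empty <- t_low >= t_upper
  if (empty)
    warning("requested rates force t_low >= t_upper; ",
            "interval is empty and nothing will be rejected")
  structure(list(t_low = t_low, t_upper = t_upper,
                 desired_tpr = desired_tpr, desired_tnr = desired_tnr,
                 empty = empty),
            class = "reject_interval")
}

#' @export
print.reject_interval <- function(x, ...) {
  cat(sprintf(
    "<reject_interval> (%.4f, %.4f)%s  [tpr >= %.2f, tnr >= %.2f]\n",
    x$t_low, x$t_upper, if (x$empty) " (empty)" else "",
    x$desired_tpr, x$desired_tnr))
  invisible(x)
}

#' Apply an abstention interval to season scores
#'
#' Scores `>= t_upper` are decided `mown`, scores `<= t_low` are decided
#' `not_mown`, scores strictly inside the interval are `abstain` (ties
#' with a threshold are decided, not abstained). The summary reports the
#' fraction rejected and, when true flags are supplied, accuracy on the
#' retained decisions only (`NA` when everything is rejected).
#'
#' @param scores season scores in \[0, 1\].
#' @param interval a [fit_reject_interval()] result.
#' @param flags optional true mown status for the summary accuracy.
#' @param field_ids optional ids for the per-field table.
#' @return A list with `decisions` (data frame: `field_id`,
#'   `season_score`, `decision`) and `summary` (list: `n`,
#'   `n_rejected`, `fraction_rejected`, `retained_accuracy`).
#' @export
apply_reject <- function(scores, interval, flags = NULL,
                         field_ids = NULL) {
  if (any(scores < 0 | scores > 1)) stop("scores must lie in [0, 1]")
  if (is.null(field_ids)) field_ids <- as.character(seq_along(scores))
  decision <- ifelse(scores >= interval$t_upper, "mown",
                     ifelse(scores <= interval$t_low, "not_mown",
                            "abstain"))
  # when t_low >= t_upper no score lies strictly between them, so an
  # empty interval abstains on nothing by construction
  retained <- decision != "abstain"
  acc <- NA_real_
  if (!is.null(flags) && any(retained)) {
    flags <- as.logical(flags)
    acc <- mean((decision[retained] == "mown") == flags[retained])
  }
  list(decisions = data.frame(field_id = field_ids,
                              season_score = scores,
                              decision = decision),
       summary = list(n = length(scores),
                      n_rejected = sum(!retained),
                      fraction_rejected = mean(!retained),
                      retained_accuracy = acc))
}
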