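#' Permutation feature importance
#'
#' The importance of a feature is the mean drop of a performance metric
#' when that feature's values are shuffled across fields, breaking its
#' link to the outcome. The permutation unit is the whole field-season
#' series (block permutation across fields), which preserves each
#' series' autocorrelation.
#'
#' @param predict_fn function taking a `feature_matrix` and returning a
#'   fields x days probability matrix.
#' @param fm a `feature_matrix`.
#' @param metric `"auc_roc"`, `"event_accuracy"` or `"eos_accuracy"`.
#' @param n_repeats permutations per feature (>= 1).
#' @param seed integer seed for the permutations.
#' @param eval_cfg decoding/evaluation settings (see [load_config()]).
#' @return A data frame of class `importance_report` with one row per
#'   feature: `feature`, `importance` (mean metric drop), `sd`,
#'   `baseline`; sorted by decreasing importance.
#' @export
permutation_importance <- function(predict_fn, fm,
                                   metric = c("auc_roc",
                                              "event_accuracy",
                                              "eos_accuracy"),
                                   n_repeats = 10L, seed = 1L,
                                   eval_cfg = default_config()$eval) {
  metric <- match.arg(metric)
  n_repeats <- as.integer(n_repeats)
  if (n_repeats < 1L) stop("n_repeats must be >= 1")
  score <- function(m) {
    ev <- evaluate_predictions(predict_fn(m), m, eval_cfg)
    switch(metric, auc_roc = ev$auc, event_accuracy = ev$event_accuracy,
           eos_accuracy = ev$eos_accuracy)
  }
  baseline <- score(fm)
  old <- get_rng_state()
  on.exit(set_rng_state(old))
  set.seed(seed)
  n <- dim(fm$values)[1]
  rows <- lapply(seq_along(fm$feature_names), function(f) {
    drops <- vapply(seq_len(n_repeats), function(r) {
      perm <- sample.int(n)
      pm <- fm
      pm$values[, , f] <- fm$values[perm, , f]
      baseline - score(pm)
    }, numeric(1))
    data.frame(feature = fm$feature_names[f],
               importance = mean(drops), sd = stats::sd(drops),
               baseline = baseline)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$importance), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("importance_report", "data.frame")
  out
}

#' Backward feature elimination
#'
#' Starting from all features: train, rank features by permutation
#' importance, and drop the least important one as long as the metric of
#' the retrained model does not decrease; stop at the first removal that
#' would decrease it.
#'
#' @param train_fn function taking a `feature_matrix` and returning a
#'   prediction function (as for [permutation_importance()]).
#' @param fm a `feature_matrix` with at least 2 features.
#' @param metric metric name (see [permutation_importance()]).
#' @param n_repeats permutations per feature for the ranking.
#' @param seed integer seed.
#' @param eval_cfg decoding/evaluation settings.
#' @return A list with `selected` (retained feature names) and
#'   `trajectory` (data frame of the metric after each accepted step).
#' @export
backward_elimination <- function(train_fn, fm,
                                 metric = c("auc_roc",
                                            "event_accuracy",
                                            "eos_accuracy"),
                                 n_repeats = 5L, seed = 1L,
                                 eval_cfg = default_config()$eval) {
  metric <- match.arg(metric)
  if (length(fm$feature_names) < 2L)
    return(list(selected = fm$feature_names,
                trajectory = data.frame(step = 0L,
                                        n_features =
                                          length(fm$feature_names),
                                        dropped = NA_character_,
                                        score = NA_real_)))
  score_of <- function(m) {
    pf <- train_fn(m)
    ev <- evaluate_predictions(pf(m), m, eval_cfg)
    list(pf = pf,
         score = switch(metric, auc_roc = ev$auc,
                        event_accuracy = ev$event_accuracy,
                        eos_accuracy = ev$eos_accuracy))
  }
  keep_features <- function(m, keep) {
    idx <- match(keep, m$feature_names)
    m$values <- m$values[, , idx, drop = FALSE]
    m$feature_names <- keep
    m
  }
  current <- fm$feature_names
  fit <- score_of(fm)
  traj <- data.frame(step = 0L, n_features = length(current),
                     dropped = NA_character_, score = fit$score)
  step <- 0L
  while (length(current) > 1L) {
    sub <- keep_features(fm, current)
    imp <- permutation_importance(fit$pf, sub, metric, n_repeats,
                                  seed + step, eval_cfg)
    weakest <- imp$feature[nrow(imp)]
    cand <- setdiff(current, weakest)
    cand_fit <- score_of(keep_features(fm, cand))
    if (cand_fit$score < fit$score) break
    step <- step + 1L
    current <- cand
    fit <- cand_fit
    traj <- rbind(traj, data.frame(step = step,
                                   n_features = length(current),
                                   dropped = weakest,
                                   score = fit$score))
  }
  list(selected = current, trajectory = traj)
}
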