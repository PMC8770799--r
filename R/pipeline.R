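#' Run the full synthetic-recovery pipeline
#'
#' Simulates a labelled dataset, preprocesses it onto the daily grid,
#' builds the 14-feature matrices, splits fields 64/16/20 into
#' train/validation/test, trains the 1-D convolutional detector with
#' early stopping, evaluates on the held-out test split, and fits and
#' applies the reject region using validation scores.
#'
#' @param sim a [sim_config()]; its seed drives the simulation.
#' @param model_cfg a [model_config()]; its seed drives training.
#' @param eval_cfg decoding/evaluation settings (see [load_config()]).
#' @param reject_cfg list with `desired_tpr`, `desired_tnr`.
#' @param label_width days labelled positive per event.
#' @param split train/validation/test fractions (sums to 1).
#' @param smoothing a [smoothing_config()].
#' @param quiet suppress per-stage messages.
#' @return A list with the trained `model`, per-split `feature_matrix`
#'   objects (`train`, `val`, `test`), test-set `metrics`
#'   (from [evaluate_predictions()]), `probs` (test probabilities),
#'   `reject` (interval + applied summary on the test split) and
#'   `split_ids`.
#' @export
run_pipeline <- function(sim = sim_config(),
                         model_cfg = model_config(),
                         eval_cfg = default_config()$eval,
                         reject_cfg = default_config()$reject,
                         label_width = 7L,
                         split = c(train = 0.64, val = 0.16, test = 0.20),
                         smoothing = smoothing_config(),
                         quiet = FALSE) {
  say <- function(...) if (!quiet) message(...)
  say("simulating ", sim$n_fields, " field-seasons")
  ds <- simulate_dataset(sim)
  say("preprocessing onto the ", sim$window$n_days, "-day grid")
  grids <- suppressMessages(
    preprocess_fields(ds$series, window = sim$window,
                      smoothing = smoothing))

  n <- length(grids)
  old <- get_rng_state()
  on.exit(set_rng_state(old))
  set.seed(model_cfg$seed + 2L)
  ord <- sample.int(n)
  n_tr <- round(split[["train"]] * n)
  n_val <- round(split[["val"]] * n)
  idx <- list(train = ord[seq_len(n_tr)],
              val = ord[n_tr + seq_len(n_val)],
              test = ord[(n_tr + n_val + 1L):n])

  stats <- gap_stats(grids[idx$train])
  fms <- lapply(idx, function(i)
    build_feature_matrix(grids[i], ds$labels, stats,
                         window = sim$window, label_width = label_width))
  say("training on ", length(idx$train), " fields (validating on ",
      length(idx$val), ")")
  model <- train_model(build_model(model_cfg), fms$train, fms$val)
  say("best epoch ", model$history$best_epoch, ", validation BCE ",
      signif(model$history$best_val_loss, 4))

  probs <- predict(model, fms$test)
  metrics <- evaluate_predictions(probs, fms$test, eval_cfg)
  say(sprintf("test: event accuracy %.3f, EOS accuracy %.3f, AUC %.3f",
              metrics$event_accuracy, metrics$eos_accuracy,
              metrics$auc))

  val_probs <- predict(model, fms$val)
  val_eval <- evaluate_predictions(val_probs, fms$val, eval_cfg)
  interval <- fit_reject_interval(val_eval$scores, val_eval$mown,
                                  reject_cfg$desired_tpr,
                                  reject_cfg$desired_tnr)
  rejected <- apply_reject(pmin(pmax(metrics$scores, 0), 1), interval,
                           metrics$mown, fms$test$field_ids)
  say(sprintf("reject region (%.3f, %.3f): %.1f%% rejected, %.3f retained accuracy",
              interval$t_low, interval$t_upper,
              100 * rejected$summary$fraction_rejected,
              rejected$summary$retained_accuracy))

  list(model = model, train = fms$train, val = fms$val, test = fms$test,
       metrics = metrics, probs = probs,
       reject = list(interval = interval, applied = rejected),
       split_ids = idx)
}
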