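# shared fixtures, all built in code at test time

# a small field_series data frame from day offsets (0-based)
series_df <- function(field_id, days, ndvi = NA_real_, cohvv = NA_real_,
                      cohvh = NA_real_, window = season_window()) {
  mowsense:::as_field_series(data.frame(
    field_id = field_id, date = window$start_date + days,
    ndvi = ndvi, cohvv = cohvv, cohvh = cohvh))
}

# assemble a feature_matrix directly from arrays (bypassing the grids),
# deriving per-field starts from 0 -> 1 rises in the label matrix
fm_from_arrays <- function(values, labels, feature_names,
                           window = season_window(n_days = ncol(labels))) {
  ids <- sprintf("S%04d", seq_len(nrow(labels)))
  dimnames(values) <- list(ids, NULL, feature_names)
  dimnames(labels) <- list(ids, NULL)
  starts <- lapply(seq_len(nrow(labels)), function(i) {
    l <- labels[i, ]
    which(l == 1L & c(1L, l[-length(l)] + 1L) != 2L) - 1L
  })
  structure(list(values = values, labels = labels, field_ids = ids,
                 feature_names = feature_names,
                 stats = structure(list(min_diff = 1, max_diff = 10),
                                   class = "gap_stats"),
                 window = window, starts = starts),
            class = "feature_matrix")
}

# synthetic classification problem for the feature-selection tests:
# labels are a threshold of the first feature only (a sharp drop),
# remaining features are independent noise
make_selection_problem <- function(n_fields, n_days = 215L,
                                   n_noise = 2L, seed = 1L) {
  set.seed(seed)
  feats <- c("signal", paste0("noise", seq_len(n_noise),
                              recycle0 = TRUE))
  values <- array(rnorm(n_fields * n_days * (1L + n_noise), sd = 0.15),
                  c(n_fields, n_days, 1L + n_noise))
  labels <- matrix(0L, n_fields, n_days)
  mown <- runif(n_fields) < 0.6
  for (i in which(mown)) {
    s <- sample(10:(n_days - 20L), 1L)
    values[i, s:(s + 6L), 1L] <- values[i, s:(s + 6L), 1L] - 1
    labels[i, (s:(s + 6L)) + 1L] <- 1L
  }
  fm_from_arrays(values, labels, feats)
}

# cheap scorer for selection tests: pooled-day logistic regression on
# the features it is given (independent of the conv detector)
glm_day_scorer <- function(fm) {
  x <- apply(fm$values, 3L, as.vector)
  y <- as.vector(fm$labels)
  fit <- suppressWarnings(
    stats::glm.fit(cbind(1, x), y, family = stats::binomial()))
  beta <- fit$coefficients
  beta[is.na(beta)] <- 0
  function(m) {
    xm <- apply(m$values, 3L, as.vector)
    p <- stats::plogis(drop(cbind(1, xm) %*% beta))
    matrix(p, nrow = dim(m$values)[1], ncol = dim(m$values)[2],
           dimnames = list(m$field_ids, NULL))
  }
}

# exhaustive oracle for event matching: maximise TP over all injective
# prediction -> actual assignments within the tolerance window
match_events_oracle <- function(predicted, actual, early = 3L,
                                late = 6L) {
  np <- length(predicted); na <- length(actual)
  compatible <- outer(predicted, actual, function(p, a)
    p >= a - early & p <= a + late)
  best <- 0L
  assign_rec <- function(ai, used_p, tp) {
    if (ai > na) { best <<- max(best, tp); return(invisible()) }
    assign_rec(ai + 1L, used_p, tp)  # leave this actual unmatched
    if (np) for (pi in seq_len(np))
      if (!used_p[pi] && compatible[pi, ai]) {
        used_p[pi] <- TRUE
        assign_rec(ai + 1L, used_p, tp + 1L)
        used_p[pi] <- FALSE
      }
  }
  assign_rec(1L, logical(np), 0L)
  tp <- best
  list(TP = tp, TN = if (np == 0L && na == 0L) 1L else 0L,
       FP = np - tp, FN = na - tp)
}

# all sorted day subsets of size 0..k from a day grid
day_subsets <- function(days, k) {
  out <- list(integer())
  for (m in seq_len(k))
    out <- c(out, combn(days, m, simplify = FALSE))
  out
}
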