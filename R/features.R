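# fixed feature order; serialized with trained models and prediction
# sidecars so train and predict always agree
MOW_FEATURES <- c("ndvi", "cohvv", "cohvh", "t", "dt",
                  "cohvv_sm", "cohvh_sm", "mixed_coh",
                  "ndvi_diff", "cohvv_sm_diff", "cohvh_sm_diff",
                  "ndvi_der", "cohvh_sm_der", "cohvv_sm_der")

#' The fixed 14-feature order
#'
#' @return Character vector of the feature names in model input order.
#' @export
mow_feature_names <- function() MOW_FEATURES

#' Mixed coherence
#'
#' Geometric mean `sqrt(cohvh * cohvv)` of the two polarization
#' channels; a simple non-linear combination capturing the overall
#' coherence trend.
#'
#' @param cohvh,cohvv coherence values in \[0, 1\] (vectorized).
#' @return Values in \[0, 1\], bounded by the two inputs.
#' @export
mixed_coherence <- function(cohvh, cohvv) {
  if (any(cohvh < 0 | cohvv < 0)) stop("coherence must be >= 0")
  if (any(cohvh > 1 | cohvv > 1)) stop("coherence must be <= 1")
  sqrt(cohvh * cohvv)
}

#' Normalized day of year
#'
#' `t = day_of_year / 365`, with January 1st as day 1. Normalized so the
#' seasonal-date feature enters the network on a comparable scale to the
#' other inputs without relying on batch statistics.
#'
#' @param day_of_year integer day in `1..366` (vectorized).
#' @return Values in (0, 1.003\].
#' @export
normalized_doy <- function(day_of_year) {
  if (any(day_of_year < 1 | day_of_year > 366))
    stop("day_of_year must lie in 1..366")
  day_of_year / 365
}

#' Observation-gap normalization statistics
#'
#' Min/max gap in days between consecutive real measurements, computed
#' from training-split grids only and reused unchanged at prediction
#' time.
#'
#' @param grids list of `daily_grid` objects (the training split).
#' @return A list of class `gap_stats` with `min_diff` and `max_diff`.
#' @export
gap_stats <- function(grids) {
  gaps <- unlist(lapply(grids, function(g) {
    d <- which(g$valid_ndvi | g$valid_coh) - 1L
    if (length(d) > 1L) diff(d) else integer()
  }))
  if (!length(gaps)) stop("no measurement gaps found in training grids")
  out <- list(min_diff = min(gaps), max_diff = max(gaps))
  if (out$min_diff >= out$max_diff)
    stop("degenerate gap statistics: min_diff >= max_diff")
  structure(out, class = "gap_stats")
}

#' Normalized measurement gap
#'
#' Min-max scaling `(diff - min_diff) / (max_diff - min_diff)` of the
#' days elapsed since the previous real measurement, clipped to \[0, 1\]
#' for gaps outside the training range.
#'
#' @param diff gap in days (vectorized, >= 0).
#' @param stats a [gap_stats()] object.
#' @return Values in \[0, 1\].
#' @export
normalized_gap <- function(diff, stats) {
  if (any(diff < 0)) stop("diff must be >= 0")
  if (stats$max_diff == stats$min_diff)
    stop("max_diff must exceed min_diff")
  pmin(pmax((diff - stats$min_diff) /
              (stats$max_diff - stats$min_diff), 0), 1)
}

#' Difference and slope between consecutive real measurements
#'
#' For each valid measurement after the first, `diff` is the change
#' since the previous valid measurement and `slope` is that change per
#' day. Both are assigned on the measurement's day and carried unchanged
#' across the following interpolated days until the next measurement;
#' days up to and including the first measurement get 0.
#'
#' @param values daily value vector.
#' @param valid_mask logical vector of the same length, `TRUE` on days
#'   with a real measurement.
#' @return A list with numeric vectors `diff` and `slope`.
#' @export
diff_and_slope <- function(values, valid_mask) {
  if (length(values) != length(valid_mask))
    stop("values and valid_mask must have the same length")
  n <- length(values)
  d <- numeric(n); s <- numeric(n)
  days <- which(valid_mask)
  if (length(days) > 1L) {
    for (i in 2:length(days)) {
      cur <- days[i]; prev <- days[i - 1L]
      upto <- if (i < length(days)) days[i + 1L] - 1L else n
      span <- cur:upto
      d[span] <- values[cur] - values[prev]
      s[span] <- d[cur] / (cur - prev)
    }
  }
  list(diff = d, slope = s)
}

# daily dt feature: gap behind the most recent real measurement pair
daily_dt <- function(grid, stats) {
  n <- grid$n_days
  days <- which(grid$valid_ndvi | grid$valid_coh)
  dt <- numeric(n)
  if (length(days) > 1L) {
    for (i in 2:length(days)) {
      upto <- if (i < length(days)) days[i + 1L] - 1L else n
      dt[days[i]:upto] <- days[i] - days[i - 1L]
    }
  }
  normalized_gap(dt, stats)
}

# 215 x 14 feature block for one field
field_features <- function(grid, stats, window) {
  t_feat <- normalized_doy(window_doy(window))
  nd <- diff_and_slope(grid$ndvi, grid$valid_ndvi)
  vv <- diff_and_slope(grid$cohvv_sm, grid$valid_coh)
  vh <- diff_and_slope(grid$cohvh_sm, grid$valid_coh)
  cbind(ndvi = grid$ndvi, cohvv = grid$cohvv, cohvh = grid$cohvh,
        t = t_feat, dt = daily_dt(grid, stats),
        cohvv_sm = grid$cohvv_sm, cohvh_sm = grid$cohvh_sm,
        mixed_coh = mixed_coherence(grid$cohvh, grid$cohvv),
        ndvi_diff = nd$diff, cohvv_sm_diff = vv$diff,
        cohvh_sm_diff = vh$diff, ndvi_der = nd$slope,
        cohvh_sm_der = vh$slope, cohvv_sm_der = vv$slope)
}

#' Assemble the model's feature matrix and daily labels
#'
#' Builds the `n_fields x n_days x 14` input array in the fixed feature
#' order together with the daily binary labels: label 1 on the
#' `label_width` days starting at each event start (clipped at the
#' season end), else 0.
#'
#' @param grids named list of `daily_grid` objects.
#' @param labels an `event_labels` list covering every field in `grids`.
#' @param stats a [gap_stats()] object from the training split.
#' @param window a [season_window()].
#' @param label_width days labelled positive per event (default 7,
#'   matching the -3/+6-day evaluation tolerance).
#' @return A list of class `feature_matrix` with `values`
#'   (`n_fields x n_days x 14` array), `labels` (`n_fields x n_days`
#'   0/1 matrix), `field_ids`, `feature_names`, `stats`, `window`,
#'   `starts` (list of true event starts per field).
#' @export
build_feature_matrix <- function(grids, labels, stats,
                                 window = season_window(),
                                 label_width = 7L) {
  label_ids <- vapply(labels, `[[`, character(1), "field_id")
  grid_ids <- unname(vapply(grids, `[[`, character(1), "field_id"))
  miss <- setdiff(grid_ids, label_ids)
  if (length(miss))
    stop("field(s) missing from labels: ", paste(miss, collapse = ", "))
  n <- length(grids)
  nd <- window$n_days
  values <- array(NA_real_, c(n, nd, length(MOW_FEATURES)),
                  dimnames = list(grid_ids, NULL, MOW_FEATURES))
  lab <- matrix(0L, n, nd, dimnames = list(grid_ids, NULL))
  starts <- vector("list", n)
  names(starts) <- grid_ids
  for (i in seq_len(n)) {
    values[i, , ] <- field_features(grids[[i]], stats, window)
    l <- labels[[match(grid_ids[i], label_ids)]]
    starts[[i]] <- l$starts
    for (s in l$starts) {
      span <- s:min(s + label_width - 1L, nd - 1L)
      lab[i, span + 1L] <- 1L
    }
  }
  if (anyNA(values) || any(!is.finite(values)))
    stop("non-finite feature values")
  structure(list(values = values, labels = lab, field_ids = grid_ids,
                 feature_names = MOW_FEATURES, stats = stats,
                 window = window, starts = starts),
            class = "feature_matrix")
}

#' Subset a feature matrix by field
#'
#' @param fm a `feature_matrix`.
#' @param idx integer or logical field index.
#' @return A `feature_matrix` over the selected fields.
#' @export
subset_fields <- function(fm, idx) {
  structure(list(values = fm$values[idx, , , drop = FALSE],
                 labels = fm$labels[idx, , drop = FALSE],
                 field_ids = fm$field_ids[idx],
                 feature_names = fm$feature_names, stats = fm$stats,
                 window = fm$window, starts = fm$starts[idx]),
            class = "feature_matrix")
}
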