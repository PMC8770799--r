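#' NDVI from Sentinel-2 band reflectances
#'
#' `NDVI = (band8 - band4) / (band8 + band4)`, the normalized difference
#' of near-infrared (band 8) and red (band 4) reflectance.
#'
#' @param band8,band4 non-negative reflectances (vectorized).
#' @return NDVI values in (-1, 1\].
#' @examples
#' ndvi_from_bands(0.3, 0.1)  # 0.5
#' @export
ndvi_from_bands <- function(band8, band4) {
  if (any(band8 < 0 | band4 < 0)) stop("reflectances must be >= 0")
  if (any(band8 + band4 == 0)) stop("band8 + band4 must be > 0")
  (band8 - band4) / (band8 + band4)
}

#' Remove cloud-mask NDVI outliers with the triplet rule
#'
#' A cloud-mask failure shows as an isolated sudden NDVI drop: a single
#' low value between two ordinary neighbours. For every window of three
#' consecutive valid NDVI measurements whose first and third values are
#' at most `max_span_days` apart, the middle one is marked as an outlier
#' when `ndvi_3 - 2*ndvi_2 + ndvi_1 >= threshold`. The span guard keeps
#' genuine mowing drops (whose signature can recover in about 10 days)
#' from being filtered. All triplets are evaluated on the original
#' values; marked measurements are removed in a single pass, so the
#' result does not depend on enumeration order.
#'
#' @param series a `field_series` data frame for one or more fields.
#' @param threshold statistic threshold (default 0.6).
#' @param max_span_days maximum days between the first and third
#'   measurement of a triplet (default 10).
#' @return A list with `series` (input with outlying NDVI values set to
#'   missing; rows left with no observed channel are dropped) and
#'   `removed` (integer row indices into the input that were filtered).
#' @examples
#' s <- data.frame(field_id = "A",
#'                 date = as.Date("2018-06-01") + c(0, 4, 8),
#'                 ndvi = c(0.75, 0.38, 0.78), cohvv = NA, cohvh = NA)
#' filter_ndvi_outliers(s)$removed  # row 2
#' @export
filter_ndvi_outliers <- function(series, threshold = 0.6,
                                 max_span_days = 10L) {
  df <- as.data.frame(series)
  removed <- integer()
  for (fid in unique(df$field_id)) {
    rows <- which(df$field_id == fid & !is.na(df$ndvi))
    rows <- rows[order(df$date[rows])]
    if (length(rows) < 3L) next
    v <- df$ndvi[rows]
    d <- as.numeric(df$date[rows])
    for (i in seq_len(length(rows) - 2L)) {
      if (d[i + 2L] - d[i] > max_span_days) next
      if (v[i + 2L] - 2 * v[i + 1L] + v[i] >= threshold)
        removed <- c(removed, rows[i + 1L])
    }
  }
  removed <- sort(unique(removed))
  df$ndvi[removed] <- NA_real_
  keep <- !(is.na(df$ndvi) & is.na(df$cohvv) & is.na(df$cohvh))
  out <- as_field_series(df[keep, , drop = FALSE])
  list(series = out, removed = removed)
}

#' Exponential moving-average smoothing
#'
#' Recursive exponentially weighted average: `out[1] = in[1]`,
#' `out[n] = alpha * in[n] + (1 - alpha) * out[n-1]`. Larger `alpha`
#' reacts more to fluctuations; smaller `alpha` smooths harder.
#'
#' @param values non-empty numeric vector in time order.
#' @param alpha smoothing parameter in (0, 1\]; default 1/3.
#' @return Smoothed vector of the same length.
#' @export
ema_smooth <- function(values, alpha = 1 / 3) {
  if (!length(values)) stop("values must be non-empty")
  if (alpha <= 0 || alpha > 1) stop("alpha must lie in (0, 1]")
  # out[n] = a*x[n] + (1-a)*out[n-1] is a first-order recursive filter
  out <- numeric(length(values))
  out[1] <- values[1]
  if (length(values) > 1L)
    for (i in 2:length(values))
      out[i] <- alpha * values[i] + (1 - alpha) * out[i - 1]
  out
}

#' Centered moving-average smoothing
#'
#' Mean over a centered window of `filter_width` measurements; at the
#' sequence edges the window is truncated symmetrically so the output
#' has the same length as the input.
#'
#' @param values non-empty numeric vector in time order.
#' @param filter_width odd window width >= 3 (default 7).
#' @return Smoothed vector of the same length.
#' @export
moving_average_smooth <- function(values, filter_width = 7L) {
  if (!length(values)) stop("values must be non-empty")
  filter_width <- as.integer(filter_width)
  if (filter_width < 3L || filter_width %% 2L == 0L)
    stop("filter_width must be an odd integer >= 3")
  half <- filter_width %/% 2L
  n <- length(values)
  vapply(seq_len(n), function(i) {
    k <- min(half, i - 1L, n - i)  # symmetric truncation at the edges
    mean(values[(i - k):(i + k)])
  }, numeric(1))
}

#' Coherence smoothing configuration
#'
#' @param method `"ema"` (exponential moving average, the default) or
#'   `"moving_average"`.
#' @param alpha EMA parameter in (0, 1\]; 1/3 by default.
#' @param filter_width odd moving-average width; 7 by default.
#' @return A list of class `smoothing_config`.
#' @export
smoothing_config <- function(method = c("ema", "moving_average"),
                             alpha = 1 / 3, filter_width = 7L) {
  method <- match.arg(method)
  if (alpha <= 0 || alpha > 1) stop("alpha must lie in (0, 1]")
  filter_width <- as.integer(filter_width)
  if (filter_width < 3L || filter_width %% 2L == 0L)
    stop("filter_width must be an odd integer >= 3")
  structure(list(method = method, alpha = alpha,
                 filter_width = filter_width),
            class = "smoothing_config")
}

apply_smoothing <- function(values, cfg) {
  switch(cfg$method,
         ema = ema_smooth(values, cfg$alpha),
         moving_average = moving_average_smooth(values, cfg$filter_width))
}

#' Interpolate one field's observations onto the daily season grid
#'
#' Each channel is linearly interpolated between its valid measurements
#' onto integer days `0 .. n_days-1`; before the first and after the
#' last measurement the nearest value is held constant. Coherence
#' channels are additionally smoothed (per `smoothing`) on the valid
#' measurements *before* interpolation, yielding `cohvv_sm`/`cohvh_sm`.
#' A channel with no valid measurement in the window is filled with a
#' season default (`fill_ndvi`, `fill_coh`) and reported via a message.
#'
#' @param series a `field_series` data frame containing a single field.
#' @param window a [season_window()].
#' @param smoothing a [smoothing_config()].
#' @param fill_ndvi,fill_coh constants used when a channel has no valid
#'   measurement in the window.
#' @return A list of class `daily_grid` with `field_id`, `n_days`,
#'   numeric vectors `ndvi`, `cohvv`, `cohvh`, `cohvv_sm`, `cohvh_sm`
#'   (length `n_days`, no missing values), and logical masks
#'   `valid_ndvi`, `valid_coh` marking days with a real measurement.
#' @export
interpolate_daily <- function(series, window = season_window(),
                              smoothing = smoothing_config(),
                              fill_ndvi = 0.5, fill_coh = 0.3) {
  if (window$n_days < 2L) stop("season window must span at least 2 days")
  df <- as.data.frame(series)
  if (length(unique(df$field_id)) > 1L)
    stop("interpolate_daily expects a single field")
  off <- day_offset(df$date, window)
  dropped <- sum(is.na(off))
  if (dropped)
    message(df$field_id[1], ": dropped ", dropped,
            " observation(s) outside the season window")
  df <- df[!is.na(off), , drop = FALSE]
  off <- off[!is.na(off)]
  grid_days <- seq_len(window$n_days) - 1L

  interp <- function(days, values, fill) {
    if (!length(days)) return(list(x = rep(fill, window$n_days),
                                   filled = TRUE))
    if (length(days) == 1L) return(list(x = rep(values, window$n_days),
                                        filled = FALSE))
    list(x = approx(days, values, xout = grid_days, method = "linear",
                    rule = 2)$y,
         filled = FALSE)
  }

  nd <- !is.na(df$ndvi)
  cv <- !is.na(df$cohvv)
  ch <- !is.na(df$cohvh)
  ndvi <- interp(off[nd], df$ndvi[nd], fill_ndvi)
  covv <- interp(off[cv], df$cohvv[cv], fill_coh)
  covh <- interp(off[ch], df$cohvh[ch], fill_coh)
  # smoothing runs on the real coherence measurements, then interpolation
  covv_sm <- interp(off[cv],
                    if (any(cv)) apply_smoothing(df$cohvv[cv], smoothing)
                    else numeric(), fill_coh)
  covh_sm <- interp(off[ch],
                    if (any(ch)) apply_smoothing(df$cohvh[ch], smoothing)
                    else numeric(), fill_coh)
  for (f in list(ndvi, covv, covh)) if (f$filled)
    message(df$field_id[1], ": channel with no valid measurement ",
            "filled with its season default")

  valid_ndvi <- valid_coh <- logical(window$n_days)
  valid_ndvi[off[nd] + 1L] <- TRUE
  valid_coh[off[cv | ch] + 1L] <- TRUE
  structure(list(field_id = df$field_id[1], n_days = window$n_days,
                 ndvi = ndvi$x, cohvv = covv$x, cohvh = covh$x,
                 cohvv_sm = covv_sm$x, cohvh_sm = covh_sm$x,
                 valid_ndvi = valid_ndvi, valid_coh = valid_coh),
            class = "daily_grid")
}

#' Preprocess a multi-field series into daily grids
#'
#' Runs [filter_ndvi_outliers()] and [interpolate_daily()] for every
#' field.
#'
#' @inheritParams interpolate_daily
#' @inheritParams filter_ndvi_outliers
#' @param series a `field_series` data frame (any number of fields).
#' @return A named list of `daily_grid` objects, one per field.
#' @export
preprocess_fields <- function(series, window = season_window(),
                              smoothing = smoothing_config(),
                              threshold = 0.6, max_span_days = 10L,
                              fill_ndvi = 0.5, fill_coh = 0.3) {
  filtered <- filter_ndvi_outliers(series, threshold, max_span_days)$series
  out <- lapply(split(as.data.frame(filtered), filtered$field_id),
                interpolate_daily, window = window, smoothing = smoothing,
                fill_ndvi = fill_ndvi, fill_coh = fill_coh)
  out[order(names(out))]
}
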