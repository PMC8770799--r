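#' Simulation configuration for synthetic field-seasons
#'
#' The generator emulates the phenomenology of Estonian grassland
#' monitoring data: around 95% of fields are mown during the season;
#' NDVI of an unmown field follows a half-oval seasonal curve; a mowing
#' event produces a sharp NDVI drop with linear regrowth and a coherence
#' rise that persists 24-36 days; Sentinel-1 coherence arrives on a
#' ~6-day cadence, Sentinel-2 NDVI on a ~4-day cadence of which about
#' 75% of samples are cloud-invalid; rare cloud-mask failures replace a
#' valid NDVI sample with an isolated spurious low value; rainy
#' acquisition days depress coherence.
#'
#' @param n_fields number of field-seasons to generate.
#' @param mown_fraction fraction of fields with at least one event.
#' @param max_events_per_field maximum number of events for a mown field.
#' @param ndvi_invalid_fraction probability an NDVI sample is cloud-invalid.
#' @param outlier_rate probability a surviving valid NDVI sample is
#'   replaced by a cloud-mask outlier (isolated, never consecutive).
#' @param s1_cadence_days,s2_cadence_days observation cadences in days.
#' @param event_ndvi_drop_range NDVI drop magnitude range per event.
#' @param event_coh_rise_range coherence rise magnitude range per event.
#' @param event_persistence_days_range days the coherence rise persists.
#' @param regrowth_days_range days for NDVI to regrow to baseline.
#' @param noise_sd_ndvi,noise_sd_coh additive Gaussian noise SDs.
#' @param rain_day_rate probability a coherence acquisition day is rainy
#'   (coherence multiplied by a factor in \[0.4, 0.8\]).
#' @param seed integer seed; each field gets an independent substream.
#' @param window a [season_window()].
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_fields = 1000L, mown_fraction = 0.95,
                       max_events_per_field = 3L,
                       ndvi_invalid_fraction = 0.75, outlier_rate = 0.001,
                       s1_cadence_days = 6L, s2_cadence_days = 4L,
                       event_ndvi_drop_range = c(0.2, 0.45),
                       event_coh_rise_range = c(0.10, 0.30),
                       event_persistence_days_range = c(24L, 36L),
                       regrowth_days_range = c(25L, 40L),
                       noise_sd_ndvi = 0.02, noise_sd_coh = 0.03,
                       rain_day_rate = 0.10, seed = 1L,
                       window = season_window()) {
  cfg <- list(n_fields = as.integer(n_fields),
              mown_fraction = mown_fraction,
              max_events_per_field = as.integer(max_events_per_field),
              ndvi_invalid_fraction = ndvi_invalid_fraction,
              outlier_rate = outlier_rate,
              s1_cadence_days = as.integer(s1_cadence_days),
              s2_cadence_days = as.integer(s2_cadence_days),
              event_ndvi_drop_range = event_ndvi_drop_range,
              event_coh_rise_range = event_coh_rise_range,
              event_persistence_days_range = event_persistence_days_range,
              regrowth_days_range = regrowth_days_range,
              noise_sd_ndvi = noise_sd_ndvi, noise_sd_coh = noise_sd_coh,
              rain_day_rate = rain_day_rate, seed = as.integer(seed),
              window = window)
  for (k in c("mown_fraction", "ndvi_invalid_fraction", "outlier_rate",
              "rain_day_rate"))
    if (cfg[[k]] < 0 || cfg[[k]] > 1) stop(k, " must lie in [0, 1]")
  for (k in c("event_ndvi_drop_range", "event_coh_rise_range",
              "event_persistence_days_range", "regrowth_days_range"))
    if (cfg[[k]][1] > cfg[[k]][2]) stop(k, ": lower bound exceeds upper")
  if (cfg$s1_cadence_days < 1L || cfg$s2_cadence_days < 1L)
    stop("cadences must be >= 1 day")
  structure(cfg, class = "sim_config")
}

# independent, reproducible RNG substream per field
field_seed <- function(seed, field_index) {
  as.integer((as.double(seed %% 100000L) * 48271 +
                as.double(field_index) * 30269 + 17) %% 2147483647)
}

#' Simulate one labelled field-season
#'
#' Draws a half-oval baseline NDVI curve, applies mowing-event signatures
#' (NDVI drop with linear regrowth; coherence rise decaying over its
#' persistence period), then samples sparse noisy observations at the
#' configured cadences with cloud invalidation, cloud-mask outliers and
#' rain-day coherence suppression. Deterministic given `(config$seed,
#' field_index)`; different field indices use independent substreams.
#'
#' @param config a [sim_config()].
#' @param field_index positive integer identifying the field's RNG stream.
#' @param mown force mown status (`TRUE`/`FALSE`), or `NULL` to draw it
#'   from `config$mown_fraction`.
#' @return A list with `series` (a `field_series` data frame), `label`
#'   (an [event_label()]) and `truth` (field id, event starts, and the
#'   noise-free daily `ndvi`, `cohvv`, `cohvh` latent curves).
#' @export
simulate_field <- function(config, field_index, mown = NULL) {
  w <- config$window
  n <- w$n_days
  old <- get_rng_state()
  on.exit(set_rng_state(old))
  set.seed(field_seed(config$seed, field_index))
  fid <- sprintf("F%05d", field_index)

  if (is.null(mown)) mown <- runif(1) < config$mown_fraction
  starts <- if (mown) draw_event_starts(config, n) else integer()

  tt <- seq_len(n) - 1L
  n_min <- runif(1, 0.1, 0.3); n_max <- runif(1, 0.6, 0.9)
  t_mid <- runif(1, 95, 120); h <- runif(1, 105, 130)
  ndvi_lat <- n_min + (n_max - n_min) *
    sqrt(pmax(0, 1 - ((tt - t_mid) / h)^2))
  base_vv <- runif(1, 0.15, 0.40)
  base_vh <- runif(1, 0.15, 0.40)
  covv_lat <- rep(base_vv, n)
  covh_lat <- rep(base_vh, n)

  for (s in starts) {
    drop <- runif(1, config$event_ndvi_drop_range[1],
                  config$event_ndvi_drop_range[2])
    regrow <- sample(config$regrowth_days_range[1]:
                       config$regrowth_days_range[2], 1L)
    persist <- sample(config$event_persistence_days_range[1]:
                        config$event_persistence_days_range[2], 1L)
    rise_vv <- runif(1, config$event_coh_rise_range[1],
                     config$event_coh_rise_range[2])
    rise_vh <- runif(1, config$event_coh_rise_range[1],
                     config$event_coh_rise_range[2])
    idx <- which(tt >= s & tt < s + regrow)
    ndvi_lat[idx] <- ndvi_lat[idx] - drop * (1 - (tt[idx] - s) / regrow)
    idx <- which(tt >= s & tt < s + persist)
    covv_lat[idx] <- covv_lat[idx] + rise_vv * (1 - (tt[idx] - s) / persist)
    covh_lat[idx] <- covh_lat[idx] + rise_vh * (1 - (tt[idx] - s) / persist)
  }
  ndvi_lat <- pmin(pmax(ndvi_lat, 0.02), 1)
  covv_lat <- pmin(pmax(covv_lat, 0), 1)
  covh_lat <- pmin(pmax(covh_lat, 0), 1)

  # Sentinel-2 sampling: cadence grid, cloud invalidation, rare outliers
  s2_days <- seq.int(sample(config$s2_cadence_days, 1L) - 1L, n - 1L,
                     by = config$s2_cadence_days)
  s2_valid <- runif(length(s2_days)) >= config$ndvi_invalid_fraction
  s2_days <- s2_days[s2_valid]
  ndvi_obs <- ndvi_lat[s2_days + 1L] +
    rnorm(length(s2_days), sd = config$noise_sd_ndvi)
  prev_outlier <- FALSE
  for (i in seq_along(s2_days)) {
    if (!prev_outlier && runif(1) < config$outlier_rate) {
      ndvi_obs[i] <- runif(1, 0, 0.45 * ndvi_lat[s2_days[i] + 1L] + 0.1)
      prev_outlier <- TRUE
    } else prev_outlier <- FALSE
  }
  ndvi_obs <- pmin(pmax(ndvi_obs, -1), 1)

  # Sentinel-1 sampling: cadence grid, rain suppression, noise
  s1_days <- seq.int(sample(config$s1_cadence_days, 1L) - 1L, n - 1L,
                     by = config$s1_cadence_days)
  rain <- runif(length(s1_days)) < config$rain_day_rate
  rain_factor <- ifelse(rain, runif(length(s1_days), 0.4, 0.8), 1)
  covv_obs <- covv_lat[s1_days + 1L] * rain_factor +
    rnorm(length(s1_days), sd = config$noise_sd_coh)
  covh_obs <- covh_lat[s1_days + 1L] * rain_factor +
    rnorm(length(s1_days), sd = config$noise_sd_coh)
  covv_obs <- pmin(pmax(covv_obs, 0), 1)
  covh_obs <- pmin(pmax(covh_obs, 0), 1)

  days <- sort(union(s2_days, s1_days))
  series <- data.frame(
    field_id = fid, date = w$start_date + days,
    ndvi = NA_real_, cohvv = NA_real_, cohvh = NA_real_)
  series$ndvi[match(s2_days, days)] <- ndvi_obs
  series$cohvv[match(s1_days, days)] <- covv_obs
  series$cohvh[match(s1_days, days)] <- covh_obs
  # drop grid days where no channel was actually observed
  series <- series[!(is.na(series$ndvi) & is.na(series$cohvv) &
                       is.na(series$cohvh)), , drop = FALSE]

  list(series = as_field_series(series),
       label = event_label(fid, starts,
                           min_gap_days = config$regrowth_days_range[2]),
       truth = list(field_id = fid, event_starts = starts,
                    ndvi = ndvi_lat, cohvv = covv_lat, cohvh = covh_lat))
}

# summer-weighted seasonal prior over event start days; consecutive
# starts at least the regrowth upper bound apart
draw_event_starts <- function(config, n_days) {
  n_events <- sample(config$max_events_per_field, 1L)
  gap <- config$regrowth_days_range[2]
  cand <- seq.int(10L, n_days - 15L)
  wts <- exp(-0.5 * ((cand - 90) / 40)^2) + 0.05
  starts <- integer()
  for (i in seq_len(n_events)) {
    ok <- if (length(starts)) {
      vapply(cand, function(d) all(abs(d - starts) >= gap), logical(1))
    } else rep(TRUE, length(cand))
    if (!any(ok)) break
    starts <- c(starts,
                cand[ok][sample.int(sum(ok), 1L, prob = wts[ok])])
  }
  sort(starts)
}

#' Simulate a labelled dataset of field-seasons
#'
#' Exactly `round(n_fields * mown_fraction)` fields receive at least one
#' mowing event; which fields are mown is drawn once from the top-level
#' seed, while each field's signals come from its own substream.
#'
#' @param config a [sim_config()].
#' @return A list with `series` (one `field_series` data frame for all
#'   fields), `labels` (an `event_labels` list) and `truths` (list of
#'   per-field latent-curve records).
#' @export
simulate_dataset <- function(config) {
  n <- config$n_fields
  if (n == 0L)
    return(list(series = as_field_series(
      data.frame(field_id = character(), date = as.Date(character()),
                 ndvi = numeric(), cohvv = numeric(), cohvh = numeric())),
      labels = structure(list(), class = "event_labels"),
      truths = list()))
  old <- get_rng_state()
  on.exit(set_rng_state(old))
  set.seed(config$seed)
  n_mown <- round(n * config$mown_fraction)
  mown <- logical(n)
  mown[sample.int(n, n_mown)] <- TRUE
  sims <- lapply(seq_len(n), function(i)
    simulate_field(config, i, mown = mown[i]))
  series <- do.call(rbind, lapply(sims, `[[`, "series"))
  list(series = as_field_series(series),
       labels = structure(lapply(sims, `[[`, "label"),
                          class = "event_labels"),
       truths = lapply(sims, `[[`, "truth"))
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

set_rng_state <- function(value) {
  if (!is.null(value))
    assign(".Random.seed", value, envir = globalenv())
  invisible(value)
}
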