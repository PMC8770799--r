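#' Load and validate a pipeline configuration
#'
#' Reads a YAML (or JSON) configuration with sections `sim`, `preprocess`,
#' `features`, `model`, `train`, `eval`, `reject` and a top-level `seed`.
#' Missing optional keys are filled with the documented defaults (EMA
#' alpha = 1/3, decision threshold theta = 0.5, season grid of 215 days);
#' unknown keys are rejected with the list of valid keys. `seed` is
#' required.
#'
#' @param path path to a YAML/JSON configuration file, or `NULL` for an
#'   all-defaults configuration (seed must then be given via `seed`).
#' @param seed optional seed overriding the file's value.
#' @return A named list of class `mow_config` with all defaults filled.
#' @export
load_config <- function(path = NULL, seed = NULL) {
  raw <- if (is.null(path)) list() else {
    if (!file.exists(path)) stop("config file not found: ", path)
    yaml::read_yaml(path)
  }
  if (is.null(raw)) raw <- list()
  defaults <- default_config()
  valid_top <- c(names(defaults), "seed")
  unknown <- setdiff(names(raw), valid_top)
  if (length(unknown))
    stop("unknown config section(s): ", paste(unknown, collapse = ", "),
         "; valid keys: ", paste(valid_top, collapse = ", "))
  cfg <- defaults
  for (sec in names(defaults)) {
    user <- raw[[sec]]
    if (is.null(user)) next
    bad <- setdiff(names(user), names(defaults[[sec]]))
    if (length(bad))
      stop("unknown key(s) in section '", sec, "': ",
           paste(bad, collapse = ", "), "; valid keys: ",
           paste(names(defaults[[sec]]), collapse = ", "))
    cfg[[sec]][names(user)] <- user
  }
  cfg$seed <- if (!is.null(seed)) seed else raw$seed
  if (is.null(cfg$seed)) stop("config key 'seed' is required")
  cfg$seed <- as.integer(cfg$seed)
  validate_config(cfg)
  structure(cfg, class = "mow_config")
}

default_config <- function() {
  list(
    sim = list(
      n_fields = 1000L, mown_fraction = 0.95, max_events_per_field = 3L,
      ndvi_invalid_fraction = 0.75, outlier_rate = 0.001,
      s1_cadence_days = 6L, s2_cadence_days = 4L,
      event_ndvi_drop_range = c(0.2, 0.45),
      event_coh_rise_range = c(0.10, 0.30),
      event_persistence_days_range = c(24L, 36L),
      regrowth_days_range = c(25L, 40L),
      noise_sd_ndvi = 0.02, noise_sd_coh = 0.03, rain_day_rate = 0.10),
    preprocess = list(
      method = "ema", alpha = 1 / 3, filter_width = 7L,
      outlier_threshold = 0.6, outlier_max_span_days = 10L,
      fill_ndvi = 0.5, fill_coh = 0.3,
      season_start = "2018-04-01", n_days = 215L),
    features = list(label_width = 7L),
    model = list(
      n_features = 14L, conv_channels = c(32L, 32L), kernel_size = 9L,
      hidden_activation = "softmax_channel"),
    train = list(
      optimizer = "nadam", learning_rate = 1e-4, beta_1 = 0.9,
      beta_2 = 0.999, schedule_decay = 0.004, max_epochs = 300L,
      batch_size = 64L, early_stopping_patience = 20L),
    eval = list(
      threshold = 0.5, min_run_days = 1L, early_tolerance = 3L,
      late_tolerance = 6L, season_score = "noisy_or"),
    reject = list(desired_tpr = 0.97, desired_tnr = 0.75))
}

validate_config <- function(cfg) {
  p <- cfg$preprocess
  if (!is.numeric(p$alpha) || p$alpha <= 0 || p$alpha > 1)
    stop("preprocess$alpha must lie in (0, 1]")
  if (!p$method %in% c("ema", "moving_average"))
    stop("preprocess$method must be 'ema' or 'moving_average'")
  fw <- as.integer(p$filter_width)
  if (fw < 3L || fw %% 2L == 0L)
    stop("preprocess$filter_width must be an odd integer >= 3")
  if (as.integer(p$n_days) < 2L) stop("preprocess$n_days must be >= 2")
  s <- cfg$sim
  for (k in c("mown_fraction", "ndvi_invalid_fraction", "outlier_rate",
              "rain_day_rate"))
    if (s[[k]] < 0 || s[[k]] > 1)
      stop("sim$", k, " must lie in [0, 1]")
  e <- cfg$eval
  if (e$threshold <= 0 || e$threshold >= 1)
    stop("eval$threshold must lie in (0, 1)")
  if (!e$season_score %in% c("noisy_or", "max"))
    stop("eval$season_score must be 'noisy_or' or 'max'")
  m <- cfg$model
  if (as.integer(m$kernel_size) %% 2L == 0L)
    stop("model$kernel_size must be odd")
  invisible(cfg)
}
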