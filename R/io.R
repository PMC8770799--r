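#' Read per-field observation series from CSV
#'
#' Expects columns `field_id, date, ndvi, cohvv, cohvh`; empty cells are
#' missing values. Dates are ISO-8601. Rows are validated (NDVI within
#' \[-1, 1\], coherence within \[0, 1\], at least one channel present) and
#' sorted by field and date.
#'
#' @param path path to a CSV file.
#' @return A `data.frame` of class `field_series` with columns
#'   `field_id` (character), `date` (`Date`), `ndvi`, `cohvv`, `cohvh`
#'   (numeric, `NA` = missing), sorted by `field_id` then `date`.
#' @export
read_field_series <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE,
                 colClasses = c(field_id = "character"))
  need <- c("field_id", "date", "ndvi", "cohvv", "cohvh")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("missing columns: ", paste(missing_cols, collapse = ", "))
  df <- df[need]
  for (ch in c("ndvi", "cohvv", "cohvh")) df[[ch]] <- as.numeric(df[[ch]])
  dates <- as.Date(df$date, format = "%Y-%m-%d")
  bad <- which(is.na(dates) & nzchar(df$date))
  if (length(bad))
    stop("malformed date at row ", bad[1] + 1L, ": '", df$date[bad[1]], "'")
  df$date <- dates
  validate_observations(df)
  as_field_series(df)
}

as_field_series <- function(df) {
  df <- df[order(df$field_id, df$date), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("field_series", "data.frame")
  df
}

validate_observations <- function(df) {
  # row numbers reported are 1-based data rows + header line
  chk <- function(bad, what) {
    if (any(bad, na.rm = TRUE)) {
      i <- which(bad)[1]
      stop("invalid ", what, " at row ", i + 1L)
    }
  }
  chk(df$ndvi < -1 | df$ndvi > 1, "ndvi (must lie in [-1, 1])")
  chk(df$cohvv < 0 | df$cohvv > 1, "cohvv (must lie in [0, 1])")
  chk(df$cohvh < 0 | df$cohvh > 1, "cohvh (must lie in [0, 1])")
  chk(is.na(df$ndvi) & is.na(df$cohvv) & is.na(df$cohvh),
      "observation (all channels missing)")
  dup <- duplicated(df[c("field_id", "date")])
  chk(dup, "observation (duplicate field/date)")
  invisible(df)
}

#' Write per-field observation series to CSV
#'
#' @param series a `field_series` data frame (see [read_field_series()]).
#' @param path output path.
#' @export
write_field_series <- function(series, path) {
  df <- as.data.frame(series)
  df$date <- format(df$date)
  write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read mowing-event labels from CSV
#'
#' One row per event with columns `field_id, start_date`; fields with no
#' events appear once with an empty `start_date`. Consecutive starts
#' within a field must be at least `min_gap_days` apart (the mowing
#' signature needs about 10 days to recover, so closer labels are
#' indistinguishable).
#'
#' @param path path to a CSV file.
#' @param window a [season_window()]; starts outside it are rejected.
#' @param min_gap_days minimum spacing between starts within a field.
#' @return A list of class `event_labels`: one element per field, each a
#'   list with `field_id`, `starts` (0-based day offsets, sorted) and
#'   `mown` (logical).
#' @export
read_event_labels <- function(path, window = season_window(),
                              min_gap_days = 10L) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE,
                 colClasses = c(field_id = "character"))
  if (!all(c("field_id", "start_date") %in% names(df)))
    stop("missing columns: need field_id, start_date")
  out <- lapply(split(df, df$field_id), function(d) {
    sd <- d$start_date[nzchar(d$start_date)]
    off <- sort(day_offset(as.Date(sd), window))
    if (length(sd) && anyNA(day_offset(as.Date(sd), window)))
      stop("event start outside season window for field ", d$field_id[1])
    event_label(d$field_id[1], off, min_gap_days = min_gap_days)
  })
  structure(unname(out), class = "event_labels")
}

#' Construct a single field's event label
#'
#' @param field_id field identifier.
#' @param starts 0-based day offsets of mowing starts (may be empty).
#' @param min_gap_days minimum spacing between consecutive starts.
#' @return A list with `field_id`, `starts`, `mown`.
#' @export
event_label <- function(field_id, starts = integer(), min_gap_days = 10L) {
  starts <- as.integer(starts)
  if (is.unsorted(starts, strictly = TRUE))
    stop("mowing starts must be strictly increasing")
  if (length(starts) > 1L && any(diff(starts) < min_gap_days))
    stop("consecutive mowing starts closer than ", min_gap_days,
         " days for field ", field_id)
  list(field_id = as.character(field_id), starts = starts,
       mown = length(starts) > 0L)
}

#' Write event labels to CSV
#'
#' @param labels an `event_labels` list.
#' @param window a [season_window()] used to convert offsets to dates.
#' @param path output path.
#' @export
write_event_labels <- function(labels, path, window = season_window()) {
  rows <- lapply(labels, function(l) {
    if (l$mown)
      data.frame(field_id = l$field_id,
                 start_date = format(window$start_date + l$starts))
    else
      data.frame(field_id = l$field_id, start_date = "")
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Write daily mowing probabilities (and decoded events) to CSV
#'
#' Long format, one row per field-day: `field_id, day, prob, event_start`.
#' `event_start` is 1 on days where a decoded event begins, else 0.
#' Probabilities are written with enough digits for a lossless round trip
#' at 8 significant digits.
#'
#' @param probs numeric matrix, fields x days, values in \[0, 1\].
#' @param path output path.
#' @param field_ids character vector, one per row of `probs`.
#' @param events optional list of integer vectors of predicted start days
#'   (0-based), one per field.
#' @export
write_predictions <- function(probs, path, field_ids = rownames(probs),
                              events = NULL) {
  probs <- as.matrix(probs)
  if (is.null(field_ids)) field_ids <- as.character(seq_len(nrow(probs)))
  if (length(field_ids) != nrow(probs))
    stop("field_ids length does not match number of probability rows")
  if (anyNA(probs) || any(probs < 0 | probs > 1))
    stop("probabilities must lie in [0, 1]")
  n_days <- ncol(probs)
  ev <- matrix(0L, nrow(probs), n_days)
  if (!is.null(events)) {
    if (length(events) != nrow(probs))
      stop("events length does not match number of fields")
    for (i in seq_along(events)) {
      s <- as.integer(events[[i]])
      if (any(s < 0L | s >= n_days))
        stop("event start outside the season grid for field ", field_ids[i])
      ev[i, s + 1L] <- 1L
    }
  }
  df <- data.frame(
    field_id = rep(field_ids, each = n_days),
    day = rep.int(seq_len(n_days) - 1L, nrow(probs)),
    prob = signif(as.vector(t(probs)), 8),
    event_start = as.integer(t(ev)))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read daily mowing probabilities written by [write_predictions()]
#'
#' @param path path to the CSV file.
#' @return A list with `probs` (fields x days matrix, rownames =
#'   field ids) and `events` (list of 0-based start-day vectors).
#' @export
read_predictions <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE,
                 colClasses = c(field_id = "character"))
  ids <- unique(df$field_id)
  n_days <- length(unique(df$day))
  if (nrow(df) != length(ids) * n_days)
    stop("ragged prediction file: unequal days per field")
  probs <- matrix(NA_real_, length(ids), n_days,
                  dimnames = list(ids, NULL))
  events <- vector("list", length(ids))
  names(events) <- ids
  for (id in ids) {
    d <- df[df$field_id == id, ]
    d <- d[order(d$day), ]
    probs[id, ] <- d$prob
    events[[id]] <- d$day[d$event_start == 1L]
  }
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  list(probs = probs, events = events)
}
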