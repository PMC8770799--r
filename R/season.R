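#' Vegetation-season window
#'
#' The fixed daily axis onto which all field observations are mapped.
#' The default covers the Estonian vegetation season, April through
#' October: 215 days starting April 1. Dates are converted internally to
#' 0-based day offsets from `start_date`; observations outside the window
#' are dropped.
#'
#' @param start_date first day of the season (`Date` or ISO-8601 string).
#' @param n_days number of days in the season grid (integer, >= 2).
#' @return An object of class `season_window` with fields `start_date`
#'   and `n_days`.
#' @examples
#' w <- season_window()
#' w$n_days  # 215
#' @export
season_window <- function(start_date = "2018-04-01", n_days = 215L) {
  start_date <- as.Date(start_date)
  if (is.na(start_date)) stop("start_date is not a valid date")
  n_days <- as.integer(n_days)
  if (is.na(n_days) || n_days < 2L) stop("n_days must be an integer >= 2")
  structure(list(start_date = start_date, n_days = n_days),
            class = "season_window")
}

#' @export
print.season_window <- function(x, ...) {
  cat(sprintf("<season_window> %s + %d days (through %s)\n",
              format(x$start_date), x$n_days,
              format(x$start_date + x$n_days - 1L)))
  invisible(x)
}

# 0-based day offset of a date within the window; NA outside
day_offset <- function(dates, window) {
  off <- as.integer(as.Date(dates) - window$start_date)
  off[off < 0L | off >= window$n_days] <- NA_integer_
  off
}

# day-of-year (Jan 1 = 1) for each grid day of the window
window_doy <- function(window) {
  as.integer(strftime(window$start_date + seq_len(window$n_days) - 1L,
                      "%j"))
}
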