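test_that("NDVI from band reflectances follows the normalized difference", {
  expect_equal(ndvi_from_bands(0.2, 0.2), 0)
  expect_equal(ndvi_from_bands(0.3, 0), 1)
  expect_equal(ndvi_from_bands(0.3, 0.1), 0.5)
  expect_error(ndvi_from_bands(0, 0), "> 0")
  expect_error(ndvi_from_bands(-0.1, 0.2), ">= 0")
})

test_that("triplet filter removes an isolated cloud-mask drop", {
  # sudden drop to 0.38 between 0.75 and 0.78 within 10 days:
  # statistic 0.78 - 2*0.38 + 0.75 = 0.77 >= 0.6
  s <- series_df("A", c(0, 4, 8), ndvi = c(0.75, 0.38, 0.78))
  out <- filter_ndvi_outliers(s)
  expect_equal(out$removed, 2L)
  expect_equal(nrow(out$series), 2L)
  expect_equal(out$series$ndvi, c(0.75, 0.78))

  # same triplet spanning 12 days is kept (mowing can recover in 10)
  s12 <- series_df("A", c(0, 4, 12), ndvi = c(0.75, 0.38, 0.78))
  expect_length(filter_ndvi_outliers(s12)$removed, 0L)

  # constant series: statistic 0, nothing removed
  sc <- series_df("A", c(0, 4, 8), ndvi = c(0.5, 0.5, 0.5))
  expect_length(filter_ndvi_outliers(sc)$removed, 0L)
})

test_that("triplet filter is single-pass, idempotent, keeps endpoints", {
  set.seed(2)
  days <- seq(0, 80, by = 4)
  ndvi <- 0.7 + rnorm(length(days), sd = 0.02)
  ndvi[c(5, 12)] <- 0.05          # two isolated outliers
  s <- series_df("A", days, ndvi = ndvi)
  out <- filter_ndvi_outliers(s)
  expect_setequal(out$removed, c(5L, 12L))
  # endpoints can never be a triplet centre
  expect_false(1L %in% out$removed)
  expect_false(length(days) %in% out$removed)
  # idempotent on its own output
  again <- filter_ndvi_outliers(out$series)
  expect_length(again$removed, 0L)
  # fewer than 3 valid NDVI measurements: returned unchanged
  tiny <- series_df("A", c(0, 4), ndvi = c(0.7, 0.1))
  expect_length(filter_ndvi_outliers(tiny)$removed, 0L)
})

test_that("EMA follows its recursion and limiting cases", {
  x <- c(0.2, 0.4)
  expect_equal(ema_smooth(x, 1 / 3), c(0.2, 1 / 3 * 0.4 + 2 / 3 * 0.2))
  expect_equal(ema_smooth(x, 1), x)           # alpha = 1: identity
  expect_equal(ema_smooth(rep(0.3, 10), 0.2), rep(0.3, 10))  # fixed point
  expect_error(ema_smooth(numeric(), 0.5), "non-empty")
  expect_error(ema_smooth(x, 0), "\\(0, 1\\]")
})

test_that("EMA equals its closed-form weighted-sum expansion", {
  # out_n = sum_k alpha (1-alpha)^k x_{n-k} + (1-alpha)^(n-1) x_1
  ema_oracle <- function(x, alpha) {
    vapply(seq_along(x), function(n) {
      w <- alpha * (1 - alpha)^(0:(n - 1))
      w[n] <- (1 - alpha)^(n - 1)
      sum(w * x[n:1])
    }, numeric(1))
  }
  set.seed(11)
  for (i in 1:25) {
    x <- runif(sample(2:40, 1))
    a <- runif(1, 0.05, 1)
    expect_equal(ema_smooth(x, a), ema_oracle(x, a), tolerance = 1e-10)
  }
})

test_that("moving average matches a brute-force windowed mean", {
  ma_oracle <- function(x, w) {
    half <- w %/% 2
    n <- length(x)
    vapply(seq_len(n), function(i) {
      k <- min(half, i - 1, n - i)
      mean(x[(i - k):(i + k)])
    }, numeric(1))
  }
  expect_equal(moving_average_smooth(c(0, 1, 2), 3)[2], 1)
  expect_equal(moving_average_smooth(rep(0.4, 9), 7), rep(0.4, 9))
  set.seed(12)
  for (i in 1:25) {
    x <- runif(sample(3:50, 1))
    w <- sample(c(3, 5, 7, 9), 1)
    expect_equal(moving_average_smooth(x, w), ma_oracle(x, w),
                 tolerance = 1e-12)
  }
  expect_error(moving_average_smooth(1:5, 4), "odd")
})

test_that("smoothing preserves the input range", {
  set.seed(13)
  for (i in 1:10) {
    x <- runif(30)
    for (sm in list(ema_smooth(x, runif(1, 0.1, 1)),
                    moving_average_smooth(x, 7))) {
      expect_gte(min(sm), min(x))
      expect_lte(max(sm), max(x))
    }
  }
})

test_that("daily interpolation is linear, held at edges, exact on data", {
  w <- season_window()
  s <- series_df("A", c(0, 2), ndvi = c(0.2, 0.4),
                 cohvv = c(0.3, 0.3), cohvh = c(0.2, 0.2))
  g <- interpolate_daily(s, w)
  expect_equal(g$ndvi[2], 0.3)               # midpoint of day 0 and 2
  expect_equal(g$ndvi[4:215], rep(0.4, 212)) # constant extension
  expect_length(g$ndvi, 215)
  expect_true(!anyNA(unlist(g[c("ndvi", "cohvv", "cohvh",
                                "cohvv_sm", "cohvh_sm")])))

  # single measurement fills the whole season
  s1 <- series_df("A", 100, ndvi = 0.5, cohvv = 0.3, cohvh = 0.2)
  g1 <- interpolate_daily(s1, w)
  expect_equal(g1$ndvi, rep(0.5, 215))

  # grid restricted to measurement days reproduces the measurements
  set.seed(3)
  days <- sort(sample(0:214, 12))
  vals <- runif(12, 0.2, 0.8)
  g2 <- interpolate_daily(
    series_df("A", days, ndvi = vals, cohvv = vals / 2, cohvh = vals / 3),
    w)
  expect_equal(g2$ndvi[days + 1], vals)
  expect_equal(g2$cohvv[days + 1], vals / 2)
  expect_true(all(g2$valid_ndvi[days + 1]))
  expect_equal(sum(g2$valid_ndvi), 12)
})

test_that("coherence is smoothed on the measurements before interpolation", {
  days <- seq(0, 60, by = 6)
  set.seed(4)
  vv <- runif(length(days), 0.2, 0.6)
  g <- interpolate_daily(series_df("A", days, cohvv = vv, cohvh = vv),
                         smoothing = smoothing_config("ema", 1 / 3))
  expect_equal(g$cohvv_sm[days + 1], ema_smooth(vv, 1 / 3))
  expect_equal(g$cohvv[days + 1], vv)  # raw channel untouched
  gm <- interpolate_daily(series_df("A", days, cohvv = vv, cohvh = vv),
                          smoothing = smoothing_config("moving_average",
                                                       filter_width = 7))
  expect_equal(gm$cohvv_sm[days + 1], moving_average_smooth(vv, 7))
})

test_that("observations outside the window and empty channels are handled", {
  w <- season_window()
  s <- series_df("A", c(-10, 5, 300), ndvi = c(0.5, 0.6, 0.2),
                 cohvv = 0.3, cohvh = 0.3)
  expect_message(g <- interpolate_daily(s, w), "outside the season")
  expect_equal(sum(g$valid_ndvi), 1L)
  s2 <- series_df("A", c(10, 20), cohvv = c(0.3, 0.4),
                  cohvh = c(0.2, 0.3))
  expect_message(g2 <- interpolate_daily(s2, w), "season default")
  expect_equal(g2$ndvi, rep(0.5, 215))
  expect_error(interpolate_daily(s2, season_window(n_days = 2)), NA)
})
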