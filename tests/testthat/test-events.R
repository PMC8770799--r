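test_that("probability decoding finds maximal above-threshold runs", {
  expect_equal(nrow(probabilities_to_events(rep(0, 215))), 0L)

  p <- rep(0.1, 215); p[51:54] <- 0.8       # days 50-53 (0-based)
  ev <- probabilities_to_events(p)
  expect_equal(ev$start, 50L)
  expect_equal(ev$end, 53L)
  expect_equal(ev$peak_prob, 0.8)

  # two runs separated by one sub-threshold day stay two events
  p2 <- rep(0.1, 30); p2[5:8] <- 0.9; p2[10:12] <- 0.7
  expect_equal(probabilities_to_events(p2)$start, c(4L, 9L))

  # min_run_days suppresses single-day blips
  p3 <- rep(0.1, 30); p3[5] <- 0.9; p3[10:12] <- 0.7
  expect_equal(probabilities_to_events(p3, min_run_days = 2)$start, 9L)
  expect_error(probabilities_to_events(p, threshold = 1), "\\(0, 1\\)")
})

test_that("event matching applies the -3/+6-day tolerance window", {
  # 3 days early is still a hit
  expect_equal(match_events(100L, 103L),
               list(TP = 1L, TN = 0L, FP = 0L, FN = 0L))
  # second prediction in the same window is an FP
  expect_equal(match_events(c(101L, 104L), 103L),
               list(TP = 1L, TN = 0L, FP = 1L, FN = 0L))
  # 7 days late misses: FP for the prediction, FN for the event
  expect_equal(match_events(110L, 103L),
               list(TP = 0L, TN = 0L, FP = 1L, FN = 1L))
  # window bounds are inclusive
  expect_equal(match_events(109L, 103L)$TP, 1L)
  expect_equal(match_events(99L, 103L)$TP, 0L)
  # a season with no events on either side is one TN
  expect_equal(match_events(integer(), integer()),
               list(TP = 0L, TN = 1L, FP = 0L, FN = 0L))
  expect_error(match_events(c(5L, 3L), 4L), "sorted")
})

test_that("greedy matching equals the exhaustive max-TP oracle", {
  # full enumeration on a short season, random draws on a 30-day one
  subsets8 <- day_subsets(0:7, 2L)
  for (p in subsets8) for (a in subsets8)
    expect_equal(match_events(p, a), match_events_oracle(p, a))

  set.seed(20)
  days <- 0:29
  for (i in 1:400) {
    p <- sort(sample(days, sample(0:3, 1)))
    a <- sort(sample(days, sample(0:3, 1)))
    expect_equal(match_events(p, a), match_events_oracle(p, a))
  }
})

test_that("event accuracy is the pooled binary accuracy", {
  expect_equal(event_accuracy(list(TP = 3, TN = 1, FP = 1, FN = 1)),
               4 / 6)
  expect_equal(event_accuracy(list(TP = 2, TN = 1, FP = 0, FN = 0)), 1)
  expect_equal(event_accuracy(list(TP = 0, TN = 0, FP = 2, FN = 1)), 0)
  expect_error(event_accuracy(list(TP = 0, TN = 0, FP = 0, FN = 0)),
               "no events")
})

test_that("season scores and EOS accuracy follow the 50% rule", {
  probs <- rbind(c(rep(0.01, 214), 0.9), rep(0.001, 215))
  s_max <- season_scores(probs, "max")
  expect_equal(s_max, c(0.9, 0.001))
  s_nor <- season_scores(probs, "noisy_or")
  expect_gte(s_nor[1], 0.9)            # noisy-or dominates the max
  expect_lt(s_nor[2], 0.2)

  expect_equal(eos_accuracy(c(0.9, 0.1), c(TRUE, FALSE)), 1)
  expect_equal(eos_accuracy(c(0.0, 0.0), c(TRUE, FALSE)), 0.5)
  expect_error(eos_accuracy(0.5, c(TRUE, FALSE)), "misaligned")
})

test_that("rank AUC equals the brute-force pair count", {
  expect_equal(auc_roc(c(1, 0.9, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(auc_roc(rep(0.5, 6), c(1, 1, 1, 0, 0, 0)), 0.5)
  # pos {0.9, 0.4}, neg {0.3, 0.8}: 3 wins of 4 pairs
  expect_equal(auc_roc(c(0.9, 0.4, 0.3, 0.8), c(1, 1, 0, 0)), 0.75)

  auc_oracle <- function(s, f) {
    pos <- s[f == 1]; neg <- s[f == 0]
    mean(outer(pos, neg, function(p, q)
      (p > q) + 0.5 * (p == q)))
  }
  set.seed(30)
  for (i in 1:20) {
    n <- sample(4:50, 1)
    f <- c(1, 0, rbinom(n - 2, 1, 0.5))  # both classes guaranteed
    s <- round(runif(n), 2)              # rounding induces ties
    expect_equal(auc_roc(s, f), auc_oracle(s, f))
  }
  expect_error(auc_roc(c(0.1, 0.2), c(1, 1)), "both classes")
})

test_that("calibration curve recovers Bernoulli-sampled rates", {
  set.seed(31)
  scores <- runif(5000)
  flags <- rbinom(5000, 1, scores)   # perfectly calibrated scores
  cc <- calibration_curve(scores, flags, n_bins = 10)
  occupied <- cc$count > 0
  expect_lt(max(abs(cc$mean_predicted[occupied] -
                      cc$observed_fraction[occupied])), 0.05)
  expect_equal(sum(cc$count), 5000L)

  one <- calibration_curve(rep(1, 10), rep(1, 10), n_bins = 5)
  expect_equal(one$count[5], 10L)
  expect_equal(one$observed_fraction[5], 1)
  expect_equal(sum(one$count[-5]), 0L)
  expect_error(calibration_curve(numeric(), logical()), "empty")
  expect_error(calibration_curve(0.5, 1, n_bins = 1), ">= 2")
})

test_that("pooled evaluation is invariant to field processing order", {
  set.seed(32)
  n <- 20
  values <- array(rnorm(n * 50 * 2), c(n, 50, 2))
  labels <- matrix(0L, n, 50)
  for (i in 1:12) {
    s <- sample(5:40, 1); labels[i, s:(s + 4)] <- 1L
  }
  fm <- fm_from_arrays(values, labels, c("f1", "f2"))
  probs <- matrix(runif(n * 50), n, 50)
  ev1 <- evaluate_predictions(probs, fm)
  perm <- sample(n)
  fm2 <- subset_fields(fm, perm)
  ev2 <- evaluate_predictions(probs[perm, ], fm2)
  expect_equal(ev1$counts, ev2$counts)
  expect_equal(ev1$event_accuracy, ev2$event_accuracy)
  expect_equal(ev1$eos_accuracy, ev2$eos_accuracy)
})
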