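test_that("reject interval thresholds sit on the requested quantiles", {
  scores <- c(0.9, 0.8, 0.6, 0.2, 0.1, 0.2, 0.5)
  flags <- c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  # top 3 of 4 positives -> t_upper = 0.6
  ri <- fit_reject_interval(scores, flags, desired_tpr = 0.75,
                            desired_tnr = 2 / 3)
  expect_equal(ri$t_upper, 0.6)
  # negatives ascending {0.1, 0.2, 0.5}, m = ceil(2/3*3) = 2 -> 0.2
  expect_equal(ri$t_low, 0.2)
  # desired_tpr = 1 retains every positive
  # demanding every positive pushes t_upper to the minimum positive
  # score, here colliding with t_low: the interval collapses
  expect_warning(
    ri1 <- fit_reject_interval(scores, flags, desired_tpr = 1,
                               desired_tnr = 0.5),
    "empty")
  expect_equal(ri1$t_upper, 0.2)     # minimum positive score
  expect_true(ri1$empty)
  expect_error(fit_reject_interval(c(0.4, 0.5), c(TRUE, TRUE), 0.9, 0.9),
               "both classes")
  expect_error(fit_reject_interval(scores, flags, 0, 0.5), "\\(0, 1\\]")
})

test_that("fitted interval achieves the requested rates on validation", {
  set.seed(40)
  for (i in 1:10) {
    n <- 120
    flags <- c(TRUE, FALSE, runif(n - 2) < 0.7)
    scores <- round(ifelse(flags, rbeta(n, 4, 2), rbeta(n, 2, 4)), 2)
    tpr <- runif(1, 0.5, 1); tnr <- runif(1, 0.5, 1)
    ri <- suppressWarnings(
      fit_reject_interval(scores, flags, tpr, tnr))
    achieved_tpr <- mean(scores[flags] >= ri$t_upper)
    achieved_tnr <- mean(scores[!flags] <= ri$t_low)
    expect_gte(achieved_tpr, tpr)
    expect_gte(achieved_tnr, tnr)
  }
})

test_that("quantile fit agrees with exhaustive threshold search", {
  set.seed(41)
  for (i in 1:10) {
    n <- sample(20:100, 1)
    flags <- c(TRUE, FALSE, runif(n - 2) < 0.6)
    scores <- round(runif(n), 2)
    tpr <- runif(1, 0.4, 1); tnr <- runif(1, 0.4, 1)
    ri <- suppressWarnings(fit_reject_interval(scores, flags, tpr, tnr))
    # largest threshold achieving TPR >= target over all candidates
    cand <- sort(unique(scores))
    ok_up <- cand[vapply(cand, function(th)
      mean(scores[flags] >= th) >= tpr, logical(1))]
    expect_equal(ri$t_upper, max(ok_up))
    ok_low <- cand[vapply(cand, function(th)
      mean(scores[!flags] <= th) >= tnr, logical(1))]
    expect_equal(ri$t_low, min(ok_low))
  }
})

test_that("rejection fraction shrinks as the requested rates grow", {
  # demanding a higher retained rate forces the threshold toward the
  # class boundary, so the abstention interval can only shrink
  set.seed(42)
  n <- 200
  flags <- c(TRUE, FALSE, runif(n - 2) < 0.6)
  scores <- ifelse(flags, rbeta(n, 5, 2), rbeta(n, 2, 5))
  grid <- seq(0.5, 1, by = 0.1)
  frac <- function(tpr, tnr) {
    ri <- suppressWarnings(fit_reject_interval(scores, flags, tpr, tnr))
    apply_reject(scores, ri)$summary$fraction_rejected
  }
  for (tnr in c(0.6, 0.9)) {
    f <- vapply(grid, frac, numeric(1), tnr = tnr)
    expect_true(all(diff(f) <= 1e-12))
  }
  for (tpr in c(0.6, 0.9)) {
    f <- vapply(grid, function(t) frac(tpr, t), numeric(1))
    expect_true(all(diff(f) <= 1e-12))
  }
})

test_that("abstention is the open interval; ties are decided", {
  ri <- structure(list(t_low = 0.2, t_upper = 0.6, desired_tpr = 0.9,
                       desired_tnr = 0.9, empty = FALSE),
                  class = "reject_interval")
  out <- apply_reject(c(0.1, 0.2, 0.4, 0.6, 0.9), ri,
                      flags = c(FALSE, FALSE, TRUE, TRUE, TRUE))
  expect_equal(out$decisions$decision,
               c("not_mown", "not_mown", "abstain", "mown", "mown"))
  expect_equal(out$summary$n_rejected, 1L)
  expect_equal(out$summary$retained_accuracy, 1)

  # empty interval rejects nothing
  empty <- structure(list(t_low = 0.6, t_upper = 0.4, desired_tpr = 1,
                          desired_tnr = 1, empty = TRUE),
                     class = "reject_interval")
  out2 <- apply_reject(c(0.1, 0.5, 0.9), empty)
  expect_equal(out2$summary$n_rejected, 0L)

  # everything strictly inside the interval: accuracy reported missing
  wide <- structure(list(t_low = 0, t_upper = 1, desired_tpr = 1,
                         desired_tnr = 1, empty = FALSE),
                    class = "reject_interval")
  out3 <- apply_reject(c(0.3, 0.5), wide, flags = c(TRUE, FALSE))
  expect_equal(out3$summary$fraction_rejected, 1)
  expect_true(is.na(out3$summary$retained_accuracy))
})

test_that("retained-set accuracy beats all-data accuracy on held-out scores", {
  # monotone-calibrated scores: abstaining on the uncertain middle can
  # only help, checked over independent draws
  set.seed(43)
  wins <- 0L; trials <- 0L
  for (i in 1:12) {
    n <- 300
    val_flags <- c(TRUE, FALSE, runif(n - 2) < 0.6)
    val_scores <- ifelse(val_flags, rbeta(n, 6, 2), rbeta(n, 2, 6))
    te_flags <- c(TRUE, FALSE, runif(n - 2) < 0.6)
    te_scores <- ifelse(te_flags, rbeta(n, 6, 2), rbeta(n, 2, 6))
    ri <- suppressWarnings(
      fit_reject_interval(val_scores, val_flags, 0.8, 0.8))
    if (ri$empty) next
    trials <- trials + 1L
    out <- apply_reject(te_scores, ri, te_flags)
    all_acc <- mean((te_scores > 0.5) == te_flags)
    if (!is.na(out$summary$retained_accuracy) &&
        out$summary$retained_accuracy >= all_acc) wins <- wins + 1L
  }
  expect_gte(trials, 6L)
  expect_gte(wins, round(0.8 * trials))
})
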