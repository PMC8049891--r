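test_that("faithful errors follow the data-minus-prediction convention", {
  ds <- tiny_dataset()
  # 1-of-4: response 4, target baseline 3 -> +1
  # 4-combined: response 5, mean baseline 4.75 -> +0.25
  err <- faithful_error(ds$trials, ds$baselines)
  expect_equal(err, c(1, 0.25, 0))
  toy <- ds$trials[1, ]
  toy$response <- 3L
  toy$target_position <- 4L  # baseline 8
  expect_equal(faithful_error(toy, ds$baselines), -5)
  # below-prediction ratings give negative errors
  toy$response <- 3L
  toy$target_position <- 3L  # baseline 6
  expect_equal(faithful_error(toy, ds$baselines), -3)
  # missing baseline errors out
  bad <- ds$baselines[-1, ]
  expect_error(faithful_error(ds$trials, bad), "missing baseline")
})

test_that("prediction binning uses one-point half-open bins", {
  # the quarter-point predictions 1.0..1.75 share one bin
  expect_identical(bin_predictions(c(1.0, 1.25, 1.5, 1.75)),
                   rep(1L, 4))
  expect_identical(bin_predictions(2.0), 2L)      # [2, 3)
  expect_identical(bin_predictions(2.999), 2L)
  expect_identical(bin_predictions(9.0), 8L)      # top bin closed
  # 1-of-4 predictions are integers and bin to themselves
  expect_identical(bin_predictions(c(1, 5, 9), "one_of_four"), c(1L, 5L, 9L))
  # brute-force interval comparison on random quarter-point predictions
  withr::with_seed(61, {
    p <- sample(seq(4, 36), 500, replace = TRUE) / 4
    got <- bin_predictions(p)
    brute <- vapply(p, function(x) {
      for (b in 1:8) if (x >= b && (x < b + 1 || b == 8)) return(b)
      NA_integer_
    }, 1)
    expect_identical(got, as.integer(brute))
  })
})

test_that("error summaries are zero for noiseless faithful observers", {
  ds <- sim_population(n = 2, seed = 62, sd = 0, guess_rate = 0,
                       n_images = 8, n_blocks = 2)
  es <- summarize_errors(ds, conditions = c("precue_1of4", "postcue_1of4"))
  expect_true(all(es$summary$mean_error == 0))
  expect_true(all(es$bins$mean_error == 0))
})

test_that("attenuation observers show negative errors only above threshold", {
  # noiseless attenuators: error = key_round(attenuated) - P_t is 0 up to
  # the threshold and increasingly negative above it
  obs <- default_observers(
    2, seed = 63, sigma_late = sigma_all(0), guess_rate = 0,
    single_precue = rule("high_pleasure_attenuation", P_beau = 4.6, g = 0.5),
    single_postcue = rule("high_pleasure_attenuation", P_beau = 4.6, g = 0.5),
    combined = rule("faithful_averaging"))
  ds <- simulate_responses(build_design(design_spec(2, seed = 63)), obs)
  es <- summarize_errors(ds, conditions = c("precue_1of4", "postcue_1of4"))
  low <- es$bins[es$bins$bin <= 4, ]
  high <- es$bins[es$bins$bin >= 6, ]
  expect_true(all(low$mean_error == 0))
  expect_true(all(high$mean_error <= -1))
  for (pid in unique(es$bins$participant_id)) {
    b <- es$bins[es$bins$participant_id == pid &
                   es$bins$condition == "postcue_1of4", ]
    expect_true(all(diff(b$mean_error[b$bin >= 5]) <= 0))
  }
})

test_that("bin-weighted means conserve the trial-level mean error", {
  ds <- sim_population(n = 3, seed = 64, sd = 1.2, n_images = 8,
                       n_blocks = 2)
  by_bins <- summarize_errors(ds, error_average = "bins")
  by_trials <- summarize_errors(ds, error_average = "trials")
  for (i in seq_len(nrow(by_trials$summary))) {
    row <- by_trials$summary[i, ]
    b <- by_bins$bins[by_bins$bins$participant_id == row$participant_id &
                        by_bins$bins$condition == row$condition, ]
    expect_equal(sum(b$n * b$mean_error) / sum(b$n), row$mean_error)
  }
  # a +1/-1 toy averages to zero over trials
  toy <- tiny_dataset()
  t2 <- toy$trials[c(1, 1), ]
  t2$response <- c(2L, 4L)  # target baseline 3 -> errors -1, +1
  t2$trial_index <- 1:2
  toy$trials <- t2
  es <- summarize_errors(toy, error_average = "trials",
                         conditions = "precue_1of4")
  expect_equal(es$summary$mean_error, 0)
})

test_that("summaries are invariant to trial order", {
  ds <- sim_population(n = 2, seed = 65, sd = 1, n_images = 8, n_blocks = 2)
  shuffled <- ds
  withr::with_seed(1, {
    shuffled$trials <- shuffled$trials[sample(nrow(shuffled$trials)), ]
  })
  a <- summarize_errors(ds)
  b <- summarize_errors(shuffled)
  expect_equal(a$summary, b$summary)
  expect_equal(a$bins, b$bins)
})

test_that("correlations and paired tests match their textbook formulas", {
  mk_summary <- function(pre_err, post_err, pre_sd, post_sd) {
    n <- length(pre_err)
    data.frame(
      participant_id = rep(sprintf("P%02d", 1:n), 2),
      condition = rep(c("precue_1of4", "postcue_1of4"), each = n),
      n_trials = 10L,
      mean_error = c(pre_err, post_err),
      rating_sd = c(pre_sd, post_sd), stringsAsFactors = FALSE)
  }
  # perfectly correlated and anti-correlated toys
  up <- c(0.1, 0.2, 0.3)
  st <- correlate_and_test(mk_summary(up, 2 * up + 1, up + 1, up + 2))
  r1 <- st$correlations[st$correlations$measure == "mean_error", ]
  expect_equal(r1$r, 1)
  st2 <- correlate_and_test(mk_summary(c(1, 2, 3), c(3, 2, 1),
                                       c(1, 2, 4), c(2, 1, 5)))
  expect_equal(st2$correlations$r[
    st2$correlations$measure == "mean_error"], -1)
  # hand-computed Pearson r on a 3-point example
  a <- c(0.2, -0.4, 0.9)
  b <- c(-0.1, 0.3, 0.8)
  st3 <- correlate_and_test(mk_summary(a, b, c(1, 2, 3), c(3, 1, 2)))
  r_hand <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(st3$correlations$r[st3$correlations$measure == "mean_error"],
               r_hand, tolerance = 1e-12)
  # paired t statistic and mean difference
  tt <- st3$paired_tests[st3$paired_tests$measure == "mean_error", ]
  d <- a - b
  expect_equal(tt$mean_diff, mean(d))
  expect_equal(tt$t, mean(d) / (sd(d) / sqrt(3)), tolerance = 1e-12)
  # degenerate zero-variance input is refused
  expect_error(
    correlate_and_test(mk_summary(c(1, 1, 1), c(1, 2, 3), 1:3, 1:3)),
    "zero-variance")
  expect_error(correlate_and_test(mk_summary(1:2, 1:2, 1:2, 2:1)[
    c(1, 2, 3, 4), ]), "at least 3 participants")
})

test_that("k-means clustering separates the two parameter groups", {
  withr::with_seed(66, {
    # the two fitted (a, b) clusters: 22 observers near (-1.4, 1.2) and 3
    # near (2.4, 0.4)
    major <- cbind(a = rnorm(22, -1.4, 0.3), b = rnorm(22, 1.2, 0.1))
    minor <- cbind(a = rnorm(3, 2.4, 0.3), b = rnorm(3, 0.4, 0.1))
    pts <- rbind(major, minor)
    cl <- cluster_params(pts, k_max = 4, seed = 1)
    expect_identical(cl$k, 2L)
    expect_identical(length(unique(cl$assignments[1:22])), 1L)
    expect_identical(length(unique(cl$assignments[23:25])), 1L)
    cent <- cl$centroids[order(cl$centroids[, "a"]), ]
    expect_lt(max(abs(cent[1, ] - colMeans(major))), 0.2)
    expect_lt(max(abs(cent[2, ] - colMeans(minor))), 0.2)
    expect_lt(max(abs(cent[1, ] - c(-1.4, 1.2))), 0.2)
    expect_lt(max(abs(cent[2, ] - c(2.4, 0.4))), 0.2)
    # objective non-increasing in k
    expect_true(all(diff(cl$mean_wss) <= 1e-9))

    # a single tight blob stays one cluster under the elbow rule
    blob <- cbind(a = rnorm(30, 0, 0.5), b = rnorm(30, 0, 0.5))
    expect_identical(cluster_params(blob, seed = 1)$k, 1L)
    expect_error(cluster_params(pts[1:4, ], k_max = 4), "at least")
  })
})
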