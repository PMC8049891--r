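test_that("zero-parameter fits just evaluate the model", {
  ds <- tiny_dataset()
  single <- ds$trials[ds$trials$trial_type == "one_of_four", ]
  f <- fit_model(single, ds$baselines, "faithful")
  expect_identical(f$params, numeric(0))
  # response 4, target baseline (pos 2) 3 -> RMSE 1
  expect_equal(f$rmse, 1)
})

test_that("attenuation parameters are recovered on noiseless data", {
  # 288 trials whose target baselines cover 1..9 in equal numbers; the
  # observer attenuates above 4.6 with gain 0.5 and presses the nearest key
  withr::with_seed(41, {
    n <- 288
    Pt <- rep(1:9, length.out = n)
    P <- cbind(Pt, matrix(sample(1:9, 3 * n, replace = TRUE), ncol = 3))
    y <- key_round(ifelse(Pt < 4.6, Pt, 4.6 + 0.5 * (Pt - 4.6)))
    fit <- fit_params("high_pleasure_attenuation", P, 1, y)

    # independent oracle: dense 2-D grid search at step 0.01, the cost in g
    # expanded in closed form for speed
    pb_grid <- seq(1, 9, 0.01)
    g_grid <- seq(0, 1, 0.01)
    best <- c(Inf, NA, NA)
    for (pb in pb_grid) {
      base0 <- pmin(Pt, pb)
      ex <- pmax(Pt - pb, 0)
      r0 <- base0 - y
      # mean((r0 + g ex)^2) = c0 + 2 c1 g + c2 g^2
      c0 <- mean(r0^2); c1 <- mean(r0 * ex); c2 <- mean(ex^2)
      costs <- c0 + 2 * c1 * g_grid + c2 * g_grid^2
      j <- which.min(costs)
      if (costs[j] < best[1]) best <- c(costs[j], pb, g_grid[j])
    }
    expect_lt(abs(fit$params[["P_beau"]] - best[2]), 0.05)
    expect_lt(abs(fit$params[["g"]] - best[3]), 0.05)
    # and both sit at the generating truth
    expect_lt(abs(fit$params[["P_beau"]] - 4.6), 0.05)
    expect_lt(abs(fit$params[["g"]] - 0.5), 0.05)
  })
})

test_that("linear fits agree with the least-squares oracle", {
  withr::with_seed(42, {
    P <- random_P(60)
    Pbar <- rowMeans(P)
    y <- -1.4 + 1.2 * Pbar
    fit <- fit_params("linear_combined", P, NULL, y)
    expect_lt(abs(fit$params[["a"]] - (-1.4)), 1e-4)
    expect_lt(abs(fit$params[["b"]] - 1.2), 1e-4)
    # with noise, the RMSE minimiser is ordinary least squares
    y2 <- y + rnorm(60, 0, 0.5)
    ls <- unname(stats::coef(stats::lm(y2 ~ Pbar)))
    fit2 <- fit_params("linear_combined", P, NULL, y2)
    expect_lt(abs(fit2$params[["a"]] - ls[1]), 1e-3)
    expect_lt(abs(fit2$params[["b"]] - ls[2]), 1e-3)
  })
})

test_that("nesting models never fit worse than their special cases", {
  withr::with_seed(43, {
    P <- random_P(80)
    t <- sample(1:4, 80, replace = TRUE)
    y <- key_round(P[cbind(1:80, t)] + rnorm(80, 0, 1.2))
    pairs <- list(c("average_biased", "faithful"),
                  c("high_pleasure_attenuation", "faithful"),
                  c("linear_single", "faithful"),
                  c("weighted_avg_biased", "average_biased"),
                  c("average_biased", "averaging"))
    for (pr in pairs) {
      big <- fit_params(pr[1], P, t, y)
      small <- fit_params(pr[2], P, t, y)
      expect_lte(big$rmse, small$rmse + 1e-6, label = paste(pr, collapse = " vs "))
    }
    yb <- key_round(rowMeans(P) + rnorm(80, 0, 1.2))
    for (fam in c("linear_combined", "attenuation_combined")) {
      big <- fit_params(fam, P, NULL, yb)
      small <- fit_params("faithful_averaging", P, NULL, yb)
      expect_lte(big$rmse, small$rmse + 1e-6, label = fam)
    }
  })
})

test_that("LOOCV of a zero-parameter model reduces to per-trial errors", {
  ds <- sim_population(n = 1, seed = 51, sd = 1, n_images = 8, n_blocks = 2)
  cond <- trial_conditions(ds$trials)
  sub <- ds$trials[cond == "precue_1of4", ]
  cv <- loocv(sub, ds$baselines, "faithful")
  # held-out predictions equal full-data predictions: no fitting occurs
  P <- sapply(1:4, function(p) {
    key <- paste(ds$baselines$participant_id, ds$baselines$image_id)
    ds$baselines$baseline_pleasure[
      match(paste(sub$participant_id, sub[[paste0("pos", p, "_image")]]), key)]
  })
  pt <- P[cbind(seq_len(nrow(sub)), sub$target_position)]
  expect_equal(cv$folds$prediction, as.numeric(pt))
  expect_equal(cv$mean_heldout_rmse, mean(abs(sub$response - pt)))
  # pooled flag takes the root of the pooled mean square instead
  cvp <- loocv(sub, ds$baselines, "faithful", pool = "pooled")
  expect_equal(cvp$mean_heldout_rmse, sqrt(mean((sub$response - pt)^2)))
})

test_that("LOOCV error is zero for a noiseless faithful observer", {
  ds <- sim_population(n = 1, seed = 52, sd = 0, guess_rate = 0,
                       n_images = 8, n_blocks = 2)
  cond <- trial_conditions(ds$trials)
  sub <- ds$trials[cond == "postcue_1of4", ]
  cv <- loocv(sub, ds$baselines, "faithful")
  expect_equal(cv$mean_heldout_rmse, 0)
})

test_that("held-out RMSE of the faithful model matches the residual SD", {
  ds <- sim_population(n = 1, seed = 53, sd = 1.0)
  sub <- ds$trials[ds$trials$trial_type == "one_of_four", ]  # 288 trials
  expect_identical(nrow(sub), 288L)
  cv <- loocv(sub, ds$baselines, "faithful", pool = "pooled")
  resid_sd <- stats::sd(cv$folds$error)  # observed response variability
  expect_lt(abs(cv$mean_heldout_rmse - resid_sd), 0.1 * resid_sd)
})

test_that("warm and grid per-fold refits agree on a small problem", {
  ds <- sim_population(n = 1, seed = 54, sd = 1, n_images = 8, n_blocks = 2)
  cond <- trial_conditions(ds$trials)
  sub <- ds$trials[cond == "precue_1of4", ]
  w <- loocv(sub, ds$baselines, "average_biased", refit = "warm")
  g <- loocv(sub, ds$baselines, "average_biased", refit = "grid")
  expect_equal(w$mean_heldout_rmse, g$mean_heldout_rmse, tolerance = 1e-6)
})

test_that("fit preconditions are enforced", {
  ds <- tiny_dataset()
  expect_error(fit_model(ds$trials, ds$baselines, "faithful"),
               "one trial type")
  single <- ds$trials[ds$trials$trial_type == "one_of_four", ]
  expect_error(fit_model(single, ds$baselines, "faithful_averaging"),
               "does not apply")
  expect_error(fit_params("linear_single", random_P(2), c(1, 2), c(5, 5)),
               "at least 3 trials")
  expect_error(loocv(single, ds$baselines, "faithful"), "at least 2 trials")
  # degenerate flag: all targets identical
  P <- matrix(c(5, 5, 5, 5), 10, 4, byrow = TRUE)
  f <- fit_params("linear_single", P, 1, rep(4, 10))
  expect_true(f$degenerate)
})

test_that("model comparison aggregates RMSEs, SEMs and winner counts", {
  cvs <- list(fake_cv("P01", "precue_1of4", "faithful", 1.0),
              fake_cv("P01", "precue_1of4", "averaging", 1.2))
  tab <- compare_models(cvs)
  expect_identical(tab$winner_count[tab$family == "faithful"], 1L)
  expect_identical(tab$winner_count[tab$family == "averaging"], 0L)

  # SEM is the sample SD of per-participant means over sqrt(n)
  r <- c(1.0, 1.3, 1.6)
  cvs3 <- c(lapply(1:3, function(i)
              fake_cv(paste0("P0", i), "precue_1of4", "faithful", r[i])),
            lapply(1:3, function(i)
              fake_cv(paste0("P0", i), "precue_1of4", "averaging", 2)))
  tab3 <- compare_models(cvs3)
  expect_equal(tab3$sem[tab3$family == "faithful"], sd(r) / sqrt(3))
  # exact ties count for every tied model
  expect_identical(sum(tab3$winner_count), 3L + 0L)
  cvs_tie <- list(fake_cv("P01", "precue_1of4", "faithful", 1),
                  fake_cv("P01", "precue_1of4", "averaging", 1 + 1e-12))
  expect_identical(sum(compare_models(cvs_tie)$winner_count), 2L)
  # incomplete grids are refused
  expect_error(compare_models(c(cvs3, list(
    fake_cv("P04", "precue_1of4", "faithful", 1)))), "incomplete")
})
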