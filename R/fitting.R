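#' Fit a rating model by box-constrained RMSE minimisation
#'
#' Fits one model family to one participant's trials of a single
#' condition. The cost is the root-mean-square error between the model's
#' deterministic predictions and the observed key presses. Optimisation is
#' `L-BFGS-B` from a fixed multi-start grid (every combination of three
#' values per parameter spanning its bounds: lower, midpoint, upper), best
#' result kept, which makes the fit deterministic and robust to the local
#' minima of the piecewise attenuation objective. For the simplex-weight
#' families the implied fourth weight is kept feasible by a continuous
#' penalty with projection.
#'
#' `fit_params()` is the low-level engine operating directly on a baseline
#' matrix `P`, target positions `t` and responses `y`; `fit_model()`
#' prepares those from a trials table and baseline table.
#'
#' @param trials Trials data frame: one participant, one trial type
#'   (all `one_of_four` or all `four_combined`).
#' @param baselines Baseline table covering every displayed image.
#' @param spec A `plt_model_spec` (or family name).
#' @param start Optional single start (named numeric); replaces the grid.
#' @return An object of class `plt_fit`: `params` (named numeric),
#'   `rmse` (training RMSE), `spec`, `n_trials`, `degenerate` (all target
#'   values identical). Zero-parameter families return an empty `params`.
#' @export
fit_model <- function(trials, baselines, spec, start = NULL) {
  if (is.character(spec)) spec <- model_spec(spec)
  tt <- unique(trials$trial_type)
  if (length(tt) != 1) {
    stop("trials must all share one trial type", call. = FALSE)
  }
  if ((spec$type == "single") != (tt == "one_of_four")) {
    stop("model '", spec$family, "' does not apply to ", tt, " trials",
         call. = FALSE)
  }
  P <- .baseline_matrix(trials, baselines)
  fit_params(spec, P, trials$target_position, trials$response,
             start = start)
}

#' @rdname fit_model
#' @param P `n x 4` matrix of baseline pleasures.
#' @param t Integer target positions (ignored by combined families).
#' @param y Observed ratings.
#' @export
fit_params <- function(spec, P, t, y, start = NULL) {
  if (is.character(spec)) spec <- model_spec(spec)
  P <- .as_P_matrix(P)
  y <- as.numeric(y)
  n <- length(y)
  if (n < spec$n_params + 1) {
    stop(sprintf("need at least %d trials to fit '%s', got %d",
                 spec$n_params + 1, spec$family, n), call. = FALSE)
  }
  target <- if (spec$type == "single") {
    P[cbind(seq_len(n), rep_len(as.integer(t), n))]
  } else {
    rowMeans(P)
  }
  degenerate <- length(unique(target)) == 1

  if (spec$n_params == 0) {
    pred <- .predict_model(spec, numeric(0), t, P)
    return(.plt_fit(spec, numeric(0), sqrt(mean((pred - y)^2)), n,
                    degenerate))
  }

  simplex <- .simplex_block(spec$family)
  simplex_idx <- match(simplex, spec$param_names)
  repair <- function(par) {
    names(par) <- spec$param_names
    if (!is.null(simplex)) {
      s <- sum(par[simplex_idx])
      if (s > 1) par[simplex_idx] <- par[simplex_idx] / s
    }
    par
  }
  predictor <- .make_predictor(spec, P, t)
  cost <- function(par) {
    pen <- 0
    if (!is.null(simplex)) {
      pen <- 10 * max(0, sum(par[simplex_idx]) - 1)
      s <- sum(par[simplex_idx])
      if (s > 1) par[simplex_idx] <- par[simplex_idx] / s
    }
    sqrt(mean((predictor(par) - y)^2)) + pen
  }

  starts <- if (!is.null(start)) {
    matrix(unlist(start)[seq_len(spec$n_params)], nrow = 1)
  } else {
    .start_grid(spec)
  }
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    res <- tryCatch(
      stats::optim(starts[i, ], cost, method = "L-BFGS-B",
                   lower = spec$lower, upper = spec$upper,
                   control = list(factr = 1e7, maxit = 200)),
      error = function(e) NULL)
    if (!is.null(res) && (is.null(best) || res$value < best$value)) {
      best <- res
    }
  }
  if (is.null(best)) {
    stop("optimisation failed for model '", spec$family, "'", call. = FALSE)
  }
  params <- repair(best$par)
  pred <- .predict_model(spec, params, t, P)
  .plt_fit(spec, params, sqrt(mean((pred - y)^2)), n, degenerate)
}

.plt_fit <- function(spec, params, rmse, n, degenerate) {
  structure(list(spec = spec, params = params, rmse = rmse,
                 n_trials = n, degenerate = degenerate),
            class = "plt_fit")
}

#' @export
print.plt_fit <- function(x, ...) {
  cat(sprintf("<fit of '%s': training RMSE %.4f on %d trials%s>\n",
              x$spec$family, x$rmse, x$n_trials,
              if (x$degenerate) ", degenerate (constant target)" else ""))
  if (length(x$params) > 0) {
    print(round(x$params, 4))
  }
  invisible(x)
}

# Fast positional-parameter predictor used inside the optimiser loop:
# precomputes the trial statistics each family needs so that a cost
# evaluation is a handful of vector operations. Predictions agree with
# predict_single()/predict_combined() exactly.
.make_predictor <- function(spec, P, t) {
  n <- nrow(P)
  if (spec$type == "combined") {
    Pbar <- rowMeans(P)
    return(switch(spec$family,
      faithful_averaging = function(par) Pbar,
      linear_combined = function(par) par[1] + par[2] * Pbar,
      attenuation_combined = function(par)
        pmin(Pbar, par[1]) + par[2] * pmax(Pbar - par[1], 0)))
  }
  Pt <- P[cbind(seq_len(n), rep_len(as.integer(t), n))]
  switch(spec$family,
    faithful = function(par) Pt,
    averaging = {
      Pbar <- rowMeans(P)
      function(par) Pbar
    },
    average_biased = {
      Pbar <- rowMeans(P)
      function(par) (1 - par[1]) * Pt + par[1] * Pbar
    },
    weighted_avg_position = function(par)
      drop(P %*% c(par, 1 - sum(par))),
    weighted_avg_biased = function(par)
      (1 - par[1]) * Pt +
        par[1] * drop(P %*% c(par[2:4], 1 - sum(par[2:4]))),
    linear_single = function(par) par[1] + par[2] * Pt,
    weighted_avg_pleasure_rank = {
      Ps <- .sort4_desc(P)
      function(par) drop(Ps %*% c(par, 1 - sum(par)))
    },
    high_pleasure_attenuation = function(par)
      pmin(Pt, par[1]) + par[2] * pmax(Pt - par[1], 0))
}

# the fixed multi-start grid: 3 values per parameter spanning the bounds
.start_grid <- function(spec) {
  vals <- lapply(seq_len(spec$n_params), function(i) {
    c(spec$lower[i], (spec$lower[i] + spec$upper[i]) / 2, spec$upper[i])
  })
  g <- as.matrix(expand.grid(vals))
  colnames(g) <- spec$param_names
  simplex <- .simplex_block(spec$family)
  if (!is.null(simplex)) {
    idx <- match(simplex, spec$param_names)
    s <- rowSums(g[, idx, drop = FALSE])
    over <- s > 1
    g[over, idx] <- g[over, idx, drop = FALSE] / s[over]
    g <- unique(g)
  }
  g
}

#' Leave-one-out cross-validation of one model
#'
#' For each trial: fit the model on all other trials, predict the held-out
#' trial. With a single trial per fold, the per-fold test RMSE is that
#' trial's absolute error, so `mean_heldout_rmse` defaults to the mean
#' absolute held-out error (`pool = "per_fold"`); `pool = "pooled"`
#' instead takes the square root of the pooled mean squared held-out
#' error. Per-fold refits start from the full-data multi-start optimum
#' (`refit = "warm"`, deterministic and fast since each fold drops one of
#' n trials); `refit = "grid"` reruns the full start grid in every fold.
#'
#' @inheritParams fit_model
#' @param pool `"per_fold"` or `"pooled"`.
#' @param refit `"warm"` or `"grid"`.
#' @return An object of class `plt_cv`: `participant_id`, `family`,
#'   `condition`, `folds` (data frame with held-out `prediction`,
#'   `observed`, `error` = observed - prediction, and the per-fold fitted
#'   parameters as columns), `mean_heldout_rmse`, `mean_params`
#'   (fold-averaged), `pool`.
#' @export
loocv <- function(trials, baselines, spec, pool = c("per_fold", "pooled"),
                  refit = c("warm", "grid")) {
  if (is.character(spec)) spec <- model_spec(spec)
  pool <- match.arg(pool)
  refit <- match.arg(refit)
  n <- nrow(trials)
  if (n < spec$n_params + 2) {
    stop(sprintf("LOOCV of '%s' needs at least %d trials, got %d",
                 spec$family, spec$n_params + 2, n), call. = FALSE)
  }
  P <- .baseline_matrix(trials, baselines)
  t <- trials$target_position
  y <- as.numeric(trials$response)
  full <- fit_params(spec, P, t, y)

  preds <- numeric(n)
  par_mat <- matrix(NA_real_, n, spec$n_params,
                    dimnames = list(NULL, spec$param_names))
  for (i in seq_len(n)) {
    if (spec$n_params == 0) {
      fold_par <- numeric(0)
    } else {
      fold <- fit_params(spec, P[-i, , drop = FALSE], t[-i], y[-i],
                         start = if (refit == "warm") full$params else NULL)
      fold_par <- fold$params
      par_mat[i, ] <- fold_par
    }
    preds[i] <- .predict_model(spec, fold_par, t[i],
                               P[i, , drop = FALSE])
  }
  err <- y - preds
  folds <- data.frame(fold = seq_len(n), prediction = preds,
                      observed = y, error = err)
  if (spec$n_params > 0) folds <- cbind(folds, par_mat)
  structure(
    list(participant_id = unique(trials$participant_id)[1],
         family = spec$family,
         condition = unique(.condition_of(trials))[1],
         folds = folds,
         mean_heldout_rmse = if (pool == "per_fold") mean(abs(err))
                             else sqrt(mean(err^2)),
         mean_params = if (spec$n_params > 0) colMeans(par_mat)
                       else numeric(0),
         pool = pool, spec = spec),
    class = "plt_cv"
  )
}

#' @export
print.plt_cv <- function(x, ...) {
  cat(sprintf("<LOOCV %s / %s / %s: mean held-out RMSE %.4f over %d folds>\n",
              x$participant_id, x$condition, x$family,
              x$mean_heldout_rmse, nrow(x$folds)))
  if (length(x$mean_params) > 0) {
    cat("fold-averaged parameters:\n")
    print(round(x$mean_params, 4))
  }
  invisible(x)
}

#' Cross-validate every applicable model for every participant
#'
#' Runs [loocv()] over the participant x condition x model grid of a
#' dataset. Conditions are fitted separately: `precue_1of4`,
#' `postcue_1of4` (single-target families) and `precue_comb`,
#' `postcue_comb` (combined families).
#'
#' @param ds A `plt_dataset`.
#' @param families Model family names; default all eleven.
#' @param conditions Conditions to fit; default all four.
#' @inheritParams loocv
#' @return List of `plt_cv` objects.
#' @export
loocv_dataset <- function(ds,
                          families = c(single_families(),
                                       combined_families()),
                          conditions = c("precue_1of4", "postcue_1of4",
                                         "precue_comb", "postcue_comb"),
                          pool = "per_fold", refit = "warm") {
  cond <- .condition_of(ds$trials)
  pids <- unique(ds$trials$participant_id)
  out <- list()
  for (pid in pids) {
    for (cn in conditions) {
      sub <- ds$trials[ds$trials$participant_id == pid & cond == cn, ,
                       drop = FALSE]
      if (nrow(sub) == 0) next
      type_needed <- if (grepl("1of4", cn)) "single" else "combined"
      for (fam in families) {
        spec <- model_spec(fam)
        if (spec$type != type_needed) next
        out[[length(out) + 1]] <- loocv(sub, ds$baselines, spec,
                                        pool = pool, refit = refit)
      }
    }
  }
  out
}

#' Cross-participant model comparison
#'
#' Aggregates LOOCV results into the comparison table: per condition and
#' model family, the mean held-out RMSE across participants, its standard
#' error, and the number of participants for whom the family attains the
#' least (or tied, at tolerance `tol`) mean held-out RMSE within the
#' condition. Ties count for every tied model, so winner counts per
#' condition can exceed the number of participants.
#'
#' @param cv_results List of `plt_cv` objects covering a full
#'   participant x model grid per condition.
#' @param tol Tie tolerance in rating points.
#' @return Data frame `condition`, `family`, `mean_rmse`, `sem`,
#'   `winner_count`, `n_participants`.
#' @export
compare_models <- function(cv_results, tol = 1e-9) {
  df <- do.call(rbind, lapply(cv_results, function(x) {
    data.frame(participant_id = x$participant_id, condition = x$condition,
               family = x$family, rmse = x$mean_heldout_rmse,
               stringsAsFactors = FALSE)
  }))
  out <- list()
  for (cn in unique(df$condition)) {
    sub <- df[df$condition == cn, , drop = FALSE]
    grid <- table(sub$participant_id, sub$family)
    if (any(grid != 1)) {
      stop("incomplete participant x model grid for condition '", cn, "'",
           call. = FALSE)
    }
    wins <- stats::setNames(integer(length(unique(sub$family))),
                            sort(unique(sub$family)))
    for (pid in unique(sub$participant_id)) {
      pp <- sub[sub$participant_id == pid, ]
      best <- min(pp$rmse)
      tied <- pp$family[pp$rmse <= best + tol]
      wins[tied] <- wins[tied] + 1L
    }
    agg <- do.call(rbind, lapply(sort(unique(sub$family)), function(fam) {
      v <- sub$rmse[sub$family == fam]
      data.frame(condition = cn, family = fam, mean_rmse = mean(v),
                 sem = stats::sd(v) / sqrt(length(v)),
                 winner_count = wins[[fam]],
                 n_participants = length(v), stringsAsFactors = FALSE)
    }))
    out[[cn]] <- agg
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
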