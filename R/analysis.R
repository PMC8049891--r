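#' Faithful-prediction error per trial
#'
#' The faithful prediction is the target image's baseline pleasure for
#' 1-of-4 trials and the arithmetic mean of the four displayed baselines
#' for 4-combined trials. The error is signed data minus prediction, so a
#' rating below the faithful prediction gives a negative error.
#'
#' @param trials Trials data frame (baseline trials are given error 0
#'   against their own baseline).
#' @param baselines Baseline table.
#' @return Numeric vector of per-trial errors, in rating points.
#' @export
faithful_error <- function(trials, baselines) {
  trials$response - .faithful_prediction(trials, baselines)
}

.faithful_prediction <- function(trials, baselines) {
  P <- .baseline_matrix(trials, baselines)
  single <- trials$trial_type == "one_of_four"
  base <- trials$trial_type == "baseline"
  pred <- rowMeans(P, na.rm = TRUE)  # combined & baseline (one image)
  if (any(single)) {
    pred[single] <- P[cbind(which(single),
                            trials$target_position[single])]
  }
  pred
}

#' Bin faithful predictions
#'
#' 1-of-4 predictions are integer baseline ratings and bin to themselves.
#' 4-combined predictions (multiples of 0.25) fall into one-point-wide
#' half-open bins [1,2), [2,3), ..., [8,9], the top bin closed so a
#' prediction of exactly 9 lands in bin 8. Bins are labelled by their
#' lower edge.
#'
#' @param predictions Numeric faithful predictions in [1, 9].
#' @param trial_type `"one_of_four"`/`"baseline"` (integer bins) or
#'   `"four_combined"` (one-point bins); scalar or vector.
#' @return Integer bin labels.
#' @export
bin_predictions <- function(predictions, trial_type = "four_combined") {
  trial_type <- rep_len(trial_type, length(predictions))
  out <- integer(length(predictions))
  comb <- trial_type == "four_combined"
  out[comb] <- pmin(8L, as.integer(floor(predictions[comb])))
  out[!comb] <- as.integer(round(predictions[!comb]))
  out
}

#' Per-participant error and variability summary
#'
#' For every participant x condition: bins trials by faithful prediction,
#' averages the signed error within each bin, and summarises
#'
#' * `mean_error`: by default the unweighted mean of the per-bin mean
#'   errors (`error_average = "bins"`; each predicted-rating bin counts
#'   equally); `error_average = "trials"` averages over trials instead.
#' * `rating_sd`: the standard deviation of responses computed within each
#'   expected-rating bin (bins with at least two trials) and then averaged
#'   across bins, i.e. variability around the predicted level rather than
#'   spread of the predictions themselves.
#'
#' @param ds A `plt_dataset`.
#' @param error_average `"bins"` or `"trials"`.
#' @param conditions Conditions to summarise.
#' @return An object of class `plt_error_summary`: `summary` (data frame
#'   `participant_id`, `condition`, `n_trials`, `mean_error`,
#'   `rating_sd`) and `bins` (per-bin detail: `participant_id`,
#'   `condition`, `bin`, `n`, `mean_error`, `sd_response`).
#' @export
summarize_errors <- function(ds, error_average = c("bins", "trials"),
                             conditions = c("precue_1of4", "postcue_1of4",
                                            "precue_comb",
                                            "postcue_comb")) {
  error_average <- match.arg(error_average)
  cond <- .condition_of(ds$trials)
  keep <- cond %in% conditions
  tr <- ds$trials[keep, , drop = FALSE]
  if (nrow(tr) == 0) stop("no trials in the requested conditions",
                          call. = FALSE)
  cond <- cond[keep]
  pred <- .faithful_prediction(tr, ds$baselines)
  err <- tr$response - pred
  bin <- bin_predictions(pred, tr$trial_type)

  key <- data.frame(participant_id = tr$participant_id, condition = cond,
                    bin = bin, err = err, resp = tr$response,
                    stringsAsFactors = FALSE)
  f <- err ~ participant_id + condition + bin
  bins <- stats::aggregate(f, data = key, FUN = length)
  names(bins)[names(bins) == "err"] <- "n"
  me <- stats::aggregate(f, data = key, FUN = mean)
  sdv <- stats::aggregate(resp ~ participant_id + condition + bin,
                          data = key,
                          FUN = function(v)
                            if (length(v) >= 2) stats::sd(v) else NA_real_)
  bins <- merge(merge(bins, me, by = c("participant_id", "condition",
                                       "bin")),
                sdv, by = c("participant_id", "condition", "bin"))
  names(bins)[names(bins) == "err"] <- "mean_error"
  names(bins)[names(bins) == "resp"] <- "sd_response"
  bins <- bins[order(bins$participant_id, bins$condition, bins$bin), ]
  rownames(bins) <- NULL

  cells <- unique(bins[c("participant_id", "condition")])
  summ <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    b <- bins[bins$participant_id == cells$participant_id[i] &
                bins$condition == cells$condition[i], ]
    sel <- key$participant_id == cells$participant_id[i] &
      key$condition == cells$condition[i]
    data.frame(
      participant_id = cells$participant_id[i],
      condition = cells$condition[i],
      n_trials = sum(sel),
      mean_error = if (error_average == "bins") mean(b$mean_error)
                   else mean(err[sel]),
      rating_sd = mean(b$sd_response, na.rm = TRUE),
      stringsAsFactors = FALSE)
  }))
  rownames(summ) <- NULL
  structure(list(summary = summ, bins = bins,
                 error_average = error_average),
            class = "plt_error_summary")
}

#' @export
print.plt_error_summary <- function(x, ...) {
  cat(sprintf("<error summary (%s-averaged), %d participant x condition cells>\n",
              x$error_average, nrow(x$summary)))
  print(utils::head(x$summary, 8))
  invisible(x)
}

#' Cross-condition correlations and paired comparisons
#'
#' Computes, over participants, Pearson correlations (with p-values)
#' between condition pairs for both the mean faithful-prediction error and
#' the rating SD, and paired two-sided t-tests of the condition mean
#' differences. Condition pairs: precue vs postcue within each trial type,
#' and 1-of-4 vs 4-combined within each cue timing.
#'
#' @param es A `plt_error_summary` (or its `summary` data frame).
#' @return List of two data frames: `correlations` (`measure`, `cond_a`,
#'   `cond_b`, `r`, `p`, `n`) and `paired_tests` (`measure`, `cond_a`,
#'   `cond_b`, `mean_diff` = mean of a - b, `t`, `df`, `p`).
#' @export
correlate_and_test <- function(es) {
  df <- if (inherits(es, "plt_error_summary")) es$summary else es
  pairs <- list(c("precue_1of4", "postcue_1of4"),
                c("precue_comb", "postcue_comb"),
                c("precue_1of4", "precue_comb"),
                c("postcue_1of4", "postcue_comb"))
  measures <- c(mean_error = "mean_error", rating_sd = "rating_sd")
  cors <- list()
  tts <- list()
  for (m in names(measures)) {
    wide <- stats::reshape(df[c("participant_id", "condition", measures[[m]])],
                           idvar = "participant_id",
                           timevar = "condition", direction = "wide")
    names(wide) <- sub(paste0(measures[[m]], "."), "", names(wide),
                       fixed = TRUE)
    for (pr in pairs) {
      if (!all(pr %in% names(wide))) next
      a <- wide[[pr[1]]]
      b <- wide[[pr[2]]]
      ok <- stats::complete.cases(a, b)
      a <- a[ok]; b <- b[ok]
      if (length(a) < 3) {
        stop("need at least 3 participants for correlations", call. = FALSE)
      }
      if (stats::sd(a) == 0 || stats::sd(b) == 0) {
        stop("degenerate zero-variance input for ", m, " (",
             paste(pr, collapse = " vs "), ")", call. = FALSE)
      }
      ct <- stats::cor.test(a, b)
      # constant paired differences have no t statistic; report NA
      tt <- tryCatch(stats::t.test(a, b, paired = TRUE),
                     error = function(e)
                       list(estimate = mean(a - b), statistic = NA_real_,
                            parameter = length(a) - 1, p.value = NA_real_))
      cors[[length(cors) + 1]] <-
        data.frame(measure = m, cond_a = pr[1], cond_b = pr[2],
                   r = unname(ct$estimate), p = ct$p.value, n = length(a),
                   stringsAsFactors = FALSE)
      tts[[length(tts) + 1]] <-
        data.frame(measure = m, cond_a = pr[1], cond_b = pr[2],
                   mean_diff = unname(tt$estimate), t = unname(tt$statistic),
                   df = unname(tt$parameter), p = tt$p.value,
                   stringsAsFactors = FALSE)
    }
  }
  list(correlations = do.call(rbind, cors),
       paired_tests = do.call(rbind, tts))
}

#' Cluster fitted linear-transform parameters
#'
#' Seeded k-means (50 restarts) on per-participant (a, b) points for
#' k = 1..`k_max`, reporting the mean within-cluster sum of squared
#' distances per k. The number of clusters is selected by an elbow rule:
#' k grows while the next k still halves the mean within-cluster sum of
#' squares (a 50%-drop heuristic).
#'
#' @param points Matrix or data frame of parameter points, one row per
#'   participant (typically columns `a`, `b`).
#' @param k_max Largest k considered.
#' @param nstart Random restarts per k.
#' @param seed Integer seed for the restarts.
#' @return An object of class `plt_clusters`: `k` (selected), `assignments`,
#'   `centroids` (for the selected k), `mean_wss` (named vector over
#'   k = 1..k_max).
#' @export
cluster_params <- function(points, k_max = 4, nstart = 50, seed = 1) {
  pts <- as.matrix(points)
  if (nrow(pts) < k_max + 1) {
    stop("need at least k_max + 1 points", call. = FALSE)
  }
  if (nrow(unique(pts)) < k_max) {
    stop("fewer distinct points than k_max", call. = FALSE)
  }
  fits <- withr::with_seed(as.integer(seed), lapply(seq_len(k_max),
    function(k) stats::kmeans(pts, centers = k, nstart = nstart,
                              iter.max = 100)))
  mean_wss <- vapply(fits, function(f) f$tot.withinss / nrow(pts), 0)
  names(mean_wss) <- paste0("k", seq_len(k_max))
  k <- 1L
  while (k < k_max && mean_wss[k + 1] <= 0.5 * mean_wss[k]) {
    k <- k + 1L
  }
  structure(list(k = k, assignments = fits[[k]]$cluster,
                 centroids = fits[[k]]$centers, mean_wss = mean_wss,
                 sizes = fits[[k]]$size),
            class = "plt_clusters")
}

#' @export
print.plt_clusters <- function(x, ...) {
  cat(sprintf("<k-means: %d cluster%s selected (sizes %s)>\n", x$k,
              if (x$k == 1) "" else "s", paste(x$sizes, collapse = "/")))
  print(round(x$centroids, 3))
  invisible(x)
}
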