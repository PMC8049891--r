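#' Pipeline run configuration
#'
#' Collects everything one reproducible simulate-fit-analyse run needs.
#' Exactly one data source applies: a synthetic design (the default) or a
#' directory of previously written / imported data (`data_dir`).
#'
#' @param seed Integer master seed (mandatory for synthetic runs).
#' @param design A [design_spec()]; ignored when `data_dir` is given.
#' @param data_dir Optional directory readable by [read_dataset()].
#' @param families Model families to fit.
#' @param conditions Conditions to fit.
#' @param error_average,pool Analysis flags, see [summarize_errors()] and
#'   [loocv()].
#' @param response_basis See [simulate_responses()].
#' @param k_max Maximum clusters for the parameter clustering.
#' @return A named list of class `plt_run_config`.
#' @export
run_config <- function(seed = 1, design = NULL, data_dir = NULL,
                       families = c(single_families(), combined_families()),
                       conditions = c("precue_1of4", "postcue_1of4",
                                      "precue_comb", "postcue_comb"),
                       error_average = "bins", pool = "per_fold",
                       response_basis = "baseline", k_max = 4) {
  if (!is.null(design) && !is.null(data_dir)) {
    stop("exactly one data source: give either 'design' or 'data_dir'",
         call. = FALSE)
  }
  if (is.null(design) && is.null(data_dir)) {
    design <- design_spec(seed = seed)
  }
  structure(list(seed = as.integer(seed), design = design,
                 data_dir = data_dir, families = families,
                 conditions = conditions, error_average = error_average,
                 pool = pool, response_basis = response_basis,
                 k_max = k_max),
            class = "plt_run_config")
}

#' Load a run configuration from YAML or JSON
#'
#' Recognised keys mirror the [run_config()] arguments; `design` may be a
#' mapping with `n_participants`, `n_images`, `n_blocks`,
#' `alternation_start`.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A `plt_run_config`.
#' @export
read_run_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("the 'yaml' package is required for YAML configs", call. = FALSE)
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  seed <- raw$seed %||% 1
  design <- NULL
  if (!is.null(raw$design)) {
    d <- raw$design
    design <- design_spec(
      n_participants = d$n_participants %||% 25,
      n_images = d$n_images %||% 36,
      n_blocks = d$n_blocks %||% 8,
      alternation_start = d$alternation_start %||% "random",
      seed = seed)
  }
  run_config(
    seed = seed, design = design, data_dir = raw$data_dir,
    families = raw$families %||% c(single_families(), combined_families()),
    conditions = raw$conditions %||% c("precue_1of4", "postcue_1of4",
                                       "precue_comb", "postcue_comb"),
    error_average = raw$error_average %||% "bins",
    pool = raw$pool %||% "per_fold",
    response_basis = raw$response_basis %||% "baseline",
    k_max = raw$k_max %||% 4)
}

.stage_log <- function(quiet, stage, expr) {
  t0 <- Sys.time()
  res <- force(expr)
  if (!quiet) {
    message(sprintf("[%s] done in %.1fs", stage,
                    as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  }
  res
}

#' Run the full pipeline
#'
#' simulate (or load) -> leave-one-out cross-validated fitting of every
#' requested model -> model comparison -> faithful-error and variability
#' summaries -> correlations and paired tests -> clustering of the fitted
#' `linear_combined` (a, b) parameters per cue timing. All outputs are
#' written as diff-able delimited/JSON files under `out_dir` together with
#' a run manifest, and the bundle is returned invisibly. Identical
#' configurations produce identical bundles.
#'
#' @param config A `plt_run_config` (or path readable by
#'   [read_run_config()]).
#' @param out_dir Output directory.
#' @param quiet Suppress stage logging.
#' @return The results bundle (named list), invisibly.
#' @export
run_pipeline <- function(config, out_dir, quiet = FALSE) {
  if (is.character(config)) config <- read_run_config(config)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)

  ds <- .stage_log(quiet, "data", {
    if (!is.null(config$data_dir)) {
      read_dataset(config$data_dir)
    } else {
      simulate_dataset(config$design,
                       response_basis = config$response_basis)
    }
  })
  if (ds$provenance == "synthetic") {
    write_dataset(ds, file.path(out_dir, "dataset"))
  }

  cvs <- .stage_log(quiet, "fit",
                    loocv_dataset(ds, families = config$families,
                                  conditions = config$conditions,
                                  pool = config$pool))
  fit_table <- .rbind_fill(lapply(cvs, function(x) {
    row <- data.frame(participant_id = x$participant_id,
                      condition = x$condition, family = x$family,
                      mean_heldout_rmse = x$mean_heldout_rmse,
                      stringsAsFactors = FALSE)
    for (p in names(x$mean_params)) row[[p]] <- x$mean_params[[p]]
    row
  }))
  utils::write.csv(fit_table, file.path(out_dir, "fits.csv"),
                   row.names = FALSE)

  comparison <- .stage_log(quiet, "compare", compare_models(cvs))
  utils::write.csv(comparison, file.path(out_dir, "comparison.csv"),
                   row.names = FALSE)

  es <- .stage_log(quiet, "errors",
                   summarize_errors(ds, error_average = config$error_average,
                                    conditions = config$conditions))
  utils::write.csv(es$summary, file.path(out_dir, "error_summary.csv"),
                   row.names = FALSE)
  utils::write.csv(es$bins, file.path(out_dir, "error_bins.csv"),
                   row.names = FALSE)

  stats_tabs <- tryCatch(correlate_and_test(es), error = function(e) NULL)
  if (!is.null(stats_tabs)) {
    utils::write.csv(stats_tabs$correlations,
                     file.path(out_dir, "correlations.csv"),
                     row.names = FALSE)
    utils::write.csv(stats_tabs$paired_tests,
                     file.path(out_dir, "paired_tests.csv"),
                     row.names = FALSE)
  }

  clusters <- .stage_log(quiet, "cluster", {
    cl <- list()
    for (cn in intersect(c("precue_comb", "postcue_comb"),
                         config$conditions)) {
      lin <- fit_table[fit_table$condition == cn &
                         fit_table$family == "linear_combined", ,
                       drop = FALSE]
      if (nrow(lin) >= config$k_max + 1 && all(c("a", "b") %in% names(lin))) {
        pts <- as.matrix(lin[c("a", "b")])
        rownames(pts) <- lin$participant_id
        cl[[cn]] <- tryCatch(cluster_params(pts, k_max = config$k_max,
                                            seed = config$seed),
                             error = function(e) NULL)
      }
    }
    cl
  })
  if (length(clusters) > 0) {
    jsonlite::write_json(
      lapply(clusters, function(cl) list(
        k = cl$k, mean_wss = as.list(cl$mean_wss),
        centroids = apply(cl$centroids, 1, as.list),
        assignments = as.list(cl$assignments))),
      file.path(out_dir, "clusters.json"), auto_unbox = TRUE, digits = NA)
  }

  manifest <- list(
    seed = config$seed,
    provenance = ds$provenance,
    n_participants = length(unique(ds$trials$participant_id)),
    n_trials = nrow(ds$trials),
    families = config$families, conditions = config$conditions,
    error_average = config$error_average, pool = config$pool,
    response_basis = config$response_basis,
    r_version = as.character(getRversion()),
    package_version = as.character(utils::packageVersion("pleasuretrack")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  bundle <- list(dataset = ds, fits = fit_table, comparison = comparison,
                 errors = es, stats = stats_tabs, clusters = clusters,
                 manifest = manifest, out_dir = out_dir)
  invisible(bundle)
}

# rbind data frames with unequal columns, filling NA
.rbind_fill <- function(dfs) {
  cols <- unique(unlist(lapply(dfs, names)))
  do.call(rbind, lapply(dfs, function(d) {
    for (c in setdiff(cols, names(d))) d[[c]] <- NA
    d[cols]
  }))
}

#' Render a human-readable report from a results bundle
#'
#' Writes `report.md` (tables of mean errors, RMSE +/- SEM, winner counts
#' and cluster centroids) and, optionally, PNG figures of the error and
#' comparison summaries into the bundle directory. Sections whose inputs
#' are absent from the bundle are marked absent rather than failing.
#'
#' @param bundle A bundle returned by [run_pipeline()], or the path of a
#'   bundle directory.
#' @param plots Also write PNG figures.
#' @return Path of the written report, invisibly.
#' @export
make_report <- function(bundle, plots = FALSE) {
  if (is.character(bundle)) {
    dir <- bundle
    read_tab <- function(f) {
      p <- file.path(dir, f)
      if (file.exists(p)) utils::read.csv(p, stringsAsFactors = FALSE)
      else NULL
    }
    bundle <- list(
      fits = read_tab("fits.csv"), comparison = read_tab("comparison.csv"),
      errors = list(summary = read_tab("error_summary.csv")),
      stats = list(correlations = read_tab("correlations.csv"),
                   paired_tests = read_tab("paired_tests.csv")),
      clusters = if (file.exists(file.path(dir, "clusters.json"))) {
        jsonlite::read_json(file.path(dir, "clusters.json"),
                            simplifyVector = FALSE)
      } else NULL,
      out_dir = dir)
  }
  if (is.null(bundle$comparison)) {
    stop("incomplete bundle: comparison table is missing", call. = FALSE)
  }
  path <- file.path(bundle$out_dir, "report.md")
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)

  w("# Pleasure-rating pipeline report")
  w("")
  w("## Faithful-prediction errors")
  if (!is.null(bundle$errors$summary)) {
    agg <- stats::aggregate(mean_error ~ condition,
                            data = bundle$errors$summary, FUN = mean)
    w("")
    w("| condition | mean error (rating points) |")
    w("|---|---|")
    for (i in seq_len(nrow(agg))) {
      w("| %s | %.3f |", agg$condition[i], agg$mean_error[i])
    }
  } else {
    w("(absent)")
  }
  w("")
  w("## Model comparison (mean held-out RMSE +/- SEM, winner counts)")
  w("")
  w("| condition | model | RMSE | SEM | winners |")
  w("|---|---|---|---|---|")
  cmp <- bundle$comparison
  for (i in order(cmp$condition, cmp$mean_rmse)) {
    w("| %s | %s | %.3f | %.3f | %d |", cmp$condition[i], cmp$family[i],
      cmp$mean_rmse[i], cmp$sem[i], cmp$winner_count[i])
  }
  best <- do.call(rbind, lapply(split(cmp, cmp$condition), function(s) {
    s[which.min(s$mean_rmse), ]
  }))
  w("")
  for (i in seq_len(nrow(best))) {
    w("Best model for %s: **%s** (mean RMSE %.3f).", best$condition[i],
      best$family[i], best$mean_rmse[i])
  }
  w("")
  w("## Rating variability")
  if (!is.null(bundle$errors$summary) &&
      "rating_sd" %in% names(bundle$errors$summary)) {
    agg <- stats::aggregate(rating_sd ~ condition,
                            data = bundle$errors$summary, FUN = mean,
                            na.rm = TRUE)
    for (i in seq_len(nrow(agg))) {
      w("- %s: mean rating SD %.3f", agg$condition[i], agg$rating_sd[i])
    }
  } else {
    w("(absent)")
  }
  w("")
  w("## Linear-transform parameter clusters")
  if (!is.null(bundle$clusters) && length(bundle$clusters) > 0) {
    for (cn in names(bundle$clusters)) {
      cl <- bundle$clusters[[cn]]
      k <- if (!is.null(cl$k)) cl$k else NA
      w("- %s: %s clusters selected", cn, k)
      cent <- cl$centroids
      if (inherits(cl, "plt_clusters")) {
        for (j in seq_len(nrow(cent))) {
          w("    - cluster %d (n = %d): a = %.2f, b = %.2f", j,
            cl$sizes[j], cent[j, "a"], cent[j, "b"])
        }
      }
    }
  } else {
    w("(cluster analysis absent)")
  }

  if (plots && !is.null(bundle$errors$summary)) {
    grDevices::png(file.path(bundle$out_dir, "comparison.png"),
                   width = 900, height = 500)
    op <- graphics::par(mar = c(10, 4, 2, 1))
    lab <- paste(cmp$condition, cmp$family)
    graphics::barplot(cmp$mean_rmse, names.arg = lab, las = 2,
                      ylab = "mean held-out RMSE (rating points)")
    graphics::par(op)
    grDevices::dev.off()
  }
  invisible(path)
}
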