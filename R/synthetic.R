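#' Experimental design specification
#'
#' Describes the trial structure of the rating experiment: per participant,
#' `n_blocks` main blocks alternating precue/postcue, each containing one
#' 1-of-4 trial per image (every image once as target, at a uniformly
#' random screen position, with distractors drawn without replacement from
#' the remaining images) and `n_images / 4` 4-combined trials (a random
#' partition of the image set into quadruples, positions randomised),
#' interleaved in random order; plus a final baseline block in which every
#' image is rated once, alone, at a random position.
#'
#' @param n_participants Number of observers.
#' @param n_images Number of images; must be divisible by 4.
#' @param n_blocks Number of main blocks.
#' @param alternation_start `"random"`, `"precue"` or `"postcue"`: cue
#'   timing of each participant's first block.
#' @param seed Integer seed controlling all design randomness.
#' @return An object of class `plt_design_spec`.
#' @export
design_spec <- function(n_participants = 25, n_images = 36, n_blocks = 8,
                        alternation_start = "random", seed = 1) {
  if (n_images %% 4 != 0) {
    stop("n_images must be divisible by 4 (combined trials partition the image set)",
         call. = FALSE)
  }
  alternation_start <- match.arg(alternation_start,
                                 c("random", "precue", "postcue"))
  structure(
    list(n_participants = n_participants, n_images = n_images,
         n_blocks = n_blocks, trials_per_block = n_images + n_images / 4,
         alternation_start = alternation_start, seed = as.integer(seed)),
    class = "plt_design_spec"
  )
}

.participant_ids <- function(n) sprintf("P%02d", seq_len(n))
.image_ids <- function(n) sprintf("img%02d", seq_len(n))

#' Build the trial design (responses unset)
#'
#' @param spec A [design_spec()].
#' @return A trials data frame with `response = NA`, one row per trial:
#'   `n_blocks * (n_images + n_images/4) + n_images` rows per participant.
#' @export
build_design <- function(spec) {
  withr::with_seed(spec$seed, .build_design_impl(spec))
}

.build_design_impl <- function(spec) {
  images <- .image_ids(spec$n_images)
  pids <- .participant_ids(spec$n_participants)
  n_comb <- spec$n_images / 4
  out <- vector("list", spec$n_participants)
  for (pi in seq_along(pids)) {
    start <- switch(spec$alternation_start,
                    random = sample(c("precue", "postcue"), 1),
                    spec$alternation_start)
    cues <- rep(c(start, setdiff(c("precue", "postcue"), start)),
                length.out = spec$n_blocks)
    blocks <- vector("list", spec$n_blocks + 1)
    for (b in seq_len(spec$n_blocks)) {
      # 1-of-4: each image once as target
      targets <- sample(images)
      tpos <- sample(1:4, spec$n_images, replace = TRUE)
      pos_mat <- matrix(NA_character_, spec$n_images, 4)
      for (i in seq_len(spec$n_images)) {
        distr <- sample(setdiff(images, targets[i]), 3)
        pos_mat[i, tpos[i]] <- targets[i]
        pos_mat[i, -tpos[i]] <- distr
      }
      single <- data.frame(trial_type = "one_of_four", pos1_image = pos_mat[, 1],
                           pos2_image = pos_mat[, 2], pos3_image = pos_mat[, 3],
                           pos4_image = pos_mat[, 4], target_position = tpos,
                           stringsAsFactors = FALSE)
      # 4-combined: random partition into quadruples, positions randomised
      part <- matrix(sample(images), ncol = 4)
      comb <- as.data.frame(t(apply(part, 1, sample)),
                            stringsAsFactors = FALSE)
      names(comb) <- paste0("pos", 1:4, "_image")
      comb <- cbind(data.frame(trial_type = "four_combined",
                               stringsAsFactors = FALSE),
                    comb, data.frame(target_position = NA_integer_))
      blk <- rbind(single, comb)
      blk <- blk[sample(nrow(blk)), , drop = FALSE]
      blk$block_index <- b
      blk$cue_timing <- cues[b]
      blk$trial_index <- seq_len(nrow(blk))
      blocks[[b]] <- blk
    }
    # final baseline block, stored as block 0
    bpos <- sample(1:4, spec$n_images, replace = TRUE)
    bmat <- matrix(NA_character_, spec$n_images, 4)
    bimg <- sample(images)
    bmat[cbind(seq_len(spec$n_images), bpos)] <- bimg
    base <- data.frame(trial_type = "baseline", pos1_image = bmat[, 1],
                       pos2_image = bmat[, 2], pos3_image = bmat[, 3],
                       pos4_image = bmat[, 4],
                       target_position = NA_integer_,
                       block_index = 0L, cue_timing = "none",
                       trial_index = seq_len(spec$n_images),
                       stringsAsFactors = FALSE)
    blocks[[spec$n_blocks + 1]] <- base
    tr <- do.call(rbind, blocks)
    tr$participant_id <- pids[pi]
    out[[pi]] <- tr
  }
  tr <- do.call(rbind, out)
  tr$response <- NA_integer_
  rownames(tr) <- NULL
  tr[.trial_columns]
}

#' Synthetic observer configuration
#'
#' The generative truth for one simulated participant. Responses in each
#' condition are a deterministic model prediction plus zero-mean Gaussian
#' late noise, rounded half-up to the nearest key and clipped to 1-9; with
#' probability `guess_rate` the key press is replaced by a uniform random
#' key (a constant guess rate across all trial types).
#'
#' @param participant_id Identifier.
#' @param true_pleasure Named numeric vector of latent image pleasures on
#'   the 1-9 scale (names = image ids).
#' @param sigma_late Named noise SDs, in rating points, for conditions
#'   `baseline`, `precue_1of4`, `postcue_1of4`, `precue_comb`,
#'   `postcue_comb`. Defaults 1.5 with 1.65 for postcued 1-of-4, mirroring
#'   the observed rating SD range 1.4-1.6 and the 0.15 postcue-precue mean
#'   difference.
#' @param guess_rate Probability of a uniform random key press.
#' @param single_precue,single_postcue Generative rules for 1-of-4 trials:
#'   `list(family = , params = )` with a family from [single_families()].
#' @param combined Generative rule for 4-combined trials (a family from
#'   [combined_families()]).
#' @param seed Integer seed for this observer's randomness.
#' @return An object of class `plt_observer_config`.
#' @export
observer_config <- function(participant_id, true_pleasure,
                            sigma_late = c(baseline = 1.5,
                                           precue_1of4 = 1.5,
                                           postcue_1of4 = 1.65,
                                           precue_comb = 1.5,
                                           postcue_comb = 1.5),
                            guess_rate = 0.05,
                            single_precue = list(family = "faithful",
                                                 params = numeric(0)),
                            single_postcue = single_precue,
                            combined = list(family = "faithful_averaging",
                                            params = numeric(0)),
                            seed = 1) {
  stopifnot(all(true_pleasure >= 1 & true_pleasure <= 9),
            all(sigma_late >= 0),
            guess_rate >= 0, guess_rate <= 1)
  need <- c("baseline", "precue_1of4", "postcue_1of4", "precue_comb",
            "postcue_comb")
  if (!all(need %in% names(sigma_late))) {
    stop("sigma_late must name all of: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  for (m in list(single_precue, single_postcue)) {
    sp <- model_spec(m$family)
    if (sp$type != "single") {
      stop("'", m$family, "' is not a 1-of-4 family", call. = FALSE)
    }
    .check_params(sp, m$params)
  }
  spc <- model_spec(combined$family)
  if (spc$type != "combined") {
    stop("'", combined$family, "' is not a 4-combined family", call. = FALSE)
  }
  .check_params(spc, combined$params)
  structure(
    list(participant_id = participant_id, true_pleasure = true_pleasure,
         sigma_late = sigma_late[need], guess_rate = guess_rate,
         single_precue = single_precue, single_postcue = single_postcue,
         combined = combined, seed = as.integer(seed)),
    class = "plt_observer_config"
  )
}

# key-press response stage shared by every condition
.respond <- function(value, sigma, guess_rate, n = length(value)) {
  r <- value + stats::rnorm(n, 0, sigma)
  r <- pmin(9, pmax(1, floor(r + 0.5)))  # round half-up, clip to keys
  guess <- stats::runif(n) < guess_rate
  r[guess] <- sample(1:9, sum(guess), replace = TRUE)
  as.integer(r)
}

#' Simulate an observer's baseline ratings
#'
#' Baseline rating = true pleasure + late noise
#' (`sigma_late["baseline"]`), rounded half-up and clipped to 1-9, with a
#' `guess_rate` chance of a uniform random key.
#'
#' @param config A [observer_config()].
#' @return Data frame `participant_id`, `image_id`, `baseline_pleasure`.
#' @export
simulate_baseline <- function(config) {
  withr::with_seed(config$seed, .simulate_baseline_impl(config))
}

.simulate_baseline_impl <- function(config) {
  data.frame(
    participant_id = config$participant_id,
    image_id = names(config$true_pleasure),
    baseline_pleasure = .respond(unname(config$true_pleasure),
                                 config$sigma_late[["baseline"]],
                                 config$guess_rate),
    stringsAsFactors = FALSE
  )
}

#' Simulate responses for a built design
#'
#' Fills in the `response` column of a design for each configured observer
#' and assembles the baseline table from the simulated baseline block. By
#' default (`response_basis = "baseline"`) the deterministic model stage is
#' evaluated on the observer's own baseline ratings, so that a simulated
#' observer "follows model M" in exactly the sense in which the models are
#' later fitted (their `P_i` are baseline ratings). With
#' `response_basis = "latent"` the model stage is instead evaluated on the
#' latent true pleasures, which decouples generation from the measured
#' baselines and is useful for studying attenuation-versus-noise
#' confounds (at the cost of regression dilution when fitting).
#'
#' @param design Trials data frame from [build_design()] (responses unset).
#' @param configs A single [observer_config()] or a list of them, one per
#'   participant id appearing in `design`.
#' @param response_basis `"baseline"` (default) or `"latent"`.
#' @return A `plt_dataset` with provenance `"synthetic"`.
#' @export
simulate_responses <- function(design, configs,
                               response_basis = c("baseline", "latent")) {
  response_basis <- match.arg(response_basis)
  if (inherits(configs, "plt_observer_config")) configs <- list(configs)
  names(configs) <- vapply(configs, `[[`, "", "participant_id")
  pids <- unique(design$participant_id)
  miss <- setdiff(pids, names(configs))
  if (length(miss) > 0) {
    stop("no observer config for participant(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  parts <- vector("list", length(pids))
  bls <- vector("list", length(pids))
  for (i in seq_along(pids)) {
    cfg <- configs[[pids[i]]]
    tr <- design[design$participant_id == pids[i], , drop = FALSE]
    sim <- withr::with_seed(cfg$seed,
                            .simulate_participant(tr, cfg, response_basis))
    parts[[i]] <- sim$trials
    bls[[i]] <- sim$baselines
  }
  trials <- do.call(rbind, parts)
  rownames(trials) <- NULL
  plt_dataset(trials, do.call(rbind, bls), provenance = "synthetic",
              metadata = list(response_basis = response_basis))
}

.simulate_participant <- function(tr, cfg, response_basis) {
  bl <- .simulate_baseline_impl(cfg)
  basis <- if (response_basis == "baseline") {
    stats::setNames(as.numeric(bl$baseline_pleasure), bl$image_id)
  } else {
    cfg$true_pleasure
  }
  # baseline block responses ARE the baseline ratings
  is_base <- tr$trial_type == "baseline"
  if (any(is_base)) {
    pos_cols <- paste0("pos", 1:4, "_image")
    img <- apply(tr[is_base, pos_cols], 1, function(r) r[!is.na(r)][1])
    tr$response[is_base] <-
      bl$baseline_pleasure[match(img, bl$image_id)]
  }
  cond <- .condition_of(tr)
  for (cn in c("precue_1of4", "postcue_1of4", "precue_comb",
               "postcue_comb")) {
    sel <- which(cond == cn)
    if (length(sel) == 0) next
    sub <- tr[sel, , drop = FALSE]
    P <- matrix(basis[unlist(sub[paste0("pos", 1:4, "_image")])],
                ncol = 4)
    rule <- switch(cn,
                   precue_1of4 = cfg$single_precue,
                   postcue_1of4 = cfg$single_postcue,
                   cfg$combined)
    spec <- model_spec(rule$family)
    pred <- .predict_model(spec, rule$params, sub$target_position, P)
    tr$response[sel] <- .respond(pred, cfg$sigma_late[[cn]],
                                 cfg$guess_rate)
  }
  list(trials = tr, baselines = bl)
}

#' A default population of synthetic observers
#'
#' Builds `n` observer configurations emulating the fitted structure of
#' the study population: latent image pleasures spanning the 1-9 scale
#' uniformly with participant-specific jitter (SD 0.5); faithful precued
#' 1-of-4 reports; postcued 1-of-4 reports following high-pleasure
#' attenuation with threshold ~ N(4.6, 0.5) and gain ~ N(0.5, 0.1)
#' (clipped to bounds); combined reports following a linear transform of
#' the 4-image mean with a 22/25 majority cluster around
#' (a, b) = (-1.4, 1.2) and a minority cluster around (2.4, 0.4)
#' (within-cluster SDs 0.3 on a, 0.1 on b).
#'
#' @param n Number of observers.
#' @param n_images Number of images.
#' @param seed Integer seed; per-observer seeds are derived from it.
#' @param sigma_late,guess_rate Passed to every [observer_config()].
#' @param single_precue,single_postcue,combined Optional overrides: a
#'   function `(i)` returning a generative rule, or a fixed rule list
#'   applied to every observer. `NULL` keeps the population defaults.
#' @return List of `plt_observer_config`.
#' @export
default_observers <- function(n = 25, n_images = 36, seed = 1,
                              sigma_late = c(baseline = 1.5,
                                             precue_1of4 = 1.5,
                                             postcue_1of4 = 1.65,
                                             precue_comb = 1.5,
                                             postcue_comb = 1.5),
                              guess_rate = 0.05,
                              single_precue = NULL,
                              single_postcue = NULL,
                              combined = NULL) {
  withr::with_seed(as.integer(seed), {
    pids <- .participant_ids(n)
    base_pleasure <- seq(1, 9, length.out = n_images)
    n_minor <- max(0L, round(n * 3 / 25))
    minor <- if (n_minor > 0) sample(n, n_minor) else integer(0)
    lapply(seq_len(n), function(i) {
      tp <- pmin(9, pmax(1, base_pleasure + stats::rnorm(n_images, 0, 0.5)))
      names(tp) <- .image_ids(n_images)
      sp <- single_precue %||% list(family = "faithful", params = numeric(0))
      spost <- single_postcue %||% list(
        family = "high_pleasure_attenuation",
        params = c(P_beau = min(9, max(1, stats::rnorm(1, 4.6, 0.5))),
                   g = min(1, max(0, stats::rnorm(1, 0.5, 0.1)))))
      cmb <- combined %||% {
        if (i %in% minor) {
          list(family = "linear_combined",
               params = c(a = stats::rnorm(1, 2.4, 0.3),
                          b = min(2, max(0, stats::rnorm(1, 0.4, 0.1)))))
        } else {
          list(family = "linear_combined",
               params = c(a = stats::rnorm(1, -1.4, 0.3),
                          b = min(2, max(0, stats::rnorm(1, 1.2, 0.1)))))
        }
      }
      if (is.function(sp)) sp <- sp(i)
      if (is.function(spost)) spost <- spost(i)
      if (is.function(cmb)) cmb <- cmb(i)
      observer_config(pids[i], tp, sigma_late = sigma_late,
                      guess_rate = guess_rate, single_precue = sp,
                      single_postcue = spost, combined = cmb,
                      seed = as.integer(seed) + 1000L + i)
    })
  })
}

#' One-call synthetic dataset
#'
#' Convenience wrapper: builds the design for `spec` and simulates
#' responses for the given (or default) observer population.
#'
#' @param spec A [design_spec()].
#' @param configs Observer configs; defaults to [default_observers()]
#'   matched to the spec.
#' @param response_basis See [simulate_responses()].
#' @return A `plt_dataset`.
#' @export
simulate_dataset <- function(spec = design_spec(),
                             configs = NULL,
                             response_basis = "baseline") {
  if (is.null(configs)) {
    configs <- default_observers(spec$n_participants, spec$n_images,
                                 seed = spec$seed)
  }
  simulate_responses(build_design(spec), configs,
                     response_basis = response_basis)
}
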