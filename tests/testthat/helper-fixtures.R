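# Shared fixtures, built in code at test time.

# A tiny hand-made valid dataset: 1 participant, 4 images, one trial of
# each type.
tiny_dataset <- function() {
  trials <- data.frame(
    participant_id = "P01",
    block_index = c(1L, 1L, 0L),
    cue_timing = c("precue", "precue", "none"),
    trial_type = c("one_of_four", "four_combined", "baseline"),
    pos1_image = c("img01", "img04", "img02"),
    pos2_image = c("img02", "img03", NA),
    pos3_image = c("img03", "img02", NA),
    pos4_image = c("img04", "img01", NA),
    target_position = c(2L, NA, NA),
    response = c(4L, 5L, 3L),
    trial_index = c(1L, 2L, 1L),
    stringsAsFactors = FALSE
  )
  baselines <- data.frame(
    participant_id = "P01",
    image_id = paste0("img0", 1:4),
    baseline_pleasure = c(2L, 3L, 6L, 8L),
    stringsAsFactors = FALSE
  )
  plt_dataset(trials, baselines)
}

# A single-observer rule list.
rule <- function(family, ...) {
  p <- c(...)
  list(family = family, params = if (length(p)) p else numeric(0))
}

# Constant late-noise vector.
sigma_all <- function(sd) {
  c(baseline = sd, precue_1of4 = sd, postcue_1of4 = sd,
    precue_comb = sd, postcue_comb = sd)
}

# Simulated dataset for n observers who all follow the given rules.
sim_population <- function(n = 25, seed = 1, sd = 1.5, guess_rate = 0.05,
                           single = rule("faithful"),
                           single_postcue = single,
                           combined = rule("faithful_averaging"),
                           n_images = 36, n_blocks = 8,
                           response_basis = "baseline") {
  obs <- default_observers(n, n_images = n_images, seed = seed,
                           sigma_late = sigma_all(sd),
                           guess_rate = guess_rate,
                           single_precue = single,
                           single_postcue = single_postcue,
                           combined = combined)
  spec <- design_spec(n_participants = n, n_images = n_images,
                      n_blocks = n_blocks, seed = seed)
  simulate_responses(build_design(spec), obs,
                     response_basis = response_basis)
}

# Round half-up to the nearest key, clipped to 1..9 (the simulator's
# response rule, restated independently for expectations).
key_round <- function(x) pmin(9, pmax(1, floor(x + 0.5)))

# Random baseline matrix for property tests.
random_P <- function(n) matrix(stats::runif(4 * n, 1, 9), ncol = 4)

# Minimal stand-in CV result for compare_models() unit tests.
fake_cv <- function(pid, cond, fam, rmse) {
  structure(list(participant_id = pid, condition = cond, family = fam,
                 mean_heldout_rmse = rmse),
            class = "plt_cv")
}
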