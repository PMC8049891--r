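#' Rating model registry
#'
#' Deterministic prediction equations relating baseline pleasures of the
#' four displayed images to the reported rating. Eight families predict
#' 1-of-4 ratings (the observer rates the image cued by position) and three
#' families predict 4-combined ratings (the observer rates the combined
#' pleasure of all four images).
#'
#' Single-target families, writing `P_t` for the target's baseline pleasure
#' and `Pbar` for the mean of the four displayed baselines:
#'
#' * `faithful`: `P_t` (no parameters).
#' * `averaging`: `Pbar` (no parameters).
#' * `average_biased`: `(1 - w) P_t + w Pbar`, `0 <= w <= 1`.
#' * `weighted_avg_position`: `sum_i w_i P_i`, weights on the 2x2 screen
#'   positions constrained to the simplex; `w1..w3` free, `w4 = 1 - sum`.
#' * `weighted_avg_biased`: `(1 - w) P_t + w sum_i v_i P_i` with `v` on the
#'   simplex; reduces to `average_biased` when `v` is uniform.
#' * `linear_single`: `a + b P_t`.
#' * `weighted_avg_pleasure_rank`: `sum_k u_k P_(k)` where `P_(1) >= ... >=
#'   P_(4)` are the baselines sorted descending and `u` lies on the simplex.
#' * `high_pleasure_attenuation`: `P_t` below the threshold `P_beau`;
#'   above it the excess is compressed, `P_beau + g (P_t - P_beau)`,
#'   `0 <= g <= 1`.
#'
#' Combined families use `Pbar` in place of `P_t`: `faithful_averaging`
#' (`Pbar`), `linear_combined` (`a + b Pbar`) and `attenuation_combined`
#' (the piecewise attenuation rule applied to `Pbar`).
#'
#' Predictions are real-valued and deliberately not clipped to the 1-9 key
#' range: out-of-range predictions are penalised naturally by the RMSE cost
#' during fitting, and clipping belongs to the response stage of the
#' simulator.
#'
#' @param family Family name; one of [single_families()] or
#'   [combined_families()].
#' @return `model_spec()` returns an object of class `plt_model_spec` with
#'   elements `family`, `type` (`"single"` or `"combined"`), `param_names`,
#'   `lower`, `upper` and `n_params`.
#' @examples
#' spec <- model_spec("high_pleasure_attenuation")
#' predict_single(spec, c(P_beau = 4.6, g = 0.5), 1, c(7, 2, 3, 4))
#' @export
model_spec <- function(family) {
  info <- .model_registry[[family]]
  if (is.null(info)) {
    stop("unknown model family: '", family, "'", call. = FALSE)
  }
  structure(
    list(
      family = family,
      type = info$type,
      param_names = info$param_names,
      lower = info$lower,
      upper = info$upper,
      n_params = length(info$param_names)
    ),
    class = "plt_model_spec"
  )
}

# Simplex-weight families store the first three weights; the fourth is
# implied (1 - sum) and must be non-negative.
.model_registry <- list(
  faithful = list(type = "single", param_names = character(0),
                  lower = numeric(0), upper = numeric(0)),
  averaging = list(type = "single", param_names = character(0),
                   lower = numeric(0), upper = numeric(0)),
  average_biased = list(type = "single", param_names = "w",
                        lower = 0, upper = 1),
  weighted_avg_position = list(type = "single",
                               param_names = c("w1", "w2", "w3"),
                               lower = rep(0, 3), upper = rep(1, 3)),
  weighted_avg_biased = list(type = "single",
                             param_names = c("w", "v1", "v2", "v3"),
                             lower = rep(0, 4), upper = rep(1, 4)),
  linear_single = list(type = "single", param_names = c("a", "b"),
                       lower = c(-8, 0), upper = c(8, 2)),
  weighted_avg_pleasure_rank = list(type = "single",
                                    param_names = c("u1", "u2", "u3"),
                                    lower = rep(0, 3), upper = rep(1, 3)),
  high_pleasure_attenuation = list(type = "single",
                                   param_names = c("P_beau", "g"),
                                   lower = c(1, 0), upper = c(9, 1)),
  faithful_averaging = list(type = "combined", param_names = character(0),
                            lower = numeric(0), upper = numeric(0)),
  linear_combined = list(type = "combined", param_names = c("a", "b"),
                         lower = c(-8, 0), upper = c(8, 2)),
  attenuation_combined = list(type = "combined",
                              param_names = c("P_beau", "g"),
                              lower = c(1, 0), upper = c(9, 1))
)

#' @rdname model_spec
#' @export
single_families <- function() {
  names(Filter(function(x) x$type == "single", .model_registry))
}

#' @rdname model_spec
#' @export
combined_families <- function() {
  names(Filter(function(x) x$type == "combined", .model_registry))
}

#' @export
print.plt_model_spec <- function(x, ...) {
  cat(sprintf("<model '%s' (%s), %d parameter%s", x$family, x$type,
              x$n_params, if (x$n_params == 1) "" else "s"))
  if (x$n_params > 0) {
    cat(": ", paste(sprintf("%s in [%g, %g]", x$param_names, x$lower,
                            x$upper), collapse = ", "), sep = "")
  }
  cat(">\n")
  invisible(x)
}

.check_params <- function(spec, params, tol = 1e-9) {
  if (spec$n_params == 0) {
    return(numeric(0))
  }
  params <- unlist(params)
  if (length(params) != spec$n_params) {
    stop(sprintf("model '%s' expects %d parameter(s) (%s), got %d",
                 spec$family, spec$n_params,
                 paste(spec$param_names, collapse = ", "),
                 length(params)), call. = FALSE)
  }
  if (!is.null(names(params)) && all(spec$param_names %in% names(params))) {
    params <- params[spec$param_names]
  } else {
    names(params) <- spec$param_names
  }
  bad <- params < spec$lower - tol | params > spec$upper + tol
  if (any(bad)) {
    stop(sprintf("parameter '%s' = %g out of bounds [%g, %g] for model '%s'",
                 spec$param_names[bad][1], params[bad][1],
                 spec$lower[bad][1], spec$upper[bad][1], spec$family),
         call. = FALSE)
  }
  # implied fourth simplex weight must be non-negative
  simplex <- .simplex_block(spec$family)
  if (!is.null(simplex)) {
    s <- sum(params[simplex])
    if (s > 1 + tol) {
      stop(sprintf("simplex weights (%s) sum to %g > 1 for model '%s'",
                   paste(simplex, collapse = ", "), s, spec$family),
           call. = FALSE)
    }
  }
  params
}

# names of the parameters forming a 3-of-4 simplex block, or NULL
.simplex_block <- function(family) {
  switch(family,
         weighted_avg_position = c("w1", "w2", "w3"),
         weighted_avg_biased = c("v1", "v2", "v3"),
         weighted_avg_pleasure_rank = c("u1", "u2", "u3"),
         NULL)
}

.as_P_matrix <- function(P) {
  if (is.null(dim(P))) {
    if (length(P) != 4) stop("baselines must have 4 entries", call. = FALSE)
    P <- matrix(P, nrow = 1)
  }
  P <- as.matrix(P)
  if (ncol(P) != 4) stop("baseline matrix must have 4 columns", call. = FALSE)
  storage.mode(P) <- "double"
  P
}

.attenuate <- function(x, P_beau, g) {
  # branchless piecewise rule, continuous at the threshold
  pmin(x, P_beau) + g * pmax(x - P_beau, 0)
}

# row-wise descending sort of an n x 4 matrix via a 5-comparator network
.sort4_desc <- function(P) {
  s1 <- pmax(P[, 1], P[, 2]); t1 <- pmin(P[, 1], P[, 2])
  s2 <- pmax(P[, 3], P[, 4]); t2 <- pmin(P[, 3], P[, 4])
  m1 <- pmin(s1, s2); m2 <- pmax(t1, t2)
  cbind(pmax(s1, s2), pmax(m1, m2), pmin(m1, m2), pmin(t1, t2))
}

#' Predict a 1-of-4 rating
#'
#' Evaluates a single-target model on one or many trials. `P` is a vector
#' of four baseline pleasures (one trial) or an `n x 4` matrix, columns in
#' screen-position order: 1 upper-left, 2 upper-right, 3 lower-left,
#' 4 lower-right. Recycled `target_position` is allowed.
#'
#' @param spec A `plt_model_spec` of type `"single"` (a family name string
#'   is also accepted).
#' @param params Named or positional numeric parameters, within bounds.
#' @param target_position Integer(s) in 1..4.
#' @param P Baseline pleasures, length-4 vector or `n x 4` matrix.
#' @return Numeric vector of predicted ratings (not clipped to 1-9).
#' @export
predict_single <- function(spec, params, target_position, P) {
  if (is.character(spec)) spec <- model_spec(spec)
  if (spec$type != "single") {
    stop("model '", spec$family, "' is not a 1-of-4 family", call. = FALSE)
  }
  params <- .check_params(spec, params)
  P <- .as_P_matrix(P)
  t <- as.integer(target_position)
  if (any(t < 1L | t > 4L)) {
    stop("target_position must be in 1..4", call. = FALSE)
  }
  t <- rep_len(t, nrow(P))
  Pt <- P[cbind(seq_len(nrow(P)), t)]
  Pbar <- rowMeans(P)
  switch(spec$family,
    faithful = Pt,
    averaging = Pbar,
    average_biased = (1 - params["w"]) * Pt + params["w"] * Pbar,
    weighted_avg_position = {
      w <- c(params[c("w1", "w2", "w3")], 1 - sum(params[c("w1", "w2", "w3")]))
      drop(P %*% w)
    },
    weighted_avg_biased = {
      v <- c(params[c("v1", "v2", "v3")], 1 - sum(params[c("v1", "v2", "v3")]))
      (1 - params["w"]) * Pt + params["w"] * drop(P %*% v)
    },
    linear_single = params["a"] + params["b"] * Pt,
    weighted_avg_pleasure_rank = {
      u <- c(params[c("u1", "u2", "u3")], 1 - sum(params[c("u1", "u2", "u3")]))
      drop(.sort4_desc(P) %*% u)
    },
    high_pleasure_attenuation =
      .attenuate(Pt, params["P_beau"], params["g"])
  ) |> unname()
}

#' Predict a 4-combined rating
#'
#' Evaluates a combined-pleasure model; all families act on the arithmetic
#' mean `Pbar` of the four displayed baselines.
#'
#' @inheritParams predict_single
#' @param spec A `plt_model_spec` of type `"combined"`.
#' @return Numeric vector of predicted ratings (not clipped to 1-9).
#' @export
predict_combined <- function(spec, params, P) {
  if (is.character(spec)) spec <- model_spec(spec)
  if (spec$type != "combined") {
    stop("model '", spec$family, "' is not a 4-combined family",
         call. = FALSE)
  }
  params <- .check_params(spec, params)
  P <- .as_P_matrix(P)
  Pbar <- rowMeans(P)
  switch(spec$family,
    faithful_averaging = Pbar,
    linear_combined = params["a"] + params["b"] * Pbar,
    attenuation_combined = .attenuate(Pbar, params["P_beau"], params["g"])
  ) |> unname()
}

# Dispatch on trial type: `t` ignored for combined families.
.predict_model <- function(spec, params, t, P) {
  if (spec$type == "single") {
    predict_single(spec, params, t, P)
  } else {
    predict_combined(spec, params, P)
  }
}
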