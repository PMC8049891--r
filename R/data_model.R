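#' Trial-level dataset container
#'
#' A `plt_dataset` bundles the two canonical tables of a rating experiment:
#'
#' * `trials`: one row per rating trial with columns `participant_id`,
#'   `block_index` (0 = baseline block, stored first although acquired
#'   last; 1-8 = main blocks), `cue_timing` (`precue`/`postcue`/`none`),
#'   `trial_type` (`one_of_four`/`four_combined`/`baseline`),
#'   `pos1_image`..`pos4_image` (image identifiers by screen quadrant:
#'   1 upper-left, 2 upper-right, 3 lower-left, 4 lower-right; `NA` for
#'   empty positions), `target_position` (1-4, `NA` unless `one_of_four`),
#'   `response` (key press 1-9) and `trial_index` (running index within
#'   block, preserving acquisition order).
#' * `baselines`: `participant_id`, `image_id`, `baseline_pleasure` (1-9),
#'   one row per participant x image. These are the `P_i` values consumed
#'   by every rating model.
#'
#' @param trials Trials data frame (see Details).
#' @param baselines Baseline table data frame.
#' @param provenance `"synthetic"` or `"deposited"`.
#' @param metadata Free-form named list.
#' @param validate Run [validate_dataset()] on construction.
#' @return An object of class `plt_dataset`.
#' @export
plt_dataset <- function(trials, baselines, provenance = "synthetic",
                        metadata = list(), validate = TRUE) {
  provenance <- match.arg(provenance, c("synthetic", "deposited"))
  ds <- structure(
    list(trials = as.data.frame(trials),
         baselines = as.data.frame(baselines),
         provenance = provenance,
         metadata = metadata),
    class = "plt_dataset"
  )
  if (validate) validate_dataset(ds)
  ds
}

#' @export
print.plt_dataset <- function(x, ...) {
  cat(sprintf(
    "<pleasure rating dataset (%s): %d trials, %d participants, %d images>\n",
    x$provenance, nrow(x$trials), length(unique(x$trials$participant_id)),
    length(unique(x$baselines$image_id))))
  invisible(x)
}

.trial_columns <- c("participant_id", "block_index", "cue_timing",
                    "trial_type", "pos1_image", "pos2_image", "pos3_image",
                    "pos4_image", "target_position", "response",
                    "trial_index")
.baseline_columns <- c("participant_id", "image_id", "baseline_pleasure")

.fail_record <- function(table, i, msg) {
  stop(sprintf("invalid %s record (row %d): %s", table, i, msg),
       call. = FALSE)
}

#' Validate a dataset against the schema invariants
#'
#' Checks, and reports the first offending record of: responses in 1..9;
#' `one_of_four` trials carry a target position and four distinct images;
#' `four_combined` trials carry four distinct images and no target;
#' `baseline` trials show exactly one image with `cue_timing` `"none"`;
#' baseline pleasures in 1..9, unique per participant x image; and every
#' image referenced by a trial having a baseline entry for that participant.
#'
#' @param ds A `plt_dataset`.
#' @param allow_na_response Permit unset responses (a design not yet
#'   simulated).
#' @return `ds`, invisibly; errors otherwise.
#' @export
validate_dataset <- function(ds, allow_na_response = FALSE) {
  tr <- ds$trials
  bl <- ds$baselines
  missing_tr <- setdiff(.trial_columns, names(tr))
  if (length(missing_tr) > 0) {
    stop("trials table lacks column(s): ", paste(missing_tr, collapse = ", "),
         call. = FALSE)
  }
  missing_bl <- setdiff(.baseline_columns, names(bl))
  if (length(missing_bl) > 0) {
    stop("baseline table lacks column(s): ",
         paste(missing_bl, collapse = ", "), call. = FALSE)
  }

  pos_cols <- paste0("pos", 1:4, "_image")
  for (i in seq_len(nrow(tr))) {
    row <- tr[i, ]
    if (!row$trial_type %in% c("one_of_four", "four_combined", "baseline")) {
      .fail_record("trial", i, paste0("unknown trial_type '", row$trial_type, "'"))
    }
    if (!row$cue_timing %in% c("precue", "postcue", "none")) {
      .fail_record("trial", i, paste0("unknown cue_timing '", row$cue_timing, "'"))
    }
    resp <- row$response
    if (is.na(resp)) {
      if (!allow_na_response) .fail_record("trial", i, "response is missing")
    } else if (!(resp %in% 1:9)) {
      .fail_record("trial", i, sprintf("response %s not in 1..9", resp))
    }
    imgs <- unlist(row[pos_cols], use.names = FALSE)
    n_img <- sum(!is.na(imgs))
    if (row$trial_type == "baseline") {
      if (n_img != 1) {
        .fail_record("trial", i, "baseline trial must show exactly one image")
      }
      if (row$cue_timing != "none") {
        .fail_record("trial", i, "baseline trial must have cue_timing 'none'")
      }
      if (!is.na(row$target_position)) {
        .fail_record("trial", i, "baseline trial must not have a target_position")
      }
    } else {
      if (n_img != 4 || anyDuplicated(imgs) > 0) {
        .fail_record("trial", i, "must reference exactly 4 distinct images")
      }
      if (row$cue_timing == "none") {
        .fail_record("trial", i, "main-block trial needs precue or postcue")
      }
      if (row$trial_type == "one_of_four") {
        if (is.na(row$target_position) || !(row$target_position %in% 1:4)) {
          .fail_record("trial", i, "one_of_four trial needs target_position in 1..4")
        }
      } else if (!is.na(row$target_position)) {
        .fail_record("trial", i, "four_combined trial must not have a target_position")
      }
    }
  }

  bad_bl <- which(is.na(bl$baseline_pleasure) |
                    !(bl$baseline_pleasure %in% 1:9))
  if (length(bad_bl) > 0) {
    .fail_record("baseline", bad_bl[1], "baseline_pleasure not in 1..9")
  }
  dup <- which(duplicated(bl[c("participant_id", "image_id")]))
  if (length(dup) > 0) {
    .fail_record("baseline", dup[1], "duplicate participant x image entry")
  }

  have <- paste(bl$participant_id, bl$image_id)
  for (col in pos_cols) {
    ref <- !is.na(tr[[col]])
    need <- paste(tr$participant_id[ref], tr[[col]][ref])
    miss <- which(!(need %in% have))
    if (length(miss) > 0) {
      .fail_record("trial", which(ref)[miss[1]],
                   sprintf("image '%s' has no baseline entry for participant '%s'",
                           tr[[col]][ref][miss[1]],
                           tr$participant_id[ref][miss[1]]))
    }
  }
  invisible(ds)
}

#' Write / read a dataset as delimited text
#'
#' `write_dataset()` stores a validated dataset as `trials.csv`,
#' `baselines.csv` and `metadata.json` inside `path` (created if needed);
#' `read_dataset()` is its inverse and re-validates. The round trip is
#' lossless. Unknown extra columns in the files are preserved under
#' `metadata$extra_columns`.
#'
#' @param ds A valid `plt_dataset`.
#' @param path Directory for the two CSV files.
#' @return `write_dataset()` returns `path` invisibly; `read_dataset()`
#'   returns a `plt_dataset`.
#' @export
write_dataset <- function(ds, path) {
  validate_dataset(ds, allow_na_response = TRUE)
  if (!dir.exists(path)) {
    dir.create(path, recursive = TRUE)
  }
  utils::write.csv(ds$trials[.trial_columns],
                   file.path(path, "trials.csv"), row.names = FALSE)
  utils::write.csv(ds$baselines[.baseline_columns],
                   file.path(path, "baselines.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(provenance = ds$provenance, metadata = ds$metadata),
    file.path(path, "metadata.json"), auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  tr_file <- file.path(path, "trials.csv")
  bl_file <- file.path(path, "baselines.csv")
  if (!file.exists(tr_file) || !file.exists(bl_file)) {
    stop("expected trials.csv and baselines.csv under '", path, "'",
         call. = FALSE)
  }
  tr <- utils::read.csv(tr_file, stringsAsFactors = FALSE)
  bl <- utils::read.csv(bl_file, stringsAsFactors = FALSE)
  meta_file <- file.path(path, "metadata.json")
  provenance <- "synthetic"
  metadata <- list()
  if (file.exists(meta_file)) {
    meta <- jsonlite::read_json(meta_file, simplifyVector = TRUE)
    provenance <- meta$provenance %||% "synthetic"
    metadata <- as.list(meta$metadata %||% list())
  }
  extra <- c(setdiff(names(tr), .trial_columns),
             setdiff(names(bl), .baseline_columns))
  if (length(extra) > 0) {
    metadata$extra_columns <- extra
  }
  miss <- setdiff(.trial_columns, names(tr))
  if (length(miss) > 0) {
    stop("trials.csv lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  # character image ids survive numeric-looking values
  for (col in paste0("pos", 1:4, "_image")) {
    tr[[col]] <- as.character(tr[[col]])
  }
  bl$image_id <- as.character(bl$image_id)
  tr$participant_id <- as.character(tr$participant_id)
  bl$participant_id <- as.character(bl$participant_id)
  plt_dataset(tr[.trial_columns], bl[.baseline_columns],
              provenance = provenance, metadata = metadata)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Import externally deposited raw data via an explicit column map
#'
#' The layout of the deposited raw-data repository is not standardised, so
#' import is driven by a user-supplied map from deposited column names to
#' the canonical schema. The map must cover every canonical trials column
#' (baseline ratings may live in the same file as `baseline` trial rows, in
#' which case the baseline table is derived from them, or in a separate
#' `baselines` file mapped likewise).
#'
#' @param path Directory containing the deposited delimited file(s).
#' @param column_map Named character vector or list,
#'   `canonical_name = deposited_name`, for the trials table.
#' @param trials_file,baselines_file File names inside `path`;
#'   `baselines_file = NULL` derives baselines from `baseline` trial rows.
#' @param recode Optional named list of recoding tables, e.g.
#'   `list(cue_timing = c(pre = "precue", post = "postcue"))`.
#' @return A `plt_dataset` with `provenance = "deposited"`; the number of
#'   dropped (unmappable) rows is recorded in `metadata$dropped_rows`.
#' @export
import_deposited <- function(path, column_map, trials_file = "trials.csv",
                             baselines_file = NULL, recode = list()) {
  if (!dir.exists(path) || length(list.files(path)) == 0) {
    stop("deposited data directory '", path, "' is missing or empty",
         call. = FALSE)
  }
  column_map <- unlist(column_map)
  need <- setdiff(.trial_columns, names(column_map))
  if (length(need) > 0) {
    stop("column_map lacks canonical field(s): ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  raw <- utils::read.csv(file.path(path, trials_file),
                         stringsAsFactors = FALSE)
  absent <- setdiff(unname(column_map), names(raw))
  if (length(absent) > 0) {
    stop("deposited file lacks mapped column(s): ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  tr <- stats::setNames(raw[unname(column_map)], names(column_map))
  for (col in names(recode)) {
    tr[[col]] <- unname(recode[[col]][as.character(tr[[col]])])
  }
  ok <- !is.na(tr$trial_type) & !is.na(tr$response)
  dropped <- sum(!ok)
  tr <- tr[ok, , drop = FALSE]

  if (is.null(baselines_file)) {
    base_rows <- tr[tr$trial_type == "baseline", , drop = FALSE]
    pos_cols <- paste0("pos", 1:4, "_image")
    img <- apply(base_rows[pos_cols], 1, function(r) r[!is.na(r)][1])
    bl <- data.frame(participant_id = base_rows$participant_id,
                     image_id = as.character(img),
                     baseline_pleasure = base_rows$response,
                     stringsAsFactors = FALSE)
  } else {
    bl <- utils::read.csv(file.path(path, baselines_file),
                          stringsAsFactors = FALSE)[.baseline_columns]
  }

  n_blocks <- length(setdiff(unique(tr$block_index), 0))
  per_block <- table(tr$block_index[tr$block_index != 0])
  if (length(per_block) > 0 && any(per_block != 45)) {
    warning("block trial counts differ from the expected 45 per block",
            call. = FALSE)
  }
  plt_dataset(tr, bl, provenance = "deposited",
              metadata = list(dropped_rows = dropped,
                              n_main_blocks = n_blocks))
}

# condition label used throughout fitting and analysis
.condition_of <- function(trials) {
  type <- ifelse(trials$trial_type == "one_of_four", "1of4",
                 ifelse(trials$trial_type == "four_combined", "comb",
                        "baseline"))
  ifelse(type == "baseline", "baseline",
         paste(trials$cue_timing, type, sep = "_"))
}

#' Condition labels of a trials table
#'
#' Maps `cue_timing` x `trial_type` to the four analysis conditions
#' `precue_1of4`, `postcue_1of4`, `precue_comb`, `postcue_comb`
#' (baseline trials map to `"baseline"`).
#'
#' @param trials A trials data frame.
#' @return Character vector of condition labels.
#' @export
trial_conditions <- function(trials) .condition_of(trials)

# Baseline lookup: returns n x 4 matrix of baseline pleasures for the
# displayed images (NA where the position is empty).
.baseline_matrix <- function(trials, baselines) {
  key <- paste(baselines$participant_id, baselines$image_id)
  val <- baselines$baseline_pleasure
  out <- matrix(NA_real_, nrow(trials), 4)
  for (p in 1:4) {
    col <- trials[[paste0("pos", p, "_image")]]
    idx <- match(paste(trials$participant_id, col), key)
    out[, p] <- val[idx]
    out[is.na(col), p] <- NA_real_
  }
  miss <- which(rowSums(is.na(out) & !is.na(
    sapply(1:4, function(p) trials[[paste0("pos", p, "_image")]]))) > 0)
  if (length(miss) > 0) {
    stop("missing baseline for trial row ", miss[1], call. = FALSE)
  }
  out
}
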