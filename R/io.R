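# Readers and writers for the TSV log schemas, plus the end-to-end pipeline.

.FIX_COLS <- c("participant_id", "trial_index", "game_id", "fix_index",
               "onset_ms", "x_px", "y_px", "duration_ms")
.CHO_COLS <- c("participant_id", "trial_index", "game_id", "choice", "rt_ms",
               "player_axis", "own_color", "own_corner", "row_swapped",
               "col_swapped")

#' Write a fixation log
#' @param fixations Fixation data frame (schema of [read_fixation_log()]).
#' @param path Output TSV.
#' @export
write_fixation_log <- function(fixations, path) {
  write.table(fixations[, .FIX_COLS], path, sep = "\t", row.names = FALSE,
              quote = FALSE)
  invisible(path)
}

#' Read a fixation log
#'
#' Tab-separated with header columns `participant_id`, `trial_index`,
#' `game_id`, `fix_index` (0-based within trial), `onset_ms`, `x_px`,
#' `y_px`, `duration_ms`. Rows are ordered by participant, trial and
#' fixation index; a missing column, non-monotone fixation index or
#' non-positive duration is an error naming the offending row.
#'
#' @param path TSV file.
#' @return Validated data frame.
#' @export
read_fixation_log <- function(path) {
  f <- read.delim(path, stringsAsFactors = FALSE)
  miss <- setdiff(.FIX_COLS, names(f))
  if (length(miss)) stop("read_fixation_log: missing columns: ",
                         paste(miss, collapse = ", "))
  if (nrow(f) == 0) return(f[, .FIX_COLS])
  bad <- which(f$duration_ms <= 0)
  if (length(bad)) stop("read_fixation_log: non-positive duration at row ", bad[1])
  f <- f[order(f$participant_id, f$trial_index, f$fix_index), ]
  key <- paste(f$participant_id, f$trial_index)
  expected <- stats::ave(f$fix_index, key, FUN = function(z) seq_along(z) - 1L)
  bad <- which(f$fix_index != expected)
  if (length(bad)) {
    stop("read_fixation_log: fix_index not consecutive from 0 at row ", bad[1],
         " (participant ", f$participant_id[bad[1]], ", trial ",
         f$trial_index[bad[1]], ")")
  }
  rownames(f) <- NULL
  f[, .FIX_COLS]
}

#' Write a choice log
#' @param choices Choice data frame (schema of [read_choice_log()]).
#' @param path Output TSV.
#' @export
write_choice_log <- function(choices, path) {
  write.table(choices[, .CHO_COLS], path, sep = "\t", row.names = FALSE,
              quote = FALSE)
  invisible(path)
}

#' Read a choice log
#'
#' Tab-separated with header columns `participant_id`, `trial_index`,
#' `game_id`, `choice` (presentation frame: top/bottom for row players,
#' left/right for column players), `rt_ms`, and the counterbalance state
#' `player_axis`, `own_color`, `own_corner`, `row_swapped`, `col_swapped`.
#'
#' @param path TSV file.
#' @return Validated data frame.
#' @export
read_choice_log <- function(path) {
  ch <- read.delim(path, stringsAsFactors = FALSE)
  miss <- setdiff(.CHO_COLS, names(ch))
  if (length(miss)) stop("read_choice_log: missing columns: ",
                         paste(miss, collapse = ", "))
  if (nrow(ch) == 0) return(ch[, .CHO_COLS])
  bad <- which(!ch$choice %in% c("top", "bottom", "left", "right"))
  if (length(bad)) stop("read_choice_log: invalid choice code at row ", bad[1])
  bad <- which(!ch$player_axis %in% c("rows", "columns"))
  if (length(bad)) stop("read_choice_log: invalid player_axis at row ", bad[1])
  ch$row_swapped <- as.logical(ch$row_swapped)
  ch$col_swapped <- as.logical(ch$col_swapped)
  ch[, .CHO_COLS]
}

#' Run the full analysis pipeline
#'
#' Chains the stages on either a synthetic cohort or logs on disk: AOI
#' assignment, canonicalization, gaze summaries, transition tallies and the
#' saturated log-linear model, gaze-bias curves, the logistic choice-model
#' suite, and the level-k mixture fit. Stage outputs are written as CSV next
#' to a single JSON report.
#'
#' @param config Either a path to a YAML/JSON configuration file or a list.
#'   Recognized entries: `synth` (a list of [cohort_config()] arguments,
#'   including `seed`) or `inputs` (list with `fixation_log`, `choice_log`,
#'   `games_csv`); optional `choice_models` (names, see
#'   [build_choice_design()]) and `n_boot` for transition-model intervals.
#' @param out_dir Output directory.
#' @return The report list (also written to `report.json`).
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) {
    config <- if (grepl("\\.json$", config)) jsonlite::read_json(config, simplifyVector = TRUE)
              else yaml::read_yaml(config)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }
  if (!is.null(config$synth)) {
    cohort <- stage("synth", {
      cfg <- do.call(cohort_config, config$synth)
      generate_cohort(cfg)
    })
    games <- cohort$games
    fixations <- cohort$fixations
    choices <- cohort$choices
    layout <- cohort$config$layout
  } else if (!is.null(config$inputs)) {
    games <- stage("read", read_games_csv(config$inputs$games_csv))
    fixations <- stage("read", read_fixation_log(config$inputs$fixation_log))
    choices <- stage("read", read_choice_log(config$inputs$choice_log))
    layout <- default_layout()
  } else stop("run_pipeline: config needs a 'synth' or 'inputs' block")

  fixations <- stage("assign", assign_fixations(fixations, layout))
  canon <- stage("canonicalize", canonicalize_trials(fixations, choices))
  summary <- stage("summary", gaze_summary_stats(canon$fixations, canon$choices))
  tally <- stage("tally", transition_tally(canon$fixations, canon$choices,
                                           strata = c("half", "choice")))
  tally_flat <- stage("tally", transition_tally(canon$fixations))
  n_boot <- if (!is.null(config$n_boot)) config$n_boot else 199
  tmodel <- stage("transition_model",
                  fit_transition_model(tally_flat, "baseline", n_boot = n_boot))
  curve <- stage("gaze_bias", gaze_bias_curve(canon$fixations, canon$choices))
  features <- stage("features", trial_features(canon$fixations, canon$choices, games))
  model_names <- if (!is.null(config$choice_models)) config$choice_models
                 else c("intercept", "attributes", "attributes_simple", "fixations",
                        "attributes_fixations", "last_fixation", "transitions",
                        "transitions_attributes", "improper_fixations",
                        "improper_transitions")
  suite <- stage("choicemodels", choice_model_suite(features, model_names))
  mixfit <- stage("levelk", {
    agg <- aggregate(cbind(top = features$choice == 1, n = 1) ~ game_id,
                     data = features, FUN = sum)
    m <- match(agg$game_id, games$game_id)
    fit_mixture(agg$top, agg$n, games[m, , drop = FALSE])
  })

  own_coef <- tmodel$coefficients$exp_coefficient[tmodel$coefficients$term == "own"]
  write.csv(summary, file.path(out_dir, "gaze_summary.csv"), row.names = FALSE)
  write.csv(tally, file.path(out_dir, "transition_tally.csv"), row.names = FALSE)
  write.csv(tmodel$coefficients, file.path(out_dir, "transition_model.csv"),
            row.names = FALSE)
  write.csv(curve, file.path(out_dir, "gaze_bias_curve.csv"), row.names = FALSE)
  write.csv(suite, file.path(out_dir, "choice_models.csv"), row.names = FALSE)
  report <- list(
    n_participants = length(unique(choices$participant_id)),
    n_trials = nrow(choices),
    pooled = as.list(summary[summary$participant_id == "(pooled)", -1]),
    own_exp_coefficient = own_coef,
    own_proportion = own_proportion_from_coef(own_coef),
    mixture = list(weights = as.list(mixfit$weights), loglik = mixfit$loglik,
                   identifiable = mixfit$identifiable),
    choice_models = suite,
    gaze_bias_final_minus_first = {
      top <- curve[curve$choice == "top", ]
      bot <- curve[curve$choice == "bottom", ]
      list(top = top$proportion[which.max(top$bin)] - top$proportion[which.min(top$bin)],
           bottom = bot$proportion[which.max(bot$bin)] - bot$proportion[which.min(bot$bin)])
    })
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}
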