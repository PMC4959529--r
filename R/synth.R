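# Synthetic cohort generator: emulates the structure of the eye-tracking
# study (54 participants x 64 games, counterbalanced presentation, ~290 ms
# fixations) with choices and gaze driven by level-k agents, the
# gaze-coupled accumulator, or pure noise, so the full pipeline can be
# validated without any recorded data.

#' Cohort configuration
#'
#' Defaults reproduce the study's structure: 54 participants, the 64-game
#' grid, fixation durations with mean 290 ms (sd 100 ms), an agent mix at
#' the fitted reasoning-level proportions (19.5% level 0, 54.8% level 1,
#' 25.7% level 2, no accumulator agents), no trembles, a trial fixation
#' target of 17, coordinate jitter of 20 px around AOI centers (keeping over
#' 99% of fixations inside the 100 px radius) and full counterbalancing.
#'
#' @param n_participants Number of participants.
#' @param games Games data frame.
#' @param agent_mix Named proportions over `level0`, `level1`, `level2`,
#'   `accumulator`; must sum to 1. Agents are apportioned to participants by
#'   largest remainder, so the realized composition matches the mix.
#' @param tremble Probability a level-k agent's intended action is replaced
#'   by a fair coin.
#' @param fixation_target Mean fixation count per trial for lookup-program
#'   and noise agents (programs are repeated whole until the target is met).
#' @param duration_mean_ms,duration_sd_ms Lognormal fixation duration
#'   moments.
#' @param nondecision_ms Offset added to summed fixation durations to form
#'   response times for non-accumulator agents.
#' @param jitter_sd_px Gaussian jitter of fixation coordinates around AOI
#'   centers.
#' @param layout Screen layout.
#' @param accumulator Parameters for accumulator agents.
#' @param seed Optional seed applied by the generators.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_participants = 54,
                          games = build_game_grid(),
                          agent_mix = c(level0 = 0.195, level1 = 0.548,
                                        level2 = 0.257, accumulator = 0),
                          tremble = 0,
                          fixation_target = 17,
                          duration_mean_ms = 290,
                          duration_sd_ms = 100,
                          nondecision_ms = 300,
                          jitter_sd_px = 20,
                          layout = default_layout(),
                          accumulator = accumulator_params(),
                          seed = NULL) {
  stopifnot(abs(sum(agent_mix) - 1) < 1e-8, all(agent_mix >= 0),
            tremble >= 0, tremble <= 1)
  validate_layout(layout)
  structure(list(n_participants = n_participants, games = games,
                 agent_mix = agent_mix, tremble = tremble,
                 fixation_target = fixation_target,
                 duration_mean_ms = duration_mean_ms,
                 duration_sd_ms = duration_sd_ms,
                 nondecision_ms = nondecision_ms,
                 jitter_sd_px = jitter_sd_px, layout = layout,
                 accumulator = accumulator, seed = seed),
            class = "cohort_config")
}

# Largest-remainder apportionment of agent types over participants.
.apportion_agents <- function(mix, n) {
  raw <- mix * n
  base <- floor(raw)
  left <- n - sum(base)
  if (left > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(left)]
    base[extra] <- base[extra] + 1
  }
  rep(names(mix), times = base)
}

# Between-participant counterbalance states, cycled over the 8 combinations.
.participant_cb <- function(n) {
  combos <- expand.grid(player_axis = c("rows", "columns"),
                        own_color = c("green", "blue"),
                        own_corner = c("top_left", "bottom_right"),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  combos[((seq_len(n) - 1) %% nrow(combos)) + 1, , drop = FALSE]
}

.sample_durations <- function(n, mean_ms, sd_ms) {
  lp <- .lnorm_pars(mean_ms, sd_ms)
  rlnorm(n, lp["meanlog"], lp["sdlog"])
}

#' Generate a synthetic cohort
#'
#' Produces presentation-frame fixation and choice logs for a cohort of
#' agents playing every game once, in randomized order, with per-trial
#' row/column swaps and between-participant counterbalancing of player axis,
#' payoff color and payoff corner. Level-k agents choose by
#' [predict_choice()] (guesses and trembles resolved by fair coins) and
#' fixate by whole repetitions of [simulate_lookups()] until the trial
#' fixation target is reached (level-0 agents, who need no payoff
#' information, emit uniform-random AOI fixations); accumulator agents are
#' simulated by [simulate_ddm_trials()]. Canonical-frame AOI labels are
#' mapped to screen positions via [presentation_permutation()] and jittered.
#'
#' Fully reproducible given `config$seed`; all randomness flows through R's
#' global stream.
#'
#' @param config A [cohort_config()].
#' @return List with `games`, `fixations`, `choices`, `agents` (data frame
#'   participant_id, agent) and `config`.
#' @export
generate_cohort <- function(config = cohort_config()) {
  if (!is.null(config$seed)) set.seed(config$seed)
  games <- config$games
  n_p <- config$n_participants
  agents <- .apportion_agents(config$agent_mix, n_p)
  cbs <- .participant_cb(n_p)
  lab_row_top <- payoff_labels()$row == "top"
  fix_list <- list(); cho_list <- list()
  for (p in seq_len(n_p)) {
    pid <- sprintf("p%02d", p)
    agent <- agents[p]
    cb_p <- cbs[p, ]
    order_g <- sample.int(nrow(games))
    for (ti in seq_along(order_g)) {
      g <- games[order_g[ti], , drop = FALSE]
      cb <- cb_p
      cb$row_swapped <- runif(1) < 0.5
      cb$col_swapped <- runif(1) < 0.5
      if (agent == "accumulator") {
        sim <- simulate_ddm_trials(g, config$accumulator, 1)
        choice <- sim$choices$choice[1]
        rt <- sim$choices$rt_ms[1]
        aoi <- sim$fixations$aoi
        dur <- sim$fixations$duration_ms
      } else {
        k <- as.integer(sub("level", "", agent))
        intended <- predict_choice(g, k)
        if (intended == "guess" || runif(1) < config$tremble) {
          choice <- if (runif(1) < 0.5) "top" else "bottom"
        } else choice <- intended
        target <- max(2L, rpois(1, config$fixation_target))
        if (k == 0) {
          aoi <- sample.int(8, target, replace = TRUE)
        } else {
          aoi <- integer(0)
          while (length(aoi) < target) {
            aoi <- c(aoi, simulate_lookups(g, k)$sequence)
          }
        }
        dur <- .sample_durations(length(aoi), config$duration_mean_ms,
                                 config$duration_sd_ms)
        rt <- sum(dur) + config$nondecision_ms
      }
      perm <- presentation_permutation(cb)
      pos <- perm[aoi]
      ctr <- config$layout$centers[pos, , drop = FALSE]
      nfix <- length(aoi)
      onset <- cumsum(c(0, dur))[seq_len(nfix)]
      fix_list[[length(fix_list) + 1]] <- data.frame(
        participant_id = pid, trial_index = ti, game_id = g$game_id,
        fix_index = seq_len(nfix) - 1L, onset_ms = round(onset, 1),
        x_px = round(ctr[, 1] + rnorm(nfix, 0, config$jitter_sd_px), 1),
        y_px = round(ctr[, 2] + rnorm(nfix, 0, config$jitter_sd_px), 1),
        duration_ms = round(dur, 1), stringsAsFactors = FALSE)
      cho_list[[length(cho_list) + 1]] <- data.frame(
        participant_id = pid, trial_index = ti, game_id = g$game_id,
        choice = choice_to_presentation(choice, cb), rt_ms = round(rt, 1),
        player_axis = cb$player_axis, own_color = cb$own_color,
        own_corner = cb$own_corner, row_swapped = cb$row_swapped,
        col_swapped = cb$col_swapped, stringsAsFactors = FALSE)
    }
  }
  agents_df <- data.frame(participant_id = sprintf("p%02d", seq_len(n_p)),
                          agent = agents, stringsAsFactors = FALSE)
  list(games = games, fixations = do.call(rbind, fix_list),
       choices = do.call(rbind, cho_list), agents = agents_df, config = config)
}

#' Generate a null cohort
#'
#' Gaze and choices are independent: AOIs are uniform over the eight payoffs
#' and choices are fair coins. Used to verify that bias statistics are flat
#' and gaze-based choice models sit at chance.
#'
#' @param config A [cohort_config()]; the agent mix is ignored.
#' @return Same structure as [generate_cohort()].
#' @export
generate_null_cohort <- function(config = cohort_config()) {
  if (!is.null(config$seed)) set.seed(config$seed)
  cfg2 <- config
  cfg2$seed <- NULL
  cfg2$agent_mix <- c(level0 = 1, level1 = 0, level2 = 0, accumulator = 0)
  out <- generate_cohort(cfg2)
  out$agents$agent <- "null"
  out$config <- config
  out
}

#' Write a cohort to disk
#'
#' Emits the games CSV, the fixation and choice TSV logs, and a JSON
#' manifest with the generating configuration and per-file MD5 checksums.
#'
#' @param cohort Output of [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the manifest list.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(games = file.path(dir, "games.csv"),
             fixations = file.path(dir, "fixations.tsv"),
             choices = file.path(dir, "choices.tsv"))
  write_games_csv(cohort$games, paths["games"])
  write_fixation_log(cohort$fixations, paths["fixations"])
  write_choice_log(cohort$choices, paths["choices"])
  cfg <- cohort$config
  manifest <- list(
    schema_version = "1.0",
    seed = cfg$seed,
    n_participants = cfg$n_participants,
    agent_mix = as.list(cfg$agent_mix),
    tremble = cfg$tremble,
    duration_mean_ms = cfg$duration_mean_ms,
    files = lapply(paths, function(p) list(path = basename(p),
                                           md5 = unname(tools::md5sum(p)))))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
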