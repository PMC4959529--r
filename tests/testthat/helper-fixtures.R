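# Shared fixtures and independent oracles, all built in code.

# A game row with arbitrary own payoffs (even payoffs follow by symmetry).
make_game <- function(x1, x3, x5, x7, id = "test") {
  g <- data.frame(game_id = id, base_config = 1L,
                  d_left = x1 - x5, d_right = x3 - x7,
                  x1 = x1, x2 = x1, x3 = x3, x4 = x5,
                  x5 = x5, x6 = x3, x7 = x7, x8 = x7,
                  stringsAsFactors = FALSE)
  for (k in 1:8) g[[paste0("y", k)]] <- 10 * g[[paste0("x", k)]] + 30
  g$quadrant <- if (g$d_left != 0 && g$d_right != 0) {
    classify_game(g$d_left, g$d_right)
  } else NA_character_
  g
}

# Independent classification oracle: best-response structure computed
# directly from the money payoff matrix.
classify_oracle <- function(game) {
  m <- game_payoff_matrix(game)
  br_left <- if (m["top", "left"] > m["bottom", "left"]) "top" else "bottom"
  br_right <- if (m["top", "right"] > m["bottom", "right"]) "top" else "bottom"
  if (br_left == "top" && br_right == "top") "dominance_no_conflict"
  else if (br_left == "bottom" && br_right == "bottom") "dominance_conflict"
  else if (br_left == "top") "symmetric_coordination"
  else "asymmetric_coordination"
}

# Independent level-1 oracle: expected money payoff against a uniform
# opponent.
level1_oracle <- function(game) {
  top <- (game$y1 + game$y3) / 2
  bottom <- (game$y5 + game$y7) / 2
  if (top > bottom) "top" else if (top < bottom) "bottom" else "guess"
}

# Hand-built canonical trial: one participant, one trial, given gaze.
make_canonical_trial <- function(aoi, choice, participant = "p1", trial = 1,
                                 game_id = "b1_dL1_dR1") {
  fix <- data.frame(participant_id = participant, trial_index = trial,
                    game_id = game_id, fix_index = seq_along(aoi) - 1L,
                    onset_ms = (seq_along(aoi) - 1) * 300,
                    x_px = 0, y_px = 0, duration_ms = 290,
                    aoi = as.integer(aoi), stringsAsFactors = FALSE)
  cho <- data.frame(participant_id = participant, trial_index = trial,
                    game_id = game_id, choice = choice, rt_ms = 300 * length(aoi),
                    player_axis = "rows", own_color = "green",
                    own_corner = "top_left", row_swapped = FALSE,
                    col_swapped = FALSE, stringsAsFactors = FALSE)
  list(fixations = fix, choices = cho)
}

# The printed level-k prediction table: one row per (d_left, d_right) pair.
levelk_prediction_table <- function() {
  tab <- rbind(
    c(-3, -3, "guess", "bottom", "bottom"),
    c(-3, -1, "guess", "bottom", "bottom"),
    c(-3,  1, "guess", "bottom", "top"),
    c(-3,  3, "guess", "guess",  "guess"),
    c(-1, -3, "guess", "bottom", "bottom"),
    c(-1, -1, "guess", "bottom", "bottom"),
    c(-1,  1, "guess", "guess",  "guess"),
    c(-1,  3, "guess", "top",    "bottom"),
    c( 1, -3, "guess", "bottom", "bottom"),
    c( 1, -1, "guess", "guess",  "guess"),
    c( 1,  1, "guess", "top",    "top"),
    c( 1,  3, "guess", "top",    "top"),
    c( 3, -3, "guess", "guess",  "guess"),
    c( 3, -1, "guess", "top",    "top"),
    c( 3,  1, "guess", "top",    "top"),
    c( 3,  3, "guess", "top",    "top"))
  data.frame(d_left = as.numeric(tab[, 1]), d_right = as.numeric(tab[, 2]),
             level0 = tab[, 3], level1 = tab[, 4], level2 = tab[, 5],
             stringsAsFactors = FALSE)
}

# All 32 counterbalance states.
all_cb_states <- function() {
  expand.grid(player_axis = c("rows", "columns"), own_color = c("green", "blue"),
              own_corner = c("top_left", "bottom_right"),
              row_swapped = c(FALSE, TRUE), col_swapped = c(FALSE, TRUE),
              KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
}
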