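# Game space: symmetric 2x2 games defined on a grid of payoff differences.
#
# Payoffs are labelled 1-8. Odd labels are the player's own payoffs, even
# labels the other player's. Labels (1,2) sit in the top-left cell, (3,4)
# top-right, (5,6) bottom-left, (7,8) bottom-right.

.PAYOFF_ROW <- c("top", "top", "top", "top", "bottom", "bottom", "bottom", "bottom")
.PAYOFF_COL <- c("left", "left", "right", "right", "left", "left", "right", "right")
.PAYOFF_OWNER <- rep(c("self", "other"), 4)

#' Payoff labels of a 2x2 symmetric game
#'
#' Returns the labelling convention used throughout the package: payoff
#' indices 1-8, with odd indices owned by the player ("self"), even indices
#' by the other player, and cells ordered top-left, top-right, bottom-left,
#' bottom-right.
#'
#' @return A data frame with columns `index`, `owner`, `row`, `col`.
#' @export
#' @examples
#' payoff_labels()
payoff_labels <- function() {
  data.frame(
    index = 1:8,
    owner = .PAYOFF_OWNER,
    row = .PAYOFF_ROW,
    col = .PAYOFF_COL,
    stringsAsFactors = FALSE
  )
}

#' Map abstract payoff values to money payoffs
#'
#' Games are defined on abstract integer payoff values `x`; money payoffs in
#' GBP are the affine image `y = 10 * x + 30`, which keeps the experimental
#' payoffs inside 0-90.
#'
#' @param x Numeric vector of abstract payoff values.
#' @return Money payoffs (GBP), same length as `x`.
#' @export
#' @examples
#' payoff_from_x(c(-3, 0, 6)) # 0, 30, 90
payoff_from_x <- function(x) {
  y <- 10 * x + 30
  if (any(y < 0 | y > 90)) {
    stop("payoff_from_x: resulting payoff outside [0, 90] for x = ",
         paste(x[y < 0 | y > 90], collapse = ", "))
  }
  y
}

#' Default base payoff configurations
#'
#' Each quarter of the game set holds two of the player's payoffs fixed while
#' the other two are generated from the payoff differences. The four quarters
#' fix (x1, x3), (x5, x3), (x1, x7) and (x5, x7) respectively. The numeric
#' values used here (2 and 1 on the abstract scale) are package defaults
#' chosen so every generated payoff stays in 0-90 GBP; they are not the
#' original experimental values, which can be supplied through a games CSV.
#'
#' @return A data frame with columns `base_config`, `fix_a`, `val_a`,
#'   `fix_b`, `val_b` where `fix_a` is one of `"x1"`/`"x5"` and `fix_b` one
#'   of `"x3"`/`"x7"`.
#' @export
default_base_configs <- function() {
  data.frame(
    base_config = 1:4,
    fix_a = c("x1", "x5", "x1", "x5"),
    val_a = c(2, 2, 2, 2),
    fix_b = c("x3", "x3", "x7", "x7"),
    val_b = c(1, 1, 1, 1),
    stringsAsFactors = FALSE
  )
}

#' Classify a game by the signs of its payoff differences
#'
#' The strategic type of a symmetric 2x2 game is a pure function of the signs
#' of `d_left = x1 - x5` and `d_right = x3 - x7`: both negative gives a
#' dominance-solvable game with a conflict between cooperation and own payoff
#' (prisoner's dilemma family); positive/negative a symmetric coordination
#' game (stag hunt family); negative/positive an asymmetric coordination game
#' (hawk-dove family); both positive a dominance-solvable game with no
#' conflict.
#'
#' @param d_left,d_right Integer vectors of payoff differences (nonzero).
#' @return Character vector of game classes.
#' @export
#' @examples
#' classify_game(-3, -3) # dominance_conflict
#' classify_game(3, -1)  # symmetric_coordination
classify_game <- function(d_left, d_right) {
  if (any(d_left == 0 | d_right == 0)) {
    stop("classify_game: zero payoff difference has no strategic class")
  }
  ifelse(d_left < 0,
    ifelse(d_right < 0, "dominance_conflict", "asymmetric_coordination"),
    ifelse(d_right < 0, "symmetric_coordination", "dominance_no_conflict")
  )
}

#' Build the grid of symmetric 2x2 games
#'
#' Constructs one game for every combination of `d_left = x1 - x5` and
#' `d_right = x3 - x7` drawn from `diff_values`, within each base
#' configuration. With the default four difference values and four base
#' configurations this yields the full 64-game space. Games are symmetric:
#' the other player's payoffs are the transpose of the player's
#' (`y1 = y2`, `y3 = y6`, `y5 = y4`, `y7 = y8`).
#'
#' @param diff_values Integer values the two payoff differences may take.
#' @param base_configs Base configuration table, see [default_base_configs()].
#' @return A data frame with one row per game: `game_id`, `base_config`,
#'   `d_left`, `d_right`, abstract payoffs `x1`-`x8`, money payoffs
#'   `y1`-`y8`, and `quadrant` (the strategic class). Ordered by base
#'   configuration, then `d_left`, then `d_right`.
#' @export
#' @examples
#' g <- build_game_grid()
#' nrow(g) # 64
build_game_grid <- function(diff_values = c(-3L, -1L, 1L, 3L),
                            base_configs = default_base_configs()) {
  if (length(diff_values) == 0) stop("build_game_grid: diff_values is empty")
  grid <- expand.grid(d_right = sort(diff_values), d_left = sort(diff_values),
                      KEEP.OUT.ATTRS = FALSE)
  out <- vector("list", nrow(base_configs))
  for (i in seq_len(nrow(base_configs))) {
    bc <- base_configs[i, ]
    x1 <- x3 <- x5 <- x7 <- numeric(nrow(grid))
    dl <- grid$d_left; dr <- grid$d_right
    if (bc$fix_a == "x1") { x1[] <- bc$val_a; x5 <- x1 - dl }
    else                  { x5[] <- bc$val_a; x1 <- x5 + dl }
    if (bc$fix_b == "x3") { x3[] <- bc$val_b; x7 <- x3 - dr }
    else                  { x7[] <- bc$val_b; x3 <- x7 + dr }
    xs <- cbind(x1, x3, x5, x7)
    if (any(10 * xs + 30 < 0 | 10 * xs + 30 > 90)) {
      stop("build_game_grid: base configuration ", bc$base_config,
           " pushes a payoff outside [0, 90] GBP")
    }
    g <- data.frame(
      game_id = sprintf("b%d_dL%d_dR%d", bc$base_config, dl, dr),
      base_config = bc$base_config,
      d_left = dl, d_right = dr,
      x1 = x1, x2 = x1, x3 = x3, x4 = x5, x5 = x5, x6 = x3, x7 = x7, x8 = x7,
      stringsAsFactors = FALSE
    )
    for (k in 1:8) g[[paste0("y", k)]] <- payoff_from_x(g[[paste0("x", k)]])
    g$quadrant <- classify_game(g$d_left, g$d_right)
    out[[i]] <- g
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' The player's payoff matrix of a game
#'
#' @param game A single-row game data frame (one row of [build_game_grid()]).
#' @return A 2x2 matrix of money payoffs for the row player, rows
#'   top/bottom, columns left/right.
#' @export
game_payoff_matrix <- function(game) {
  stopifnot(nrow(game) == 1)
  matrix(c(game$y1, game$y5, game$y3, game$y7), 2, 2,
         dimnames = list(c("top", "bottom"), c("left", "right")))
}

#' Write a games table to CSV
#'
#' The on-disk schema carries `game_id`, `base_config`, `d_left`, `d_right`
#' and the money payoffs `y1`-`y8`; abstract values and classes are
#' reconstructed on read.
#'
#' @param games Games data frame.
#' @param path Output file.
#' @export
write_games_csv <- function(games, path) {
  cols <- c("game_id", "base_config", "d_left", "d_right", paste0("y", 1:8))
  write.csv(games[, cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a games table from CSV
#'
#' Validates the symmetry of the payoffs, the payoff range and the
#' consistency of the stated differences before reconstructing the abstract
#' payoff values and strategic classes.
#'
#' @param path CSV file written by [write_games_csv()] (or transcribed by
#'   hand to replicate a particular experimental set).
#' @return A games data frame in the layout of [build_game_grid()].
#' @export
read_games_csv <- function(path) {
  g <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("game_id", "base_config", "d_left", "d_right", paste0("y", 1:8))
  miss <- setdiff(need, names(g))
  if (length(miss)) stop("read_games_csv: missing columns: ", paste(miss, collapse = ", "))
  ys <- as.matrix(g[, paste0("y", 1:8)])
  if (any(ys < 0 | ys > 90)) stop("read_games_csv: payoff outside [0, 90]")
  if (!all(g$y1 == g$y2 & g$y3 == g$y6 & g$y5 == g$y4 & g$y7 == g$y8)) {
    stop("read_games_csv: payoffs violate the symmetry y1=y2, y3=y6, y5=y4, y7=y8")
  }
  for (k in 1:8) g[[paste0("x", k)]] <- (g[[paste0("y", k)]] - 30) / 10
  if (!all(g$x1 - g$x5 == g$d_left & g$x3 - g$x7 == g$d_right)) {
    stop("read_games_csv: stated d_left/d_right disagree with payoffs")
  }
  g$quadrant <- classify_game(g$d_left, g$d_right)
  g[, c("game_id", "base_config", "d_left", "d_right",
        paste0("x", 1:8), paste0("y", 1:8), "quadrant")]
}
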