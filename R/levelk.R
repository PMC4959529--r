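# Level-k theory: choice predictions, lookup programs, and mixture fitting.
#
# A level-0 player randomizes; a level-k player best responds to a simulated
# level-(k-1) opponent. Because the games are symmetric, the column player's
# decision problem is identical to the row player's, so the same recursion
# serves both roles (a column player's "top" is the left column).

#' Level-k choice prediction
#'
#' Predicts the row choice of a level-`k` player. Level 0 guesses. Level 1
#' best responds to a uniformly randomizing opponent, so it chooses top when
#' `d_left + d_right > 0`, bottom when negative, and guesses on a tie. Higher
#' levels best respond to the simulated level-(k-1) column choice; when that
#' simulated choice is itself a guess, the best response is computed against
#' the uniform mixture and ties propagate as a guess.
#'
#' @param games Games data frame (any number of rows).
#' @param k Reasoning level, a single integer >= 0.
#' @return Character vector over games: `"top"`, `"bottom"` or `"guess"`.
#' @export
#' @examples
#' g <- build_game_grid()
#' table(predict_choice(g, 1))
predict_choice <- function(games, k) {
  stopifnot(length(k) == 1, k >= 0, k == round(k))
  if (k == 0) return(rep("guess", nrow(games)))
  # Opponent's column choice at level k-1; symmetry maps their top -> left.
  opp <- predict_choice(games, k - 1)
  opp_col <- c(top = "left", bottom = "right", guess = "guess")[opp]
  sgn_choice <- function(d) ifelse(d > 0, "top", ifelse(d < 0, "bottom", "guess"))
  unname(ifelse(opp_col == "left", sgn_choice(games$d_left),
    ifelse(opp_col == "right", sgn_choice(games$d_right),
      sgn_choice(games$d_left + games$d_right))))
}

#' Prediction scores for a set of reasoning levels
#'
#' @param games Games data frame.
#' @param levels Integer vector of levels.
#' @return Matrix (games x levels) of top-choice scores: 1 for a predicted
#'   top, 0 for bottom, 0.5 for a guess.
#' @export
levelk_scores <- function(games, levels = 0:2) {
  s <- sapply(levels, function(k) {
    p <- predict_choice(games, k)
    c(top = 1, bottom = 0, guess = 0.5)[p]
  })
  s <- matrix(s, nrow = nrow(games), dimnames = list(games$game_id, paste0("level", levels)))
  s
}

#' Top-choice probability of a mixture of levels
#'
#' @param weights Nonnegative mixture weights summing to one, one per level.
#' @param games Games data frame.
#' @param levels Levels the weights refer to (default 0:2).
#' @return Probability of a top choice for each game.
#' @export
#' @examples
#' g <- build_game_grid()
#' mixture_choice_probability(c(0.195, 0.548, 0.257), g)[1]
mixture_choice_probability <- function(weights, games, levels = 0:2) {
  stopifnot(length(weights) == length(levels), all(weights >= 0))
  if (abs(sum(weights) - 1) > 1e-8) stop("mixture weights must sum to 1")
  drop(levelk_scores(games, levels) %*% weights)
}

#' Fit a mixture of reasoning levels to choice counts
#'
#' Estimates mixture proportions over reasoning levels from per-game counts
#' of top choices, under a binomial likelihood with the top probability given
#' by [mixture_choice_probability()]. The default estimator is maximum
#' likelihood on the simplex (softmax reparameterization, BFGS); a
#' least-squares fit to the observed proportions is also available since the
#' aggregation level of the original estimator is not fixed by theory.
#'
#' When two levels predict identical choices on every supplied game the
#' mixture direction between them is flat; the fit is still returned but
#' flagged as unidentified.
#'
#' @param top_counts Integer vector, top choices per game.
#' @param totals Integer vector, choices per game.
#' @param games Games data frame aligned with the counts.
#' @param levels Levels in the mixture (default 0:2).
#' @param method `"ml"` (default) or `"ls"`.
#' @return List with `weights` (named), `loglik`, `convergence` (0 = ok),
#'   `identifiable` (logical) and `method`.
#' @export
fit_mixture <- function(top_counts, totals, games, levels = 0:2,
                        method = c("ml", "ls")) {
  method <- match.arg(method)
  stopifnot(length(top_counts) == nrow(games), length(totals) == nrow(games),
            all(top_counts >= 0), all(top_counts <= totals))
  s <- levelk_scores(games, levels)
  # identifiability: any two score columns equal on all games => flat direction
  identifiable <- TRUE
  for (a in seq_len(ncol(s) - 1)) for (b in seq((a + 1), ncol(s))) {
    if (all(s[, a] == s[, b])) identifiable <- FALSE
  }
  if (!identifiable) {
    warning("fit_mixture: some levels predict identical choices on every supplied game; ",
            "mixture weights between them are not identified")
  }
  eps <- 1e-9
  objective <- function(theta) {
    w <- exp(c(0, theta)); w <- w / sum(w)
    p <- pmin(pmax(drop(s %*% w), eps), 1 - eps)
    if (method == "ml") {
      -sum(top_counts * log(p) + (totals - top_counts) * log(1 - p))
    } else {
      sum((top_counts / totals - p)^2)
    }
  }
  opt <- optim(rep(0, length(levels) - 1), objective, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-12))
  w <- exp(c(0, opt$par)); w <- w / sum(w)
  names(w) <- paste0("level", levels)
  p <- pmin(pmax(drop(s %*% w), eps), 1 - eps)
  ll <- sum(top_counts * log(p) + (totals - top_counts) * log(1 - p))
  list(weights = w, loglik = ll, convergence = opt$convergence,
       identifiable = identifiable, method = method)
}

# ---- lookup programs -------------------------------------------------------

# Relabelling between the two players' frames: payoff j in the opponent's
# frame is payoff .TRANSPOSE_MAP[j] in ours (owner flips, actions swap roles).
.TRANSPOSE_MAP <- c(2L, 1L, 6L, 5L, 4L, 3L, 8L, 7L)

#' Lookup program of a level-k player
#'
#' The ordered stages of payoff lookups a level-k player needs: each stage is
#' a set of payoff labels that must each be looked up once. A level-1 stage
#' is the player's four own payoffs; at higher levels the program is the
#' opponent's level-(k-1) program relabelled into this player's frame,
#' followed by a responding stage covering the player's own payoffs in the
#' column the simulated opponent chooses (both columns when that simulated
#' choice is a guess).
#'
#' @param game Single-row games data frame.
#' @param k Reasoning level >= 0.
#' @return List of stages, each a list with `label` and `set` (payoff
#'   indices). Level 0 gives an empty program.
#' @export
lookup_program <- function(game, k) {
  stopifnot(nrow(game) == 1, k >= 0, k == round(k))
  if (k == 0) return(list())
  if (k == 1) return(list(list(label = "own_expected_payoff", set = c(1L, 3L, 5L, 7L))))
  opp <- lookup_program(game, k - 1)
  stages <- lapply(opp, function(st) {
    list(label = paste0("simulate_level", k - 1, ".", st$label),
         set = sort(.TRANSPOSE_MAP[st$set]))
  })
  opp_col <- c(top = "left", bottom = "right", guess = "guess")[predict_choice(game, k - 1)]
  respond_set <- switch(opp_col,
    left = c(1L, 5L), right = c(3L, 7L), guess = c(1L, 3L, 5L, 7L))
  c(stages, list(list(label = paste0("respond_to_level", k - 1), set = respond_set)))
}

# Arrange a 4-payoff stage set as a cycle through the 2x2 location grid so
# single-axis moves are exactly the cycle edges.
.stage_cycle <- function(set) {
  lab <- payoff_labels()[set, ]
  tl <- set[lab$row == "top" & lab$col == "left"]
  tr <- set[lab$row == "top" & lab$col == "right"]
  br <- set[lab$row == "bottom" & lab$col == "right"]
  bl <- set[lab$row == "bottom" & lab$col == "left"]
  c(tl, tr, br, bl)
}

# All directed orders of a 4-set consistent with single-axis transitions
# (Hamiltonian paths on the location cycle): 4 starts x 2 directions.
.stage_orders <- function(set) {
  cyc <- .stage_cycle(set)
  out <- list()
  for (s in 0:3) for (dir in c(1, -1)) {
    idx <- ((s + dir * (0:3)) %% 4) + 1
    out[[length(out) + 1]] <- cyc[idx]
  }
  out
}

#' Allowed within-stage transitions of a level-k lookup program
#'
#' Within a stage, lookups may move between two payoffs only when exactly one
#' of the location axes (row or column) changes; diagonal moves are excluded.
#'
#' @param k Reasoning level.
#' @param game Single-row games data frame; required for `k >= 2` because the
#'   responding stage depends on the simulated opponent's choice. May be
#'   omitted for `k <= 1`.
#' @return List of stages, each with `label` and `pairs`, a two-column matrix
#'   of unordered allowed transitions. Empty list for `k = 0`.
#' @export
#' @examples
#' predicted_transitions(1)
predicted_transitions <- function(k, game = NULL) {
  if (k >= 2 && is.null(game)) stop("predicted_transitions: game required for k >= 2")
  if (is.null(game)) game <- build_game_grid()[1, , drop = FALSE]
  prog <- lookup_program(game, k)
  lab <- payoff_labels()
  lapply(prog, function(st) {
    set <- st$set
    prs <- t(utils::combn(set, 2))
    keep <- apply(prs, 1, function(p) {
      (lab$row[p[1]] != lab$row[p[2]]) + (lab$col[p[1]] != lab$col[p[2]]) == 1
    })
    list(label = st$label, pairs = prs[keep, , drop = FALSE])
  })
}

#' Simulate the lookup sequence of a level-k player
#'
#' Concatenates the stages of [lookup_program()], randomizing the order of
#' lookups within each stage uniformly over orders consistent with the
#' single-axis transition rule. In the final (responding) stage the last two
#' lookups are constrained to lie one in each row, reflecting the terminal
#' between-row comparison that decides the row choice; with a two-payoff
#' responding stage this holds by construction.
#'
#' Uses R's global random number stream; seed with [set.seed()].
#'
#' @param game Single-row games data frame.
#' @param k Reasoning level >= 0.
#' @return List with `sequence` (integer payoff labels, empty for level 0)
#'   and `program` (the stage list).
#' @export
#' @examples
#' set.seed(1)
#' simulate_lookups(build_game_grid()[1, ], 2)$sequence
simulate_lookups <- function(game, k) {
  prog <- lookup_program(game, k)
  n <- length(prog)
  seqs <- lapply(seq_len(n), function(i) {
    set <- prog[[i]]$set
    if (length(set) == 2) {
      if (runif(1) < 0.5) set else rev(set)
    } else {
      orders <- .stage_orders(set)
      if (i == n) {
        lab <- payoff_labels()
        orders <- Filter(function(o) lab$row[o[3]] != lab$row[o[4]], orders)
      }
      orders[[sample.int(length(orders), 1)]]
    }
  })
  list(sequence = as.integer(unlist(seqs)), program = prog)
}

#' Predicted gaze-bias curve of a level-k player
#'
#' Simulates lookup sequences for every supplied game, conditions on the
#' predicted choice (guesses resolved by a fair coin), bins each sequence
#' into time bins by fractional position, and reports the proportion of
#' top-row lookups per bin and choice. Because every program ends with a
#' between-row comparison, level-k predicts no late bias toward the chosen
#' row -- the discriminating contrast with accumulation accounts.
#'
#' @param k Reasoning level >= 1.
#' @param n_sims Simulated plays per game.
#' @param games Games data frame (default the 64-game grid).
#' @param n_bins Number of time bins (default deciles).
#' @return Data frame with `bin`, `choice`, `proportion` (top-row share) and
#'   `n` (lookups contributing).
#' @export
predicted_gaze_bias <- function(k, n_sims, games = build_game_grid(), n_bins = 10) {
  stopifnot(k >= 1, n_sims >= 1)
  pred <- predict_choice(games, k)
  top_row <- payoff_labels()$row == "top"
  bin_v <- integer(0); choice_v <- character(0); top_v <- logical(0)
  for (i in seq_len(nrow(games))) {
    for (s in seq_len(n_sims)) {
      sq <- simulate_lookups(games[i, , drop = FALSE], k)$sequence
      ch <- pred[i]
      if (ch == "guess") ch <- if (runif(1) < 0.5) "top" else "bottom"
      m <- length(sq)
      bins <- ceiling(((seq_len(m) - 0.5) / m) * n_bins)
      bin_v <- c(bin_v, bins)
      choice_v <- c(choice_v, rep(ch, m))
      top_v <- c(top_v, top_row[sq])
    }
  }
  agg <- aggregate(top_v, by = list(bin = bin_v, choice = choice_v), FUN = mean)
  n <- aggregate(top_v, by = list(bin = bin_v, choice = choice_v), FUN = length)
  out <- data.frame(bin = agg$bin, choice = agg$choice,
                    proportion = agg$x, n = n$x, stringsAsFactors = FALSE)
  out[order(out$choice, out$bin), ]
}
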