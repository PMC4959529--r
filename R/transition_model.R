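# Saturated log-linear model of the 24 common transition frequencies.
#
# The baseline design has one column per coefficient: an intercept; seven
# fixation-frequency terms coding the destination payoff (own, top, left and
# their interactions, each +/-1); eight within-vs-between-cell adjustments
# (the same eight terms multiplied by +1 for within-cell transitions and -1
# otherwise); and eight row-vs-column adjustments (multiplied by +1 for
# within-column transitions, -1 for within-row, 0 for within-cell). The
# 24x24 matrix is full rank, so the per-participant fit is exact.

.base_terms <- function(to) {
  lab <- payoff_labels()
  own <- ifelse(lab$owner[to] == "self", 1, -1)
  top <- ifelse(lab$row[to] == "top", 1, -1)
  left <- ifelse(lab$col[to] == "left", 1, -1)
  cbind(intercept = 1, own = own, top = top, left = left,
        own_top = own * top, own_left = own * left, top_left = top * left,
        own_top_left = own * top * left)
}

#' Build the transition design matrix
#'
#' @param scheme `"baseline"` for the saturated 24x24 design over the common
#'   transitions; `"game"` extends every baseline column with interactions
#'   with the two payoff differences and their product, each scaled so a
#'   coefficient is the effect of a difference moving from its minimum to
#'   its maximum (rows are then transition x difference-pair combinations);
#'   `"gaze_bias"` crosses the baseline with half-of-trial, choice, and
#'   their interaction (+/-1 coded; rows are transition x half x choice).
#' @param diff_values Difference values spanned by the game scheme.
#' @return List with `X` (design matrix), `rows` (data frame describing each
#'   row) and `terms` (column names).
#' @export
build_transition_design <- function(scheme = c("baseline", "game", "gaze_bias"),
                                    diff_values = c(-3, -1, 1, 3)) {
  scheme <- match.arg(scheme)
  ct <- common_transitions()
  B <- .base_terms(ct$to)
  within_cell <- ifelse(ct$category == "within_cell", 1, -1)
  axis <- ifelse(ct$category == "within_cell", 0,
                 ifelse(ct$category == "within_column", 1, -1))
  W <- B * within_cell
  colnames(W) <- paste0("cell_", colnames(B))
  R <- B * axis
  colnames(R) <- paste0("axis_", colnames(B))
  X24 <- cbind(B, W, R)
  if (scheme == "baseline") {
    return(list(X = X24, rows = ct, terms = colnames(X24)))
  }
  if (scheme == "game") {
    span <- max(diff_values) - min(diff_values)
    pairs <- expand.grid(d_right = sort(diff_values), d_left = sort(diff_values),
                         KEEP.OUT.ATTRS = FALSE)
    rows <- cbind(pairs[rep(seq_len(nrow(pairs)), each = nrow(ct)), , drop = FALSE],
                  ct[rep(seq_len(nrow(ct)), times = nrow(pairs)), , drop = FALSE])
    rownames(rows) <- NULL
    g1 <- rows$d_left / span
    g2 <- rows$d_right / span
    base_rows <- X24[rep(seq_len(nrow(ct)), times = nrow(pairs)), ]
    X <- cbind(base_rows,
               base_rows * g1, base_rows * g2, base_rows * (g1 * g2))
    colnames(X) <- c(colnames(X24), paste0(colnames(X24), ":dL"),
                     paste0(colnames(X24), ":dR"), paste0(colnames(X24), ":dLxdR"))
    return(list(X = X, rows = rows, terms = colnames(X)))
  }
  # gaze_bias: transition x half x choice, +/-1 coding (second half = +1,
  # top choice = +1)
  strata <- expand.grid(choice = c("bottom", "top"), half = c("first", "second"),
                        KEEP.OUT.ATTRS = FALSE)
  rows <- do.call(rbind, lapply(seq_len(nrow(strata)), function(i) {
    cbind(ct, half = strata$half[i], choice = strata$choice[i])
  }))
  h <- ifelse(rows$half == "second", 1, -1)
  c2 <- ifelse(rows$choice == "top", 1, -1)
  base_rows <- X24[rep(seq_len(nrow(ct)), times = nrow(strata)), ]
  X <- cbind(base_rows, base_rows * h, base_rows * c2, base_rows * (h * c2))
  colnames(X) <- c(colnames(X24), paste0(colnames(X24), ":half"),
                   paste0(colnames(X24), ":choice"), paste0(colnames(X24), ":halfxchoice"))
  list(X = X, rows = rows, terms = colnames(X))
}

# Order a participant's counts to match design rows; dies on missing cells.
.align_counts <- function(tally, rows) {
  key_cols <- intersect(c("from", "to", "half", "choice", "d_left", "d_right"),
                        names(rows))
  rk <- do.call(paste, rows[, key_cols, drop = FALSE])
  tk <- do.call(paste, tally[, key_cols, drop = FALSE])
  idx <- match(rk, tk)
  if (anyNA(idx)) stop("fit_transition_model: tally is missing design cells; ",
                       "run transition_tally with complete = TRUE and the needed strata")
  tally$count[idx]
}

#' Fit the log-linear transition model
#'
#' Per-participant estimation with geometric-mean aggregation: for the
#' saturated baseline and gaze-bias schemes the coefficient vector solves
#' the square design exactly on log counts, reproducing each participant's
#' cells without error; the game scheme (more cells than coefficients) is
#' fitted by per-participant Poisson regression. Exponentiated coefficients
#' are aggregated across participants as geometric means, and confidence
#' intervals come from a participant-level bootstrap. Participants with a
#' zero count in any modelled cell receive a +0.5 continuity correction on
#' all their cells and are flagged.
#'
#' @param tally Output of [transition_tally()] with the strata the scheme
#'   needs (`half` and `choice` for `"gaze_bias"`; `game` for `"game"`).
#' @param scheme Design scheme, see [build_transition_design()].
#' @param games Games table, required for `scheme = "game"` (maps game_id to
#'   payoff differences).
#' @param n_boot Bootstrap replicates for the intervals (0 to skip).
#' @param conf Confidence level.
#' @return A `transition_model_fit` list: `coefficients` (data frame with
#'   term, section, exp_coefficient, ci_low, ci_high), `per_participant`
#'   (log-scale coefficient matrix), `corrected` (participant ids that
#'   needed the continuity correction), `scheme`.
#' @export
fit_transition_model <- function(tally, scheme = c("baseline", "game", "gaze_bias"),
                                 games = NULL, n_boot = 199, conf = 0.95) {
  scheme <- match.arg(scheme)
  design <- build_transition_design(scheme)
  common <- common_transitions()
  ckey <- paste(common$from, common$to)
  tally <- tally[paste(tally$from, tally$to) %in% ckey, , drop = FALSE]
  if (scheme == "game") {
    if (is.null(games)) stop("fit_transition_model: games required for the game scheme")
    if (!"game_id" %in% names(tally)) stop("tally lacks game_id; stratify by game")
    m <- match(tally$game_id, games$game_id)
    tally$d_left <- games$d_left[m]
    tally$d_right <- games$d_right[m]
    agg_by <- c("participant_id", "d_left", "d_right", "from", "to")
    tally <- aggregate(list(count = tally$count), by = tally[, agg_by], FUN = sum)
  }
  pids <- unique(tally$participant_id)
  corrected <- character(0)
  theta <- matrix(NA_real_, nrow = length(design$terms), ncol = length(pids),
                  dimnames = list(design$terms, pids))
  for (p in seq_along(pids)) {
    tp <- tally[tally$participant_id == pids[p], , drop = FALSE]
    y <- .align_counts(tp, design$rows)
    if (any(y == 0)) {
      y <- y + 0.5
      corrected <- c(corrected, pids[p])
    }
    if (nrow(design$X) == ncol(design$X)) {
      theta[, p] <- solve(design$X, log(y))
    } else {
      fit <- suppressWarnings(glm.fit(design$X, y, family = stats::poisson()))
      theta[, p] <- fit$coefficients
    }
  }
  agg <- rowMeans(theta)
  ci <- matrix(NA_real_, length(agg), 2)
  if (n_boot > 0 && length(pids) > 1) {
    boot <- replicate(n_boot, {
      rowMeans(theta[, sample.int(length(pids), replace = TRUE), drop = FALSE])
    })
    alpha <- (1 - conf) / 2
    ci <- t(apply(boot, 1, quantile, probs = c(alpha, 1 - alpha)))
  }
  section <- ifelse(grepl("^cell_", design$terms), "within_vs_between_cell",
                    ifelse(grepl("^axis_", design$terms), "row_vs_column",
                           "fixation_frequencies"))
  coefs <- data.frame(term = design$terms, section = section,
                      exp_coefficient = exp(agg),
                      ci_low = exp(ci[, 1]), ci_high = exp(ci[, 2]),
                      stringsAsFactors = FALSE)
  structure(list(coefficients = coefs, per_participant = theta,
                 corrected = unique(corrected), scheme = scheme,
                 design = design),
            class = "transition_model_fit")
}

#' @export
print.transition_model_fit <- function(x, ...) {
  cat("Saturated log-linear transition model (", x$scheme, " scheme)\n", sep = "")
  cat(ncol(x$per_participant), "participants;",
      length(x$corrected), "needed the +0.5 continuity correction\n\n")
  print(head(x$coefficients, 12), digits = 3)
  if (nrow(x$coefficients) > 12) cat("...", nrow(x$coefficients) - 12, "more terms\n")
  invisible(x)
}

#' Own-payoff fixation proportion implied by a multiplicative coefficient
#'
#' Under the symmetric multiplicative model, an own-payoff factor `c`
#' multiplies the base fixation frequency for own payoffs and divides it for
#' the other player's, so the implied own-fixation proportion is
#' `c / (c + 1/c)`.
#'
#' @param c Exponentiated own-payoff coefficient (> 0).
#' @return Proportion of fixations on the player's own payoffs.
#' @export
#' @examples
#' own_proportion_from_coef(1.20) # about 0.59
own_proportion_from_coef <- function(c) {
  stopifnot(all(c > 0))
  c / (c + 1 / c)
}
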