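# Gaze processing: screen layout, fixation-to-AOI assignment, counterbalance
# canonicalization, transition taxonomy and tallies, gaze-bias curves.
#
# Screen coordinates are pixels with the origin at the top left. Position
# labels 1-8 index screen locations with the same cell layout as payoff
# labels, odd = the top-left sub-position of a cell. In the canonical frame
# (row player, own payoffs top-left, no swaps) position label == payoff
# label.

#' Construct a screen layout
#'
#' @param screen Width/height in pixels.
#' @param cell_centers 4x2 matrix of cell centers ordered top-left,
#'   top-right, bottom-left, bottom-right.
#' @param corner_offset Offset of the two payoffs from the cell center; the
#'   top-left sub-position sits at `-corner_offset`, the bottom-right at
#'   `+corner_offset`.
#' @param radius AOI radius in pixels; a fixation belongs to a payoff when it
#'   falls within `radius` of its center (boundary inclusive).
#' @return A `gaze_layout` list with `screen`, `centers` (8x2, position
#'   labels 1-8) and `radius`.
#' @export
make_layout <- function(screen = c(1280, 1024),
                        cell_centers = rbind(c(427, 341), c(853, 341),
                                             c(427, 683), c(853, 683)),
                        corner_offset = c(75, 75),
                        radius = 100) {
  centers <- matrix(NA_real_, 8, 2)
  for (cell in 1:4) {
    centers[2 * cell - 1, ] <- cell_centers[cell, ] - corner_offset
    centers[2 * cell, ] <- cell_centers[cell, ] + corner_offset
  }
  layout <- structure(list(screen = screen, centers = centers, radius = radius),
                      class = "gaze_layout")
  validate_layout(layout)
  layout
}

#' @rdname make_layout
#' @export
default_layout <- function() make_layout()

#' Validate a layout
#'
#' Checks that all AOI centers are on-screen and that no two AOIs overlap
#' (pairwise center distance greater than twice the radius), which
#' guarantees every fixation matches at most one payoff.
#'
#' @param layout A `gaze_layout`.
#' @return The layout, invisibly; errors on violation.
#' @export
validate_layout <- function(layout) {
  ctr <- layout$centers
  if (any(ctr[, 1] < 0 | ctr[, 1] > layout$screen[1] |
          ctr[, 2] < 0 | ctr[, 2] > layout$screen[2])) {
    stop("layout: AOI center off-screen")
  }
  d <- as.matrix(stats::dist(ctr))
  diag(d) <- Inf
  if (any(d <= 2 * layout$radius)) {
    stop("layout: AOI circles overlap (center distance <= 2 * radius)")
  }
  invisible(layout)
}

#' Assign fixations to payoff areas of interest
#'
#' A fixation is assigned to a payoff position when it falls within the
#' layout radius (inclusive) of that position's center; the non-overlap
#' invariant makes the assignment unique. Unassigned fixations get `NA`.
#'
#' @param fixations Data frame with at least `x_px` and `y_px`.
#' @param layout A `gaze_layout`.
#' @return `fixations` with an added/overwritten `aoi` column of position
#'   labels 1-8 or `NA`, rows in input order.
#' @export
assign_fixations <- function(fixations, layout = default_layout()) {
  validate_layout(layout)
  ctr <- layout$centers
  d2 <- outer(fixations$x_px, ctr[, 1], "-")^2 + outer(fixations$y_px, ctr[, 2], "-")^2
  hit <- d2 <= layout$radius^2
  idx <- apply(hit, 1, function(h) if (any(h)) which(h)[1] else NA_integer_)
  fixations$aoi <- as.integer(idx)
  fixations
}

# ---- counterbalancing ------------------------------------------------------

.CORNER_SWAP <- c(2L, 1L, 4L, 3L, 6L, 5L, 8L, 7L)
.ROW_SWAP <- c(5L, 6L, 7L, 8L, 1L, 2L, 3L, 4L)
.COL_SWAP <- c(3L, 4L, 1L, 2L, 7L, 8L, 5L, 6L)
.AXIS_SWAP <- c(1L, 2L, 5L, 6L, 3L, 4L, 7L, 8L) # screen transpose of positions

.check_cb <- function(cb) {
  stopifnot(cb$player_axis %in% c("rows", "columns"),
            cb$own_corner %in% c("top_left", "bottom_right"),
            cb$own_color %in% c("green", "blue"),
            cb$row_swapped %in% c(TRUE, FALSE),
            cb$col_swapped %in% c(TRUE, FALSE))
}

#' Map canonical payoff labels to presentation screen positions
#'
#' The canonical frame describes every participant as a row player with own
#' payoffs odd-labelled in the top-left sub-position and unswapped rows and
#' columns. Presentation applies, in order: the axis transpose for column
#' players (their actions are columns, their opponent's rows), the own-corner
#' swap, and the per-trial row/column swaps. Payoff color does not move
#' anything.
#'
#' @param cb A one-row data frame or list with `player_axis`, `own_color`,
#'   `own_corner`, `row_swapped`, `col_swapped`.
#' @return Integer permutation `p` with `p[label]` the screen position.
#' @export
presentation_permutation <- function(cb) {
  .check_cb(cb)
  p <- 1:8
  if (cb$player_axis == "columns") p <- .AXIS_SWAP[p]
  if (cb$own_corner == "bottom_right") p <- .CORNER_SWAP[p]
  if (cb$row_swapped) p <- .ROW_SWAP[p]
  if (cb$col_swapped) p <- .COL_SWAP[p]
  p
}

#' Map a canonical choice to its presentation code
#'
#' Row players respond top/bottom (flipped when rows are swapped); column
#' players respond left/right, with canonical top corresponding to left
#' (flipped when columns are swapped).
#'
#' @param choice `"top"` or `"bottom"` (canonical frame).
#' @param cb Counterbalance state, see [presentation_permutation()].
#' @return Presentation choice code: top/bottom or left/right.
#' @export
choice_to_presentation <- function(choice, cb) {
  .check_cb(cb)
  stopifnot(choice %in% c("top", "bottom"))
  if (cb$player_axis == "rows") {
    out <- if (cb$row_swapped) c(top = "bottom", bottom = "top")[choice] else choice
  } else {
    out <- c(top = "left", bottom = "right")[choice]
    if (cb$col_swapped) out <- c(left = "right", right = "left")[out]
  }
  unname(out)
}

#' Undo counterbalancing: presentation choice to canonical
#' @inheritParams choice_to_presentation
#' @param choice Presentation choice code.
#' @return `"top"` or `"bottom"`.
#' @export
choice_from_presentation <- function(choice, cb) {
  .check_cb(cb)
  if (cb$player_axis == "rows") {
    if (!choice %in% c("top", "bottom")) {
      stop("inconsistent counterbalance state: row player with choice code '", choice, "'")
    }
    if (cb$row_swapped) c(top = "bottom", bottom = "top")[[choice]] else choice
  } else {
    if (!choice %in% c("left", "right")) {
      stop("inconsistent counterbalance state: column player with choice code '", choice, "'")
    }
    ch <- if (cb$col_swapped) c(left = "right", right = "left")[[choice]] else choice
    c(left = "top", right = "bottom")[[ch]]
  }
}

#' Canonicalize trials
#'
#' Re-expresses presentation-frame logs in the canonical frame: AOI position
#' labels become payoff labels via the inverse of
#' [presentation_permutation()], and choices become top/bottom via
#' [choice_from_presentation()]. Counterbalance columns are read from the
#' choice log (`player_axis`, `own_color`, `own_corner`, `row_swapped`,
#' `col_swapped`).
#'
#' @param fixations Fixation log with `participant_id`, `trial_index` and an
#'   `aoi` column of position labels (from [assign_fixations()]).
#' @param choices Choice log with the counterbalance columns and a
#'   presentation-frame `choice`.
#' @return List with canonical `fixations` (aoi = payoff labels) and
#'   `choices` (`choice` in top/bottom).
#' @export
canonicalize_trials <- function(fixations, choices) {
  key_f <- paste(fixations$participant_id, fixations$trial_index)
  key_c <- paste(choices$participant_id, choices$trial_index)
  idx <- match(key_f, key_c)
  if (anyNA(idx)) stop("canonicalize_trials: fixation rows without a matching choice row")
  out_aoi <- fixations$aoi
  canon_choice <- character(nrow(choices))
  for (i in seq_len(nrow(choices))) {
    cb <- choices[i, ]
    perm <- presentation_permutation(cb)     # label -> position
    inv <- order(perm)                       # position -> label
    rows <- which(idx == i)
    a <- fixations$aoi[rows]
    out_aoi[rows] <- ifelse(is.na(a), NA_integer_, inv[a])
    canon_choice[i] <- choice_from_presentation(cb$choice, cb)
  }
  fixations$aoi <- as.integer(out_aoi)
  choices$choice <- canon_choice
  list(fixations = fixations, choices = choices)
}

# ---- transition taxonomy ---------------------------------------------------

#' Classify a transition between payoff labels
#'
#' A transition is described by which of three properties change between the
#' two payoffs: the owner, the player's own action (row), and the other
#' player's action (column). Exactly one change makes a *common* transition
#' (within a cell for an owner change, within a column for an own-action
#' change, within a row for an other-action change); two or more changes make
#' a *rare* transition; no change is a repeat.
#'
#' @param from,to Integer payoff labels 1-8 (vectorized).
#' @return Data frame with `from`, `to`, logical change indicators
#'   (`owner_change`, `own_action_change`, `other_action_change`),
#'   `n_changes`, and `category` in `within_cell`, `within_column`,
#'   `within_row`, `rare`, `repeat`.
#' @export
#' @examples
#' classify_transition(1, 2)$category # within_cell
#' classify_transition(1, 8)$category # rare
classify_transition <- function(from, to) {
  stopifnot(all(from %in% 1:8), all(to %in% 1:8))
  lab <- payoff_labels()
  oc <- lab$owner[from] != lab$owner[to]
  rc <- lab$row[from] != lab$row[to]
  cc <- lab$col[from] != lab$col[to]
  n <- oc + rc + cc
  category <- ifelse(n == 0, "repeat",
    ifelse(n >= 2, "rare",
      ifelse(oc, "within_cell", ifelse(rc, "within_column", "within_row"))))
  data.frame(from = from, to = to, owner_change = oc, own_action_change = rc,
             other_action_change = cc, n_changes = n, category = category,
             stringsAsFactors = FALSE)
}

#' All ordered transitions and their categories
#'
#' @param include_repeats Include the 8 diagonal (repeat) cells.
#' @return Data frame of ordered label pairs with categories; 56 rows without
#'   repeats, of which 24 are common and 32 rare.
#' @export
transition_classes <- function(include_repeats = FALSE) {
  grid <- expand.grid(to = 1:8, from = 1:8, KEEP.OUT.ATTRS = FALSE)[, c("from", "to")]
  out <- classify_transition(grid$from, grid$to)
  if (!include_repeats) out <- out[out$from != out$to, ]
  rownames(out) <- NULL
  out
}

#' The 24 common ordered transitions
#' @return Data frame `from`, `to`, `category` in a fixed order (used as the
#'   row order of the saturated transition design).
#' @export
common_transitions <- function() {
  tc <- transition_classes()
  tc <- tc[tc$category %in% c("within_cell", "within_column", "within_row"),
           c("from", "to", "category")]
  tc <- tc[order(match(tc$category, c("within_cell", "within_column", "within_row")),
                 tc$from, tc$to), ]
  rownames(tc) <- NULL
  tc
}

# Collapse consecutive fixations in the same AOI into single gazes; NA AOIs
# break the sequence. Returns the gaze label sequence(s) as a list split by
# NA runs.
.gaze_runs <- function(aoi, collapse_repeats = TRUE) {
  segs <- split(aoi, cumsum(is.na(aoi)))
  segs <- lapply(segs, function(s) s[!is.na(s)])
  segs <- Filter(function(s) length(s) > 0, segs)
  if (collapse_repeats) segs <- lapply(segs, function(s) s[c(TRUE, diff(s) != 0)])
  segs
}

#' Tally ordered gaze transitions
#'
#' Counts ordered transitions between consecutive distinct-AOI gazes within
#' each trial, per participant. Consecutive fixations on the same payoff are
#' collapsed into one gaze by default (repeats are then never counted);
#' unlabelled fixations break the sequence. A trial contributing `n` labelled
#' gazes contributes `n - 1` transitions.
#'
#' @param fixations Canonical fixation log (`participant_id`, `trial_index`,
#'   `aoi`; rows in fixation order within trial).
#' @param choices Canonical choice log; required when stratifying by
#'   `"choice"`.
#' @param strata Optional character subset of `c("half", "choice", "game")`.
#'   `"half"` splits each trial's gaze sequence at its midpoint (a middle
#'   gaze goes to the second half; a transition belongs to the half of its
#'   destination gaze).
#' @param collapse_repeats Collapse same-AOI runs before counting.
#' @param complete Return all 56 ordered cells (64 with repeats allowed)
#'   per participant/stratum, zero-filled.
#' @return Data frame `participant_id`, stratum columns, `from`, `to`,
#'   `count`, with attribute `n_repeats` (repeat transitions seen when not
#'   collapsing; 0 otherwise).
#' @export
transition_tally <- function(fixations, choices = NULL, strata = NULL,
                             collapse_repeats = TRUE, complete = TRUE) {
  if (!is.null(strata)) {
    stopifnot(all(strata %in% c("half", "choice", "game")))
    if ("choice" %in% strata && is.null(choices)) {
      stop("transition_tally: choices required for choice stratification")
    }
  }
  trial_key <- paste(fixations$participant_id, fixations$trial_index)
  trials <- split(seq_len(nrow(fixations)), trial_key)
  recs <- list(); n_repeats <- 0L
  for (rows in trials) {
    pid <- fixations$participant_id[rows[1]]
    tix <- fixations$trial_index[rows[1]]
    gid <- if ("game_id" %in% names(fixations)) fixations$game_id[rows[1]] else NA
    segs <- .gaze_runs(fixations$aoi[rows], collapse_repeats)
    gaze <- unlist(segs)
    n_all <- length(gaze)
    pos <- 0L
    for (s in segs) {
      if (length(s) < 2) { pos <- pos + length(s); next }
      from <- s[-length(s)]; to <- s[-1]
      if (!collapse_repeats) n_repeats <- n_repeats + sum(from == to)
      dest_pos <- pos + seq_along(to) + 1L
      recs[[length(recs) + 1L]] <- data.frame(
        participant_id = pid, trial_index = tix, game_id = gid,
        from = from, to = to,
        half = ifelse(dest_pos <= floor(n_all / 2), "first", "second"),
        stringsAsFactors = FALSE)
      pos <- pos + length(s)
    }
  }
  if (length(recs) == 0) {
    empty <- data.frame(participant_id = character(0), from = integer(0),
                        to = integer(0), count = integer(0))
    attr(empty, "n_repeats") <- 0L
    return(empty)
  }
  tr <- do.call(rbind, recs)
  if (!is.null(choices)) {
    key <- paste(tr$participant_id, tr$trial_index)
    ckey <- paste(choices$participant_id, choices$trial_index)
    tr$choice <- choices$choice[match(key, ckey)]
  }
  by_cols <- c("participant_id",
               if ("game" %in% strata) "game_id",
               if ("half" %in% strata) "half",
               if ("choice" %in% strata) "choice")
  agg <- aggregate(list(count = rep(1L, nrow(tr))),
                   by = tr[, c(by_cols, "from", "to"), drop = FALSE], FUN = sum)
  if (complete) {
    cells <- transition_classes(include_repeats = !collapse_repeats)[, c("from", "to")]
    groups <- unique(agg[, by_cols, drop = FALSE])
    full <- merge(groups, cells, by = NULL)
    agg <- merge(full, agg, by = c(by_cols, "from", "to"), all.x = TRUE)
    agg$count[is.na(agg$count)] <- 0L
  }
  agg <- agg[do.call(order, agg[, c(by_cols, "from", "to")]), ]
  rownames(agg) <- NULL
  attr(agg, "n_repeats") <- n_repeats
  agg
}

#' Gaze-bias curve
#'
#' Bins each trial's labelled fixations into `n_bins` time bins by fractional
#' position `(index - 0.5) / n` and reports, per bin and per choice stratum,
#' the proportion of fixations on a given side of the display. With
#' `dimension = "top"` this is the classic gaze-bias (cascade) curve: an
#' emerging late bias toward the chosen row.
#'
#' @param fixations Canonical fixation log with `aoi`.
#' @param choices Canonical choice log (`choice` in top/bottom).
#' @param n_bins Number of bins (default deciles).
#' @param dimension `"top"` (row), `"own"` (payoff owner) or `"left"`
#'   (column).
#' @return Data frame `bin`, `choice`, `proportion`, `n`; trials without
#'   labelled fixations are excluded and counted in attribute `n_excluded`.
#' @export
gaze_bias_curve <- function(fixations, choices, n_bins = 10, dimension = c("top", "own", "left")) {
  dimension <- match.arg(dimension)
  lab <- payoff_labels()
  side <- switch(dimension,
    top = lab$row == "top", own = lab$owner == "self", left = lab$col == "left")
  key <- paste(fixations$participant_id, fixations$trial_index)
  ckey <- paste(choices$participant_id, choices$trial_index)
  fixations$choice <- choices$choice[match(key, ckey)]
  ok <- !is.na(fixations$aoi)
  n_excluded <- length(unique(key)) - length(unique(key[ok]))
  f <- fixations[ok, ]
  fkey <- paste(f$participant_id, f$trial_index)
  pos <- stats::ave(seq_along(fkey), fkey, FUN = seq_along)
  n_in_trial <- stats::ave(seq_along(fkey), fkey, FUN = length)
  bin <- ceiling(((pos - 0.5) / n_in_trial) * n_bins)
  on_side <- side[f$aoi]
  agg <- aggregate(on_side, by = list(bin = bin, choice = f$choice), FUN = mean)
  cnt <- aggregate(on_side, by = list(bin = bin, choice = f$choice), FUN = length)
  out <- data.frame(bin = agg$bin, choice = agg$choice, proportion = agg$x,
                    n = cnt$x, stringsAsFactors = FALSE)
  out <- out[order(out$choice, out$bin), ]
  rownames(out) <- NULL
  attr(out, "n_excluded") <- n_excluded
  out
}

#' Per-participant gaze summary statistics
#'
#' @param fixations Canonical fixation log with `aoi` and `duration_ms`.
#' @param choices Canonical choice log (defines the trial count).
#' @return Data frame per participant plus a pooled row: trials, labelled
#'   fixations per trial, mean fixation duration (ms), proportion of
#'   fixations on own payoffs, and the common-transition share
#'   common / (common + rare) with repeats excluded.
#' @export
gaze_summary_stats <- function(fixations, choices) {
  lab <- payoff_labels()
  tally <- transition_tally(fixations, complete = FALSE)
  tcat <- classify_transition(tally$from, tally$to)$category
  one <- function(pid) {
    f <- fixations[fixations$participant_id == pid & !is.na(fixations$aoi), ]
    n_trials <- sum(choices$participant_id == pid)
    tl <- tally[tally$participant_id == pid, ]
    cat <- tcat[tally$participant_id == pid]
    common <- sum(tl$count[cat %in% c("within_cell", "within_column", "within_row")])
    rare <- sum(tl$count[cat == "rare"])
    data.frame(
      participant_id = pid, n_trials = n_trials,
      fixations_per_trial = nrow(f) / max(n_trials, 1),
      mean_duration_ms = mean(f$duration_ms),
      own_proportion = mean(lab$owner[f$aoi] == "self"),
      common_share = if (common + rare > 0) common / (common + rare) else NA_real_,
      stringsAsFactors = FALSE)
  }
  per <- do.call(rbind, lapply(unique(choices$participant_id), one))
  f_all <- fixations[!is.na(fixations$aoi), ]
  cat_all <- tcat
  common <- sum(tally$count[cat_all %in% c("within_cell", "within_column", "within_row")])
  rare <- sum(tally$count[cat_all == "rare"])
  pooled <- data.frame(
    participant_id = "(pooled)", n_trials = nrow(choices),
    fixations_per_trial = nrow(f_all) / nrow(choices),
    mean_duration_ms = mean(f_all$duration_ms),
    own_proportion = mean(lab$owner[f_all$aoi] == "self"),
    common_share = if (common + rare > 0) common / (common + rare) else NA_real_,
    stringsAsFactors = FALSE)
  rbind(per, pooled)
}
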