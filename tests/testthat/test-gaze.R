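test_that("fixations are assigned by the inclusive 100-px radius rule", {
  layout <- default_layout()
  ctr3 <- layout$centers[3, ]
  fx <- data.frame(
    x_px = c(ctr3[1], ctr3[1] + 99, ctr3[1] + 101, ctr3[1] + 100, 5),
    y_px = c(ctr3[2], ctr3[2], ctr3[2], ctr3[2], 5))
  out <- assign_fixations(fx, layout)
  expect_equal(out$aoi, c(3L, 3L, NA, 3L, NA)) # boundary inclusive at <= radius
})

test_that("overlapping layouts are rejected before any assignment", {
  expect_error(make_layout(cell_centers = rbind(c(300, 300), c(450, 300),
                                                c(300, 700), c(450, 700))),
               "overlap")
  expect_error(make_layout(cell_centers = rbind(c(-200, 300), c(853, 341),
                                                c(427, 683), c(853, 683))),
               "off-screen")
})

test_that("canonicalization inverts every counterbalance state exactly", {
  set.seed(11)
  cbs <- all_cb_states()
  for (i in seq_len(nrow(cbs))) {
    cb <- cbs[i, ]
    aoi <- sample(1:8, 15, replace = TRUE)
    choice <- sample(c("top", "bottom"), 1)
    perm <- presentation_permutation(cb)
    fx <- data.frame(participant_id = "p1", trial_index = 1, aoi = perm[aoi])
    ch <- cbind(data.frame(participant_id = "p1", trial_index = 1,
                           choice = choice_to_presentation(choice, cb),
                           stringsAsFactors = FALSE), cb)
    canon <- canonicalize_trials(fx, ch)
    expect_equal(canon$fixations$aoi, aoi)
    expect_equal(canon$choices$choice, choice)
  }
})

test_that("specific counterbalance states produce the documented relabellings", {
  id <- data.frame(player_axis = "rows", own_color = "green",
                   own_corner = "top_left", row_swapped = FALSE, col_swapped = FALSE)
  expect_equal(presentation_permutation(id), 1:8)
  rs <- id; rs$row_swapped <- TRUE
  expect_equal(presentation_permutation(rs), c(5L, 6L, 7L, 8L, 1L, 2L, 3L, 4L))
  expect_equal(choice_to_presentation("top", rs), "bottom")
  colp <- id; colp$player_axis <- "columns"
  expect_equal(presentation_permutation(colp), c(1L, 2L, 5L, 6L, 3L, 4L, 7L, 8L))
  expect_equal(choice_to_presentation("top", colp), "left")
  # inconsistent state: column player with a vertical choice code
  expect_error(choice_from_presentation("top", colp), "inconsistent")
  expect_error(choice_from_presentation("left", id), "inconsistent")
})

test_that("the transition taxonomy matches brute-force enumeration of ordered pairs", {
  tc <- transition_classes()
  expect_equal(nrow(tc), 56)
  expect_equal(sum(tc$n_changes == 1), 24)
  expect_equal(sum(tc$n_changes >= 2), 32)
  expect_equal(as.vector(table(tc$category)[c("within_cell", "within_column", "within_row")]),
               c(8L, 8L, 8L))
  expect_equal(classify_transition(1, 2)$category, "within_cell")
  expect_equal(classify_transition(1, 5)$category, "within_column")
  expect_equal(classify_transition(1, 3)$category, "within_row")
  expect_equal(classify_transition(1, 8)$category, "rare")
  expect_equal(classify_transition(1, 1)$category, "repeat")
  expect_equal(nrow(common_transitions()), 24)
})

test_that("transition tallies conserve counts and respect strata", {
  tr <- make_canonical_trial(c(1, 3, 1), "top")
  tal <- transition_tally(tr$fixations, complete = FALSE)
  expect_equal(sum(tal$count), 2)
  expect_equal(tal$count[tal$from == 1 & tal$to == 3], 1)
  expect_equal(tal$count[tal$from == 3 & tal$to == 1], 1)
  # a trial of n labelled gazes contributes n - 1 transitions
  set.seed(12)
  aoi <- sample(1:8, 30, replace = TRUE)
  aoi <- aoi[c(TRUE, diff(aoi) != 0)]
  tr2 <- make_canonical_trial(aoi, "bottom")
  tal2 <- transition_tally(tr2$fixations, complete = FALSE)
  expect_equal(sum(tal2$count), length(aoi) - 1)
  # repeats collapse by default; NA breaks the sequence
  tr3 <- make_canonical_trial(c(1, 1, 3, NA, 5, 7), "top")
  tal3 <- transition_tally(tr3$fixations, complete = FALSE)
  expect_equal(sum(tal3$count), 2) # 1->3 and 5->7
  # strata sum to the unstratified tally
  set.seed(13)
  fixs <- do.call(rbind, lapply(1:6, function(t) {
    make_canonical_trial(sample(1:8, 11, TRUE), "top", trial = t)$fixations
  }))
  chos <- do.call(rbind, lapply(1:6, function(t) {
    make_canonical_trial(1, sample(c("top", "bottom"), 1), trial = t)$choices
  }))
  flat <- transition_tally(fixs)
  strat <- transition_tally(fixs, chos, strata = c("half", "choice"))
  agg <- aggregate(count ~ from + to, data = strat, FUN = sum)
  m <- merge(flat, agg, by = c("from", "to"))
  expect_equal(m$count.x, m$count.y)
})

test_that("gaze-bias curves expose constructed and null patterns", {
  # last 30% of fixations on the chosen row
  set.seed(14)
  trials <- lapply(1:40, function(t) {
    choice <- if (t %% 2 == 0) "top" else "bottom"
    n <- 20
    head_part <- sample(1:8, 14, replace = TRUE)
    tail_part <- if (choice == "top") sample(1:4, 6, TRUE) else sample(5:8, 6, TRUE)
    make_canonical_trial(c(head_part, tail_part), choice, trial = t)
  })
  fixs <- do.call(rbind, lapply(trials, `[[`, "fixations"))
  chos <- do.call(rbind, lapply(trials, `[[`, "choices"))
  cv <- gaze_bias_curve(fixs, chos)
  expect_equal(cv$proportion[cv$choice == "top" & cv$bin == 10], 1.0)
  expect_equal(cv$proportion[cv$choice == "bottom" & cv$bin == 10], 0.0)
  # uniform gaze: all bins near 0.5
  set.seed(15)
  trials0 <- lapply(1:60, function(t) {
    make_canonical_trial(sample(1:8, 20, TRUE), sample(c("top", "bottom"), 1), trial = t)
  })
  cv0 <- gaze_bias_curve(do.call(rbind, lapply(trials0, `[[`, "fixations")),
                         do.call(rbind, lapply(trials0, `[[`, "choices")))
  expect_true(all(abs(cv0$proportion - 0.5) < 3 * sqrt(0.25 / cv0$n)))
})

test_that("summary statistics report durations, own proportion and common share", {
  tr <- make_canonical_trial(c(1, 3, 5, 7, 1), "top")
  ss <- gaze_summary_stats(tr$fixations, tr$choices)
  pooled <- ss[ss$participant_id == "(pooled)", ]
  expect_equal(pooled$own_proportion, 1.0)
  expect_equal(pooled$mean_duration_ms, 290)
  expect_equal(pooled$fixations_per_trial, 5)
  # common share is common / (common + rare), repeats excluded
  tr2 <- make_canonical_trial(c(1, 2, 8, 8, 1), "top") # 1->2 common, 2->8 & 8->1 rare
  ss2 <- gaze_summary_stats(tr2$fixations, tr2$choices)
  expect_equal(ss2$common_share[ss2$participant_id == "(pooled)"], 1 / 3)
})
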