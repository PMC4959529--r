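games64 <- build_game_grid()

test_that("trial features count fixations, transitions and the last-fixation row", {
  tr <- make_canonical_trial(c(1, 3, 5), "top")
  ft <- trial_features(tr$fixations, tr$choices, games64)
  expect_equal(ft$F1, 1); expect_equal(ft$F3, 1); expect_equal(ft$F5, 1)
  expect_equal(ft$fix_diff, 2 - 1)
  expect_equal(ft$T13, 1); expect_equal(ft$T35, 1)
  expect_equal(ft$last_row, -1)
  # accounting identity: between-row balance = [last on top] - [first on top]
  set.seed(41)
  for (r in 1:25) {
    aoi <- sample(1:8, sample(5:15, 1), replace = TRUE)
    aoi <- aoi[c(TRUE, diff(aoi) != 0)]
    tr <- make_canonical_trial(aoi, "top", trial = r)
    ft <- trial_features(tr$fixations, tr$choices, games64)
    lab_top <- function(a) a <= 4
    expect_equal(ft$trans_row_diff,
                 as.integer(lab_top(aoi[length(aoi)])) - as.integer(lab_top(aoi[1])))
  }
})

test_that("the improper transition balance is antisymmetric under a row mirror", {
  set.seed(42)
  aoi <- sample(1:8, 12, replace = TRUE)
  aoi <- aoi[c(TRUE, diff(aoi) != 0)]
  mirror <- c(5:8, 1:4)
  t1 <- make_canonical_trial(aoi, "top")
  t2 <- make_canonical_trial(mirror[aoi], "bottom")
  f1 <- trial_features(t1$fixations, t1$choices, games64)
  f2 <- trial_features(t2$fixations, t2$choices, games64)
  expect_equal(f2$trans_row_diff, -f1$trans_row_diff)
  expect_equal(f2$fix_diff, -f1$fix_diff)
})

test_that("intercept model accuracy is the majority share and its R2 is zero", {
  set.seed(43)
  trials <- lapply(1:50, function(t) {
    make_canonical_trial(sample(1:8, 8, TRUE),
                         if (t <= 30) "top" else "bottom", trial = t)
  })
  ft <- trial_features(do.call(rbind, lapply(trials, `[[`, "fixations")),
                       do.call(rbind, lapply(trials, `[[`, "choices")), games64)
  d <- build_choice_design(ft, "intercept")
  fit <- fit_choice_model(d$X, d$y, d$clusters, "intercept")
  expect_equal(fit$accuracy, 0.6)
  expect_equal(fit$nagelkerke_r2, 0, tolerance = 1e-10)
})

test_that("a generating logistic slope on the fixation balance is recovered", {
  set.seed(44)
  beta <- 0.8
  trials <- lapply(1:600, function(t) {
    aoi <- sample(1:8, 12, replace = TRUE)
    fd <- sum(aoi <= 4) - sum(aoi > 4)
    choice <- if (runif(1) < plogis(beta * fd)) "top" else "bottom"
    make_canonical_trial(aoi, choice, participant = paste0("p", (t %% 6) + 1), trial = t)
  })
  ft <- trial_features(do.call(rbind, lapply(trials, `[[`, "fixations")),
                       do.call(rbind, lapply(trials, `[[`, "choices")), games64)
  d <- build_choice_design(ft, "improper_fixations")
  fit <- fit_choice_model(d$X, d$y, d$clusters)
  # refit with glm to get a CI for the slope
  m <- glm(d$y ~ ft$fix_diff, family = binomial)
  se <- summary(m)$coefficients["ft$fix_diff", "Std. Error"]
  expect_lt(abs(fit$coefficients[["fix_diff"]] - beta), 1.96 * se + 0.05)
  expect_false(fit$separation)
})

test_that("separated data falls back to a flagged ridge fit instead of failing", {
  trials <- lapply(1:40, function(t) {
    aoi <- if (t %% 2 == 0) c(1, 3, 1, 3) else c(5, 7, 5, 7)
    make_canonical_trial(aoi, if (t %% 2 == 0) "top" else "bottom", trial = t)
  })
  ft <- trial_features(do.call(rbind, lapply(trials, `[[`, "fixations")),
                       do.call(rbind, lapply(trials, `[[`, "choices")), games64)
  d <- build_choice_design(ft, "improper_fixations")
  fit <- fit_choice_model(d$X, d$y, d$clusters)
  expect_true(fit$separation)
  expect_equal(fit$accuracy, 1.0)
})

test_that("nesting-corrected BIC penalizes parameters by cluster count", {
  expect_equal(bic_nested(-100, 0, 10), 200)
  expect_equal(bic_nested(-100, 5, 54), 200 + 5 * log(54))
  expect_gt(bic_nested(-100, 6, 54), bic_nested(-100, 5, 54))
})

test_that("Nagelkerke R2 matches its closed form and bounds", {
  expect_equal(nagelkerke_r2(-50, -50, 100), 0)
  expect_equal(nagelkerke_r2(0, -69.3, 100), 1, tolerance = 1e-3)
  # frozen oracle: logistic fit on a 10-observation toy set
  y <- c(0, 0, 0, 1, 0, 1, 1, 0, 1, 1); x <- 1:10
  m1 <- glm(y ~ x, family = binomial)
  m0 <- glm(y ~ 1, family = binomial)
  expect_equal(nagelkerke_r2(as.numeric(logLik(m1)), as.numeric(logLik(m0)), 10),
               0.4377645872, tolerance = 1e-8)
  expect_error(nagelkerke_r2(-60, -50, 100), "ll_model")
})

test_that("variance partitioning is additive and flags suppression", {
  vp <- variance_partition(0.56, 0.27, 0.66)
  expect_equal(vp$shared, 0.17)
  expect_equal(vp$unique_a, 0.39)
  expect_equal(vp$unique_b, 0.10)
  expect_equal(vp$shared + vp$unique_a + vp$unique_b, 0.66)
  vp2 <- variance_partition(0.5, 0.3, 0.8)
  expect_equal(vp2$shared, 0)
  expect_false(vp2$suppression)
  expect_error(variance_partition(0.2, 0.2, 0.9), "exceeds")
})

test_that("entering the last fixation first shrinks the transition coefficients", {
  # choice is purely the last fixation's row
  set.seed(45)
  trials <- lapply(1:300, function(t) {
    aoi <- sample(1:8, 10, replace = TRUE)
    aoi <- aoi[c(TRUE, diff(aoi) != 0)]
    choice <- if (aoi[length(aoi)] <= 4) "top" else "bottom"
    make_canonical_trial(aoi, choice, participant = paste0("p", (t %% 4) + 1), trial = t)
  })
  ft <- trial_features(do.call(rbind, lapply(trials, `[[`, "fixations")),
                       do.call(rbind, lapply(trials, `[[`, "choices")), games64)
  lf <- last_fixation_correction(ft)
  expect_equal(lf$uncorrected$n_obs, lf$corrected$n_obs)
  tn <- grep("^T", names(lf$uncorrected$coefficients), value = TRUE)
  size_un <- mean(abs(lf$uncorrected$coefficients[tn]), na.rm = TRUE)
  size_co <- mean(abs(lf$corrected$coefficients[tn]), na.rm = TRUE)
  expect_lt(size_co, size_un)
})

test_that("constrained single-coefficient models never beat their parents in likelihood", {
  set.seed(46)
  cfg <- cohort_config(n_participants = 6,
                       agent_mix = c(level0 = 0, level1 = 0, level2 = 0, accumulator = 1),
                       seed = 46)
  coh <- generate_cohort(cfg)
  canon <- canonicalize_trials(assign_fixations(coh$fixations, cfg$layout), coh$choices)
  ft <- trial_features(canon$fixations, canon$choices, coh$games)
  suite <- choice_model_suite(ft, c("fixations", "improper_fixations",
                                    "transitions", "improper_transitions"))
  fits <- attr(suite, "fits")
  expect_lte(fits$improper_fixations$loglik, fits$fixations$loglik + 1e-6)
  expect_lte(fits$improper_transitions$loglik, fits$transitions$loglik + 1e-6)
  expect_lte(fits$improper_fixations$accuracy, fits$fixations$accuracy + 1e-9)
  expect_lte(fits$improper_transitions$accuracy, fits$transitions$accuracy + 1e-9)
})
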