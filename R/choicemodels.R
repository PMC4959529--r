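# Logistic choice models: fitting the trial-level choice from payoff
# attributes, fixation counts, transition counts, or the last fixation,
# with in-sample accuracy, nesting-corrected BIC, Nagelkerke R-squared and
# variance partitioning.

.t_names <- function() {
  tc <- transition_classes()
  paste0("T", tc$from, tc$to)
}

#' Trial-level features for choice modelling
#'
#' Builds one row per trial from canonical logs: the choice (1 = top), the
#' game's payoff differences and base configuration, per-AOI fixation counts
#' `F1`-`F8`, ordered transition counts `T12`-`T87` (56 columns, repeats
#' collapsed), the row of the last labelled fixation (`last_row`, +1 top /
#' -1 bottom), and two improper single-column summaries: `fix_diff`, the
#' top-minus-bottom fixation count, and `trans_row_diff`, the count of
#' between-row transitions ending on the top row minus those ending on the
#' bottom row.
#'
#' @param fixations Canonical fixation log with `aoi`.
#' @param choices Canonical choice log with `choice` (top/bottom).
#' @param games Games data frame.
#' @return Data frame of features; trials with no labelled fixation have NA
#'   gaze features (dropped by gaze-based designs, with a count recorded by
#'   the design builder).
#' @export
trial_features <- function(fixations, choices, games) {
  lab <- payoff_labels()
  gm <- match(choices$game_id, games$game_id)
  if (anyNA(gm)) stop("trial_features: choice rows reference unknown game_id")
  n <- nrow(choices)
  Fm <- matrix(0L, n, 8, dimnames = list(NULL, paste0("F", 1:8)))
  t_names <- .t_names()
  Tm <- matrix(0L, n, length(t_names), dimnames = list(NULL, t_names))
  last_row <- rep(NA_real_, n)
  key <- paste(fixations$participant_id, fixations$trial_index)
  ckey <- paste(choices$participant_id, choices$trial_index)
  rows_by_trial <- split(seq_len(nrow(fixations)), factor(key, levels = unique(ckey)))
  for (i in seq_len(n)) {
    rows <- rows_by_trial[[ckey[i]]]
    if (is.null(rows)) next
    a <- fixations$aoi[rows]
    a <- a[!is.na(a)]
    if (length(a) == 0) next
    Fm[i, ] <- tabulate(a, nbins = 8)
    last_row[i] <- ifelse(lab$row[a[length(a)]] == "top", 1, -1)
    segs <- .gaze_runs(fixations$aoi[rows], collapse_repeats = TRUE)
    for (s in segs) {
      if (length(s) < 2) next
      nm <- paste0("T", s[-length(s)], s[-1])
      tb <- table(nm)
      Tm[i, names(tb)] <- Tm[i, names(tb)] + as.integer(tb)
    }
  }
  top_cols <- paste0("T", rep(5:8, each = 4), rep(1:4, times = 4))
  bot_cols <- paste0("T", rep(1:4, each = 4), rep(5:8, times = 4))
  out <- data.frame(
    participant_id = choices$participant_id,
    trial_index = choices$trial_index,
    game_id = choices$game_id,
    choice = as.integer(choices$choice == "top"),
    d_left = games$d_left[gm], d_right = games$d_right[gm],
    base_config = games$base_config[gm],
    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(Fm), as.data.frame(Tm))
  out$last_row <- last_row
  out$fix_diff <- rowSums(Fm[, 1:4, drop = FALSE]) - rowSums(Fm[, 5:8, drop = FALSE])
  out$trans_row_diff <- rowSums(Tm[, top_cols, drop = FALSE]) -
    rowSums(Tm[, bot_cols, drop = FALSE])
  out$has_gaze <- !is.na(last_row)
  out
}

.CHOICE_MODEL_NAMES <- c("intercept", "attributes", "attributes_simple",
                         "fixations", "attributes_fixations", "last_fixation",
                         "transitions", "transitions_attributes",
                         "transitions_lastfix", "improper_fixations",
                         "improper_transitions")

#' Build the design of a named choice model
#'
#' Model recipes: `intercept`; `attributes` (payoff differences as factors,
#' base configuration, and all interactions -- one coefficient per game);
#' `attributes_simple` (numeric `d_left + d_right`); `fixations`
#' (`F1`-`F8`); `attributes_fixations`; `last_fixation` (`last_row`);
#' `transitions` (all 56 ordered counts); `transitions_attributes`;
#' `transitions_lastfix` (last fixation entered alongside the transition
#' counts, correcting them for the forced relation between the between-row
#' transition balance and the final fixation); `improper_fixations` and
#' `improper_transitions` (the single-column constrained summaries).
#'
#' @param features Output of [trial_features()].
#' @param model One of the names above.
#' @return List with `X` (model matrix incl. intercept), `y`, `clusters`
#'   (participant ids), `model`, and `n_dropped` (trials without gaze
#'   excluded from gaze-based designs).
#' @export
build_choice_design <- function(features, model = .CHOICE_MODEL_NAMES) {
  model <- match.arg(model)
  gaze_based <- !model %in% c("intercept", "attributes", "attributes_simple")
  f <- if (gaze_based) features[features$has_gaze, , drop = FALSE] else features
  n_dropped <- nrow(features) - nrow(f)
  tcols <- paste(.t_names(), collapse = " + ")
  fml <- switch(model,
    intercept = ~ 1,
    attributes = ~ factor(d_left) * factor(d_right) * factor(base_config),
    attributes_simple = ~ d_left + d_right,
    fixations = ~ F1 + F2 + F3 + F4 + F5 + F6 + F7 + F8,
    attributes_fixations = ~ factor(d_left) * factor(d_right) * factor(base_config) +
      F1 + F2 + F3 + F4 + F5 + F6 + F7 + F8,
    last_fixation = ~ last_row,
    transitions = stats::as.formula(paste("~", tcols)),
    transitions_attributes = stats::as.formula(
      paste("~ factor(d_left) * factor(d_right) * factor(base_config) +", tcols)),
    transitions_lastfix = stats::as.formula(paste("~ last_row +", tcols)),
    improper_fixations = ~ fix_diff,
    improper_transitions = ~ trans_row_diff)
  X <- stats::model.matrix(fml, data = f)
  list(X = X, y = f$choice, clusters = f$participant_id, model = model,
       n_dropped = n_dropped)
}

#' Nesting-corrected Bayesian information criterion
#'
#' BIC with the effective sample size taken as the number of clusters
#' (participants) rather than the number of observations, a policy for
#' choices nested within subjects: `-2 loglik + n_params log(n_clusters)`.
#'
#' @param loglik Model log-likelihood.
#' @param n_params Number of estimated parameters.
#' @param n_clusters Number of clusters (>= 1).
#' @export
bic_nested <- function(loglik, n_params, n_clusters) {
  stopifnot(n_clusters >= 1)
  -2 * loglik + n_params * log(n_clusters)
}

#' Nagelkerke pseudo R-squared
#'
#' `(1 - exp(2 (ll_null - ll_model) / n)) / (1 - exp(2 ll_null / n))`;
#' 0 when the model adds nothing over the null, 1 for a perfect fit.
#'
#' @param ll_model,ll_null Log-likelihoods of the model and of the
#'   null (intercept-only) model on the same data.
#' @param n Number of observations.
#' @export
nagelkerke_r2 <- function(ll_model, ll_null, n) {
  if (ll_model < ll_null - 1e-8) stop("nagelkerke_r2: ll_model < ll_null")
  (1 - exp(2 * (ll_null - ll_model) / n)) / (1 - exp(2 * ll_null / n))
}

# Penalized logistic fallback for separated fits: minimizes the negative
# log-likelihood plus (lambda/2) * sum(beta^2) over non-intercept terms.
.ridge_logistic <- function(X, y, lambda) {
  pen <- c(0, rep(lambda, ncol(X) - 1))
  nll <- function(b) {
    eta <- drop(X %*% b)
    -sum(y * eta - log1p(exp(eta))) + sum(pen * b^2) / 2
  }
  grd <- function(b) {
    p <- plogis(drop(X %*% b))
    -drop(crossprod(X, y - p)) + pen * b
  }
  opt <- optim(rep(0, ncol(X)), nll, grd, method = "BFGS",
               control = list(maxit = 1000))
  opt$par
}

#' Fit a logistic choice model
#'
#' Maximum-likelihood logistic regression with a ridge-penalized fallback
#' under complete separation (flagged, never an error). Reports coefficients,
#' log-likelihood, in-sample classification accuracy at 0.5, the
#' nesting-corrected BIC, and Nagelkerke R-squared against the intercept-only
#' null on the same observations.
#'
#' @param X Model matrix including the intercept column.
#' @param y 0/1 outcomes (1 = top).
#' @param clusters Cluster (participant) id per observation.
#' @param model Label carried through to the output.
#' @param ridge_lambda Penalty used by the separation fallback.
#' @return A `choice_model_fit` list.
#' @export
fit_choice_model <- function(X, y, clusters, model = "custom", ridge_lambda = 1e-2) {
  stopifnot(nrow(X) == length(y), length(clusters) == length(y))
  if (length(unique(y)) < 2) stop("fit_choice_model: outcome has a single class")
  sep_flag <- FALSE
  fit <- suppressWarnings(glm.fit(X, y, family = binomial(),
                                  control = list(maxit = 100)))
  beta <- fit$coefficients
  # complete separation: every fitted probability is numerically 0 or 1 on
  # the correct side, or the IRLS path diverged
  p_hat <- fit$fitted.values
  separated <- all(p_hat[y == 1] > 1 - 1e-6) && all(p_hat[y == 0] < 1e-6)
  if (!fit$converged || anyNA(beta) || any(abs(beta[-1]) > 25) || separated) {
    sep_flag <- TRUE
    keep <- !apply(X, 2, function(col) all(col == col[1])) | colnames(X) == "(Intercept)"
    beta <- rep(0, ncol(X)); names(beta) <- colnames(X)
    beta[keep] <- .ridge_logistic(X[, keep, drop = FALSE], y, ridge_lambda)
  }
  eta <- drop(X %*% ifelse(is.na(beta), 0, beta))
  p <- plogis(eta)
  eps <- 1e-12
  ll <- sum(y * log(pmax(p, eps)) + (1 - y) * log(pmax(1 - p, eps)))
  pbar <- mean(y)
  ll0 <- sum(y * log(pbar) + (1 - y) * log(1 - pbar))
  n_params <- sum(!is.na(fit$coefficients))
  n_clusters <- length(unique(clusters))
  structure(list(
    model = model, coefficients = beta, loglik = ll,
    accuracy = mean((p > 0.5) == (y == 1)),
    bic_nested = bic_nested(ll, n_params, n_clusters),
    nagelkerke_r2 = nagelkerke_r2(ll, ll0, length(y)),
    n_params = n_params, n_obs = length(y), n_clusters = n_clusters,
    loglik_null = ll0, separation = sep_flag), class = "choice_model_fit")
}

#' @export
print.choice_model_fit <- function(x, ...) {
  cat("Logistic choice model '", x$model, "': ", x$n_obs, " trials, ",
      x$n_clusters, " participants\n", sep = "")
  cat(sprintf("  accuracy %.3f | BIC(nested) %.1f | Nagelkerke R2 %.3f | %d params%s\n",
              x$accuracy, x$bic_nested, x$nagelkerke_r2, x$n_params,
              if (x$separation) " | ridge fallback" else ""))
  invisible(x)
}

#' Fit the full suite of choice models
#'
#' @param features Output of [trial_features()].
#' @param models Model names to fit (see [build_choice_design()]).
#' @return Data frame comparing the models (accuracy, nesting-corrected BIC,
#'   Nagelkerke R-squared, parameters, observations), with the fitted
#'   objects in attribute `fits`.
#' @export
choice_model_suite <- function(features, models = .CHOICE_MODEL_NAMES) {
  fits <- lapply(models, function(m) {
    d <- build_choice_design(features, m)
    fit_choice_model(d$X, d$y, d$clusters, model = m)
  })
  names(fits) <- models
  out <- data.frame(
    model = models,
    accuracy = sapply(fits, `[[`, "accuracy"),
    bic = sapply(fits, `[[`, "bic_nested"),
    nagelkerke_r2 = sapply(fits, `[[`, "nagelkerke_r2"),
    n_params = sapply(fits, `[[`, "n_params"),
    n_obs = sapply(fits, `[[`, "n_obs"),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "fits") <- fits
  out
}

#' Partition explained variance between two predictor sets
#'
#' Given pseudo R-squared values for models A, B and the combined model,
#' the shared component is `r2_a + r2_b - r2_ab` and the unique components
#' are the combined value minus the other model's. A negative shared
#' component beyond `tolerance` (suppression) is flagged.
#'
#' @param r2_a,r2_b,r2_ab R-squared of model A, model B, combined model.
#' @param tolerance Slack for the additivity check.
#' @return List with `shared`, `unique_a`, `unique_b`, `suppression`.
#' @export
#' @examples
#' variance_partition(0.56, 0.27, 0.66)$shared # 0.17
variance_partition <- function(r2_a, r2_b, r2_ab, tolerance = 0.02) {
  stopifnot(r2_a >= 0, r2_a <= 1, r2_b >= 0, r2_b <= 1, r2_ab >= 0, r2_ab <= 1)
  if (r2_ab > r2_a + r2_b + tolerance) {
    stop("variance_partition: combined R2 exceeds the sum of the parts beyond tolerance")
  }
  shared <- r2_a + r2_b - r2_ab
  list(shared = shared, unique_a = r2_ab - r2_b, unique_b = r2_ab - r2_a,
       suppression = shared < -tolerance)
}

#' Transition coefficients corrected for the last fixation
#'
#' The balance of between-row transitions and the row of the final fixation
#' are mechanically linked (starting and ending rows force the difference of
#' opposite-row transition counts to 0 or -1), so part of the transition
#' model's fit is bookkeeping for where gaze ended. Entering the last
#' fixation into the regression alongside the transition counts corrects the
#' transition coefficients for this.
#'
#' @param features Output of [trial_features()].
#' @return List with `uncorrected` and `corrected` `choice_model_fit`s; both
#'   are fitted on the same trials.
#' @export
last_fixation_correction <- function(features) {
  d0 <- build_choice_design(features, "transitions")
  d1 <- build_choice_design(features, "transitions_lastfix")
  list(uncorrected = fit_choice_model(d0$X, d0$y, d0$clusters, "transitions"),
       corrected = fit_choice_model(d1$X, d1$y, d1$clusters, "transitions_lastfix"))
}
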