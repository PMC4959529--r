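---
title: "Process tracing in 2x2 strategic games: models, estimators, and the synthetic cohort"
author: "gazegames"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Process tracing in 2x2 strategic games}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gazegames)
```

## The problem

When two players each pick one of two actions, the payoff structure of the
resulting 2x2 symmetric game determines whether the situation is a prisoner's
dilemma, a stag hunt, a hawk-dove game, or a dominance-solvable game with no
conflict. Two families of cognitive models make different claims about *how*
people choose in such games. Level-*k* theories hold that a player simulates
an opponent who reasons one step less deeply and best responds; each level
implies a specific program of payoff lookups. Evidence-accumulation
(drift-diffusion) theories hold that noisy evidence about the difference in
row payoffs integrates to a threshold; they imply characteristic response-time
patterns and an emerging gaze bias toward the eventually chosen row. The two
families fit *choices* about equally well; they separate on *process*
measures: fixation counts, transition types, and the time course of gaze.

`gazegames` implements both model families, the full processing chain from
raw fixation logs to the statistics that discriminate between them, and a
synthetic cohort generator so that every stage is testable end to end without
access to recorded eye movements.

## The game space

A game is built from four abstract own payoffs $x_1, x_3, x_5, x_7$ (the
opponent's payoffs follow by symmetry: $y_1=y_2$, $y_3=y_6$, $y_5=y_4$,
$y_7=y_8$). Money payoffs are $y_i = 10x_i + 30$ GBP, keeping everything in
[0, 90]. The strategically relevant coordinates are the differences
$d_L = x_1 - x_5$ and $d_R = x_3 - x_7$, each ranging over {-3, -1, 1, 3}, so
16 difference pairs form a 4x4 grid; four *base configurations* (which two
payoffs are held fixed while the differences generate the rest) replicate the
grid into 64 games. The sign pattern of $(d_L, d_R)$ classifies the game:
$(-,-)$ dominance with conflict, $(+,-)$ symmetric coordination, $(-,+)$
asymmetric coordination, $(+,+)$ dominance without conflict.

The numeric values fixed by the four base configurations in the original
experiment are published only as a table figure and are not machine-readable,
so the package's defaults (fixing values 2 and 1 on the abstract scale) are
explicitly *non-canonical*: they preserve the published structure -- every
payoff in range, each quarter fixing the documented pair -- and a transcribed
games CSV can be supplied to `read_games_csv()` for exact replication.

```{r}
games <- build_game_grid()
table(games$quadrant)
```

## Level-k: predictions, lookup programs, mixtures

Level 0 guesses. Level 1 best responds to a uniform opponent: top iff
$d_L + d_R > 0$, guessing on ties. Level *k* simulates the opponent at level
*k*-1 (symmetry makes the opponent's problem identical, with "top" read as
"left") and best responds to that column; a simulated guess is answered
against the uniform mixture and ties propagate as guesses. `predict_choice()`
implements the recursion for any *k*.

The implied lookup program (`lookup_program()`) is a sequence of stages, each
a set of payoffs that must each be looked up once: level 1 needs the four own
payoffs; level 2 first scans the opponent's four payoffs and then the own
payoffs of the predicted column -- six lookups when the simulated choice is
strict, eight when the opponent is predicted to guess. Within a stage,
`simulate_lookups()` randomizes order uniformly over orders whose consecutive
lookups change exactly one location axis; the terminal pair of the final
stage is constrained to lie one in each row, because the closing comparison
decides between rows. Those are the weakest adjacency assumptions consistent
with the stage structure; order across stages is fixed by the recursion.

`fit_mixture()` estimates proportions of levels from per-game top-choice
counts under a binomial likelihood, with the probability of top being the
weighted level scores (1 / 0 / 0.5 for top / bottom / guess). Because it is
not documented whether the original estimate maximized a trial-level
likelihood or fitted aggregated proportions, both are implemented
(`method = "ml"`, the default, and `"ls"`); neither is claimed canonical.
The simplex is parameterized by softmax, so degenerate solutions approach
the boundary smoothly. When two levels predict identical choices on every
supplied game the likelihood is flat between them and the fit is flagged
unidentified rather than silently returned.

## The gaze-coupled accumulator

The simulator is a generic gaze-coupled diffusion -- the model family is
deliberately non-committal among decision field theory, attention-weighted
diffusion, and random walks, because the process signatures tested here are
shared by the family. Evidence $E$ for top-over-bottom evolves in discrete
steps of `dt_ms`:

$$E_{t+1} = E_t + \delta\,(w_\text{top} S_\text{top} - w_\text{bot} S_\text{bot}) + \varepsilon_t,
\qquad \varepsilon_t \sim N(0, \sigma^2),$$

where $S_\text{top} = x_1 + x_3$ and $S_\text{bot} = x_5 + x_7$ are the row
payoff signals, the fixated row gets weight 1 and the other row the
`gaze_discount`, and choice fires at $\pm$ `threshold`. Fixations follow a
first-order Markov walk over the eight payoff AOIs whose weights favor
common transitions (one property change) over rare ones by a configurable
ratio, with a mild own-payoff destination preference; durations are
lognormal. The analytic companion rule, `choice_probability()`, is the logit
of the drift basis $d_L + d_R$ with slope `beta`.

Parameter defaults (none are published for this task) were calibrated once,
at design time, against the study-level summary statistics the generator is
meant to emulate: with 10 ms steps, threshold 1.1, drift 0.0017 per unit
payoff difference per step, noise sd 0.03 per step, gaze discount 0.3, and
290/100 ms lognormal fixations, simulated cohorts produce about 17-18
fixations per game, mean response times around 5 s, and essentially no
censoring at the 60,000-step guard. `beta = 0.85` makes the analytic rule's
per-unit odds ratio about 2.3, matching the scale of the reported choice
sensitivity. The diffusion core is compiled (Rcpp) and draws from R's RNG,
so `set.seed()` governs it.

With `gaze_discount = 1` the gaze coupling disappears and the simulator's
choice probabilities converge to the closed form of a symmetric diffusion,
$P(\text{top}) = \text{logit}^{-1}(2 a m / s^2)$ -- this is used as an
independent oracle in the tests.

## From fixation logs to canonical process data

Fixations are assigned to a payoff if they fall within a 100-px-radius
circle of its center, boundary inclusive; the layout validator guarantees
non-overlap so assignment is unique. The default layout places cell centers
on a 1280x1024 screen with the two payoffs of a cell offset diagonally; it
is a to-scale reconstruction, fully configurable, since exact coordinates
are unpublished.

Counterbalancing (row vs column player, payoff color, payoff corner, and
per-trial row/column swaps) is undone by `canonicalize_trials()` into a
canonical frame: every participant a row player, own payoffs odd-labelled
top-left, unswapped. The color factor moves nothing; the axis factor is the
screen transpose; all maps are involutions composed in presentation order
and inverted exactly (a property test checks all 32 states). A column player
whose log contains vertical choice codes is reported as an inconsistency,
not silently recoded.

Transitions between consecutive distinct-AOI gazes are classified by which
of three properties change: payoff owner (within-cell), the player's action
(within-column), or the opponent's action (within-row). Exactly one change
is *common* (24 ordered types), two or more is *rare* (32). Consecutive
fixations inside one AOI are collapsed into a single gaze before counting
(exposed as a flag, since the original treatment of repeats is unstated);
unlabelled fixations break the sequence. Decile gaze-bias curves bin
fixations by fractional position $(i - 0.5)/n$, so trials of any length
spread over the bins; for very short sequences the extreme bins can be
empty, and analyses that need "the final bin" use the last populated one.

## The saturated transition model

The 24 common transition frequencies are modelled log-linearly with 24
coefficients: an intercept; seven destination terms (own, top, left and
their products, coded +1/-1); eight within-vs-between-cell adjustments (the
same terms times +1 within a cell, -1 otherwise); and eight row-vs-column
adjustments (+1 within-column, -1 within-row, 0 within-cell). The design is
square and full rank, so the per-participant solve on log counts is exact --
the model reproduces every participant's counts with zero residual, which
the tests assert. Estimation is two-stage: exact (or Poisson-GLM, for the
game-interaction design, which has 4x the columns and 16x the rows)
per-participant fits, aggregated as geometric means across participants,
with participant-level bootstrap intervals. This replaces a full
random-effects Poisson fit; for the saturated designs the two-stage point
estimates are exact, and the intervals are labelled as bootstrap intervals.
A participant with a zero count in any modelled cell gets +0.5 added to all
cells and is flagged.

One algebraic consequence of the +1/-1 cell coding with 8 within-cell versus
16 between-cell rows: the exponentiated intercept is a *weighted* geometric
mean of the counts -- within-cell cells at weight 1/2, the two between-cell
groups at 1/4 each -- not the plain geometric mean. The tests pin down the
exact identity.

The own-payoff factor $c$ implies an own-fixation share $c/(c + 1/c)$
(`own_proportion_from_coef()`); at the reported $c = 1.20$ this is 0.59.

## Choice models

`choice_model_suite()` fits the logistic models that ask how well choices
can be fitted from attributes (difference factors crossed with base
configuration -- one coefficient per game), fixation counts, transition
counts, the last fixation's row, and the *improper* one-coefficient
versions (top-minus-bottom fixation balance; between-row transition
balance). Reported per model: in-sample accuracy at 0.5, log-likelihood,
Nagelkerke $R^2$ against the intercept model, and a BIC whose sample-size
term uses the number of participants -- a documented policy for choices
nested within subjects, not a reconstruction of the original correction,
which is unstated. Complete separation (common in deterministic synthetic
cohorts) falls back to a ridge-penalized fit with a flag, never an error.
Variance partitioning over two predictor sets uses the additivity of
Nagelkerke $R^2$: shared $= R^2_A + R^2_B - R^2_{AB}$.

The balance of between-row transitions and the final fixation's row are
mechanically linked (the difference must be 0 or -1 depending on where gaze
started and ended), so `last_fixation_correction()` refits the transition
model with the last fixation entered alongside, shrinking the bookkeeping
component out of the transition coefficients.

## The synthetic cohort

`generate_cohort()` emulates the study's data structure: 54 participants by
64 games, between-participant counterbalancing cycled over the eight
axis/color/corner combinations, per-trial row and column swaps, lognormal
290/100 ms fixations, and jittered AOI-centered coordinates (sd 20 px keeps
over 99% of fixations recoverable by the 100-px rule). The default agent mix
is the fitted reasoning-level composition (19.5/54.8/25.7% for levels
0/1/2); agents are apportioned to participants by largest remainder so the
realized composition equals the target rather than a multinomial draw of
it. Trembles default to zero because the level-0 share already carries the
response randomness a tremble would add. Level-k agents repeat whole lookup
programs until a Poisson(17) fixation target is met -- empirical trials
revisit payoffs, while the theoretical program is single-pass, so repetition
is an explicit emulation choice; the final repetition still ends with the
terminal between-row comparison, preserving the theory's no-terminal-bias
signature. Level-0 agents emit uniform-random AOIs: they need no payoff
information, but an empirical trial still has gaze somewhere.
`generate_null_cohort()` decouples gaze from choice entirely and anchors the
false-positive checks.

What the generator does *not* emulate -- and therefore what passing tests do
not establish about real data: saccade dynamics, blinks, calibration drift
and off-AOI gaze; learning or fatigue across trials; payoff-magnitude
effects on fixation frequency; any within-participant mixing of strategies;
and real RT distributions for the lookup agents (their RT is just summed
fixation time plus a constant).

## Numerical choices and problem sizes

Tolerances and tie-breaks not already covered: the AOI boundary is
inclusive; classification requires strictly nonzero differences; guesses are
fair coins; the mixture optimizer runs BFGS on the softmax scale with a
1e-12 relative tolerance; zero transition counts trigger the +0.5
correction; separation detection requires every fitted probability
numerically at its label. The test suite exercises the estimators at the
sizes the statistics need rather than the maximum the hardware allows:
full 54-participant cohorts for mixture recovery, 2,000 trials per game for
the analytic choice rule, 300 trials per game for the simulator's signature
battery, and 4,000-trial batches against the diffusion closed form; the
whole suite runs in about a minute.

## Known limitations

The base payoff values are non-canonical defaults (see above). Confidence
intervals for the transition model are participant-bootstrap, not
random-effects, intervals. The BIC nesting correction is a policy choice.
The gaze policy of the accumulator is a stand-in calibrated to the
common/rare ratio, not a fitted attention model. None of the headline
empirical coefficients of the original study can be reproduced here, because
the raw human data are not public; the package's claims are structural and
behavioral (oracle equivalences, parameter recovery, signature contrasts),
and the synthetic defaults merely parameterize those checks.
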