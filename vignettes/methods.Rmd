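---
title: "Methods: inferring and validating dominance hierarchies with domhier"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: inferring and validating dominance hierarchies with domhier}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`domhier` infers dominance hierarchies in closed single-sex groups from
time-stamped dyadic agonistic events. This vignette documents the models
it implements, the parameters that matter, the design decisions taken
where the methodology was genuinely open, and what the synthetic-herd
validation does and does not demonstrate.

## Data model

The unit of observation is a dyadic event: pen, start time in seconds
since mixing, duration, actor, receiver, one of three behavior classes
(*active attack*, *being bullied*, *standoff*) and an outcome
(actor wins, receiver wins, draw). Seconds are the single internal time
unit; hours appear only at the presentation layer. Events are kept
sorted by start time with a stable tie-break on input order, because the
sequential rating methods are order-dependent by construction.
Interactions are the backbone of the analysis, so a row with a missing
required field, an unknown animal, or actor equal to receiver is
rejected outright with its row number; missing optional metadata (body
weights, backtest counts) is tolerated and propagated as `NA`, excluding
that animal only from the statistics that need the field.

Two backtest replicates (struggle counts while restrained supine for one
minute) are stored separately and also exposed as their mean. How the
two replicates should be combined is not settled; the mean is the
package's default because it is the obvious symmetric choice, and both
raw columns remain available for sensitivity analyses.

## Fight validity and merging

A countable fight must last at least 3 s (`min_dur_s`). Two fights of
the same unordered pair separated by less than 8 s (`merge_gap_s`,
measured from the end of one to the start of the next) are one fight:
the merged event spans from the first start to the last end and takes
its behavior class and outcome from the last constituent, on the
reasoning that the resolution of a bout is what its ending shows.
Merging is applied transitively left-to-right, so a chain of short gaps
collapses into a single event. Duration filtering precedes merging.
Overlapping same-pair records (possible with two observers) have a
negative gap and merge under any positive threshold; with
`merge_gap_s = 0` the operation is exactly the identity, which the test
suite asserts.

Per-animal summaries accrue active attacks to the actor (DAA/FAA,
duration in seconds and count), received attacks and bullying to the
receiver (DBB/FBB), and standoffs — defined without an aggressor — to
both participants (DSO/FSO). The log transform for the statistical panel
is `log10(x + 1)`: the offset keeps animals with zero activity defined,
and the base only rescales coefficients, not tests.

## I&SI ranking

The per-pen sociomatrix counts decided wins (winners in rows); the
binary dominance matrix awards 1 to the more frequent winner of each
dyad and 0–0 on ties, including never-interacting pairs. The I&SI
criterion seeks the order minimizing first the number of inconsistencies
I (dyads whose binary dominance points up the order), then their summed
positional distance SI.

The search is the package's own: start from descending net wins (row
sums minus column sums, ties alphabetical), then repeat first-improvement
sweeps over two neighborhoods — all pairwise swaps and all single-element
insertions — accepting only strict lexicographic improvements, followed
by seeded random restarts (default 20) keeping the lexicographic best.
Insertion moves are included alongside swaps because swap-only descent
can stall in local optima even on small matrices, and the package's
contract is that results on pens of up to 8 animals equal the exhaustive
optimum; the test suite and the acceptance script verify that contract
against full enumeration (`isi_exhaustive`) on dozens of random
matrices. Optima need not be unique: the result records whether distinct
orders attaining the same (I, SI) were observed, and the reported order
is the first best found under the declared seed, making runs exactly
reproducible. A worked consequence of the definitions worth noting: a
3-cycle admits no order with fewer than one inconsistency, and that one
inconsistent dyad always spans positional distance 2, so its optimum is
(I, SI) = (1, 2).

Ranks are reported 1..n with 1 most dominant. In correlations with the
cardinal ratings this sign convention makes agreement show up as
*negative* rho, so the panel reports |rho| alongside the signed value.

## Elo ratings

All animals start at 1000 points. After each decided interaction (draws
are excluded), with `p` the expected score of the higher-rated opponent,
the winner gains `(1 - p) k` if it was the higher-rated (or ratings were
equal) and `p k` after an upset; the loser loses the same amount, so a
pen's rating total is conserved to floating-point precision — an
invariant the tests assert at every step of a 1000-event sequence. The
constant `k = 100` sets the stake per encounter.

The expected-score function is not uniquely standard. The default is the
normal model `p = Phi((r_high - r_low)/200)`, the convention of Elo
applications to animal contest data; the chess-style logistic
`p = 1/(1 + 10^(-(diff)/400))` is available via `elo_params(model =
"logistic")`. Both give `p = 0.5` at equal ratings and differ only in
the tail shape. Equal ratings take the "expected winner" branch, where
the two branches coincide anyway.

## Glicko ratings

Glicko-1 extends Elo with a per-animal rating deviation RD quantifying
uncertainty. Defaults: initial rating 2200, initial RD 300. Updates are
per rating period; the package's default period is one hour, giving
72-period trajectories over a 72 h observation window. Within a period
every game uses opponents' pre-period values; the update follows the
standard equations with `q = ln(10)/400`,
`g(RD) = 1/sqrt(1 + 3 q^2 RD^2 / pi^2)`,
`E = 1/(1 + 10^(-g(RD_j)(r - r_j)/400))`, the precision term
`d^2 = [q^2 sum g^2 E (1 - E)]^{-1}`, and
`r' = r + q/(1/RD^2 + 1/d^2) sum g (s - E)`,
`RD' = sqrt((1/RD^2 + 1/d^2)^{-1})`.

Numerical guards and choices:

- `rd_floor = 30` prevents degenerate certainty after very many games.
- Inactivity inflation `c = 0` by default: the 72 h window is one
  continuous observation, and `c = 0` makes RD monotonically
  non-increasing — a clean testable invariant. Animals with no games in
  a period keep rating and (with `c = 0`) RD.
- Draws are excluded by default, for consistency with the Elo module;
  `glicko_params(draws = "half")` scores them 0.5 instead.
- Glicko is not exactly zero-sum; symmetric fresh opponents move by
  equal and opposite amounts, which the tests check against hand-derived
  values, but pen means drift slightly once RDs differ.

## Stability dynamics

Hourly ranks order animals by rating within each period, ties broken by
the previous period's rating and then by id, so every column is a full
permutation. Two per-animal stability definitions are computed and
reported side by side, because "time to social stability" has no single
operational definition:

- **rank fixation** (primary): the smallest hour h such that the
  animal's rank is identical from h through the final hour;
- **rating plateau** (sensitivity): the smallest hour after which every
  hour-to-hour rating change is below `eps` (default 10 rating points).

Rank fixation is adopted as primary because it is parameter-free and
matches the intuition "the hierarchy stopped changing", but it is
deliberately strict: a single late flip between two nearly equal ratings
resets it, so its values run high in dense pens. `first_rank_emergence`
applies the same backward scan to the identity of the rank-1 animal
only. Hour-by-final Spearman correlations (with the final-hour leaders
of each sex pooled across pens) quantify how early the eventual
hierarchy is predictable.

## Statistical panel

Partial correlations between each index and each behavior indicator use
the remaining five indicators as covariates (residual-on-residual
Pearson correlation, t test on `n - k - 2` degrees of freedom); the
backtest mean, initial body weight and average daily gain are tested
with all six behavior indicators as covariates. Multiple regression is
ordinary least squares of each index on the six indicators. The sex
contrast on stability time fits a fixed-effects linear model with sex,
parity, sire, initial body weight and the sex-by-weight interaction, and
reports covariate-adjusted sex means with standard errors via estimated
marginal means; with no covariates it reduces exactly to the
pooled-variance two-sample t test, which the tests verify. A pen random
effect is deliberately not fitted — pens are few and the package favors
a transparent OLS surface; pen can be added as a fixed factor by the
user if desired. No multiple-testing correction is applied; raw p-values
are reported with the conventional 0.05/0.1 read.

## The synthetic herd

The generator exists so that every stage is testable without observation
data, and its defaults are fixed once: 10 single-sex pens — five female
pens of 10 and five barrow pens of 10, 10, 10, 11, 11 animals (102
total; a 47/55 split cannot be partitioned into single-sex pens of
10–11, so 50/52 is used) — observed 72 h. Each animal has a latent
dominance value `d ~ N(0, 1)`; a decided event between i and j is won by
i with probability `plogis(steepness * (d_i - d_j))`, a Bradley–Terry
structure chosen because all three indices presuppose a near-linear
underlying order, and `steepness` maps directly to detectability
(default 1.5, a clear but imperfect hierarchy; 0 is coin-flip
outcomes). Dyadic contact follows an exponentially decaying rate
(initial 0.4 events per pair-hour, half-life 24 h), reproducing the
empirical pattern that most fighting happens right after mixing; the
female/barrow half-lives are offset by `sex_effect_h` (default 15 h,
female pens faster), so sex differences in settling have a recoverable
direction. Standoffs are always draws; other events draw with
probability 0.15; durations are lognormal (median 10 s). Everything is
deterministic given the seed.

What the generator does *not* emulate: winner–loser carry-over effects,
bystander effects, individual aggressiveness heterogeneity beyond the
latent value, observation error in winner assignment, and any coupling
of body weight or backtest behavior to dominance (the metadata are
independent noise). Consequently, passing the rank-recovery tests shows
the pipeline recovers a latent order of the assumed form from realistic
event volumes — it does not certify performance on real herds, where the
model is at best an approximation. Likewise, because late low-rate
events still occasionally flip adjacent ranks, the strict rank-fixation
stability of a default simulated herd shows only a weak and
seed-dependent sex difference; the package's ability to detect a true
stability shift is instead established directly on stability tables
with a known 15 h offset.

## Validation problem sizes

The test suite and acceptance script size their computations to be exact
where exactness is claimed and cheap elsewhere: exhaustive I&SI
verification uses 50 random matrices of 4–7 animals (up to 5040
permutations each); Elo zero-sum is tracked over 1000 events in a pen of
11; rank recovery averages 10 simulated herds of 102 animals
(roughly 550 filtered events per pen) at steepness 3 and again at 0;
the partial-correlation recovery check uses a trivariate Gaussian with a
closed-form partial correlation of 0.5 at n = 10000; and determinism is
checked by hashing every file of two full pipeline bundles run with the
same seed.
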