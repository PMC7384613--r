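---
title: "State-switching models for animal movement: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{State-switching models for animal movement: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

High-resolution tracking data — an ant colony filmed at 1 Hz, a gull
relocated every 20–30 minutes — show animals switching between discrete
movement regimes: long stationary bouts, bursts of directed movement,
excursions out of the observation arena, seasonal migration legs. This
package models such data in two coupled steps:

1. **State step.** A classifier predicts the behavioural state of animal
   $i$ at time $t$ from a vector $u_{t-1}$ of variables derived from the
   observed history,
   $P(m_{it} = k \mid \text{history}) = f_{mk}(u_{t-1})$.
2. **Velocity step.** Conditional on the state, a continuous bivariate
   model predicts the discrete-time velocity
   $v_{it} = (p_{it} - p_{it-1})/\delta t = f_{vk}(u_{t-1}) +
   \epsilon_{it}$, and the next position is
   $p_{it} = p_{it-1} + v_{it}\,\delta t$.

Both steps are *observable-state* models: the temporal resolution is
assumed fine enough, and measurement error small enough, that the state is
evident from the positions themselves (a repeated coordinate is a
stationary record; an absent coordinate is an out-of-nest record). No
hidden-state inference is attempted, which is a deliberate scope boundary,
not an oversight.

For ants the state alphabet is `0` (stationary in nest), `1` (out of the
nest) and `2` (moving within the nest). States 0 and 1 have deterministic
kinematics: a stationary animal has exactly zero displacement
($f_{v0} = 0$, $\epsilon = 0$), and an animal leaving the nest is placed
at the exit point with velocity $(exit_x - x_{t-1}, exit_y - y_{t-1})$,
because its true position outside is unobserved. Only state-2 movement is
learned from data. For gulls the alphabet is the four migratory states
(Northern range, Southbound migration, Southern range, Northbound
migration) and each state carries its own learned velocity model.

At the **individual level** one model is fitted to all animals' data and
applied per animal — a population-average assumption. At the **colony
level** a single joint model maps the concatenation $U_{t-1}$ of every
animal's feature vector to all states (one categorical head per animal)
and all velocities (a $2N$-dimensional response). The colony velocity
model is trained on all rows, because the output dimension cannot change
with which animals happen to move; the state output then zeroes out
velocities of animals classified stationary and overrides exiting animals
to the exit point. The composition invariants — state-0 rows move by
exactly zero, state-1 rows sit exactly at the exit, state probabilities
sum to one — hold by construction and are asserted in the test suite.

## Derived variables

The ant feature vector has 39 entries: five lags of position and velocity
per axis (20), the stationary time (length of the zero-displacement run
ending at the previous step), the penultimate-step distance, the
sub-chamber index (eight half-chambers numbered left to right), distances
to the nearest wall in the four cardinal directions (interior barriers
count), the nearest neighbour's distance, position and velocity, four
quadrant counts (8 mm squares cornered on the focal ant; Q1 = NE, Q2 = NW,
Q3 = SW, Q4 = SE), the number of still neighbours within 10 mm and moving
neighbours within 12 mm (closed balls; the asymmetric radii are kept as
printed in the source data description and are configurable), and the
distance to the queen. "Still" means a displacement of exactly zero over
the preceding step — hand-clicked tracking repeats coordinates verbatim —
with a configurable tolerance `eps_move` (default 0) for noisier data.

Two conventions needed a decision because the data description leaves them
open. Stationary time counts *steps*: a query at time $t$ scans the run of
zero-displacement steps ending at step $t-1$, so ten identical positions
queried at the tenth time give 8 (steps 2 through 9). Quadrant orientation
(Q1 = NE, counter-clockwise) is configurable. Out-of-nest animals are
represented at the exit point with zero velocity in the feature rows of
*other* animals' histories, and are excluded from neighbour pools since
their positions are unobserved; if no in-nest neighbour exists the
nearest-neighbour distance takes the nest diagonal as a sentinel, keeping
rows fixed-width.

Gull features are lagged planar positions and velocities up to `lags`
lags (candidates 30/40/50 in the motivating analysis), the day number
since 1 June of the bird-year, the time of day as a fraction in $[0,1)$,
and the penultimate-step distance. Latitude/longitude tracks are first
linearly interpolated onto the regular sampling grid and converted to UTM;
the conversion uses the standard WGS84 transverse-Mercator series, with
one zone (the track's modal zone) per track so a whole year lives in one
planar frame.

A single code path (`features_for_time()`) computes the feature block for
one prediction time from history arrays; batch derivation and simulation
rollouts both call it, so training features and rollout features cannot
drift apart.

## Migratory state labelling

A bird starts in the Northern range. It enters Southbound migration when
its track covers more than 0.91 degrees of latitude southward within a
trailing ten-hour window, and Northbound migration symmetrically at 1.0
degrees; each migration state persists while its condition holds. The
window is *trailing* — whether it could be centred or any sub-window is
not determined by the verbal rule; trailing is the simplest reading and is
configurable. Interruptions of a migration leg shorter than a stopover
threshold (12 hours by default — the rule's source gives no duration, so
one had to be chosen) remain in the migration state; longer interruptions
are stopovers and are assigned to the Northern or Southern range according
to whether the stopover site is closer to the year's farthest-North or
farthest-South observed latitude, as are all residency periods after the
first. The labeller is deterministic and idempotent, and the emitted
state sequence always follows the cycle 1 → 2 → 3 → 4 → 1 (possibly
re-entering a migration state after a stopover).

## Learners

Three learner families stand behind $f_m$ and $f_v$:

* **Univariate random forests** (via `ranger`): probability forests for
  the state step, one regression forest per velocity axis. Stochastic
  simulation draws one ensemble member uniformly at random and uses its
  prediction; the same member index is used for both velocity axes of a
  row so that a draw is internally coherent. The package owns the CART
  split contract: candidate thresholds at midpoints between consecutive
  sorted distinct values, the weighted-impurity criterion, and
  deterministic tie-breaking (ties within $10^{-10}$ resolved by lowest
  predictor index, then lowest threshold). `best_split()` is verified
  against an exhaustive brute-force oracle on hundreds of random datasets.
* **Multi-output forests** (`fit_mv_forest()`, package-owned): joint CART
  trees whose splits minimise the *average* impurity across outputs —
  mean per-output Gini for classification, mean squared Euclidean
  deviation (an identity-weighted covariance impurity) for regression.
  These serve the colony level, where states and velocities of all
  animals are predicted from shared splits.
* **Dense neural networks with Monte Carlo dropout** (`fit_mlp()`,
  package-owned): one or two hidden layers with relu/tanh/elu
  activations, a softmax head for one categorical response, a
  multi-softmax head (one group per animal, loss = sum of per-group
  cross-entropies) for the colony state step, and a linear head for
  velocities; Adam optimisation; inverted dropout kept active at
  prediction time so repeated forward passes approximate posterior
  predictive draws. A simple recurrent (Elman) first-layer variant is
  trained by truncated backpropagation through time, treating the
  training set as one long series with hidden-state resets at animal
  boundaries. An LSTM variant is not implemented; the simple recurrent
  layer demonstrates the recurrent pathway, and nothing downstream
  depends on gating.

Colony-level inputs for network learners are reduced by centred PCA
(`pca_reduce()`), with the transform stored in the fitted model and
re-applied to new rows; tree learners take the raw concatenated features.
Hyperparameters (tree counts, node sizes, hidden widths, dropout
probability, learning rate) are ordinary arguments with moderate defaults
— tuning grids are the user's choice, since no canonical values exist.
Permutation importance (`variable_importance()`) measures the loss
increase when a predictor column is shuffled, averaged over seeded
repeats.

## The SDE comparator

The parametric benchmark is a stochastic differential equation whose
drift is the negative gradient of a spatial *potential* surface $h$ and
whose speed is modulated by a spatial *motility* surface $m$, both
piecewise-constant on a regular grid of square cells (1 mm by default;
the tests and examples use coarser grids to keep runtimes short).
Euler–Maruyama discretisation gives the order-2 autoregression

$$p_{t+2} = \beta\, m(p_t)\,[-\nabla h(p_t)] + (2-\beta)\,p_{t+1}
            - (1-\beta)\,p_t + m(p_t)\,\epsilon_t,
  \qquad \epsilon_t \sim N(0, I),$$

with friction coefficient $\beta \in (0, 1]$ controlling velocity
autocorrelation and the noise scale fixed to 1 for identifiability. (The
sign of the $(1-\beta)p_t$ term follows from substituting the discretised
velocity equation into the position equation; the $\beta = 0$ limit,
constant-velocity extrapolation $2p_{t+1} - p_t$, fixes it unambiguously.)
The gradient of the indicator-spline potential is defined by central
finite differences between adjacent cells (one-sided at edges), since the
indicator basis itself is flat almost everywhere.

Fitting is staged, on within-nest moving segments only (the SDE assumes
constant movement):

1. $\hat\beta = 1 - \hat\rho$, the pooled lag-1 autocorrelation of
   velocity components over runs of consecutive moving steps — under the
   model $v_{t+1} = (1-\beta)v_t + m\epsilon$ this is an exact moment
   estimator, and it decouples one scalar from the two $J$-dimensional
   surface problems.
2. **Motility** by penalised Gaussian likelihood of the AR(2) residuals
   with the drift omitted: per-cell scale $m_j$, penalty
   $\lambda_m \sum_{j \sim j'} (\log m_j - \log m_{j'})^2$ over
   4-neighbour adjacency, optimised by L-BFGS with an analytic gradient.
   Cells without data shrink to their neighbours through the penalty.
3. **Potential** by penalised weighted least squares with $\hat m$
   plugged in: residuals are regressed on the finite-difference gradient
   operator, weighted $1/\hat m^2$, with roughness penalty
   $\lambda_h h^\top L h$ ($L$ the adjacency Laplacian); the normal
   equations are solved sparsely. $h$ is identified up to a constant and
   anchored to mean zero.

The penalty forms and the blocked 5-fold cross-validation default for
$\lambda$ are this package's choices; the original fitting procedure for
this model class is described elsewhere and not reproduced line by line.
The behavioural-state step of the comparator is a multinomial logistic
regression on the derived variables with backward elimination (drop the
predictor whose removal most improves AIC until none does).

Numerical behaviour worth knowing: the stationary per-axis velocity
variance under flat potential is $m^2 / (1 - (1-\beta)^2)$, and a
100,000-step simulation reproduces it within a few percent — this
closed-form check is part of the acceptance suite. Surface recovery from
50,000 moving steps on a 16 × 8 grid (cells of 10 mm) yields Pearson
correlations above 0.9 for motility and above 0.8 for the potential on
data-rich cells (≥ 50 steps), with $\hat\beta$ within ±0.05. Potential
recovery degrades gracefully as the drift-to-noise ratio falls; the
synthetic truth used in the tests sets the bowl height so that drift at
the arena rim is a moderate fraction of the per-step noise, a regime
comparable to visible directional structure in real nest data.

## Simulation and evaluation

Long-range simulation is an autoregressive rollout: each sampled step is
projected onto the nest rectangle and fed back into feature computation,
so simulations depend only on the model, the initial history window and
the seed — never on held-out truth (asserted by corrupting post-window
data and observing identical output). Replicate $r$ runs on a sub-seed
drawn deterministically from the master seed, so replicates differ from
each other but the whole ensemble is reproducible bit for bit.

One-step evaluation uses the mean squared prediction error
$\mathrm{MSPE} = \tfrac1n \sum (x-\hat x)^2 + (y-\hat y)^2$ on positions,
with predictions projected onto the nest boundary first. The evaluation
path uses the most probable state and the mean velocity, the simulation
path full sampling — which of the two a published error table used is
not stated in the motivating analysis, so both are exposed and the
evaluation default is the deterministic one. Long-range simulations are
summarised by a metric suite (total distance; percent stationary and
percent out of all animal-time records, so the three state fractions sum
to 100; per-sub-chamber occupancy of in-nest records; mean number of
other animals within 12 mm) and judged against 25th/75th percentile bands
of the same metrics over every 1000-step moving window of the observed
data (stride 1, linearly interpolated percentiles). An 80/20 contiguous
temporal split and whole-group (bird-year) cross-validation folds
complete the evaluation tools.

## Synthetic data

`generate_ant_colony()` produces the default test-bed: 20 animals
(including a queen, id `"Que"`) over 10,000 1-Hz steps in a four-chamber
160 × 65 mm nest with mid-chamber barriers, 6 mm doorways and an exit at
the bottom-right corner. States evolve as a sticky Markov chain whose
transition matrix is constructed (`ant_transition_matrix()`) to have
stationary occupancy 76% stationary / 2% out / 22% moving — the
decomposition reported for a real carpenter-ant colony — given chosen
dwell probabilities; moving steps follow the AR(2) model under a known
truth (β = 0.5, motility 0.8 mm, a shallow quadratic potential bowl
centred on the nest, values picked once as a realistic moderate-drift
regime); re-entry resumes just inside the exit. The generator returns the
ground-truth states and parameters so estimator-recovery tests close the
loop: the labelling rule recovers over 99% of generator states, and the
surface estimators recover the SDE truth as described above.

`generate_gull_year()` produces one annual track: Northern range from 1
June, an 8-day southbound leg at 1.2°/10 h, a Southern range residency,
an 8-day northbound leg, small Gaussian positional noise, sampled every
25 minutes. Eight-day legs at that drift are realistic for a
Scandinavia–Iberia migration and leave the trailing-window detection lag
(≈ 7.6 h at onset) small relative to leg duration, so the threshold
labeller recovers ≥ 95% of migration-state records.

What the synthetic data deliberately does *not* emulate: inter-animal
interaction in the generating process (neighbour features carry no causal
signal beyond chance), wall-following and corridor effects of real nests
(interior walls constrain the generator only through the potential and
boundary projection), social structure (no worker/queen behavioural
difference), and measurement error. Passing tests therefore demonstrate
correctness of the machinery and recoverability of the assumed structure
— not that real colonies satisfy the model.

## Problem sizes and runtime choices

The default fixtures are sized so the whole test suite runs comfortably
on a single CPU: the full colony (20 × 10,000) is generated once per
session and shared; surface recovery uses 30,000–50,000 steps on a 128-
cell grid; the closed-form variance check uses 100,000 steps; forests use
30–100 trees. These are the package's documented defaults for examples
and verification, chosen to make every result reproducible in minutes.

## Known limitations

* Observable states only; no HMM fallback when states are ambiguous.
* Arenas are axis-aligned rectangles with axis-aligned interior walls;
  no polygonal nests, holes, or 3-D movement.
* The recurrent learner is a simple Elman layer; no gated (LSTM/GRU)
  variant.
* Gull velocity models with the recurrent learner are not supported
  (the per-state windowing scheme that a gated recurrent model would
  need is out of scope); use the dense or forest learners there.
* The SDE comparator's λ defaults (blocked CV) assume temporally ordered
  fitting data; shuffled input would make the folds exchangeable and the
  selection optimistic.
* One UTM zone per track: tracks spanning many zones inherit the modal
  zone's distortion at their edges.
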