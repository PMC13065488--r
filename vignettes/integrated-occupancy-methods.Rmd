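---
title: "Methods: integrated occupancy models for heterogeneous survey data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrated occupancy models for heterogeneous survey data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

# Scope and model

`occufuse` fits a single latent occupancy process to three survey datasets
with different observation protocols, and provides the machinery to compare
*strategies* for handling two chronic problems of mixed-source species
data: heterogeneous sampling effort and unequal reliability across
datasets. This vignette records the model, the assumptions, the tunable
parameters, and the design decisions that were genuinely open.

## Process model

Occupancy at site $i$ is $z_i \sim \mathrm{Bernoulli}(\psi_i)$ with
$\mathrm{logit}(\psi_i) = \beta' X_i$. Two designs are available:

* **linear** — intercept plus the standardized covariates. Used when
  covariate effects are (assumed) linear, e.g. in the calibration
  experiments where the generating truth is linear.
* **spline** — a GAM: one cubic B-spline smooth with second-difference
  (P-spline) penalty per covariate, $k = 10$ basis functions each, plus an
  optional tensor-product smooth of the planar coordinates with
  $k = 100$ capturing residual spatial autocorrelation. Sum-to-zero
  constraints are absorbed per smooth; a free intercept identifies the
  model. Bases and penalties are built with mgcv's smooth constructors
  (`smoothCon`/`PredictMat`, `bs = "ps"`), i.e. the same representation a
  jagam-style Bayesian GAM uses; mgcv's *default* thin-plate basis family
  differs, which is why the basis family is pinned to P-splines here.

Each smooth's coefficients get the partially improper Gaussian prior
$\beta_j \sim N(0, (\lambda_j S_j)^-)$ with
$\lambda_j \sim \mathrm{Gamma}(0.05, 0.005)$ — the jagam default, stated
explicitly because "a gamma prior" alone underdetermines it. Unpenalized
coefficients get $N(0, 10)$ on the logit scale (weakly informative over
probabilities).

## Observation models

With $z_i$ marginalized analytically in every likelihood term:

* single-visit: $P(y=1) = \psi p + (1-\psi) f^*$,
  $\mathrm{logit}(p) = \alpha_0 + \alpha_1 d + \alpha_2 d^2$ in
  standardized day-of-year $d$;
* five-interval: $P(W=w) = \psi\,\mathrm{Binom}(w; 5, p) +
  (1-\psi)\,[w=0]$, with quadratic standardized time-of-day and day terms;
* checklist: $p = 1 - (1-p^*)^{E}$, $E = \delta_1\,\mathrm{duration}
  + \delta_2\,\mathrm{distance}$, $\delta \ge 0$, $p^* = 0.5$, so unit
  standardized effort means detection probability one half. With the
  effort model disabled (scenarios F5/F6) checklist detection is a single
  free intercept on the logit scale — the natural reading of "equal
  detection probability across all checklists".

Marginalizing $z$ analytically (rather than sampling it as data
augmentation) is exact here because sites are not shared across datasets —
each record's $z$ enters only its own term — and it mixes far better and
is directly testable against brute-force enumeration.

**False positives.** For a dataset declared less reliable, unoccupied
sites can still yield detections: $P(y=1\mid z=0) = f^* = 1-(1-f)^{E}$
with $f \sim U(0, 0.25)$. The box avoids the well-known identifiability
collapse of false-positive occupancy models; `check_boundaries()` verifies
posterior mass is not piling at the bounds. Five-interval records get no
false-positive path (the repeated-interval structure is what makes them
reliable); for records without effort fields, $E = 1$ so $f^* = f$.

**Covariate integration.** Alternatively the unreliable stream is
summarized within a closed 1000-m ball around each reliable survey point
into `lists` (records) and `count` (records with a detection), entering
the occupancy logit with $\beta_{count} \ge 0$, $\beta_{lists} \le 0$.
Boundary handling at exactly 1000 m is inclusive (a choice the buffer
description leaves open). Counting positive records rather than total
individuals is deliberate: all outcomes are treated as binary, so record
counts are the coherent summary. The summarized source is effort-filtered
but *not* spatially balanced — balancing discards exactly the density
information the `lists` covariate is supposed to carry.

Sign constraints ($\delta$, $f$, $\beta_{count}$, $\beta_{lists}$) are
enforced by rejection at the bound rather than by transformation, keeping
the prior uniform over each box near its edges.

## Filtering and spatial balancing

Checklist quality filters follow the standard recommendations: strictly
less than 5 h duration, 10 km distance, 10 observers; complete lists only;
optionally no traveling lists (distance $> 0$). Comparisons are strict
because the recommendations are printed as strict inequalities.

Spatial balancing keeps one checklist per occupied cell of a hexagonal
grid. Conventions the balancing description leaves open, fixed here so the
partition contract is testable: flat-top hexagons, origin at the region's
lower-left corner, and "1 km" read as the center-to-center spacing of
adjacent cells (the common hex-binning usage). The within-cell survivor is
chosen uniformly at random under a seed, with the selection a function of
the record-id *set* per cell, so results are invariant to input row order;
"keep the most recent" or "highest effort" would be equally defensible
rules, and the seed-based choice is exposed rather than hidden. These
choices can matter in principle; they are configuration, not substance.

## Inference

Adaptive blockwise random-walk Metropolis within Gibbs. Blocks: each
smooth's coefficients (or the whole linear coefficient vector), each
detection parameter set, the effort coefficients, the false-positive rate,
the integration pair. Proposal scales adapt by Robbins–Monro toward 0.44
(scalar) / 0.234 (vector) acceptance during burn-in only, preserving the
stationary distribution afterwards. Smoothing parameters use their
conjugate Gamma full conditional
$\lambda_j \mid \beta \sim \mathrm{Gamma}(a + r_j/2,\; b + \beta_j' S_j
\beta_j / 2)$ with $r_j$ the penalty rank. The default schedule is 3
chains × 2500 iterations, burn-in 500, thinning 2 (1000 retained draws per
chain). Initialization: coefficients 0, $\delta = (1,1)$, $f = 0.05$,
$\lambda = 1$, jittered across chains. Convergence is reported as
split-$\widehat R$ and effective sample size; we treat
$\widehat R < 1.05$ on monitored scalars as the pass bar — a reporting
convention of this package, not a claim about anyone else's practice.

## Validation

20% of the holdout pool is moved to a test set, stratified by dataset:
the structured datasets for the effort/checklist-reliability comparisons,
current-era data for the historic-data comparisons; historic records are
never held out. Holdout records are scored on the *detection* scale —
outcomes are detections, so predictions are the posterior mean of
$\psi p$ (plus the false-positive path where the scenario models it), and
five-interval outcomes reduce to the binary event $w > 0$ with predicted
probability $\psi(1 - (1-p)^5)$. Scoring $\psi$ alone is a defensible
alternative (the choice is exposed through `predict_occupancy()` vs
`predict_detection()`); the detection-scale composite is the default
because it is the quantity the outcomes realize. Metrics are the Brier
score and AUC (Mann–Whitney tie convention, 0.5 per tied pair, with a
strict-inequality toggle), and scenarios are reported as percent change
versus their family reference, signed so positive is always better.

# The synthetic-data generator

The generator defines the study conditions; its defaults are fixed and are
not tuned per experiment.

* **Landscape**: low-frequency random cosine fields on a planar rectangle
  — smooth, finite, bounded-gradient surfaces standing in for gridded
  environmental layers. Covariates are standardized; a shared reference
  standardization (dense uniform grid) keeps one parameterization of the
  truth across all site sets.
* **Checklist locations**: a Thomas cluster process (Poisson parents,
  Poisson offspring with Gaussian dispersal), reproducing the extreme
  spatial clustering of participatory sampling so balancing has real work
  to do. Clustering intensity is configuration (`cluster_spec()`).
* **Effort**: duration lognormal (median 0.75 h, heavy tail past 5 h);
  distance 0 with probability 0.4 (stationary lists) else lognormal
  (median 2 km, tail past 10 km); observers $1 + \mathrm{Pois}(0.7)$ plus
  a rare (3%) large-group component. A bare $1+\mathrm{Pois}(0.7)$ has
  essentially no mass past 10, so the group component is what makes the
  observer filter bind — the defaults are chosen so *every* quality filter
  removes a nontrivial fraction. About 10% of lists are flagged
  incomplete. These distributions are plausible stand-ins, not calibrated
  to any real region's checklist stream.
* **Historic shift**: an additive logit-intercept change plus an additive
  change to one covariate coefficient, under the same covariate
  standardization — a prevalence change plus a habitat-association change.
  Magnitude is configuration (`historic_shift()`).
* Day-of-year and time-of-day are standardized before entering the
  quadratic detection terms (the quadratics are numerically unstable on
  raw day scales); the model applies the same convention using
  training-data statistics.

What the generator does *not* emulate: real geography and projections
(coordinates are planar meters), observer-level heterogeneity and
expertise, temporal autocorrelation within seasons, counts greater than
one, and route structure in the single-visit data. Passing tests therefore
demonstrate internal correctness and the direction of method effects under
the stated data-generating mechanisms — not performance on any particular
real dataset.

# Numerical choices and degenerate inputs

* Likelihood terms guard `log` against underflow at machine minimum;
  outcome probabilities per record sum to 1 to 1e-12 by construction.
* Constraint violations give posterior density $-\infty$ (rejection), so
  retained states always satisfy the boxes exactly.
* Constant covariate columns are a degenerate-basis error at spline
  construction; zero-length datasets are dropped from the likelihood; an
  empty bundle has log-likelihood 0 (posterior = prior).
* Hexagon edge points resolve deterministically through cube rounding;
  ties in AUC score one half per pair by default.
* Per-dataset log-likelihood parts are cached in the sampler, and only the
  parts a block touches are recomputed; occupancy probabilities are reused
  across detection-parameter updates.

# Problem sizes used in the shipped experiments

The calibration experiment uses 20 replicates of ~2800 records
(500 single-visit, 300 five-interval, 2000 checklists) with the linear
process design, 2 chains of 1500 iterations each; the directional
comparisons use 10 replicates of smaller bundles (roughly 1300–1600
records) with single short chains. These sizes are the package's chosen
experiment scale: large enough for stable coverage and directional
conclusions, small enough to re-run routinely. The spline path is
validated on 1-D smooths and at the basis level rather than inside the
replicated experiments, where the linear truth matches the linear design.

# Known limitations

* The spatial tensor smooth is expensive to mix with random-walk
  proposals at $k = 100$; for serious spatial fits, a gradient-based
  sampler would be the next step (deliberately out of scope — the
  inferential target, not the engine, is the contract here).
* The false-positive rate is only weakly identified when contamination is
  small and the occupancy surface is flexible; the $[0, 0.25]$ box and
  boundary checks mitigate but do not remove this.
* Covariate-integration buffers use raw counts; with very dense source
  data the sign-constrained linear terms can saturate the logit. Scaling
  the summaries is a reasonable refinement left to the user.
* AUC on small holdouts with rare species can be undefined (single-class
  outcomes); the experiment runner surfaces this as an error rather than
  imputing a value.
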