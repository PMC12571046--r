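---
title: "Models and methods behind motr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind motr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(motr)
```

## The problem

Mouse tracking for reading (MoTR) is a web-deployable paradigm for
measuring incremental reading behavior: the text is blurred except for a
small spotlight at the cursor, so the trajectory of the mouse is a proxy
for the reader's attention. The raw data are timestamped x/y samples at a
nominal 20 Hz. `motr` turns those trajectories into the standard
eye-movement-style reading measures, and provides the full analysis chain
used in factorial agreement-processing experiments: a generative
simulator with known ground truth, custom hypothesis-matrix contrasts, a
Bayesian hierarchical model for durations and regression probabilities,
Bayes-factor model comparison, and simulation-based power analysis.

The motivating design is a gender-agreement reading study: sentences with
a head noun (the critical region, region 3 of a five-region, single-line
layout) preceded by an agreeing element that either matches or mismatches
the noun's gender. Three agreeing elements are crossed with
grammaticality and noun gender: modifying adjectives instantiate
phrase-internal agreement (concord), while predicative adjectives and
verbs instantiate external agreement; predicative adjectives share the
adjectival lexical category with modifying adjectives, which lets
agreement type be separated from lexical category. Because verbs cannot
instantiate internal agreement, the 2 x 2 x 2 factorial collapses to six
element-by-grammaticality conditions (twelve cells once gender is
counted).

## From trajectories to reading measures

Every sample is assigned to the word whose bounding box is nearest
(Euclidean distance to the box, zero inside it; exact ties go to the
leftmost word, deterministically). Distance to the box rather than to the
word center keeps the assignment robust to word-length differences, which
are a known confound in this paradigm. Maximal runs of consecutive
same-word samples are merged into *attentional associations*, the
fixation analogue: an association's duration is the onset of the next run
minus its own onset, and the final run of a trial gets one nominal sample
period (50 ms) beyond its last sample, so a single-sample trial yields
one 50 ms association rather than zero.

Associations shorter than 160 ms or longer than 4000 ms are removed
(strict comparisons: exactly 160 or 4000 ms survive), mirroring fixation
exclusion practice. After removal, same-word associations that have
become adjacent are re-merged and re-checked against the maximum only;
the re-merge is toggleable (`filter_policy(remerge_after_filter =
FALSE)`) because fixation pipelines differ on this point and the choice
is worth exposing to sensitivity analysis.

Five measures are computed per unit (word or region; region is the
default since the analyses target the critical region):

* **gaze duration** — dwell during the first pass, which ends at the
  first association off the unit in either direction; a skipped unit
  entered later from the right still starts its first pass at its first
  actual association;
* **go-past time** — all dwell from first encounter until the first
  association strictly to the right, including regressive revisits to
  earlier material; missing (right-censored) if the unit is never exited
  rightward before the trial ends, rather than truncated;
* **total duration** — all dwell on the unit;
* **FPReg** — 1 iff the first association after the first pass lies to
  the left;
* **RegIn** — 1 iff the unit receives an association after having been
  exited rightward; 0 for units read but never so revisited, missing only
  for units never read at all. A revisit arriving after a *leftward*
  exit does not count as an incoming regression.

Never-visited units have all measures missing. "To the right" is defined
by word order, not x-coordinate, so multi-line input degrades gracefully.
These definitions are locked down by an oracle-equivalence test: on 1000
random association sequences the pipeline must agree exactly with an
independent literal implementation of the definitions, and totals must
conserve the filtered association time.

Participants whose comprehension-question accuracy falls below 0.8 are
excluded (a participant at exactly 0.8 is kept); the exclusion report
carries every participant's accuracy so audits are testable.

## The synthetic-data generator

The generator reproduces the study's counting scheme: 24 target items (8
per agreeing element), 48 fillers (half ungrammatical), 4 practice items,
3 lists, 42 comprehension questions over the 72 experimental trials, and
8 targets per element per participant (4 match / 4 mismatch, gender
balanced 2/2 within grammaticality). Lists rotate items through the four
grammaticality-by-gender versions Latin-square style, so participants on
the same list see identical condition assignments and every item occurs
in both grammaticalities across lists. One master seed drives everything;
per-participant substreams are derived by counter, so adding participants
never perturbs existing ones.

Reading measures are drawn from the same hierarchical model the package
fits (next section), so simulator and fitter share one generative story
and parameter-recovery tests are meaningful. Default generative values
were chosen once to resemble total-duration reading times on a critical
region — log-ms intercept 6.2 (about 490 ms), mismatch penalty 0.10 on
the log scale, small negative agreement-type and lexical-category main
effects, a modest positive grammaticality-by-agreement-type interaction,
participant intercept SD 0.25, slope SDs 0.05, item SDs 0.10/0.03,
residual scale 0.45 — and for the binary family a -1.5 log-odds baseline
(about an 18% regression rate) with a 0.5 mismatch effect. Fillers use
the same response model with all condition effects zeroed.

Trajectories realizing target per-region dwell times come in two
profiles. The *saccadic* profile dwells near each word's center
(lognormal-consistent jitter clamped inside the box) for
`round(target/50)` samples and jumps between words in one inter-sample
step; round-trip tests require the processed total durations to land
within one 50 ms sample period of their targets. The *smooth* profile
sweeps each word at piecewise-constant velocity. Regressions are inserted
with a grammaticality-dependent probability (defaults 0.12 match / 0.17
mismatch, consistent with regression rates and mismatch effects typical
of this paradigm): after the first pass on a launch region (default 4,
the region after the critical one) the cursor revisits a landing region
(default 3, or any earlier region by argument) for a lognormal revisit
time and then resumes. Layouts are synthesized from a fixed-width
character metric (14 px per character), which is deterministic and
length-sensitive. Word visits shorter than one sample period are skipped
with a warning.

What the simulator does **not** emulate: motor noise beyond positional
jitter, smooth-pursuit idiosyncrasies, re-reading strategies, comma/line
effects, or any claim about how real readers generate regressions — the
regression mechanism is a stand-in that realizes target rates, nothing
more. Passing round-trip tests therefore validates the processing
pipeline's arithmetic, not behavioral realism.

## Custom contrasts via the generalized inverse

Hypotheses live as named weight rows over the twelve design cells: `Gram`
(mismatch - match), `Gen` (masculine - feminine; no printed convention
constrains this sign, it is simply documented), `AgrType` (internal -
external, so negative estimates mean external agreement reads slower),
`LexCat` (verb - adjective, so negative estimates mean adjectives read
slower), the two grammaticality interactions as differences of mismatch
penalties, and the gender differences of those interactions as three-way
rows. The `GramxGen` two-way term is omitted by default — matching the
predictor set of the reported models — but `default_hypothesis_matrix(
include_gram_gen = TRUE)` adds it. Every row's weights sum to zero and
are scaled so that applying the row to cell means yields a difference of
(averaged) condition means.

The model (coding) matrix is the Moore-Penrose generalized inverse of the
hypothesis matrix augmented with an equal-weight intercept row. This
makes the fitted coefficients *be* the hypothesis-weighted condition
differences: for any coefficient vector, mapping through the coding
matrix to cell means and back through the hypothesis weights is the
identity (tested at 1e-10 relative tolerance), and ordinary least squares
on a balanced design returns exactly the weights applied to the empirical
cell means. A consequence worth stating explicitly: scaling a
*hypothesis row* by k scales the recovered coefficient by k (the
coefficient is the weighted difference itself), whereas scaling a
*contrast code column* by k scales the fitted coefficient by 1/k; both
directions are pinned by tests so the scaling convention cannot drift.

## The Bayesian hierarchical model

For participant i and item j the linear predictor is

$$\eta_{ij} = (\beta_0 + b_{0i} + c_{0j}) + \sum_p (\beta_p + b_{pi} + c_{pj})\,x_p,$$

with durations modeled as Lognormal(eta, sigma) — equivalently a normal
model on log milliseconds; the package fits raw ms with priors read on
the log-ms scale and applies no response scaling — and binary regression
indicators as Bernoulli(logit^-1(eta)). By-participant random effects
cover the intercept and all predictors; by-item effects cover the
intercept and the within-item predictors only (agreement type and lexical
category are properties of the item and get no item slopes). Priors are
mildly informative: for durations beta_0 ~ Normal(6, 1) (prior predictive
median reading time near exp(6) = 403 ms, a wide-band sanity check in the
tests), slopes Normal(0, 0.1), random-effect SDs Exponential(2),
correlation matrices LKJ(2) (favoring correlations near zero), residual
scale Exponential(2); the binary family uses Normal(0, 1) on intercept
and slopes and has no residual scale.

Sampling is by a blocked Gibbs sampler written for this model
(RcppArmadillo):

* fixed effects and the non-centred random-effect coordinates have
  conjugate Gaussian full conditionals;
* the random-effect scales enter the predictor linearly given everything
  else, so each gets an exact truncated-normal update against its
  Exponential prior;
* the LKJ-distributed correlation Cholesky factors are parameterized by
  canonical partial correlations (the C-vine construction, under which
  LKJ(2) makes the partial correlations independent scaled Betas — a fact
  verified in tests against an independent onion-method sampler) and
  updated by an independence Metropolis step proposing from the prior
  (acceptance is the bare likelihood ratio, giving near-perfect mixing
  wherever correlations are weakly identified) followed by an adaptive
  random-walk refinement;
* the residual scale is slice-sampled on the log scale;
* the Bernoulli family is handled by exact Polya-Gamma augmentation
  (alternating-series sampler for PG(1, psi), checked against the
  analytic mean and variance), which restores the Gaussian updates;
* a "sweep" step translates the fixed effects along likelihood-invariant
  directions against the random effects each iteration, eliminating the
  slow random-walk behavior the shared location would otherwise induce.

Defaults mirror standard practice for this model class: 4 chains of
4000 iterations with 2000 warmup. Convergence is summarized by split
R-hat (threshold 1.01) and rank-normalized bulk ESS (threshold 400) on
every monitored parameter; a fit failing either is flagged, not rejected.
Divergence counts are a Hamiltonian-specific diagnostic and do not exist
for a Gibbs scheme; the analogous health indicators reported here are the
Metropolis acceptance rates of the correlation updates. Rows with a
missing response are dropped per measure (skipped regions are genuinely
unobserved, not imputable) and counted.

Effect sizes are back-transformed per posterior draw: the twelve cell
predictors are mapped through the inverse link (exp for durations —
i.e. cellwise medians on the ms scale; lognormal *means* would multiply
by exp(sigma^2/2) — logistic for probabilities) and the effect's
hypothesis-row weights are applied to the transformed cell values, so a
back-transformed `Gram` of 60 ms reads as "mismatch conditions cost 60 ms
on this measure". A posterior-mean shortcut (`method = "posterior_mean"`)
is available; the draw-level path is the default because it propagates
posterior uncertainty through the nonlinearity. Per-element mismatch
costs (`marginal_mismatch_cost()`) average over gender within each
agreeing element, reporting the ms-scale effect with a credible interval,
a two-sided posterior tail probability as the primary evidence summary,
and a normal-approximation p-value solely for comparability with
frequentist marginal-means output — the two are different quantities and
should not be conflated.

## Bayes factors and power

Model comparison opposes two non-nested reduced models sharing all main
effects and random-effect structure: one carries only the
grammaticality-by-agreement-type interaction, the other only the
grammaticality-by-lexical-category interaction. Evidence is the ratio of
marginal likelihoods, estimated by the iterative (optimal) bridge
estimator. Two implementation choices matter:

* For the lognormal family the random effects are integrated out
  analytically — given the scales and correlations the marginal of the
  data is multivariate normal with a low-rank-plus-diagonal covariance,
  evaluated via the Woodbury identity (and verified against a dense
  multivariate-normal oracle in tests) — so the bridge runs over the
  fixed effects, scales and correlation parameters only. For the
  Bernoulli family no such collapse exists and the bridge runs over the
  full parameter space including the non-centred random effects, which
  is noisier.
* Every coordinate is warped through its prior CDF onto the
  standard-normal scale before bridging. Weakly identified coordinates
  (most correlation parameters, small scales) then have near-N(0,1)
  posteriors, so the multivariate-normal proposal overlaps the posterior
  in every direction and the prior contributes exactly a standard-normal
  log density with no Jacobian bookkeeping.

The reported Monte-Carlo standard error treats proposal draws as
independent and discounts posterior draws by their effective sample size;
it is approximate, and between-refit dispersion of roughly two to five
times the nominal MCSE should be expected for hierarchical fits — the
tests therefore use refit-level tolerances, and the estimator itself is
validated to closed-form conjugate evidence. The prior-sensitivity sweep
refits both models over a grid of prior SDs on the interaction
coefficient only (all other priors fixed) and labels Bayes factors on the
conventional ladder (1-3 anecdotal, 3-10 moderate, and so on — the bands
above 3 are a convention, not a finding).

Power analysis simulates counterfactual experiments on a grid of item and
participant counts (item counts must be divisible by 6: three elements,
grammaticality counterbalanced), refits the full model with reduced
sampler settings (2 chains x 800 iterations by default, a deliberate
deviation from the inference defaults for throughput), and reports the
raw fraction of replicates in which the target interaction is detected —
no monotone smoothing — alongside per-replicate seeds for exact re-runs.
The default detection criterion is a 95% credible interval excluding
zero; a normal-approximation p < .05 criterion is available. Under a true
zero interaction the CrI criterion detects *at or below* the nominal 5%
rate: the Normal(0, 0.1) slope prior shrinks interval endpoints toward
zero, so the realized null detection rate at 24 items x 32 participants
is conservative (near zero), which is the expected behavior of a
shrinkage prior, not a calibration defect.

## Numerical and design notes

* Word boxes are half-open ([x_min, x_max)); regions print 1-based as in
  the stimulus schema while words are 0-based internally.
* Problem sizes in the shipped tests and acceptance script — 50
  calibration replicates and 100 null-power simulations at 24 items x 32
  participants, reduced-chain refits — were chosen as the smallest sizes
  at which coverage, bias and detection-rate statements are stable under
  the fixed seeds; the same code runs the full 4 x 4000 defaults at the
  64-participant study size in the acceptance script's headline fit.
* Degenerate inputs are defined, not special-cased: zero random-effect
  SDs simulate exactly, a single-sample trial yields one 50 ms
  association, an empty layout and rank-deficient hypothesis matrices
  are errors that name the offending object.
* Known limitations: the Gibbs sampler's correlation updates mix more
  slowly than the rest of the chain when correlations are strongly
  identified; Bernoulli-family marginal likelihoods carry larger
  Monte-Carlo error than lognormal ones; and the trajectory simulator's
  regression model realizes rates without modeling their cause.
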