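---
title: "A feature-based redintegration model of retrieval in sentence comprehension"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A feature-based redintegration model of retrieval in sentence comprehension}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(redint)
```

## The retrieval model

Memory items are represented as ordered vectors of symbolic features,
e.g. `[C C 2 3 1]`.  At a retrieval site (for instance, the embedded
verb of an object relative clause, where the head noun must be
re-accessed) a retrieval probe — the lingering, possibly blurry remnant
of the target's encoding plus local context cues — is compared against
the set of candidate memory traces.  Comparison is *positional* and
*probe-asymmetric*:

* distance `d` = number of mismatching features / number of compared
  features, where the compared features are the **probe's** slots;
* a probe slot with no counterpart in a candidate is a mismatch, while
  candidate features beyond the probe's length are ignored — it is the
  probe that determines how many mismatches there can be;
* similarity `s = exp(-d)`, so `d` in [0, 1] implies `s` in
  [exp(-1), 1];
* the probability of sampling candidate `E_i` is the Luce ratio
  `s(X, E_i) / sum_j s(X, E_j)`.

Positional (slot-aligned) comparison is forced by the worked scenarios
the model is calibrated against: a set-overlap comparison would assign
similarity 1 to two traces containing the same tokens in different
orders, whereas the intended value for `[C C 2 3 1]` vs. `[C C 1 2 3]`
is `exp(-3/5) = 0.55`.

```{r}
scens <- read_scenarios(system.file("extdata", "worked_scenarios.txt",
                                    package = "redint"))
scens[[1]]
sampling_probabilities(scens[[1]], sim_digits = 2)
```

**A note on printed precision.**  Published versions of these worked
scenarios display similarities to 2 decimal places and normalize the
*displayed* values: with exact arithmetic the elaborated-probe target
has sampling probability `1 / (1 + 2 exp(-6/8)) = 0.514`, while
normalizing the rounded similarities (0.47) gives `1/1.94 = 0.515`,
which prints as 0.52.  `sampling_probabilities(..., sim_digits = 2)`
reproduces the printed convention; the default (`sim_digits = NULL`)
uses exact similarities and is what every other function in the package
consumes.

**Degraded slots.**  A probe may contain the reserved token `"?"` for a
blurry slot.  Two scoring policies are implemented because the choice is
not decidable from first principles: the default (`"mismatch"`) treats a
blurry slot as failing to support any match, so degradation lowers
similarity monotonically; the alternative (`"exclude"`) drops the slot
from both the comparison and the denominator.  A `"?"` in a *stored*
trace (a feature lost to overwriting, see below) matches nothing under
either policy.

## Distinctiveness and competitor-load sweeps

`distinctiveness_sweep()` and `competitor_sweep()` evaluate abstract
configurations in which the probe equals the target and consists of `m`
features shared with every competitor plus `u` features unique to the
target.  Each grid point is deterministic — the target probability has
the closed form `1 / (1 + n exp(-u/(m+u)))` — so no averaging over
random feature assignments is needed and none is performed.  Three
consequences, all verified in the test suite:

* with `u = 0`, all `n + 1` candidates are equally similar and the
  target probability is `1/(n+1)`: going from one to three competitors
  nearly halves the chances of retrieval;
* unique target features help monotonically but with diminishing
  returns, asymptoting at `1 / (1 + n exp(-1))`;
* the number of shared features matters far less than the number of
  competitors: over `u` in 0..20 with two competitors, the gap between
  `m = 2` and `m = 10` never exceeds 0.10.

Default grids are `m` in 2..10, `u` in 0..20, `n` in 1..10; the axes
are conventions, not measurements, and are fully configurable.

## Encoding interference and the 2x2 complexity design

`encode_np()` maps a noun phrase to a schematic feature vector: a
configurable number of shared form tokens (default 2), one unique
head-noun token, and one unique semantic token per modifier word
(default 1).  These counts are package conventions — nothing in the
underlying theory fixes them — so the qualitative predictions are
required (and tested) to hold across a grid of `base_form_features` in
1..3, `features_per_modifier` in 1..2 and overwriting probabilities
0.1..0.5.

A complex NP differs from its simple counterpart only by *appended*
unique tokens.  Because candidate features beyond the probe's length
are ignored, a non-target's elaboration is invisible to the probe:
without interference, target sampling probability is exactly invariant
to NP1's complexity.  This is the model's core asymmetry between target
and non-target distinctiveness.

**Feature overwriting.**  Encoding interference is modelled as
overwriting of form features between NPs that *match in structural
form* (same modifier count): for each form-matched pair, each shared
form feature of each trace is overwritten independently with
probability `p` (default 0.3), so a feature shared with `k` form-matched
neighbours survives with probability `(1-p)^k`.  Restricting
overwriting to form-matched pairs implements the idea that altering the
form of a neighbouring NP relieves encoding interference; unique
semantic tokens are never overwritten.

**Why overwriting must act through recovery, not through the Luce
ratio.**  Form features at the defaults are carried by *every* NP in
the scenario at the same slot.  A probe slot that matches (or
mismatches) all candidates equally multiplies every similarity by the
same factor and cancels from the Luce ratio — one can show that no
overwriting scheme confined to universally shared slots can move the
sampling probability at all.  The model therefore scores a condition by
`retrieval_probability = sampling_probability x intact_proportion`: a
sampled trace must still be *redintegrated*, and reconstruction fails
in proportion to its lost features.  Both factors are reported
separately by `predict_conditions()`, which supports exact enumeration
over loss patterns (`method = "exact"`, the default; the at-risk slot
set is small) and Monte-Carlo averaging with a standard error
(`method = "mc"`).

```{r}
predict_conditions(method = "exact")
```

The resulting ordering — elaborated targets best, simple targets
protected by a complex NP1 next, all-simple worst — mirrors the
empirical pattern in which NP1 complexity speeds retrieval only when
NP2 is simple.  No prediction is imposed on complex-complex versus
simple-complex beyond "no worse than the protected simple target",
since the underlying account is deliberately tentative there.

## The synthetic self-paced-reading generator

`generate_exp1()` emulates a 2x2 NP1/NP2-complexity object-relative
design (defaults: 52 participants, 28 items, 70 fillers, Latin-square
assignment, yes/no accuracy flags at 84% marginal accuracy);
`generate_exp2()` emulates a 2x2 noun-color/verb-color design
(44 participants, 32 items, 60 fillers).  Log reading time is the sum
of:

* a grand mean (5.9 log-ms, about 365 ms), word-length effect
  (0.025/character) and log-list-position practice effect (-0.04);
* by-participant and by-item random intercepts (SD 0.12 / 0.05) and
  by-unit random slopes for the condition effects (SD 0.015) at the
  retrieval region;
* an encoding cost at the head of a modified NP (0.03 per extra
  feature), and for Experiment 2 color costs at the colored word
  (0.08 noun, 0.065 verb, reinstatement interaction 0 by default —
  color confers no retrieval benefit, the empirical finding);
* a retrieval cost `kappa * (-log p_target)` at the relative-clause
  verb, with `p_target` the condition's retrieval probability from the
  memory model (centered across conditions), a standard surprisal-style
  monotone link;
* Gaussian residual noise (SD 0.25, back-derived from the credible
  interval widths a 52-participant study of this design reports), and a
  0.001 contamination fraction drawn from a slow tail above 5.5 s to
  exercise trimming.

Spillover is mechanistic: the word after a manipulated word inherits a
fraction (`carryover`, default 0.9) of the preceding word's *realized*
deviation — condition cost, condition slopes and trial noise — not just
its deterministic part.  This matters for the covariate check below: a
purely deterministic spillover could never be absorbed by conditioning
on the (noisy) previous-word reading time.

`kappa` defaults to 0.22, which places the verb-region NP2 coefficient
near -0.04 on the residual log scale — the upper edge of the
0.01..0.04 magnitude range such designs report — so that the effect is
reliably detectable in reduced 20-participant simulation studies while
the NP1 coefficient (generated with no direct retrieval cost) stays
near zero and the implied interaction is small and positive, matching
the qualitative pattern of the modelled experiment.

What the generator does *not* emulate: lexical or syntactic variability
beyond word length (words are random letter strings), attention lapses
and speed-accuracy coupling (accuracy flags are independent of RT),
serial correlation within trials beyond one-word spillover, and any
dependence of later trials on feedback.  Passing tests on these data
therefore certify the pipeline's statistical machinery, not its
robustness to every property of human reading times.

## The analysis pipeline

The preprocessing chain follows standard self-paced-reading practice:
raw RTs outside [100, 5000] ms are removed (`trim_rts()`; no
accuracy-based exclusion), log RTs are regressed on word length and log
list position over the whole sample including fillers with
by-participant intercept adjustments (`residualize()`), and the
residuals are the dependent variable.  The default estimator is a
mixed model with shrinkage on the participant intercepts; a
fixed-effects per-participant variant is provided and agrees with it to
well within 1% RMSE at realistic sizes.  Intercept-only adjustment is
deliberate: by-participant *slopes* for length and position are not
part of the residualization contract.

`fit_region()` fits, for one word region, a Bayesian hierarchical
regression of residual log RT on the two sum-coded condition factors
and their interaction (marked levels `complex`/`green` = +1, so
facilitation is a negative coefficient), with by-participant and
by-item intercepts and slopes for all three terms.  Sampling is via
JAGS; the contract is backend-agnostic — any sampler achieving
split-Rhat < 1.01 and ESS > 400 on the fixed effects is acceptable, and
summaries are flagged when the diagnostics miss those marks.  Inference
is reported as `P(beta < 0)`, the share of posterior draws below zero,
alongside the posterior mean and 95% credible interval.  Regions are
analyzed independently with no multiplicity correction, mirroring
standard practice for this design; treat the per-region sign
probabilities accordingly.

**Priors.**  Random-effect structures are independent (diagonal): with
at most one observation per participant-item cell at a region,
random-effect correlations are essentially unidentified, and JAGS has
no native LKJ density, so modelling them would cost much and inform
little.  Default priors are weakly informative and autoscaled to the
response SD `s`: Normal(0, 2.5 s) on fixed effects, half-Normal(0, s)
on the residual and random-intercept SDs, and half-Normal(0, s/10) on
random-slope SDs.  The narrower slope scale reflects the scale on which
by-unit condition slopes plausibly vary relative to the residual noise;
with unit-scale half-Normal priors instead, the weakly identified slope
SDs inflate the fixed-effect posteriors by roughly 40% at
desk-simulation sizes and the posterior sign probabilities become
severely conservative (observed tail rate ~0 instead of ~5% under the
null).  With the autoscaled defaults the end-to-end type-I rate in
simulation is ~4-5%.  Flat scalar priors remain available through
`prior_sd_fixed` / `prior_sd_scale`.

**Sampler settings.**  Defaults are 4 chains of 5000 samples with 2500
warmup (10,000 retained draws).  Simulation studies and the test suite
use scaled-down settings (2 chains, 1200-3000 samples, 400-500 warmup),
which are ample for sign probabilities; the problem sizes used are 20
participants x 28 items for power and calibration replicates and 8-16
participants for unit tests, chosen as the smallest designs at which
the studied properties are identified.

`covariate_check()` refits a region with the previous region's residual
log RT (centered, matched within participant and item) as an extra
fixed covariate.  Because generated spillover carries the previous
word's realized deviation, a purely spilled-over effect attenuates
toward `P(beta < 0) = 0.5` under the covariate, while a genuine
verb-region effect survives — the logic used to argue that verb-region
effects are not continuations of earlier processing.

## Numerical choices and edge cases

* Probabilities are normalized exactly (sums differ from 1 by < 1e-12);
  no ties are possible in the deterministic sweeps.
* An all-`"?"` probe under the `"exclude"` policy has zero compared
  features and raises an error rather than returning 0/0.
* `trim_rts()` warns (not errors) when everything is removed;
  `residualize()` errors on a single participant or a constant
  predictor; `read_spr()` names the offending line on malformed input.
* All generators and samplers are seed-deterministic: identical
  parameters and seed give byte-identical CSV output and identical
  posterior summaries.

## Known limitations

* Feature vectors are symbolic and equally weighted; there is no
  graded feature similarity, no learning of features from text, and no
  time-course (activation decay) component.
* The encoding-interference module predicts condition-level retrieval
  probabilities, not reading times; the link to RTs lives entirely in
  the generator's `kappa` term.
* The pipeline's credible intervals inherit the usual caveats of
  desk-scale hierarchical models: slope SDs are weakly identified, and
  calibration statements rest on the generator's own assumptions.
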