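---
title: "Census-reweighted norming for web-based cognitive batteries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Census-reweighted norming for web-based cognitive batteries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ncpt)
```

## The problem

Web-collected cognitive test data come from convenience samples whose
demographics differ sharply from the general population: participants skew
younger and far more educated than a census sample. A percentile computed
within such a sample answers "how did this person do relative to other
volunteers", not "relative to the population". This package implements a
norming pipeline that corrects for that: a *census-reweighted* rank-based
inverse normal transformation (INT), a battery-level composite (the Grand
Index, GI), normative tables, session-level inclusion filters, and a
technical-validation stage — plus a synthetic-cohort generator that makes
all of it testable end to end.

## The model

### Demographic bins

Participants are binned by age (six bins: 18–29, 30–39, 40–49, 50–59,
60–69, 70–99, bounds inclusive) crossed with three educational-attainment
groups — {some high school, high-school diploma/GED}, {some college,
college degree, associate's degree}, {professional degree, master's
degree, Ph.D.} — giving K = 18 bins, `k = 3 * age_bin + edu_bin`.
Education code 99 ("Other") belongs to none of the three groups and is
treated as unbinnable, exactly like missing education: such participants
cannot enter the norm sample (they are still normalized by interpolation,
below). Norms add a gender partition (36 bins).

### The reweighted INT

Let the norm sample hold N oriented scores with sample bin proportions
$f_k$, and let $f^*_k$ be the reference population's proportions. Each
observation gets a percentile-bin width and, after rank-ordering, a
centered cumulative rank:

$$w_i = \frac{f^*_{k_i}}{N\,f_{k_i}}, \qquad
  \tilde r_i = \frac{w_i}{2} + \sum_{j<i} w_j, \qquad
  y_i = \Phi^{-1}(\tilde r_i)$$

with $\Phi^{-1}$ the quantile function of a normal with mean 100, SD 15.
The construction has two limiting properties the tests pin down exactly:
with $f^* = f$ it reduces to the textbook centered-rank INT,
$\tilde r_i = (i - \tfrac12)/N$; and when every reference bin is present
in the sample, $\sum_i w_i = 1$ to machine precision. Orientation:
subtests whose raw score grows as performance worsens (go/no-go mean
reaction time, IDs 26/32; trail-making time, IDs 39/40) are negated before
ranking. Raw scores in all output files stay unnegated.

Intuition for the reweighting: each sample member "stands in" for
$f^*_k / f_k$ of a reference-population member. Over-represented bins
(young, highly educated) get widths below $1/N$; under-represented bins
get wider ones. A consequence worth stating because it is easy to get
backwards: shifting reference mass *toward* a low-scoring bin *raises*
the normalized scores of everyone above that bin — the reference
population got weaker, so a fixed raw score ranks higher against it.

### Grand Index

For each complete battery run the GI is the mean of that run's normalized
subtest scores, passed through a *second* reweighted INT at (100, 15).
Because the second stage is rank-based, the GI is invariant to the first
stage's affine target; (100, 15) is used at both stages. The GI is
computed separately per battery against the shared reference, which is
what makes GIs comparable across batteries; it exists only for runs with a
score for every battery subtest. Versions of the same task (e.g. the two
go/no-go variants) are never pooled when norming.

### Norm sample, and scores outside it

The norm sample excludes participants who did not report age or education,
logged more than 25 platform gameplays before testing (practice effects),
or did not complete their battery. The sample defines an empirical
(oriented score → $\tilde r$) step curve per subtest version; everyone
else is normalized by linear interpolation between adjacent sample points,
clamped to $[w_{\min}/2,\; 1 - w_{\min}/2]$. This makes normalization
total without letting outsiders influence the norms. Ties in raw scores
get the weight-averaged $\tilde r$ of their tie group (the midrank
analogue), so equal raw scores always map to equal normalized scores.

## Inclusion filters

All thresholds are strict, following the wording "more than" / "longer
than": a pause is the gap from one subtest's end to the next subtest's
start, and a run is excluded when a gap exceeds 24 h (exactly 24 h is
kept); a user is excluded when a second run starts strictly inside another
run's span (interleaving); a user's entire record is excluded when either
trail-making subtest took over 15 min; only each user's earliest run is
kept, ties broken by the lexicographically smaller run id so the result
does not depend on input order. The time-based filters need session logs
(timestamps); given only released-schema score tables the pipeline skips
them and records a prominent warning in the run manifest. Ages above 89
are top-coded to 90 (Safe-Harbor de-identification).

## Normative tables

Per battery, raw-score mean, SD, N and the 10th/25th/50th/75th/90th
percentiles are reported in each of the 36 gendered bins, for every
subtest and for the GI. A battery is reported only when *every*
(subtest × bin) cell holds at least 20 participants. Percentiles use
linear interpolation between order statistics (R quantile type 7; the
method is a package decision, held fixed by tests). Reported percentiles
follow the convention that a higher percentile means better performance:
for time-scored subtests the p-th performance percentile is the
(100 − p)-th raw-score quantile, reported as a raw value — so a fast
(small) time appears at the 90th percentile.

## Technical validation

Each subtest's raw score is regressed (OLS) on age (linear), education and
gender (both categorical; education "Other" is a level of its own here,
since validation needs complete, not binnable, demographics), over
participants with complete batteries and complete demographics (listwise).
Residuals feed per-battery Pearson correlation matrices and a
positive-manifold check (all off-diagonals strictly positive).
`residualize()` defaults to raw scores as the outcome, but the pipeline's
correlation stage uses *oriented* residuals: with raw trail-making times,
trails-versus-count correlations are negative by construction, which would
make the manifold check meaningless in batteries containing trails.
Constant predictors (e.g. a single-age cohort) are dropped from the design
rather than producing a singular fit; categorical levels observed once
trigger a warning.

## The synthetic cohort generator

The generator emulates the *structure* the analysis assumes, not any real
score distribution. Each participant has a latent general ability
$g \sim N(0,1)$; subtest ability is
$a_s = \lambda_s g + \sqrt{1-\lambda_s^2}\,e_s + \eta_s(\text{demogr.})$,
so positive loadings produce a positive manifold by construction. Defaults
(the generator's stated world, chosen once): loadings $\lambda_s = 0.6$
for every subtest (typical of a first factor across brief cognitive
tasks); ability declining 0.15 SD per decade of age; education-group
offsets (−0.2, 0, +0.25 SD); no gender effect; an adult web-sample
demographic mix with ~7% missing education, ~2% "Other" and ~10%
unreported gender; negative-binomial pre-test gameplay counts with mean 8,
putting most users under the 25-gameplay cutoff.

Two fidelity modes exist. `trial_level = TRUE` plays every task by its
published rules: go/no-go runs until 10 (v2) or 5 (v1) correct go trials
or three errors (three failed attempts yield a missing score); divided
visual attention runs 12 trials with a 100-ms staircase on presentation
time (step size is an artifact default); memory spans start at span 3 and
grow every two (IDs 28/33, 500 ms timing) or three (IDs 43/44, 333 ms
timing) trials, ending on two errors at one level, capped at the 10
available circles; timed streams (arithmetic 45 s, grammar 45 s with a
correct-minus-incorrect floor-zero score, digit symbol 90 s) count
completed trials; progressive matrices runs 17 increasingly difficult
trials, stopping after three consecutive errors; word lists present 12
words over three rounds (the delayed version retains round-3 words with a
retention probability); trail making sums per-click times with
error-backtrack penalties; scale balance offers 25 trials in ten minutes,
stopping on three straight errors; Posner cueing shows 100 trials with the
stimulus at the cued location on 60% of them; complex span grows by one
after each correct response (capped at 30 trials as a guard for forced
agents); object recognition asks 40 yes/no probes; dual search poses one
of two question types over 50 trials. Agent behaviour is an artifact
model: correctness is Bernoulli with probability
$\mathrm{logistic}(1.7\,(a_s - d))$ and response times are lognormal;
ability may be $\pm\infty$ to force extreme agents in tests.

`trial_level = FALSE` draws continuous raw scores directly from per-subtest
affine (or, for timed subtests, log-linear) maps of $a_s$. The latent
structure, demographics and contamination machinery are identical; only
score marginals differ (continuous, unbounded, no floor/ceiling ties).
Because the reweighted INT and the GI are rank statistics, rank-based
calibration results are unaffected by that substitution — which is why the
large-n calibration checks use the fast mode, while trial-level behaviour
is verified at small n. A green large-n test therefore establishes the
*transformation's* calibration, not the realism of any task's score
distribution; discreteness-induced ties in real data are exercised
separately by the tie-policy tests.

Contamination assigns each user at most one violation (24–48 h pause,
interleaved second run, a > 15-min trail-making session, or mid-battery
dropout), recorded in a truth table, so each filter's recovered set can be
compared to the injected set exactly. Determinism: every stage derives its
seed from the master seed via a fixed hash, so cohorts, sessions and
pipeline outputs are byte-identical under the same (config, seed).

## Numerical and design decisions

* Reference compositions are plain length-18 probability vectors
  (`reference_composition()`); the package ships `uniform_reference()` and
  `make_reference(mode = "match")` because no joint 18-bin census table is
  published — only marginals — so any concrete reference is a user input.
* Tie policy (weight-averaged $\tilde r$ per tie group) and the percentile
  estimator (type 7) are fixed, documented choices; changing either
  changes norms at the margin.
* CSV I/O writes numbers with `%.17g`, so write-then-read round trips are
  bit-exact; empty fields encode missing gender/education/GI.
* The GI column emitted by the generator is missing by design: the GI is a
  derived quantity the norming stage fills in.
* Degenerate inputs: a single-score norm sample yields a step curve with
  clamped extrapolation; zero-variance residual vectors are an error in
  the correlation stage (undefined correlation), as is a singular OLS
  design after constant-predictor pruning.

## Known limitations

* No attempt is made to match real score distributions, Lumosity training
  effects (beyond the gameplay-count covariate), or the published
  dataset's exact exclusion counts, which require the raw platform logs.
* The released score schema carries no timestamps, so on score-only input
  the time-based filters are skipped (with a manifest warning) rather than
  approximated.
* The trail-making simulator does not differentiate the six circle
  layouts; several task parameters (staircase step, word-list difficulty,
  click-speed scale) have no published values and are labelled artifact
  defaults in the code.
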