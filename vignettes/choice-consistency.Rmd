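---
title: "Measuring and modelling choice consistency in binary preference tasks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring and modelling choice consistency in binary preference tasks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(intrans)
```

## The problem

When a person chooses between every pair of a set of options — say 20 candy
bars, one choice per unordered pair, 190 choices in all — the choices define
a complete directed graph (a tournament) on the options. If preferences were
read off a stable utility scale, the tournament would be an order: whenever
A is chosen over B and B over C, A would be chosen over C. Violations of
this property are *intransitive triplets*: item triples whose three pairwise
choices form a directed 3-cycle. The proportion of intransitive triplets
among all `choose(n, 3)` triples is a standard index of choice consistency
in decision neuroscience, used to compare clinical groups — here,
mediotemporal-lobe epilepsy patients with hippocampal sclerosis (MTL),
extratemporal-lobe epilepsy patients (ETL), and healthy controls (CON) — on
a value-based preference task and a number-comparison control task with the
identical pairwise structure.

`intrans` implements the full analysis chain: the intransitivity statistic
and its triplet-level features, a random-utility noise simulator that maps
observed inconsistency onto an interpretable noise fraction, the group- and
trial-level statistical stages, a lesion-extent index, and a synthetic
cohort generator so that every stage can be exercised and validated without
access to clinical data.

## The intransitivity statistic

For each subject and task we enumerate all triples of items, look up the
three pairwise winners, and classify the triple. Of the $2^3 = 8$ possible
orientation patterns of one triple, exactly 2 are cyclic, so a responder
whose choices are independent fair coins produces an *expected* proportion
of $2/8 = 25\%$ intransitive triples — the ceiling of the expected
proportion over symmetric random choice, and the anchor we use for
simulator validation. Note the distinction from the *realised* per-subject
maximum: tournament theory puts the attainable number of cyclic triangles
at $(n^3 - 4n)/24$ for even $n$ (330 of 1140, i.e. 28.9%, for $n = 20$), so
single subjects may exceed 25% while no mechanism of independent symmetric
choice can exceed it in expectation. Tests assert the tournament bound, not
the looser 25%, on realised scores.

Scoring uses a vectorised lookup over the full triple enumeration; an
internal fast path used by the Monte-Carlo sweep counts cyclic triangles
through the score-sequence identity
$\#\text{cyclic} = \binom{n}{3} - \sum_i \binom{w_i}{2}$, where $w_i$ is
item $i$'s number of pairwise wins. The equality of the two routes is
asserted in the test-suite against a brute-force triple loop.

Each triplet record carries the trial indices of its three constituent
choices, the index of the last-seen trial (the choice that can close a
cycle), and the sample variance (divisor 2) of the three indices — the
features used by the episodic-memory analyses below. The divisor convention
only rescales the corresponding regression coefficient; it is recorded with
the standardisation constants in the model output.

## The random-utility noise model

Choices are simulated from a logistic random-utility model. Option $A$ with
deterministic utility $u(A)$ receives an effective utility
$(1-\alpha)\,u(A) + \alpha\,\varepsilon_A$, with $\varepsilon$ drawn
independently per option per trial, and

$$p(A) = \frac{1}{1 + e^{\,[(1-\alpha)u(B) + \alpha\varepsilon_B] -
[(1-\alpha)u(A) + \alpha\varepsilon_A]}}.$$

The noise fraction $\alpha \in [0, 1]$ is the share of the effective
utility attributable to random error: $\alpha = 0$ is noiseless preference,
$\alpha = 1$ is pure random choice. A written-out reading in which a single
$\varepsilon$ enters both exponent terms makes the error cancel
algebraically and reduces to an $\alpha$-scaled deterministic logistic
choice; that variant is available as `shared_error = TRUE` for
documentation, but the default draws independent errors — the standard
random-utility formulation, and the only one in which $\alpha$ has its
intended meaning.

Choice generation is deliberately two-stage: realise the error draws,
compute $p(A)$, then draw the binary choice from it. This is exactly the
model as written (a logistic response on noise-perturbed utilities), not an
argmax of perturbed utilities.

### The reference configuration

The mapping from $\alpha$ to expected intransitivity depends on the
utility spacing relative to the error scale, neither of which is
identified by the statistic alone; they are *units* of the model. We fix a
reference configuration — 20 utilities evenly spaced on $[0, 16]$ with
standard-normal errors scaled by 6 — calibrated once against two anchors:

* at $\alpha = 0$ the mean intransitivity is below 1% (near-noiseless
  preference is nearly consistent);
* at $\alpha = 0.3$ the mean intransitivity is about 6%, the level observed
  in hippocampal-lesion patients, so that the noise fraction recovered for
  an MTL-like cohort is about 0.3;
* at $\alpha = 1$ it reaches the analytic 25% ceiling regardless of
  configuration (any zero-mean symmetric error family preserves this
  anchor, which is why the error family is configurable).

A naive configuration with utilities on $[0, 1]$ and unit errors would put
even the noiseless model at ~24% intransitivity — the logistic response to
utility gaps of $1/19$ is almost a coin flip — and no $\alpha$ could
reproduce single-digit percentages. The spacing is therefore part of the
model's definition, is embedded in every sweep result, and all
sweep-derived $\alpha$ estimates are interpretable only relative to it.

### Sweep and inversion

`sweep_alpha()` simulates many subjects per grid value of $\alpha$ and
records the mean and standard error of the intransitivity percentage; the
rise is non-linear (slow at first, steep in the mid-range, saturating at
25%). `invert_alpha()` maps an observed percentage back to $\alpha^*$
through the isotonic (monotone non-decreasing) fit of the sweep curve,
with an uncertainty interval from inverting the mean $\pm$ SE curves.
Observations below the curve floor are pinned to the smallest grid
$\alpha$ and flagged; observations within 3 SE above the ceiling saturate
at the top $\alpha$; anything further above is an error instructing a
wider grid. Sub-stream seeds are derived deterministically from
`(seed, round(alpha * 1e6), replicate)`, so refining the grid does not
perturb existing replicates and identical seeds give bitwise-identical
sweeps.

## Statistical stages

**Log transform.** Intransitivity percentages are right-skewed, and the
near-ceiling control task has a far smaller variance than the preference
task, so percentages are analysed as $\log(\text{pct} + c)$. Because the
transform's purpose is variance homogenisation, the default policy chooses
the offset $c$ that minimises the between-task Bartlett statistic of the
transformed values (searched over $[100/(2\binom{n}{3}),\,5]$ percentage
points; deterministic given the data). On cohorts in the study's regime
this lands near 0.5 pp and takes the Bartlett statistic from the hundreds
to order one — the same pre/post drop the transform is meant to produce. A
fixed half-triplet offset ($100/(2\binom{n}{3})$, the resolution of the
statistic) is available as `offset_policy = "half_triplet"`; it keeps zeros
finite but leaves the control-task zeros piled far below all non-zero
values, and the task variances grossly unequal. The offset and policy used
are recorded on the output.

**Group-by-task mixed model.** The planned comparisons are encoded as
orthogonal contrasts — ETL vs CON $(-1, +1, 0)$ and MTL vs the mean of both
control groups $(-\tfrac12, -\tfrac12, +1)$ — interacted with a centred
task code ($+\tfrac12$ preference, $-\tfrac12$ number), with a random
intercept per subject. The scientific term is the MTL-by-task interaction:
whether the preference/control consistency gap is selectively enlarged in
the hippocampal-lesion group. Fitting is delegated to `lmer` with
Satterthwaite degrees of freedom (reported in the output; degrees-of-freedom
conventions differ across fitters, and coefficients fitted to the original
patient data are not reproduction targets). The design-matrix construction
is a separate, independently tested function.

**Trial-level regressions.** Two logistic regressions at the triplet level
probe episodic-memory accounts of inconsistency: intransitivity on the
standardised last-trial index (does inconsistency decline when earlier
choices could simply be remembered?) and on the standardised variance of
the three trial indices (are choices made further apart less mutually
consistent?). Each includes an MTL interaction. Published reports of such
trial-level analyses are often ambiguous between plain and mixed logistic
models, so the default is a plain logistic fit with cluster-robust (by
subject) standard errors — valid under either reading — with the model
description recorded in the result.

**Response times.** Involvement of a trial in intransitive triplets is
regressed on its standardised response time (plus a quadratic term and an
MTL interaction, cluster-robust): a positive linear coefficient means
slower, more effortful trials are the inconsistent ones, the opposite of a
speed-accuracy-tradeoff account. Subject mean response times are compared
across groups through the same contrast scheme.

**Item heterogeneity.** Counts of intransitive-triplet involvement per
subject and item enter a two-way ANOVA with subject blocks; the item factor
F statistic (df $19, 19(n_\text{subj}-1)$ for 20 items) asks whether
specific items drive the inconsistency. The degrees of freedom follow this
formulation and are reported with the result.

**Lesion index.** For unilateral damage, the lateral damage index
$\mathrm{LDI} = |V_L - V_R|/(V_L + V_R)$ is a dimensionless asymmetry in
$[0, 1)$, symmetric in the two sides and zero only for equal volumes. Its
association with preference intransitivity uses Spearman's rank correlation
(midranks, two-tailed), which is insensitive to outliers in either margin.

All tests are two-tailed at $\alpha = 0.05$ with no multiplicity
correction, matching standard practice for these planned analyses; the
number of tests run is visible in the pipeline output.

## The synthetic cohort generator

`cohort_spec()` / `generate_cohort()` emulate the three-group study design:
31 MTL, 30 ETL and 30 CON subjects, each completing the 20-item preference
task and the matched number-comparison task (identical 190-pair structure),
with lesion records for a random subset of 16 MTL subjects. The generator
is the package's test-bed: its defaults *are* the study conditions, chosen
once as follows.

* **Preference noise.** Each subject's noise fraction is a truncated-normal
  draw (sd 0.05) around the group value; group values (CON 0.09, ETL 0.14,
  MTL 0.27) were calibrated through the sweep/inversion machinery so that
  group mean intransitivity lands near the published regime
  (2.75 / 3.37 / 6.07%).
* **Utility drift.** Item utilities follow a slow Gaussian random walk over
  the session (per-trial sd 0.25 on the reference utility scale). This
  injects the trial-spacing effect — triplets whose three choices are
  further apart are more often cyclic — without any trial-position trend,
  mirroring the dissociation the trial-level regressions are built to
  detect.
* **Control task.** Responses are the objectively correct larger-number
  choice flipped with a lapse probability that decays with numerical
  distance, $q_d = q_0\,e^{-(d-1)/\tau}$ with $\tau = 1.5$ — the classic
  numerical distance effect. Distance-dependent lapses reproduce not only
  the published control-task group means (0.14 / 1.00 / 0.50%) but also
  their single-triplet granularity (medians of a few hundredths of a
  percent); a uniform lapse cannot, because each far-apart flip creates
  about six cycles at once. A uniform lapse remains available
  (`lapse_tau = Inf`), and under it a lapse rate of $\tfrac12$ reduces the
  control task to random choice with the full 25% expectation.
* **Response times.** Lognormal (meanlog 0.4, sdlog 0.35, i.e. a median
  around 1.5 s), with a subject-level spread, a slowdown (meanlog +0.15) on
  trials involved in intransitive triplets, and a subject-level MTL shift
  (+0.12) — the directions reported for the response-time analyses. The
  slowdown is injected by regenerating the response times of involved
  trials after scoring.
* **Lesion link.** The lateral damage index for the lesion subset is a
  scaled logistic of the subject's true noise fraction plus Gaussian noise
  (sd 0.01), then converted into a synthetic left/right volume pair with a
  random damaged side. The link is a modelling convenience — it encodes
  "more damage, more noise" monotonically — and with the default settings
  the LDI-intransitivity Spearman correlation falls in the 0.6-0.8 band.
  Its ceiling is set less by the link noise than by the sampling noise of
  the intransitivity statistic itself given a subject's noise fraction.
* **Null cohorts.** `generate_null_cohort()` equalises all group
  parameters, switches off drift, slowdown and the MTL shift, and shuffles
  the utility-to-item assignment per subject so items are exchangeable.
  Every group, trial-position and item statistic is then null by
  construction; the test-suite verifies 5% empirical size on 200 such
  cohorts.

The same spec and seed give a bitwise-identical cohort; per-subject
sub-seeds come from the documented hash of the master seed and the subject
identifier.

### What the generator does not emulate

The generator reproduces the study's design, group means, and the
directions and rough magnitudes of its secondary effects — not real
behaviour. Real preference data have heterogeneous, correlated utilities
(not an evenly spaced scale), overdispersed control-task errors (the
published ETL control SD of 2.54 against a mean of 1.00 suggests a few
high-lapse subjects, which the homogeneous per-group lapse does not
produce), response-time distributions with session structure, and lesion
morphometry far richer than a noisy monotone link. Passing tests on
synthetic cohorts therefore validate the *pipeline* — that every stage
computes what it claims, holds its nominal size on null data, and detects
effects of the modelled kind at the study's sample sizes — not any clinical
conclusion.

## Numerical choices and degenerate inputs

* Unordered pairs are canonicalised as (min, max); item codes are 1-based
  and normalised on read, with original labels kept.
* Missing responses are accepted by the reader, flagged by
  `validate_design()`, and excluded (with counts) from both numerator and
  denominator of the triplet statistic.
* Choice probabilities go through `plogis`, stable for extreme utility
  differences.
* All-transitive data make the triplet-level logistic regression separable;
  this is an informative error, not a silent fit. Constant response times
  degrade the response-time coefficient to an explicit zero with a warning.
  A zero-variance group is an error in the Bartlett check, naming the
  group.
* An observed percentage below the sweep floor inverts to the grid minimum
  with a flag; a flat isotonic segment at the observation is an error
  advising a denser grid.

## Problem sizes used by the validation suite

Unit tests run on reduced designs (4-12 items, cohorts of 15) where
exhaustive brute-force oracles are feasible; the acceptance-style checks
run at the study's sizes — 20 items, 1000-replicate sweeps at maximum
noise, 200 null cohorts of 91 subjects for size calibration, 100
repetitions per noise level for recovery of $\alpha \in \{0.2, 0.3, 0.4\}$
from cohorts of 31, and 25 calibrated cohorts for effect recovery. These
sizes were chosen so that Monte-Carlo standard errors are small relative
to the tolerances being asserted.

## Known limitations

* $\alpha$ estimates are meaningful only relative to the reference utility
  configuration; the package deliberately does not fit utilities to
  observed choices (no logit/MLE preference estimation), as the inversion
  is simulation-based by design.
* The laterality-side comparison (left- vs right-predominant lesions) is
  expressible with the generic two-sample machinery but is not part of the
  validated pipeline: at `n = 16` split two ways it is severely
  underpowered and no quantitative behaviour is asserted for it.
* Model-based probabilistic transitivity frameworks (weak/strong
  stochastic transitivity, mixture models) are out of scope; the binary
  exhaustive design analysed here counts cycles instead.
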