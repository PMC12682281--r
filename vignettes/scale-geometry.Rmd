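---
title: "Scale geometry and sensitivity to melodic deviants: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scale geometry and sensitivity to melodic deviants: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scalegeom)
```

This vignette documents the models, parameter choices and numerical
conventions behind `scalegeom`, in the spirit of a methods appendix: what
is computed, why each default is what it is, and what a passing test suite
does and does not establish.

## 1. The problem

A musical scale can be described purely relationally: as a subset of the
step positions of an equal-division tuning system, identified up to
transposition (cyclic rotation). The empirical question the package
supports is whether the *geometry* of that subset — how evenly its notes
are spread around the span, and which interval classes it contains —
predicts how easily listeners notice a note that does not belong to the
scale. The behavioral assay is a two-alternative forced choice: a probe
melody drawn from a set is followed by a *note deviant* (one middle note
moved one step, to a pitch the probe never used) and a *contour deviant*
(the two middle notes exchanged — same pitches, different order). A
listener attuned to the set should find the note deviant more salient, and
the signed preference for note deviants over contour deviants is the
per-condition **bias** statistic.

## 2. Set algebra

**Tuning systems.** `tuning_system(divisions, span_ratio, base_frequency)`
maps step $s$ to frequency $f_0 \cdot r^{s/n}$. Two instances matter in
practice: the octave system ($n = 12$, $r = 2$; ordinary semitones) and the
"UT" system ($n = 12$, $r = 3$): twelve logarithmically equal divisions of
a tritave, which preserves all 12-fold pitch-class arithmetic while making
every interval unfamiliar. Throughout the package "one step" means one
division of whichever system is active.

**Set classes.** `enumerate_set_classes(n, k)` partitions the
$\binom{n}{k}$ subsets into transpositional classes; the canonical
representative is the lexicographically least rotation re-anchored at 0
(for the pentatonic class, `02479`). The class counts are verified in the
tests against an independent Burnside-lemma oracle for every $n \le 12$:
the number of classes is $\frac{1}{n}\sum_{r} \#\{\text{subsets fixed by
rotation } r\}$. For $n = 12, k = 5$ this gives 66 classes over 792
subsets.

**Interval vectors.** Entry $k$ counts unordered pairs at circular
distance $\min(d, n - d) = k$. The vector is transposition-invariant and
its entries sum to $\binom{k}{2}$ — both properties are tested across all
66 classes. Note a consequence used repeatedly below: *for fixed
cardinality the six counts sum to a constant*, so as predictors they are
exactly collinear.

**Evenness.** The perfectly even template for a $k$-note set is $t_i = i
\cdot n / k$. Each rotation of the set is re-anchored at 0 and differenced
element-wise against the template; the score is the minimum over rotations
of the population SD (divide by $k$) of the differences, and `evenness` is
its negative so that larger = more even. Three deliberate conventions:

* *Alignment.* How set and template are aligned before differencing is
  genuinely underdetermined in the literature this follows; we re-anchor
  each rotation at 0 and minimize over rotations. No continuous-offset
  minimization is performed — the statistic stays simple and reproducible.
* *Rotation invariance is automatic.* Re-anchoring the rotation starting
  at element $j$ turns the difference vector into a cyclic permutation of
  itself plus a constant ($d'_i = d_{i+j} + jc - s_j$ with $c = n/k$), and
  the SD ignores constants — so every rotation gives the same SD and the
  minimum is a formality. This is why the score is mode-invariant by
  construction, as a class-level statistic must be.
* *Population SD.* Dividing by $k$ rather than $k-1$ scales the statistic
  by a constant; correlations and regression signs are unaffected.

`sd_deviation` is zero exactly for perfectly even sets, which exist only
when $k \mid n$: `0369` and `02468T` in twelve divisions.

## 3. Stimulus model

Probe melodies are pseudo-random walks with the following constraints, all
checked by `validate_melody()` and exercised 10,000 times in the
acceptance suite:

| parameter | default | meaning |
|---|---|---|
| `length` | 8 / 12 / 16 | notes per melody (cohort-dependent) |
| `range_steps` | $[0, 12]$ | one full span, *both endpoints included*; step 12 is the span note and its pitch class is evaluated modulo 12 |
| `leap_limit` | 6 steps | maximum consecutive interval, inclusive (a 6-step leap is legal) |
| repetition | gap 1 | no immediate pitch repetition only |
| mode | random | one mode of the set class, drawn uniformly per melody and fixed |
| tone / gap | 250 / 83 ms | 333 ms onset spacing, 3 notes per second |

The walk restarts on a dead end (cap 1,000 restarts; in practice dead ends
essentially never occur with `leap_limit` 6).

**Deviants.** The two middle positions are 4/5, 6/7 and 8/9 (1-based) for
lengths 8, 12 and 16. The contour deviant exchanges them (it is exempt
from the walk constraints — the swap may create a repetition). The note
deviant shifts one of them by ±1 step; the shifted pitch must stay in
range and must not occur anywhere in the probe. Which of the two admissible
positions is shifted is uniform random (unspecified in the source design).
If neither position admits a legal shift in the prescribed direction, the
whole triplet is regenerated — failure is a normal outcome, capped at
1,000 attempts.

**Sessions.** The default session is 6 blocks × 20 trials. Shift
direction and deviant presentation order are *exactly* counterbalanced
within each block and condition (5/5 out of 10). Transpositions: for the
octave system the base offset (the MIDI note of melody step 0) ranges over
54..66, so melodies span F#3–F#5 across transpositions. How transpositions
should be "counterbalanced across blocks" is underdetermined, so the
scheme is: a session-length pool containing each admissible base
near-equally often (`rep(band, length.out = n_trials)`) is shuffled and
dealt to trials block by block; over 120 trials each of the 13 bases
occurs 9 or 10 times. MIDI export (format 0, 480 ticks per quarter at 120
bpm) is refused for non-octave tunings, where a frequency timeline (CSV)
is the export format.

## 4. The synthetic-participant model

Per trial, a participant reports "no difference" with probability $\nu$,
lapses (uniform note/contour) with probability $\lambda$, and otherwise
chooses the note deviant with probability
$\mathrm{logit}^{-1}(\alpha + u_i + \beta_e \cdot \text{evenness} +
\sum_k \beta_{ic_k} \cdot ic_k + \beta_\ell (\text{length} - 8))$,
with participant intercepts $u_i \sim N(0, \sigma_u)$. Features enter
*raw* (counts 0–6, evenness in step units) so planted coefficients are on
the same scale as the analysis module's raw-predictor regression.

**Defaults and their sizing.** Defaults are $\alpha = 0.6$, $\beta_e =
0.20$, $\beta_{ic} = (-0.06, 0, 0.06, 0, 0.08, -0.12)$, $\beta_\ell =
0.02$, $\sigma_u = 0.5$, $\lambda = 0.05$, $\nu = 0.10$. They encode the
qualitative world the analysis is designed to detect — sensitivity rising
with evenness, IC3 and IC5 content and melody length, falling with IC1 and
IC6 — with set-level mean biases spanning roughly 0.05–0.45 (some sets
near-ineffective, the pentatonic near the top) and per-count effects of
order 0.01–0.05 bias units, the magnitude range reported for comparable
human data. One subtlety drove the sizing and deserves emphasis: because
evenness and the interval-class counts are collinear (and the counts sum
to 10), *the population-level ridge coefficients are not the structural
plants* — part of the evenness effect is redistributed onto the counts.
The defaults were therefore calibrated once, at design time, against the
noiseless limit of the pipeline (expected bias integrated over the
random-intercept distribution, then ridge-fit), so that the population
ridge signs for IC1/IC3/IC5/IC6 are unambiguous (at least ~4 finite-sample
standard errors at a 500-participant cohort). Parameter-recovery tests
compare Monte-Carlo means to that noiseless-limit estimand, not to the raw
plants.

**Assignment.** In the many-sets design each participant receives 6 of
the 66 sets, dealt from successive random permutations of the set list:
coverage stays balanced to within one participant while the
participant–set pairing is random. The randomness is not cosmetic: a
deterministic consecutive-block assignment couples each participant's
random intercept to a *fixed band* of neighboring sets, giving the set
means a structured correlation that is not exchangeable and demonstrably
inflates the permutation test's type-I error (we measured ~0.21 at nominal
0.05 before fixing the dealer). With random dealing the set means are
exchangeable under the null and calibration is restored.

**What the generator does not emulate.** Familiarity and long-term
exposure effects, within-session learning, reaction times, serial
dependence between trials, any link between musical training and
sensitivity (the training covariate is generated but inert), and
item-level variation between melodies of the same set. A green test
therefore establishes that the *pipeline* recovers what was planted in a
well-specified world — not that the world is a faithful model of human
listeners.

## 5. Analysis choices

* **Exclusions.** Participants with comprehension rating ≤ 3 (of 5) are
  removed; then (participant, set) conditions with fewer than 15 *usable*
  responses are removed. "Usable" counts note + contour choices only,
  because "no difference" reports are excluded from the analysis — this
  reading of the threshold is an interpretation, documented here.
* **Bias.** $(n_\text{note} - n_\text{contour}) / (n_\text{note} +
  n_\text{contour})$; a condition with zero usable responses is flagged
  `NA`, never silently zero.
* **Mixed ANOVA.** Classical univariate decomposition with subject error
  strata (`aov(y ~ b*w + Error(s/w))`), listwise deletion of incomplete
  subjects, partial $\eta^2 = SS_\text{eff} / (SS_\text{eff} +
  SS_\text{err of stratum})$. The designs this serves are balanced, where
  the sequential and Type-II decompositions coincide; the tests verify
  against a hand-computed sums-of-squares oracle.
* **Ridge.** Unpenalized intercept via centering; raw predictors; penalty
  1.0. This matches scikit-learn's `Ridge(alpha = 1.0)` exactly (verified
  in a test against the Python implementation). Because the six counts sum
  to a constant, the penalty is what identifies the fit; coefficients are
  regularized contrasts, not independent slopes, and the package
  documentation says so prominently.
* **Permutation inference.** Permute the response across sets, refit,
  record model R and coefficients. $p = (r+1)/(n_\text{perm}+1)$, so p is
  never zero. Coefficient CIs are $B \pm q_{0.975}(|B^\ast -
  \bar{B^\ast}|)$ — a centered-absolute-quantile construction; the CI
  recipe is genuinely underdetermined in the tradition this follows, and
  the chosen form is recorded in the result object (`ci_method`). Model R
  is in-sample (fitted vs observed), as conventionally reported;
  `ridge_loo_r()` provides a clearly-labeled leave-one-out alternative.
* **A caveat on coefficient p-values.** The permutation null is "no
  association at all". If the response is driven by a variable correlated
  with the counts (evenness, say), coefficient p-values are
  anti-conservative — they test exchangeability, not the partial effect.
  We verified this empirically (an evenness-only world rejects the IC1
  null far above nominal rate). Calibration claims in the tests are
  therefore made under the full null only.

## 6. Numerical and interface choices

Seeds are mandatory for all randomized commands (no clock seeding); one
global seed fans out to per-stage seeds through a small deterministic
string hash kept below $2^{31}$, and every pipeline run writes its stage
seeds into `manifest.json`. Configuration files are JSON (a YAML reader
would add a dependency unavailable in the supported environment).
Tie-breaks: lexicographic order for canonical forms and class ordering;
uniform random choice among admissible deviant positions. Degenerate
inputs error early: empty sets, singleton interval vectors, zero-variance
t tests, more predictors than sets.

## 7. Known limitations

Inversional (reflection) equivalence, Z-relations and voice-leading
geometry are out of scope; set classes are transpositional only. The
evenness alignment convention is ours (Section 2) and other conventions
would scale scores differently, though not their ordering by much. The
simulator's bias magnitudes are calibrated to a plausible world, not
fitted to human data; nothing in this package reproduces the source
study's human statistics, and the test suite makes no claim that it does —
every empirical number quoted anywhere in the documentation is computed by
the package itself at run time.
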