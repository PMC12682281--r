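# scalegeom

Tools for studying how the **geometric structure of musical scales** shapes
perceptual sensitivity to out-of-scale notes in melodies. The package is
aimed at auditory-cognition and music-perception researchers who want a
tested, reproducible implementation of the full computational pipeline
behind this class of behavioral experiment:

1. **Set algebra** — pitch-class sets in generalized equal-division tuning
   systems (octave 12-EDO, or 12 equal divisions of a tritave), enumeration
   of transpositional set classes, interval-class vectors, and evenness
   scores.
2. **Stimuli** — probe melodies generated by a constrained pseudo-random
   walk within one mode of a set, plus the two test melodies of the
   forced-choice task: a *note deviant* (one middle note shifted by one
   step, to a pitch absent from the probe) and a *contour deviant* (the two
   middle notes exchanged), with counterbalanced sessions and MIDI /
   frequency-timeline export.
3. **Synthetic participants** — a generative logistic response model with
   participant random intercepts, lapses and "no difference" reports, so
   every downstream stage can be validated by parameter recovery without
   human data.
4. **Analysis** — exclusion rules, the response-bias statistic, t tests and
   a two-way mixed ANOVA, the evenness–bias correlation, and ridge
   regression of set scores on interval-class counts with permutation
   inference.

## The statistics at the core

For each (participant, set) condition with `n_note` note-deviant choices
and `n_contour` contour-deviant choices (after discarding "no difference"
reports):

```
bias = (n_note − n_contour) / (n_note + n_contour)        ∈ [−1, 1]
```

Evenness of a set with steps `s_0 < … < s_{k−1}` in an `n`-division system
compares each rotation (re-anchored at 0) to the perfectly even template
`t_i = i·n/k` and takes the population SD of the element-wise differences
(the SD is rotation-invariant, so the score is mode-invariant);
`evenness = −sd_deviation`.

Set-level mean biases are regressed on the six interval-class counts by
ridge regression (penalty 1.0, unpenalized intercept, raw counts — note the
counts of a fixed-cardinality set sum to `C(k,2)`, so the penalty is what
identifies the fit). Model R is the Pearson correlation of fitted with
observed scores; p-values come from permuting the response across sets
(10,000 permutations by default, `p = (r+1)/(n_perm+1)`).

## Worked example

```r
library(scalegeom)

pent <- pc_set(c(0, 2, 4, 7, 9))          # the pentatonic set
interval_vector(pent)
#> ic1 ic2 ic3 ic4 ic5 ic6
#>   0   3   2   1   4   0
evenness(pent)$sd_deviation
#> [1] 0.2828427                            # very close to perfectly even

feats <- set_class_table(12, 5)            # all 66 five-note set classes
tab <- simulate_cohort(response_model(), cohort_design(feats),
                       n_participants = 300, seed = 7)
scores <- set_scores(compute_bias(apply_exclusions(tab)), feats)

evenness_correlation(scores)
#> $R 0.5184655  $p 8.03e-06                # more even sets → larger bias

ridge_interval_regression(scores, penalty = 1.0, n_perm = 10000, seed = 7)
#> <ridge_perm> penalty 1, 10000 permutations
#> model R = 0.775, permutation p = 9.999e-05
#>           B  ci_low ci_high      p
#> ic1 -0.0415 -0.0662 -0.0168 0.0001
#> ic2 -0.0056 -0.0302  0.0190 0.6140
#> ic3  0.0321  0.0075  0.0568 0.0027
#> ic4  0.0108 -0.0134  0.0351 0.3370
#> ic5  0.0434  0.0188  0.0680 0.0002
#> ic6 -0.0392 -0.0714 -0.0071 0.0057
```

Reading: in this synthetic cohort the interval-class profile of a set
predicts its average bias toward note deviations (model R = 0.78); minor
seconds/major sevenths (IC1) and tritones (IC6) depress sensitivity while
minor thirds (IC3) and perfect fourths/fifths (IC5) enhance it, and the
pentatonic set 02479 attains the highest mean bias (0.44) while 01289
attains the lowest (0.04). These are properties of the simulator's
generative model — chosen to mirror the qualitative structure reported for
human listeners — recovered by the analysis pipeline.

## Command line

```sh
Rscript -e 'scalegeom::cli_main(commandArgs(TRUE))' sets enumerate \
    --divisions 12 --cardinality 5 --out sets.csv        # 66 rows
Rscript -e 'scalegeom::cli_main(commandArgs(TRUE))' pipeline run \
    --preset exp1 --seed 1 --out out/                    # full pipeline
```

Presets `exp1`–`exp4` reproduce the four standard designs (pentatonic vs
chromatic at lengths 8/12/16; all 66 five-note sets; the two perfectly even
sets; the tritave system with sets 02479 vs 01248). Configuration files are
JSON; randomized commands require an explicit `--seed`.

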