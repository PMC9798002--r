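# mieeg

Do interactions *between* EEG electrodes carry class information that
band-power features miss?  `mieeg` is an R package for studying that
question in a two-class motor-imagery brain-computer-interface setting
(left- vs right-hand imagery over the sensorimotor channels C3, Cz, C4).
It compares a static classifier (shared-covariance linear discriminant
analysis, LDA) against a dynamic one (a hidden conditional random field,
HCRF, consuming an ordered window sequence), each run with and without
pairwise inter-electrode interaction features, and tests the difference
with a randomized-blocks ANOVA over subjects.

Because raw motor-imagery recordings cannot ship with a package, `mieeg`
includes a first-class synthetic cohort generator that emulates the
standard feedback paradigm (3 bipolar channels at 250 Hz, 4 runs x 20
trials per class per run = 160 trials per session, imagery segment 3-6 s)
with the two statistical structures the analysis is about: contralateral
event-related desynchronization (ERD) of the mu/beta rhythms, and
class-dependent mu-band coupling between C3 and C4.

## The measures and models

Per sliding window (length *k* samples, displacement Δ*i*), the features
are the mu/alpha (8-12 Hz) and beta (15-25 Hz) band powers of each channel,
optionally followed by one interaction value per electrode pair (C3-Cz,
C4-Cz, C3-C4), computed on the raw windowed samples:

- **Pearson correlation** ρ(x, y) = E[xy] / (σ_x σ_y) after per-window
  demeaning;
- **generalized Jaccard index** J(A, B) = A·B / (‖A‖² + ‖B‖² − A·B),
  the dot-product extension of the set-based Jaccard measure to
  real-valued signals, with range [−1/3, 1] (J = 1 at B = A, J = −1/3 at
  B = −A), and its distance JD = 1 − J = ‖A−B‖² / (‖A‖² + ‖B‖² − A·B)
  with range [0, 4/3].

The static model scores a flattened per-trial feature vector with the
Gaussian discriminant δ_k(x) = −½·log|Σ| − ½·(x−μ_k)ᵀΣ⁻¹(x−μ_k) + log π_k
using one covariance Σ shared across classes (linear decision boundary),
shrunk towards its diagonal at strength λ.  The dynamic model is a
linear-chain HCRF: each label owns a disjoint set of m hidden states, and
p(y|x) ∝ Σ over hidden paths in that label's set of
Π_t exp(Σ_k θ_k f_k(h_t, h_{t−1}, x_t)), trained by L2-regularized maximum
conditional likelihood with log-space forward-backward recursions.

Evaluation follows a nested cross-validation protocol — five rounds of
stratified 3-fold CV with an inner 4-fold grid search on the training side
for λ (LDA) and (m, regularization) (HCRF) — and accuracy
p₀ = trace(H) / N over the confusion matrix H.  Per-subject accuracies are
compared by a one-way randomized-blocks ANOVA (subjects as blocks), with
Tukey-Kramer all-pairs and level-vs-overall-average post-hoc comparisons.

## Worked example

Generate a 6-subject cohort, evaluate LDA with and without Jaccard-distance
interaction features, and test the difference across subjects:

```r
library(mieeg)

cohort <- generate_cohort(n_subjects = 6, sessions_per_subject = 1,
                          paradigm = paradigm_config(n_runs = 2,
                                                     trials_per_class_per_run = 20),
                          model = signal_model(), seed = 42)
conds <- list(mi_condition("lda", "none",    lda_lambda_grid = 1e-2),
              mi_condition("lda", "jaccard", lda_lambda_grid = 1e-2))
tab <- run_condition_grid(cohort, conds, seed = 42, rounds = 2)
an <- rb_anova_oneway(tab, "interaction_mode")
an
#> Randomized-blocks ANOVA (interaction_mode + subject)
#>   interaction_mode F =   18.512  d.f. = (1, 5)  p = 0.008
#>   residual MS = 0.00109901 on 5 d.f.
level_vs_overall(an)
#> Post-hoc comparison (level-vs-overall, alpha = 0.05)
#>    level      mean grand_mean        diff   critical p_adj reject
#>  jaccard 0.8141337  0.7729588  0.04117487 0.02460036 0.008   TRUE
#>     none 0.7317839  0.7729588 -0.04117487 0.02460036 1.000  FALSE
```

Each row of `tab` is one subject's mean CV accuracy under one condition.
Here adding the Jaccard-distance features lifts the average accuracy from
0.73 to 0.81; the blocked ANOVA rejects equality of the two conditions
(F = 18.5 on (1, 5) d.f., p = 0.008), and the level-vs-overall post-hoc
flags only the with-interaction condition as above the overall average —
the no-interaction condition reports p = 1 by construction of the
one-sided rule.

`run_experiment(experiment_config(preset = "full-grid", seed = 1), "out/")`
runs the full 48-condition comparison grid (4 window sizes x 3 slides x
2 interaction measures x 2 classifiers) end to end and writes the blocked
accuracy table, ANOVA/post-hoc CSVs, a text report, and a reproducibility
manifest.

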