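---
title: "Inter-electrode interaction features for motor-imagery classification: models, generator, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inter-electrode interaction features for motor-imagery classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(mieeg)
```

## The question and the analysis

Motor imagery — mentally rehearsing a left- or right-hand movement —
modulates the sensorimotor mu (8-12 Hz) and beta (15-25 Hz) rhythms: power
drops over the hemisphere contralateral to the imagined hand
(event-related desynchronization, ERD).  Classical brain-computer
interfaces classify trials from per-electrode band powers alone, which
discards any *relationship between* electrodes.  `mieeg` implements an
analysis that asks whether adding a pairwise interaction feature — the
Pearson correlation or a generalized Jaccard distance between two
electrodes' raw signals — improves two-class classification, under both a
static classifier (shared-covariance LDA on a flattened feature vector)
and a dynamic one (a hidden conditional random field consuming the window
sequence), and whether the answer survives a subjects-as-blocks ANOVA.

The pipeline is: synthesize (or adapt) trials → sliding-window feature
extraction → per-subject nested cross-validation per condition → blocked
accuracy table → randomized-blocks ANOVA with Tukey-Kramer post-hocs.

## The synthetic cohort generator

Real motor-imagery recordings cannot ship inside a package, so the
generator is a first-class module, not a test fixture.  It emulates the
standard cue-based feedback paradigm: three bipolar channels (C3, Cz, C4)
at 250 Hz, four runs of 20 randomized trials per class per run (160 trials
per session; the screening preset emits 6 x 10 x 2 = 120), with only the
3-6 s imagery segment emitted by default (750 samples).  Full-trial
synthesis exists behind a flag but is unused by the pipeline.

Each channel is a sum of three spectrally shaped Gaussian processes,
synthesized in the frequency domain and scaled so their *expected*
variance is fixed while per-trial power fluctuates naturally (this is what
gives band-power estimators realistic variance; per-trial empirical
normalization would suppress it):

- **background**: 1/f^alpha noise, `background_sd = 1`, `alpha = 1` — the
  canonical EEG spectral shape;
- **mu and beta oscillations**: band-limited noise (not sinusoids), base
  amplitudes 1 and 0.7;
- **a shared latent mu-band source** mixed into C3 and C4 with per-class
  gain g: each channel's mu component is `sqrt(1 - g^2) * private +
  g * shared`, so the marginal band power is *unchanged* while the C3-C4
  correlation is approximately g² within the mu band.  This is the crucial
  design point: the coupling channel of class information is orthogonal to
  the band-power channel, so tests can switch one off and isolate the
  other.

Class structure enters through `erd_depth` (multiplicative amplitude
attenuation of the channel contralateral to the imagined hand; default
0.9 contralateral, 0.95 at Cz, 1.0 ipsilateral) and through
`coupling_strength` (default 0.45 for left, 0.75 for right — a 0.3
contrast between classes).  The depth default was calibrated once, by
pilot simulation, so that a whole-trial band-power LDA lands near 0.72
accuracy — the operating regime typically reported for this task — rather
than at ceiling, where added features could show no effect.  Subjects
differ by an additive shift on `erd_depth` (sd 0.05, clamped into (0, 1]),
drawn once per subject and reused across sessions; this creates the
between-subject variability that the blocked ANOVA removes.

Seeding is counter-based: per-subject and per-session seeds are derived
from the root seed by a multiplicative-congruential step over (subject,
session) counters, so cohorts are bit-reproducible and independent of
generation order.  What the generator does *not* model: EOG and other
artifacts, feedback-driven adaptation within a session, volume-conduction
mixing beyond the single shared source, and non-stationarities across
sessions.  A passing pipeline on synthetic cohorts therefore demonstrates
correctness and sensitivity of the *analysis*, not performance on real
recordings; the `read_session_adapter()` contract is the hook for the
latter.

## Features

`slide_windows()` uses 0-based half-open ranges `[i, i + k)`, stepping
Δi samples, discarding partial windows — so the window count is
`floor((N - k) / Δi) + 1`, and a window equal to the segment reproduces
the whole-trial (no sliding) analysis as the one-window case.

**Band power** is a Welch-style averaged periodogram integrated over the
band: segments of at least 250 samples are split into two Hann-tapered
half-overlapping sub-segments, shorter windows use a single taper.  The
choice matters at the smallest window (0.5 s = 125 samples, where the
frequency resolution is 2 Hz and the mu band covers 3 bins); a
multi-taper or parametric estimator would be lower-variance but the
averaged periodogram is unbiased, fast, and standard.

**Scaling "to order of magnitude 10"** is interpreted as one global
power-of-ten factor per training fold, chosen so the maximum training-set
band power lands in [1, 10), then reused verbatim on held-out data (which
may therefore exceed 10).  Alternatives (per-feature scaling, per-subject
fixed factors) were considered; a single train-fitted factor is the
weakest assumption that makes the band-power and interaction features
commensurate for the regularized discriminant, and it preserves the
train/test firewall.

**Interaction features** are computed on the raw windowed samples, not on
band envelopes (a band-limited variant is available via the bands
argument chain for exploration, but is not the default).  Pearson
correlation demeans each window first, since its defining ratio assumes
zero-mean variables; the Jaccard measures do not demean, because the
dot-product construction is mean-sensitive by design.  A zero-variance
window yields correlation 0 with a warning rather than an error — a flat
window must not abort a cross-validation fold.  The Jaccard pair
(index J, distance JD = 1 − J) is undefined only when both windows are
identically zero, which is an error.

## The classifiers

**LDA.**  The fit is closed-form: class means, empirical priors, pooled
within-class covariance shrunk as `(1 - λ) S + λ diag(S)`.  Shrinkage is
needed because flattened sliding-window vectors can be long relative to
the per-fold trial count (e.g. 24 windows x 9 features vs ~50 training
trials); λ is tuned by the inner CV over {0, 1e-3, 1e-2, 1e-1}.
Zero-variance diagonal entries are floored at 1e-8 of the largest so that
shrinkage can regularize even a degenerate zero pooled covariance.  All
discriminant evaluations go through one Cholesky factorization (log-det
from the factor, Mahalanobis terms by triangular solves); no inverse is
formed.  Exact score ties go to the lexicographically first label.

**HCRF.**  Each label owns m disjoint hidden states (m may differ per
label); features are first-order: state-observation weights on the raw
per-window feature vector, a per-state bias, and within-label transition
weights.  Transitions across label sets are structurally absent, which is
the disjoint-state-set restriction.  Everything runs in log space —
forward and backward recursions with max-subtraction on both the state
and transition factors — and the partition function is never formed
linearly; scores stay finite for weight scales up to 10³.  The gradient
is expected feature counts (forward-backward node and pairwise marginals)
under the model minus under the label-clamped distribution, plus the
ridge term; it is verified against central finite differences in the
tests.  Training is L-BFGS-B from N(0, 0.1²) seeded starts, stopping at
projected gradient < 1e-5 or 500 iterations; because the hidden-variable
likelihood is non-convex, 3 random restarts are the default and the
lowest final objective wins.  m (default 3, grid {2, 3, 4}) and the L2
strength (grid {0.1, 1, 10}) are tuned by the inner CV; none of these is
dictated by the problem, so all are exposed.

## Evaluation protocol

Five rounds of stratified 3-fold cross-validation, re-seeded per round
from the root seed, with a stratified 4-fold grid search inside every
outer training set; the selected configuration is refit on the full outer
training set.  Stratification keeps the class ratio within one trial per
fold.  Band-power scaling is fitted on the training side of whichever
split is in force — the per-fold factors are recorded in the result so
the property is directly assertable.  Inner-CV ties resolve to the
smallest hidden-state count, then the strongest regularization — the
simplest model wins, deterministically.  Each condition derives its seed
stream from a hash of its own identity rather than its list position, so
extending a condition grid never changes existing rows.  Whether to pool
a subject's sessions before CV was open; the package pools (the
alternative, per-session CV, is a flag away via subsetting the cohort).

## Statistics

"One-way randomized-blocks ANOVA" is implemented as the standard additive
two-way fixed-effects decomposition (treatment + block, no interaction),
F = MS_treatment / MS_residual on ((a−1), (a−1)(b−1)) degrees of freedom;
blocks are estimated but not tested.  The multi-way variant (window size +
slide size + block) is additive main-effects only; the window x slide
interaction is deliberately excluded as the model is linear in its
factors, and a flag can re-add it.  Post-hoc comparisons use the
studentized range with the blocked residual mean square: all-pairs
Tukey-Kramer, plus a *level-vs-overall-average* procedure that compares
each level's mean against the grand mean one-sidedly, rejecting only when
the level exceeds the grand mean and clears the Tukey critical value —
a nonstandard reporting rule implemented exactly as described in the
analysis it mirrors, which is why the baseline condition reports p = 1.
p-values are kept at machine precision internally; the "<0.001" rendering
is applied only at report time.  With fewer than 2 residual degrees of
freedom (e.g. the 2-subject smoke preset) the studentized-range p-value
is undefined and reported as NA with a warning.

Degenerate inputs are handled explicitly: an effect whose sum of squares
is numerically zero reports F = 0, p = 1 even when the residual is also
zero (where the raw 0/0 ratio would be garbage).

## Problem sizes in the test suite

The suite validates the headline property on a scaled-down analogue of
the full comparison: 9 subjects x 80 trials, 2 rounds of 3-fold CV,
whole-trial LDA and 1 s / 0.5 s HCRF windows with a single-point
hyperparameter grid, run twice — once with the default class-coupling
contrast of 0.3 and once with coupling removed.  These sizes were chosen
so the blocked ANOVA has clear power for the ~0.08 accuracy gain the
default generator produces while the whole run stays desk-scale; the full
48-condition grid with the complete 5 x 3 + 4-fold protocol is available
through `experiment_config(preset = "full-grid")`.  Calibration checks
use 2000-replicate null simulations (type-I error of the blocked ANOVA
within [0.035, 0.065] at α = 0.05) and exhaustive hidden-path enumeration
for all sequence lengths ≤ 4 and state counts ≤ 3.

## Known limitations

- The generator's subject effect is a single scalar shift on ERD depth;
  real inter-subject variability is far richer (spectral peaks, SNR,
  spatial topography).
- Correlation and Jaccard features are computed on broadband signals; if
  the coupling of interest is narrow-band, the band-limited variant will
  be more sensitive.
- The HCRF is first-order with label-private states; latent-dynamic
  variants and higher-order transitions are out of scope, as are more
  than two classes.
- Whole-trial conditions make the slide size inert; the full grid still
  enumerates them per slide so the design stays balanced for the
  multi-way ANOVA.
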