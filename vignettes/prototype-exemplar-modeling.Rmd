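---
title: "Prototype and exemplar models of category learning: fitting, strategy classification, and model-based fMRI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prototype and exemplar models of category learning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(protex)
library(dplyr)
```

## The scientific problem

A long-standing question in category learning is whether people represent a
newly learned category by its individual members (exemplars) or by an
abstracted central tendency (a prototype). Both accounts have quantitative
forms that predict, trial by trial, the probability that a stimulus will be
classified into one category or the other, so they can be fit to a subject's
classification choices and compared. Their latent similarity signals can
also be used as parametric regressors for BOLD data, which lets brain
regions be characterised as prototype-tracking or exemplar-tracking even
when behavior alone cannot separate the accounts.

`protex` implements the full analysis pipeline for a two-category design
over stimuli with eight binary features:

1. **design** — the stimulus space, prototypes, training set and
   generalization test sets;
2. **models** — prototype and exemplar similarity, choice probabilities,
   and the summed-similarity ("representational match") latent;
3. **fitting** — maximum-likelihood estimation of attention weights and
   sensitivity from a subject's choices;
4. **strategy** — a per-subject permutation test labeling each subject
   prototype / exemplar / similar;
5. **behavior** — typicality gradients, old-item advantages, linear trends;
6. **fmri** — gamma-HRF design matrices with model-based parametric
   modulators, collinearity screening, OLS GLM, and normalized-beta ROI
   effect sizes;
7. **synth** — synthetic observers and synthetic ROI BOLD with known ground
   truth, so that every stage is testable end to end without any real data.

## The stimulus design

Stimuli are binary vectors of length 8. The category-A prototype is chosen
from a small candidate set and everything is re-coded so that internally
proto-A is `11111111` and proto-B, which shares no features with it, is
`00000000`. Distance is the number of differing features (Hamming
distance); items at distance 0–3 from proto-A belong to category A, 5–8 to
category B, and the 70 equidistant items are never used.

```{r}
s <- build_structure(seed = 1)
s$training
```

The training set is four items per category, each at distance 2 from its
own prototype and 6 from the other, arranged so that within-category
training pairs are 4 apart — category membership cannot be recovered by
clustering the training items alone. Generalization test sets follow the
study schedule: four interim tests of 22 unique stimuli each (8 training
items, 2 prototypes, and 2 new items at each distance 1, 2, 3, 5, 6, 7),
and a final test of 58 unique stimuli (48 new items, 8 per distance, once
each; training items and prototypes twice each; 68 trials). New interim
items are disjoint across cycles; because only eight distance-1 items
exist per prototype, those are fully consumed by the interim tests and
reused in the final test.

```{r}
sets <- build_test_sets(s, seed = 2)
sapply(sets, nrow)
```

## The models

Both models share one parameterisation: attention weights $w$ (eight
non-negative values summing to 1) and a sensitivity $c \in [0, 100]$.
Similarity decays exponentially with attention-weighted city-block
distance. The prototype model compares a stimulus to the two prototypes;
the exemplar model (the generalized-context-model form) sums similarity
over each category's stored training items. Choice follows a Luce rule:
the probability of responding "A" is the A-similarity over the summed
similarity. The distance exponent is fixed at 1, the natural metric for
binary features; other values are rejected rather than guessed at.

Two numerical guards matter in practice: similarities are floored at
1e-300 (at $c$ near 100 and distance 8 the exponential underflows double
precision), and inside the likelihood the choice probability is clipped to
$[\varepsilon, 1-\varepsilon]$ with $\varepsilon = 10^{-10}$ so a single
surprising response cannot produce an infinite misfit.

## Fitting

The misfit of a parameter vector is the negative log likelihood of the
subject's whole response string. Optimization uses a derivative-free
simplex (Nelder–Mead) search, the method traditionally used for these
models, in an unconstrained reparameterisation: $w$ through a softmax of
eight free reals with one pinned to zero, $c$ through a scaled logistic.
This respects the simplex and box constraints exactly without penalty
terms. Because the likelihood is multimodal in $w$, fitting is
multi-start: one start at uniform attention and $c = 1$, plus (by default)
20 random starts with $w$ from a flat Dirichlet and $c$ log-uniform on
[0.1, 20]. Convergence uses a relative function tolerance of 1e-6 with at
most 2000 evaluations per start. The simplex loop is implemented in C++;
the test suite cross-checks it against `stats::optim` on the identical
objective and against a naive R implementation of the likelihood.

Choices during learning are analysed in halves — interim tests 1–2
concatenated, and 3–4 concatenated — and the final test as one block,
with one parameter set fit per block per model. Omitted trials are
excluded from the likelihood and from accuracy denominators.

## Strategy classification

Within a subject, the two fits are compared against a permutation null:
the stimulus sequence is shuffled against the subject's actual response
string, both models are refit, and the difference in fits recorded; 10,000
shuffles replicate the original procedure, while 500 with 5 optimizer
starts per refit (one of them warm-started at the observed fit) is the
scaled-down default used in the tests here. Each model is also tested
against its own null one-tailed (is the fit better than chance?), with the
add-one p-value estimator so p is never exactly zero. The strategy label
is two-tailed on |difference|: "similar" unless the observed difference is
more extreme than 95% of null differences, otherwise "prototype" or
"exemplar" by sign. Whether the original analysis re-ran a full
multi-start search per shuffle is not stated anywhere we know of; the
warm-start economy is a deliberate implementation choice, and the full
setting is available through the configuration objects.

## What the synthetic observers emulate — and what they cannot show

`observer_spec()` defines generative subjects whose per-trial choice
probabilities come from the prototype model, the exemplar model, a convex
mixture, or random guessing, with a per-phase sensitivity schedule to
emulate learning. `simulate_cohort()` draws a cohort (29 subjects by
default, matching the analysed sample size of the study design this
package targets) with independent seeded streams derived from one master
seed.

Simulations with these observers show an important property of the design
itself: with four training items per category at distance 2 and test sets
of 22–68 trials, the prototype and exemplar models mimic each other
closely. A prototype observer's choices are identified reliably; an
exemplar observer's advantage over the best-fitting prototype account is
only a fraction of a nat per test block, so at realistic trial counts its
label is frequently "similar" or even "prototype". The identification is
asymmetric in exactly the way the mimicry analysis predicts: in the
small-sensitivity limit the exemplar model's log-odds are exactly
proportional to the prototype model's on this training structure, and at
high sensitivity both models chase the same deterministic partition of
the stimuli. The "strong" synthetic observers used in the acceptance
checks are therefore defined at sensitivity c = 10 with mildly unequal
attention across the eight features — a well-learned observer whose
choices are close to deterministic for typical items — and are
classified on the final test, the phase with the most trials. Under
these conditions simulated prototype observers are labeled "prototype"
reliably, while simulated exemplar observers remain only partially
identifiable (roughly half are labeled "exemplar", the rest "similar" or
"prototype") at any sensitivity we examined. This asymmetry is an
intrinsic property of the category structure and trial counts, not of
the estimator, and the package reports it rather than masks it. These synthetic observers capture the generative
structure of the models but not, of course, lapses, attention drift,
response bias, or strategy switching in real subjects, so passing tests
demonstrate correctness of the pipeline, not claims about human behavior.

## Model-based fMRI

For each trial the modulation value is the representational match — the
summed similarity of the stimulus to both category representations, the
denominator of the choice rule — under each model's own fitted
parameters. The design matrix has three task regressors: all trial onsets,
the prototype-match modulator, and the exemplar-match modulator, each a
5-s boxcar convolved with a gamma HRF of mean lag 6 s, SD 3 s and phase 0
(shape 4, scale 1.5). Convolution is done on a 16x oversampled grid and
decimated to the TR. The kernel is normalized to unit sum by default
(unit peak is available); the exact amplitude convention cancels in the
normalized effect size. Modulators are not mean-centered by default — the
onset regressor carries the shared mean — but a `center_modulators`
switch provides the demeaned variant, since either convention is found in
practice and the choice is not derivable from the analysis description we
follow.

Runs are screened before fitting: the Pearson correlation between the two
convolved modulators (|r| > 0.9 excludes the run) and the numerical rank
of the task matrix (a constant exemplar modulator, for example, makes the
design rank deficient). The GLM is ordinary least squares per voxel; the
ROI effect size is the mean coefficient across voxels divided by their
standard deviation, averaged over the phase's runs, which de-weighs
noisy estimates the same way lower-level precisions are used in group
analyses. An undefined effect (zero voxel SD) is flagged rather than
silently zeroed.

`bold_spec()`/`simulate_bold()` generate ROI time series that linearly
encode the onset regressor plus a weighted mix of the two modulators with
Gaussian noise and small per-voxel weight jitter. A prototype-coding and
an exemplar-coding region simulated this way reproduce the expected
double dissociation in the normalized-beta effects; this validates the
regressor construction and the effect-size estimator, not any
autocorrelated, drifting, motion-contaminated property of real BOLD,
which is explicitly out of scope (the package consumes preprocessed time
series and user-supplied masks).

## Numerical and design choices

* Trial timing is fixed at 5 s stimulus + 7 s ITI, the event grid of the
  target design; interim tests are single runs, the final test is split
  across four runs of 17 trials.
* All randomness flows from explicit integer seeds through a
  counter-based splitting scheme (`derive_seed`), so any sub-result —
  one observer, one permutation stream — is reproducible in isolation.
* The candidate prototypes from which the raw category-A prototype is
  drawn are configurable; re-coding makes the choice irrelevant to every
  analysis, so the default is four mutually distant vectors.
* Problem sizes in the test-suite and acceptance runs are scaled to
  single-CPU use: 500-permutation nulls with 5 starts per refit,
  10-to-50-subject cohorts, 60-voxel ROIs. The full-size settings
  (10,000 permutations, 21 starts) are plain configuration values.
* Ties and degenerate inputs error loudly: equidistant stimuli in a
  scoring call, empty exemplar sets, rank-deficient designs, zero voxel
  SD, and exhausted stimulus pools all raise informative conditions
  instead of returning numbers.

## Known limitations

* The distance exponent r is implemented only at 1; the behavior of the
  similarity kernel at other exponents is deliberately unimplemented.
* The permutation classifier inherits the design's weak exemplar
  identifiability at the study's trial counts; this is a property of the
  category structure, not of the estimator, and the package reports it
  honestly rather than compensating for it.
* No hierarchical or Bayesian fitting, no AIC/BIC (the two models have
  equal parameter counts, so raw likelihood comparison is the intended
  contrast), and no replication of FSL's prewhitening; the GLM here is
  plain OLS on preprocessed series.
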