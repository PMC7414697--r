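---
title: "Non-uniform label smoothing for ordinal disease grading"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Non-uniform label smoothing for ordinal disease grading}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ordsmooth)
```

## The problem

Diabetic retinopathy (DR) grading assigns each fundus photograph one of
five ordered severity stages, 0 (no DR) through 4 (proliferative DR). Two
properties make this harder than generic multiclass classification. First,
the grades are *ordinal*: predicting stage 4 for a healthy eye is a far
worse error than predicting stage 1, yet the standard cross-entropy (CE)
loss with one-hot targets penalizes both identically. Second, annotations
are *noisy in a structured way*: expert graders who disagree almost always
disagree by one neighboring stage, so the labels a model trains on carry
neighbor-concentrated ambiguity. Screening datasets are also severely
imbalanced — in the reference screening profile bundled with this package,
about 78% of gradable images are stage 0 and fewer than 1% are stage 3.

`ordsmooth` implements a label representation that encodes the ordinal
structure directly into the training targets, together with the complete
evaluation and significance-testing protocol appropriate for grading
models.

## Label schemes

Three ways of encoding an annotated grade $y \in \{0, \dots, K-1\}$ as a
length-$K$ target vector:

* **Hard (one-hot).** All mass on the annotated grade.
* **Uniform label smoothing (ULS).** A convex mixture with the uniform
  distribution: the true grade gets $(1-a) + a/K$ and every other grade
  $a/K$. The smoothing weight $a$ (argument `alpha`, default 0.1) controls
  the regularization amount; the redistribution is divided by $K$, the
  number of classes, so every ULS label sums to exactly 1. ULS ignores the
  ordinal structure — mass leaks equally to adjacent and distant grades.
* **Non-uniform (Gaussian) label smoothing (N-ULS).** The target for
  grade $j$ is the mass of a Gaussian centred at the annotated grade $y$,
  integrated over the unit bin $[j - 0.5, j + 0.5]$:
  $q_j = \Phi\!\big(\tfrac{j + 0.5 - y}{\sigma}\big) -
         \Phi\!\big(\tfrac{j - 0.5 - y}{\sigma}\big).$
  Mass decays with grade distance, so the target itself expresses that a
  stage-2 image is "almost stage 1 or 3, certainly not stage 4".

Bin integration (rather than sampling the density at integer grades) is
used because it gives the neighborhood constraint below an exact meaning
and produces the corner-grade mass deficit discussed next.

### Choosing the decay factor

Rather than tuning $\sigma$ directly, it is derived from an interpretable
constraint: a fraction `neighbor_mass` (default 0.95) of the Gaussian's
mass must fall within the true grade and its two immediate neighbors,
i.e. within $[-1.5, +1.5]$ grade units of the centre.
`sigma_for_neighbor_mass()` solves
$\Phi(1.5/\sigma) - \Phi(-1.5/\sigma) = m$ by root bracketing on
$[10^{-6}, 50]$ grade units to an absolute tolerance of $10^{-10}$; for
$m = 0.95$ this gives $\sigma \approx 0.765$.

```{r sigma}
sigma_for_neighbor_mass(0.95)
round(nuls_encode(2, 5), 4)
sum(nuls_encode(2, 5)[2:4])   # exactly the neighbor mass
```

### Corner grades and renormalization

At the scale boundaries part of the Gaussian's mass falls outside the
grade range, so unrenormalized corner labels sum to less than 1:

```{r corners}
round(rbind(g0 = nuls_encode(0, 5), g2 = nuls_encode(2, 5)), 4)
rowSums(rbind(g0 = nuls_encode(0, 5), g2 = nuls_encode(2, 5)))
```

The package's default keeps labels *unnormalized*: the mass at the
annotated grade (the "degree of truth" the loss pushes towards) is then
identical for every grade, including the corners, which keeps the
per-grade supervision strength uniform. Renormalizing instead
(`renormalize = TRUE` in `smoothing_config()`) makes corner labels sum to
1 but inflates their peak, giving grades 0 and $K-1$ systematically
sharper targets. Both variants are provided; the unnormalized one is the
default. The soft cross-entropy loss is linear in the target, so
unnormalized targets are consumed as-is, without hidden rescaling.

## Evaluation protocol

`evaluate_metrics()` computes the six-metric panel used throughout:

* **Quadratic-weighted kappa** — chance-corrected agreement with weights
  $w_{ij} = (i-j)^2/(K-1)^2$, the standard statistic for inter-observer
  grading agreement. It is the headline metric here because it penalizes
  exactly what ordinal smoothing targets: errors far from the true grade.
* **Pairwise-averaged multiclass AUROC** — for every class pair present,
  the rank-based (Mann–Whitney, ties 0.5) AUROC in both score directions,
  averaged per pair and then across pairs.
* **Support-weighted precision, recall, F1** — per-class values averaged
  with weights equal to the true class supports, so the panel remains
  interpretable under heavy imbalance. A class that receives no
  predictions contributes 0 to its precision term (with a warning) rather
  than poisoning the average with a 0/0.
* **Multiclass Matthews correlation coefficient** — the covariance-style
  generalization of binary MCC; degenerate marginals yield 0 by
  convention, flagged with a warning.

Arg-max predictions break score ties toward the *lower* (less severe)
grade index — a deterministic, conservative convention.

## Significance testing

`bootstrap_compare()` implements a paired, stratified bootstrap: in each
of `n_boot` (default 1000) replicates a single index set — drawn with
replacement *within each true-grade stratum*, so every replicate preserves
the exact class counts — is applied to both models' predictions, and the
metric difference is recorded. The two-sided percentile p-value uses
add-one smoothing, $p = 2\min(\#\{\Delta^* \le 0\} + 1, \#\{\Delta^* \ge
0\} + 1)/(B+1)$, capped at 1, so $p = 0$ is impossible and the minimum
attainable p-value with $B = 1000$ is about 0.002. With two simultaneous
comparisons (N-ULS vs CE and N-ULS vs ULS) the Bonferroni-corrected
decision threshold is $0.05/2 = 0.025$. Pairing uses the same resample
for both models because the quantity of interest is the difference; independent
resamples would inflate its variance. One master seed spawns one RNG
sub-stream per replicate, so reports are bit-reproducible and independent
of execution order.

## The synthetic grading task

`simulate_dataset()` produces a desk-scale stand-in for a fundus-grading
dataset with the statistical structure the method assumes:

* **Prevalence.** Clean grades are drawn i.i.d. from the bundled screening
  profile (`default_prevalence()`: 0.778 / 0.031 / 0.169 / 0.006 / 0.017),
  i.e. the same severe imbalance a real screening programme produces.
* **Features.** In *vector* mode each of `feature_dim` (default 4)
  dimensions is the latent grade plus independent Gaussian noise
  (`severity_noise_sd`, default 1.0 grade units — enough overlap that
  adjacent grades are genuinely confusable, as in real grading). In
  *image* mode each sample is a small circular fundus-like field
  containing Poisson$(1 + 3 \cdot \text{grade})$ bright lesion blobs at
  random positions plus pixel noise, clamped to $[0,1]$: a countable,
  strictly grade-monotone severity signal.
* **Annotator noise.** Each training label is independently perturbed with
  probability `annotator_noise_rate` (default 0.3); a perturbation moves
  ±1 grade with probability `neighbor_bias` (default 0.9, reflected at the
  boundaries) and otherwise jumps to a random non-neighbor grade.
* **Split.** Stratified 75/10/15 train/validation/test by clean grade with
  floor allocation and remainders assigned in that order.

What the generator does **not** emulate: photorealistic fundus appearance,
camera and illumination artifacts, grader-specific bias, multi-grader
panels, or an "ungradable" category. Passing tests on this generator show
that the machinery behaves as specified under the assumed noise structure;
they are not evidence about real fundus images.

## Training harness

`train_model()` fits a linear scorer or a small one-hidden-layer network
(`small_net`, tanh, width 32; for images a fixed block-mean pooling stage
reduces the input to an 8×8 lesion-density map first) by plain mini-batch
SGD with learning rate 0.001 and batch size 8 — the optimization
conventions of the comparison design — for at most 30 epochs. Inputs are
standardized with a scaler fitted on the training split. The label scheme
is applied to the *noisy training annotations only*; after each epoch the
cross-entropy against hard validation labels is monitored, training stops
once it fails to improve for more than `patience` (default 5) epochs, and
the best epoch's parameters are kept. Smoothing is an optimization device;
assessment is always against hard grades.

## The three-arm experiment and its regime

`run_experiment()` reproduces the comparison design end-to-end: one
dataset, three arms (CE, ULS with $a = 0.1$, N-ULS with neighbor mass
0.95) trained on identical data and settings, the six-metric panel on the
test split against the clean grades, and the two paired bootstrap
comparisons.

The defaults put the experiment in the image + `small_net` regime, and
this choice is deliberate. The smoothing contrast is a statement about
*regularization*: it requires a model expressive enough to be distorted by
noisy, imbalanced supervision. In the low-dimensional vector/linear
pairing all three schemes drive the classifier toward the same decision
boundaries (adding a constant or a symmetric neighbor kernel to the
targets does not move the arg-max of the asymptotic solution), so that
regime — kept as a fast diagnostics setting — cannot separate the schemes
and, while still under-trained, favours whichever target is sharpest. The
higher-dimensional image task with a nonlinear scorer is where the
target's shape influences what the model learns from noisy labels, and is
the regime the method is for. The directional property — N-ULS matching or
beating CE on test quadratic-weighted kappa across seeded replications,
and beating ULS on average — is asserted by the test suite at the default
conditions (about 2000 training images, noise rate 0.3, neighbor bias
0.9, 10 seeds).

ULS's default $a = 0.1$ is the conventional smoothing amount in the image
classification literature; no claim is made that it is optimal here.

## Numerical conventions

* Probabilities are clamped at $10^{-12}$ before logs; well below any
  metric resolution used.
* The decay-factor solver brackets $[10^{-6}, 50]$ grade units, tolerance
  $10^{-10}$.
* Score ties in the AUROC count 0.5; arg-max ties resolve to the lower
  grade.
* Degenerate metrics (single-class tables, empty marginals) warn and
  return `NA` (kappa, AUROC) or 0 (MCC) rather than failing silently.
* All randomness flows from explicit integer seeds; datasets, training
  histories and bootstrap reports are bit-reproducible.

Problem sizes used by the bundled checks — 200-instance oracle-equivalence
sweeps for the metrics, 1000-replicate bootstraps, and the 10-seed
three-arm experiment at ~2700 images of 32×32 pixels — were chosen so the
whole suite runs comfortably on a single CPU.

## Limitations

* The trainer is a desk-scale harness, not a replacement for training a
  deep network on real images; conclusions about real fundus data require
  real data.
* The bootstrap p-value is a percentile construction; it is well suited to
  paired model comparison but is not a confidence-interval procedure.
* Only Bonferroni correction across the two planned comparisons is
  provided.
* The "ungradable" category present in real screening data is excluded
  throughout, mirroring its exclusion from the grading task itself.
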