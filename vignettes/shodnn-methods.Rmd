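---
title: "Sea Horse Optimization training of gesture-recognition networks: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sea Horse Optimization training of gesture-recognition networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shodnn)
```

## The problem

Medication adherence monitoring with a wrist-worn inertial sensor reduces to
a gesture-recognition task: the five hand movements of taking a pill
(opening the bottle, tipping a pill out, tossing it to the mouth, drinking
water, closing the bottle) must be recognized in tri-axial accelerometer and
gyroscope streams, against a background of everything else the hand does.
This package implements the full pipeline — per-sensor CSV ingestion,
sliding-window segmentation and featurization, z-score normalization, a
small fully connected classifier whose weights are found by the Sea Horse
Optimization (SHO) swarm metaheuristic, and ten-fold cross-validated
evaluation — together with a synthetic signal generator that stands in for
the study data, which were never deposited.

## Sea Horse Optimization

SHO maintains a population of `pp` candidate solutions in a box
`[lb, ub]^Dm` and repeats three phases for `T` iterations, always tracking
the *elite* (the current lowest-fitness individual):

* **Movement.** A standard-normal draw `r1` splits the population roughly in
  half. With `r1 > 0` the individual spirals toward the elite:
  `Xnew1 = Levy * (X_elite - X_i) * x*y*z + X_elite`, where
  `x = rho*cos(theta)`, `y = rho*sin(theta)`, `z = rho*theta` and
  `rho = u*exp(v*theta)` with `u = v = 0.05`, `theta ~ U(0, 2*pi)`, and the
  Lévy step `s*w*sigma/|k|^(1/lambda)` (scale `s = 0.01`, exponent
  `lambda = 1.5`, `sigma` from the Mantegna closed form) supplies occasional
  long jumps. With `r1 <= 0` it diffuses:
  `Xnew1 = X_i + rand*l*beta*(X_i - beta*X_elite)` with `l = 0.05` and
  `beta` standard normal.
* **Predation.** A uniform draw `r2` succeeds with probability 0.9
  (sea horses catch their prey about nine times in ten). Success pulls onto
  the elite, `alpha*(X_elite - rand*Xnew1) + (1-alpha)*X_elite`; failure
  explores away, `(1-alpha)*(Xnew1 - rand*X_elite) + alpha*Xnew1`. The step
  size `alpha = (1 - t/T)^(2t/T)` decays from 1 through 0.5 at `T/2` to 0.
* **Breeding and selection.** The population is sorted by fitness; the
  better half (fathers) pairs with the worse half (mothers) and each pair
  produces one offspring `r3*father + (1-r3)*mother`. The `pp` predated
  individuals plus `pp/2` offspring form a 1.5 `pp` pool from which the best
  `pp` survive. The best-so-far solution is tracked outside the population,
  so the reported trajectory is monotone even when selection loses the
  historical best.

### Readings the source equations leave open

The source formulation is typeset ambiguously in places; the package fixes
one reading per ambiguity and exposes switches where both are defensible:

* The spiral move is implemented with the elite as its fixed point (an
  individual already sitting on the elite stays there). A typeset reading
  with a leading `X_i +` term exists but contradicts the fixed-point
  behaviour of a spiral "toward the elite".
* The Brownian factor `beta` is described both as a standard-normal *draw*
  and by the normal *density* formula; it is implemented as a draw, which is
  the only reading that actually produces motion.
* The Lévy numerator/denominator variates `w`, `k` are drawn Uniform(0, 1)
  as the text states ("on a scale of zero to one"), with `k` re-drawn at
  exactly 0; `levy_normal = TRUE` selects the classical Mantegna scheme with
  normal draws.
* `theta` is drawn on `(0, 2*pi)` per the prose; the pseudocode's
  `(-2*pi, 2*pi)` is available through `theta_range`.
* Per-individual scalars vs. per-coordinate vectors: `r1`, `theta`, `r2`,
  `r3` are scalar per individual (the spiral coefficients `x`, `y`, `z`
  multiply the whole difference vector as scalars), while the Lévy variates,
  the Brownian `beta` and the uniform `rand` factors are drawn per
  coordinate. Scalar draws everywhere would make every proposal a rank-one
  perturbation of the current point, which measurably cripples the search in
  the several-hundred-dimensional weight spaces this package exists for.
* Out-of-bounds proposals are clipped to the box.

## The network and its training

The classifier is a small fully connected network: affine layers, a hidden
activation (default the radial-basis bump `exp(-z^2)`, named in the source
hyperparameter table; logistic, tanh and relu are available), and a
per-class sigmoid output layer scored by mean squared error against one-hot
targets (softmax is available but non-default). All weights and biases live
in one flat vector — `param_count()` gives its length, and the printed
"151 weights and biases" figure is reproduced exactly by the
`[13, 10, 1]` preset. The published hyperparameter table is internally
inconsistent (three hidden layers of ten neurons cannot give 151 parameters
for any input size), so both readings ship as `network_presets()` and
neither is asserted as canonical.

`shodnn_train()` hands the flat vector to SHO, which minimizes the training
cost inside `[-weight_bound, weight_bound]^N` (default 5: sigmoidal units
saturate beyond `|z|` of about 5, so wider boxes waste budget). Two hybrid
ingredients are enabled by default:

* **Offspring mutation** (`mutation_p = 0.2`, `mutation_sd = 0.5`). The
  source training pseudocode generates offspring "by combining and mutating
  the selected parents"; the standalone breeding equation contains only the
  convex combination. Pure convex recombination proposes points only inside
  the population's convex hull while movement and predation propose
  multiplicative perturbations of the elite; together they stall at
  constant-output networks (we measured flat best-so-far traces over
  hundreds of iterations). The sparse Gaussian mutation restores an additive
  proposal direction and is the package's reading of the pseudocode.
* **Gradient-descent refinement** (`refine_with_gd = TRUE`, `eta = 0.5`,
  `epochs = 300`). The network's gradient-descent update is fully specified
  in the source (backpropagated analytic gradient; the update is implemented
  as descent, i.e. with a minus sign — the typeset plus sign would ascend
  the cost). The population search is global but slow to fine-tune several
  hundred weights within its evaluation budget; full-batch descent from the
  SHO optimum is the natural local polish, and the refinement keeps the
  best-seen parameters so it can never worsen the cost. Setting
  `refine_with_gd = FALSE` and `sho = list(mutation_p = 0)` recovers the
  bare population search.

Binary problems use one 0/1 output with threshold 0.5 (a score of exactly
0.5 predicts the positive class); multi-class problems use arg-max over
per-class sigmoid scores with ties broken toward the lowest class index.
The abstract-level claim that the optimizer also tunes the number of hidden
layers is implemented as an outer validation loop
(`optimize_architecture()`), not as an extra search dimension: the
population updates are real-vector arithmetic and have no meaningful action
on an integer depth coordinate.

## Preprocessing

`fit_zscore()` / `apply_zscore()` standardize each feature column with the
population SD (divisor `n`; the formula's divisor is unstated and the
population form keeps a single-row table defined). Constant columns
transform to 0 instead of dividing by zero. Models are always fitted on
training folds only and applied unchanged to test folds; whether the
original study fitted per fold or globally is unstated, and the per-fold
choice is the stricter, leakage-free one.

## The synthetic gesture generator

`simulate_dataset()` emulates the reference data's shape: 15 participants
and at least 4116 labeled one-second windows (50% overlap) at 100 Hz, the
device's streaming rate. Each gesture is a raised-cosine-windowed sinusoid
burst on a dominant axis — sustained gyroscope oscillation with opposite
mean sign for opening vs. closing the bottle (distinct frequency bands),
a brief accelerometer pitch transient for tipping a pill, a sharp
accelerometer spike for tossing it to the mouth, a slow large arc for
drinking — over a 1 g gravity baseline, low-amplitude smoothed background
motion, white sensor noise (defaults 0.05 g and 2 deg/s, realistic for
wrist IMUs against ~1 g / ~150 deg/s gestures), and a lognormal per-subject
gain (sdlog 0.1) standing in for inter-subject variability.

Because long gestures cover many sliding windows and short ones few, episode
counts per gesture are set inversely to each template's expected window
yield (`balanced_episode_counts()`), keeping the five gesture classes within
±10% of one another; the default target of 55 windows per class per subject
was chosen once so the default corpus exceeds 4116 windows with a small
margin. A window takes the label of the annotation overlapping it most
(ties toward the earlier annotation; BACKGROUND when none overlaps), so
windows at episode edges carry a gesture label while containing mostly
background signal. This deliberate label noise mirrors real sliding-window
annotation and is why even the zero-noise corpus is not exactly 100%
fittable by a 10-neuron network — the per-class sample counts, not the
signal model, are the quantity the generator controls exactly. What a green
end-to-end test establishes is therefore that the pipeline separates
well-formed, realistically noisy burst signatures — not that it would reach
the same numbers on the study's unpublished recordings.

## Evaluation

Metrics come from one-vs-rest confusion counts: accuracy, sensitivity
(recall), precision and F1 per class, macro-averaged by default (the
published single-number summaries do not state their pooling; macro is
robust to the BACKGROUND class imbalance). Zero denominators yield 0 with a
warning rather than NaN so fold means stay defined. `ten_fold_cv()` uses
stratified folds (shuffle each class, deal round-robin), fits the z-score
model per fold, and appends a mean row that is exactly the arithmetic mean
of the ten fold rows; the published per-fold table's printed averages do not
equal its column means, and this package reports recomputed means only.
`comparison_report()` differences a result vector against the published
competitor table (NA entries preserved) and reports the min/max difference
per metric. Both the 80:20 holdout and ten-fold protocols are exposed;
ten-fold is the headline path.

## Numerical choices and degenerate inputs

* Logistic units use the stable branch form; pre-activations are clipped at
  ±500 before exponentiation.
* The relu subgradient at 0 is 0; the radial-basis derivative is
  `-2 z exp(-z^2)`.
* Ties in arg-max prediction go to the lowest class index; the binary
  threshold is `>= 0.5`.
* Empty recordings segment to zero windows (not an error); trailing
  fragments shorter than a window are dropped; malformed CSV rows are
  dropped and counted; non-monotone timestamps are an error naming the first
  offending row.
* Fold assignment falls back to unstratified (with a warning) when a class
  has fewer members than folds.
* All randomness flows through R's RNG under a caller-supplied seed: a fixed
  seed reproduces an optimization trajectory, a simulated corpus and a
  trained model bit for bit.

## Known limitations

* SHO alone (no mutation, no refinement) is adequate for low-dimensional
  search but stalls on network weight spaces; the package's defaults reflect
  that finding rather than hiding it.
* The generator makes no attempt at biomechanical realism, magnetometer
  physics, sensor drift or missing data; it controls class structure and
  noise level, nothing more.
* Batch normalization is mentioned in the source prose but absent from its
  hyperparameter table; it is not implemented (a no-op placeholder would
  change nothing the optimizer sees).
* Published headline figures (98.59% accuracy etc.) were computed on private
  recordings and are not reproducible here; the package reproduces the
  in-paper worked arithmetic (parameter counts, comparison differences) and
  validates everything else property-based on synthetic data.
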