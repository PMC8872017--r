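---
title: "Methods: GA-based cell search for sepsis onset prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: GA-based cell search for sepsis onset prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's own account of the model it implements, the
parameters that matter, what the synthetic generator does and does not
emulate, and the design decisions taken where the method description left
the design open. It states no empirical result that the test suite does not
itself compute.

## 1. Labeling model

An admission is represented as an hourly grid of 40 features. SIRS is scored
per hour with the standard two-of-four criteria (temperature > 38 or
< 36 degC, HR > 90 bpm, RR > 20 /min, WBC > 12 or < 4 x10^3/mm^3); a missing
feature contributes zero to the count, which biases the flag toward
specificity in sparse hours. Sepsis onset is the first hour of the earliest
continuous SIRS run of at least 5 h, and requires infection evidence —
any antibiotic prescription for the admission, matched case-insensitively
against a configurable drug list. Both the thresholds and the list are
config-overridable; the defaults are the package's reading of the cited
clinical standard, which the method description does not reprint.

Windows of exactly 5 h slide forward 1 h at a time; a window starting at
hour `s` is emitted while `s + 5 + T <= L` (record length), generalizing the
stated 8 h minimum at `T = 3` to `5 + T`. The label is 1 iff onset falls
exactly at the target hour `s + 5 + T`. Two points were genuinely open:

* **Post-onset windows.** Whether windows at or after onset were emitted as
  negatives is unstated. They are suppressed here: treating the established
  septic state as a "negative" would teach the classifier that florid SIRS
  means no sepsis — label leakage in reverse.
* **Exact-hour labeling.** A +/- 1 h tolerance is exposed in
  `extract_episodes()`-level code paths via the onset equality rule but off
  by default; the single-target-hour reading matches the sliding-window
  illustration.

Hours are 0-based; windows are half-open `[s, s + 5)`; within-hour values
are averaged and times floor-bucketed — the simplest defensible conventions,
fixed once.

Class balancing oversamples positives (with replacement, originals retained)
and undersamples negatives to a common target; the description prescribes
both directions but no target ratio, so the geometric mean
`round(sqrt(n_pos * n_neg))` is used — it moves both classes symmetrically
on the log scale. Balancing precedes the random 5:3:2 split
(largest-remainder rounding), matching the published dataset-construction
figure; consequently duplicated positives can appear in the test split,
which is one reason synthetic-data metrics must not be read as clinical
performance.

## 2. Preprocessing

**GP imputation.** Each feature series is imputed by the posterior mean of a
GP with squared-exponential kernel over the time axis, fitted per series —
never across patients. Kernel hyperparameters are fixed (length scale 3 h,
unit signal variance on internally standardized values, noise variance
1e-2) rather than optimized: the description names the method but no kernel,
and fixed values keep every run deterministic. Imputation conditions only on
observations *inside* the 5 h window, so no post-window information leaks
into an episode; a column with no observations falls back to the
training-split feature mean. Because GP extrapolation can leave the
physiologic range, an optional clamp range is supported and clamps are
applied to imputed values only.

**Normalization and denoising.** Features are z-scored with training-split
statistics (scale fallback 1 for constants). The denoising autoencoder is a
symmetric tanh MLP on the flattened window (200 inputs; default widths
200-128-100-128-200), trained with Gaussian input corruption (sd 0.1 on
z-scored data) to reconstruct its input, Adam at 1e-3. The architecture,
depth and corruption level are package defaults, not reconstructions — the
description specifies none of them. The DAE is trained once on the training
split and applied uniformly to all splits, per the stated data flow
(impute, then normalize, then denoise).

## 3. Cell encoding and the search space

Each node after the first selects exactly **one** predecessor. This is the
unique reading under which the stated genotype count `4^N (N-1)!` is exact,
and it matches the weight-sharing cell-search convention the method builds
on; "skip connections" then arise as edges that bypass intermediate nodes.
Multi-parent aggregation is out of scope. Node 1 alone sees the input and
the previous state; the cell output — the average of terminal (out-degree-0)
nodes — is also the recurrent state fed back to node 1. The recurrence
wiring is not specified in the text; this choice follows the cited
convention. The classification head (hidden -> 2 softmax) is global, lives
in the shared store under a reserved key, and is not a genetic property, so
GA operators act on cell genes only.

Weight genes exist for *all possible* edges, not just selected ones, so
crossover and mutation can recombine latent connections. Weights have dual
residence: chromosomes carry weight genes (inherited through crossover),
and a global store shares learned matrices across lineages. At
materialization the store wins; chromosome genes seed the store when a key
is absent; after training, `commit_weights()` writes the learned matrices to
both.

## 4. GA settings

Population 100, elite fraction 0.10, crossover rate 0.7 and the 3x roulette
cap are the stated values (desk-scale runs shrink the population and
generations, stated per test). Decisions taken here:

* **Mutation rate** is absent from the description: default 0.1,
  config-exposed, reported in the per-generation log.
* **Roulette rescaling compresses only** (identity when max/min <= cap):
  the stated motivation is preventing starvation of weak chromosomes, not
  sharpening selection; an additive shift `b` with `max + b = 3 (min + b)`
  achieves exactly the 3x ratio.
* **Crossover cut points are independent per property** (activations,
  connections, weight genes); the text says properties cross "between
  themselves" but not whether one cut is shared.
* **Elites** are `max(1, floor(0.1 * size))`, ties broken by lower id, and
  parents are drawn with replacement — determinism and simplicity.
* **Stop rules.** The stated "10 epochs / 200 epochs" rule is ambiguous
  between child training and the outer loop; it is applied to child
  training (patience 10, cap 200), while the outer loop has its own
  plateau patience (10 generations) and cap (50). During search, children
  run under a reduced epoch cap (default 10) — a deliberate desk-scale
  deviation; the full rule is reserved for final retraining.
* One master seed forks labeled sub-streams (init/selection/training/
  bootstrap), so component behavior is independently reproducible.

## 5. The synthetic world

The generator emulates the *structure* of an ICU extraction, not its
marginals: per-feature cadences (monitored vitals charted about twice an
hour, labs a few times a day, escalating during the septic run), mid-hour
timestamps with +/- 15 min jitter, duplicate source ids, a configurable
fraction of events in alternate units (degF, lb, g), occasional charted
copies of lab values (exercising lab priority), row-level missingness, and
antibiotic prescriptions — for every septic patient near the infection
time, and for some controls without SIRS.

Sepsis patients carry an intended-SIRS run of >= 5 h (temperature ~38.8,
HR ~110, RR ~26, WBC ~14.5 during the run) preceded by a linear-in-
amplitude drift of the same features (plus lactate) toward just-below-
threshold values, starting `signal_lead_h` (default 12) hours before onset
and attenuated by `signal_decay` (default 0.9) per hour of lead. The drift
is what a recurrent cell can exploit, and its decay is what makes
performance fall with the prediction horizon. Defaults were chosen once as
a plausible stated world: 48 h mean stay (clamped 24-96 h), onset no
earlier than hour 18 (so every horizon up to 12 h has room), prevalence
and missingness as configured.

What a green test does **not** establish: realism of marginal
distributions, inter-feature physiological correlation, informative
missingness, treatment confounding, or clinical transportability. With the
default decay, substantial signal survives even at 12 h lead, so the
horizon sweep shows a *shallow* decline; the acceptance criterion therefore
checks non-increase within a 0.03 tolerance rather than strict monotonicity.

The generator's contract that downstream detection recovers >= 95% of
planted onsets at missingness <= 0.1 drove two structural choices: vitals
are charted twice hourly (so a dropped row rarely blanks an hour) and labs
triple their cadence during the septic run (escalation of care). One spec
invariant was found incoherent under exact-hour labeling — "label
prevalence among episodes increases with `signal_lead_h`" — because the
number of positive windows is fixed at one per septic admission regardless
of the drift's lead; it is recorded as unattainable rather than tested
against a different quantity.

## 6. Numerical choices

* AUROC is computed by the rank statistic (ties 1/2), which equals the
  trapezoidal ROC area; confidence intervals are percentile bootstrap over
  episodes (2000 replicates by default), since the reference CI method is
  unreported. Degenerate one-class resamples are redrawn (capped).
* The operating point for sensitivity/specificity is 0.5 on the softmax
  positive-class score — also unreported in the reference.
* All training is plain-R minibatch Adam with hand-written backpropagation,
  verified against finite differences in the test suite; early stopping
  restores the best-validation-loss weights.
* The baseline comparator is a single-layer GRU with the same hidden size,
  training regime and scoring path as the searched cells.

## 7. Known limitations

* Desk-scale only: `N = 12`, population 100 and 200-epoch children are
  supported but not exercised by the tests; the acceptance run uses
  `N = 5`, population 12.
* The GP is refit per window (5 points), which is exact but wasteful; a
  per-admission fit with window slicing would be faster at identical
  output only if windows were imputed before filtering, which would change
  the missingness accounting.
* Scoring-system comparators (SOFA/qSOFA/SAPS II) and ICD-based labeling
  are intentionally absent; the 12-node architecture reported by the
  reference is not numerically specified and no fixture asserts it.
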