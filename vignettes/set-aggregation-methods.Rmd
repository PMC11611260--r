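---
title: "Learned set-level aggregation of single-cell morphological profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Learned set-level aggregation of single-cell morphological profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Image-based cell profiling measures hundreds to thousands of morphological
features for every segmented cell in a well, then compares *wells* — so the
per-cell feature table must be collapsed into one profile per well. The
near-universal choice is the per-feature average. Averaging discards
everything about a cell population except its first moment: two perturbations
that shift the *shape* of the population (its covariance, its skewness, the
mix of subpopulations) while leaving the mean unchanged are invisible to an
average profile.

`cytosets` replaces the average with a learned, permutation-invariant
aggregation function and provides the evaluation and interpretation machinery
around it: retrieval-based scoring of profile quality, a per-cell relevance
decomposition of the trained model, the classical average-profiling baseline
it is compared against, and a synthetic-data generator that produces
populations whose class identity lives purely in higher moments — the
situation where learned aggregation should pay off, and measurably does.

## The aggregation model

A well is a set $X \in \mathbb{R}^{M \times D}$ of $M$ cells with $D$
features. The aggregator is a Deep Sets network

$$ f(X) \;=\; \rho\!\left( \sum_{m=1}^{M} \phi(x_m) \right), $$

where $\phi: \mathbb{R}^D \to \mathbb{R}^{N}$ is one fully connected layer
(default $N = 2048$) with a leaky ReLU, and
$\rho: \mathbb{R}^{N} \to \mathbb{R}^{L}$ is two fully connected layers (512
then $L = 2048$ units), each with a leaky ReLU. Summation is the only
interaction between cells, so $f$ is exactly permutation invariant and accepts
any $M \ge 1$. Sums of nonlinear per-cell maps can approximate general
moment statistics of the population, which is what lets the profile encode
covariance and skewness structure that the plain mean cannot.

Two consequences of *sum* (rather than mean) pooling are worth knowing:

* $\lVert z \rVert$ grows with the number of cells $M$. The training
  augmentation draws sets of variable size, which exposes the network to this
  variation, but the property is inherent to the architecture and documented
  rather than "fixed". A mean-pooling switch is not provided.
* Padding wells to a common size would corrupt the sum through $\phi$'s bias
  term, so batches are processed as lists of sets; results are identical to
  sequential per-well evaluation.

Parameters that matter:

| parameter | default | meaning |
|---|---|---|
| `phi_dim`, `hidden_dim`, `out_dim` | 2048, 512, 2048 | layer widths of $\phi$ and $\rho$ |
| `leaky_slope` | 0.01 | negative-region slope of all activations |
| `seed` | — | weight initialization, uniform fan-in $U(\pm 1/\sqrt{\text{fan-in}})$ |

The widths are configurable because the appropriate capacity scales with the
problem: the desk-scale experiments in this package use 256/64/256 (or
128/64/128 for the repeated-seed interpretability study), which is ample for
20-feature synthetic populations and keeps a full experiment in seconds on
one CPU. Defaults remain the full-scale widths.

## Training objective and augmentation

Profiles are compared by cosine similarity, and the model is trained with the
supervised contrastive (SupCon) loss using perturbation identity as the
label: for each anchor $i$ with positive set $P(i)$ (other samples of the
same perturbation) and comparison set $A(i)$ (all other samples),

$$ \mathcal{L} = \sum_i \frac{-1}{|P(i)|} \sum_{p \in P(i)}
   \log \frac{\exp(v_i \cdot v_p / \tau)}
             {\sum_{a \in A(i)} \exp(v_i \cdot v_a / \tau)}, $$

with embeddings L2-normalized before dot products. Two formulation choices
are deliberately exposed:

* `denominator`: `"all"` (default; the standard SupCon form, $A(i)$ = every
  sample but the anchor) or `"negatives_only"`. The latter variant appears in
  some descriptions of the loss; both are implemented and tested against a
  brute-force oracle, the default is the standard form.
* `anchor_reduction`: `"mean"` (default; scale-free across batch sizes) or
  `"sum"` (the loss exactly as written above). Analytic test values use the
  sum form.

Each epoch, every perturbation contributes
`sets_per_perturbation_per_epoch` (default 2) augmented views: a set size is
drawn from a Gaussian (default mean 400, sd 100, floored at 1), and cells are
sampled with replacement either from one replicate well or — on a coin flip
with probability `mix_probability` (default 0.5) — from the pooled cells of
two distinct replicate wells. Mixing composes sets across plate positions and
counteracts well-position effects.

Optimization is AdamW (decoupled weight decay) with defaults
`learning_rate = 5e-4`, `weight_decay = 1e-2`, up to 100 epochs. After each
epoch the un-augmented validation wells are aggregated and scored by
replicate-retrieval mAP, with the training wells present in the candidate
pool as distractors (a small held-out compound set alone saturates
immediately); the checkpoint with the highest validation mAP is returned,
ties resolved toward the later epoch because the contrastive loss continues
to fall at equal validation performance. All randomness flows from one seed
recorded in the result; identical seeds reproduce logs and profiles
bit-for-bit.

At the package's desk-scale problem sizes (tens of wells, hundreds of cells,
$D = 20$, widths 256/64/256) the published learning rate of 5e-4 is
conservative enough that optimization can stall at its initial plateau for
some initializations — the batches are far smaller than in a full screen. The
bundled experiments therefore pass `learning_rate = 2e-3` explicitly; the
package default stays at the standard recipe.

## Preprocessing

The preprocessing order is fixed and tested:

1. rows (cells) containing any missing value are dropped at load time;
2. features are standardized *per plate*, pooling all cells of all wells on
   the plate — including negative controls — to zero mean and unit
   *population* variance (constant features map to 0 under a $10^{-12}$
   floor);
3. negative-control wells are then removed.

The average-profiling baseline continues: per-well feature means, per-plate
RobustMAD normalization $(x - \text{median})/(1.4826 \cdot \text{MAD} +
10^{-18})$, then feature selection (variance threshold $10^{-8}$, then
greedy removal within pairs exceeding $|r| > 0.9$, walking feature names in
sorted order so the later name loses — a deterministic tie-break). RobustMAD
uses the *median* absolute deviation by default, following cytominer
convention; a mean-absolute-deviation variant is selectable
(`deviation = "mean"`). The model path consumes the standardized cells
directly.

## Retrieval evaluation

Profile quality is scored by mean average precision over cosine-similarity
rankings:

* **Replicate retrieval** — each treatment well queries all other treatment
  wells; positives are replicates of the same perturbation. Query APs average
  per compound; the mAP is the mean over compounds. A `within_plate` switch
  restricts candidate pools per plate.
* **MoA retrieval** — positives are wells of *different* compounds sharing at
  least one mechanism-of-action label (label sets intersecting counts as
  positive, since compounds may carry several annotations); the query's own
  compound is removed from the pool entirely. Compounds whose MoA has no
  other compound are excluded and reported. The headline mAP is the mean over
  included compounds; per-MoA means are also reported.

AP follows the precision–recall staircase
$\sum_k (r(k) - r(k-1))\,p(k)$, which for binary relevance equals the mean of
precision-at-rank over the positives' positions; the test suite checks the
implementation against an independent staircase enumeration for every binary
relevance vector up to length 12. Similarity ties are broken by a stable
secondary sort on `well_id` and the number of tied candidates is reported, so
rankings are bit-reproducible. A permutation null
(`permutation_null_replicate_map`, label shuffles with the similarity
structure fixed) supplies the chance-level reference interval used
throughout.

## Per-cell relevance

Two complementary scores explain which cells drive a trained model:

* **Sensitivity analysis (SA)**: the contrastive loss over a batch of wells
  (labels = perturbation ids) is backpropagated to the inputs;
  $R_{m,d} = |\partial \mathcal{L} / \partial x_{m,d}|$ and the per-cell
  score is $\sum_d R_{m,d}$. A variant backpropagating the model output
  instead of the loss is available (`mode = "output"`) but non-default — the
  loss-gradient form is what the training signal actually sees.
* **Critical-point analysis (CPA)**: because pooling is a sum, cells with
  large first-layer activations dominate the profile; the score is
  $\lVert \phi(x_m) \rVert_1$, post-activation by default (that is the
  quantity entering the sum; pre-activation by flag).

Each score is min–max normalized per well, the two are added, and the sum is
min–max normalized again. A constant score vector would divide by zero in
min–max; it maps to all zeros and is flagged. Cells with combined score
strictly above 0.8 are "most relevant", strictly below 0.2 "least relevant".
Pearson correlations between the combined score and each input feature
(pooled over the analyzed wells; constant features get $r = 0$ with a flag)
summarize what morphology the model attends to.

## The synthetic generator

The generator emulates the structure of a multi-well imaging screen without
any imaging: plates of replicate wells, Gaussian per-well cell counts,
CellProfiler-style feature columns, negative controls, additive per-plate and
per-well-position shifts, MoA annotations (including deliberate singleton
MoAs to exercise the exclusion rule), and an optional class-independent
"debris" subpopulation with designated small-area / bright-edge marker
columns and no class signal — giving the interpretability analysis a named,
literally testable target.

Class signal placement is the scientific core:

* `mean` — classes differ by mean shifts (sd = `effect_size` per feature);
  the regime where average profiling is already sufficient. Calibration: with
  a strong mean signal the average baseline reaches mAP near 1, confirming
  the simulator is not trivially hard.
* `covariance` — all classes share zero mean and the same covariance
  eigenvalues $(e^{\text{effect}}, e^{-\text{effect}})$ in a two-feature
  block; only the rotation angle (equally spaced over $[0, \pi)$)
  distinguishes classes. Average profiles are uninformative by construction.
* `skewness` — classes share mean and variance exactly; the third moment of
  one feature varies via a monotone sinh–arcsinh warp
  $\sinh(\operatorname{asinh}(Z) + \delta_c)$ of a standard normal, recentred
  and rescaled with numerically integrated moments, so the third moment is
  the *only* class signal. The warp was chosen over mixing distribution
  families precisely because it isolates that moment.

Generation is bit-reproducible from `sim_config(seed)`; ground truth (class
parameters, theoretical skewness, plate shifts, per-cell debris flags) is
returned alongside the data.

What the simulator does *not* emulate: correlated feature blocks of real
CellProfiler output, heavy-tailed technical artifacts, segmentation errors,
batch effects beyond additive shifts, or dose structure. Passing the bundled
experiments therefore demonstrates that the mechanism works — that learned
aggregation recovers higher-moment signal that averaging cannot — not that
any particular performance level transfers to real screens.

## The bundled experiments and their problem sizes

`moment_recovery_experiment()` runs the headline study at a fixed desk
scale: 10 classes × 4 replicate wells × ~500 cells × 20 features, signal in
covariance or skewness only, average-baseline mAP compared against a
1000-shuffle permutation null, model trained 100 epochs at widths 256/64/256.
`debris_relevance_experiment()` repeats a smaller screen (8 perturbations,
~300 cells/well, 25% debris, widths 128/64/128, 30 epochs) over 8 independent
seeds and t-tests the per-seed relevance gap between informative and debris
cells. These sizes are the package's chosen study conditions: large enough
that moment estimation is stable and retrieval has headroom, small enough
that the full suite runs in minutes on one CPU.

## Numerical choices and degenerate inputs

* Standardization uses the population (divide-by-$n$) standard deviation, so
  realized plate variance is exactly 1; constant features map to 0.
* L2 normalizations (embeddings, cosine) floor norms at $10^{-12}$;
  zero-norm *profiles* are an error naming the well, since a zero profile has
  no direction to rank by.
* The leaky ReLU derivative at exactly 0 takes the positive-side slope.
* Min–max over a constant vector returns zeros with a degeneracy flag.
* Empty wells, empty files, plates with zero cells, batches without positive
  pairs, MoA maps without any shared mechanism: all are errors, not silent
  degradation.
* AP for a query with no positive is undefined; callers exclude such queries
  (replicate task) or whole compounds (MoA task, reported in `excluded`).

## Known limitations

* Training is plain R + BLAS; it is intended for the desk-scale synthetic
  regime and modest real datasets, not for thousand-plate screens.
* Sum pooling's set-size dependence is documented, not removed.
* The checkpoint criterion (validation replicate mAP) is coarse when the
  held-out compound set is small; the distractor-augmented pool mitigates
  but does not eliminate this.
* The generator's skewness mode warps a single feature; multi-feature joint
  skew structure is not modeled.
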