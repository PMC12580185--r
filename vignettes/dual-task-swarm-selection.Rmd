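---
title: "Dual-task competitive swarm feature selection: model, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-task competitive swarm feature selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(swarmsel)
```

## The problem and the method

High-dimensional classification data — gene-expression matrices are the
canonical case — routinely have thousands of features and under two hundred
samples. Wrapper feature selection, which scores candidate subsets by a
classifier's cross-validated error, finds better subsets than intrinsic
filter scores but faces an enormous search space in which population-based
optimizers converge prematurely.

`swarmsel` attacks this with an evolutionary-multitasking design built from
three pieces:

1. **Multi-criteria task construction.** Each feature gets two relevance
   scores — Relief-F (neighborhood-based instance discrimination) and the
   Fisher score (between-class over within-class scatter). Both are min-max
   normalized and fused as \(w_i = \alpha\, w_i^{RF} + \beta\, w_i^{FS}\).
   Features are ranked by \(w_i\) and the ranked curve is cut at its **knee
   point**: the point of maximum perpendicular distance from the chord
   joining the curve's endpoints. Features at or above the knee define a
   compact *auxiliary* task; the *primary* task keeps the full feature set.
   The threshold therefore adapts to the data instead of a fixed top-\(k\).

2. **Elite-guided competitive swarm search.** Each task evolves a swarm of
   particles (continuous positions in \([0,1]^d\), decoded to feature masks
   by thresholding). Each generation the particles are randomly paired; the
   worse particle of each pair (the *loser*) updates its velocity by learning
   from the pair winner and a second guidance source, while winners pass
   through unchanged. A *hierarchical elite pool* — the top-\(K\) particles
   of the task — offers an alternative learning target that acts as longer
   memory than the per-pair winner.

3. **Probabilistic cross-task transfer.** For every loser two independent
   uniform draws pick one of four update modes: with probability
   \(P_{trans}\) the second guidance source comes from the *other* task
   (its elite pool, or a random winner of its current generation), and with
   probability \(P_k\) elites replace winners as the learning target. With
   neither, the update is the classical competitive-swarm rule
   \(V \leftarrow r_1 V + r_2 (X_W - X) + \varphi r_3 (\bar X - X)\),
   \(X \leftarrow X + V\), with \(r_1,r_2,r_3\) uniform per dimension.

Subsets are scored by
\(\mathrm{fitness} = \alpha_f\, \gamma + (1 - \alpha_f)\, |S|/|N|\), where
\(\gamma\) is the balanced error rate (one minus the mean per-class
true-positive rate) of an internal stratified cross-validation with a
plug-in classifier, \(|S|\) the subset size and \(|N|\) the total feature
count. With the default \(\alpha_f = 0.999999\) the sparsity term is a pure
tie-breaker: among equally accurate subsets the smaller one always wins, but
no accuracy is ever traded away for sparsity.

## Parameters that matter

| parameter | default | meaning and rationale |
|---|---|---|
| `pop_size` | 70 | particles per task; the conventional budget for this problem scale |
| `max_iter` | 100 | generations per run |
| `p_trans` | 0.6 | probability a loser learns across tasks |
| `p_k` | 0.6 | probability a loser learns from an elite rather than a winner |
| `phi` | 0.1 | pull toward the swarm mean (or elite mean); small values preserve diversity without dominating the winner term |
| `k_elite` | `ceiling(0.1 * pop_size)` | elite-pool size; a 10% elite fraction is the common convention |
| `alpha`, `beta` | 0.5, 0.5 | fusion weights after normalization; equal contribution is the neutral prior since normalization makes the two scales commensurate |
| `relief_neighbors` | 10 | Relief-F neighbors per group, clamped to class size − 1 |
| `decode_threshold` | 0.6 | continuous-to-binary decode cut; the common convention in swarm feature-selection encodings |
| `alpha_f` | 0.999999 | accuracy/sparsity trade-off (see above) |
| `inner_folds` | 5 | stratified folds of the wrapper fitness |

Several of these (fusion weights, \(\varphi\), \(K\), the decode threshold,
the internal CV protocol) are genuinely open design choices: no single
canonical value exists in the literature the method draws on. The defaults
above were fixed once, before any benchmarking, at the values a practitioner
would consider standard; all are exposed for sensitivity analysis.

Two further choices deserve explanation:

* **Elite-learning direction.** The two natural readings of the elite
  probability are "learn from an elite with probability \(P_k\)" and "learn
  from an elite when a draw *exceeds* \(P_k\)". This package fires the
  elite mode when the draw is *below* \(P_k\), i.e. \(P_k\) *is* the elite
  probability — the definitional reading.
* **Cross-task representation.** Particles of both tasks live in the same
  full \(d\)-dimensional space; the auxiliary task pins its non-candidate
  dimensions to exactly 0 and excludes them from decoding. This makes
  cross-task arithmetic well-defined without any index-mapping layer, at the
  cost of carrying dead dimensions in the auxiliary swarm.

## Classifier plug-in

The wrapper is model-agnostic: any `list(fit = function(x, y),
predict = function(model, x))` can be supplied. The default is an in-package
1-nearest-neighbor on z-scored features (training-fold statistics), chosen
because it is fast, parameter-free, and standard in high-dimensional
wrapper selection. It is implemented with a vectorized squared-distance
argmin and *first-index tie-breaking*, making it fully deterministic —
external k-NN routines that break distance ties randomly would silently
consume random numbers and break the package's bit-reproducibility
contract (they serve as a cross-check in the test suite instead). A
zero-variance training column contributes nothing to the distance.

## Reproducibility contract

Seeded runs are exactly repeatable because the order of random draws is
fixed and documented:

* run start: `set.seed(seed)` → inner-CV fold assignment → task construction
  → swarm initialization (task 1, then task 2; one uniform per particle and
  dimension, row per particle);
* per generation: pairing permutation for task 1, then task 2; losers then
  update task 1 first, pair by pair in matching order;
* per loser: two mode uniforms (always drawn, whatever the probabilities),
  then \(r_1, r_2, r_3\) as length-\(d\) vectors in that order, then any
  source-selection draw (own elite index before other-task index).

All ties anywhere (pair fitness, elite ranking, score ranking, nearest
neighbors, knee distances) resolve to the lowest index. Fitness evaluation
is memoized per decoded mask and consumes no randomness, so caching cannot
perturb the stream.

## Numerical and degenerate-input choices

* Fisher denominator: \(\varepsilon = 10^{-12}\) guards zero within-class
  variance while preserving ranking.
* Knee detection: an exactly collinear curve has no knee; the fallback keeps
  the top \(\lceil d/2 \rceil\) features. Distance ties pick the smallest
  rank (the more selective cut), and the knee feature itself is *included*
  in the auxiliary task.
* Min-max normalization maps an all-equal score vector to all zeros.
* Velocities are clamped to \([-1,1]\) and positions to \([0,1]\) so decode
  thresholds stay meaningful.
* An empty decoded subset gets fitness 1.0 (worst), pushing the search away
  from the degenerate solution.
* When a class is smaller than the requested fold count, folds are reduced
  to the smallest class size with a warning.
* Exact fitness ties in pairing and elite selection go to the lower particle
  index.

## The synthetic generator, and what passing tests do and do not show

`make_synthetic_dataset()` emulates the wide-microarray regime: balanced
classes; `n_informative` features whose class-\(c\) values are
\(N(c \cdot \mathrm{class\_sep} \cdot u_j, 1)\) with a fixed random sign
\(u_j\); `n_redundant` noisy copies (added noise SD `redundant_noise_sd`) of
randomly chosen informative features; everything else independent
\(N(0,1)\) noise. The benchmark configuration used throughout the tests is
frozen at \(n = 120\), \(d = 500\), 10 informative + 20 redundant, 3
classes, separation 2.0, copy-noise SD 0.3, seeds 1–10 — a desk-scale
mirror of the \(d \gg n\) regime with a known ground truth.

The generator deliberately omits batch effects, heteroscedastic noise, and
nonlinear class structure. Passing the recovery tests therefore shows that
the machinery finds planted linear signal in heavy noise at \(d \gg n\); it
does not certify performance on real expression data.

One structural property of this benchmark is worth understanding when
reading recovery metrics. Redundant features are near-copies of informative
ones, and the fitness's sparsity term strictly prefers the smallest subset
among equally accurate ones. Once the search reaches zero inner-CV balanced
error — which at these settings happens with roughly five of the thirty
planted signal features — informative originals and their redundant copies
are interchangeable, so the *identity-level* recall of the ten originals is
low even though the selected subset consists almost entirely of planted
signal features (the acceptance script reports both: `signal_precision`,
the fraction of selected features that are planted, is at or near 1.0,
while `informative_recall` of the specific originals medians around 0.3).
This is a property of redundancy plus sparsity pressure, not a search
failure; no sparsity-minimizing optimizer can recover most of the originals
by identity on data with near-duplicate signal features.
The scoring stage, before sparsity enters, recovers the originals
essentially perfectly: the knee-selected auxiliary task contains all ten in
every benchmark seed.

## The outer evaluation protocol

`evaluate_benchmark()` implements the unbiased protocol: selection (scoring,
task construction, swarm search, wrapper fitness) runs strictly inside each
outer training fold, and only the resulting mask crosses to the held-out
fold, where the classifier is refit on the training rows and scored.
Reported accuracy is balanced accuracy \(100 (1 - \gamma)\), consistent with
the fitness metric; plain accuracy is reported alongside. Run \(r\) uses
seed \(\texttt{base\_seed} + r - 1\). `compare_runs()` applies the Wilcoxon
signed-rank test at 0.05 to paired per-run values and emits the
conventional `+`/`−`/`=` calls. A leak detector (an access-logging option
used by the test suite) verifies that no held-out row is ever touched
during selection.

## Problem sizes used by the test suite

Unit and property tests run on small instances (tens of samples, up to a
few hundred features) where brute-force oracles — exhaustive knee search,
naive Relief-F neighbor sorts, enumeration of the signed-rank null — are
exact and fast. The end-to-end recovery and ablation checks run the frozen
benchmark above at full search budget (population 70, 100 generations, ten
seeds, both the full method and the plain-CSO ablation). The
50-generation equivalence check drives the engine and a standalone
classical competitive-swarm loop with the same seed on a 20-dimensional toy
objective and requires bit-identical states.

## Known limitations

* Exactly two tasks; no adaptive tuning of \(P_{trans}\) or \(P_k\).
* The scalarized fitness is single-objective by design; no Pareto front.
* Relief-F is \(O(n^2 d)\); for very large \(n\) subsample via
  `relief_sample`.
* Inner-CV error with tiny samples is an optimistically biased selection
  signal; the outer protocol exists precisely to measure honest held-out
  performance.
* The benchmark generator's linear, homoscedastic signal is a lower bound
  on real-data difficulty.
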