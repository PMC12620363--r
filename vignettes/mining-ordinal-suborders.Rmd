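---
title: "Mining ordinal suborders and alternative progressions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining ordinal suborders and alternative progressions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(suborders)
options(suborders.verbose = FALSE)
```

## The model

`suborders` asks which orderings of a set of class labels
`L = {l_1, …, l_|L|}` a labeled molecular dataset supports. The working
assumption is that an ordinal process, if present, is expressible along
a *single direction* in feature space: after projecting every sample to
one dimension, classes that follow one another in the process occupy
successive intervals of the axis. Three ingredients operationalize this.

**Projection.** A soft-margin linear max-margin classifier is trained on
one chosen class pair (the *projection pair*), and all samples are
projected onto the unit normal of its decision boundary. A max-margin
model is used because it is supervised (the pair anchors the direction),
deterministic (reproducible axes), and margin-maximizing (the two anchor
classes are pushed apart, which is what a progression axis needs).
Because no quadratic-programming SVM backend is available in the
supported environment, the classifier is implemented in-package as the
convex squared-hinge primal
`min ½‖w‖² + C Σ max(0, 1 − y(w·x+b))²`, minimized by BFGS from a zero
start. With the default `C = 10⁶` the solution is hard-margin for all
practical purposes on separable pairs (tests verify the normal against
closed-form geometry to 10⁻³ angular error). Features are standardized
using the pair's samples only, so the direction is scale-invariant;
orientation is fixed by requiring the pair's second class to lie to the
right, which makes the swapped pair produce the exactly mirrored axis.

**Directed threshold classifiers.** On the 1-D axis, a DTC between an
oriented class pair is a threshold `τ` assigning the higher class iff
`x ≥ τ`. Under the misclassification budget `θ = 1 − sens` the feasible
set of thresholds is the interval `(q_L, q_U]` where `q_L` is the
`(⌊θ·n_left⌋+1)`-th largest left-class value and `q_U` the
`(⌊θ·n_right⌋+1)`-th smallest right-class value; it is non-empty iff
`q_L < q_U`. This order-statistic form is exact (unit tests sweep every
candidate threshold by brute force and compare) and guarantees each
class's training sensitivity at the representative threshold is at
least `1 − θ`. The representative `τ` is the interval midpoint — in one
dimension the hard-margin SVM solution is exactly the gap midpoint, so
the point is computed analytically rather than by a solver.

**Cascades and screening.** A candidate order is accepted when every
adjacent pair admits a feasible DTC, the threshold points increase
strictly (yielding a contiguous, non-overlapping partition of the axis),
and every class-wise sensitivity of the sequential cascade prediction is
at least `1 − θ`. Screening enumerates *maximal* accepted sequences:
accepted sequences into which no single class can be inserted at any
position.

## Alternative progressions

Two suborders are merged as parallel routes when they *share
thresholds*. For branch classes `l_a ∈ o\o'` and `l_b ∈ o'\o` with a
common left neighbor `l_l ∈ o∩o'`, the left-shared region is
`X_{l_l} < τ_ls ≤ min(X_{l_a}, X_{l_b})`; right-shared is the mirror.
Under `θ > 0` the same order-statistic budget is applied per class, i.e.
the shared region is the intersection of the two branch transitions'
feasible DTC intervals. (The rate-scaled display form
`X + θ·(X' − X)` that motivates the tolerant bounds mixes strict and
non-strict inequalities; this package applies the `x ≥ τ` convention
and integer budgets `⌊θ·n⌋` uniformly, the only reading under which
"sensitivity ≥ 1 − θ" holds as an empirical fraction.) Equivalence is
decided on feasible *regions* — a non-empty region means equivalent —
not on equality of point estimates, which would be measure-zero fragile.
Region emptiness uses a relative tolerance of 10⁻⁹ on endpoints.

Aggregation, for which no published algorithm exists, is this package's
own construction and works globally rather than by pairwise merging
alone: all thresholds of all suborders (from one projection) are pooled;
thresholds of identical transitions, and thresholds related by a left-
or right-shared region, are merged by transitive closure into boundary
groups positioned at their mean threshold point. A boundary group that
no class segment straddles is a *cut*; classes between consecutive cuts
form one layer, inside which chains from individual suborders are the
parallel units. This reduces to a path of singleton layers for a single
suborder, keeps class chains such as `(l0<l1)` intact as one branch unit
against a single spanning class such as `l6`, and leaves suborders over
disjoint class sets in disconnected components (a shared threshold
requires a shared anchor class, so no equivalence can bridge them).
Every contributing suborder remains recoverable as a path; tests check
this along with parallel soundness (two classes in the same layer but
different units never co-occur in any contributing suborder).

## Reversed orders

Swapping the projection pair mirrors the axis exactly (the optimizer's
trajectory negates term by term), so screening the swapped pair returns
the element-wise reversed suborders — mathematical artifacts, not new
structure. `canonicalize()` therefore flips each sequence to the
lexicographically smaller of `{sequence, reverse}`, collapsing both
orientations to one set; `report_reversed = TRUE` keeps both, tagged.
Whether a reversal is biologically meaningful is left to the analyst.

## Screening completeness (a design choice)

Candidate growth proceeds by right extension over *chains* — sequences
whose every adjacent pair has a feasible DTC — with memoized pairwise
classifiers providing early rejection, and full cascade acceptance
re-checked per candidate. The textbook alternative, growing only from
fully *accepted* sequences, is subtly incomplete when `θ > 0`: cascade
acceptance (monotonicity, cascade-level sensitivities) is not hereditary
under class deletion, so a valid long order can have no valid
single-deletion parent. Chain feasibility, by contrast, is trivially
prefix-hereditary, making right extension provably complete at any
`θ`; the cost is enumerating some chains that fail the full cascade
check, negligible at `|L| ≤ 10`. A brute-force enumeration of all
ordered subsets is retained (`method = "exhaustive"`) as the oracle, and
the two routes are compared on randomized layouts in the tests.

At `θ = 0` two useful facts hold and are exploited/tested: feasibility
of consecutive pairs implies pairwise separation along the whole chain
(transitivity of interval separation), and consecutive feasible
intervals are automatically ordered, so threshold monotonicity can only
fail for `θ > 0` (the test suite constructs such a case at `θ = 0.5`).

## The synthetic world

The generator samples each class **uniformly** inside a fixed interval
on feature 1 and adds pure-noise features (`U(0, noise_scale)`).
Uniform-with-gaps rather than Gaussian sampling is deliberate: class
separations hold at *any* sample size with sensitivity 1, so acceptance
counts measure the algorithm, not sampling luck. The ten-class benchmark
uses intervals `l0 [0,1]`, `l1 [1.5,2.5]`, `l2 = l7 [3,4]`,
`l3 = l8 [4.5,5.5]`, `l4 [6,7]`, `l5 [7.5,8.5]`, `l6 [0.2,2.3]`,
`l9 [6.2,8.3]`, 100 samples/class, one noise feature — two parallel
ordinal chains whose published description (counts and memberships of
the maximal suborders) fixes the overlap pattern while the numeric
coordinates are this package's choice. Ground truth is computed by brute
force over the interval layout: all maximal sequences of classes with
pairwise separated intervals. That enumeration yields the four length-6
and eight length-5 suborders plus four maximal length-4 sequences
(`l6 < {l2|l7} < {l3|l8} < l9`) that use both branch substitutions at
once; the benchmark's headline counts concern lengths 6 and 5 only.

What a green test does *not* establish: behaviour under Gaussian class
overlap calibrated to a target error rate, heteroscedastic noise,
class imbalance, batch structure, or the `d ≫ N` regime of real
transcriptomes. The generator's noise feature checks only that the
projection ignores directions with no class signal.

## Numerical and degenerate-input choices

- DTC interval: lower bound exclusive, upper inclusive, matching
  `x ≥ τ → `higher class; ties between equal values from both classes
  are handled exactly by the order statistics.
- Degenerate interval width (midpoint underflows to the lower bound):
  the point snaps to the upper bound.
- Threshold monotonicity is enforced on point estimates; overlapping
  feasible intervals with orderable points are allowed.
- Monotone-matrix detection uses non-strict decrease with absolute tie
  tolerance 10⁻¹² — real separability values tie (e.g. at 1.0), and
  strictness would spuriously reject; the pruned backtracking search is
  exact and is compared against the factorial brute force in tests.
- The Fisher separability score is `J/(1+J)` with
  `J = d' S_w⁻¹ d` (pooled within-class covariance, SVD pseudo-inverse
  fallback when singular). Resubstitution accuracy remains the default
  score of `build_separability_matrix()`, but
  `cross_validate_substructures()` defaults to Fisher: perfectly
  separable class pairs all tie at accuracy 1.0, leaving the monotone
  detector no order information, whereas the Fisher ratio grows with
  class distance and orders them.
- Non-separable projection pairs are allowed (soft margin) and logged;
  a zero-norm direction (identical classes) is an error.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `min_sensitivity` | 1 | per-class sensitivity floor in `[0.5, 1]`; `θ = 1 −` floor |
| `projection_pairs` | `"all"` | `"all"`, `"most_distant"`, or explicit pairs |
| `max_order_length` | `|L|` | cap on screened sequence length |
| `report_reversed` | `FALSE` | keep mirror orientations |
| `cost` (projection) | `10⁶` | soft-margin cost; large ⇒ hard-margin behaviour |
| `seed` | 1 | drives all randomness (generation only; fitting is deterministic) |

## Known limitations

- One projection axis per analysis: structures orthogonal to the chosen
  pair's direction are invisible; graphs are per projection pair and are
  not fused across pairs.
- Only threshold base learners and the max-margin projection are
  implemented (the cascade framework itself is classifier-agnostic).
- No probabilistic outputs or confidence intervals on thresholds.
- Screening cost grows with the number of feasible chains; fine for
  `|L| ≤ 10`, not engineered for dozens of classes.
- Aggregation layering relies on threshold point positions; with
  near-coincident boundary groups the cut test uses a relative
  tolerance and extremely close groups could in principle merge layers.
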