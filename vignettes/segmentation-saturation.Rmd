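---
title: "Estimating the training-set size at which segmentation performance plateaus"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating the training-set size at which segmentation performance plateaus}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(segsat)
```

## The problem

Curating reference segmentations for 3D medical images is expensive: each
case is contoured slice by slice by a trained reader. A team building a
segmentation model therefore wants to know, as early as possible, whether
labelling another hundred cases will still buy measurable test performance
or whether the model has already saturated. `segsat` answers that question
for experiments of the common design "train at several nested dataset
sizes, evaluate every size on one held-out test set": it computes the
per-case agreement metrics, fuses cross-validation folds into per-size
ensembles, fits a saturating learning-curve model to the (size, test Dice)
points, and reports the dataset size at which the curve comes within a
tolerance of its asymptote — together with a stability analysis that says
how much that estimate should be trusted.

## The learning-curve model

Mean test Dice as a function of the number of training + validation images
$x$ is modelled as an exponential rise to a plateau:

$$D(x) = D_M - (D_M - D_0)\,e^{-kx}$$

with three parameters: $D_M$, the maximum achievable Dice (the plateau);
$D_0$, the minimum Dice (the value as $x \to 0$); and $k > 0$, the
exponential rate constant (per image). The curve is strictly increasing
when $D_M > D_0$ and bounded in $[D_0, D_M]$.

The **plateau point** is defined as the smallest integer $x$ whose
predicted Dice is within a tolerance $\tau$ (default 0.01 Dice) of $D_M$.
Because $D_M - D(x) = (D_M - D_0)e^{-kx}$, it has the closed form

$$x^\* = \left\lceil \frac{1}{k}\,\ln\frac{D_M - D_0}{\tau} \right\rceil$$

clipped below at 1; a flat curve ($D_M - D_0 \le \tau$) plateaus at 1. We
report the ceiling because dataset sizes are whole image counts.
`plateau_point()` is tested against a brute-force integer scan of $D(x)$.

### Fitting

`fit_plateau()` estimates $(D_M, D_0, k)$ by nonlinear least squares
(Levenberg–Marquardt via `minpack.lm::nlsLM`). Three choices here were
genuinely open and are our own:

* **Constraints.** Dice is bounded in $[0,1]$, so we constrain
  $0 \le D_0 \le D_M \le 1$ (implemented by the reparameterization
  $D_0 = s \cdot D_M$ with $s \in [0,1]$, which turns the ordering
  constraint into a box) and $k \in (10^{-6}, 1]$. An unconstrained fit
  can extrapolate above Dice 1, which is not meaningful.
* **Initialization.** Deterministic and seed-free: $D_M^0$ = max observed
  Dice, $D_0^0$ = mean Dice at the smallest size, and $k^0$ from the slope
  of a log-linear regression of $\ln(D_M^0 + 10^{-3} - \text{dice})$ on
  $x$ — the model linearized around the starting plateau. For curves of
  the saturating shape this lands in the right basin; noiseless curves are
  recovered to $10^{-6}$ in every parameter.
* **Which points to fit.** A cross-validated experiment yields both
  per-fold test Dice and the per-size ensemble Dice. The default
  (`use = "ensemble_only"`) fits the ensemble points, which are the
  quantities one extrapolates; `use = "all_points"` includes fold points
  unweighted for users who prefer more observations over homoscedasticity.

Degenerate inputs are handled explicitly rather than passed to the
optimizer: identical Dice at all sizes returns the flat fit
$D_M = D_0 = \bar D$ with `flat_curve = TRUE` and plateau 1; fewer than
three distinct sizes is an error (three free parameters); optimizer
non-convergence is raised, never silently accepted.

If the plateau point exceeds the largest observed size the fit is flagged
`extrapolated = TRUE`. Such estimates rest entirely on the assumed
functional form and deserve less confidence; the stability analysis below
is the operational check.

### Stability under dropout of the largest sizes

`stability_analysis()` refits the curve after removing all observations at
the largest size, then the two largest, and so on (`max_drops` times,
default 2), and reports the largest change in $D_M$ between successive
fits. The estimate is called stable when that gap does not exceed
`gap_threshold`, default **0.02 Dice** — a heuristic chosen to separate
fits that agree to within typical fold noise (gaps of ≲0.01) from the
clearly drifting case where dropping a size moves the plateau by ~0.05;
it is configurable and reported alongside the gap, never used to hide it.

## Agreement metrics

Per case and per label, `evaluate_case()` reports:

* **Dice** $2TP/(2TP+FP+FN)$, **Jaccard** $TP/(TP+FP+FN)$ and **TPR**
  $TP/(TP+FN)$ from voxel confusion counts. Conventions for empty masks:
  both-empty Dice/Jaccard = 1 (perfect agreement on absence),
  empty-reference TPR = 1; both situations are flagged (`ref_empty`,
  `pred_empty`) so cohort summaries can exclude them deliberately. The
  identity $J = D/(2-D)$ is asserted in the tests on every evaluated case.
* **Mean surface distance (MSD)** in mm. Boundary voxels are mask voxels
  with at least one face-adjacent (6-connectivity) neighbour outside the
  mask, the grid edge counting as outside; distances are Euclidean between
  voxel centres scaled by the per-axis spacing; the reported MSD is the
  arithmetic mean of the two directed mean nearest-boundary distances.
  Several surface definitions circulate; we fix the cheapest-to-verify one
  and expose the directed components (`surface_distances()`) so either
  one-sided reading can be reconstructed. MSD of an **empty mask is
  MISSING** (`NA`), not a sentinel: a model that predicts no tumor has no
  surface, and a large sentinel would corrupt cohort means. Summaries
  exclude missing values and report the exclusion count.
* **Physical volumes** in mL (voxel count × spacing product / 1000),
  feeding the cohort-level volume regression and the Bland–Altman percent
  difference analysis (bias ± 1.96 SD limits of agreement). The percent
  difference denominator is the *reference* volume by default — the sign
  then reads as relative error against ground truth — with the classical
  mean-of-pair denominator available by flag.

Paired Student's t-tests (two-sided) compare per-case Dice between
consecutive dataset sizes on the shared test set; stars follow the usual
0.001/0.01/0.05 coding and no multiple-testing correction is applied
across the adjacent-size comparisons (each p is reported as-is, and the
report says so).

Volumes are compared only on identical grids: shapes must match exactly
and spacings within $10^{-6}$ relative tolerance (`check_comparable()`).
No resampling or reorientation is performed, and only the header spacing —
not the affine rotation/flips — is consumed; metrics here are
orientation-invariant, and refusing mismatched grids removes a class of
silent header-interpretation bugs. Files whose voxel values are not within
$10^{-6}$ of integers are rejected rather than rounded.

## Ensembling

`majority_vote()` fuses K fold predictions per voxel to the modal label.
With five voters and three labels 2-2-1 ties occur; the default rule picks
the numerically smallest tied label — with the background/kidney/tumor =
0/1/2 map this prefers background, the conservative choice — and a
`background_wins` variant is available. Both rules are deterministic and
order-independent (permutation invariance is property-tested, and the
full $3^5$ vote table is checked against an enumeration oracle).

## The synthetic generators

Every input the toolkit consumes can be generated, seeded, from
`make_phantom()`, `degrade_volume()`, `simulate_folds()` and
`simulate_learning_curve()`:

* **Phantoms** are two kidney ellipsoids plus a tumor sphere on a default
  48×48×32 grid at 1.5×1.5×3 mm — abdominal-CT-like anisotropy at a size
  that keeps a full simulate–evaluate–ensemble–fit cycle fast. Tumor takes
  precedence over kidney where they overlap, as an endophytic lesion
  replaces parenchyma.
* **Degradations** flip boundary voxels (balanced false negatives and
  false positives), erode, dilate, or delete the structure outright, and
  iterate-and-remeasure until the Dice against the original is within
  ±0.05 of the requested target — exact targets are unreachable by
  discrete flips. Other labels are never altered.
* **Curve observations** are drawn as $D(x)$ plus Gaussian fold noise
  (clamped to $[0,1]$), with the ensemble point per size the mean of its
  folds. Defaults mirror a typical saturation experiment: sizes 50–300 in
  steps of 50, five folds, noise SD 0.02 — the fold-level scatter of a
  stable segmentation task.

What the generators deliberately do **not** emulate: intensity images and
the segmentation model itself (only label masks are simulated), anatomical
shape variation beyond ellipsoids/spheres, spatially correlated error
structure, and inter-rater ambiguity in the reference. Passing tests
therefore demonstrate that the measurement and modelling chain is correct,
not that any particular network saturates at any particular size on real
data.

## Numerical choices and limitations

* Comparability tolerance $10^{-6}$ (relative) on spacing; label rounding
  tolerance $10^{-6}$ (absolute); fit convergence tolerances $10^{-14}$ on
  the LM objective with a 500-iteration cap.
* Quartile analysis (`quartile_curve_analysis()`) ranks test cases by
  reference volume with ties broken by `case_id` order — deterministic for
  identical volumes — and refits the curve within each quartile; quartiles
  with too few distinct sizes report the error rather than a fit.
* Problem sizes used in the test-suite simulations (8³ random volumes for
  oracle equality, 32×32×24 phantoms, 200 replicates for the noisy
  recovery study) were chosen so the whole suite completes in about a
  minute while the properties under test are exercised at full strength;
  all are trivially enlargeable.
* The exponential-plateau family is an assumption. Power-law learning
  curves, bootstrap confidence intervals on the plateau point, and
  probabilistic (soft) ensembling are natural extensions and out of scope.
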