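---
title: "Measuring rules of dietary compromise with the Thales angle"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring rules of dietary compromise with the Thales angle}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nutriangle)
```

## The problem

In the Geometric Framework for nutrition, an animal's diet is a point in a
two-dimensional nutrient space (here nutrient A = protein, nutrient B =
carbohydrate, in mg by convention). A *nutritional rail* is the ray from the
origin whose direction is a diet's fixed nutrient ratio: an animal confined
to a diet can move along its rail by eating more or less, but never across
rails. The *intake target* is the coordinate animals actively defend when
they can mix foods freely. When the target is unreachable on an imbalanced
rail, the animal must trade off a surplus of one nutrient against a deficit
of the other; the systematic pattern of those trade-offs across rails (the
shape of the *nutrient array*) is the species' *rule of compromise*.

A canonical rule is closest-distance optimisation (CDO): eat until the
Euclidean distance to the intake target is minimal, i.e. stop at the
perpendicular foot of the target on the rail. `nutriangle` turns "how far is
an array from CDO?" into a per-observation angle statistic.

## The statistic

For an observed intake point $B$, the origin $A = (0,0)$ and the intake
target $C$, let $\beta = \angle ABC$. Draw the circle whose diameter is the
segment $\overline{AC}$. By Thales' theorem, $\beta = 90^\circ$ exactly when
$B$ lies on that circle — and the perpendicular feet of $C$ on every rail
lie on it. Hence:

* $\beta = 90^\circ$: the intake is exactly the CDO prediction for its rail;
* $\beta > 90^\circ$: $B$ is *inside* the circle — the animal stopped short
  of the CDO foot (under-consumption; the surplus nutrient is strongly
  avoided);
* $\beta < 90^\circ$: $B$ is *outside* — the animal overshot the foot
  (the surplus is tolerated).

All reporting uses the deviation $\beta - 90$ in degrees, so zero is the CDO
reference, positive is inside, negative is outside. The angle is invariant
to rescaling of both axes by a common factor and to swapping the two
nutrients, so it compares species and datasets measured on different
absolute intake scales.

Numerically, $\beta$ is the arccosine of the normalised dot product of the
directions $B\to A$ and $B\to C$, evaluated as
$\mathrm{atan2}(\lVert u \times v\rVert,\ u\cdot v)$; the two forms are
algebraically identical, but the `atan2` form keeps full precision for
near-collinear configurations where a clamped arccosine loses up to
$10^{-8}$ degrees. A point collinear with and strictly between origin and
target returns $180^\circ$ (the limit case), a point beyond the target on
its ray returns $0^\circ$, and points coinciding with the origin or the
target are degenerate vertices: `thales_angle()` raises an error,
while `angle_records()` drops such rows with a warning and a count,
because an animal whose intake sits exactly on the target carries no
information about compromise.

## From data to inference

`read_intake_csv()` reads one row per individual (species, treatment
`rail`/`choice`, rail label like `"1:4"`, protein, carbohydrate; column
names remappable). Intakes must be finite and non-negative; offending rows
abort the read with their row numbers. The intake target is either supplied
explicitly or estimated as the plain mean of the choice-treatment records —
deliberately the unweighted "average coordinates", with no trimming, since
robust target estimation is a separate problem.

`angle_records()` computes $\beta$ for every rail observation against the
(per-species) target; choice rows never enter the angle computation — they
define the target, and their geometry at the target is near-degenerate.

`estimate_rail_deviations()` fits, per species, the cell-means linear model
$\text{deviation} \sim \text{rail} - 1$: each coefficient is a rail's mean
deviation, its `confint()` bound is the interval reported, and the residual
variance is pooled across rails. The cell-means parameterisation is chosen
so the output *is* the customary summary table (ratio, mean, lower, upper)
with no contrast arithmetic. A rail whose interval covers zero is flagged
consistent with CDO. `pooled = FALSE` switches to independent per-rail
t-intervals for data whose dispersion differs visibly across rails (see
"Assumptions" below). No multiple-testing adjustment is applied across
rails — the intervals are reported raw, as is customary for these summary
tables; users comparing many rails formally should adjust downstream.

`omnibus_rail_test()` is the one-way ANOVA F for the rail factor;
`interaction_test()` fits
$\text{deviation} \sim \text{species} + \text{rail} +
\text{species{:}rail}$ on the rails both species share and reports the
interaction term from sequential (fit-order) sums of squares — with
balanced synthetic designs this coincides with the other ANOVA types, and
with unbalanced field data the main effects are deliberately entered first.
A significant interaction is the formal statement that two species follow
different rules of compromise.

### Assumptions and a known limitation

The pooled model assumes equal deviation variance across rails. Under
additive coordinate noise of standard deviation $\sigma$, the delta method
gives the angle variance at an on-circle point as
$\sigma^2 (1/d_A^2 + 1/d_C^2)$, where $d_A$ and $d_C$ are the distances
from the point to the origin and to the target. These distances — hence the
variance — differ across rails unless the rails sit symmetrically about the
target direction. With markedly asymmetric designs the pooled intervals are
mildly too narrow on the noisiest rails; use `pooled = FALSE` there.

Second, the per-point angles are computed against the *estimated* target
mean, and its sampling uncertainty is not propagated into the intervals.
In typical designs the choice sample is comparable in size to a rail cell
and the target error is small against the per-point angle spread, so the
intervals are close to nominal, but they are conditional on the target.

## Synthetic arrays

`generate_archetype_array()` builds the classic array shapes, as noiseless
base points per rail plus optional per-coordinate noise:

* `cdo`: the perpendicular foot on each rail (all angles exactly 90);
* `equal_distance`: every point at the same Euclidean distance from the
  origin, by default $|C|$, i.e. the circular arc through the target. On
  the target's own rail the point is the target itself, and on a rail at
  angular distance $\Delta$ from the target direction the deviation is
  exactly $-\Delta/2$: all points outside the circle, worst at the most
  imbalanced rails — the parabola-shaped profile of a surplus-tolerant
  generalist. (The variant `from = "target"`, intersecting each rail with
  a circle centred on the target, is also provided; note its outer branch
  produces the *opposite* profile — deviation most negative near the
  target's rail — which is why the arc-through-target definition is the
  default.)
* `square` / `inverted_square`: one nutrient held at its target coordinate;
* `linear`: total intake $a + b$ held at the target's total;
* `concave`: interpolates between the square and inverted-square points
  along each rail, shrunk toward the origin maximally at the rails most
  distant in angle from the target.

Noise (`noise_model()`) is additive per coordinate: Gaussian with `sd =
scale`, Poisson with `lambda = scale`, or gamma with `shape = scale` (rate
1). By default the Poisson and gamma draws are *not* mean-centred: raw
`rpois()`/`rgamma()` errors have mean `scale`, so they translate the array
as well as dispersing it. That is exactly what makes skewed error families
dangerous for this estimator, and the default preserves it;
`centered = TRUE` subtracts the theoretical mean for experiments that want
pure dispersion. Generated arrays can contain negative coordinates under
strong noise; they are kept (clamping would bias the angle distribution)
and are flagged only when such data are written and re-read as observed
CSV, where negative intakes are invalid.

What the generators do *not* emulate: between-individual variation in the
target, correlated protein/carbohydrate errors, day-by-day feeding
structure, and rail-dependent error variance of real feeding data. Passing
the calibration tests below therefore validates the estimator and its
intervals under the stated error model, not the biology of any particular
dataset.

## The noise-stability simulation

`noise_stability_simulation()` quantifies estimator stability: for each
error family and each `scale` on a grid, it builds `reps` CDO arrays of `n`
points (default `n = 100`, points cycled across the rails), estimates each
array's mean angle, and records the mean and the 2.5/97.5 percentile band
of those estimates. `noise_proportion` is `scale / |target|`, the error
magnitude relative to the intake target norm — the natural reference length
of the construction. A single root seed spawns a fixed substream per
(family, scale) cell, so any grid row is bit-reproducible in isolation.

Stability is judged by how far the 95% band strays from the known truth of
$90^\circ$ (the envelope $\max(|q_{2.5} - 90|, |q_{97.5} - 90|)$). Under
Gaussian error the estimates stay centred on 90 at every noise level; under
uncentred Poisson or gamma error the estimates drift progressively away
from 90 as the scale grows, so their envelope is wider at essentially every
grid point. Centred, variance-matched families are statistically
indistinguishable from Gaussian in band *width* — the instability of the
skewed families is a bias phenomenon, not extra spread, which is why the
envelope (not the band width alone) is the right stability measure.

## Numerical and design choices

* Degrees everywhere in public output; radians never leak.
* On-circle classification tolerance `tol_deg = 1e-8` degrees by default
  (exact constructions); raise it when describing noisy data.
* Degenerate-vertex detection uses a relative tolerance of `1e-9` times the
  target norm.
* Rails are rays restricted to the non-negative quadrant; rail labels are
  scale-invariant (`"7:35"` is `"1:5"`), and tables/plots order rails by
  increasing A:B ratio (`0:1` first, `1:0` last).
* Ties/limits: collinear-between is 180, beyond-target is 0, both
  documented rather than errors, so grid searches along a rail are
  well-defined end to end.
* The test suite sizes are chosen to keep the full run within a couple of
  minutes: coverage and type-I calibration use 1000 replicates of a
  two-rail, n = 20/rail design (the symmetric 1:2/2:1 pair, where the
  pooled model's equal-variance assumption holds exactly — coverage was
  verified at 0.951 and type-I at 0.050 with 20000 replicates during
  development); the stability check uses 21 grid points and 100 replicates
  per cell; the oracle-agreement check uses $10^5$ random triangles,
  excluding those within 0.05 intake units of exact collinearity, where a
  side-length (law-of-cosines) oracle provably cannot resolve the angle
  once the sides are rounded to double precision.

## Limitations

* Two nutrients only. The inscribed-angle construction is inherently
  planar; higher-dimensional intake data must be analysed pairwise or
  after dimension reduction, with the distortions that entails.
* The method conditions on a point estimate of the intake target
  (uncertainty propagation from the target into the angles is out of
  scope).
* The per-rail intervals inherit the pooled-variance assumption discussed
  above.
* The archetype generators are idealised shapes for method validation and
  power exploration, not generative models of feeding behaviour.
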