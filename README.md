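# nutriangle

Quantifying rules of dietary compromise in two-dimensional nutrient space
with an inscribed-angle statistic.

## The problem

In Geometric-Framework nutrition experiments, animals are confined to
*nutritional rails* — diets with a fixed ratio of two nutrients (typically
protein and carbohydrate), rays from the origin of nutrient space — or
allowed to feed freely, which reveals their *intake target*. On an
imbalanced rail the target is unreachable, and where an animal stops
feeding encodes its *rule of compromise* between nutrient surpluses and
deficits. The canonical rule of diet specialists, closest-distance
optimisation (CDO), predicts feeding to the perpendicular foot of the
target on each rail.

`nutriangle` tests that prediction per observation. For the origin `A`,
an observed intake point `B`, and the intake target `C`, it computes the
angle β = ∠ABC. By Thales' theorem, β = 90° exactly when `B` lies on the
circle with diameter `AC` — which is where every CDO foot lies. So:

* β − 90 = 0 — the intake matches CDO on that rail;
* β − 90 > 0 — the point is inside the circle: under-consumption, the
  surplus nutrient is strongly avoided;
* β − 90 < 0 — outside the circle: the surplus is tolerated.

Per-rail mean deviations get pooled-variance 95% confidence intervals
(cell-means linear model), a one-way F-test for the rail effect, and a
species × rail interaction test that formally compares rules of compromise
between two species. Archetypal array generators (CDO, equal-distance,
square, inverted-square, linear, concave) and a noise-stability simulation
(Gaussian vs Poisson vs gamma error) support validation and power
exploration. Figures show the nutrient array with the Thales circle and the
per-rail deviation profile.

## Worked example

Simulate a surplus-tolerant generalist — every intake at the same total
distance from the origin, the arc through the target — with measurement
noise, then analyse it:

```r
library(nutriangle)

run_generate("array.csv",
  kind = "equal_distance", target = c(100, 150),
  rails = c("1:5", "1:2", "1:1", "2:1", "5:1"), n_per_rail = 10,
  noise = noise_model("gaussian", 2), seed = 42, species = "generalist"
)
ds  <- read_intake_csv("array.csv")
rec <- angle_records(ds, target = c(100, 150))
summarize_array(rec)
#> Per-rail deviation of the Thales angle from 90 deg
#> # A tibble: 5 x 7
#>   species    rail      n mean_dev  lwr95  upr95 cdo_consistent
#>   <chr>      <chr> <int>    <dbl>  <dbl>  <dbl> <lgl>
#> 1 generalist 1:5      10   -11.2  -12.7   -9.68 FALSE
#> 2 generalist 1:2      10    -6.01  -7.53  -4.49 FALSE
#> 3 generalist 1:1      10    -4.71  -6.23  -3.20 FALSE
#> 4 generalist 2:1      10   -14.5  -16.0  -13.0  FALSE
#> 5 generalist 5:1      10   -22.5  -24.0  -21.0  FALSE
generalist rail: F(4, 45) = 90.657, p < 0.001
```

Every deviation is negative — all intakes outside the Thales circle — and
the profile is parabola-shaped: mildest near the target's own ratio (the
target here has P:C 1:1.5, between rails 1:2 and 1:1) and most negative at
the most imbalanced rails. No interval covers zero, so every rail departs
from CDO, and the F-test confirms the deviation differs across rails. A
CDO-following specialist would instead show a flat profile at zero with all
intervals covering it; `interaction_test()` compares the two formally.

`plot_nutrient_array(rec)` draws the array, rails, target and Thales
circle; `plot_beta_summary(estimate_rail_deviations(rec))` draws the
deviation profile.

The same workflow is available from a shell via the thin wrapper:

```sh
Rscript inst/scripts/nutriangle analyze --input array.csv --out results \
    --target "100,150"
Rscript inst/scripts/nutriangle simulate --out results --seed 1
```

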