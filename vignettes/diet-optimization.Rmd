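---
title: "Diet optimization under nutrient, cost and emission constraints"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diet optimization under nutrient, cost and emission constraints}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dietlp)
```

## The model

`dietlp` solves the classical least-cost diet problem extended with
greenhouse-gas (GHG) accounting and Monte Carlo uncertainty. The decision
variables are the daily quantities $x_i \ge 0$ (grams of *edible*,
ready-to-eat food $i$). Three linear functionals of $x$ matter throughout:

* **cost** $\;C(x) = \sum_i x_i\, p_i / (100\,(1-w_i))$ — NZ\$/day, where
  $p_i$ is the price per 100 g *purchased* and $w_i$ the wastage fraction
  (inedible portions plus discarded food), so buying enough to eat $x_i$
  grams means purchasing $x_i/(1-w_i)$ grams;
* **emissions** $\;G(x) = \sum_i x_i\, g_i / (1000\,(1-w_i))$ — kg
  CO$_2$e/day with $g_i$ in kg CO$_2$e per kg purchased;
* **nutrient intakes** $\;N_n(x) = \sum_i x_i\, c_{in} / 100$, with
  $c_{in}$ the content of nutrient $n$ per 100 g edible.

A scenario minimizes either $C$ or $G$ subject to:

* requirement rows $N_n(x) \ge \underline{b}_n$ (estimated average
  requirements — energy $\ge$ 11,450 kJ, protein $\ge$ 52 g, iron $\ge$ 8 mg
  using the stricter female value, and so on) and
  $N_n(x) \le \overline{b}_n$ for sodium (2,300 mg), saturated fat (30 g)
  and vitamin A (3,000 µg RE). Energy is a floor, not an equality: scenarios
  whose forced meal components oversupply energy simply exceed the target;
* per-food variety caps (240 g for flour/pasta/oat-type staples and pulses,
  200 g for any single vegetable or fruit, 60 g of vegetable oil, 100 g of
  peanut butter, 60 g of added sugar) and scenario-specific recipe minima;
* aggregate rows over tag-selected groups (e.g. non-starchy vegetables
  $\ge$ 412 g in the high-vegetable scenario, $\ge$ 549 g plus fruit and
  nuts $\ge$ 363 g in the Mediterranean one);
* linked-ingredient equalities (flour = 7 × oil for flatbread making);
* a budget row $C(x) \le$ cap for emission-minimizing scenarios (NZ\$5/day
  for G1, NZ\$9/day elsewhere).

Emissions are charged on **purchased** weight: food that is bought and
wasted was still produced. The alternative (edible-weight accounting) can be
obtained by setting every `wastage_mean` to zero in a copy of the database.

A strict budget ("< \$5/day") cannot be expressed in an LP; the built-in cap
is stored as $\le 5.00$, with a `match_paper` switch using the just-binding
4.99 for users comparing against published tables where the binding value is
printed as 4.99.

## Solver

The solver (`solve_lp`) is a dense two-phase primal simplex written for this
package: no LP library is imported, which keeps the dependency surface to
base R and makes the pivot rules explicit. Determinism is part of the
contract: entering variable = most negative reduced cost with the lowest
column index on ties; leaving variable = minimum ratio with the lowest basic
index on ties; Bland's rule engages after a long run of degenerate pivots to
exclude cycling. Identical input therefore yields the identical vertex, and
degenerate alternate optima are resolved the same way on every run. Pivot
tolerance is $10^{-9}$; reported solutions satisfy all rows to $10^{-6}$
relative. Two independent oracles check it in the test suite:
vertex-enumeration brute force on random 3–5-food instances, and
`boot::simplex`.

### Minimum-portion rule

Any freely selected non-condiment food must enter at $\ge$ 10 g/day or not
at all — trace amounts are not a practical purchase. Condiments (salt,
sugar, yeast spread) and recipe-pinned components (e.g. the 8 g of wholemeal
flour in the mince meal) are exempt. This semicontinuity is not linear;
two strategies are provided:

* `method = "iterative"` (default): solve the LP, fix to zero all foods in
  the open interval (0, 10) g, re-solve to a fixpoint (forcing a food *up*
  to 10 g instead when zeroing is infeasible), at most 20 rounds;
* `method = "milp"`: exact branch-and-bound on the semicontinuous choices
  (each violating food branches into "absent" and "$\ge$ 10 g"), intended
  for small instances and used as the oracle for the heuristic in the tests.

On the shipped instance families the heuristic attains the exact
semicontinuous optimum or sits within a few percent of it; it can in
principle be suboptimal, which is why the exact method exists.

### Salt and the sodium ceiling

Several scenarios pin minimum cooking salt (e.g. 3 g = 0.5 teaspoon). Salt
at 3 g already contributes ~1,160 mg sodium, and the familiar-meal scenarios
also force salty components (bread, cheese, sausages, canned tuna). Where
the pinned components alone would breach the 2,300 mg sodium ceiling, the
salt minimum — and only the salt minimum — is trimmed at compile time so
that forced sodium stays below 95% of the ceiling, mirroring the practice of
adjusting added salt to keep total sodium within recommended levels. The
sodium row itself always remains active.

### Constraints that are not LP-expressible

"Any **two** other vegetables of at least 100 g each" is a cardinality
constraint on distinct items; it is encoded as an aggregate row
($\ge$ 200 g over non-starchy vegetables), and similarly for the other
"any other vegetable" meal components. A scenario recipe minimum above a
default variety cap (426 g of potatoes against the 200 g vegetable cap)
lifts the cap to the minimum: the recipe wins.

## Uncertainty model

`run_simulation` re-optimizes the scenario on `n_iterations` (default
2,000) independently perturbed worlds:

| quantity | distribution | parameters |
|---|---|---|
| price | gamma (method of moments) | `price_mean`, `price_sd`; foods without an sd use the median CV of their category |
| nutrient content | normal, truncated at 0 | sd = 5% of the mean |
| wastage | beta (method of moments) | `wastage_mean`, `wastage_sd` |
| requirement minima | normal, truncated at 0, clamped to any upper bound | heterogeneity sd; energy uses 184.4 kJ, other minima default to 5% of the bound (the source survey's spread by body size and activity level is not published food-by-food, so a single realistic relative spread is used) |

All perturbations are independent across foods, nutrients and requirements;
price co-movement within a category is a known omission (see Limitations).
Draw $k$ seeds its own RNG stream from `(seed, k)`, so summaries are
bit-reproducible and independent of evaluation order. Infeasible draws are
counted and excluded from summaries rather than redrawn — redrawing would
bias the sampled parameter space toward easy worlds, and the infeasibility
rate is itself informative. Simulation intervals (SI) are the 2.5th–97.5th
percentiles using R's default linear-interpolation quantile (type 7).
Nutrient ratios (PUFA/saturated fat, potassium/sodium) are reported as
ratios of the summary statistics, not statistics of per-draw ratios.

## The synthetic database

Real national price series, food-composition tables and emission factors
are licensed/third-party datasets, so the package generates databases with
their *structure*: 76 foods by default, across fruit/vegetables, cereals,
pulses/seeds/nuts, dairy, meat/fish/eggs, fats/oils, condiments and other.
A fixed catalogue of 62 anchor foods carries the ids the built-in scenarios
reference (flour, oats, olive oil, beef mince, taro, ...) with
order-of-magnitude-realistic prices, nutrient profiles, wastage (potatoes at
mean 0.45, sd 0.0142) and emission factors encoding plant $\ll$ dairy <
ruminant meat; filler foods are drawn from category-level ranges. Per-seed
jitter (±10% prices, ±5% nutrients and emission factors) makes every seed a
distinct but structurally equivalent study population.

Feasibility is guaranteed constructively, not by rejection alone: a hidden
low-sodium, low-saturated-fat reference diet is priced against every
requirement row and any shortfall is closed by scaling that nutrient's
column (the reference diet is then discarded); afterwards the generator
*verifies by solving* that the base scenario — and, when the full anchor set
is present, the budget-capped scenarios — are feasible, regenerating with a
shifted seed otherwise (at most 50 attempts).

What passing tests on synthetic data do and do not show: they demonstrate
that the pipeline reproduces the *structural* findings — emission-optimized
diets emit no more than cost-optimized ones; a typical meat-heavy diet costs
and emits strictly more than every optimized scenario; optimized costs sit
in the few-dollars-a-day range — on every seed. They do not reproduce any
published point estimate: those depend on one specific national food table
that users must supply themselves (load it with `load_food_database` and
pass it to `run_config(database = ...)`, with `match_paper = TRUE` for the
just-binding budget cap).

The typical-diet comparator splits the 11,450 kJ energy target across
categories by fixed shares (cereal-heavy, 22% meat, 15% discretionary
"other"), allocates each category's energy equally across its
energy-supplying members, and rescales exactly to target. It is evaluated,
never optimized.

## Numerical and design choices

* Feasibility tolerance $10^{-6}$ relative; solver pivot tolerance
  $10^{-9}$; money rounded to cents and emissions to 0.01 kg only in
  printed output, never in computation or stored files.
* Compilation is deterministic with a documented row order (nutrient rows
  in requirement-table order, then category aggregates, the added-sugar
  cap, linked ratios, budget).
* The flour:oil link is compiled as an *equality* (7:1); a minimum-oil
  reading ("at least 1 part oil per 7 flour") would be a one-sided
  inequality and is not what a fixed recipe ratio describes.
* The Asian scenario's bulk-rice price is a scenario-scoped override; it
  does not change the database.
* Maxima and price overrides referencing foods absent from a database are
  vacuously ignored; minima and linked ratios referencing absent foods are
  compile errors, because they force the food into the diet.

## Problem sizes

The test suite runs on the 76-food default database, a 5–12-food micro
configuration, and hundreds of random 3–5-food instances; Monte Carlo
calibration tests use 2,000 draws on a one-food analytic instance and
150–400 draws elsewhere. The acceptance script solves all sixteen scenarios
on the default database and runs the full 2,000-draw simulations for the C1
and G1 scenarios (about a minute in total on one CPU).

## Limitations

* Price draws are independent across foods; real food prices co-move within
  categories and with inflation. A correlation hook would change simulation
  intervals for diet-level cost more than for composition.
* The iterative minimum-portion heuristic is not guaranteed optimal;
  `method = "milp"` is exponential in the number of violating foods and is
  intended for small instances.
* Only one B vitamin (thiamine) and no vitamin D constraint are modeled,
  matching the requirement table's scope.
* The synthetic generator aims at structural realism, not numerical
  fidelity to any country's food supply; conclusions about specific foods
  (as opposed to categories and orderings) should be drawn only from a real
  database.
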