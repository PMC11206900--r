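# dietscale

Can a diet pattern observed in one population meet the nutritional demands
of a very different one? `dietscale` answers a concrete instance of that
question: it scales the nutrient-density profile of a completely
plant-based cohort to the daily energy requirements of professional
American-football players and screens the result against Dietary Reference
Intakes (DRIs). It is aimed at sports dietitians and nutrition researchers
who want position-level protein, leucine and micronutrient projections —
and at anyone who wants to rerun or perturb that model with their own
roster, cohort profile or reference table.

## The model

The scaling substrate is a **nutrient-density profile**: mean cohort
intakes *d\_i* per reference energy *E\_ref* (here 2000 kcal/day). For an
athlete with daily energy requirement *E*, each nutrient scales
proportionally,

    a_i = d_i × E / E_ref,

while percent-of-energy nutrients (saturated fat as % kcal, the protein
energy fraction) are scale-invariant. Energy requirements come either from
a fixed per-athlete override or from lean body mass via the Cunningham
equation with an activity factor:

    LBM = M × (1 − f),   RMR = 500 + 22 × LBM,   E = RMR × AF,

with body mass *M* (kg), body-fat fraction *f*, and activity factor *AF*.

Derived provisions:

* absolute protein `P = E × 0.145 / 4` g/day (14.5% of energy at 4 kcal/g),
* relative protein `P / M` g/kg/day, compared against the 1.6 g/kg/day
  recommendation for strength athletes,
* daily leucine `L = P × 0.071` (mean leucine share of plant protein) and
  per-meal leucine `L / 4` under equal partition over four meals, compared
  against the ~2 g/meal muscle-protein-synthesis threshold,
* an energy-indexed fiber target of 14 g per 1000 kcal,
* for mixed diets, `L = P_animal × 0.088 + P_plant × 0.071`.

Adequacy screening is direction-aware: RDA/AI/rate targets are floors,
DGA-limit/CDRR targets are ceilings, rate targets are resolved at the
diet's energy, and tolerable upper intake levels (ULs) are exceeded only on
a strict comparison — a not-determinable (ND) UL never flags. Caveats (the
folate UL applies to synthetic folate only, the magnesium UL to
pharmacological sources, vitamin A's UL to preformed retinol) are carried
as annotations, never as numeric adjustments.

## Worked example

```r
library(dietscale)

rep <- run_pipeline(reproduce_tables = TRUE)
as.data.frame(rep$table1)
#>            position body_mass_kg energy_kcal_day protein_requirement_g_day
#> 1 Defensive Lineman        134.7            6250                       216
#> 2 Offensive Lineman        144.0            6350                       230
#> 3      Running Back        110.5            5850                       177
#> 4         Tight End        123.3            6150                       197
#> 5        Linebacker        108.1            6050                       173
#> 6       Quarterback        100.9            5300                       161
#>   protein_g_day protein_g_per_kg_day leucine_g_day leucine_g_per_meal
#> 1           227                  1.7          16.1                4.0
#> 2           230                  1.6          16.3                4.1
#> 3           212                  1.9          15.1                3.8
#> 4           223                  1.8          15.8                4.0
#> 5           223                  2.1          15.8                4.0
#> 6           219                  2.2          15.5                3.9
```

Every position's scaled diet supplies 1.6–2.2 g/kg/day of protein (at or
above the 1.6 g/kg/day recommendation) and 3.8–4.1 g of leucine at each of
four meals (above the ~2 g/meal threshold), without supplementation. The
upper-limit summary shows which micronutrients overshoot their limits at
these energy intakes:

```r
as.data.frame(rep$ul_summary[, c("nutrient", "n_positions_exceeding",
                                 "min_amount", "max_amount", "limit")])
#>     nutrient n_positions_exceeding min_amount max_amount limit
#> 1     folate                     6       2353       2819  1000
#> 2    calcium                     6       3063       3670  2500
#> 3       iron                     6         85        102    45
#> 4  magnesium                     6       1728       2070   350
#> 5 phosphorus                     5       4010       4353  4000
#> 6     sodium                     6       9357      11211  2300
#> 7       zinc                     6         42         51    40
```

Six nutrients exceed their limit at every position; phosphorus exceeds its
UL everywhere except for the quarterback (3633 vs 4000 mg/day). Each
carries a caveat column explaining why the exceedance is or is not a
practical concern (e.g. the folate UL applies to synthetic folate only).

A mixed animal/plant comparison, using published animal (94–113 g/day) and
plant (30–39 g/day) protein intakes of omnivorous players:

```r
round_half_up(mixed_diet_leucine(94, 30), 1)   # 10.4 g/day
round_half_up(mixed_diet_leucine(113, 39), 1)  # 12.7 g/day
```

`run_pipeline(reproduce_tables = TRUE)` honors two per-player absolute-
protein overrides shipped with the bundled roster (linebacker 223,
quarterback 219 g/day); with the default `FALSE` those rows are computed
from the stated energy-fraction procedure instead (219 and 192 g/day). The
methods vignette (`vignettes/diet-scaling-methods.Rmd`) explains the
discrepancy.

A command-line shell over the same functions is included:

```sh
Rscript inst/scripts/dietscale.R scale --out reports --reproduce-tables
Rscript inst/scripts/dietscale.R generate --seed 7 --out synth
Rscript inst/scripts/dietscale.R fixtures --out fixtures
```

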