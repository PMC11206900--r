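---
title: "Methods: scaling a plant-based cohort diet to athlete energy requirements"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scaling a plant-based cohort diet to athlete energy requirements}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dietscale)
```

## The modeling question

Strength athletes are conventionally advised to anchor their diets on
animal protein, yet dietary guidelines push in the opposite direction. The
model in this package asks a sharply scoped version of the reconciliation
question: if an athlete ate exactly the diet *pattern* of a completely
plant-based cohort — same nutrient density, same food composition — but in
quantities meeting their energy requirement, what protein, leucine and
micronutrient provisions would result, and how do they compare with
reference intakes?

This is a scaling model, not a meal planner. It assumes nutrient density is
invariant under energy intake: eating 3× the calories of the cohort's mean
diet supplies 3× each nutrient. That is the model's central, deliberately
simple assumption; it ignores food-choice changes that real athletes would
make at 6000 kcal/day.

## Pipeline

For each athlete the package runs four stages, kept unrounded end to end:

1. **Energy.** If the roster row carries a fixed `energy_kcal_day`, it is
   used verbatim (`source = "override"`). Otherwise lean body mass
   `LBM = M (1 − f)` feeds the Cunningham equation `RMR = 500 + 22 LBM`
   and an activity factor multiplies it. The bundled roster uses
   overrides: its published energies were computed upstream from
   anthropometrics that were never published, and inventing body-fat
   fractions to reverse-engineer them would add nothing. The computed path
   is exercised by synthetic data instead. The Cunningham coefficients are
   the standard 1980 formulation and are exposed as arguments because the
   equation is auxiliary here, not the contribution.
2. **Scaling.** Every per-reference-energy density becomes
   `d × E / E_ref`. Percent-of-energy entries (saturated fat, the protein
   energy fraction) pass through unchanged — a proportional rescaling of
   all foods cannot change a percent-of-energy quantity.
3. **Protein and leucine.** Absolute protein is `E × 0.145 / 4` g/day: the
   cohort's protein energy fraction times energy, converted at the general
   Atwater factor of 4 kcal/g. Relative protein divides by body mass; the
   requirement line is `1.6 g/kg/day × M`. Daily leucine multiplies
   protein by the plant-food mean leucine share (0.071); per-meal leucine
   divides by four meals (equal partition — the published per-meal values
   are exactly daily/4). The animal-protein share (0.088) is used only by
   `mixed_diet_leucine()`; the dairy share is known only as ">10%" and is
   therefore stored as a note, never as a number.
4. **Adequacy.** Each scaled amount is compared with its reference:
   floors (RDA, AI, energy-indexed rates) use `>=`, ceilings (DGA limits,
   the sodium CDRR) use `<=`, and ULs use strict `>`. The inclusive/strict
   split is not arbitrary: a diet meeting a requirement exactly counts as
   "met", while an intake exactly at a UL is not an exceedance.

## Parameters

| parameter | default | units | why |
|---|---|---|---|
| `protein_energy_fraction` | 0.145 | proportion | cohort protein share of calories |
| `protein_kcal_per_g` | 4 | kcal/g | general Atwater factor for protein |
| `leucine_fraction_plant` | 0.071 | proportion | mean leucine share of plant proteins |
| `leucine_fraction_animal` | 0.088 | proportion | mean leucine share of animal proteins |
| `meals_per_day` | 4 | count | per-meal leucine dosing convention |
| `protein_requirement_g_per_kg` | 1.6 | g/kg/day | strength-athlete protein recommendation |
| `leucine_threshold_g_per_meal` | 2 | g | muscle-protein-synthesis trigger dose |
| `fiber_rate_g_per_1000kcal` | 14 | g/1000 kcal | energy-indexed fiber recommendation |
| Cunningham `intercept`, `slope` | 500, 22 | kcal/day, kcal/day/kg | standard equation coefficients |

All are plain function arguments and serialize to JSON/YAML via
`write_model_parameters()`.

## Design choices that were genuinely open

**Table-reproduction mode.** Two bundled roster rows (linebacker,
quarterback) ship absolute-protein values (223 and 219 g/day) that the
energy-fraction procedure does not yield from their energies (it gives
219.3 and 192.1). Whether this reflects a transcription shift or an
unstated per-position fraction cannot be determined from the available
text, so the package takes no stance: by default it computes per the
stated procedure, and `reproduce_tables = TRUE` honors the per-player
override so the published table — including the headline 2.2 g/kg/day —
is reproduced verbatim. Both paths are tested.

**Sodium in the upper-limit tally.** Sodium has no UL (ND); its operative
limit is the 2300 mg CDRR, which is a target, not a UL. Per-nutrient
assessments therefore never mark sodium's `ul_exceeded` (an ND UL never
flags), but `ul_exceedance_summary()` counts ceiling-type target
violations with ND ULs alongside strict UL exceedances — that is how limit
nutrients are conventionally tallied, and it is the only reading under
which the published "seven micronutrients exceeded the UL" counts sodium.

**Density precision.** Densities are stored at the best recoverable
precision, never display precision where better is known: fiber at
46.7 g/2000 kcal (the cohort mean from the running text; the table
displays 47). Iron, zinc and linoleic acid are the exception — their
published position cells are consistent only with unrounded densities
(~31.6 mg, ~16.3 mg, ~19.5 g) that were never printed, so the fixture
keeps the printed 32/16/20 and the package documents that these three
nutrients' position cells may differ by ~1 unit in the last place. No
unprinted precision is invented. Their upper-limit verdicts are unaffected:
even at display precision they exceed their ULs at every position.

**Verdict caveats.** The folate, magnesium, calcium and vitamin A UL
caveats travel as annotation strings on every assessment. They are never
applied numerically — the model reports exceedances and surfaces the
argument, it does not recompute limits. Vitamin A's UL is ND in the
bundled references because the UL covers only preformed vitamin A, which a
plant-sourced profile does not supply; a numeric UL can be provided for
omnivorous profiles.

## Numerical conventions

* **Rounding** is a reporting concern only; all composition identities
  (`leucine_per_meal × meals = leucine_day`, `g/kg × mass = g/day`) hold
  unrounded. Display rounding is half-up (2037.5 → 2038), implemented in
  `round_half_up()` with a `sqrt(.Machine$double.eps)` guard so decimal
  halves that are not exact binary halves (6.35 at one decimal) still
  round upward. Base R's `round()` rounds half to even and reproduces
  neither convention. One decimal is used for omega-3, vitamins B6 and
  B12, and percent-of-energy entries; integers otherwise.
* **Degenerate inputs.** Zero energy scales to a zero diet; zero protein
  gives zero leucine; a single-food category has SEM 0 with a warning; an
  empty roster produces empty reports with success status; an empty
  reference list produces an empty assessment.
* **Boundaries.** Targets inclusive, ULs strict (see above). Body-fat
  fraction lives in `[0, 1)`; activity factors in `[1, ∞)`.

## The synthetic-data generator

The generator exists so every pipeline stage is testable without any
external data. It emulates the *inputs* of the study design: a roster of
athletes and a per-2000-kcal density profile.

* Body masses are truncated-normal with default location 120 kg and SD
  10 kg — spanning the 100.9–144.0 kg range of the bundled positions;
  body-fat fractions truncated-normal at 0.16 ± 0.04 (typical
  professional-football composition); activity factors uniform on
  1.8–2.4 (heavy daily training). Generated athletes use the computed
  Cunningham path, which the bundled roster cannot exercise.
* Densities are lognormal around the configured means with a default
  coefficient of variation of 0.25, a realistic between-subject spread for
  FFQ-derived intakes; the lognormal is parameterized so the mean equals
  the configured location exactly and every draw is positive. With
  `density_cv = 0` the bundled profile is regenerated verbatim.
  A truncated-normal family is available as an alternative.
* One integer seed drives everything through per-component sub-streams
  (`(seed × 69621 + hash(label)) mod (2³¹ − 1)`, one stream for the roster
  and one per nutrient), so adding a nutrient never perturbs roster draws
  and profiles are reproducible nutrient by nutrient. Generators save and
  restore the caller's RNG state.

What the generator does **not** emulate: correlation between nutrients
(real diets correlate sodium with energy, for instance), FFQ measurement
error, supplement/diet partitioning, or any food-level structure. Passing
tests on synthetic data therefore demonstrate the pipeline's mechanics —
determinism, invariances, parameter recovery — not that the model captures
real dietary variation.

## Verification scale

The test suite checks parameter recovery with 500 synthetic profiles at
`density_cv = 0.1` (each nutrient's sample mean within three standard
errors of its configured mean), property loops of 25–50 random cases per
invariant, and full golden reproduction of both published tables on the
six-position roster. These sizes make the whole suite run in well under a
minute while leaving the statistical checks adequately powered.

## Known limitations

* Nutrient density is assumed intake-invariant; behavioral food-choice
  shifts at very high energy intakes are out of scope.
* Protein quality (DIAAS/PDCAAS), digestibility, and amino acids other
  than leucine are not modeled; leucine stands in for protein quality via
  the per-meal threshold argument.
* No probabilistic adequacy assessment (EAR cut-point): the model compares
  means with references, it does not estimate prevalence of inadequacy.
* Thiamin, riboflavin, niacin, pantothenic acid, biotin, chloride, iodine,
  copper, manganese and selenium are absent from the cohort profile and
  hence unassessed.
* Sodium's verdict is reported against the CDRR as printed; athlete sweat
  losses are surfaced as a caveat, not modeled.
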