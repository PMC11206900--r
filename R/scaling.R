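#' Model parameters for diet scaling
#'
#' Tunable constants of the scaling model, with defaults matching the
#' published modeling conditions:
#' * `protein_energy_fraction` — protein share of total calories in the
#'   cohort diet (0.145, i.e. 14.5% of energy);
#' * `protein_kcal_per_g` — Atwater energy density of protein (4 kcal/g),
#'   used to convert the energy fraction to grams;
#' * `leucine_fraction_plant` — mean leucine share of plant protein (0.071);
#' * `leucine_fraction_animal` — mean leucine share of animal protein
#'   (0.088), used only for mixed-diet projections;
#' * `leucine_fraction_dairy_note` — dairy proteins carry a qualitative
#'   ">10%" leucine share; kept as a note, never as a number;
#' * `meals_per_day` — meals over which daily leucine is evenly split (4);
#' * `protein_requirement_g_per_kg` — protein recommendation for strength
#'   athletes (1.6 g/kg/day);
#' * `leucine_threshold_g_per_meal` — per-meal leucine dose hypothesized to
#'   maximally stimulate muscle protein synthesis (2 g);
#' * `fiber_rate_g_per_1000kcal` — energy-indexed fiber recommendation
#'   (14 g per 1000 kcal).
#'
#' @param protein_energy_fraction Proportion in (0, 1).
#' @param protein_kcal_per_g Energy density, kcal per g.
#' @param leucine_fraction_plant Proportion in (0, 1).
#' @param leucine_fraction_animal Proportion in (0, 1).
#' @param meals_per_day Integer `>= 1`.
#' @param protein_requirement_g_per_kg Rate, g/kg/day, `> 0`.
#' @param leucine_threshold_g_per_meal Amount, g/meal, `> 0`.
#' @param fiber_rate_g_per_1000kcal Rate, g per 1000 kcal, `> 0`.
#' @return A list of class `model_parameters`.
#' @export
#' @examples
#' model_parameters()
model_parameters <- function(protein_energy_fraction = 0.145,
                             protein_kcal_per_g = 4,
                             leucine_fraction_plant = 0.071,
                             leucine_fraction_animal = 0.088,
                             meals_per_day = 4,
                             protein_requirement_g_per_kg = 1.6,
                             leucine_threshold_g_per_meal = 2,
                             fiber_rate_g_per_1000kcal = 14) {
  p <- list(
    protein_energy_fraction = protein_energy_fraction,
    protein_kcal_per_g = protein_kcal_per_g,
    leucine_fraction_plant = leucine_fraction_plant,
    leucine_fraction_animal = leucine_fraction_animal,
    leucine_fraction_dairy_note = ">10% of protein (qualitative)",
    meals_per_day = meals_per_day,
    protein_requirement_g_per_kg = protein_requirement_g_per_kg,
    leucine_threshold_g_per_meal = leucine_threshold_g_per_meal,
    fiber_rate_g_per_1000kcal = fiber_rate_g_per_1000kcal
  )
  for (f in c("protein_energy_fraction", "leucine_fraction_plant",
              "leucine_fraction_animal")) {
    if (!is.finite(p[[f]]) || p[[f]] <= 0 || p[[f]] >= 1) {
      abort_invalid("%s must lie in (0, 1)", f)
    }
  }
  if (!is.finite(p$meals_per_day) || p$meals_per_day < 1) {
    abort_invalid("meals_per_day must be >= 1")
  }
  for (f in c("protein_kcal_per_g", "protein_requirement_g_per_kg",
              "leucine_threshold_g_per_meal", "fiber_rate_g_per_1000kcal")) {
    if (!is.finite(p[[f]]) || p[[f]] <= 0) {
      abort_invalid("%s must be > 0", f)
    }
  }
  structure(p, class = "model_parameters")
}

#' @export
print.model_parameters <- function(x, ...) {
  cat("<model parameters>\n")
  for (nm in names(x)) cat(sprintf("  %-30s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

#' Read or write model parameters as JSON/YAML
#'
#' Only recognised parameter names are accepted; unspecified parameters keep
#' their defaults.
#'
#' @param path File path; extension (`.json`, `.yaml`, `.yml`) selects the
#'   format.
#' @return For `read_model_parameters`, a `model_parameters` object; for
#'   `write_model_parameters`, `path` invisibly.
#' @export
read_model_parameters <- function(path) {
  if (!file.exists(path)) abort_invalid("parameter file not found: %s", path)
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    json = jsonlite::fromJSON(path),
    yaml = ,
    yml  = yaml::read_yaml(path),
    abort_invalid("unsupported parameter format '.%s'", ext))
  raw$leucine_fraction_dairy_note <- NULL
  known <- names(formals(model_parameters))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    abort_invalid("unknown parameter(s): %s", paste(unknown, collapse = ", "))
  }
  do.call(model_parameters, raw)
}

#' @rdname read_model_parameters
#' @param params A `model_parameters` object.
#' @export
write_model_parameters <- function(params, path) {
  stopifnot(inherits(params, "model_parameters"))
  ext <- tolower(tools::file_ext(path))
  payload <- unclass(params)
  if (ext == "json") {
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else if (ext %in% c("yaml", "yml")) {
    yaml::write_yaml(payload, path)
  } else {
    abort_invalid("unsupported parameter format '.%s'", ext)
  }
  invisible(path)
}

#' Scale a nutrient density to a target energy level
#'
#' The proportional-scaling primitive: an amount consumed per
#' `reference_energy_kcal` becomes `amount * target / reference` at the
#' target energy. Percent-of-energy entries (basis `"percent_of_energy"`)
#' are scale-invariant and returned unchanged.
#'
#' @param density_amount Amount per reference energy, `>= 0`.
#' @param reference_energy_kcal Reference energy, kcal, `> 0`.
#' @param target_energy_kcal Target energy, kcal, `>= 0`.
#' @param basis `"per_reference_energy"` (default) or `"percent_of_energy"`.
#' @return The scaled amount.
#' @export
#' @examples
#' scale_nutrient(888, 2000, 6250)  # 2775 (folate, mcg/day)
scale_nutrient <- function(density_amount, reference_energy_kcal,
                           target_energy_kcal,
                           basis = "per_reference_energy") {
  if (any(!is.finite(reference_energy_kcal) | reference_energy_kcal <= 0)) {
    abort_invalid("reference_energy_kcal must be > 0")
  }
  if (any(!is.finite(target_energy_kcal) | target_energy_kcal < 0)) {
    abort_invalid("target_energy_kcal must be >= 0")
  }
  if (any(density_amount < 0, na.rm = TRUE)) {
    abort_invalid("density_amount must be >= 0")
  }
  ifelse(basis == "percent_of_energy",
         density_amount,
         density_amount * target_energy_kcal / reference_energy_kcal)
}

#' Absolute protein provision from energy
#'
#' Protein supplied by a diet delivering `protein_energy_fraction` of its
#' calories as protein: `energy * fraction / protein_kcal_per_g` (g/day).
#'
#' @param energy_kcal_day Daily energy, kcal, `>= 0`.
#' @param params [model_parameters()].
#' @return Protein in g/day (unrounded).
#' @export
#' @examples
#' protein_grams(6250)  # 226.5625 -> displays as 227
protein_grams <- function(energy_kcal_day, params = model_parameters()) {
  if (any(!is.finite(energy_kcal_day) | energy_kcal_day < 0)) {
    abort_invalid("energy_kcal_day must be >= 0")
  }
  energy_kcal_day * params$protein_energy_fraction / params$protein_kcal_per_g
}

#' Relative protein provision
#'
#' @param protein_g_day Protein, g/day, `>= 0`.
#' @param body_mass_kg Body mass, kg, `> 0`.
#' @return Protein in g/kg/day.
#' @export
relative_protein <- function(protein_g_day, body_mass_kg) {
  if (any(!is.finite(body_mass_kg) | body_mass_kg <= 0)) {
    abort_invalid("body_mass_kg must be > 0")
  }
  protein_g_day / body_mass_kg
}

#' Protein requirement for a strength athlete
#'
#' @param body_mass_kg Body mass, kg, `> 0`.
#' @param requirement_g_per_kg Requirement rate, g/kg/day (default 1.6).
#' @return Requirement in g/day.
#' @export
#' @examples
#' protein_requirement(134.7)  # 215.52 -> displays as 216
protein_requirement <- function(body_mass_kg, requirement_g_per_kg = 1.6) {
  if (any(!is.finite(body_mass_kg) | body_mass_kg <= 0)) {
    abort_invalid("body_mass_kg must be > 0")
  }
  if (any(!is.finite(requirement_g_per_kg) | requirement_g_per_kg <= 0)) {
    abort_invalid("requirement_g_per_kg must be > 0")
  }
  body_mass_kg * requirement_g_per_kg
}

#' Daily leucine from total protein
#'
#' @param protein_g_day Total dietary protein, g/day, `>= 0`.
#' @param leucine_fraction Leucine share of protein, proportion in (0, 1);
#'   the plant-food mean 0.071 for a fully plant-based diet.
#' @return Leucine in g/day.
#' @export
leucine_daily <- function(protein_g_day, leucine_fraction = 0.071) {
  if (any(!is.finite(protein_g_day) | protein_g_day < 0)) {
    abort_invalid("protein_g_day must be >= 0")
  }
  if (any(!is.finite(leucine_fraction) | leucine_fraction <= 0 |
          leucine_fraction >= 1)) {
    abort_invalid("leucine_fraction must lie in (0, 1)")
  }
  protein_g_day * leucine_fraction
}

#' Per-meal leucine under equal partition
#'
#' @param leucine_g_day Daily leucine, g.
#' @param meals_per_day Meals per day, integer `>= 1`.
#' @return Leucine in g/meal.
#' @export
leucine_per_meal <- function(leucine_g_day, meals_per_day = 4) {
  if (any(!is.finite(meals_per_day) | meals_per_day < 1)) {
    abort_invalid("meals_per_day must be >= 1")
  }
  leucine_g_day / meals_per_day
}

#' Leucine projection for a mixed animal/plant diet
#'
#' Applies the category-mean leucine shares to separately reported animal
#' and plant protein intakes: `animal * fraction_animal + plant *
#' fraction_plant`.
#'
#' @param animal_protein_g_day Animal protein, g/day, `>= 0`.
#' @param plant_protein_g_day Plant protein, g/day, `>= 0`.
#' @param params [model_parameters()]; supplies the 0.088 and 0.071 means.
#' @return Leucine in g/day.
#' @export
#' @examples
#' mixed_diet_leucine(113, 39)  # 12.713 -> displays as 12.7
mixed_diet_leucine <- function(animal_protein_g_day, plant_protein_g_day,
                               params = model_parameters()) {
  if (any(!is.finite(animal_protein_g_day) | animal_protein_g_day < 0) ||
      any(!is.finite(plant_protein_g_day) | plant_protein_g_day < 0)) {
    abort_invalid("protein amounts must be >= 0")
  }
  animal_protein_g_day * params$leucine_fraction_animal +
    plant_protein_g_day * params$leucine_fraction_plant
}

#' Energy-indexed fiber target
#'
#' @param energy_kcal_day Daily energy, kcal, `>= 0`.
#' @param rate_g_per_1000kcal Recommendation rate (default 14 g/1000 kcal).
#' @return Fiber target in g/day.
#' @export
#' @examples
#' fiber_target(6350)  # 88.9 -> displays as 89
fiber_target <- function(energy_kcal_day, rate_g_per_1000kcal = 14) {
  if (any(!is.finite(energy_kcal_day) | energy_kcal_day < 0)) {
    abort_invalid("energy_kcal_day must be >= 0")
  }
  energy_kcal_day * rate_g_per_1000kcal / 1000
}

#' Category mean and SEM of leucine fractions
#'
#' Arithmetic mean and standard error of the mean (sample SD / sqrt(n)) of
#' the leucine share of protein over the foods of one category. With a
#' single food the SEM is reported as 0 and flagged.
#'
#' @param foods A [food_protein_composition()] table.
#' @param category `"animal"`, `"dairy"` or `"plant"`.
#' @return A list with `mean`, `sem`, `n`, and `single_item` (TRUE when the
#'   SEM is degenerate because n = 1).
#' @export
mean_fraction_with_sem <- function(foods, category) {
  foods <- food_protein_composition(foods)
  f <- foods$leucine_fraction_of_protein[foods$category == category]
  if (length(f) == 0) {
    abort_invalid("no foods in category '%s'", category)
  }
  n <- length(f)
  single <- n == 1
  if (single) {
    warning("SEM undefined for a single food; reporting 0", call. = FALSE)
  }
  list(mean = mean(f),
       sem = if (single) 0 else stats::sd(f) / sqrt(n),
       n = n,
       single_item = single)
}

#' Scale a diet to one athlete's energy requirement
#'
#' The core pipeline for one athlete: resolve the energy requirement
#' ([energy_requirement()]), scale every nutrient density to it
#' ([scale_nutrient()]), and derive the protein and leucine provisions
#' (absolute protein from the energy fraction, relative protein per kg, the
#' 1.6 g/kg/day requirement, daily leucine from the plant-food mean, and
#' per-meal leucine under equal partition). All values are retained
#' unrounded; rounding is applied only when reports are rendered.
#'
#' When `use_protein_override = TRUE` and the profile row carries a
#' `protein_override_g_day`, that value replaces the computed absolute
#' protein (and propagates to relative protein and leucine). This
#' table-reproduction mode exists because two published roster rows
#' (linebacker and quarterback) carry absolute-protein values that the
#' stated energy-fraction procedure does not yield from their printed
#' energies; the override reproduces the published artifact verbatim while
#' the default remains faithful to the procedure.
#'
#' @param player A one-row roster.
#' @param profile A [density_profile()].
#' @param params [model_parameters()].
#' @param use_protein_override Honor the roster's per-player absolute
#'   protein override (default `FALSE`).
#' @return An object of class `scaled_diet`: a list with the position
#'   label, energy, a `nutrients` tibble (nutrient, amount, unit, basis),
#'   and the derived protein/leucine quantities.
#' @export
#' @examples
#' fx <- bundled_fixtures()
#' scale_diet(fx$roster[1, ], fx$profile)
scale_diet <- function(player, profile, params = model_parameters(),
                       use_protein_override = FALSE) {
  player <- validate_roster(player)
  if (nrow(player) != 1) {
    abort_invalid("scale_diet() expects a single athlete; got %d rows (see scale_roster())",
                  nrow(player))
  }
  profile <- validate_density_profile(profile)
  energy <- energy_requirement(player)$total_kcal_day

  e <- profile$entries
  nutrients <- tibble::tibble(
    nutrient = e$nutrient,
    amount = scale_nutrient(e$amount, profile$reference_energy_kcal, energy,
                            e$basis),
    unit = e$unit,
    basis = e$basis
  )

  protein <- protein_grams(energy, params)
  override <- player$protein_override_g_day
  overridden <- use_protein_override && !is.na(override)
  if (overridden) protein <- override

  leu_day <- leucine_daily(protein, params$leucine_fraction_plant)
  structure(list(
    position = player$position,
    body_mass_kg = player$body_mass_kg,
    energy_kcal_day = energy,
    nutrients = nutrients,
    protein_g_day = protein,
    protein_overridden = overridden,
    protein_g_per_kg_day = relative_protein(protein, player$body_mass_kg),
    protein_requirement_g_day =
      protein_requirement(player$body_mass_kg,
                          params$protein_requirement_g_per_kg),
    leucine_g_day = leu_day,
    leucine_g_per_meal = leucine_per_meal(leu_day, params$meals_per_day),
    meals_per_day = params$meals_per_day,
    fiber_target_g_day = fiber_target(energy, params$fiber_rate_g_per_1000kcal),
    params = params
  ), class = "scaled_diet")
}

#' Scale a diet for every athlete in a roster
#'
#' @inheritParams scale_diet
#' @param roster A validated roster.
#' @return A named list of `scaled_diet` objects in roster order.
#' @export
scale_roster <- function(roster, profile, params = model_parameters(),
                         use_protein_override = FALSE) {
  roster <- validate_roster(roster)
  diets <- lapply(seq_len(nrow(roster)), function(i) {
    scale_diet(roster[i, ], profile, params, use_protein_override)
  })
  names(diets) <- roster$position
  diets
}

#' @export
print.scaled_diet <- function(x, ...) {
  cat(sprintf("<scaled diet: %s, %g kcal/day>\n", x$position,
              x$energy_kcal_day))
  cat(sprintf("  protein  %.1f g/day (%.2f g/kg/day; requirement %.1f g/day%s)\n",
              x$protein_g_day, x$protein_g_per_kg_day,
              x$protein_requirement_g_day,
              if (x$protein_overridden) "; override" else ""))
  cat(sprintf("  leucine  %.2f g/day, %.2f g over each of %d meals\n",
              x$leucine_g_day, x$leucine_g_per_meal, x$meals_per_day))
  cat(sprintf("  %d scaled nutrient(s)\n", nrow(x$nutrients)))
  invisible(x)
}
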