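test_that("proportional scaling reproduces printed spot values", {
  expect_equal(scale_nutrient(888, 2000, 6250), 2775)    # folate, mcg
  expect_equal(scale_nutrient(1156, 2000, 5300), 3063.4) # calcium, mg
  x <- 12.34
  expect_equal(scale_nutrient(x, 2000, 2000), x)         # identity
  expect_equal(scale_nutrient(5.2, 2000, 6250, basis = "percent_of_energy"),
               5.2)                                      # scale-invariant
  expect_error(scale_nutrient(1, 0, 100), "reference_energy_kcal")
  expect_error(scale_nutrient(1, 2000, -1), "target_energy_kcal")
})

test_that("scaling is linear in the energy target", {
  set.seed(7)
  for (i in 1:50) {
    d <- runif(1, 0, 5000)
    r <- runif(1, 500, 4000)
    t <- runif(1, 0, 8000)
    a <- runif(1, 0, 4)
    expect_equal(scale_nutrient(d, r, a * t), a * scale_nutrient(d, r, t))
  }
})

test_that("protein provision follows the energy fraction and Atwater factor", {
  expect_equal(protein_grams(6250), 226.5625)
  expect_equal(round_half_up(protein_grams(6250)), 227)
  expect_equal(round_half_up(protein_grams(5850)), 212)
  expect_equal(protein_grams(0), 0)
  p <- model_parameters(protein_energy_fraction = 0.2, protein_kcal_per_g = 4)
  expect_equal(protein_grams(2000, p), 100)
})

test_that("relative protein and the requirement reproduce printed rows", {
  expect_equal(round_half_up(relative_protein(protein_grams(6250), 134.7), 1),
               1.7)
  expect_equal(round_half_up(relative_protein(230, 144.0), 1), 1.6)
  expect_equal(relative_protein(42, 1), 42)
  expect_equal(round_half_up(protein_requirement(134.7, 1.6)), 216)
  expect_equal(round_half_up(protein_requirement(110.5, 1.6)), 177)
  expect_equal(protein_requirement(100, 1.0), 100)
  expect_error(relative_protein(100, 0), "body_mass_kg")
})

test_that("leucine derivation uses the plant-food mean and equal meal partition", {
  expect_equal(round_half_up(leucine_daily(230, 0.071), 1), 16.3)
  expect_equal(round_half_up(leucine_daily(223, 0.071), 1), 15.8)
  expect_equal(leucine_daily(0, 0.071), 0)
  expect_equal(round_half_up(leucine_per_meal(16.1, 4), 1), 4.0)
  expect_equal(round_half_up(leucine_per_meal(15.1, 4), 1), 3.8)
  expect_equal(leucine_per_meal(9.9, 1), 9.9)
  expect_error(leucine_per_meal(8, 0), "meals_per_day")
})

test_that("mixed animal/plant diets project the published leucine range", {
  expect_equal(round_half_up(mixed_diet_leucine(113, 39), 1), 12.7)
  expect_equal(round_half_up(mixed_diet_leucine(94, 30), 1), 10.4)
  expect_equal(mixed_diet_leucine(0, 0), 0)
  # per-meal doses for the same worked example
  expect_equal(round_half_up(leucine_per_meal(mixed_diet_leucine(113, 39)), 1),
               3.2)
  expect_equal(round_half_up(leucine_per_meal(mixed_diet_leucine(94, 30)), 1),
               2.6)
})

test_that("fiber targets resolve the 14 g/1000 kcal rate", {
  expect_equal(round_half_up(fiber_target(6350)), 89)
  expect_equal(round_half_up(fiber_target(5300)), 74)
  expect_equal(fiber_target(0), 0)
})

test_that("category leucine means and SEMs match a hand-computed oracle", {
  foods <- food_protein_composition(tibble::tibble(
    food_name = c("a", "b", "c"),
    category = c("plant", "plant", "animal"),
    leucine_fraction_of_protein = c(0.06, 0.08, 0.09)))
  res <- mean_fraction_with_sem(foods, "plant")
  expect_equal(res$mean, 0.07)
  expect_equal(res$sem, 0.01)  # sd(c(.06,.08))/sqrt(2) = 0.01
  expect_false(res$single_item)

  expect_warning(single <- mean_fraction_with_sem(foods, "animal"),
                 "single food")
  expect_equal(single$mean, 0.09)
  expect_equal(single$sem, 0)
  expect_true(single$single_item)

  expect_error(mean_fraction_with_sem(foods, "dairy"), "no foods")
})

test_that("scale_diet composes the full per-athlete derivation", {
  fx <- bundled_fixtures()
  ol <- scale_diet(fx$roster[fx$roster$position == "Offensive Lineman", ],
                   fx$profile)
  expect_equal(round_half_up(ol$protein_g_day), 230)
  expect_equal(round_half_up(ol$leucine_g_day, 1), 16.3)
  expect_equal(round_half_up(ol$leucine_g_per_meal, 1), 4.1)
  expect_equal(round_half_up(ol$protein_g_per_kg_day, 1), 1.6)

  te <- scale_diet(fx$roster[fx$roster$position == "Tight End", ], fx$profile)
  b6 <- te$nutrients$amount[te$nutrients$nutrient == "vitamin_b6"]
  expect_equal(round_half_up(b6, 1), 44.3)
})

test_that("scaling to the reference energy reproduces the density column", {
  fx <- bundled_fixtures()
  p <- player_profile("ref", 80, energy_kcal_day = 2000)
  diet <- scale_diet(p, fx$profile)
  expect_equal(diet$nutrients$amount, fx$profile$entries$amount)
})

test_that("scaled diets satisfy the composition identities unrounded", {
  fx <- bundled_fixtures()
  diets <- scale_roster(fx$roster, fx$profile)
  for (d in diets) {
    expect_equal(d$leucine_g_per_meal * d$meals_per_day, d$leucine_g_day)
    expect_equal(d$protein_g_per_kg_day * d$body_mass_kg, d$protein_g_day)
    expect_equal(d$leucine_g_day,
                 d$protein_g_day * d$params$leucine_fraction_plant)
    expect_true(all(d$nutrients$amount >= 0))
  }
})

test_that("scale_diet is invariant to the profile's reference energy basis", {
  fx <- bundled_fixtures()
  e <- fx$profile$entries
  rescaled <- e
  per <- rescaled$basis == "per_reference_energy"
  rescaled$amount[per] <- rescaled$amount[per] * 1250 / 2000
  profile_1250 <- density_profile(rescaled, reference_energy_kcal = 1250)
  a <- scale_diet(fx$roster[1, ], fx$profile)
  b <- scale_diet(fx$roster[1, ], profile_1250)
  expect_equal(b$nutrients$amount, a$nutrients$amount)
  expect_equal(b$protein_g_day, a$protein_g_day)
})

test_that("percent-of-energy entries are identical at every energy level", {
  fx <- bundled_fixtures()
  for (d in scale_roster(fx$roster, fx$profile)) {
    sat <- d$nutrients$amount[d$nutrients$nutrient == "saturated_fat"]
    expect_equal(sat, 5.2)
  }
})

test_that("the protein override replaces the computed value when requested", {
  fx <- bundled_fixtures()
  lb_row <- fx$roster[fx$roster$position == "Linebacker", ]
  default <- scale_diet(lb_row, fx$profile)
  expect_equal(round_half_up(default$protein_g_day), 219)  # 0.145*6050/4
  expect_false(default$protein_overridden)

  repro <- scale_diet(lb_row, fx$profile, use_protein_override = TRUE)
  expect_equal(repro$protein_g_day, 223)
  expect_true(repro$protein_overridden)
  expect_equal(round_half_up(repro$protein_g_per_kg_day, 1), 2.1)
  expect_equal(round_half_up(repro$leucine_g_day, 1), 15.8)
})

test_that("model parameters validate and round-trip through JSON and YAML", {
  expect_error(model_parameters(protein_energy_fraction = 1.2), "in \\(0, 1\\)")
  expect_error(model_parameters(meals_per_day = 0), "meals_per_day")
  expect_error(model_parameters(protein_kcal_per_g = -4), "> 0")
  p <- model_parameters(protein_energy_fraction = 0.18, meals_per_day = 5)
  for (ext in c(".json", ".yaml")) {
    path <- withr::local_tempfile(fileext = ext)
    write_model_parameters(p, path)
    expect_equal(read_model_parameters(path), p)
  }
  bad <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(not_a_param = 1), bad)
  expect_error(read_model_parameters(bad), "unknown parameter")
})
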