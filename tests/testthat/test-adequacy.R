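ref_row <- function(nutrient = "x", target = 100, type = "RDA", ul = NA_real_,
                    unit = "mg", caveat = "") {
  nutrient_reference(tibble::tibble(
    nutrient = nutrient, target_value = target, target_type = type,
    ul_value = ul, unit = unit, caveat = caveat))
}

test_that("assessment direction depends on the target type", {
  refs <- dri_reference_table()
  sodium <- assess_nutrient(11034, refs[refs$nutrient == "sodium", ], 6250)
  expect_false(sodium$target_met)          # CDRR is a ceiling
  expect_false(sodium$ul_applicable)       # ND UL
  expect_true(is.na(sodium$ul_exceeded))

  sat <- assess_nutrient(5.2, refs[refs$nutrient == "saturated_fat", ], 6250)
  expect_true(sat$target_met)              # DGA limit is a ceiling, 5.2 <= 10

  mg <- assess_nutrient(2038, refs[refs$nutrient == "magnesium", ], 6250)
  expect_true(mg$target_met)               # RDA floor: 2038 >= 400
  expect_true(mg$ul_exceeded)              # 2038 > 350
  expect_match(mg$caveat, "pharmacological")
})

test_that("rate targets are resolved at the diet's energy", {
  refs <- dri_reference_table()
  fiber <- assess_nutrient(146, refs[refs$nutrient == "fiber", ], 6250)
  expect_equal(fiber$target_value_resolved, 87.5)  # 14 * 6250/1000
  expect_true(fiber$target_met)
  low <- assess_nutrient(80, refs[refs$nutrient == "fiber", ], 6250)
  expect_false(low$target_met)
  expect_error(assess_nutrient(80, refs[refs$nutrient == "fiber", ]),
               "energy_kcal_day required")
})

test_that("boundary conventions: inclusive targets, strict upper limits", {
  at_target <- assess_nutrient(100, ref_row(target = 100, ul = 200), 2000)
  expect_true(at_target$target_met)
  at_ul <- assess_nutrient(200, ref_row(target = 100, ul = 200), 2000)
  expect_false(at_ul$ul_exceeded)
  above_ul <- assess_nutrient(200.01, ref_row(target = 100, ul = 200), 2000)
  expect_true(above_ul$ul_exceeded)
  limit_at <- assess_nutrient(10, ref_row(target = 10, type = "DGA_limit"),
                              2000)
  expect_true(limit_at$target_met)
})

test_that("unit mismatches are rejected", {
  expect_error(
    assess_nutrient(5, ref_row(unit = "mg"), 2000, unit = "mcg"),
    "unit mismatch")
})

test_that("verdicts are monotone in intake, against a brute-force comparator", {
  # independent comparator: direction looked up from first principles
  brute <- function(amount, type, target, energy) {
    resolved <- if (type == "DGA_rate") target * energy / 1000 else target
    floor_types <- c(RDA = TRUE, AI = TRUE, DGA_rate = TRUE,
                     DGA_limit = FALSE, CDRR = FALSE)
    if (floor_types[[type]]) amount >= resolved else amount <= resolved
  }
  set.seed(11)
  types <- c("RDA", "AI", "DGA_rate", "DGA_limit", "CDRR")
  for (i in 1:40) {
    type <- sample(types, 1)
    target <- runif(1, 1, 500)
    energy <- runif(1, 1500, 7000)
    amounts <- sort(runif(8, 0, 1500))
    ref <- ref_row(target = target, type = type)
    met <- vapply(amounts, function(a) {
      assess_nutrient(a, ref, energy)$target_met
    }, logical(1))
    expected <- vapply(amounts, brute, logical(1),
                       type = type, target = target, energy = energy)
    expect_equal(met, expected)
    # monotone non-decreasing for floors, non-increasing for ceilings
    if (type %in% c("RDA", "AI", "DGA_rate")) {
      expect_true(all(diff(met) >= 0))
    } else {
      expect_true(all(diff(met) <= 0))
    }
  }
})

test_that("not-determinable upper limits never flag an exceedance", {
  set.seed(3)
  for (a in runif(20, 0, 1e5)) {
    res <- assess_nutrient(a, ref_row(target = 1, ul = NA_real_), 2000)
    expect_false(isTRUE(res$ul_exceeded))
    expect_false(res$ul_applicable)
  }
})

test_that("a scaled diet's verdict column matches the published pattern", {
  fx <- bundled_fixtures()
  dl <- scale_diet(fx$roster[1, ], fx$profile)
  a <- assess_diet(dl, fx$references)
  evaluated <- a[a$evaluated, ]
  expect_equal(nrow(evaluated), nrow(fx$references))
  expect_false(evaluated$target_met[evaluated$nutrient == "sodium"])
  expect_true(all(evaluated$target_met[evaluated$nutrient != "sodium"]))
  # diet nutrients without a reference pass through flagged
  protein_row <- a[a$nutrient == "protein", ]
  expect_false(protein_row$evaluated)
  expect_true(is.na(protein_row$target_met))
})

test_that("missing diet nutrients yield explicit not-evaluated records", {
  fx <- bundled_fixtures()
  tiny <- density_profile(tibble::tibble(
    nutrient = "calcium", amount = 1156, unit = "mg",
    basis = "per_reference_energy"))
  diet <- scale_diet(player_profile("x", 100, energy_kcal_day = 6250), tiny)
  a <- assess_diet(diet, fx$references)
  expect_equal(nrow(a), nrow(fx$references))
  expect_true(a$evaluated[a$nutrient == "calcium"])
  expect_false(any(a$evaluated[a$nutrient != "calcium"]))
})

test_that("an empty reference list yields an empty assessment", {
  fx <- bundled_fixtures()
  diet <- scale_diet(fx$roster[1, ], fx$profile)
  a <- assess_diet(diet, nutrient_reference(tibble::tibble(
    nutrient = character(), target_value = numeric(),
    target_type = character(), ul_value = numeric(), unit = character(),
    caveat = character())))
  expect_equal(nrow(a), 0)
})

test_that("quarterback phosphorus stays within the UL while others exceed it", {
  fx <- bundled_fixtures()
  diets <- scale_roster(fx$roster, fx$profile)
  assessments <- lapply(diets, assess_diet, references = fx$references)
  phos <- vapply(assessments, function(a) {
    a$ul_exceeded[a$nutrient == "phosphorus"]
  }, logical(1))
  expect_false(phos[["Quarterback"]])
  expect_true(all(phos[names(phos) != "Quarterback"]))
})

test_that("the exceedance summary groups nutrients with min-max ranges", {
  fx <- bundled_fixtures()
  diets <- scale_roster(fx$roster, fx$profile)
  assessments <- lapply(diets, assess_diet, references = fx$references)
  summ <- ul_exceedance_summary(assessments)
  folate <- summ[summ$nutrient == "folate", ]
  expect_equal(folate$n_positions_exceeding, 6L)
  expect_equal(folate$min_amount, 2353)
  expect_equal(folate$max_amount, 2819)
  phos <- summ[summ$nutrient == "phosphorus", ]
  expect_equal(phos$n_positions_exceeding, 5L)
  expect_false(grepl("Quarterback", phos$positions))
  expect_equal(c(phos$min_amount, phos$max_amount), c(4010, 4353))
})

test_that("a position with no exceedances yields an empty summary", {
  refs <- ref_row("calcium", target = 1, ul = 1e9, unit = "mg")
  diet <- scale_diet(player_profile("x", 100, energy_kcal_day = 2500),
                     density_profile(tibble::tibble(
                       nutrient = "calcium", amount = 1156, unit = "mg",
                       basis = "per_reference_energy")))
  summ <- ul_exceedance_summary(list(x = assess_diet(diet, refs)))
  expect_equal(nrow(summ), 0)
  expect_error(ul_exceedance_summary(list()), "at least one")
})
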