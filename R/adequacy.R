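#' Assess one nutrient against its reference
#'
#' Direction-aware comparison of a scaled intake against its Dietary
#' Reference Intake target and tolerable upper level (UL):
#' * `RDA`, `AI`, `DGA_rate` targets are floors — met when the intake is
#'   greater than or equal to the (resolved) target;
#' * `DGA_limit`, `CDRR` targets are ceilings — met when the intake is
#'   less than or equal to the target;
#' * `DGA_rate` targets are energy-indexed (g per 1000 kcal) and are
#'   resolved at the diet's energy level before comparison;
#' * the UL is exceeded only on a strict `>` comparison; a not-determinable
#'   (ND, i.e. `NA`) UL is never exceeded (`ul_exceeded` is `NA`).
#'
#' Boundary conventions are inclusive for targets (an intake exactly at an
#' adequacy target counts as met) and strict for ULs, so an intake exactly
#' at the UL does not count as exceeding.
#'
#' @param scaled_amount Intake in the reference's unit.
#' @param reference A one-row [nutrient_reference()] table.
#' @param energy_kcal_day Diet energy, kcal/day; required to resolve
#'   `DGA_rate` targets.
#' @param unit Optional unit of `scaled_amount`; when given it must match
#'   the reference unit.
#' @return A one-row tibble with columns `nutrient`, `scaled_amount`,
#'   `unit`, `target_value_resolved`, `target_type`, `target_met`,
#'   `ul_value`, `ul_applicable`, `ul_exceeded`, `caveat`.
#' @export
#' @examples
#' refs <- dri_reference_table()
#' assess_nutrient(11034, refs[refs$nutrient == "sodium", ], 6250)
assess_nutrient <- function(scaled_amount, reference, energy_kcal_day,
                            unit = NULL) {
  reference <- nutrient_reference(reference)
  if (nrow(reference) != 1) {
    abort_invalid("assess_nutrient() expects a single reference row")
  }
  if (!is.null(unit) && !identical(unit, reference$unit)) {
    abort_invalid("unit mismatch for %s: intake in '%s', reference in '%s'",
                  reference$nutrient, unit, reference$unit)
  }
  type <- reference$target_type
  target <- reference$target_value
  if (type == "DGA_rate") {
    if (missing(energy_kcal_day) || !is.finite(energy_kcal_day)) {
      abort_invalid("energy_kcal_day required to resolve a DGA_rate target")
    }
    target <- fiber_target(energy_kcal_day, reference$target_value)
  }
  met <- if (type %in% c("RDA", "AI", "DGA_rate")) {
    scaled_amount >= target
  } else if (type %in% c("DGA_limit", "CDRR")) {
    scaled_amount <= target
  } else {
    abort_invalid("unknown target_type '%s'", type)  # unreachable post-validation
  }
  ul_applicable <- !is.na(reference$ul_value)
  tibble::tibble(
    nutrient = reference$nutrient,
    scaled_amount = scaled_amount,
    unit = reference$unit,
    target_value_resolved = target,
    target_type = type,
    target_met = met,
    ul_value = reference$ul_value,
    ul_applicable = ul_applicable,
    ul_exceeded = if (ul_applicable) scaled_amount > reference$ul_value else NA,
    caveat = reference$caveat
  )
}

#' Assess a scaled diet against a reference table
#'
#' One assessment per reference row, in reference-table order. Reference
#' nutrients absent from the diet yield explicit `evaluated = FALSE`
#' records; diet nutrients without a reference are appended unassessed with
#' the same flag.
#'
#' @param diet A [scale_diet()] result.
#' @param references A [nutrient_reference()] table.
#' @return A tibble of assessments with an `evaluated` flag column.
#' @export
#' @examples
#' fx <- bundled_fixtures()
#' assess_diet(scale_diet(fx$roster[1, ], fx$profile), fx$references)
assess_diet <- function(diet, references) {
  stopifnot(inherits(diet, "scaled_diet"))
  references <- nutrient_reference(references)
  if (nrow(references) == 0) {
    return(empty_assessment())
  }
  rows <- lapply(seq_len(nrow(references)), function(i) {
    ref <- references[i, ]
    j <- match(ref$nutrient, diet$nutrients$nutrient)
    if (is.na(j)) {
      out <- not_evaluated_row(ref$nutrient, NA_real_, ref$unit, ref$caveat)
      out$target_type <- ref$target_type
      return(out)
    }
    out <- assess_nutrient(diet$nutrients$amount[j], ref,
                           energy_kcal_day = diet$energy_kcal_day,
                           unit = diet$nutrients$unit[j])
    out$evaluated <- TRUE
    out
  })
  extra <- setdiff(diet$nutrients$nutrient, references$nutrient)
  for (nut in extra) {
    j <- match(nut, diet$nutrients$nutrient)
    rows <- c(rows, list(not_evaluated_row(
      nut, diet$nutrients$amount[j], diet$nutrients$unit[j],
      "no reference for this nutrient")))
  }
  dplyr::bind_rows(rows)
}

empty_assessment <- function() {
  tibble::tibble(
    nutrient = character(), scaled_amount = numeric(), unit = character(),
    target_value_resolved = numeric(), target_type = character(),
    target_met = logical(), ul_value = numeric(), ul_applicable = logical(),
    ul_exceeded = logical(), caveat = character(), evaluated = logical())
}

not_evaluated_row <- function(nutrient, amount, unit, caveat) {
  tibble::tibble(
    nutrient = nutrient, scaled_amount = amount, unit = unit,
    target_value_resolved = NA_real_, target_type = NA_character_,
    target_met = NA, ul_value = NA_real_, ul_applicable = FALSE,
    ul_exceeded = NA, caveat = caveat, evaluated = FALSE)
}

#' Upper-limit exceedance summary across positions
#'
#' Groups nutrients by their exceedance pattern over a set of per-position
#' assessments. A nutrient counts as exceeding for a position when its
#' numeric UL is strictly exceeded, or — for ceiling-type targets (CDRR,
#' DGA_limit) whose UL is not determinable — when the ceiling itself is
#' exceeded. The second clause makes the summary treat the sodium CDRR as
#' the operative limit, matching how limit nutrients are conventionally
#' tallied alongside UL exceedances.
#'
#' @param assessments A named list, position label -> [assess_diet()] tibble.
#' @return A tibble with one row per flagged nutrient: `nutrient`,
#'   `n_positions_exceeding`, `positions` (comma-separated), `min_amount`
#'   and `max_amount` (display-rounded scaled intakes over the exceeding
#'   positions), and `limit` (the operative numeric limit).
#' @export
ul_exceedance_summary <- function(assessments) {
  if (length(assessments) == 0) {
    abort_invalid("at least one position's assessments are required")
  }
  if (is.null(names(assessments)) || any(!nzchar(names(assessments)))) {
    abort_invalid("assessments must be a named list keyed by position")
  }
  per_pos <- lapply(names(assessments), function(pos) {
    a <- assessments[[pos]]
    flag <- (a$ul_applicable & !is.na(a$ul_exceeded) & a$ul_exceeded) |
      (!a$ul_applicable & !is.na(a$target_met) & !a$target_met &
         a$target_type %in% c("CDRR", "DGA_limit"))
    limit <- ifelse(a$ul_applicable, a$ul_value, a$target_value_resolved)
    tibble::tibble(position = pos, nutrient = a$nutrient,
                   amount = a$scaled_amount, limit = limit, flag = flag)
  })
  all <- dplyr::bind_rows(per_pos)
  flagged <- all[all$flag, , drop = FALSE]
  if (nrow(flagged) == 0) {
    return(tibble::tibble(nutrient = character(),
                          n_positions_exceeding = integer(),
                          positions = character(),
                          min_amount = numeric(), max_amount = numeric(),
                          limit = numeric()))
  }
  out <- flagged |>
    dplyr::group_by(.data$nutrient) |>
    dplyr::summarise(
      n_positions_exceeding = dplyr::n(),
      positions = paste(.data$position, collapse = ", "),
      min_amount = min(.data$amount),
      max_amount = max(.data$amount),
      limit = .data$limit[1],
      .groups = "drop"
    )
  out$min_amount <- display_round(out$nutrient, out$min_amount)
  out$max_amount <- display_round(out$nutrient, out$max_amount)
  # keep first-appearance nutrient order, not alphabetical
  out[match(unique(flagged$nutrient), out$nutrient), , drop = FALSE]
}
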