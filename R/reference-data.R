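#' Construct an athlete profile
#'
#' One athlete (or position archetype) with the determinants of their daily
#' energy requirement. Energy must be computable one way or the other: either
#' a fixed `energy_kcal_day` override is given, or both `body_fat_fraction`
#' and `activity_factor` are present so the Cunningham path can be used
#' (see [energy_requirement()]).
#'
#' @param position Free-text position label.
#' @param body_mass_kg Body mass in kg, strictly positive.
#' @param body_fat_fraction Body fat as a proportion in `[0, 1)`, or `NA`.
#' @param activity_factor Dimensionless activity multiplier `>= 1`, or `NA`.
#' @param energy_kcal_day Fixed daily energy requirement in kcal, or `NA`.
#' @param protein_override_g_day Optional fixed absolute protein provision in
#'   g/day used by table-reproduction mode (see [scale_diet()]); `NA` to
#'   compute protein from the energy fraction.
#' @return A one-row tibble with class `player_profile` prepended.
#' @export
#' @examples
#' player_profile("Defensive Lineman", 134.7, energy_kcal_day = 6250)
player_profile <- function(position, body_mass_kg,
                           body_fat_fraction = NA_real_,
                           activity_factor = NA_real_,
                           energy_kcal_day = NA_real_,
                           protein_override_g_day = NA_real_) {
  p <- tibble::tibble(
    position = as.character(position),
    body_mass_kg = as.numeric(body_mass_kg),
    body_fat_fraction = as.numeric(body_fat_fraction),
    activity_factor = as.numeric(activity_factor),
    energy_kcal_day = as.numeric(energy_kcal_day),
    protein_override_g_day = as.numeric(protein_override_g_day)
  )
  validate_roster(p)
}

#' Validate a roster of athlete profiles
#'
#' Enforces the profile invariants: positive body mass; body-fat fraction in
#' `[0, 1)` when present; activity factor `>= 1` when present; and an energy
#' requirement that is computable either from a fixed override or from the
#' body-fat fraction plus activity factor.
#'
#' @param roster A data frame with (at least) the columns of
#'   [player_profile()].
#' @return The validated roster as a tibble, invisibly classed
#'   `player_profile`.
#' @export
validate_roster <- function(roster) {
  roster <- tibble::as_tibble(roster)
  required <- c("position", "body_mass_kg")
  missing <- setdiff(required, names(roster))
  if (length(missing) > 0) {
    abort_invalid("roster is missing required column(s): %s",
                  paste(missing, collapse = ", "))
  }
  for (col in c("body_fat_fraction", "activity_factor", "energy_kcal_day",
                "protein_override_g_day")) {
    if (!col %in% names(roster)) roster[[col]] <- NA_real_
  }
  problems <- roster_problems(roster)
  if (length(problems) > 0) {
    abort_invalid("invalid roster:\n%s", paste(problems, collapse = "\n"))
  }
  class(roster) <- unique(c("player_profile", class(roster)))
  roster
}

# Per-row invariant diagnostics; returns character vector (empty when valid).
roster_problems <- function(roster) {
  problems <- character(0)
  for (i in seq_len(nrow(roster))) {
    row <- roster[i, ]
    tag <- sprintf("row %d (%s)", i,
                   ifelse(is.na(row$position), "?", row$position))
    if (is.na(row$body_mass_kg)) {
      problems <- c(problems, sprintf("%s: body_mass_kg is missing", tag))
    } else if (row$body_mass_kg <= 0) {
      problems <- c(problems,
                    sprintf("%s: body_mass_kg must be > 0 (got %g)",
                            tag, row$body_mass_kg))
    }
    if (!is.na(row$body_fat_fraction) &&
        (row$body_fat_fraction < 0 || row$body_fat_fraction >= 1)) {
      problems <- c(problems,
                    sprintf("%s: body_fat_fraction must be in [0, 1) (got %g)",
                            tag, row$body_fat_fraction))
    }
    if (!is.na(row$activity_factor) && row$activity_factor < 1) {
      problems <- c(problems,
                    sprintf("%s: activity_factor must be >= 1 (got %g)",
                            tag, row$activity_factor))
    }
    if (!is.na(row$energy_kcal_day) && row$energy_kcal_day <= 0) {
      problems <- c(problems,
                    sprintf("%s: energy_kcal_day must be > 0 (got %g)",
                            tag, row$energy_kcal_day))
    }
    if (is.na(row$energy_kcal_day) &&
        (is.na(row$body_fat_fraction) || is.na(row$activity_factor))) {
      problems <- c(problems, sprintf(
        "%s: energy is not computable: supply energy_kcal_day or both body_fat_fraction and activity_factor",
        tag))
    }
  }
  problems
}

#' Read an athlete roster from CSV
#'
#' Column headers are matched case- and punctuation-insensitively
#' (`"Body Mass (kg)"` resolves to `body_mass_kg`). Rows violating a profile
#' invariant are rejected with a diagnostic naming the row and invariant;
#' valid rows are returned in file order.
#'
#' @param path Path to a CSV file with columns `position`, `body_mass_kg`
#'   and optionally `body_fat_fraction`, `activity_factor`,
#'   `energy_kcal_day`, `protein_override_g_day`.
#' @param quiet If `FALSE` (default), rejected rows raise a warning.
#' @return A validated roster tibble. Rejected-row diagnostics are attached
#'   as attribute `"rejected"`.
#' @export
read_roster <- function(path, quiet = FALSE) {
  if (!file.exists(path)) abort_invalid("roster file not found: %s", path)
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  cols <- c(position = "position", body_mass_kg = "body_mass_kg",
            body_fat_fraction = "body_fat_fraction",
            activity_factor = "activity_factor",
            energy_kcal_day = "energy_kcal_day",
            protein_override_g_day = "protein_override_g_day")
  out <- tibble::tibble(.rows = nrow(raw))
  for (std in names(cols)) {
    actual <- resolve_column(names(raw), cols[[std]])
    if (std %in% c("position", "body_mass_kg") && is.na(actual)) {
      abort_invalid("roster file %s lacks a resolvable '%s' column",
                    path, std)
    }
    if (is.na(actual)) {
      out[[std]] <- NA_real_
    } else if (std == "position") {
      out[[std]] <- as.character(raw[[actual]])
    } else {
      v <- raw[[actual]]
      num <- suppressWarnings(as.numeric(v))
      bad <- which(!is.na(v) & is.na(num) & trimws(as.character(v)) != "")
      if (length(bad) > 0) {
        abort_invalid("roster file %s: non-numeric '%s' in row(s) %s",
                      path, std, paste(bad, collapse = ", "))
      }
      out[[std]] <- num
    }
  }
  problems <- roster_problems(out)
  if (length(problems) > 0) {
    bad_rows <- unique(as.integer(sub("^row (\\d+).*", "\\1", problems)))
    if (!quiet) {
      warning(sprintf("rejected %d roster row(s):\n%s",
                      length(bad_rows), paste(problems, collapse = "\n")),
              call. = FALSE)
    }
    out <- out[-bad_rows, , drop = FALSE]
  }
  out <- validate_roster(out)
  attr(out, "rejected") <- if (length(problems) > 0) problems else character(0)
  out
}

#' Write an athlete roster to CSV
#'
#' Inverse of [read_roster()]: writing then reading reproduces every field
#' to full stored precision.
#'
#' @param roster A validated roster.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_roster <- function(roster, path) {
  roster <- validate_roster(roster)
  readr::write_csv(tibble::as_tibble(unclass_roster(roster)), path)
  invisible(path)
}

unclass_roster <- function(roster) {
  class(roster) <- setdiff(class(roster), "player_profile")
  roster
}

#' @export
print.player_profile <- function(x, ...) {
  cat(sprintf("<roster of %d athlete profile(s)>\n", nrow(x)))
  NextMethod()
}

#' Construct a nutrient-density profile
#'
#' A cohort's nutrient intake expressed per fixed reference energy (the
#' substrate of the scaling model). Each entry carries a basis:
#' `per_reference_energy` amounts scale proportionally with energy, while
#' `percent_of_energy` amounts (e.g. saturated fat as % kcal, the protein
#' energy fraction) are scale-invariant.
#'
#' @param entries A data frame with columns `nutrient`, `amount`, `unit`,
#'   `basis`. Nutrient names are canonicalized via
#'   [normalize_nutrient_id()].
#' @param reference_energy_kcal Reference energy in kcal (default 2000).
#' @param provenance_note Free-text provenance annotation.
#' @return An object of class `density_profile`.
#' @export
#' @examples
#' density_profile(
#'   data.frame(nutrient = "calcium", amount = 1156, unit = "mg",
#'              basis = "per_reference_energy")
#' )
density_profile <- function(entries, reference_energy_kcal = 2000,
                            provenance_note = "") {
  entries <- tibble::as_tibble(entries)
  needed <- c("nutrient", "amount", "unit", "basis")
  missing <- setdiff(needed, names(entries))
  if (length(missing) > 0) {
    abort_invalid("density profile entries lack column(s): %s",
                  paste(missing, collapse = ", "))
  }
  entries$nutrient <- normalize_nutrient_id(entries$nutrient)
  entries$amount <- as.numeric(entries$amount)
  entries$basis <- as.character(entries$basis)
  obj <- structure(
    list(reference_energy_kcal = as.numeric(reference_energy_kcal),
         entries = entries[, needed],
         provenance_note = as.character(provenance_note)),
    class = "density_profile")
  validate_density_profile(obj)
}

#' Validate a nutrient-density profile
#'
#' @param profile A `density_profile`.
#' @return The profile, if valid; otherwise an error naming the violated
#'   invariant (and the offending nutrient where applicable).
#' @export
validate_density_profile <- function(profile) {
  if (!inherits(profile, "density_profile")) {
    abort_invalid("not a density_profile object")
  }
  if (!is.finite(profile$reference_energy_kcal) ||
      profile$reference_energy_kcal <= 0) {
    abort_invalid("reference_energy_kcal must be > 0")
  }
  e <- profile$entries
  dup <- e$nutrient[duplicated(e$nutrient)]
  if (length(dup) > 0) {
    abort_invalid("duplicate nutrient entries: %s",
                  paste(unique(dup), collapse = ", "))
  }
  bad_basis <- setdiff(unique(e$basis),
                       c("per_reference_energy", "percent_of_energy"))
  if (length(bad_basis) > 0) {
    abort_invalid("unknown basis value(s): %s",
                  paste(bad_basis, collapse = ", "))
  }
  if (any(is.na(e$amount) | e$amount < 0)) {
    bad <- e$nutrient[is.na(e$amount) | e$amount < 0]
    abort_invalid("negative or missing amount for: %s",
                  paste(bad, collapse = ", "))
  }
  pct <- e$basis == "percent_of_energy"
  if (any(e$amount[pct] > 100)) {
    abort_invalid("percent_of_energy amounts must be <= 100")
  }
  profile
}

#' @export
print.density_profile <- function(x, ...) {
  cat(sprintf("<density profile: %d nutrient(s) per %g kcal>\n",
              nrow(x$entries), x$reference_energy_kcal))
  if (nzchar(x$provenance_note)) cat(" ", x$provenance_note, "\n")
  print(x$entries, ...)
  invisible(x)
}

#' Read a nutrient-density profile from JSON or YAML
#'
#' Accepts the canonical serialization
#' `{reference_energy_kcal, provenance_note, entries: [{nutrient, amount,
#' unit, basis}, ...]}`. Format is chosen by file extension (`.json`,
#' `.yaml`/`.yml`).
#'
#' @param path Path to a JSON or YAML profile.
#' @return A validated `density_profile`.
#' @export
read_density_profile <- function(path) {
  if (!file.exists(path)) abort_invalid("profile file not found: %s", path)
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    json = jsonlite::fromJSON(path, simplifyDataFrame = TRUE),
    yaml = ,
    yml  = yaml::read_yaml(path),
    abort_invalid("unsupported profile format '.%s' (use JSON or YAML)", ext))
  entries <- raw$entries
  if (is.list(entries) && !is.data.frame(entries)) {
    entries <- dplyr::bind_rows(lapply(entries, tibble::as_tibble))
  }
  density_profile(
    entries,
    reference_energy_kcal = raw$reference_energy_kcal %||% 2000,
    provenance_note = raw$provenance_note %||% ""
  )
}

#' Write a nutrient-density profile to JSON or YAML
#'
#' @param profile A `density_profile`.
#' @param path Output path; extension selects the format.
#' @return `path`, invisibly.
#' @export
write_density_profile <- function(profile, path) {
  profile <- validate_density_profile(profile)
  payload <- list(
    reference_energy_kcal = profile$reference_energy_kcal,
    provenance_note = profile$provenance_note,
    entries = profile$entries
  )
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else if (ext %in% c("yaml", "yml")) {
    payload$entries <- lapply(seq_len(nrow(profile$entries)), function(i) {
      as.list(profile$entries[i, ])
    })
    yaml::write_yaml(payload, path)
  } else {
    abort_invalid("unsupported profile format '.%s' (use JSON or YAML)", ext)
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Construct a nutrient reference table
#'
#' Dietary Reference Intake targets and tolerable upper intake levels (UL).
#' The target type determines the comparison direction during adequacy
#' screening: `RDA`, `AI` and `DGA_rate` are floors (intake should meet or
#' exceed), `DGA_limit` and `CDRR` are ceilings (intake should not exceed).
#' `DGA_rate` targets are energy-indexed (g per 1000 kcal, e.g. fiber) and
#' are resolved at the diet's energy level before comparison. A missing
#' (`NA`) UL means "not determinable" (ND).
#'
#' @param refs A data frame with columns `nutrient`, `target_value`,
#'   `target_type`, `ul_value`, `unit`, `caveat`.
#' @return A tibble classed `nutrient_reference`.
#' @export
nutrient_reference <- function(refs) {
  refs <- tibble::as_tibble(refs)
  needed <- c("nutrient", "target_value", "target_type", "ul_value",
              "unit", "caveat")
  missing <- setdiff(needed, names(refs))
  if (length(missing) > 0) {
    abort_invalid("reference table lacks column(s): %s",
                  paste(missing, collapse = ", "))
  }
  refs$nutrient <- normalize_nutrient_id(refs$nutrient)
  refs$target_value <- as.numeric(refs$target_value)
  refs$ul_value <- suppressWarnings(as.numeric(refs$ul_value))
  refs$caveat[is.na(refs$caveat)] <- ""
  allowed <- c("RDA", "AI", "DGA_limit", "DGA_rate", "CDRR")
  bad <- setdiff(unique(refs$target_type), allowed)
  if (length(bad) > 0) {
    abort_invalid("unknown target_type value(s): %s",
                  paste(bad, collapse = ", "))
  }
  if (any(is.na(refs$target_value) | refs$target_value <= 0)) {
    abort_invalid("target_value must be > 0 for every nutrient")
  }
  if (any(!is.na(refs$ul_value) & refs$ul_value <= 0)) {
    abort_invalid("ul_value, when present, must be > 0")
  }
  if (any(duplicated(refs$nutrient))) {
    abort_invalid("duplicate reference rows: %s",
                  paste(unique(refs$nutrient[duplicated(refs$nutrient)]),
                        collapse = ", "))
  }
  refs <- refs[, needed]
  class(refs) <- unique(c("nutrient_reference", class(refs)))
  refs
}

#' Read a nutrient reference table from CSV
#'
#' @param path CSV with columns `nutrient,target_value,target_type,ul_value,
#'   unit,caveat`; `ul_value` of `ND` (or empty) means not determinable.
#' @return A validated `nutrient_reference` tibble.
#' @export
read_reference_table <- function(path) {
  if (!file.exists(path)) abort_invalid("reference file not found: %s", path)
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(.default = "c"))
  std <- c("nutrient", "target_value", "target_type", "ul_value", "unit",
           "caveat")
  out <- tibble::tibble(.rows = nrow(raw))
  for (s in std) {
    actual <- resolve_column(names(raw), s)
    if (is.na(actual)) abort_invalid("reference file lacks column '%s'", s)
    out[[s]] <- raw[[actual]]
  }
  out$ul_value[toupper(trimws(out$ul_value)) %in% c("ND", "")] <- NA
  nutrient_reference(out)
}

#' Write a nutrient reference table to CSV
#'
#' @param refs A `nutrient_reference` table.
#' @param path Output CSV path. `NA` ULs are serialized as `ND`.
#' @return `path`, invisibly.
#' @export
write_reference_table <- function(refs, path) {
  refs <- nutrient_reference(refs)
  out <- tibble::as_tibble(refs)
  out$ul_value <- ifelse(is.na(out$ul_value), "ND",
                         format(out$ul_value, trim = TRUE, scientific = FALSE))
  class(out) <- setdiff(class(out), "nutrient_reference")
  readr::write_csv(out, path)
  invisible(path)
}

#' Construct a food protein composition table
#'
#' Leucine content of protein sources, as a proportion of total protein, by
#' food category (animal, dairy, plant). Used to derive category means and
#' standard errors for leucine modeling (see [mean_fraction_with_sem()]).
#'
#' @param foods Data frame with columns `food_name`, `category`,
#'   `leucine_fraction_of_protein`.
#' @return A tibble classed `food_protein_composition`.
#' @export
food_protein_composition <- function(foods) {
  foods <- tibble::as_tibble(foods)
  needed <- c("food_name", "category", "leucine_fraction_of_protein")
  missing <- setdiff(needed, names(foods))
  if (length(missing) > 0) {
    abort_invalid("food table lacks column(s): %s",
                  paste(missing, collapse = ", "))
  }
  bad_cat <- setdiff(unique(foods$category), c("animal", "dairy", "plant"))
  if (length(bad_cat) > 0) {
    abort_invalid("category must be one of animal/dairy/plant (got: %s)",
                  paste(bad_cat, collapse = ", "))
  }
  f <- as.numeric(foods$leucine_fraction_of_protein)
  if (any(is.na(f) | f <= 0 | f >= 1)) {
    abort_invalid("leucine_fraction_of_protein must lie in (0, 1)")
  }
  foods$leucine_fraction_of_protein <- f
  foods <- foods[, needed]
  class(foods) <- unique(c("food_protein_composition", class(foods)))
  foods
}
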