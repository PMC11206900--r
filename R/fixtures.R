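#' Path to a bundled data file
#'
#' @param file File name under the package's `extdata` directory; with no
#'   argument, lists the available files.
#' @return Absolute path (or a vector of file names).
#' @export
dietscale_extdata <- function(file = NULL) {
  if (is.null(file)) {
    return(list.files(system.file("extdata", package = "dietscale")))
  }
  path <- system.file("extdata", file, package = "dietscale")
  if (path == "") abort_invalid("no bundled file '%s'", file)
  path
}

#' Bundled professional American-football roster
#'
#' Six position archetypes (defensive lineman, offensive lineman, running
#' back, tight end, linebacker, quarterback) with published mean body masses
#' and daily energy requirements. Energies come pre-computed from a report
#' on NFL athletes (Cunningham equation with unpublished anthropometrics),
#' so each row carries a fixed energy override rather than body-fat and
#' activity inputs. The linebacker and quarterback rows additionally carry
#' the published absolute-protein overrides used by table-reproduction mode
#' (see [scale_diet()] for why these two rows differ from the
#' energy-fraction procedure).
#'
#' @return A validated roster tibble of six profiles.
#' @export
#' @examples
#' nfl_roster()
nfl_roster <- function() {
  read_roster(dietscale_extdata("nfl_roster.csv"), quiet = TRUE)
}

#' Bundled plant-based cohort nutrient-density profile
#'
#' Mean nutrient intakes per 2000 kcal/day of the completely plant-based
#' (vegan) stratum of the Adventist Health Study 2 cohort, the scaling
#' substrate. Saturated fat and protein are stored as percent of energy
#' (scale-invariant); all other entries are per-reference-energy densities.
#' Fiber is stored at the cohort mean of 46.7 g/2000 kcal rather than the
#' display-rounded 47. Iron, zinc and linoleic acid are stored at display
#' precision because their unrounded densities were never published; scaled
#' values for these three nutrients may differ by about 1 unit-in-the-last-
#' place from published position tables.
#'
#' @return A validated `density_profile`.
#' @export
#' @examples
#' ahs2_density_profile()
ahs2_density_profile <- function() {
  read_density_profile(dietscale_extdata("ahs2_density_profile.json"))
}

#' Bundled Dietary Reference Intake table
#'
#' Targets (RDA/AI/DGA/CDRR, values for men aged 19-30) and tolerable upper
#' intake levels for the nutrients covered by the bundled density profile,
#' with applicability caveats carried as annotations: the folate UL applies
#' only to synthetic forms, the magnesium UL only to pharmacological
#' sources, and the vitamin A UL (established only for preformed vitamin A)
#' is set to ND for a plant-sourced profile. Fiber is an energy-indexed
#' `DGA_rate` target of 14 g per 1000 kcal.
#'
#' @return A validated `nutrient_reference` tibble.
#' @export
#' @examples
#' dri_reference_table()
dri_reference_table <- function() {
  read_reference_table(dietscale_extdata("dri_references.csv"))
}

#' All bundled fixtures
#'
#' @return A list with elements `roster`, `profile`, `references` — the
#'   bundled six-position roster, plant-based cohort density profile, and
#'   DRI reference table.
#' @export
bundled_fixtures <- function() {
  list(
    roster = nfl_roster(),
    profile = ahs2_density_profile(),
    references = dri_reference_table()
  )
}
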