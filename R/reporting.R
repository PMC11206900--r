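#' Run the full diet-scaling pipeline
#'
#' For every athlete in the roster: resolve the energy requirement, scale
#' the density profile to it, derive protein and leucine provisions, and
#' screen the scaled diet against the reference table. Produces a
#' protein/leucine report (one row per athlete), a nutrient report (one row
#' per nutrient, one column per athlete, with the adequacy verdict), and an
#' upper-limit exceedance summary.
#'
#' @param roster Roster tibble, path to a roster CSV, or `NULL` for the
#'   bundled six-position roster.
#' @param profile `density_profile`, path to a JSON/YAML profile, or `NULL`
#'   for the bundled cohort profile.
#' @param references `nutrient_reference` table, path to a reference CSV,
#'   or `NULL` for the bundled DRI table.
#' @param params [model_parameters()] or a path to a JSON/YAML parameter
#'   file.
#' @param reproduce_tables Honor per-player absolute-protein overrides
#'   (table-reproduction mode, see [scale_diet()]). Default `FALSE`
#'   (procedure-faithful).
#' @param out_dir Optional output directory; reports are written there in
#'   each requested format.
#' @param formats Subset of `c("csv", "json", "markdown")`.
#' @return A list of class `dietscale_report`: `table1` (protein/leucine by
#'   athlete, display-rounded), `table2` (nutrients by athlete,
#'   display-rounded, with verdicts), `ul_summary`, `assessments` (named
#'   list of unrounded per-athlete assessment tibbles), and `diets` (the
#'   unrounded `scaled_diet` objects).
#' @export
#' @examples
#' rep <- run_pipeline(reproduce_tables = TRUE)
#' rep$table1
run_pipeline <- function(roster = NULL, profile = NULL, references = NULL,
                         params = model_parameters(),
                         reproduce_tables = FALSE,
                         out_dir = NULL,
                         formats = "csv") {
  roster <- if (is.null(roster)) nfl_roster()
            else if (is.character(roster)) read_roster(roster)
            else validate_roster(roster)
  profile <- if (is.null(profile)) ahs2_density_profile()
             else if (is.character(profile)) read_density_profile(profile)
             else validate_density_profile(profile)
  references <- if (is.null(references)) dri_reference_table()
                else if (is.character(references)) read_reference_table(references)
                else nutrient_reference(references)
  if (is.character(params)) params <- read_model_parameters(params)
  stopifnot(inherits(params, "model_parameters"))
  bad_fmt <- setdiff(formats, c("csv", "json", "markdown"))
  if (length(bad_fmt) > 0) {
    abort_invalid("unknown format(s): %s", paste(bad_fmt, collapse = ", "))
  }

  diets <- scale_roster(roster, profile, params,
                        use_protein_override = reproduce_tables)
  assessments <- lapply(diets, assess_diet, references = references)

  report <- structure(list(
    table1 = build_table1(diets),
    table2 = build_table2(diets, assessments, profile),
    ul_summary = if (length(diets) > 0) ul_exceedance_summary(assessments)
                 else NULL,
    assessments = assessments,
    diets = diets,
    params = params
  ), class = "dietscale_report")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (fmt in formats) {
      ext <- c(csv = "csv", json = "json", markdown = "md")[[fmt]]
      for (nm in c("table1", "table2", "ul_summary")) {
        tab <- report[[nm]]
        if (is.null(tab)) next
        writeLines(render_table(tab, fmt),
                   file.path(out_dir, sprintf("%s.%s", nm, ext)))
      }
    }
  }
  report
}

# Protein/leucine report, display-rounded to table precision.
build_table1 <- function(diets) {
  if (length(diets) == 0) {
    return(tibble::tibble(
      position = character(), body_mass_kg = numeric(),
      energy_kcal_day = numeric(), protein_requirement_g_day = numeric(),
      protein_g_day = numeric(), protein_g_per_kg_day = numeric(),
      leucine_g_day = numeric(), leucine_g_per_meal = numeric()))
  }
  dplyr::bind_rows(lapply(diets, function(d) {
    tibble::tibble(
      position = d$position,
      body_mass_kg = d$body_mass_kg,
      energy_kcal_day = round_half_up(d$energy_kcal_day),
      protein_requirement_g_day = round_half_up(d$protein_requirement_g_day),
      protein_g_day = round_half_up(d$protein_g_day),
      protein_g_per_kg_day = round_half_up(d$protein_g_per_kg_day, 1),
      leucine_g_day = round_half_up(d$leucine_g_day, 1),
      leucine_g_per_meal = round_half_up(d$leucine_g_per_meal, 1)
    )
  }))
}

# Nutrient report: density column, one scaled column per athlete,
# reference columns and the aggregated verdict.
build_table2 <- function(diets, assessments, profile) {
  e <- profile$entries
  out <- tibble::tibble(
    nutrient = e$nutrient,
    unit = e$unit,
    density = display_round(e$nutrient, e$amount, e$basis)
  )
  for (i in seq_along(diets)) {
    d <- diets[[i]]
    amounts <- d$nutrients$amount[match(e$nutrient, d$nutrients$nutrient)]
    out[[d$position]] <- display_round(e$nutrient, amounts, e$basis)
  }
  if (length(assessments) > 0) {
    first <- assessments[[1]]
    j <- match(out$nutrient, first$nutrient)
    out$ul_value <- first$ul_value[j]
    out$target_value <- first$target_value_resolved[j]
    out$target_type <- first$target_type[j]
    met_mat <- vapply(assessments, function(a) {
      a$target_met[match(out$nutrient, a$nutrient)]
    }, logical(nrow(out)))
    met_mat <- matrix(met_mat, nrow = nrow(out))
    out$target_met <- apply(met_mat, 1, function(v) {
      if (all(is.na(v))) NA else all(v[!is.na(v)])
    })
  } else {
    out$ul_value <- NA_real_
    out$target_value <- NA_real_
    out$target_type <- NA_character_
    out$target_met <- NA
  }
  out
}

#' Render a report table to text
#'
#' @param report A tibble from [run_pipeline()] (`table1`, `table2` or
#'   `ul_summary`).
#' @param format `"markdown"`, `"csv"` or `"json"`. CSV output round-trips
#'   through [readr::read_csv()]; JSON deep-equals the in-memory tibble on
#'   re-parse; markdown is a pipe table in column order.
#' @return A character scalar (the rendered artifact).
#' @export
render_table <- function(report, format = c("markdown", "csv", "json")) {
  if (is.null(report)) abort_invalid("report is NULL")
  format <- match.arg(format)
  df <- tibble::as_tibble(report)
  switch(format,
    csv = readr::format_csv(df),
    json = as.character(
      jsonlite::toJSON(df, dataframe = "rows", auto_unbox = FALSE,
                       digits = NA, na = "null", pretty = TRUE)),
    markdown = render_markdown(df))
}

render_markdown <- function(df) {
  fmt_cell <- function(x) {
    if (is.numeric(x)) {
      ifelse(is.na(x), "", vapply(x, function(v) format(v, scientific = FALSE),
                                  character(1)))
    } else if (is.logical(x)) {
      ifelse(is.na(x), "", ifelse(x, "yes", "no"))
    } else {
      ifelse(is.na(x), "", as.character(x))
    }
  }
  cells <- vapply(df, fmt_cell, character(nrow(df)))
  cells <- matrix(cells, nrow = nrow(df),
                  dimnames = list(NULL, names(df)))
  widths <- pmax(nchar(names(df)),
                 if (nrow(df) > 0) apply(nchar(cells), 2, max) else 0)
  pad <- function(v, w) formatC(v, width = w, flag = "-")
  header <- paste0("| ", paste(mapply(pad, names(df), widths),
                               collapse = " | "), " |")
  rule <- paste0("|", paste(vapply(widths + 2, function(w) {
    strrep("-", w)
  }, character(1)), collapse = "|"), "|")
  body <- vapply(seq_len(nrow(df)), function(i) {
    paste0("| ", paste(mapply(pad, cells[i, ], widths), collapse = " | "),
           " |")
  }, character(1))
  paste(c(header, rule, body), collapse = "\n")
}

#' @export
print.dietscale_report <- function(x, ...) {
  cat(sprintf("<diet-scaling report: %d athlete(s), %d nutrient(s)>\n",
              nrow(x$table1), nrow(x$table2)))
  cat("\nProtein and leucine provision:\n")
  print(x$table1)
  if (!is.null(x$ul_summary) && nrow(x$ul_summary) > 0) {
    cat("\nUpper-limit exceedances:\n")
    print(x$ul_summary)
  }
  invisible(x)
}
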