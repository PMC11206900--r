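#' Round half away from zero
#'
#' Commercial ("half-up") rounding, as used in printed nutrition tables.
#' Differs from [base::round()], which rounds half to even (banker's
#' rounding): `round(0.5)` is 0 but `round_half_up(0.5)` is 1.
#'
#' A guard of `sqrt(.Machine$double.eps)` absorbs binary representation
#' error so that values that are exact halves in decimal (e.g. `6.35` at one
#' decimal place) round upward as a human would round them.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 0).
#' @return `x` rounded to `digits` places, halves away from zero.
#' @export
#' @examples
#' round_half_up(0.5)        # 1
#' round_half_up(2.5)        # 3, where round(2.5) == 2
#' round_half_up(6.35, 1)    # 6.4
round_half_up <- function(x, digits = 0) {
  stopifnot(is.numeric(x), is.numeric(digits), length(digits) == 1)
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5 + sqrt(.Machine$double.eps)) / scale
}

# Decimal places used when displaying a nutrient amount, keyed by nutrient id.
# Nutrients reported to one decimal in the source tables; everything else is
# shown as an integer. Percent-of-energy entries are always one decimal.
.display_digits_map <- c(
  total_omega_3 = 1,
  vitamin_b6    = 1,
  vitamin_b12   = 1,
  saturated_fat = 1
)

#' Display rounding for a nutrient amount
#'
#' Internal computations are kept at full floating precision; rounding is a
#' reporting concern only. Amounts are rounded half-up to the precision
#' conventional for each nutrient: one decimal for total omega-3 fatty
#' acids, vitamins B6 and B12, and percent-of-energy entries; integers for
#' everything else (kcal, g, mg, mcg, IU, RAE).
#'
#' @param nutrient Character vector of nutrient ids (see
#'   [normalize_nutrient_id()]).
#' @param amount Numeric vector of amounts, recycled against `nutrient`.
#' @param basis Optional basis vector; `"percent_of_energy"` entries are
#'   rounded to one decimal regardless of nutrient id.
#' @return Rounded numeric vector.
#' @export
display_round <- function(nutrient, amount, basis = NULL) {
  digits <- unname(.display_digits_map[nutrient])
  digits[is.na(digits)] <- 0
  if (!is.null(basis)) {
    digits[basis == "percent_of_energy"] <- 1
  }
  mapply(round_half_up, amount, digits, USE.NAMES = FALSE)
}

#' Canonical nutrient identifier
#'
#' Nutrient identity is a controlled lowercase token: case is folded,
#' whitespace and punctuation collapse to underscores ("Vitamin B12" ->
#' "vitamin_b12", "Total omega-3 (g)" -> "total_omega_3_g" is avoided by
#' stripping parenthesised unit suffixes first).
#'
#' @param x Character vector of nutrient names.
#' @return Character vector of canonical ids.
#' @export
#' @examples
#' normalize_nutrient_id(c("Vitamin B12", "total omega-3", "FOLATE"))
normalize_nutrient_id <- function(x) {
  x <- tolower(trimws(as.character(x)))
  x <- gsub("\\s*\\([^)]*\\)", "", x)   # drop unit suffixes like "(mg)"
  x <- gsub("[^a-z0-9]+", "_", x)
  gsub("^_+|_+$", "", x)
}

# Case/space-insensitive header resolution for tabular readers. Returns the
# actual column name in `names` matching `wanted`, or NA.
resolve_column <- function(names, wanted) {
  canon <- function(v) gsub("[^a-z0-9]", "", tolower(v))
  hit <- match(canon(wanted), canon(names))
  if (is.na(hit)) NA_character_ else names[hit]
}

# Stop with a consistent error class so callers can distinguish validation
# failures from programming errors.
abort_invalid <- function(msg, ...) {
  stop(sprintf(msg, ...), call. = FALSE)
}
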