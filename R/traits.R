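#' Derive growth and reproduction variables from raw plant records
#'
#' Adds the analysis variables to a per-plant measurement table: plant
#' `area` (cm^2) as the product of maximum height and maximum diameter (a
#' proxy for the ground area a plant occupies), `summed_repro` as the total
#' of bud, flower and fruit counts, and `repro_per_area` as the
#' area-standardized reproductive output `summed_repro / area`. Rows whose
#' reproduction columns are missing (e.g. sedges, whose phenophases cannot
#' be distinguished) get `NA` in the reproduction-derived columns.
#'
#' Rows with non-positive or missing height/diameter fail row-level
#' validation: they are excluded from the result, logged via a message,
#' and returned in the `excluded` attribute with a reason column.
#'
#' @param records A tibble of plant records with at least `species`,
#'   `height_cm`, `diameter_cm` and (optionally) `buds`, `flowers`,
#'   `fruits` columns.
#' @return The trait table: input rows (minus exclusions) plus `area`,
#'   `summed_repro`, `repro_per_area`. Attribute `excluded` is a tibble of
#'   dropped rows with a `reason` column.
#' @export
#' @examples
#' tbl <- tibble::tibble(species = "sp", height_cm = 10, diameter_cm = 20,
#'                       buds = 2L, flowers = 1L, fruits = 1L)
#' derive_traits(tbl)[, c("area", "summed_repro", "repro_per_area")]
derive_traits <- function(records) {
  required <- c("species", "height_cm", "diameter_cm")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols) > 0) {
    abort(paste0("records are missing columns: ",
                 paste(missing_cols, collapse = ", ")),
          class = "trampler_trait_error")
  }
  for (col in c("buds", "flowers", "fruits")) {
    if (!col %in% names(records)) records[[col]] <- NA_integer_
  }
  bad <- !is.finite(records$height_cm) | !is.finite(records$diameter_cm) |
    records$height_cm <= 0 | records$diameter_cm <= 0
  excluded <- records[bad, , drop = FALSE]
  if (nrow(excluded) > 0) {
    excluded$reason <- ifelse(
      !is.finite(excluded$height_cm) | excluded$height_cm <= 0,
      "non-positive or missing height", "non-positive or missing diameter")
    inform(sprintf("derive_traits: excluded %d row(s) with non-positive size",
                   nrow(excluded)))
  }
  out <- records[!bad, , drop = FALSE]
  out$area <- out$height_cm * out$diameter_cm
  out$summed_repro <- out$buds + out$flowers + out$fruits
  out$repro_per_area <- out$summed_repro / out$area
  out <- tibble::as_tibble(out)
  attr(out, "excluded") <- tibble::as_tibble(excluded)
  out
}

#' Relative reproductive output per species
#'
#' Divides each plant's area-standardized reproductive output by its
#' species' maximum (the individual with the highest output over all
#' transects), yielding `relative_repro` in [0, 1] with the species maximum
#' at exactly 1. Species in which no plant reproduced (all-zero or all-`NA`
#' output) get `relative_repro = 0` and are listed in the
#' `non_informative_species` attribute rather than raising an error: they
#' carry no information for a Beta model of reproduction.
#'
#' @param table A trait table from [derive_traits()].
#' @return The table with a `relative_repro` column; attribute
#'   `non_informative_species` names species with no nonzero output.
#' @export
relative_reproduction <- function(table) {
  if (nrow(table) == 0L) {
    abort("empty trait table", class = "trampler_trait_error")
  }
  if (!"repro_per_area" %in% names(table)) {
    abort("run derive_traits() first (no repro_per_area column)",
          class = "trampler_trait_error")
  }
  sp_max <- tapply(table$repro_per_area, table$species,
                   function(x) if (all(is.na(x))) NA_real_ else
                     max(x, na.rm = TRUE))
  mx <- as.numeric(sp_max[table$species])
  rel <- ifelse(is.na(mx) | mx <= 0, 0, table$repro_per_area / mx)
  rel[is.na(table$repro_per_area) & !is.na(mx) & mx > 0] <- NA_real_
  table$relative_repro <- rel
  flagged <- names(sp_max)[is.na(sp_max) | sp_max <= 0]
  if (length(flagged) > 0) {
    inform(paste0("relative_reproduction: no nonzero output for: ",
                  paste(flagged, collapse = ", ")))
  }
  attr(table, "non_informative_species") <- flagged
  table
}

#' Round size measurements to integers for the negative binomial family
#'
#' Nearest-integer rounding with ties (x.5) rounded half away from zero,
#' as needed to treat continuous centimetre measurements as count-family
#' responses. Idempotent; negative input is an error.
#'
#' @param values Non-negative numeric vector (cm).
#' @return An integer vector.
#' @export
#' @examples
#' round_for_nb(c(12.3, 12.5, 0.4)) # 12, 13, 0
round_for_nb <- function(values) {
  if (!is.numeric(values)) {
    abort("`values` must be numeric", class = "trampler_trait_error")
  }
  if (any(!is.finite(values)) || any(values < 0)) {
    abort("`values` must be finite and non-negative",
          class = "trampler_trait_error")
  }
  as.integer(floor(values + 0.5))
}

#' Nudge unit-interval data strictly inside (0, 1)
#'
#' The Beta likelihood is undefined at exactly 0 and 1; exact zeros become
#' `eps` and exact ones become `1 - eps` (default `eps = 0.0001`), leaving
#' interior values untouched.
#'
#' @param values Numeric vector in [0, 1].
#' @param eps Adjustment size (default 1e-4).
#' @return The adjusted vector, strictly inside (0, 1).
#' @export
#' @examples
#' adjust_unit_interval(c(0, 0.5, 1)) # 0.0001, 0.5, 0.9999
adjust_unit_interval <- function(values, eps = 0.0001) {
  if (!is.numeric(values) || any(!is.finite(values)) ||
      any(values < 0 | values > 1)) {
    abort("`values` must lie in [0, 1]", class = "trampler_trait_error")
  }
  if (!is.numeric(eps) || eps <= 0 || eps >= 0.5) {
    abort("`eps` must be in (0, 0.5)", class = "trampler_trait_error")
  }
  values[values == 0] <- eps
  values[values == 1] <- 1 - eps
  values
}

#' Randomly select up to k individuals from one quadrat
#'
#' Mirrors the field protocol of selecting five individuals per focal
#' species per quadrat with a random number generator: if there are at most
#' `k` candidates all are kept, otherwise a seeded uniform sample without
#' replacement of size `k` is taken.
#'
#' @param candidates A tibble of plant records from a single
#'   (quadrat, species) combination.
#' @param k Maximum number to keep (default 5).
#' @param seed Integer seed.
#' @return A tibble with `min(nrow(candidates), k)` rows.
#' @export
select_individuals <- function(candidates, k = 5, seed) {
  stopifnot_scalar_count(k, "k")
  if (nrow(candidates) <= k) return(candidates)
  idx <- with_seed(seed, sort(sample.int(nrow(candidates), k)))
  candidates[idx, , drop = FALSE]
}
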