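## Carbon accounting: crop carbon sequestration (desired output) and
## agricultural carbon emissions (undesired output), plus the auxiliary
## indicator constructions used when assembling the DEA input/output system.

.crop_table_defaults <- data.frame(
  crop = c("rice", "wheat", "corn", "beans", "canola", "peanut", "sunflower",
           "cotton", "potato", "sugar_cane", "sugar_beets", "vegetables",
           "melon", "tobacco", "other_crops"),
  economic_coeff = c(0.45, 0.40, 0.40, 0.34, 0.25, 0.43, 0.30, 0.10, 0.70,
                     0.50, 0.70, 0.60, 0.70, 0.55, 0.40),
  water_content  = c(0.12, 0.12, 0.13, 0.13, 0.10, 0.10, 0.10, 0.08, 0.70,
                     0.50, 0.75, 0.90, 0.90, 0.85, 0.12),
  uptake_rate    = c(0.414, 0.485, 0.471, 0.450, 0.450, 0.450, 0.450, 0.450,
                     0.423, 0.450, 0.407, 0.450, 0.450, 0.450, 0.450),
  stringsAsFactors = FALSE
)

.emission_table_defaults <- data.frame(
  source      = c("pesticide", "fertilizer", "diesel", "film",
                  "irrigation", "tillage"),
  coefficient = c(4.9341, 0.8956, 0.5927, 5.18, 266.48, 312.6),
  unit        = c("kg/kg", "kg/kg", "kg/kg", "kg/kg", "kg/hm2", "kg/hm2"),
  unit_class  = c("mass", "mass", "mass", "mass", "area", "area"),
  stringsAsFactors = FALSE
)

#' Crop carbon-uptake coefficient table
#'
#' The fifteen major crop types with their economic coefficient (harvest
#' index, HI), water content r and carbon uptake rate cs. Per-crop carbon
#' sequestration is `(1 - r) * cs * y / HI` (or `* HI` under the multiplying
#' convention), where y is economic yield in tons.
#'
#' @param file optional path to a CSV with columns `crop`, `economic_coeff`,
#'   `water_content`, `uptake_rate`; defaults to the table shipped with the
#'   package.
#' @return data.frame with one row per crop.
#' @export
#' @examples
#' head(crop_coefficients())
crop_coefficients <- function(file = NULL) {
  if (is.null(file))
    file <- system.file("extdata", "crop_carbon_coefficients.csv",
                        package = "agrecoeff")
  tab <- utils::read.csv(file, stringsAsFactors = FALSE)
  need <- c("crop", "economic_coeff", "water_content", "uptake_rate")
  assert_that(all(need %in% names(tab)),
              paste("coefficient file must have columns:",
                    paste(need, collapse = ", ")))
  assert_that(all(tab$water_content >= 0 & tab$water_content < 1),
              "water content must lie in [0, 1)")
  assert_that(all(tab$economic_coeff > 0 & tab$economic_coeff <= 1),
              "economic coefficient must lie in (0, 1]")
  assert_that(all(tab$uptake_rate > 0), "uptake rate must be positive")
  tab
}

#' Agricultural carbon-emission coefficient table
#'
#' The six emission sources with their coefficients: pesticide, fertilizer,
#' diesel and film in kg C per kg applied; irrigation and tillage in kg C per
#' hectare (hm2).
#'
#' @param file optional path to a CSV with columns `source`, `coefficient`,
#'   `unit`, `unit_class`; defaults to the shipped table.
#' @return data.frame with one row per source.
#' @export
#' @examples
#' emission_coefficients()
emission_coefficients <- function(file = NULL) {
  if (is.null(file))
    file <- system.file("extdata", "emission_coefficients.csv",
                        package = "agrecoeff")
  tab <- utils::read.csv(file, stringsAsFactors = FALSE)
  need <- c("source", "coefficient", "unit", "unit_class")
  assert_that(all(need %in% names(tab)),
              paste("coefficient file must have columns:",
                    paste(need, collapse = ", ")))
  assert_that(all(tab$coefficient > 0), "emission coefficients must be positive")
  assert_that(all(tab$unit_class %in% c("mass", "area")),
              "unit_class must be 'mass' or 'area'")
  tab
}

#' Crop carbon sequestration (CSA)
#'
#' Total carbon uptake of a set of crop records,
#' `CSA = sum_i (1 - r_i) * cs_i * y_i / HI_i` by default (the economic-yield
#' to biomass conversion divides by the harvest index), or with `* HI_i`
#' under `hi_mode = "multiply"`.
#'
#' @param crops data.frame with columns `crop` and `yield` (tons); the
#'   coefficient columns `economic_coeff`, `water_content`, `uptake_rate` are
#'   looked up from `coefficients` when absent.
#' @param hi_mode `"divide"` (default) or `"multiply"`: how the economic
#'   coefficient HI enters.
#' @param coefficients coefficient table, see [crop_coefficients()].
#' @return total sequestration in tons (nonnegative scalar).
#' @export
#' @examples
#' carbon_sequestration(data.frame(crop = "rice", yield = 1))
carbon_sequestration <- function(crops,
                                 hi_mode = c("divide", "multiply"),
                                 coefficients = crop_coefficients()) {
  hi_mode <- match.arg(hi_mode)
  if (is.null(crops) || nrow(crops) == 0L) return(0)
  assert_that(all(c("crop", "yield") %in% names(crops)),
              "crops needs columns 'crop' and 'yield'")
  assert_that(all(is.finite(crops$yield)) && all(crops$yield >= 0),
              "yields must be nonnegative")
  have <- c("economic_coeff", "water_content", "uptake_rate") %in% names(crops)
  if (!all(have)) {
    idx <- match(crops$crop, coefficients$crop)
    if (anyNA(idx))
      stop_agrecoeff(paste("no coefficients for crop(s):",
                           paste(unique(crops$crop[is.na(idx)]), collapse = ", ")),
                     "agrecoeff_lookup_error")
    crops$economic_coeff <- coefficients$economic_coeff[idx]
    crops$water_content <- coefficients$water_content[idx]
    crops$uptake_rate <- coefficients$uptake_rate[idx]
  }
  assert_that(all(crops$water_content < 1), "water content must be < 1")
  assert_that(all(crops$uptake_rate > 0), "uptake rate must be positive")
  if (hi_mode == "divide") {
    if (any(crops$economic_coeff == 0))
      stop_agrecoeff("economic coefficient of 0 is not valid in divide mode",
                     "agrecoeff_domain_error")
    sum((1 - crops$water_content) * crops$uptake_rate * crops$yield /
          crops$economic_coeff)
  } else {
    sum((1 - crops$water_content) * crops$uptake_rate * crops$yield *
          crops$economic_coeff)
  }
}

#' Agricultural carbon emission (CE)
#'
#' Sums `beta_i * A_i` over emission activities and converts the kg aggregate
#' to tons. Mass-class sources (pesticide, fertilizer, diesel, film) expect
#' activity in kg; area-class sources (irrigation, tillage) expect hectares.
#'
#' @param activities data.frame with columns `source` and `activity`; a
#'   `coefficient` column overrides the table lookup.
#' @param coefficients coefficient table, see [emission_coefficients()].
#' @param as_tons convert the kg total to tons (default TRUE).
#' @return total emission (tons when `as_tons`, else kg).
#' @export
#' @examples
#' carbon_emission(data.frame(source = "pesticide", activity = 1000))
carbon_emission <- function(activities,
                            coefficients = emission_coefficients(),
                            as_tons = TRUE) {
  if (is.null(activities) || nrow(activities) == 0L) return(0)
  assert_that(all(c("source", "activity") %in% names(activities)),
              "activities needs columns 'source' and 'activity'")
  assert_that(all(is.finite(activities$activity)),
              "activity levels must be finite")
  assert_that(all(activities$activity >= 0),
              "activity levels must be nonnegative")
  if (!"coefficient" %in% names(activities)) {
    idx <- match(activities$source, coefficients$source)
    if (anyNA(idx))
      stop_agrecoeff(paste("no coefficient for source(s):",
                           paste(unique(activities$source[is.na(idx)]),
                                 collapse = ", ")),
                     "agrecoeff_lookup_error")
    activities$coefficient <- coefficients$coefficient[idx]
  }
  assert_that(all(activities$coefficient > 0),
              "emission coefficients must be positive")
  kg <- sum(activities$coefficient * activities$activity)
  if (as_tons) kg / 1000 else kg
}

#' Impute agricultural labor from primary-industry employment
#'
#' Agricultural employees = primary-industry employment times the share of
#' agricultural output value in total output value of agriculture, forestry,
#' animal husbandry and fishery.
#'
#' @param primary_employment nonnegative head count.
#' @param agri_output agricultural output value.
#' @param total_afah_output total output value of the agriculture, forestry,
#'   animal husbandry and fishery sector (must be positive and at least
#'   `agri_output`).
#' @return imputed labor, bounded above by `primary_employment`.
#' @export
#' @examples
#' impute_labor(100, 50, 100)  # 50
impute_labor <- function(primary_employment, agri_output, total_afah_output) {
  assert_that(all(total_afah_output > 0), "total sector output must be positive")
  assert_that(all(primary_employment >= 0), "employment must be nonnegative")
  assert_that(all(agri_output >= 0), "agricultural output must be nonnegative")
  assert_that(all(agri_output <= total_afah_output),
              "agricultural output share cannot exceed 1")
  primary_employment * (agri_output / total_afah_output)
}

#' Composite chemical input
#'
#' Pesticide use + fertilizer (pure nutrient) + agricultural film, all in
#' tons; the chemical-input proxy on the DEA input side.
#'
#' @param pesticide,fertilizer_pure,film nonnegative masses (tons).
#' @return their sum.
#' @export
chemical_composite <- function(pesticide, fertilizer_pure, film) {
  assert_that(all(c(pesticide, fertilizer_pure, film) >= 0),
              "chemical inputs must be nonnegative")
  pesticide + fertilizer_pure + film
}

#' Non-point-source pollution aggregate
#'
#' Sum of chemical oxygen demand, ammonia nitrogen, total nitrogen and total
#' phosphorus discharges (tons); the pollution proxy on the undesired-output
#' side.
#'
#' @param cod,nh,tn,tp nonnegative component discharges, or a single
#'   data.frame in `cod` with columns `cod`, `nh`, `tn`, `tp`.
#' @return total discharge.
#' @export
nps_pollution <- function(cod, nh = NULL, tn = NULL, tp = NULL) {
  if (is.data.frame(cod)) {
    p <- cod
    assert_that(all(c("cod", "nh", "tn", "tp") %in% names(p)),
                "pollution record needs columns cod, nh, tn, tp")
    cod <- p$cod; nh <- p$nh; tn <- p$tn; tp <- p$tp
  }
  assert_that(all(c(cod, nh, tn, tp) >= 0),
              "pollution components must be nonnegative")
  cod + nh + tn + tp
}
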