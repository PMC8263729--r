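#' Land-use class dictionary
#'
#' The categorical legend used throughout the package: eleven habitat classes
#' (with intrinsic habitat suitability) plus three construction subtypes that
#' carry no habitat value of their own. Six of the fourteen classes also act
#' as degradation threat sources (see [threat_table()]).
#'
#' @return A data.frame with columns `code` (integer raster value), `name`
#'   (snake_case label), `habitat` (logical: has a habitat-suitability row),
#'   and `construction` (logical: counted as built-up land).
#' @seealso [threat_table()], [sensitivity_table()]
#' @export
habitat_classes <- function() {
  data.frame(
    code = 1:14,
    name = c("cropland", "forestland", "bush_forest", "sparse_woodland",
             "other_woodland", "high_grassland", "medium_grassland",
             "low_grassland", "water", "unused_land", "reclamation",
             "city_town", "rural_settlement", "other_construction"),
    habitat = c(rep(TRUE, 11), FALSE, FALSE, FALSE),
    construction = c(rep(FALSE, 11), TRUE, TRUE, TRUE),
    stringsAsFactors = FALSE
  )
}

#' Construction land-use codes
#'
#' @param classes class dictionary, by default [habitat_classes()].
#' @return Integer vector of codes counted as construction (built-up) land.
#' @export
construction_codes <- function(classes = habitat_classes()) {
  classes$code[classes$construction]
}

#' Default threat-factor parameterization
#'
#' The six degradation sources with their maximum effect distance, weight and
#' distance-decay law. `source_codes` lists the land-use codes whose cells
#' emit the threat; the three construction subtypes are treated as disjoint
#' code sets.
#'
#' @return A data.frame with columns `threat`, `d_rmax_km`, `weight`, `decay`
#'   and a list-column `source_codes`.
#' @export
threat_table <- function() {
  tb <- data.frame(
    threat = c("cropland", "city_town", "rural_settlement",
               "other_construction", "unused_land", "reclamation"),
    d_rmax_km = c(5, 9, 6, 2, 1, 2),
    weight = c(0.5, 1.0, 0.6, 1.0, 0.4, 0.3),
    decay = c("exponential", "exponential", "exponential", "exponential",
              "linear", "linear"),
    stringsAsFactors = FALSE
  )
  tb$source_codes <- list(1L, 12L, 13L, 14L, 10L, 11L)
  tb
}

#' Default habitat suitability and sensitivity table
#'
#' Per habitat class: intrinsic suitability `H` in [0, 1] and its sensitivity
#' to each of the six threat sources. Land classes absent from this table
#' (the construction subtypes) default to `H = 0` and zero sensitivity.
#'
#' @return A data.frame with columns `code`, `habitat_type`, `H`, then one
#'   sensitivity column per threat (named as in [threat_table()]).
#' @export
sensitivity_table <- function() {
  data.frame(
    code = 1:11,
    habitat_type = c("cropland", "forestland", "bush_forest",
                     "sparse_woodland", "other_woodland", "high_grassland",
                     "medium_grassland", "low_grassland", "water",
                     "unused_land", "reclamation"),
    H = c(0.4, 1.0, 1.0, 0.8, 0.6, 0.9, 0.8, 0.6, 0.8, 0.4, 0.0),
    cropland           = c(0.0, 0.7, 0.6, 0.7, 0.7, 0.6, 0.6, 0.6, 0.4, 0.3, 0.0),
    city_town          = c(0.8, 0.9, 0.8, 0.8, 0.8, 0.7, 0.7, 0.7, 0.7, 0.5, 0.0),
    rural_settlement   = c(0.6, 0.8, 0.6, 0.7, 0.7, 0.7, 0.7, 0.7, 0.6, 0.4, 0.0),
    other_construction = c(0.7, 0.8, 0.7, 0.8, 0.8, 0.7, 0.7, 0.7, 0.7, 0.5, 0.0),
    unused_land        = c(0.4, 0.5, 0.4, 0.5, 0.4, 0.7, 0.7, 0.7, 0.4, 0.0, 0.0),
    reclamation        = c(0.4, 0.5, 0.4, 0.5, 0.4, 0.7, 0.7, 0.7, 0.4, 0.0, 0.0),
    stringsAsFactors = FALSE
  )
}

#' Aggregate source groups for transition reporting
#'
#' Maps the fourteen detailed codes onto the six aggregate donor groups used
#' when reporting conversions to construction land (cropland, woodland,
#' grassland, water, unused land, sea reclamation) plus construction itself.
#'
#' @return Named character vector indexed by class code.
#' @export
class_groups <- function() {
  cl <- habitat_classes()
  grp <- c("cropland", "woodland", "woodland", "woodland", "woodland",
           "grassland", "grassland", "grassland", "water", "unused_land",
           "reclamation", "construction", "construction", "construction")
  names(grp) <- as.character(cl$code)
  grp
}

#' Published Pearl River Delta reference statistics
#'
#' Reference values reported for the Pearl River Delta (1990--2018) analysis
#' of land conversion to construction land: per donor group the mean per-cell
#' habitat-quality change (HQCI), the transferred area (km^2) and the total
#' contribution index (CI). Used for internal-consistency checks of the
#' HQCI/CI reporting arithmetic (CI / S must round to the printed HQCI).
#'
#' @return A data.frame with columns `source`, `hqci`, `area_km2`, `ci`.
#' @export
transition_reference <- function() {
  data.frame(
    source = c("cropland", "woodland", "grassland", "water",
               "unused_land", "reclamation"),
    hqci = c(-0.12, -0.18, -0.30, -0.18, -0.28, -0.21),
    area_km2 = c(3090.40, 1233.74, 123.71, 690.39, 8.67, 22.01),
    ci = c(-386.02, -216.24, -36.87, -121.87, -2.44, -4.70),
    stringsAsFactors = FALSE
  )
}

#' Published grade-change reference (km^2 per period)
#'
#' Reported habitat-quality grade area changes for the Pearl River Delta over
#' three sub-periods and the full period, per grade I--V. Sub-period rows sum
#' (up to rounding of the printed addends) to the full-period row.
#'
#' @return A data.frame with a `period` column and grade columns I..V.
#' @export
grade_change_reference <- function() {
  data.frame(
    period = c("1990-2000", "2000-2010", "2010-2018", "1990-2018"),
    I = c(1231.45, 2893.47, 786.16, 4911.07),
    II = c(-1467.49, -1794.23, -235.64, -3497.36),
    III = c(96.70, 141.36, -78.49, 159.57),
    IV = c(457.77, -521.39, -372.51, -436.12),
    V = c(-344.96, -598.84, -91.90, -1035.70),
    stringsAsFactors = FALSE
  )
}

#' Published grade-share reference (% per epoch)
#'
#' Reported share of area per habitat-quality grade at each of the four
#' epochs; per-epoch shares sum to 100 within printing precision.
#'
#' @return A data.frame with a `year` column and grade columns I..V.
#' @export
grade_share_reference <- function() {
  data.frame(
    year = c(1990, 2000, 2010, 2018),
    I = c(5.66, 7.96, 13.32, 14.78),
    II = c(29.51, 26.79, 23.40, 22.96),
    III = c(3.07, 3.25, 3.51, 3.36),
    IV = c(12.37, 13.23, 12.23, 11.54),
    V = c(49.38, 48.76, 47.54, 47.36),
    stringsAsFactors = FALSE
  )
}
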