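## Planar grid geometry and area-attribute joins.
##
## Coordinates are metres on a planar national grid (OSGB-style easting /
## northing); distances are straight-line Euclidean, reported in kilometres.
## No spherical geometry: at the spatial scale of a single region the planar
## approximation is standard and matches how open practice/pharmacy
## coordinates are published.

#' Euclidean distance between grid points, in kilometres
#'
#' Distance between points given as planar easting/northing metres:
#' `sqrt((delta northing)^2 + (delta easting)^2) / 1000`. Vectorised over
#' rows; inputs recycle as usual.
#'
#' @param a,b lists or data.frames with numeric `easting` and `northing`
#'   components in metres.
#' @return Numeric vector of distances in km.
#' @export
#' @examples
#' distance_km(list(easting = 0, northing = 0),
#'             list(easting = 3000, northing = 4000)) # 5 km
distance_km <- function(a, b) {
  pick <- function(p, f) {
    v <- p[[f]]
    if (is.null(v)) stop_(sprintf("missing numeric '%s'", f))
    as.numeric(v)
  }
  de <- pick(a, "easting") - pick(b, "easting")
  dn <- pick(a, "northing") - pick(b, "northing")
  if (!all(is.finite(de)) || !all(is.finite(dn))) {
    stop_("non-finite coordinate in distance_km()")
  }
  sqrt(de^2 + dn^2) / 1000
}

#' Load a location-code to grid-point lookup
#'
#' Reads (or validates) a table mapping opaque location codes to planar
#' coordinates. This stands in for postcode geocoding: coordinates are
#' supplied, never derived.
#'
#' @param table path to a CSV with columns
#'   `location_code,easting_m,northing_m`, or an equivalent data.frame.
#' @return A `data.table` keyed by `location_code` with columns
#'   `location_code`, `easting_m`, `northing_m`.
#' @export
load_coordinate_lookup <- function(table) {
  dt <- if (is.character(table)) {
    fread(table, colClasses = list(character = "location_code"))
  } else {
    as.data.table(table)
  }
  dt <- as_table(dt, c("location_code", "easting_m", "northing_m"),
                 "coordinate lookup")
  dup <- dt$location_code[duplicated(dt$location_code)]
  if (length(dup)) {
    stop_(sprintf("duplicate location code(s) in lookup: %s",
                  paste(unique(dup), collapse = ", ")))
  }
  bad <- which(!is.finite(dt$easting_m) | !is.finite(dt$northing_m) |
                 dt$easting_m < 0 | dt$northing_m < 0)
  if (length(bad)) {
    stop_(sprintf("unparseable or negative coordinate at row(s): %s",
                  paste(bad, collapse = ", ")))
  }
  setkey(dt, location_code)
  dt[]
}

## Resolve codes against a lookup, erroring with the offending codes.
lookup_points <- function(lookup, codes, what = "location") {
  idx <- match(codes, lookup$location_code)
  if (anyNA(idx)) {
    stop_(sprintf("unmatched %s code(s): %s", what,
                  paste(unique(codes[is.na(idx)]), collapse = ", ")))
  }
  list(easting = lookup$easting_m[idx], northing = lookup$northing_m[idx])
}

#' Attach area attributes (population density, deprivation rank) to practices
#'
#' Strict left join of a practice table onto an area-attribute table by
#' location code. With `strict = TRUE` (default) any unmatched practice code
#' aborts the run, naming every unmatched code: silently dropping practices
#' would corrupt the per-patient normalisation downstream. With
#' `strict = FALSE` unmatched rows are dropped with a warning.
#'
#' @param practices data.frame with a `location_code` column (plus anything
#'   else, preserved).
#' @param attrs data.frame with columns
#'   `location_code,population_density_km2,deprivation_rank`.
#' @param strict fail on unmatched codes (default) instead of dropping them.
#' @return `practices` with `population_density_km2` and `deprivation_rank`
#'   columns appended; row order preserved.
#' @export
attach_area_attributes <- function(practices, attrs, strict = TRUE) {
  practices <- as_table(practices, "location_code", "practice table")
  attrs <- as_table(attrs,
                    c("location_code", "population_density_km2",
                      "deprivation_rank"),
                    "area attributes")
  if (any(attrs$population_density_km2 < 0, na.rm = TRUE)) {
    stop_("negative population density in area attributes")
  }
  idx <- match(practices$location_code, attrs$location_code)
  if (anyNA(idx)) {
    unmatched <- unique(practices$location_code[is.na(idx)])
    msg <- sprintf("practice location code(s) not in area table: %s",
                   paste(unmatched, collapse = ", "))
    if (strict) stop_(msg)
    warning(msg, call. = FALSE)
    practices <- practices[!is.na(idx)]
    idx <- idx[!is.na(idx)]
  }
  out <- copy(practices)
  out[, population_density_km2 := attrs$population_density_km2[idx]]
  out[, deprivation_rank := attrs$deprivation_rank[idx]]
  out[]
}
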