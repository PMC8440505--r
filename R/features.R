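## Practice-level feature derivation over a 12-month window.
##
## Six features describe each practice: the number of distinct dispensing
## pharmacies, annual items per registered patient, the item-weighted median
## and item-weighted SD of the practice-to-pharmacy distance, the local
## population density, and the mean registered list size. Distances are
## weighted by dispensed items because each item proxies one patient journey.

#' Number of distinct pharmacies dispensing for one practice
#'
#' @param records dispensing rows for a single practice
#'   (`practice_id,pharmacy_id,year_month,items`).
#' @return Integer count of distinct `pharmacy_id`s; 0 (with a warning) for
#'   an empty record set.
#' @export
unique_pharmacy_count <- function(records) {
  records <- as_table(records, c("practice_id", "pharmacy_id"), "records")
  if (uniqueN(records$practice_id) > 1L) {
    stop_("records span more than one practice")
  }
  if (nrow(records) == 0L) {
    warning("no dispensing records: pharmacy count is 0", call. = FALSE)
    return(0L)
  }
  uniqueN(records$pharmacy_id)
}

#' Annualised items per registered patient for one practice
#'
#' Total items dispensed over the window divided by the mean monthly
#' registered-patient count over the same window. Quarterly list sizes are
#' expected pre-expanded to monthly rows (each quarterly figure repeated for
#' its three months).
#'
#' @param records dispensing rows for one practice within the window.
#' @param sizes monthly list-size rows
#'   (`practice_id,year_month,registered_patients`) for the same practice.
#' @return Items per patient per window (per year for a 12-month window).
#' @export
annual_items_per_patient <- function(records, sizes) {
  records <- as_table(records, c("practice_id", "items"), "records")
  sizes <- as_table(sizes, c("practice_id", "registered_patients"), "sizes")
  if (nrow(sizes) == 0L) stop_("no registered-patient data for practice")
  if (any(sizes$registered_patients <= 0)) {
    stop_("registered_patients must be positive")
  }
  sum(records$items) / mean(sizes$registered_patients)
}

#' Weighted median via multiset expansion semantics
#'
#' Equals the ordinary median of the multiset formed by repeating each value
#' by its (positive integer) weight, including the mean-of-two-central-values
#' rule for even total weight.
#'
#' @param values numeric vector
#' @param weights positive integer weights, same length
#' @return The weighted median.
#' @export
weighted_median <- function(values, weights) {
  w <- check_weights(values, weights)
  ord <- order(values)
  v <- values[ord]; w <- w[ord]
  total <- sum(w)
  cw <- cumsum(w)
  lo_pos <- (total + total %% 2) / 2        # ceiling(total/2)
  hi_pos <- lo_pos + (1 - total %% 2)       # lo for odd, lo+1 for even
  lo <- v[which(cw >= lo_pos)[1L]]
  hi <- v[which(cw >= hi_pos)[1L]]
  (lo + hi) / 2
}

#' Weighted (population) standard deviation via multiset expansion
#'
#' Population SD of the expanded multiset: `sqrt(sum(w (x - m)^2) / W)` with
#' `m` the weighted mean and `W` the total weight. Requires total weight
#' `>= 2`.
#'
#' @inheritParams weighted_median
#' @return The weighted population SD.
#' @export
weighted_sd <- function(values, weights) {
  w <- check_weights(values, weights)
  total <- sum(w)
  if (total < 2) stop_("total weight must be >= 2")
  m <- sum(w * values) / total
  sqrt(sum(w * (values - m)^2) / total)
}

check_weights <- function(values, weights) {
  if (length(values) == 0L) stop_("empty input")
  if (length(values) != length(weights)) stop_("values/weights length mismatch")
  if (any(!is.finite(values))) stop_("non-finite values")
  if (any(weights < 1) || any(weights != round(weights))) {
    stop_("weights must be positive integers")
  }
  as.numeric(weights)
}

#' Item-weighted distance profile of one practice
#'
#' Computes the practice-to-pharmacy distance for every dispensing record's
#' pharmacy and returns the item-weighted median and item-weighted population
#' SD. Each dispensed item counts as one journey.
#'
#' @param records dispensing rows for one practice.
#' @param practice_pt list with `easting`/`northing` (metres) for the practice.
#' @param pharmacy_lookup coordinate lookup (see [load_coordinate_lookup()])
#'   resolving every `pharmacy_id`.
#' @return Named numeric vector `c(median_distance_km, sd_distance_km)`.
#' @export
distance_profile <- function(records, practice_pt, pharmacy_lookup) {
  records <- as_table(records, c("pharmacy_id", "items"), "records")
  per_pharm <- records[, .(items = sum(items)), by = pharmacy_id]
  if (sum(per_pharm$items) == 0) stop_("all item counts are zero")
  per_pharm <- per_pharm[items > 0]
  pts <- lookup_points(pharmacy_lookup, per_pharm$pharmacy_id, "pharmacy")
  d <- distance_km(pts, practice_pt)
  c(median_distance_km = weighted_median(d, per_pharm$items),
    sd_distance_km = weighted_sd(d, per_pharm$items))
}

#' Mean pairwise distance among the pharmacies serving one practice
#'
#' Unweighted mean of the Euclidean distance over all unordered pairs of a
#' practice's distinct pharmacies: a proxy for the spread of the practice's
#' catchment. Undefined (NA) for fewer than two pharmacies.
#'
#' @param points data.frame/list with `easting` and `northing` in metres,
#'   one row per distinct pharmacy.
#' @return Mean pairwise distance in km, or `NA_real_` if `< 2` points.
#' @export
pharmacy_dispersion <- function(points) {
  xy <- cbind(points$easting, points$northing)
  if (is.null(xy) || nrow(xy) < 2L) return(NA_real_)
  if (!all(is.finite(xy))) stop_("non-finite pharmacy coordinate")
  mean(dist(xy)) / 1000
}

#' Per-practice pharmacy dispersion from a dispensing table
#'
#' @param dispensing dispensing table
#'   (`practice_id,pharmacy_id,year_month,items`).
#' @param coords coordinate lookup resolving every pharmacy.
#' @return data.table `practice_id, dispersion_km` (NA for single-pharmacy
#'   practices).
#' @export
practice_dispersion <- function(dispensing, coords) {
  dispensing <- as_table(dispensing, c("practice_id", "pharmacy_id"),
                         "dispensing")
  pharm <- unique(dispensing[, .(practice_id, pharmacy_id)])
  pharm[, {
    pts <- lookup_points(coords, pharmacy_id, "pharmacy")
    .(dispersion_km = pharmacy_dispersion(pts))
  }, by = practice_id]
}

#' Summarise pharmacy dispersion by cluster
#'
#' @param labels data.frame `practice_id,label` assigning each practice to a
#'   cluster.
#' @param dispersion data.frame `practice_id,dispersion_km` as returned by
#'   [practice_dispersion()].
#' @return data.table with per-cluster `mean_km`, `sd_km` (sample SD across
#'   practices, NA for singletons), `n`, and `n_missing` (practices without a
#'   defined dispersion).
#' @export
cluster_dispersion_summary <- function(labels, dispersion) {
  labels <- as_table(labels, c("practice_id", "label"), "labels")
  dispersion <- as_table(dispersion, c("practice_id", "dispersion_km"),
                         "dispersion")
  dt <- merge(labels, dispersion, by = "practice_id")
  if (nrow(dt) < nrow(labels)) stop_("practice without a dispersion row")
  out <- dt[, {
    v <- dispersion_km[!is.na(dispersion_km)]
    if (length(v) == 0L) stop_(sprintf("cluster '%s' has no valid dispersion",
                                       label[1L]))
    .(mean_km = mean(v),
      sd_km = if (length(v) >= 2L) sd(v) else NA_real_,
      n = length(v),
      n_missing = sum(is.na(dispersion_km)))
  }, by = label]
  setorder(out, label)[]
}

#' Build the six-feature profile table for every eligible practice
#'
#' Collates dispensing, list-size, coordinate, and area tables into one row
#' per practice over a 12-month window. Practices are retained only when they
#' have dispensing activity in every one of the 12 window months, mirroring
#' the exclusion of practices that opened or closed mid-period.
#'
#' @param dispensing dispensing table
#'   (`practice_id,pharmacy_id,year_month,items`).
#' @param sizes monthly list sizes (`practice_id,year_month,registered_patients`).
#' @param coords coordinate lookup covering every practice and pharmacy.
#' @param areas area attributes (`location_code,population_density_km2,
#'   deprivation_rank`), with practice IDs as location codes.
#' @param window the 12-month window: either 12 consecutive `"YYYY-MM"`
#'   strings or a single start month.
#' @return data.table with `practice_id` plus the six columns of
#'   [feature_names()], one row per retained practice.
#' @export
build_practice_profiles <- function(dispensing, sizes, coords, areas, window) {
  window <- resolve_window(window)
  dispensing <- as_table(dispensing,
                         c("practice_id", "pharmacy_id", "year_month", "items"),
                         "dispensing")
  sizes <- as_table(sizes,
                    c("practice_id", "year_month", "registered_patients"),
                    "sizes")
  if (any(dispensing$items < 0)) stop_("negative item count in dispensing")

  dispensing <- dispensing[year_month %in% window]
  sizes <- sizes[year_month %in% window]

  months_present <- dispensing[, .(n_months = uniqueN(year_month)),
                               by = practice_id]
  keep <- months_present[n_months == 12L, practice_id]
  dropped <- setdiff(months_present$practice_id, keep)
  message(sprintf("retained %d practices present in all 12 months (%d dropped)",
                  length(keep), length(dropped)))
  if (length(keep) == 0L) stop_("no practice present in all 12 window months")
  dispensing <- dispensing[practice_id %in% keep]
  sizes <- sizes[practice_id %in% keep]

  no_size <- setdiff(keep, unique(sizes$practice_id))
  if (length(no_size)) {
    stop_(sprintf("practice(s) without list-size data: %s",
                  paste(no_size, collapse = ", ")))
  }

  size_stats <- sizes[, .(registered_patients = mean(registered_patients)),
                      by = practice_id]

  profiles <- dispensing[, {
    ppt <- lookup_points(coords, practice_id[1L], "practice")
    prof <- distance_profile(.SD, ppt, coords)
    .(n_pharmacies = uniqueN(pharmacy_id),
      total_items = sum(items),
      median_distance_km = prof[["median_distance_km"]],
      sd_distance_km = prof[["sd_distance_km"]])
  }, by = practice_id]

  profiles <- merge(profiles, size_stats, by = "practice_id")
  profiles[, items_per_patient := total_items / registered_patients]
  profiles[, total_items := NULL]

  enriched <- attach_area_attributes(
    profiles[, .(location_code = practice_id)], areas, strict = TRUE)
  profiles[, population_density := enriched$population_density_km2]

  setcolorder(profiles, c("practice_id", feature_names()))
  setorder(profiles, practice_id)[]
}
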