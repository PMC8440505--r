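## Readers for the five analysis input tables. All are UTF-8 CSVs with a
## header; identifier columns are read as character.

read_checked <- function(path, required, what, id_cols) {
  if (!file.exists(path)) stop_(sprintf("input file not found: %s", path))
  dt <- fread(path, colClasses = setNames(rep("character", length(id_cols)),
                                          id_cols))
  as_table(dt, required, what)
}

#' Read a dispensing table (`practice_id,pharmacy_id,year_month,items`)
#' @param path CSV path.
#' @return data.table.
#' @export
read_dispensing <- function(path) {
  dt <- read_checked(path, c("practice_id", "pharmacy_id", "year_month",
                             "items"),
                     "dispensing", c("practice_id", "pharmacy_id"))
  check_ym(dt$year_month)
  if (any(dt$items < 0)) stop_("negative item count in dispensing")
  dt
}

#' Read a prescribing table
#' (`practice_id,year_month,bnf_chapter,bnf_section,items`); empty
#' chapter/section fields become NA and take the chapter-99 exclusion path.
#' @param path CSV path.
#' @return data.table.
#' @export
read_prescribing <- function(path) {
  dt <- read_checked(path, c("practice_id", "year_month", "bnf_chapter",
                             "bnf_section", "items"),
                     "prescribing", "practice_id")
  check_ym(dt$year_month)
  dt[, bnf_chapter := as.integer(bnf_chapter)]
  dt[, bnf_section := as.integer(bnf_section)]
  if (any(dt$items < 0)) stop_("negative item count in prescribing")
  dt
}

#' Read a monthly practice-size table
#' (`practice_id,year_month,registered_patients`)
#' @param path CSV path.
#' @return data.table.
#' @export
read_practice_sizes <- function(path) {
  dt <- read_checked(path, c("practice_id", "year_month",
                             "registered_patients"),
                     "practice sizes", "practice_id")
  check_ym(dt$year_month)
  if (any(dt$registered_patients <= 0)) {
    stop_("registered_patients must be positive")
  }
  dt
}

#' Read an area-attribute table
#' (`location_code,population_density_km2,deprivation_rank`)
#' @param path CSV path.
#' @return data.table.
#' @export
read_area_attributes <- function(path) {
  read_checked(path, c("location_code", "population_density_km2",
                       "deprivation_rank"),
               "area attributes", "location_code")
}
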