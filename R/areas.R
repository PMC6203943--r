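#' Spatial stratification scheme for the study region
#'
#' The study region spans the south-east Atlantic and south-west Indian
#' Ocean around southern Africa and is split into four analysis areas:
#' West (cool temperate Benguela-influenced waters from the Namibian
#' border south to 33S, west of 20E), Southwest (the dynamic boundary zone
#' over the western Agulhas Bank, west of 20E and south of 33S), South
#' (the lower Agulhas Current area between 20E and 26E) and East
#' (subtropical waters under the upper Agulhas Current, from 26E to the
#' Mozambique border). Longitude 20E also separates the ICCAT (Atlantic)
#' and IOTC (Indian Ocean) tRFMO reporting regions. All east/south edges
#' are half-open, so points exactly on 20E or 26E fall east; the exact
#' border latitudes are configurable because only region membership, not
#' the border itself, affects the analysis.
#'
#' @param rfmo_split_longitude longitude (degrees E) separating ICCAT from
#'   IOTC reporting; also the West/Southwest vs South boundary.
#' @param west_south_boundary_latitude latitude separating West from
#'   Southwest (degrees, negative south).
#' @param south_east_boundary_longitude longitude separating South from
#'   East (degrees E).
#' @param north_west_latitude northern bound of the Atlantic side (the
#'   Namibian border latitude).
#' @param north_east_latitude northern bound of the Indian-Ocean side (the
#'   Mozambique border latitude).
#' @param south_latitude,west_longitude,east_longitude outer bounds of the
#'   study region.
#' @return an object of class `area_scheme`.
#' @export
area_scheme <- function(rfmo_split_longitude = 20,
                        west_south_boundary_latitude = -33,
                        south_east_boundary_longitude = 26,
                        north_west_latitude = -28.6,
                        north_east_latitude = -26.85,
                        south_latitude = -40,
                        west_longitude = 10,
                        east_longitude = 36.5) {
  if (rfmo_split_longitude >= south_east_boundary_longitude) {
    stop_config("rfmo split longitude must be west of the South/East boundary")
  }
  if (west_longitude >= east_longitude || south_latitude >= max(north_west_latitude, north_east_latitude)) {
    stop_config("area scheme bounds define an empty study region")
  }
  structure(
    list(rfmo_split_longitude = rfmo_split_longitude,
         west_south_boundary_latitude = west_south_boundary_latitude,
         south_east_boundary_longitude = south_east_boundary_longitude,
         north_west_latitude = north_west_latitude,
         north_east_latitude = north_east_latitude,
         south_latitude = south_latitude,
         west_longitude = west_longitude,
         east_longitude = east_longitude),
    class = "area_scheme"
  )
}

in_study_region <- function(latitude, longitude, scheme) {
  north <- ifelse(longitude < scheme$rfmo_split_longitude,
                  scheme$north_west_latitude, scheme$north_east_latitude)
  longitude >= scheme$west_longitude & longitude < scheme$east_longitude &
    latitude >= scheme$south_latitude & latitude <= north
}

#' Assign longline sets to analysis areas
#'
#' Vectorised assignment of positions to the four analysis areas. Points
#' outside the study region return `NA`. Boundaries are half-open on each
#' area's eastern/southern edge, so assignment is total and deterministic:
#' every in-region point maps to exactly one area.
#'
#' @param latitude,longitude positions in decimal degrees (negative south,
#'   positive east).
#' @param scheme an [area_scheme()].
#' @return character vector over `c("West", "Southwest", "South", "East")`,
#'   `NA` outside the study region.
#' @examples
#' assign_area(-31, 16)   # West
#' assign_area(-36, 18)   # Southwest
#' @export
assign_area <- function(latitude, longitude, scheme = area_scheme()) {
  if (!inherits(scheme, "area_scheme")) stop_config("`scheme` must be an area_scheme")
  n <- max(length(latitude), length(longitude))
  latitude <- rep_len(latitude, n)
  longitude <- rep_len(longitude, n)
  if (any(!is.finite(latitude) | !is.finite(longitude))) {
    stop_config("positions must be finite decimal degrees")
  }
  area <- rep(NA_character_, n)
  ok <- in_study_region(latitude, longitude, scheme)
  west_side <- longitude < scheme$rfmo_split_longitude
  area[ok & west_side & latitude >= scheme$west_south_boundary_latitude] <- "West"
  area[ok & west_side & latitude < scheme$west_south_boundary_latitude] <- "Southwest"
  area[ok & !west_side & longitude < scheme$south_east_boundary_longitude] <- "South"
  area[ok & !west_side & longitude >= scheme$south_east_boundary_longitude] <- "East"
  area
}

#' Assign sets to a tRFMO reporting region
#'
#' The study area straddles the ICCAT (Atlantic, west of 20E) and IOTC
#' (Indian Ocean, east of 20E) reporting regions; longitude exactly on the
#' split falls east (IOTC) by the half-open convention, consistent with
#' [assign_area()] (West/Southwest report to ICCAT, South/East to IOTC).
#'
#' @param longitude decimal degrees E.
#' @inheritParams assign_area
#' @return character vector over `c("ICCAT", "IOTC")`.
#' @export
assign_rfmo <- function(longitude, scheme = area_scheme()) {
  if (any(!is.finite(longitude))) stop_config("longitude must be finite")
  ifelse(longitude < scheme$rfmo_split_longitude, "ICCAT", "IOTC")
}

#' Add area and tRFMO columns to a logbook
#'
#' @param records logbook data.frame with `latitude`/`longitude`.
#' @inheritParams assign_area
#' @return the logbook with `area` and `rfmo` columns (re)computed.
#' @export
add_strata <- function(records, scheme = area_scheme()) {
  assert_logbook(records)
  records$area <- assign_area(records$latitude, records$longitude, scheme)
  records$rfmo <- assign_rfmo(records$longitude, scheme)
  records
}
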