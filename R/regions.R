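#' Default Northern Hemisphere analysis regions
#'
#' Eight rectangular regions covering the Northern Hemisphere landmass, used
#' to localise screening rules, transfer-function parameters and composite
#' stacks: western North America (W_NA), northeastern North America (NE_NA),
#' southeastern North America (SE_NA), western Europe (W_EU), northeastern
#' Europe (NE_EU), southeastern Europe (SE_EU), northern Asia (N_AS) and
#' southern Asia (S_AS). Bounds are interpreted as half-open intervals
#' `[lower, upper)` on both latitude and longitude, so boundary sites are
#' assigned deterministically. The table can be replaced by any tibble with
#' the same columns.
#'
#' @return A tibble with columns `region_id`, `lat_min`, `lat_max`,
#'   `lon_min`, `lon_max` (degrees; longitudes in \[-180, 180\]).
#' @export
#' @examples
#' default_regions()
default_regions <- function() {
  tibble::tribble(
    ~region_id, ~lat_min, ~lat_max, ~lon_min, ~lon_max,
    "W_NA",   25, 75, -180, -105,
    "NE_NA",  40, 75, -105,  -50,
    "SE_NA",  25, 40, -105,  -50,
    "W_EU",   30, 65,  -15,    5,
    "NE_EU",  48, 75,    5,   56,
    "SE_EU",  30, 48,    5,   56,
    "N_AS",   50, 75,   56,  180,
    "S_AS",    0, 50,   56,  140
  )
}

#' Assign sites to regions
#'
#' Pure function of coordinates and the region table. Each site is assigned
#' to the first region whose `[lower, upper)` box contains it; sites in no
#' box get `"other"`. Longitudes are normalised to \[-180, 180) first, so
#' files using 0-360 conventions are handled transparently.
#'
#' @param lat,lon Numeric vectors of coordinates (degrees).
#' @param regions Region table as returned by [default_regions()].
#' @return Character vector of region ids.
#' @export
#' @examples
#' assign_region(c(45, 60), c(-120, 100))
assign_region <- function(lat, lon, regions = default_regions()) {
  if (any(lat < -90 | lat > 90)) abort("latitude outside [-90, 90]")
  lon <- normalize_lon(lon)
  out <- rep("other", length(lat))
  for (i in seq_len(nrow(regions))) {
    r <- regions[i, ]
    hit <- out == "other" &
      lat >= r$lat_min & lat < r$lat_max &
      lon >= r$lon_min & lon < r$lon_max
    out[hit] <- r$region_id
  }
  out
}

#' Construct a site table
#'
#' @param site_id Character ids.
#' @param lat,lon Coordinates in degrees; `lon` is normalised to
#'   \[-180, 180).
#' @param elev Elevation in m above sea level.
#' @param regions Region table used for `region_id` assignment.
#' @return A tibble with columns `site_id`, `lat`, `lon`, `elev`,
#'   `region_id`.
#' @export
site_table <- function(site_id, lat, lon, elev = NA_real_,
                       regions = default_regions()) {
  tibble(
    site_id = as.character(site_id),
    lat = lat,
    lon = normalize_lon(lon),
    elev = elev,
    region_id = assign_region(lat, lon, regions)
  )
}
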