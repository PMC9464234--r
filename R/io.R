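# On-disk formats: delimited UTF-8 CSV throughout (header required; depth in
# cm, ages in calendar years BP with present = 1950). Gridded fields travel
# as long-format CSV with one row per cell (and time step), which keeps the
# whole artifact chain plain-text.

#' Read a pollen count table
#'
#' Expects a CSV with columns `sample_id`, `depth` (cm, increasing downcore)
#' and one column per taxon. The `percentages` dialect divides values by 100
#' and records the original row sums as the `"row_sums"` attribute.
#'
#' @param path File path.
#' @param dialect `"counts"` (non-negative integers) or `"percentages"`.
#' @return A tibble of class `pollen_counts` with attributes `taxa` and
#'   `dialect`.
#' @export
read_pollen_counts <- function(path, dialect = c("counts", "percentages")) {
  dialect <- match.arg(dialect)
  x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("sample_id", "depth") %in% names(x))) {
    abort("pollen table must have 'sample_id' and 'depth' columns")
  }
  taxa <- setdiff(names(x), c("sample_id", "depth"))
  if (anyDuplicated(taxa)) {
    abort(paste0("duplicate taxon column: ", taxa[duplicated(taxa)][1]))
  }
  m <- as.matrix(x[taxa])
  bad <- which(m < 0, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    abort(sprintf("negative value at sample '%s', taxon '%s'",
                  x$sample_id[bad[1, 1]], taxa[bad[1, 2]]))
  }
  if (is.unsorted(x$depth, strictly = FALSE)) {
    abort("depths must be monotone increasing downcore")
  }
  row_sums <- rowSums(m)
  if (dialect == "percentages") {
    x[taxa] <- m / 100
  }
  structure(
    as_tibble(x),
    taxa = taxa,
    dialect = dialect,
    row_sums = row_sums,
    class = c("pollen_counts", class(as_tibble(x)))
  )
}

#' Write a pollen count table
#' @param x A `pollen_counts` tibble (or any tibble with `sample_id`,
#'   `depth` and taxon columns).
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_pollen_counts <- function(x, path) {
  readr::write_csv(as_tibble(x), path, progress = FALSE)
  invisible(path)
}

# Extract the numeric taxa matrix from a pollen_counts tibble (numeric
# matrices pass through).
count_matrix <- function(x) {
  if (is.matrix(x)) return(x)
  taxa <- attr(x, "taxa") %||% setdiff(names(x), c("sample_id", "depth"))
  m <- as.matrix(as_tibble(x)[taxa])
  rownames(m) <- x$sample_id
  m
}

#' Read a taxa-to-PFT assignment matrix
#'
#' CSV with a `taxon` column, an optional `region_id` column (one matrix per
#' region), and one column per plant functional type holding weights in
#' \[0, 1\]. A PFT column that is zero everywhere is retained with a
#' warning.
#'
#' @param path File path.
#' @return A tibble; PFT names in attribute `pfts`.
#' @export
read_taxa_pft_matrix <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!"taxon" %in% names(x)) abort("taxa-PFT matrix must have a 'taxon' column")
  pfts <- setdiff(names(x), c("taxon", "region_id"))
  m <- as.matrix(x[pfts])
  if (any(m < 0 | m > 1)) abort("PFT weights must lie in [0, 1]")
  empty <- pfts[colSums(m) == 0]
  if (length(empty) > 0) {
    warn(paste0("PFT column(s) with no assigned taxa retained: ",
                paste(empty, collapse = ", ")))
  }
  structure(as_tibble(x), pfts = pfts,
            class = c("pft_matrix", class(as_tibble(x))))
}

#' Report fossil taxa not covered by a taxa-PFT matrix
#'
#' Unknown taxa are never silently dropped by the scoring step; this report
#' enumerates them so coverage can be audited per record.
#'
#' @param taxa Character vector of fossil taxon names.
#' @param pft_matrix A taxa-PFT tibble (see [read_taxa_pft_matrix()]).
#' @return A tibble with columns `taxon` and `covered`.
#' @export
pft_coverage <- function(taxa, pft_matrix) {
  tibble(taxon = taxa, covered = taxa %in% pft_matrix$taxon)
}

#' Construct a climate grid
#'
#' Regular lat/lon grid of monthly mean temperatures plus elevation. The
#' canonical resolution is 0.5 degrees but any regular axes are accepted.
#'
#' @param lat,lon Strictly monotone ascending axes (degrees).
#' @param elev `length(lat) x length(lon)` elevation matrix (m).
#' @param temp `12 x length(lat) x length(lon)` array of monthly mean
#'   temperatures (degC).
#' @return An object of class `climate_grid`.
#' @export
climate_grid <- function(lat, lon, elev, temp) {
  if (is.unsorted(lat, strictly = TRUE) || is.unsorted(lon, strictly = TRUE)) {
    abort("climate grid axes must be strictly ascending")
  }
  stopifnot(dim(temp)[1] == 12,
            dim(temp)[2] == length(lat), dim(temp)[3] == length(lon),
            nrow(elev) == length(lat), ncol(elev) == length(lon))
  structure(list(lat = lat, lon = lon, elev = elev, temp = temp),
            class = "climate_grid")
}

#' @export
print.climate_grid <- function(x, ...) {
  cat(sprintf("<climate_grid> %d x %d cells, lat %.1f..%.1f, lon %.1f..%.1f\n",
              length(x$lat), length(x$lon), min(x$lat), max(x$lat),
              min(x$lon), max(x$lon)))
  invisible(x)
}

#' Convert a climate grid to a long tibble
#' @param x A `climate_grid`.
#' @param ... Unused.
#' @return Tibble with `lat`, `lon`, `elev`, `t01`..`t12`.
#' @exportS3Method tibble::as_tibble
as_tibble.climate_grid <- function(x, ...) {
  cells <- expand.grid(lat = x$lat, lon = x$lon, KEEP.OUT.ATTRS = FALSE)
  out <- tibble(lat = cells$lat, lon = cells$lon, elev = as.vector(x$elev))
  for (m in 1:12) {
    out[[sprintf("t%02d", m)]] <- as.vector(x$temp[m, , ])
  }
  out
}

#' Write / read a climate grid as long-format CSV
#'
#' Temperatures may be stored in degC or K; on read, values whose minimum
#' exceeds 150 are treated as Kelvin and converted to degC. Axes are sorted
#' ascending on read and the grid must be complete (every lat/lon
#' combination present).
#'
#' @param x A `climate_grid`.
#' @param path File path.
#' @return `write_climate_grid()` returns `path` invisibly;
#'   `read_climate_grid()` returns a `climate_grid`.
#' @export
write_climate_grid <- function(x, path) {
  readr::write_csv(as_tibble(x), path, progress = FALSE)
  invisible(path)
}

#' @rdname write_climate_grid
#' @export
read_climate_grid <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  mcols <- sprintf("t%02d", 1:12)
  for (nm in c("lat", "lon", "elev", mcols)) {
    if (!nm %in% names(x)) abort(paste0("climate grid file missing column: ", nm))
  }
  lat <- sort(unique(x$lat))
  lon <- sort(unique(normalize_lon(x$lon)))
  x$lon <- normalize_lon(x$lon)
  if (nrow(x) != length(lat) * length(lon)) {
    abort("climate grid file is not a complete regular grid")
  }
  x <- arrange(x, .data$lon, .data$lat)
  tm <- as.matrix(x[mcols])
  if (min(tm) > 150) tm <- tm - 273.15  # stored in Kelvin
  temp <- array(NA_real_, c(12, length(lat), length(lon)))
  for (m in 1:12) temp[m, , ] <- matrix(tm[, m], nrow = length(lat))
  climate_grid(lat, lon, matrix(x$elev, nrow = length(lat)), temp)
}

#' Construct a topographic-anomaly field
#'
#' Time-resolved elevation anomalies relative to present (glacio-isostatic
#' style). The anomaly at time 0 must be identically zero.
#'
#' @param times_ka Ascending time axis in ka BP (must include 0).
#' @param lat,lon Strictly ascending axes (degrees).
#' @param anomaly `length(times_ka) x length(lat) x length(lon)` array (m).
#' @return An object of class `topo_field`.
#' @export
topo_field <- function(times_ka, lat, lon, anomaly) {
  if (is.unsorted(times_ka, strictly = TRUE)) abort("time axis must be ascending")
  stopifnot(dim(anomaly)[1] == length(times_ka),
            dim(anomaly)[2] == length(lat), dim(anomaly)[3] == length(lon))
  i0 <- which(times_ka == 0)
  if (length(i0) != 1 || any(abs(anomaly[i0, , ]) > 1e-9)) {
    abort("topographic anomaly must be identically 0 at time 0")
  }
  structure(list(times_ka = times_ka, lat = lat, lon = lon, anomaly = anomaly),
            class = "topo_field")
}

#' Write / read a topographic-anomaly field as long-format CSV
#' @param x A `topo_field`.
#' @param path File path.
#' @return `write_topo_field()` returns `path` invisibly;
#'   `read_topo_field()` a `topo_field`.
#' @export
write_topo_field <- function(x, path) {
  cells <- expand.grid(lat = x$lat, lon = x$lon, time_ka = x$times_ka,
                       KEEP.OUT.ATTRS = FALSE)
  vals <- as.vector(aperm(x$anomaly, c(2, 3, 1)))
  readr::write_csv(tibble(time_ka = cells$time_ka, lat = cells$lat,
                          lon = cells$lon, anomaly_m = vals),
                   path, progress = FALSE)
  invisible(path)
}

#' @rdname write_topo_field
#' @export
read_topo_field <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  for (nm in c("time_ka", "lat", "lon", "anomaly_m")) {
    if (!nm %in% names(x)) abort(paste0("topo field file missing column: ", nm))
  }
  times <- sort(unique(x$time_ka))
  lat <- sort(unique(x$lat))
  lon <- sort(unique(normalize_lon(x$lon)))
  x$lon <- normalize_lon(x$lon)
  x <- arrange(x, .data$time_ka, .data$lon, .data$lat)
  anom <- array(x$anomaly_m, c(length(lat), length(lon), length(times)))
  topo_field(times, lat, lon, aperm(anom, c(3, 1, 2)))
}

#' Read a radiocarbon calibration curve
#'
#' Three-column CSV matching the standard calibration-curve distribution
#' layout: calendar age BP, radiocarbon age BP, one-sigma curve error (yr).
#'
#' @param path File path.
#' @return A tibble of class `calib_curve` with columns `cal_bp`, `c14_bp`,
#'   `sigma`, sorted by ascending `cal_bp`.
#' @export
read_calib_curve <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  names(x)[1:3] <- c("cal_bp", "c14_bp", "sigma")
  new_calib_curve(x)
}

new_calib_curve <- function(x) {
  x <- arrange(as_tibble(x), .data$cal_bp)
  if (any(diff(x$cal_bp) <= 0)) abort("calibration curve cal ages must be strictly increasing")
  if (any(x$sigma < 0)) abort("calibration curve errors must be non-negative")
  structure(x, class = c("calib_curve", class(x)))
}

#' Read an age-control table
#'
#' CSV with columns `depth` (cm), `kind` (`c14`, `calendar`, `core_top`,
#' `lamination`, `biostratigraphic`), `age` (14C yr BP for `c14`, cal yr BP
#' otherwise), `sigma` (yr) and logical `independent`.
#'
#' @param path File path.
#' @return A tibble.
#' @export
read_age_controls <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  kinds <- c("c14", "calendar", "core_top", "lamination", "biostratigraphic")
  if (!all(x$kind %in% kinds)) {
    abort(paste0("unknown age-control kind: ",
                 paste(setdiff(unique(x$kind), kinds), collapse = ", ")))
  }
  if (any(x$kind == "c14" & (is.na(x$sigma) | x$sigma <= 0))) {
    abort("radiocarbon controls require sigma > 0")
  }
  as_tibble(x)
}

#' Write a reconstruction series to CSV
#' @param x A `recon_series` tibble.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_recon <- function(x, path) {
  out <- as_tibble(x)
  if ("analogues" %in% names(out)) {
    out$analogues <- purrr::map_chr(out$analogues,
                                    ~ paste(.x, collapse = ";"))
  }
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}
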