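# Glacio-isostatic correction: remove the temperature signal of past
# surface-elevation change using interpolated topographic-anomaly histories
# and locally estimated present-day lapse rates.

#' Extract a site's topographic-anomaly history
#'
#' Inverse-distance-weighted spatial interpolation (power 2 over the 4
#' nearest grid nodes by great-circle distance) at each time step of the
#' field; queries landing exactly on a node return the node series.
#'
#' @param field A `topo_field` (see [topo_field()]).
#' @param site One-row site tibble (`lat`, `lon`).
#' @param power IDW power.
#' @param n_neighbours Number of nearest nodes used.
#' @return A tibble of class `topo_history` with `time_ka` and
#'   `delta_elev` (m relative to present; 0 at time 0).
#' @export
topo_history_at_site <- function(field, site, power = 2, n_neighbours = 4) {
  if (site$lat < min(field$lat) || site$lat > max(field$lat) ||
      normalize_lon(site$lon) < min(field$lon) ||
      normalize_lon(site$lon) > max(field$lon)) {
    abort("site lies outside the topographic field bounds")
  }
  nodes <- expand.grid(lat = field$lat, lon = field$lon, KEEP.OUT.ATTRS = FALSE)
  d <- haversine_km(site$lat, normalize_lon(site$lon), nodes$lat, nodes$lon)
  nn <- order(d)[seq_len(min(n_neighbours, length(d)))]
  dn <- d[nn]
  if (dn[1] < 1e-9) {
    w <- as.numeric(dn < 1e-9)
  } else {
    w <- 1 / dn^power
  }
  w <- w / sum(w)
  ii <- ((nn - 1) %% length(field$lat)) + 1
  jj <- ((nn - 1) %/% length(field$lat)) + 1
  series <- vapply(seq_along(field$times_ka), function(t) {
    sum(w * field$anomaly[cbind(t, ii, jj)])
  }, numeric(1))
  structure(tibble(time_ka = field$times_ka, delta_elev = series),
            class = c("topo_history", class(tibble())))
}

#' Estimate local topographic lapse rates from a climate grid
#'
#' Ordinary least-squares slope of each temperature variable against
#' elevation over all grid cells within `radius_km` of the site.
#'
#' @param grid A `climate_grid`.
#' @param site One-row site tibble (`lat`, `lon`).
#' @param radius_km Search radius (default 300 km).
#' @return A tibble of class `lapse_rate` with `variable`, `rate`
#'   (degC per m), `n_cells`, `radius_km`.
#' @export
local_lapse_rate <- function(grid, site, radius_km = 300) {
  cells <- expand.grid(lat = grid$lat, lon = grid$lon, KEEP.OUT.ATTRS = FALSE)
  d <- haversine_km(site$lat, site$lon, cells$lat, cells$lon)
  sel <- which(d <= radius_km)
  if (length(sel) < 3) abort("fewer than 3 grid cells within the lapse radius")
  elev <- as.vector(grid$elev)[sel]
  if (max(elev) - min(elev) <= 0) {
    abort("no elevation spread within the lapse radius; site uncorrectable")
  }
  tmat <- vapply(1:12, function(m) as.vector(grid$temp[m, , ])[sel],
                 numeric(length(sel)))
  vals <- cbind(annt = rowMeans(tmat),
                mtwa = apply(tmat, 1, max),
                mtco = apply(tmat, 1, min))
  rates <- vapply(climate_vars(), function(v) {
    unname(coef(lm(vals[, v] ~ elev))[2])
  }, numeric(1))
  structure(tibble(variable = climate_vars(), rate = unname(rates),
                   n_cells = length(sel), radius_km = radius_km),
            class = c("lapse_rate", class(tibble())))
}

#' Apply the isostatic temperature correction to a reconstruction
#'
#' Subtracts the topography-induced temperature component
#' `rate * delta_elev(t)` from each estimate: a past surface standing
#' `delta_elev > 0` m higher than present with a negative lapse rate
#' implies a topographic cooling of `rate * delta_elev` degC, which is
#' removed (so the corrected estimate is warmer). Sample errors are
#' unchanged. Applying the correction twice is guarded by the `corrected`
#' attribute.
#'
#' @param recon A `recon_series` (see [reconstruct()]).
#' @param topo A `topo_history` covering the reconstruction ages
#'   (linear interpolation in time; extrapolation uses the end values and
#'   is flagged in the `extrapolated` column).
#' @param lapse A `lapse_rate` tibble (`variable`, `rate`).
#' @return The corrected `recon_series` with an added `topo_correction`
#'   column (the subtracted component, degC) and `corrected = TRUE`.
#' @export
isostatic_correct <- function(recon, topo, lapse) {
  if (isTRUE(attr(recon, "corrected"))) {
    abort("reconstruction is already isostatically corrected")
  }
  age_ka <- recon$age / 1000
  delev <- approx(topo$time_ka, topo$delta_elev, age_ka, rule = 2,
                  ties = "ordered")$y
  extrap <- age_ka < min(topo$time_ka) | age_ka > max(topo$time_ka)
  rates <- setNames(lapse$rate, lapse$variable)
  out <- recon %>%
    mutate(topo_correction = unname(rates[.data$variable]) * delev,
           estimate = .data$estimate - .data$topo_correction,
           extrapolated = extrap)
  attr(out, "corrected") <- TRUE
  class(out) <- class(recon)
  out
}
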