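# Radiocarbon recalibration, age-depth models and the record/sample
# screening rules applied before any reconstruction.

#' Calibrate a radiocarbon date
#'
#' Computes the posterior of calendar age theta given a radiocarbon
#' determination, `p(theta) proportional to
#' Normal(age14c; mu(theta), sqrt(sigma^2 + curve_sigma(theta)^2))`,
#' normalised over the calibration-curve support. The curve is linearly
#' interpolated onto a fine internal grid (default 1 yr) before quadrature,
#' and the point estimate is the posterior mean with its posterior standard
#' deviation.
#'
#' @param age14c Radiocarbon age, 14C yr BP.
#' @param sigma One-sigma dating error, yr (> 0).
#' @param curve A `calib_curve` tibble (`cal_bp`, `c14_bp`, `sigma`).
#' @param grid_step Internal quadrature step in years.
#' @return A list with `point_age` (cal yr BP), `age_sd` (yr) and `density`
#'   (tibble `cal_bp`, `density` integrating to 1).
#' @export
#' @examples
#' curve <- make_calib_curve("identity")
#' calibrate_c14(5000, 50, curve)$point_age
calibrate_c14 <- function(age14c, sigma, curve, grid_step = 1) {
  if (sigma <= 0) abort("sigma must be > 0")
  span <- 5 * sqrt(sigma^2 + max(curve$sigma)^2)
  if (age14c - span < min(curve$c14_bp) || age14c + span > max(curve$c14_bp)) {
    abort("date (+/- 5 sigma) lies beyond calibration-curve support")
  }
  grid <- seq(min(curve$cal_bp), max(curve$cal_bp), by = grid_step)
  mu <- approx(curve$cal_bp, curve$c14_bp, grid, ties = "ordered")$y
  cs <- approx(curve$cal_bp, curve$sigma, grid, ties = "ordered")$y
  dens <- dnorm(age14c, mean = mu, sd = sqrt(sigma^2 + cs^2))
  # trapezoidal normalisation on the grid
  w <- rep(grid_step, length(grid))
  w[c(1, length(grid))] <- grid_step / 2
  z <- sum(dens * w)
  if (z <= 0 || !is.finite(z)) abort("calibration produced a zero-density posterior")
  dens <- dens / z
  point <- sum(grid * dens * w)
  sd_post <- sqrt(max(0, sum((grid - point)^2 * dens * w)))
  list(point_age = point, age_sd = sd_post,
       density = tibble(cal_bp = grid, density = dens))
}

#' Build a piecewise-linear age-depth model
#'
#' Radiocarbon controls are calibrated first (point estimate = posterior
#' mean); other control kinds contribute their stated calendar ages. Sample
#' ages are obtained by piecewise-linear interpolation of the control point
#' ages against depth, extrapolating linearly from the end segments.
#' Consecutive controls whose calibrated ages reverse raise an error naming
#' the offending pair.
#'
#' @param controls Tibble of age controls (`depth`, `kind`, `age`, `sigma`,
#'   `independent`); see [read_age_controls()].
#' @param depths Sample depths (cm) at which ages are required.
#' @param curve A `calib_curve`, required when any control has
#'   `kind == "c14"`.
#' @return A tibble of class `age_model` with columns `depth`, `age`
#'   (cal yr BP) and `flag` (`direct`, `interpolated`, `extrapolated`);
#'   calibrated control points in attribute `controls`.
#' @export
build_age_model <- function(controls, depths, curve = NULL) {
  if (nrow(controls) < 2) abort("need at least 2 usable age controls")
  cal_age <- numeric(nrow(controls))
  cal_sd <- numeric(nrow(controls))
  for (i in seq_len(nrow(controls))) {
    if (controls$kind[i] == "c14") {
      if (is.null(curve)) abort("radiocarbon controls present but no calibration curve given")
      cc <- calibrate_c14(controls$age[i], controls$sigma[i], curve)
      cal_age[i] <- cc$point_age
      cal_sd[i] <- cc$age_sd
    } else {
      cal_age[i] <- controls$age[i]
      cal_sd[i] <- controls$sigma[i] %||% 0
    }
  }
  ord <- order(controls$depth)
  cal_age <- cal_age[ord]
  cal_sd <- cal_sd[ord]
  cdepth <- controls$depth[ord]
  rev_idx <- which(diff(cal_age) < 0)
  if (length(rev_idx) > 0) {
    i <- rev_idx[1]
    abort(sprintf(
      "age reversal between controls at %.1f cm (%.0f cal BP) and %.1f cm (%.0f cal BP)",
      cdepth[i], cal_age[i], cdepth[i + 1], cal_age[i + 1]))
  }
  ages <- approx_extrap(cdepth, cal_age, depths)
  flag <- dplyr::case_when(
    vapply(depths, function(d) any(abs(d - cdepth) < 1e-9), logical(1)) ~ "direct",
    depths < min(cdepth) | depths > max(cdepth) ~ "extrapolated",
    TRUE ~ "interpolated"
  )
  ctl <- tibble(depth = cdepth, age = cal_age, age_sd = cal_sd,
                kind = controls$kind[ord],
                independent = controls$independent[ord])
  structure(tibble(depth = depths, age = ages, flag = flag),
            controls = ctl,
            class = c("age_model", class(tibble())))
}

#' Screen individual samples on dating quality and pollen sum
#'
#' A sample is retained iff (its age is within `near_yr` of the nearest
#' chronological control, OR it lies between two consecutive controls whose
#' ages are at most `bracket_yr` apart) AND its total pollen count is at
#' least `min_count`.
#'
#' @param model An `age_model`.
#' @param counts A `pollen_counts` tibble aligned with `model` by row order.
#' @param near_yr Maximum distance (yr) to the nearest control.
#' @param bracket_yr Maximum separation (yr) of a bracketing control pair.
#' @param min_count Minimum total pollen count.
#' @param independent_only If `TRUE`, only controls flagged independent
#'   count as dates for the age rules.
#' @return Logical vector, `TRUE` for retained samples.
#' @export
screen_samples <- function(model, counts, near_yr = 1000, bracket_yr = 6000,
                           min_count = 200, independent_only = FALSE) {
  ctl <- attr(model, "controls")
  if (independent_only) ctl <- ctl[ctl$independent, ]
  dates <- sort(ctl$age)
  total <- rowSums(count_matrix(counts))
  vapply(seq_len(nrow(model)), function(i) {
    t <- model$age[i]
    near <- length(dates) > 0 && min(abs(t - dates)) <= near_yr
    bracketed <- FALSE
    if (length(dates) >= 2) {
      j <- findInterval(t, dates)
      if (j >= 1 && j < length(dates)) {
        bracketed <- (dates[j + 1] - dates[j]) <= bracket_yr
      }
    }
    (near || bracketed) && total[i] >= min_count
  }, logical(1))
}

#' Screen a whole record against the selection criteria
#'
#' A record passes iff it has more than three chronological controls with at
#' least two independent dates, spans more than 5 kyr, includes a sample
#' younger than 1 ka BP (required to compute anomalies), and its median
#' Holocene inter-sample age gap is below the resolution limit (400 yr,
#' relaxed to 1000 yr in northern Asia, `N_AS`).
#'
#' @param record A `fossil_record` (see [make_fossil_record()]) whose age
#'   model has been built, or any list with `samples` (tibble with `age`)
#'   and `controls` elements.
#' @param region_id Region id used for the resolution relaxation.
#' @param min_controls,min_independent,min_duration,max_top_age Screening
#'   thresholds (counts / yr).
#' @param resolution_yr,resolution_yr_relaxed Median-resolution limits (yr).
#' @param holocene_max_age Upper age bound (yr BP) of the window over which
#'   resolution is measured.
#' @return A list with `pass` (logical) and `reasons` (character vector of
#'   failed criteria, empty when passing).
#' @export
screen_record <- function(record, region_id = "other",
                          min_controls = 4, min_independent = 2,
                          min_duration = 5000, max_top_age = 1000,
                          resolution_yr = 400, resolution_yr_relaxed = 1000,
                          holocene_max_age = 11700) {
  ages <- sort(record$samples$age)
  ctl <- record$controls
  reasons <- character(0)
  if (nrow(ctl) < min_controls) {
    reasons <- c(reasons, sprintf("fewer than %d chronological controls", min_controls))
  }
  if (sum(ctl$independent) < min_independent) {
    reasons <- c(reasons, sprintf("fewer than %d independent dates", min_independent))
  }
  if (length(ages) < 2 || diff(range(ages)) <= min_duration) {
    reasons <- c(reasons, sprintf("duration does not exceed %d yr", min_duration))
  }
  if (length(ages) == 0 || min(ages) >= max_top_age) {
    reasons <- c(reasons, sprintf("no sample younger than %d yr BP", max_top_age))
  }
  holo <- ages[ages <= holocene_max_age]
  limit <- if (identical(region_id, "N_AS")) resolution_yr_relaxed else resolution_yr
  if (length(holo) < 2 || median(diff(holo)) >= limit) {
    reasons <- c(reasons, sprintf("median sampling interval not finer than %d yr", limit))
  }
  list(pass = length(reasons) == 0, reasons = reasons)
}

# Bilinear interpolation of a lat x lon matrix at a point.
bilinear_at <- function(lat_axis, lon_axis, z, lat, lon) {
  if (lat < min(lat_axis) || lat > max(lat_axis) ||
      lon < min(lon_axis) || lon > max(lon_axis)) {
    abort("site lies outside the grid bounds")
  }
  i <- findInterval(lat, lat_axis, rightmost.closed = TRUE)
  j <- findInterval(lon, lon_axis, rightmost.closed = TRUE)
  i2 <- min(i + 1, length(lat_axis)); j2 <- min(j + 1, length(lon_axis))
  fx <- if (i2 == i) 0 else (lat - lat_axis[i]) / (lat_axis[i2] - lat_axis[i])
  fy <- if (j2 == j) 0 else (lon - lon_axis[j]) / (lon_axis[j2] - lon_axis[j])
  z[i, j] * (1 - fx) * (1 - fy) + z[i2, j] * fx * (1 - fy) +
    z[i, j2] * (1 - fx) * fy + z[i2, j2] * fx * fy
}

#' Assign modern climate to a site from a gridded field
#'
#' Monthly temperatures and grid elevation are bilinearly interpolated to
#' the site position; ANNT is the mean, MTWA the maximum and MTCO the
#' minimum of the twelve monthly values. When the site elevation differs
#' from the interpolated grid elevation, a per-variable lapse-rate
#' correction `rate * (site_elev - grid_elev)` is applied (default a
#' uniform -6.5 degC/km; pass a [local_lapse_rate()] result for locally
#' estimated rates). The ordering `mtco <= annt <= mtwa` is enforced.
#'
#' @param site One-row site tibble (`lat`, `lon`, `elev`).
#' @param grid A `climate_grid`.
#' @param lapse Optional lapse-rate tibble (`variable`, `rate`) from
#'   [local_lapse_rate()].
#' @param default_lapse Uniform lapse rate (degC per m) used when `lapse`
#'   is `NULL`.
#' @return A tibble with columns `annt`, `mtwa`, `mtco` (degC).
#' @export
assign_site_climate <- function(site, grid, lapse = NULL,
                                default_lapse = -0.0065) {
  monthly <- vapply(1:12, function(m) {
    bilinear_at(grid$lat, grid$lon, grid$temp[m, , ], site$lat, site$lon)
  }, numeric(1))
  grid_elev <- bilinear_at(grid$lat, grid$lon, grid$elev, site$lat, site$lon)
  out <- c(annt = mean(monthly), mtwa = max(monthly), mtco = min(monthly))
  delev <- if (is.na(site$elev)) 0 else site$elev - grid_elev
  rates <- setNames(rep(default_lapse, 3), climate_vars())
  if (!is.null(lapse)) rates[lapse$variable] <- lapse$rate
  out <- out + rates[names(out)] * delev
  out["annt"] <- min(max(out["annt"], out["mtco"]), out["mtwa"])
  tibble(annt = out[["annt"]], mtwa = out[["mtwa"]], mtco = out[["mtco"]])
}
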