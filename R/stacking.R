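# Monte-Carlo stacking: site reconstructions -> 200-yr binned anomalies ->
# 2-degree grid cells -> hemispheric/regional composites with 95% bands,
# plus seasonality and trend-rate summaries.

#' Bin one reconstruction into anomaly space by Monte Carlo
#'
#' Each of `n_mc` draws perturbs every sample estimate by
#' `Normal(0, sample_error)`, subtracts that draw's mean over the reference
#' window (ages <= `ref_age`, the latest-millennium baseline), and linearly
#' interpolates the perturbed series to the 200-yr bin lattice covered by
#' the record's age span. The bin value is the ensemble median; `bin_sd` is
#' the ensemble standard deviation (the propagated error used downstream)
#' and `bin_se` scales it by the square root of the number of contributing
#' samples.
#'
#' @param recon A `recon_series`.
#' @param variable Climate variable to bin.
#' @param n_mc Ensemble size (default 1000).
#' @param seed Optional integer seed.
#' @param bin_width Bin width in years (default 200).
#' @param anchor First bin centre in yr BP (default 100, so bins tile
#'   0-11 ka).
#' @param max_age Last possible bin centre (yr BP).
#' @param ref_age Upper age of the anomaly reference window (yr BP,
#'   inclusive).
#' @return A tibble of class `binned_series`: `bin_center`, `anomaly`,
#'   `bin_sd`, `bin_se`, `n_contributing`; site coordinates are carried in
#'   the `site` attribute when present on `recon`.
#' @export
to_binned <- function(recon, variable = "mtco", n_mc = 1000, seed = NULL,
                      bin_width = 200, anchor = 100, max_age = 10900,
                      ref_age = 1000) {
  x <- as_tibble(recon) %>%
    filter(.data$variable == !!variable, is.finite(.data$estimate)) %>%
    arrange(.data$age)
  if (nrow(x) < 2) abort("need at least 2 finite samples to bin")
  if (min(x$age) > ref_age) {
    abort("no samples inside the anomaly reference window (record should have been screened out)")
  }
  # collapse duplicate ages so the interpolation lattice is strict
  x <- x %>%
    group_by(.data$age) %>%
    summarise(estimate = mean(.data$estimate),
              sample_error = sqrt(mean(.data$sample_error^2)),
              .groups = "drop")
  centers <- seq(anchor, max_age, by = bin_width)
  centers <- centers[centers >= min(x$age) & centers <= max(x$age)]
  if (length(centers) == 0) abort("record span covers no bin centre")
  W <- interp_weights(centers, x$age)
  if (!is.null(seed)) set.seed(seed)
  m <- nrow(x)
  E <- x$estimate + matrix(rnorm(m * n_mc, 0, x$sample_error), m, n_mc)
  ref <- x$age <= ref_age
  E <- sweep(E, 2, colMeans(E[ref, , drop = FALSE]))
  B <- W %*% E
  n_contrib <- vapply(centers, function(ct) {
    sum(abs(x$age - ct) <= bin_width / 2)
  }, integer(1))
  out <- tibble(
    bin_center = centers,
    anomaly = apply(B, 1, median),
    bin_sd = apply(B, 1, sd),
    bin_se = apply(B, 1, sd) / sqrt(pmax(1, n_contrib)),
    n_contributing = n_contrib
  )
  structure(out, site = attr(recon, "site"), variable = variable,
            n_mc = n_mc,
            class = c("binned_series", class(out)))
}

#' Average binned site series onto a regular grid
#'
#' Cell membership uses `[lower, upper)` bounds, so a site exactly on a
#' cell edge belongs to the higher-index cell only. Within a cell and bin
#' the site anomalies are averaged unweighted; the cell error pools the
#' site `bin_sd` values as independent
#' (`sqrt(sum(sd^2)) / n_sites`).
#'
#' @param binned A list of `binned_series`, each carrying a `site`
#'   attribute (one-row tibble with `lat`, `lon`) or accompanied by
#'   `sites`.
#' @param sites Optional tibble of site coordinates (row i for series i),
#'   used when the series lack `site` attributes.
#' @param cell_size Cell size in degrees (default 2).
#' @return A tibble of class `grid_cells`: `cell_lat`, `cell_lon` (cell
#'   centres), `bin_center`, `anomaly`, `se`, `n_sites`.
#' @export
grid_average <- function(binned, sites = NULL, cell_size = 2) {
  rows <- purrr::imap_dfr(binned, function(b, i) {
    s <- attr(b, "site") %||% sites[i, ]
    if (is.null(s)) abort("binned series carry no site coordinates")
    tibble(lat = s$lat, lon = normalize_lon(s$lon),
           bin_center = b$bin_center, anomaly = b$anomaly,
           bin_sd = b$bin_sd)
  })
  out <- rows %>%
    mutate(cell_lat = floor(.data$lat / cell_size) * cell_size + cell_size / 2,
           cell_lon = floor(.data$lon / cell_size) * cell_size + cell_size / 2) %>%
    group_by(.data$cell_lat, .data$cell_lon, .data$bin_center) %>%
    summarise(se = sqrt(sum(.data$bin_sd^2)) / dplyr::n(),
              anomaly = mean(.data$anomaly),
              n_sites = dplyr::n(), .groups = "drop")
  structure(out, cell_size = cell_size,
            class = c("grid_cells", class(out)))
}

#' Composite a set of grid cells with Monte-Carlo uncertainty
#'
#' Per draw, every cell/bin anomaly is perturbed by `Normal(0, se)` and the
#' perturbed cells are averaged (unweighted) within each bin; the composite
#' is the per-bin median with 2.5/97.5 percentile bounds across draws.
#'
#' @param cells A `grid_cells` tibble from [grid_average()].
#' @param n_mc Number of Monte-Carlo draws (default 1000).
#' @param seed Optional integer seed.
#' @param region Optional region id; cells whose centre falls in that
#'   region's box are kept.
#' @param regions Region table used with `region`.
#' @return A tibble of class `composite_curve`: `bin_center`, `median`,
#'   `lower95`, `upper95`, `n_cells`.
#' @export
composite <- function(cells, n_mc = 1000, seed = NULL, region = NULL,
                      regions = default_regions()) {
  x <- as_tibble(cells)
  if (!is.null(region)) {
    x <- x[assign_region(x$cell_lat, x$cell_lon, regions) == region, ]
  }
  if (nrow(x) == 0) abort("no grid cells after region filtering")
  if (!is.null(seed)) set.seed(seed)
  bins <- sort(unique(x$bin_center))
  cell_id <- paste(x$cell_lat, x$cell_lon)
  ids <- unique(cell_id)
  V <- matrix(NA_real_, length(ids), length(bins))
  S <- matrix(NA_real_, length(ids), length(bins))
  V[cbind(match(cell_id, ids), match(x$bin_center, bins))] <- x$anomaly
  S[cbind(match(cell_id, ids), match(x$bin_center, bins))] <- x$se
  med <- lo <- hi <- numeric(length(bins))
  n_cells <- colSums(!is.na(V))
  draws <- matrix(NA_real_, n_mc, length(bins))
  for (j in seq_along(bins)) {
    use <- which(!is.na(V[, j]))
    P <- V[use, j] + matrix(rnorm(length(use) * n_mc, 0, S[use, j]),
                            length(use), n_mc)
    draws[, j] <- colMeans(P)
  }
  out <- tibble(
    bin_center = bins,
    median = apply(draws, 2, median),
    lower95 = apply(draws, 2, quantile, 0.025, names = FALSE),
    upper95 = apply(draws, 2, quantile, 0.975, names = FALSE),
    n_cells = n_cells
  )
  structure(out, n_mc = n_mc, region = region,
            class = c("composite_curve", class(out)))
}

#' Seasonality (summer minus winter) of two composites
#'
#' Per-bin difference of the medians; the band combines the two 95% bands
#' in quadrature, which assumes the summer and winter composites are
#' independent.
#'
#' @param summer,winter `composite_curve` tibbles on identical bin
#'   lattices.
#' @return A `composite_curve` tibble of the difference.
#' @export
seasonality <- function(summer, winter) {
  if (!identical(summer$bin_center, winter$bin_center)) {
    abort("summer and winter composites have misaligned bins")
  }
  hw_s <- (summer$upper95 - summer$lower95) / 2
  hw_w <- (winter$upper95 - winter$lower95) / 2
  hw <- sqrt(hw_s^2 + hw_w^2)
  ctr <- summer$median - winter$median
  out <- tibble(bin_center = summer$bin_center, median = ctr,
                lower95 = ctr - hw, upper95 = ctr + hw,
                n_cells = pmin(summer$n_cells, winter$n_cells))
  structure(out, class = class(summer))
}

#' Fit a linear trend rate to a composite window
#'
#' OLS slope of the composite median against age over the bins inside the
#' window. Sign convention: a positive rate means warming toward the
#' present (temperature decreasing with age BP).
#'
#' @param curve A `composite_curve`.
#' @param window `c(lo, hi)` window in ka BP (bounds inclusive).
#' @return A tibble with `rate` (degC per ka), `se`, `n_bins`,
#'   `window_lo`, `window_hi`.
#' @export
fit_trend <- function(curve, window) {
  sel <- curve$bin_center >= min(window) * 1000 &
    curve$bin_center <= max(window) * 1000 & is.finite(curve$median)
  if (sum(sel) < 3) abort("fewer than 3 bins in the trend window")
  age_ka <- curve$bin_center[sel] / 1000
  fit <- lm(curve$median[sel] ~ age_ka)
  r <- residuals(fit)
  se <- sqrt(sum(r^2) / (length(r) - 2) / sum((age_ka - mean(age_ka))^2))
  tibble(rate = -unname(coef(fit)[2]), se = se, n_bins = sum(sel),
         window_lo = min(window), window_hi = max(window))
}
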