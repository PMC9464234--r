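# Leave-one-out and h-block cross-validation, and the data-driven h
# selection rule that matches the fossil analogue quality.

#' Cross-validate a transfer function on the calibration set
#'
#' For each calibration sample the training pool excludes the sample itself
#' (`loo`) or additionally every sample whose site lies within `h` km
#' great-circle distance (`h_block`; `h = 0` reproduces leave-one-out
#' exactly, since only zero-distance sites are excluded). Performance is the
#' squared Pearson correlation (R2) and the root-mean-square error of
#' prediction per climate variable.
#'
#' @param calib A [calibration_set()].
#' @param method `"mat"` or `"wapls"`.
#' @param scheme `"loo"` or `"h_block"`.
#' @param h Exclusion radius in km (used by `h_block`).
#' @param k Analogue count (MAT).
#' @param n_comp Component count (WA-PLS).
#' @param variables Climate variables to validate.
#' @param seed Unused (both schemes are deterministic); kept for interface
#'   symmetry.
#' @return A tibble of class `cv_result` with columns `variable`, `method`,
#'   `scheme`, `h`, `r2`, `rmsep`, `n_used`, `n_dropped`; per-sample
#'   predictions in attribute `"predictions"`.
#' @export
cross_validate <- function(calib, method = c("mat", "wapls"),
                           scheme = c("loo", "h_block"), h = 0, k = 6,
                           n_comp = 2, variables = climate_vars(),
                           seed = NULL) {
  method <- match.arg(method)
  scheme <- match.arg(scheme)
  if (h < 0) abort("h must be >= 0")
  n <- nrow(calib$features)
  climate <- as.matrix(calib$climate[variables])
  excl <- cv_exclusions(calib, scheme, h)
  pred <- matrix(NA_real_, n, length(variables),
                 dimnames = list(NULL, variables))
  dropped <- logical(n)
  if (method == "mat") {
    D <- scd_matrix(calib$features)
    for (i in seq_len(n)) {
      d <- D[i, ]
      d[excl[[i]]] <- Inf
      if (!any(is.finite(d))) {
        dropped[i] <- TRUE
        next
      }
      pred[i, ] <- mat_from_distances(d, climate, k)$est
    }
  } else {
    for (i in seq_len(n)) {
      pool <- setdiff(seq_len(n), excl[[i]])
      if (length(pool) < n_comp + 2) {
        dropped[i] <- TRUE
        next
      }
      for (v in variables) {
        fit <- wapls_fit(calib$features[pool, , drop = FALSE],
                         calib$climate[[v]][pool], n_comp = n_comp)
        pred[i, v] <- predict(fit, calib$features[i, , drop = FALSE])
      }
    }
  }
  if (any(dropped)) {
    warn(sprintf("%d sample(s) had an empty training pool and were dropped",
                 sum(dropped)))
  }
  use <- !dropped
  out <- purrr::map_dfr(variables, function(v) {
    tibble(variable = v, method = method, scheme = scheme, h = h,
           r2 = cor(pred[use, v], climate[use, v])^2,
           rmsep = sqrt(mean((pred[use, v] - climate[use, v])^2)),
           n_used = sum(use), n_dropped = sum(dropped))
  })
  attr(out, "predictions") <-
    tibble(row = rep(seq_len(n), length(variables)),
           variable = rep(variables, each = n),
           predicted = as.numeric(pred),
           observed = as.numeric(climate))
  class(out) <- c("cv_result", class(out))
  out
}

# Per-sample exclusion index lists (always includes the sample itself).
cv_exclusions <- function(calib, scheme, h) {
  n <- nrow(calib$features)
  if (scheme == "loo") return(lapply(seq_len(n), identity))
  s <- calib$sites
  lapply(seq_len(n), function(i) {
    d <- haversine_km(s$lat[i], s$lon[i], s$lat, s$lon)
    union(i, which(d <= h))
  })
}

#' Select the h-block radius by matching fossil analogue quality
#'
#' For each candidate `h` the median nearest-analogue SCD of an h-block
#' analogue search over the calibration set is recorded; the selected
#' `h_star` is the smallest `h` whose median meets or exceeds the median of
#' the fossil minimum SCDs. This aligns the spatial exclusion severity with
#' the analogue quality actually available to the fossil samples. If the
#' fossil median lies above the whole curve, the largest `h` is returned
#' with a warning.
#'
#' @param calib A [calibration_set()].
#' @param fossil_min_scds Minimum SCDs of the fossil samples (e.g. the
#'   `min_scd` column of a `recon_series`).
#' @param h_grid Ascending candidate radii in km.
#' @return A list with `h_star` (km) and `curve` (tibble `h`,
#'   `median_scd`).
#' @export
select_h <- function(calib, fossil_min_scds, h_grid = seq(0, 1000, by = 100)) {
  fossil_min_scds <- fossil_min_scds[is.finite(fossil_min_scds)]
  if (length(fossil_min_scds) == 0) abort("no finite fossil minimum SCDs supplied")
  if (length(h_grid) == 0 || is.unsorted(h_grid)) {
    abort("h_grid must be non-empty and ascending")
  }
  D <- scd_matrix(calib$features)
  s <- calib$sites
  n <- nrow(D)
  dist_km <- outer(seq_len(n), seq_len(n), function(i, j) {
    haversine_km(s$lat[i], s$lon[i], s$lat[j], s$lon[j])
  })
  med <- vapply(h_grid, function(h) {
    mins <- vapply(seq_len(n), function(i) {
      d <- D[i, ]
      d[dist_km[i, ] <= h] <- Inf
      if (any(is.finite(d))) min(d) else NA_real_
    }, numeric(1))
    median(mins, na.rm = TRUE)
  }, numeric(1))
  target <- median(fossil_min_scds)
  hit <- which(med >= target)
  if (length(hit) == 0) {
    warn("fossil median SCD exceeds the whole h-block curve; using max(h_grid)")
    h_star <- max(h_grid)
  } else {
    h_star <- h_grid[hit[1]]
  }
  list(h_star = h_star, curve = tibble(h = h_grid, median_scd = med),
       fossil_median = target)
}
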