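# Independent oracles and shared fixtures for the test suite.

# Brute-force radiocarbon calibration by quadrature on a 1-yr grid,
# independent of calibrate_c14's internals.
quad_calibrate <- function(age14c, sigma, curve) {
  grid <- seq(min(curve$cal_bp), max(curve$cal_bp), by = 1)
  mu <- approx(curve$cal_bp, curve$c14_bp, grid)$y
  cs <- approx(curve$cal_bp, curve$sigma, grid)$y
  dens <- dnorm(age14c, mu, sqrt(sigma^2 + cs^2))
  dens <- dens / sum(dens)
  mean_ <- sum(grid * dens)
  list(point_age = mean_, age_sd = sqrt(sum((grid - mean_)^2 * dens)))
}

# Plain two-step weighted averaging with inverse deshrinking: species
# optima as abundance-weighted means of x, initial site estimates as
# weighted means of optima, then regression of x on the initial estimates.
wa_oracle <- function(y, x) {
  opt <- colSums(y * x) / colSums(y)
  init <- as.numeric(y %*% opt) / rowSums(y)
  fit <- lm(x ~ init)
  list(
    fitted = unname(fitted(fit)),
    predict = function(ynew) {
      init_new <- as.numeric(ynew %*% opt) / rowSums(ynew)
      unname(coef(fit)[1] + coef(fit)[2] * init_new)
    }
  )
}

# Small deterministic calibration set: sites on a lat transect, climates a
# linear function of latitude, features = softmax-like niche responses
# evaluated exactly (no sampling noise).
toy_calib <- function(n = 24, n_taxa = 6, feature_kind = "taxa") {
  lat <- seq(30, 70, length.out = n)
  lon <- seq(-120, 60, length.out = n)
  mtco <- 10 - 0.6 * (lat - 30)
  mtwa <- 26 - 0.25 * (lat - 30)
  opt <- seq(min(mtco), max(mtco), length.out = n_taxa)
  feats <- sapply(opt, function(o) exp(-(mtco - o)^2 / 50))
  feats <- feats / rowSums(feats)
  colnames(feats) <- paste0("t", seq_len(n_taxa))
  calibration_set(
    site_table(sprintf("s%02d", seq_len(n)), lat, lon, elev = 0),
    feats,
    tibble::tibble(annt = (mtco + mtwa) / 2, mtwa = mtwa, mtco = mtco),
    feature_kind = feature_kind
  )
}

# Climate grid with temperature an exact linear function of elevation,
# T_m(cell) = base_m - lapse * elev; used for lapse-rate recovery.
lapse_grid <- function(lapse = 0.0065, base = 20) {
  lat <- seq(40, 50, by = 1)
  lon <- seq(0, 10, by = 1)
  elev <- outer(lat, lon, function(a, b) 100 * (a - 40) + 20 * b)
  temp <- array(NA_real_, c(12, length(lat), length(lon)))
  for (m in 1:12) temp[m, , ] <- base + m - lapse * elev
  climate_grid(lat, lon, elev, temp)
}

# Minimal recon_series tibble for stacking tests.
toy_recon <- function(ages, estimate, sample_error, variable = "mtco") {
  structure(
    tibble::tibble(sample_id = as.character(seq_along(ages)), age = ages,
                   variable = variable, estimate = estimate,
                   sample_error = sample_error),
    corrected = FALSE,
    class = c("recon_series", class(tibble::tibble()))
  )
}
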