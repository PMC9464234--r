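test_that("noiseless records bin exactly to their anomalies", {
  ages <- seq(100, 10900, by = 200)
  vals <- sin(ages / 2000)
  rec <- toy_recon(ages, vals, rep(0, length(ages)))
  b <- to_binned(rec, "mtco", n_mc = 50, seed = 1)
  ref <- mean(vals[ages <= 1000])
  expect_equal(b$anomaly, vals - ref, tolerance = 1e-12)
  expect_equal(b$bin_sd, rep(0, nrow(b)))
  # constant series: all anomalies zero
  bc <- to_binned(toy_recon(ages, rep(3, length(ages)), rep(0, length(ages))),
                  "mtco", n_mc = 50, seed = 1)
  expect_equal(bc$anomaly, rep(0, nrow(bc)))
})

test_that("binned medians track the noiseless interpolation within 2 se", {
  ages <- c(150, 900, 2300, 4100, 6050, 8200, 10600)
  vals <- c(0, 0.3, 1.2, 2.0, 2.6, 1.1, -1.5)
  rec <- toy_recon(ages, vals, rep(0.4, length(ages)))
  b <- to_binned(rec, "mtco", n_mc = 2000, seed = 2)
  ref <- mean(vals[ages <= 1000])
  oracle <- approx(ages, vals, b$bin_center)$y - ref
  expect_true(all(abs(b$anomaly - oracle) <= 2 * b$bin_sd + 1e-9))
  expect_error(to_binned(toy_recon(c(2000, 9000), c(1, 2), c(0.1, 0.1)),
                         "mtco", 10, 1),
               "reference window")
})

test_that("grid averaging follows cell membership conventions", {
  ages <- seq(100, 1100, 200)
  mk <- function(lat, lon, val) {
    b <- to_binned(toy_recon(ages, rep(val, 6), rep(0, 6)), "mtco", 10, 1,
                   ref_age = 2000)
    attr(b, "site") <- tibble::tibble(lat = lat, lon = lon)
    b
  }
  # one site per cell: cell series equal site series (anomalies are zero
  # here, so use two sites per cell with opposite anomalies instead)
  b1 <- mk(45.5, 10.5, 0); b2 <- mk(45.9, 10.1, 0)
  b1$anomaly <- rep(1, 6); b2$anomaly <- rep(-1, 6)
  cells <- grid_average(list(b1, b2))
  expect_equal(nrow(cells), 6)
  expect_equal(cells$anomaly, rep(0, 6))
  expect_equal(cells$n_sites, rep(2L, 6))
  # a site exactly on a cell edge joins the higher-index cell only
  be <- mk(46, 10.5, 0)
  cells2 <- grid_average(list(b1, be))
  expect_setequal(unique(cells2$cell_lat), c(45, 47))
})

test_that("composites propagate errors with the expected band width", {
  ages <- seq(100, 10900, 200)
  n_sites <- 25
  sigma <- 0.8
  bs <- lapply(seq_len(n_sites), function(j) {
    b <- to_binned(toy_recon(ages, rep(0, length(ages)),
                             rep(0, length(ages))), "mtco", 10, j)
    b$bin_sd <- rep(sigma, nrow(b))
    attr(b, "site") <- tibble::tibble(lat = 30 + 2 * (j %% 5),
                                      lon = 10 + 2 * (j %/% 5))
    b
  })
  cells <- grid_average(bs)
  cmp <- composite(cells, n_mc = 2000, seed = 3)
  n_cells <- length(unique(paste(cells$cell_lat, cells$cell_lon)))
  half <- (cmp$upper95 - cmp$lower95) / 2
  expected <- 1.96 * sigma / sqrt(n_cells)
  expect_equal(mean(half), expected, tolerance = 0.1)
  expect_true(all(cmp$n_cells == n_cells))
  # single cell with zero error: the composite is that series exactly
  one <- grid_average(bs[1])
  one$se <- 0
  c1 <- composite(one, n_mc = 10, seed = 4)
  expect_equal(c1$median, one$anomaly)
  expect_equal(c1$upper95 - c1$lower95, rep(0, nrow(c1)))
  expect_error(composite(cells, region = "N_AS"), "no grid cells")
})

test_that("composites are invariant to site ordering", {
  ages <- seq(100, 10900, 200)
  set.seed(5)
  bs <- lapply(1:8, function(j) {
    b <- to_binned(toy_recon(ages, rnorm(length(ages)),
                             rep(0.2, length(ages))), "mtco", 50, 10 + j)
    attr(b, "site") <- tibble::tibble(lat = 30 + 3 * j, lon = 15)
    b
  })
  a <- composite(grid_average(bs), n_mc = 200, seed = 6)
  b <- composite(grid_average(rev(bs)), n_mc = 200, seed = 6)
  expect_equal(a$median, b$median, tolerance = 1e-12)
  expect_equal(a$n_cells, b$n_cells)
})

test_that("seasonality subtracts aligned composites with quadrature bands", {
  bins <- seq(100, 10900, 200)
  mk_cmp <- function(med, hw) {
    structure(tibble::tibble(bin_center = bins, median = med,
                             lower95 = med - hw, upper95 = med + hw,
                             n_cells = 5L),
              class = c("composite_curve", class(tibble::tibble())))
  }
  s <- mk_cmp(rep(2, length(bins)), 0.3)
  w <- mk_cmp(seq(0, 1, length.out = length(bins)), 0.4)
  d <- seasonality(s, w)
  expect_equal(d$median, 2 - seq(0, 1, length.out = length(bins)))
  expect_equal(d$upper95 - d$median, rep(sqrt(0.3^2 + 0.4^2), length(bins)))
  # identical curves difference to zero
  expect_equal(seasonality(s, s)$median, rep(0, length(bins)))
  w_bad <- w[-1, ]
  expect_error(seasonality(s, w_bad), "misaligned")
})

test_that("trend rates follow the warming-toward-present convention", {
  bins <- seq(100, 10900, 200)
  # temperature falls by 0.5 degC per ka of age: warming toward present
  lin <- structure(tibble::tibble(bin_center = bins,
                                  median = -0.5 * bins / 1000,
                                  lower95 = NA, upper95 = NA, n_cells = 1L),
                   class = c("composite_curve", class(tibble::tibble())))
  tr <- fit_trend(lin, c(0, 11))
  expect_equal(tr$rate, 0.5, tolerance = 1e-12)
  cst <- lin; cst$median <- rep(1, length(bins))
  expect_equal(fit_trend(cst, c(0, 11))$rate, 0)
  expect_error(fit_trend(lin, c(0, 0.3)), "fewer than 3 bins")
})

test_that("noisy trends are recovered within two standard errors", {
  set.seed(7)
  bins <- seq(100, 10900, 200)
  truth_rate <- 0.22
  med <- -truth_rate * bins / 1000 + rnorm(length(bins), 0, 0.15)
  cur <- structure(tibble::tibble(bin_center = bins, median = med,
                                  lower95 = NA, upper95 = NA, n_cells = 1L),
                   class = c("composite_curve", class(tibble::tibble())))
  tr <- fit_trend(cur, c(0, 11))
  expect_lt(abs(tr$rate - truth_rate), 2 * tr$se)
})
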