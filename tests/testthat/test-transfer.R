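test_that("squared chord distance matches hand values", {
  expect_equal(scd(c(0.5, 0.5), c(0.5, 0.5)), 0)
  expect_equal(scd(c(1, 0), c(0, 1)), 2)
  expect_equal(scd(c(0.5, 0.5), c(0.25, 0.75)),
               (sqrt(0.5) - sqrt(0.25))^2 + (sqrt(0.5) - sqrt(0.75))^2,
               tolerance = 1e-12)
  expect_lt(abs(scd(c(0.5, 0.5), c(0.25, 0.75)) - 0.0681), 1e-4)
  expect_error(scd(c(-0.1, 1.1), c(0.5, 0.5)), "non-negative")
  expect_error(scd(c(1), c(0.5, 0.5)), "equal length")
})

test_that("scd is a metric on the simplex", {
  set.seed(1)
  for (i in 1:50) {
    p <- to_proportions(matrix(runif(4), 1))[1, ]
    q <- to_proportions(matrix(runif(4), 1))[1, ]
    r <- to_proportions(matrix(runif(4), 1))[1, ]
    expect_equal(scd(p, q), scd(q, p), tolerance = 1e-12)
    expect_equal(scd(p, p), 0)
    # triangle inequality holds for the chord distance sqrt(scd)
    expect_lte(sqrt(scd(p, r)), sqrt(scd(p, q)) + sqrt(scd(q, r)) + 1e-12)
  }
})

test_that("scd_matrix agrees with the pairwise definition", {
  set.seed(2)
  A <- matrix(runif(12), 3, 4)
  B <- matrix(runif(8), 2, 4)
  D <- scd_matrix(A, B)
  An <- A / rowSums(A); Bn <- B / rowSums(B)
  for (i in 1:3) for (j in 1:2) {
    expect_equal(D[i, j], scd(An[i, ], Bn[j, ]), tolerance = 1e-12)
  }
})

test_that("MAT predictions are dissimilarity-weighted analogue means", {
  calib <- toy_calib()
  # k = 1: the nearest sample's climate exactly
  target <- calib$features[5, , drop = FALSE] + 0
  p1 <- mat_predict(target, calib, k = 1)
  expect_equal(p1$estimate[p1$variable == "mtco"], calib$climate$mtco[5])
  expect_equal(p1$min_scd[1], 0)
  # hand oracle sum(c/d) / sum(1/d) on fixed distances
  m <- pollenclim:::mat_from_distances(
    c(0.02, 0.04, 0.08, 1, 1), matrix(c(-10, -6, -2, 0, 0)), k = 3)
  expect_equal(m$est, -7.714286, tolerance = 1e-3)
  # two analogues at equal distance average their climates
  m2 <- pollenclim:::mat_from_distances(c(0.1, 0.1, 5), matrix(c(4, 8, 0)), 2)
  expect_equal(m2$est, 6)
})

test_that("MAT estimates stay inside the analogue climate hull", {
  calib <- toy_calib()
  set.seed(3)
  target <- matrix(runif(30), 5, 6)
  colnames(target) <- colnames(calib$features)
  pr <- mat_predict(target, calib, k = 6, scd_max = Inf)
  for (i in seq_len(nrow(target))) {
    sub <- pr[pr$row == i & pr$variable == "mtco", ]
    idx <- sub$analogues[[1]]
    expect_gte(sub$estimate, min(calib$climate$mtco[idx]) - 1e-12)
    expect_lte(sub$estimate, max(calib$climate$mtco[idx]) + 1e-12)
  }
})

test_that("no-analogue samples are flagged and withheld", {
  calib <- toy_calib()
  odd <- matrix(c(rep(0, 5), 1), 1)  # all mass on the rarest feature
  colnames(odd) <- colnames(calib$features)
  pr <- mat_predict(odd, calib, k = 3, scd_max = 0.05)
  expect_true(all(pr$no_analogue))
  expect_true(all(is.na(pr$estimate)))
  expect_error(mat_predict(odd, calib, exclude = rep(TRUE, 24)), "excluded")
})

test_that("bootstrap errors combine boot spread with RMSEP", {
  # degenerate calibration: every sample identical -> all resampled
  # predictions equal -> sample_error reduces to the rmsep term
  feats <- matrix(rep(c(0.5, 0.5), each = 12), 12, 2)
  calib <- calibration_set(
    site_table(paste0("s", 1:12), seq(40, 51, 1), seq(0, 11, 1), 0),
    feats,
    tibble::tibble(annt = rep(5, 12), mtwa = rep(15, 12), mtco = rep(-5, 12)),
    "taxa")
  be0 <- bootstrap_error(matrix(c(0.5, 0.5), 1), calib, k = 3, rmsep = 0,
                         seed = 1)
  expect_equal(be0$sample_error, rep(0, 3))
  be4 <- bootstrap_error(matrix(c(0.5, 0.5), 1), calib, k = 3, rmsep = 0.4,
                         seed = 1)
  expect_equal(be4$sample_error, rep(0.4, 3))

  # reproducible under a fixed seed; monotone in rmsep
  calib2 <- toy_calib()
  tg <- calib2$features[7, , drop = FALSE] * 0.9 + 0.01
  a <- bootstrap_error(tg, calib2, k = 4, rmsep = 0.2, seed = 42)
  b <- bootstrap_error(tg, calib2, k = 4, rmsep = 0.2, seed = 42)
  expect_equal(a, b)
  c2 <- bootstrap_error(tg, calib2, k = 4, rmsep = 0.6, seed = 42)
  expect_true(all(c2$sample_error > a$sample_error))
})

test_that("WA-PLS with one component equals two-step weighted averaging", {
  calib <- toy_calib()
  y <- calib$features
  x <- calib$climate$mtco
  fit <- wapls_fit(y, x, n_comp = 1)
  or <- wa_oracle(y, x)
  expect_equal(predict(fit, y), or$fitted, tolerance = 1e-10)
  set.seed(4)
  ynew <- matrix(runif(12), 2, 6)
  expect_equal(predict(fit, ynew), or$predict(ynew), tolerance = 1e-10)
})

test_that("WA-PLS self-prediction R2 is non-decreasing in components", {
  calib <- toy_calib()
  y <- calib$features
  set.seed(21)
  x <- calib$climate$mtco + rnorm(nrow(y), 0, 0.5)
  r2 <- vapply(1:4, function(a) {
    cor(predict(wapls_fit(y, x, n_comp = a), y), x)^2
  }, numeric(1))
  expect_true(all(diff(r2) >= -1e-10))
  expect_error(wapls_fit(y, x, n_comp = 6), "feasible rank")
  expect_error(wapls_fit(y, x, n_comp = 2, deshrink = "classical"),
               "n_comp = 1")
})

test_that("WA-PLS recovers a noiseless Gaussian-niche gradient", {
  set.seed(5)
  n <- 300
  x <- seq(-5, 25, length.out = n)
  opt <- seq(-6, 26, length.out = 12)
  y <- sapply(opt, function(o) exp(-(x - o)^2 / 18))
  y <- y / rowSums(y)
  fit <- wapls_fit(y, x, n_comp = 3)
  expect_gt(cor(predict(fit, y), x), 0.95)
})

test_that("cross-validation: h = 0 h-block is exactly leave-one-out", {
  calib <- toy_calib()
  loo <- cross_validate(calib, "mat", "loo", k = 4)
  hb <- cross_validate(calib, "mat", "h_block", h = 0, k = 4)
  expect_equal(attr(loo, "predictions")$predicted,
               attr(hb, "predictions")$predicted)
  expect_equal(loo$r2, hb$r2)
})

test_that("duplicated sites give a perfect 1-NN leave-one-out", {
  base <- toy_calib()
  feats <- rbind(base$features, base$features)
  sites <- dplyr::bind_rows(base$sites, base$sites)
  sites$site_id <- paste0(sites$site_id, rep(c("", "_dup"), each = 24))
  clim <- dplyr::bind_rows(base$climate, base$climate)
  dup <- calibration_set(sites, feats, clim, "taxa")
  cv <- cross_validate(dup, "mat", "loo", k = 1)
  expect_equal(cv$r2, rep(1, 3), tolerance = 1e-12)
  expect_equal(cv$rmsep, rep(0, 3), tolerance = 1e-12)
})

test_that("WA-PLS cross-validates through the same interface", {
  calib <- toy_calib()
  cv <- cross_validate(calib, "wapls", "loo", n_comp = 2,
                       variables = "mtco")
  expect_gt(cv$r2, 0.9)
})

test_that("h-block exclusion can only worsen the nearest analogue", {
  set.seed(6)
  field <- make_climate_field(n_lat = 20, n_lon = 24, corr_target = 0.5,
                              seed = 11)
  niches <- make_niches(12, range(field$cells$mtco), range(field$cells$mtwa),
                        seed = 12)
  calib <- make_calibration_set(80, field, niches, seed = 13,
                                clustered = TRUE, feature_kind = "taxa")
  sel <- select_h(calib, fossil_min_scds = rep(0.05, 10),
                  h_grid = seq(0, 1000, 250))
  expect_true(all(diff(sel$curve$median_scd) >= -1e-12))
})

test_that("select_h picks the boundary radii per contract", {
  calib <- toy_calib()
  sel_lo <- select_h(calib, fossil_min_scds = rep(1e-6, 5),
                     h_grid = c(0, 200, 400))
  expect_equal(sel_lo$h_star, 0)
  expect_warning(
    sel_hi <- select_h(calib, fossil_min_scds = rep(5, 5),
                       h_grid = c(0, 200, 400)),
    "max\\(h_grid\\)")
  expect_equal(sel_hi$h_star, 400)
  expect_error(select_h(calib, numeric(0)), "fossil")
})

test_that("significance test honours its boundary contracts", {
  calib <- toy_calib()
  set.seed(7)
  Yf <- matrix(runif(60), 10, 6)
  colnames(Yf) <- colnames(calib$features)
  # the fossil matrix's own first PC is the best single constraint
  pc1 <- prcomp(scale(Yf))$x[, 1]
  s <- significance_test(Yf, pc1, calib, "mtco", n_rand = 49, seed = 8)
  expect_true(s$pass)
  expect_gt(s$observed_var, max(s$null_var))
  # quantile = 1: pass only if observed exceeds every null value
  s1 <- significance_test(Yf, pc1, calib, "mtco", n_rand = 49,
                          quantile = 1, seed = 8)
  expect_equal(s1$threshold, max(s1$null_var))
  # constant reconstructions can never pass
  s0 <- significance_test(Yf, rep(1, 10), calib, "mtco", n_rand = 9, seed = 9)
  expect_equal(s0$observed_var, 0)
  expect_false(s0$pass)
})

test_that("reconstruction output is tidy and bounded by the calibration", {
  calib <- toy_calib()
  set.seed(10)
  feats <- calib$features[c(3, 9, 15), ] * 0.95 + 0.005
  rec <- reconstruct(feats, c(500, 5000, 9500), calib, k = 4,
                     n_boot = 20, rmsep = 0.3, seed = 1)
  expect_s3_class(rec, "recon_series")
  expect_equal(nrow(rec), 9)
  expect_true(all(rec$sample_error > 0))
  expect_true(all(rec$min_scd >= 0))
  expect_false(isTRUE(attr(rec, "corrected")))
})
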