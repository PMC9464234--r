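test_that("generators are pure functions of their seeds", {
  f1 <- make_climate_field(n_lat = 20, n_lon = 24, corr_target = 0.5, seed = 3)
  f2 <- make_climate_field(n_lat = 20, n_lon = 24, corr_target = 0.5, seed = 3)
  expect_identical(f1, f2)
  niches <- make_niches(10, c(-30, 10), c(5, 28), seed = 4)
  site <- site_table("r", 50, 10, 100)
  clim <- tibble::tibble(annt = 0, mtwa = 14, mtco = -14)
  curve <- make_calib_curve("wiggly")
  r1 <- make_fossil_record(site, clim, holocene_truth(), curve, niches,
                           n_samples = 20, seed = 5)
  r2 <- make_fossil_record(site, clim, holocene_truth(), curve, niches,
                           n_samples = 20, seed = 5)
  expect_identical(r1$counts, r2$counts)
  expect_identical(r1$samples, r2$samples)
})

test_that("climate fields hit the requested MTCO-MTWA correlation", {
  f0 <- make_climate_field(n_lat = 30, n_lon = 36, corr_target = 0,
                           seed = 3)
  expect_lt(abs(f0$achieved_r), 0.05)
  # upper end of the observed regional correlation range
  f76 <- make_climate_field(n_lat = 30, n_lon = 36, corr_target = 0.76,
                            seed = 3)
  expect_gte(f76$achieved_r, 0.71)
  expect_lte(f76$achieved_r, 0.81)
  # physical ordering holds everywhere
  expect_true(all(f0$cells$mtco <= f0$cells$annt))
  expect_true(all(f0$cells$annt <= f0$cells$mtwa))
  expect_error(make_climate_field(corr_target = 1), "corr_target")
})

test_that("multinomial sampling follows the niche probabilities", {
  niches <- make_niches(8, c(-30, 10), c(5, 28), seed = 6)
  clim <- c(mtco = -10, mtwa = 16)
  # single taxon gets every grain
  one <- niches[3, ]
  cnt1 <- sample_counts(clim, one, total_count = 57, seed = 1)
  expect_equal(unname(cnt1), 57L)
  # a taxon at its joint optimum dominates when the others are far away
  tight <- niches
  tight$tolerance_mtco <- 0.5
  tight$tolerance_mtwa <- 0.5
  at_opt <- c(mtco = tight$optimum_mtco[2], mtwa = tight$optimum_mtwa[2])
  cnt2 <- sample_counts(at_opt, tight, total_count = 1000, seed = 2)
  expect_gt(cnt2[2] / 1000, 0.99)
  # law of large numbers: empirical proportions approach expectations
  p <- pollenclim:::niche_probs(clim["mtco"], clim["mtwa"], niches)
  cnt3 <- sample_counts(clim, niches, total_count = 10000, seed = 3)
  expect_lt(max(abs(cnt3 / 10000 - p)), 4 * sqrt(max(p * (1 - p)) / 10000))
})

test_that("synthetic calibration curves stay invertible", {
  wig <- make_calib_curve("wiggly")
  expect_true(all(diff(wig$c14_bp) > 0))
  expect_error(make_calib_curve("wiggly", amplitude = 500, period = 1200),
               "non-monotone")
})

test_that("topographic anomalies decay to zero at present", {
  tf <- make_topo_field(decay_halflife = 2, max_anomaly = 150)
  expect_true(all(tf$anomaly[1, , ] == 0))
  # anomaly grows monotonically with age at every node
  expect_true(all(apply(tf$anomaly, c(2, 3), function(v) all(diff(v) >= 0))))
  # infinite halflife: constant (zero) anomaly at all times
  tf_inf <- make_topo_field(decay_halflife = 1e9, max_anomaly = 150)
  expect_lt(max(abs(tf_inf$anomaly)), 1e-4)
})

test_that("clustered site placement raises spatial autocorrelation", {
  field <- make_climate_field(n_lat = 20, n_lon = 24, corr_target = 0.5,
                              seed = 8)
  niches <- make_niches(10, range(field$cells$mtco), range(field$cells$mtwa),
                        seed = 9)
  moran <- function(calib) {
    z <- calib$climate$mtco - mean(calib$climate$mtco)
    s <- calib$sites
    d <- outer(seq_len(nrow(s)), seq_len(nrow(s)), function(i, j) {
      pollenclim:::haversine_km(s$lat[i], s$lon[i], s$lat[j], s$lon[j])
    })
    w <- 1 / (d + 50)
    diag(w) <- 0
    nrow(s) / sum(w) * sum(w * outer(z, z)) / sum(z^2)
  }
  cal_u <- make_calibration_set(60, field, niches, seed = 10,
                                feature_kind = "taxa")
  cal_c <- make_calibration_set(60, field, niches, seed = 10,
                                clustered = TRUE, feature_kind = "taxa")
  expect_gt(moran(cal_c), moran(cal_u))
  expect_error(make_calibration_set(0, field, niches), "n_sites")
})

test_that("default fossil records pass the screening rules", {
  field <- make_climate_field(n_lat = 20, n_lon = 24, corr_target = 0.5,
                              seed = 11)
  niches <- make_niches(12, range(field$cells$mtco), range(field$cells$mtwa),
                        seed = 12)
  curve <- make_calib_curve("wiggly")
  site <- site_table("r", 50, 10, 100)
  clim <- assign_site_climate(site, field$grid)
  rec <- make_fossil_record(site, clim, holocene_truth(), curve, niches,
                            seed = 13)
  expect_true(screen_record(rec, site$region_id)$pass)
  keep <- screen_samples(rec$age_model, rec$counts)
  expect_gt(mean(keep), 0.9)
  # modelled ages stay close to the true ages
  expect_lt(median(abs(rec$samples$age - rec$samples$age_true)), 150)
})

test_that("the truth history keeps annual between winter and summer", {
  tr <- holocene_truth()(seq(0, 11000, by = 100))
  expect_true(all(tr$annt_anom >= pmin(tr$mtco_anom, tr$mtwa_anom)))
  expect_true(all(tr$annt_anom <= pmax(tr$mtco_anom, tr$mtwa_anom)))
  # anomalies vanish at present and peak at 7 ka
  tr0 <- holocene_truth()(0)
  expect_equal(unlist(tr0), c(mtco_anom = 0, mtwa_anom = 0, annt_anom = 0))
  tr7 <- holocene_truth()(7000)
  expect_equal(tr7$mtco_anom, 0.7)
  expect_equal(tr7$mtwa_anom, 0.5)
  tr11 <- holocene_truth()(11000)
  expect_equal(tr11$mtco_anom, 0.7 - 4.1)
})

test_that("exotic samples create no-analogue situations on demand", {
  field <- make_climate_field(n_lat = 20, n_lon = 24, corr_target = 0.5,
                              seed = 14)
  niches <- make_niches(12, range(field$cells$mtco), range(field$cells$mtwa),
                        seed = 15)
  pm <- make_pft_matrix(niches, seed = 16)
  calib <- make_calibration_set(150, field, niches, seed = 17,
                                feature_kind = "pft", pft_matrix = pm)
  curve <- make_calib_curve("identity")
  site <- site_table("r", 50, 10, 100)
  clim <- assign_site_climate(site, field$grid)
  rec <- make_fossil_record(site, clim, holocene_truth(), curve, niches,
                            exotic_fraction = 0.5, seed = 18)
  feats <- record_features(rec, pm)
  pr <- mat_predict(feats, calib, k = 6, scd_max = 0.2)
  expect_gt(sum(pr$no_analogue), 0)
})
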