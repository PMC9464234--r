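test_that("calibration recovers identity and linear synthetic curves", {
  ident <- make_calib_curve("identity")
  cc <- calibrate_c14(5000, 50, ident)
  expect_equal(cc$point_age, 5000, tolerance = 1e-6)
  expect_equal(cc$age_sd, 50, tolerance = 1e-3)

  lin <- make_calib_curve("linear", slope = 0.9)
  expect_equal(calibrate_c14(4500, 45, lin)$point_age, 5000, tolerance = 1e-6)
})

test_that("calibration posterior matches quadrature and integrates to 1", {
  wig <- make_calib_curve("wiggly")
  for (case in list(c(4000, 60), c(8000, 120), c(2500, 35))) {
    cc <- calibrate_c14(case[1], case[2], wig)
    oracle <- quad_calibrate(case[1], case[2], wig)
    expect_lt(abs(cc$point_age - oracle$point_age), 0.1)
    # trapezoidal integral of the returned density
    d <- cc$density
    dx <- diff(d$cal_bp)
    integral <- sum((d$density[-1] + d$density[-nrow(d)]) / 2 * dx)
    expect_equal(integral, 1, tolerance = 1e-9)
  }
})

test_that("calibration is translation-equivariant under a constant offset", {
  wig <- make_calib_curve("wiggly")
  shifted <- pollenclim:::new_calib_curve(
    tibble::tibble(cal_bp = wig$cal_bp, c14_bp = wig$c14_bp + 250,
                   sigma = wig$sigma))
  a <- calibrate_c14(4000, 50, wig)$point_age
  b <- calibrate_c14(4250, 50, shifted)$point_age
  expect_equal(a, b, tolerance = 1e-6)
})

test_that("calibration rejects dates beyond curve support", {
  ident <- make_calib_curve("identity", span = c(0, 6000))
  expect_error(calibrate_c14(6500, 50, ident), "beyond calibration-curve support")
  expect_error(calibrate_c14(3000, -1, ident), "sigma")
})

test_that("age models interpolate linearly and flag samples", {
  curve <- make_calib_curve("identity")
  controls <- tibble::tibble(
    depth = c(0, 100), kind = "calendar", age = c(0, 10000),
    sigma = 10, independent = TRUE)
  m <- build_age_model(controls, c(0, 50, 120), curve)
  expect_equal(m$age, c(0, 5000, 12000))
  expect_equal(m$flag, c("direct", "interpolated", "extrapolated"))

  controls3 <- tibble::tibble(
    depth = c(0, 40, 100), kind = "calendar", age = c(0, 3000, 10500),
    sigma = 10, independent = TRUE)
  m3 <- build_age_model(controls3, 70, curve)
  # hand oracle: two-point interpolation between the 2nd and 3rd controls
  expect_equal(m3$age, 3000 + (70 - 40) / (100 - 40) * (10500 - 3000))

  rev <- tibble::tibble(
    depth = c(0, 50, 100), kind = "calendar", age = c(0, 8000, 6000),
    sigma = 10, independent = TRUE)
  expect_error(build_age_model(rev, 25, curve), "age reversal")
  expect_error(build_age_model(controls[1, ], 25, curve), "at least 2")
})

test_that("radiocarbon controls are calibrated inside the age model", {
  lin <- make_calib_curve("linear", slope = 0.9)
  controls <- tibble::tibble(
    depth = c(0, 100),
    kind = c("core_top", "c14"),
    age = c(0, 9000),      # 9000 14C yr on the 0.9 curve -> 10000 cal yr
    sigma = c(30, 50), independent = c(FALSE, TRUE))
  m <- build_age_model(controls, 50, lin)
  expect_equal(m$age, 5000, tolerance = 1)
})

test_that("sample screening applies the dating and count rules", {
  curve <- make_calib_curve("identity")
  controls <- tibble::tibble(
    depth = c(0, 20, 90), kind = "calendar", age = c(0, 2000, 9000),
    sigma = 10, independent = TRUE)
  depths <- c(28, 55, 29)
  m <- build_age_model(controls, depths, curve)
  # ages: 2800 (800 yr from the 2000 control, bracketed by a 7000-yr pair),
  # 5500 (3500 from nearest, 7000-yr bracket), 2900 (900 from nearest)
  counts <- matrix(c(250, 250, 199), ncol = 1,
                   dimnames = list(c("a", "b", "c"), "Pinus"))
  keep <- screen_samples(m, counts)
  expect_equal(keep, c(TRUE, FALSE, FALSE))
  # second sample passes once the bracketing pair is within 6 kyr
  controls2 <- tibble::tibble(
    depth = c(0, 20, 75), kind = "calendar", age = c(0, 2000, 7500),
    sigma = 10, independent = TRUE)
  m2 <- build_age_model(controls2, 55, curve)
  expect_true(screen_samples(m2, matrix(250, dimnames = list("a", "Pinus"))))
  # screening is idempotent
  expect_equal(screen_samples(m, counts), keep)
})

test_that("record screening enumerates every failed criterion", {
  mk <- function(ages, n_ctl = 4, n_indep = 2) {
    list(samples = tibble::tibble(age = ages),
         controls = tibble::tibble(
           independent = rep(c(TRUE, FALSE),
                             c(n_indep, max(0, n_ctl - n_indep)))))
  }
  good <- mk(seq(300, 9300, by = 200))
  expect_true(screen_record(good, "W_EU")$pass)

  coarse <- mk(seq(300, 9300, by = 600))
  expect_false(screen_record(coarse, "W_EU")$pass)
  expect_match(screen_record(coarse, "W_EU")$reasons, "sampling interval")
  # the resolution limit relaxes to 1000 yr in northern Asia
  expect_true(screen_record(coarse, "N_AS")$pass)

  short <- mk(seq(300, 4800, by = 200))
  expect_match(screen_record(short, "W_EU")$reasons, "duration")

  old_top <- mk(seq(1500, 9500, by = 200))
  expect_match(screen_record(old_top, "W_EU")$reasons, "younger than")

  few <- mk(seq(300, 9300, by = 200), n_ctl = 3, n_indep = 1)
  rs <- screen_record(few, "W_EU")$reasons
  expect_length(rs, 2)
})

test_that("site climate assignment honours grid nodes and lapse rates", {
  g <- lapse_grid(lapse = 0.0065, base = 20)
  # exact node with matching elevation: the node's monthly statistics
  site <- tibble::tibble(site_id = "a", lat = 45, lon = 5,
                         elev = g$elev[6, 6])
  cl <- assign_site_climate(site, g)
  monthly <- g$temp[, 6, 6]
  expect_equal(cl$annt, mean(monthly))
  expect_equal(cl$mtwa, max(monthly))
  expect_equal(cl$mtco, min(monthly))

  # flat field: same value regardless of position
  flat <- climate_grid(g$lat, g$lon, matrix(0, 11, 11),
                       array(7, c(12, 11, 11)))
  cl2 <- assign_site_climate(tibble::tibble(lat = 42.3, lon = 3.7, elev = 0),
                             flat)
  expect_equal(unlist(cl2), c(annt = 7, mtwa = 7, mtco = 7))

  # site 100 m above the grid elevation: node value - 0.65 degC
  site_hi <- tibble::tibble(lat = 45, lon = 5, elev = g$elev[6, 6] + 100)
  cl3 <- assign_site_climate(site_hi, g, default_lapse = -0.0065)
  expect_equal(cl3$annt, cl$annt - 0.65)
  expect_equal(cl3$mtco, cl$mtco - 0.65)

  expect_error(assign_site_climate(tibble::tibble(lat = 80, lon = 5, elev = 0), g),
               "outside the grid")
})
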