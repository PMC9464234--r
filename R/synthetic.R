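# Seeded synthetic-data generators: Gaussian-niche taxa responding to
# winter (MTCO) and summer (MTWA) temperature, smooth correlated climate
# fields, sparse radiocarbon chronologies, and a glacio-isostatic
# elevation-anomaly field. Every generator is a pure function of its seed.

#' Generate a synthetic radiocarbon calibration curve
#'
#' `identity` maps calendar to radiocarbon age one-to-one with zero curve
#' error; `linear` uses a fixed slope; `wiggly` adds a bounded sinusoid to
#' a monotone baseline, erroring if the requested amplitude would break
#' invertibility.
#'
#' @param kind Curve shape.
#' @param span `c(min, max)` calendar range (cal yr BP).
#' @param step Grid step (yr).
#' @param slope Baseline slope of the `linear`/`wiggly` kinds.
#' @param amplitude,period Sinusoid parameters of the `wiggly` kind (yr).
#' @param sigma Constant one-sigma curve error (yr; 0 for `identity`).
#' @return A `calib_curve` tibble.
#' @export
make_calib_curve <- function(kind = c("identity", "linear", "wiggly"),
                             span = c(0, 15000), step = 5, slope = 0.9,
                             amplitude = 80, period = 1200, sigma = 20) {
  kind <- match.arg(kind)
  cal <- seq(span[1], span[2], by = step)
  c14 <- switch(kind,
    identity = cal,
    linear = slope * cal,
    wiggly = {
      if (amplitude * 2 * pi / period >= slope) {
        abort("wiggly curve would be non-monotone; reduce amplitude or increase period")
      }
      slope * cal + amplitude * sin(2 * pi * cal / period)
    })
  new_calib_curve(tibble(cal_bp = cal, c14_bp = c14,
                         sigma = if (kind == "identity") 0 else sigma))
}

#' Generate a glacio-isostatic topographic-anomaly field
#'
#' A spatially localised Gaussian bump (ice-margin analogue) whose
#' amplitude decays exponentially toward the present:
#' `anomaly(t) = max_anomaly * bump(lat, lon) * (1 - 2^(-t / halflife))`,
#' exactly 0 at `t = 0`.
#'
#' @param decay_halflife Halflife of the decay (ka).
#' @param max_anomaly Asymptotic bump amplitude (m).
#' @param lat,lon Grid axes (degrees).
#' @param times_ka Time axis (ka BP; must include 0).
#' @param center `c(lat, lon)` of the bump.
#' @param width Bump standard deviation (degrees).
#' @return A `topo_field`.
#' @export
make_topo_field <- function(decay_halflife = 2.5, max_anomaly = 200,
                            lat = seq(21, 77, by = 2),
                            lon = seq(-179, 179, by = 4),
                            times_ka = seq(0, 11, by = 0.5),
                            center = c(60, -75), width = 18) {
  bump <- outer(lat, lon, function(la, lo) {
    exp(-((la - center[1])^2 + (normalize_lon(lo - center[2]))^2) /
          (2 * width^2))
  })
  decay <- 1 - 2^(-times_ka / decay_halflife)
  anom <- array(0, c(length(times_ka), length(lat), length(lon)))
  for (t in seq_along(times_ka)) anom[t, , ] <- max_anomaly * decay[t] * bump
  topo_field(times_ka, lat, lon, anom)
}

# Standardised smooth random field: a sum of Gaussian bumps with random
# centres, widths and signs, normalised to mean 0 / sd 1 over the grid.
smooth_bump_field <- function(lat, lon, n_bumps = 8) {
  f <- matrix(0, length(lat), length(lon))
  for (b in seq_len(n_bumps)) {
    c_lat <- runif(1, min(lat), max(lat))
    c_lon <- runif(1, min(lon), max(lon))
    w_lat <- runif(1, 10, 30)
    w_lon <- runif(1, 20, 60)
    s <- sample(c(-1, 1), 1)
    f <- f + s * outer(lat, lon, function(la, lo) {
      exp(-((la - c_lat)^2 / (2 * w_lat^2) +
              (normalize_lon(lo - c_lon))^2 / (2 * w_lon^2)))
    })
  }
  (f - mean(f)) / sd(f)
}

#' Generate a synthetic modern climate field
#'
#' Smooth latitudinal MTCO and MTWA fields (gradient + random Gaussian
#' bumps) over a regular grid, with an elevation field whose lapse-rate
#' imprint (-6.5 degC/km) is shared by both variables. The MTWA field is a
#' mixture of the MTCO structure and an independent smooth field; the
#' mixing weight is tuned by bisection until the sample Pearson correlation
#' between the final per-cell MTCO and MTWA matches `corr_target` within
#' +/- 0.05 (error after `max_attempts` failures). ANNT is the mean of a
#' sinusoidal monthly cycle between MTCO (January) and MTWA (July), so
#' `mtco <= annt <= mtwa` holds by construction.
#'
#' @param n_lat,n_lon Grid dimensions.
#' @param corr_target Target Pearson correlation between MTCO and MTWA in
#'   \[0, 1).
#' @param seed Integer seed (the field is a pure function of it).
#' @param lat_range,lon_range Domain bounds (degrees).
#' @param mtco_mean,mtco_sd,mtwa_mean,mtwa_sd Field scale parameters
#'   (degC).
#' @param max_attempts Bisection budget for the correlation tuning.
#' @return A list with `grid` (a [climate_grid()]), `cells` (tibble `lat`,
#'   `lon`, `elev`, `annt`, `mtwa`, `mtco`), `achieved_r` and the mixing
#'   weight `gamma`.
#' @export
make_climate_field <- function(n_lat = 55, n_lon = 72, corr_target = 0.6,
                               seed = 1, lat_range = c(22, 76),
                               lon_range = c(-178, 178),
                               mtco_mean = -10, mtco_sd = 10,
                               mtwa_mean = 17, mtwa_sd = 5,
                               max_attempts = 50) {
  if (corr_target < 0 || corr_target >= 1) abort("corr_target must lie in [0, 1)")
  set.seed(seed)
  lat <- seq(lat_range[1], lat_range[2], length.out = n_lat)
  lon <- seq(lon_range[1], lon_range[2], length.out = n_lon)
  z_lat <- matrix(rep(-(lat - mean(lat)) / sd(lat), length(lon)),
                  length(lat), length(lon))
  bump_c <- smooth_bump_field(lat, lon)
  bump_b <- smooth_bump_field(lat, lon)
  bump_e <- smooth_bump_field(lat, lon)
  elev <- (bump_e - min(bump_e)) * 300  # smooth, everywhere >= 0 with local relief
  mtco_z <- 1.2 * z_lat + 0.6 * bump_c
  mtco_z <- (mtco_z - mean(mtco_z)) / sd(mtco_z)
  mtco <- mtco_mean + mtco_sd * mtco_z - 0.0065 * elev
  build_mtwa <- function(gamma) {
    z <- gamma * mtco_z + sqrt(1 - gamma^2) * bump_b
    pmax(mtwa_mean + mtwa_sd * z - 0.0065 * elev, mtco + 1)
  }
  lo <- -0.999; hi <- 0.999
  gamma <- NA_real_
  for (i in seq_len(max_attempts)) {
    mid <- (lo + hi) / 2
    r <- cor(as.vector(mtco), as.vector(build_mtwa(mid)))
    if (abs(r - corr_target) <= 0.05) {
      gamma <- mid
      break
    }
    if (r < corr_target) lo <- mid else hi <- mid
  }
  if (is.na(gamma)) {
    abort(sprintf("could not reach correlation %.2f within %d attempts",
                  corr_target, max_attempts))
  }
  mtwa <- build_mtwa(gamma)
  achieved_r <- cor(as.vector(mtco), as.vector(mtwa))
  temp <- array(NA_real_, c(12, length(lat), length(lon)))
  mid_t <- (mtco + mtwa) / 2
  amp <- (mtwa - mtco) / 2
  for (m in 1:12) temp[m, , ] <- mid_t - amp * cos(2 * pi * (m - 1) / 12)
  grid <- climate_grid(lat, lon, elev, temp)
  cells <- expand.grid(lat = lat, lon = lon, KEEP.OUT.ATTRS = FALSE)
  list(grid = grid,
       cells = tibble(lat = cells$lat, lon = cells$lon,
                      elev = as.vector(elev), annt = as.vector(mid_t),
                      mtwa = as.vector(mtwa), mtco = as.vector(mtco)),
       achieved_r = achieved_r, gamma = gamma)
}

#' Generate Gaussian-niche parameters for synthetic taxa
#'
#' Optima tile the joint (MTCO, MTWA) climate range on a jittered grid with
#' overlapping tolerances, so no-analogue situations are rare at default
#' settings.
#'
#' @param n_taxa Number of taxa.
#' @param mtco_range,mtwa_range Climate ranges the optima must tile (degC).
#' @param seed Integer seed.
#' @param tol_range Uniform range of the niche tolerances (degC).
#' @return A tibble of class `niche_params`: `taxon`, `optimum_mtco`,
#'   `tolerance_mtco`, `optimum_mtwa`, `tolerance_mtwa`, `max_abundance`.
#' @export
make_niches <- function(n_taxa = 20, mtco_range = c(-35, 15),
                        mtwa_range = c(5, 30), seed = 1,
                        tol_range = c(5, 8)) {
  set.seed(seed)
  n_co <- ceiling(sqrt(n_taxa))
  n_wa <- ceiling(n_taxa / n_co)
  g <- expand.grid(
    co = seq(mtco_range[1], mtco_range[2], length.out = n_co),
    wa = seq(mtwa_range[1], mtwa_range[2], length.out = n_wa),
    KEEP.OUT.ATTRS = FALSE
  )[seq_len(n_taxa), ]
  structure(tibble(
    taxon = sprintf("taxon_%02d", seq_len(n_taxa)),
    optimum_mtco = g$co + runif(n_taxa, -2, 2),
    tolerance_mtco = runif(n_taxa, tol_range[1], tol_range[2]),
    optimum_mtwa = g$wa + runif(n_taxa, -2, 2),
    tolerance_mtwa = runif(n_taxa, tol_range[1], tol_range[2]),
    max_abundance = runif(n_taxa, 0.5, 1.5)
  ), class = c("niche_params", class(tibble())))
}

#' Draw one multinomial pollen count vector
#'
#' Expected relative abundance of taxon i is
#' `max_abundance_i * exp(-(mtco - opt_i)^2 / (2 tol_i^2)) *
#' exp(-(mtwa - opt'_i)^2 / (2 tol'_i^2))`; counts are multinomial with
#' that probability vector.
#'
#' @param climate One-row tibble or named vector with `mtco` and `mtwa`
#'   (degC).
#' @param niches A `niche_params` tibble.
#' @param total_count Total pollen count (>= 1).
#' @param seed Optional integer seed.
#' @return Named integer vector of counts summing to `total_count`.
#' @export
sample_counts <- function(climate, niches, total_count = 400, seed = NULL) {
  if (total_count < 1) abort("total_count must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  p <- niche_probs(climate[["mtco"]], climate[["mtwa"]], niches)
  setNames(as.integer(rmultinom(1, total_count, p)), niches$taxon)
}

niche_probs <- function(mtco, mtwa, niches) {
  p <- niches$max_abundance *
    exp(-(mtco - niches$optimum_mtco)^2 / (2 * niches$tolerance_mtco^2)) *
    exp(-(mtwa - niches$optimum_mtwa)^2 / (2 * niches$tolerance_mtwa^2))
  if (sum(p) <= 0 || !all(is.finite(p))) {
    abort("all expected abundances are zero at this climate")
  }
  p / sum(p)
}

#' Generate a synthetic modern calibration set
#'
#' Sites are placed uniformly (or with spatial clustering, for h-block
#' experiments) over the climate-field domain, assigned the field climate
#' at their position, and given multinomial assemblages from the niche
#' model. Features are taxon proportions or PFT scores.
#'
#' @param n_sites Number of surface samples (> 0).
#' @param field A [make_climate_field()] result.
#' @param niches A `niche_params` tibble.
#' @param total_count Pollen count per sample.
#' @param seed Integer seed.
#' @param clustered Place sites in spatial clusters instead of uniformly.
#' @param n_clusters Number of clusters when `clustered`.
#' @param feature_kind `"taxa"` (proportions) or `"pft"` (scores; requires
#'   `pft_matrix`).
#' @param pft_matrix Taxa-PFT tibble used when `feature_kind = "pft"`.
#' @param theta PFT presence threshold.
#' @return A [calibration_set()].
#' @export
make_calibration_set <- function(n_sites = 300, field, niches,
                                 total_count = 400, seed = 1,
                                 clustered = FALSE, n_clusters = 15,
                                 feature_kind = c("pft", "taxa"),
                                 pft_matrix = NULL, theta = 0.005) {
  feature_kind <- match.arg(feature_kind)
  if (n_sites < 1) abort("n_sites must be >= 1")
  set.seed(seed)
  g <- field$grid
  lat_r <- range(g$lat); lon_r <- range(g$lon)
  if (clustered) {
    cl <- tibble(lat = runif(n_clusters, lat_r[1] + 3, lat_r[2] - 3),
                 lon = runif(n_clusters, lon_r[1] + 3, lon_r[2] - 3))
    pick <- sample.int(n_clusters, n_sites, replace = TRUE)
    lat <- pmin(pmax(cl$lat[pick] + rnorm(n_sites, 0, 1.5), lat_r[1]), lat_r[2])
    lon <- pmin(pmax(cl$lon[pick] + rnorm(n_sites, 0, 1.5), lon_r[1]), lon_r[2])
  } else {
    lat <- runif(n_sites, lat_r[1], lat_r[2])
    lon <- runif(n_sites, lon_r[1], lon_r[2])
  }
  elev <- vapply(seq_len(n_sites), function(i) {
    bilinear_at(g$lat, g$lon, g$elev, lat[i], lon[i])
  }, numeric(1))
  sites <- site_table(sprintf("cal_%04d", seq_len(n_sites)), lat, lon, elev)
  climate <- purrr::map_dfr(seq_len(n_sites), function(i) {
    assign_site_climate(sites[i, ], g)
  })
  counts <- t(vapply(seq_len(n_sites), function(i) {
    sample_counts(climate[i, c("mtco", "mtwa")], niches, total_count)
  }, integer(nrow(niches))))
  colnames(counts) <- niches$taxon
  props <- to_proportions(counts)
  features <- if (feature_kind == "pft") {
    if (is.null(pft_matrix)) abort("feature_kind = 'pft' requires a pft_matrix")
    compute_pft_scores(props, pft_matrix, theta = theta)
  } else {
    props
  }
  calibration_set(sites, features, climate, feature_kind)
}

#' Generate a synthetic taxa-to-PFT assignment matrix
#'
#' Each taxon is assigned to one or two of `n_pfts` functional types with
#' unit weight. Types are formed by clustering the taxa in the joint
#' (MTCO, MTWA) niche-optimum space, mirroring how real biomization
#' schemes encode both cold tolerance and warmth requirement; the second
#' membership (for about half the taxa) goes to the next-nearest type.
#'
#' @param niches A `niche_params` tibble (taxon order defines the rows).
#' @param n_pfts Number of PFTs.
#' @param seed Integer seed.
#' @return A taxa-PFT tibble usable by [compute_pft_scores()].
#' @export
make_pft_matrix <- function(niches, n_pfts = 8, seed = 1) {
  set.seed(seed)
  n <- nrow(niches)
  n_pfts <- min(n_pfts, n)
  opt <- scale(cbind(niches$optimum_mtco, niches$optimum_mtwa))
  km <- stats::kmeans(opt, centers = n_pfts, nstart = 10, iter.max = 50)
  W <- matrix(0, n, n_pfts)
  W[cbind(seq_len(n), km$cluster)] <- 1
  # second membership in the next-nearest type for about half the taxa
  d2 <- as.matrix(stats::dist(rbind(opt, km$centers)))
  d2 <- d2[seq_len(n), n + seq_len(n_pfts), drop = FALSE]
  extra <- which(runif(n) < 0.5)
  for (i in extra) {
    alt <- order(d2[i, ])[2]
    W[i, alt] <- 1
  }
  out <- tibble(taxon = niches$taxon)
  for (j in seq_len(n_pfts)) out[[sprintf("pft_%d", j)]] <- W[, j]
  structure(out, pfts = sprintf("pft_%d", seq_len(n_pfts)),
            class = c("pft_matrix", class(tibble())))
}

#' Default Holocene-like temperature anomaly truth
#'
#' Piecewise-linear anomalies relative to present: winter (MTCO) warms
#' `mtco_rise` degC from 11 to 7 ka BP then cools `mtco_fall` degC to the
#' present; summer (MTWA) warms `mtwa_rise` and cools `mtwa_fall`. The
#' annual anomaly is the mean of the two (consistent with the sinusoidal
#' monthly cycle of the synthetic climate field).
#'
#' @param mtco_rise,mtco_fall,mtwa_rise,mtwa_fall Amplitudes (degC).
#' @param peak_ka,start_ka Breakpoints (ka BP).
#' @return A function `f(age_yr_bp)` returning a tibble with `mtco_anom`,
#'   `mtwa_anom`, `annt_anom`.
#' @export
holocene_truth <- function(mtco_rise = 4.1, mtco_fall = 0.7,
                           mtwa_rise = 1.4, mtwa_fall = 0.5,
                           peak_ka = 7, start_ka = 11) {
  anom <- function(t_ka, rise, fall) {
    ifelse(t_ka <= peak_ka,
           fall * t_ka / peak_ka,
           fall - rise * (t_ka - peak_ka) / (start_ka - peak_ka))
  }
  function(age_yr_bp) {
    t_ka <- age_yr_bp / 1000
    co <- anom(t_ka, mtco_rise, mtco_fall)
    wa <- anom(t_ka, mtwa_rise, mtwa_fall)
    tibble(mtco_anom = co, mtwa_anom = wa, annt_anom = (co + wa) / 2)
  }
}

#' Generate a synthetic fossil pollen record with known truth
#'
#' Sample ages spread over 0-11 ka BP (top sample younger than 1 ka),
#' assemblages drawn from the niche model at the site's true climate
#' history, and radiocarbon controls synthesised by inverting the
#' calibration curve at roughly `date_spacing`-yr intervals and adding
#' Gaussian dating error. Default settings guarantee the record passes
#' [screen_record()].
#'
#' @param site One-row site tibble.
#' @param site_climate One-row tibble with the site's present `annt`,
#'   `mtwa`, `mtco` (degC).
#' @param truth A truth function from [holocene_truth()].
#' @param curve A `calib_curve` used both to synthesise and to recalibrate
#'   the dates.
#' @param niches A `niche_params` tibble.
#' @param n_samples Number of pollen samples (>= 5).
#' @param date_spacing Nominal control spacing (yr).
#' @param date_sigma One-sigma dating error (yr).
#' @param total_count Pollen count per sample.
#' @param accumulation Sedimentation rate (cm per yr) mapping age to depth.
#' @param truth_scale Multiplier on the anomaly history (spatial
#'   variability hook).
#' @param exotic_fraction Fraction of samples drawn from an equal mixture
#'   of the most cold-adapted and most warm-adapted taxa — an ecologically
#'   impossible community with no modern counterpart — to create
#'   no-analogue situations on demand (for `scd_max` tests).
#' @param topo_history Optional `topo_history` tibble for the site; when
#'   given, the glacio-isostatic temperature signal
#'   `topo_lapse * delta_elev(t)` is added to the climate the assemblages
#'   experience, while the returned `truth` keeps the climate-only series
#'   (what an isostatic correction should recover).
#' @param topo_lapse Lapse rate (degC per m) of the imposed topographic
#'   signal.
#' @param seed Integer seed.
#' @return An object of class `fossil_record`: `site`, `samples` (tibble
#'   with modelled `age`, true `age_true`, `depth`, flags), `counts`
#'   matrix, `controls`, `age_model`, and the per-sample `truth` tibble.
#' @export
make_fossil_record <- function(site, site_climate, truth, curve, niches,
                               n_samples = 60, date_spacing = 1000,
                               date_sigma = 60, total_count = 400,
                               accumulation = 0.05, truth_scale = 1,
                               exotic_fraction = 0, topo_history = NULL,
                               topo_lapse = -0.0065, seed = 1) {
  if (n_samples < 5) abort("n_samples must be >= 5")
  set.seed(seed)
  ages_true <- sort(seq(150, 10950, length.out = n_samples) +
                      runif(n_samples, -70, 70))
  an <- truth(ages_true)
  mtco_t <- site_climate$mtco + truth_scale * an$mtco_anom
  mtwa_t <- site_climate$mtwa + truth_scale * an$mtwa_anom
  exotic <- exotic_fraction > 0 & runif(n_samples) < exotic_fraction
  # glacio-isostatic imprint: a higher past surface cools the vegetation's
  # experienced climate; the stored truth stays climate-only
  topo_dt <- rep(0, n_samples)
  if (!is.null(topo_history)) {
    delev <- approx(topo_history$time_ka, topo_history$delta_elev,
                    ages_true / 1000, rule = 2, ties = "ordered")$y
    topo_dt <- topo_lapse * delev
  }
  counts <- t(vapply(seq_len(n_samples), function(i) {
    p <- if (exotic[i]) {
      pe <- numeric(nrow(niches))
      pe[c(which.min(niches$optimum_mtco), which.max(niches$optimum_mtwa))] <- 0.5
      pe
    } else {
      niche_probs(mtco_t[i] + topo_dt[i], mtwa_t[i] + topo_dt[i], niches)
    }
    as.integer(rmultinom(1, total_count, p))
  }, integer(nrow(niches))))
  colnames(counts) <- niches$taxon
  rownames(counts) <- sprintf("s%03d", seq_len(n_samples))
  depths <- ages_true * accumulation
  ctl_ages <- seq(min(ages_true), max(ages_true), by = date_spacing)
  c14_true <- approx(curve$cal_bp, curve$c14_bp, ctl_ages, ties = "ordered")$y
  controls <- tibble(
    depth = ctl_ages * accumulation,
    kind = c("core_top", rep("c14", length(ctl_ages) - 1)),
    age = c(ctl_ages[1],
            c14_true[-1] + rnorm(length(ctl_ages) - 1, 0, date_sigma)),
    sigma = c(50, rep(date_sigma, length(ctl_ages) - 1)),
    independent = c(FALSE, rep(TRUE, length(ctl_ages) - 1))
  )
  model <- build_age_model(controls, depths, curve)
  samples <- tibble(sample_id = rownames(counts), depth = depths,
                    age = model$age, age_true = ages_true,
                    flag = model$flag)
  structure(list(site = site, samples = samples, counts = counts,
                 taxa = colnames(counts), controls = controls,
                 age_model = model,
                 truth = tibble(age_true = ages_true, mtco_true = mtco_t,
                                mtwa_true = mtwa_t,
                                annt_true = (mtco_t + mtwa_t) / 2,
                                topo_dt = topo_dt)),
            class = "fossil_record")
}

#' @export
print.fossil_record <- function(x, ...) {
  cat(sprintf("<fossil_record> %s: %d samples, %d controls, %.0f-%.0f yr BP\n",
              x$site$site_id, nrow(x$samples), nrow(x$controls),
              min(x$samples$age), max(x$samples$age)))
  invisible(x)
}

#' PFT score features for a fossil record
#'
#' @param record A `fossil_record`.
#' @param pft_matrix Taxa-PFT tibble.
#' @param theta Presence threshold.
#' @return Samples x PFT score matrix.
#' @export
record_features <- function(record, pft_matrix, theta = 0.005) {
  compute_pft_scores(to_proportions(record$counts), pft_matrix, theta = theta)
}

#' Assemble the end-to-end synthetic study ("holocene_demo")
#'
#' One seeded bundle containing everything the pipeline consumes: a
#' correlated climate field, niche parameters, a taxa-PFT matrix, a
#' 300-sample modern calibration set with PFT features, 60 fossil records
#' with radiocarbon chronologies generated from the Holocene-like truth, a
#' wiggly calibration curve and a decaying topographic-anomaly field.
#'
#' @param n_records Number of fossil records.
#' @param n_calib Number of modern surface samples.
#' @param n_taxa Number of synthetic taxa.
#' @param total_count Pollen count per sample.
#' @param corr_target Target MTCO-MTWA correlation of the climate field.
#' @param seed Master seed; stage seeds are derived with [split_seed()].
#' @param truth A truth function (default [holocene_truth()] with the
#'   study amplitudes).
#' @return A list with `field`, `niches`, `pft_matrix`, `calib`,
#'   `records`, `truth`, `curve`, `topo`, `seed`.
#' @export
holocene_demo <- function(n_records = 60, n_calib = 300, n_taxa = 20,
                          total_count = 400, corr_target = 0.6, seed = 42,
                          truth = holocene_truth()) {
  sim_seed <- split_seed(seed, "simulate")
  field <- make_climate_field(corr_target = corr_target, seed = sim_seed)
  niches <- make_niches(n_taxa,
                        mtco_range = range(field$cells$mtco),
                        mtwa_range = range(field$cells$mtwa),
                        seed = sim_seed + 1)
  pm <- make_pft_matrix(niches, seed = sim_seed + 2)
  calib <- make_calibration_set(n_calib, field, niches,
                                total_count = total_count,
                                seed = sim_seed + 3,
                                feature_kind = "pft", pft_matrix = pm)
  curve <- make_calib_curve("wiggly")
  topo <- make_topo_field()
  set.seed(sim_seed + 4)
  g <- field$grid
  lat <- runif(n_records, min(g$lat) + 2, max(g$lat) - 2)
  lon <- runif(n_records, min(g$lon) + 2, max(g$lon) - 2)
  sites <- site_table(sprintf("rec_%03d", seq_len(n_records)), lat, lon,
                      elev = vapply(seq_len(n_records), function(i) {
                        bilinear_at(g$lat, g$lon, g$elev, lat[i], lon[i])
                      }, numeric(1)))
  records <- lapply(seq_len(n_records), function(i) {
    clim <- assign_site_climate(sites[i, ], g)
    th <- topo_history_at_site(topo, sites[i, ])
    make_fossil_record(sites[i, ], clim, truth, curve, niches,
                       total_count = total_count, topo_history = th,
                       seed = sim_seed + 10 + i)
  })
  list(field = field, niches = niches, pft_matrix = pm, calib = calib,
       records = records, truth = truth, curve = curve, topo = topo,
       seed = seed)
}
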