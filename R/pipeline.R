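# Orchestration: one config drives simulate -> screen -> pft -> recon ->
# validate -> significance -> correct -> stack -> eof, with a manifest of
# parameters, seeds and attrition counts at every stage.

#' Default pipeline configuration
#'
#' Every defaulted value matches the canonical study settings: 100
#' bootstrap iterations, 1000 Monte-Carlo draws, 999 random
#' reconstructions at the 0.842 retention quantile, 200-yr bins anchored at
#' 100 BP, 2-degree cells, 300-km lapse radius, 1-kyr/6-kyr sample
#' screening with a 200-grain minimum, and 400/1000-yr resolution limits.
#' Override any entry via `...`.
#'
#' @param ... Named overrides.
#' @return A validated config list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    seed = 42,
    n_records = 60, n_calib = 300, n_taxa = 20, total_count = 400,
    corr_target = 0.6,
    k = 6, scd_max = 0.2, theta = 0.005,
    n_boot = 100, n_mc = 1000, n_rand = 999, quantile = 0.842,
    bin_width = 200, bin_anchor = 100, cell_size = 2,
    lapse_radius_km = 300,
    near_yr = 1000, bracket_yr = 6000, min_count = 200,
    resolution_yr = 400, resolution_yr_relaxed = 1000,
    variables = climate_vars(),
    do_significance = TRUE, do_correction = TRUE, do_eof = TRUE
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown) > 0) {
    abort(paste0("unknown config entries: ", paste(unknown, collapse = ", ")))
  }
  cfg[names(over)] <- over
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  errs <- character(0)
  if (cfg$quantile <= 0 || cfg$quantile > 1) {
    errs <- c(errs, "quantile must lie in (0, 1]")
  }
  for (nm in c("n_records", "n_calib", "k", "n_boot", "n_mc", "n_rand",
               "bin_width", "cell_size", "lapse_radius_km")) {
    if (!is.numeric(cfg[[nm]]) || cfg[[nm]] <= 0) {
      errs <- c(errs, paste0(nm, " must be a positive number"))
    }
  }
  if (cfg$scd_max <= 0) errs <- c(errs, "scd_max must be > 0")
  if (length(errs) > 0) {
    abort(paste0("invalid pipeline config:\n  ",
                 paste(errs, collapse = "\n  ")))
  }
  invisible(cfg)
}

#' Read a pipeline configuration file
#'
#' YAML or JSON; entries override [pipeline_config()] defaults and the
#' merged config is validated.
#'
#' @param path File path (`.yml`/`.yaml` or `.json`).
#' @return A validated config list.
#' @export
read_pipeline_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  over <- if (ext == "json") {
    if (!requireNamespace("jsonlite", quietly = TRUE)) abort("jsonlite not installed")
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    if (!requireNamespace("yaml", quietly = TRUE)) abort("yaml not installed")
    yaml::read_yaml(path)
  }
  do.call(pipeline_config, over)
}

#' Run the full synthetic reconstruction pipeline
#'
#' Generates the synthetic study, screens records and samples, converts
#' assemblages to PFT scores, cross-validates the MAT transfer function,
#' reconstructs every record with bootstrap sample errors, applies the
#' significance test and isostatic correction, stacks the retained
#' reconstructions into gridded composites for each climate variable, and
#' runs EOF analysis on the early (11-7 ka) and late (7-0 ka) windows.
#' Identical configs produce identical results (all stochastic stages are
#' seeded from the master seed via [split_seed()]).
#'
#' @param config A config list from [pipeline_config()].
#' @return A list of class `pollenclim_pipeline` with elements `demo`,
#'   `screening`, `cv`, `recons`, `significance`, `binned`, `cells`,
#'   `composites` (per variable), `eof` (per window) and `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  validate_config(config)
  cfg <- config
  demo <- holocene_demo(n_records = cfg$n_records, n_calib = cfg$n_calib,
                        n_taxa = cfg$n_taxa, total_count = cfg$total_count,
                        corr_target = cfg$corr_target, seed = cfg$seed)
  # record screening
  screening <- purrr::map_dfr(demo$records, function(r) {
    sc <- screen_record(r, r$site$region_id,
                        resolution_yr = cfg$resolution_yr,
                        resolution_yr_relaxed = cfg$resolution_yr_relaxed)
    tibble(site_id = r$site$site_id, pass = sc$pass,
           reasons = paste(sc$reasons, collapse = "; "))
  })
  records <- demo$records[screening$pass]
  # transfer-function validation (LOO) supplies the model RMSEP
  cv <- cross_validate(demo$calib, method = "mat", scheme = "loo", k = cfg$k,
                       variables = cfg$variables)
  rmsep <- setNames(cv$rmsep, cv$variable)
  # per-record reconstruction with sample screening and bootstrap errors
  recon_seed <- split_seed(cfg$seed, "recon")
  recons <- purrr::imap(records, function(r, i) {
    keep <- screen_samples(r$age_model, r$counts,
                           near_yr = cfg$near_yr, bracket_yr = cfg$bracket_yr,
                           min_count = cfg$min_count)
    feats <- record_features(r, demo$pft_matrix, theta = cfg$theta)
    rec <- reconstruct(feats[keep, , drop = FALSE], r$samples$age[keep],
                       demo$calib, k = cfg$k, scd_max = cfg$scd_max,
                       n_boot = cfg$n_boot, rmsep = rmsep,
                       seed = recon_seed + i, variables = cfg$variables)
    attr(rec, "site") <- r$site
    attr(rec, "features") <- feats[keep, , drop = FALSE]
    rec
  })
  # significance selection per record and variable
  sig <- NULL
  retained <- NULL
  if (cfg$do_significance) {
    sig_seed <- split_seed(cfg$seed, "significance")
    sig <- purrr::imap_dfr(recons, function(rec, i) {
      purrr::map_dfr(cfg$variables, function(v) {
        est <- rec$estimate[rec$variable == v]
        if (sum(is.finite(est)) < 3 || sd(est, na.rm = TRUE) == 0) {
          return(tibble(site_id = attr(rec, "site")$site_id, variable = v,
                        observed_var = 0, threshold = NA_real_, pass = FALSE))
        }
        s <- significance_test(attr(rec, "features"), rec, demo$calib,
                               variable = v, n_rand = cfg$n_rand,
                               quantile = cfg$quantile, k = cfg$k,
                               seed = sig_seed + 37L * i +
                                 match(v, cfg$variables))
        tibble(site_id = attr(rec, "site")$site_id, variable = v,
               observed_var = s$observed_var, threshold = s$threshold,
               pass = s$pass)
      })
    })
    retained <- sig
  }
  # isostatic correction
  n_uncorrectable <- 0L
  if (cfg$do_correction) {
    recons <- purrr::map(recons, function(rec) {
      site <- attr(rec, "site")
      out <- tryCatch({
        hist <- topo_history_at_site(demo$topo, site)
        lapse <- local_lapse_rate(demo$field$grid, site,
                                  radius_km = cfg$lapse_radius_km)
        isostatic_correct(rec, hist, lapse)
      }, error = function(e) {
        # site flagged uncorrectable (e.g. too few cells or flat relief)
        n_uncorrectable <<- n_uncorrectable + 1L
        rec
      })
      attr(out, "site") <- site
      attr(out, "features") <- attr(rec, "features")
      out
    })
  }
  # stacking
  stack_seed <- split_seed(cfg$seed, "stack")
  binned <- list()
  cells <- list()
  composites <- list()
  for (v in cfg$variables) {
    use <- seq_along(recons)
    if (!is.null(retained)) {
      ok_sites <- retained$site_id[retained$variable == v & retained$pass]
      use <- which(purrr::map_chr(recons, ~ attr(.x, "site")$site_id) %in% ok_sites)
    }
    bs <- purrr::imap(recons[use], function(rec, i) {
      to_binned(rec, variable = v, n_mc = cfg$n_mc,
                seed = stack_seed + 101L * i + match(v, cfg$variables),
                bin_width = cfg$bin_width, anchor = cfg$bin_anchor)
    })
    binned[[v]] <- bs
    cells[[v]] <- grid_average(bs, cell_size = cfg$cell_size)
    composites[[v]] <- composite(cells[[v]], n_mc = cfg$n_mc,
                                 seed = stack_seed + 7L * match(v, cfg$variables))
  }
  # EOF of site-level binned series, early and late windows
  eofs <- NULL
  if (cfg$do_eof) {
    eofs <- purrr::map(list(early = c(7100, 10900), late = c(100, 6900)),
                       function(win) {
      purrr::map(cfg$variables, function(v) {
        bins <- sort(unique(unlist(purrr::map(binned[[v]], "bin_center"))))
        M <- vapply(binned[[v]], function(b) {
          b$anomaly[match(bins, b$bin_center)]
        }, numeric(length(bins)))
        colnames(M) <- purrr::map_chr(binned[[v]],
                                      ~ attr(.x, "site")$site_id %||% "x")
        tryCatch(eof_analysis(M, times = bins, window = win),
                 error = function(e) NULL)
      }) %>% setNames(cfg$variables)
    })
  }
  manifest <- list(
    config = cfg,
    n_records_simulated = cfg$n_records,
    n_records_screened = sum(screening$pass),
    n_retained = if (is.null(retained)) NULL else
      retained %>% group_by(.data$variable) %>%
        summarise(n = sum(.data$pass), .groups = "drop"),
    rmsep = rmsep,
    n_uncorrectable = n_uncorrectable,
    achieved_climate_r = demo$field$achieved_r
  )
  structure(list(demo = demo, screening = screening, cv = cv,
                 recons = recons, significance = sig, binned = binned,
                 cells = cells, composites = composites, eof = eofs,
                 manifest = manifest),
            class = "pollenclim_pipeline")
}

#' @export
print.pollenclim_pipeline <- function(x, ...) {
  m <- x$manifest
  cat(sprintf("<pollenclim_pipeline> %d/%d records screened in\n",
              m$n_records_screened, m$n_records_simulated))
  if (!is.null(m$n_retained)) {
    for (i in seq_len(nrow(m$n_retained))) {
      cat(sprintf("  %s: %d significant record(s)\n",
                  m$n_retained$variable[i], m$n_retained$n[i]))
    }
  }
  invisible(x)
}
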