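# Reconstruction core: squared chord distance, modern analogue technique
# with analogue thresholds, and bootstrap sample-specific errors.

#' Construct a modern calibration set
#'
#' Bundles surface-sample sites, their assemblage features (taxon
#' proportions or PFT scores) and their modern climate into the object all
#' transfer-function operations consume.
#'
#' @param sites Tibble with `site_id`, `lat`, `lon`, `elev`, `region_id`
#'   (see [site_table()]); one row per surface sample.
#' @param features Samples x features numeric matrix, rows aligned with
#'   `sites`.
#' @param climate Tibble with `annt`, `mtwa`, `mtco` (degC), aligned rows.
#' @param feature_kind `"pft"` or `"taxa"`.
#' @return An object of class `calibration_set`.
#' @export
calibration_set <- function(sites, features, climate,
                            feature_kind = c("pft", "taxa")) {
  feature_kind <- match.arg(feature_kind)
  features <- check_assemblage(features, "calibration features")
  stopifnot(nrow(sites) == nrow(features), nrow(climate) == nrow(features))
  if (anyNA(climate[climate_vars()])) abort("calibration climate has missing values")
  if (any(climate$mtco > climate$annt + 1e-9 | climate$annt > climate$mtwa + 1e-9)) {
    abort("climate invariant violated: need mtco <= annt <= mtwa")
  }
  structure(list(sites = as_tibble(sites), features = features,
                 climate = as_tibble(climate)[climate_vars()],
                 feature_kind = feature_kind),
            class = "calibration_set")
}

#' @export
print.calibration_set <- function(x, ...) {
  cat(sprintf("<calibration_set> %d samples x %d %s features\n",
              nrow(x$features), ncol(x$features), x$feature_kind))
  invisible(x)
}

#' Squared chord distance
#'
#' `sum_i (sqrt(p_i) - sqrt(q_i))^2` between two non-negative compositional
#' vectors; 0 iff identical, 2 for fully disjoint unit-sum vectors.
#'
#' @param p,q Equal-length non-negative vectors.
#' @return A single dissimilarity.
#' @export
#' @examples
#' scd(c(0.5, 0.5), c(0.25, 0.75))
scd <- function(p, q) {
  if (length(p) != length(q)) abort("vectors must have equal length")
  if (any(p < 0) || any(q < 0)) abort("squared chord distance requires non-negative entries")
  sum((sqrt(p) - sqrt(q))^2)
}

#' Squared-chord-distance matrix between two assemblage sets
#'
#' Rows are normalised to unit sum first (the convention for both taxon
#' proportions and PFT scores here); all-zero rows are flagged and their
#' distances set to `NA`.
#'
#' @param A,B Non-negative matrices with matching columns (`B = NULL`
#'   computes self-distances of `A`).
#' @param normalize Normalise rows to sum 1 (default).
#' @return `nrow(A) x nrow(B)` distance matrix.
#' @export
scd_matrix <- function(A, B = NULL, normalize = TRUE) {
  A <- check_assemblage(A, "assemblage A")
  B <- if (is.null(B)) A else check_assemblage(B, "assemblage B")
  if (ncol(A) != ncol(B)) abort("assemblage matrices must have matching columns")
  norm_rows <- function(M) {
    rs <- rowSums(M)
    zero <- rs == 0
    rs[zero] <- 1
    list(m = M / rs, zero = zero)
  }
  if (normalize) {
    na <- norm_rows(A); nb <- norm_rows(B)
    A <- na$m; B <- nb$m
  } else {
    na <- list(zero = rowSums(A) == 0); nb <- list(zero = rowSums(B) == 0)
  }
  SA <- sqrt(A); SB <- sqrt(B)
  D <- outer(rowSums(A), rowSums(B), "+") - 2 * tcrossprod(SA, SB)
  D[D < 0] <- 0
  D[na$zero, ] <- NA_real_
  D[, nb$zero] <- NA_real_
  D
}

# Analogue selection and dissimilarity-weighted prediction from a
# precomputed distance row. Weights are 1/SCD; zero-distance analogues
# short-circuit to the mean climate of the exact matches. Ties at the k-th
# analogue are broken by calibration sample order (stable sort).
mat_from_distances <- function(d, climate, k) {
  ord <- order(d, method = "radix")  # stable: ties keep calibration order
  take <- ord[seq_len(min(k, sum(is.finite(d))))]
  dk <- d[take]
  if (length(take) == 0 || !is.finite(dk[1])) {
    return(list(est = rep(NA_real_, ncol(climate)), min_scd = NA_real_,
                idx = integer(0), w = numeric(0)))
  }
  zero <- dk < 1e-12
  if (any(zero)) {
    w <- as.numeric(zero) / sum(zero)
  } else {
    w <- (1 / dk) / sum(1 / dk)
  }
  list(est = as.numeric(w %*% climate[take, , drop = FALSE]),
       min_scd = dk[1], idx = take, w = w)
}

#' Modern analogue technique prediction
#'
#' For each target assemblage the `k` closest calibration samples by
#' squared chord distance are selected (ties broken by stable calibration
#' order) and the dissimilarity-weighted (1/SCD) mean of their climate is
#' returned. Samples whose closest analogue exceeds `scd_max` are flagged
#' `no_analogue` and their estimates withheld; an exact (zero-distance)
#' analogue short-circuits to its climate.
#'
#' @param target Assemblage matrix (or single vector) with columns matching
#'   the calibration features.
#' @param calib A [calibration_set()].
#' @param k Number of analogues (>= 1).
#' @param scd_max No-analogue threshold on the minimum SCD.
#' @param exclude Optional logical vector (length = calibration samples) or
#'   predicate on the site table marking calibration samples to exclude.
#' @param variables Climate variables to predict.
#' @return A tibble with one row per target sample and variable: `row`,
#'   `variable`, `estimate`, `min_scd`, `n_analogues`, `no_analogue`, and
#'   list-column `analogues` of calibration row indices.
#' @export
mat_predict <- function(target, calib, k = 6, scd_max = 0.2, exclude = NULL,
                        variables = climate_vars()) {
  if (k < 1) abort("k must be >= 1")
  if (is.vector(target)) target <- matrix(target, nrow = 1)
  D <- scd_matrix(target, calib$features)
  if (!is.null(exclude)) {
    if (is.function(exclude)) exclude <- exclude(calib$sites)
    if (all(exclude)) abort("all calibration samples excluded")
    D[, exclude] <- Inf
  }
  climate <- as.matrix(calib$climate[variables])
  out <- purrr::map_dfr(seq_len(nrow(D)), function(i) {
    d <- D[i, ]
    if (anyNA(d)) {
      return(tibble(row = i, variable = variables, estimate = NA_real_,
                    min_scd = NA_real_, n_analogues = 0L,
                    no_analogue = TRUE, analogues = list(integer(0))))
    }
    m <- mat_from_distances(d, climate, k)
    bad <- is.na(m$min_scd) || m$min_scd > scd_max
    tibble(row = i, variable = variables,
           estimate = if (bad) NA_real_ else m$est,
           min_scd = m$min_scd, n_analogues = length(m$idx),
           no_analogue = bad, analogues = list(m$idx))
  })
  out
}

#' Bootstrap sample-specific reconstruction error
#'
#' Resamples the calibration rows with replacement `n_boot` times, repeats
#' the MAT prediction in each resample, and combines the bootstrap spread
#' with the model RMSEP in quadrature:
#' `sample_error = sqrt(sd(boot)^2 + rmsep^2)`. Degenerate resamples with
#' no finite analogue are redrawn (and counted in the `"redraws"`
#' attribute).
#'
#' @inheritParams mat_predict
#' @param n_boot Number of bootstrap iterations.
#' @param rmsep Model root-mean-square error of prediction, a single value
#'   or named per-variable vector (degC).
#' @param seed Optional integer seed.
#' @return A tibble `row`, `variable`, `sample_error` with attribute
#'   `redraws`.
#' @export
bootstrap_error <- function(target, calib, k = 6, n_boot = 100, rmsep = 0,
                            exclude = NULL, seed = NULL,
                            variables = climate_vars()) {
  if (is.vector(target)) target <- matrix(target, nrow = 1)
  if (!is.null(seed)) set.seed(seed)
  D <- scd_matrix(target, calib$features)
  if (!is.null(exclude)) {
    if (is.function(exclude)) exclude <- exclude(calib$sites)
    D[, exclude] <- Inf
  }
  climate <- as.matrix(calib$climate[variables])
  if (length(rmsep) == 1) rmsep <- setNames(rep(rmsep, length(variables)), variables)
  n_cal <- nrow(calib$features)
  redraws <- 0L
  out <- purrr::map_dfr(seq_len(nrow(D)), function(i) {
    d <- D[i, ]
    preds <- matrix(NA_real_, n_boot, length(variables))
    for (b in seq_len(n_boot)) {
      repeat {
        idx <- sample.int(n_cal, replace = TRUE)
        db <- d[idx]
        if (any(is.finite(db))) break
        redraws <<- redraws + 1L
      }
      preds[b, ] <- mat_from_distances(db, climate[idx, , drop = FALSE], k)$est
    }
    boot_sd <- apply(preds, 2, sd)
    tibble(row = i, variable = variables,
           sample_error = unname(sqrt(boot_sd^2 + rmsep[variables]^2)))
  })
  attr(out, "redraws") <- redraws
  out
}

#' Reconstruct climate for a dated fossil assemblage series
#'
#' Runs [mat_predict()] and [bootstrap_error()] over the samples of one
#' record and assembles a tidy reconstruction series.
#'
#' @param features Samples x features matrix for the fossil samples
#'   (columns matching the calibration features).
#' @param ages Sample ages, cal yr BP (aligned with rows).
#' @param calib A [calibration_set()].
#' @inheritParams bootstrap_error
#' @param sample_ids Optional sample ids.
#' @return A tibble of class `recon_series`: `sample_id`, `age`,
#'   `variable`, `estimate`, `sample_error`, `min_scd`, `n_analogues`,
#'   `no_analogue`, `analogues`; attribute `corrected = FALSE`.
#' @export
reconstruct <- function(features, ages, calib, k = 6, scd_max = 0.2,
                        n_boot = 100, rmsep = 0, seed = NULL,
                        variables = climate_vars(), sample_ids = NULL) {
  features <- check_assemblage(features, "fossil features")
  stopifnot(length(ages) == nrow(features))
  est <- mat_predict(features, calib, k = k, scd_max = scd_max,
                     variables = variables)
  err <- bootstrap_error(features, calib, k = k, n_boot = n_boot,
                         rmsep = rmsep, seed = seed, variables = variables)
  ids <- sample_ids %||% rownames(features) %||% as.character(seq_along(ages))
  out <- est %>%
    left_join(err, by = c("row", "variable")) %>%
    mutate(sample_id = ids[.data$row], age = ages[.data$row]) %>%
    select("sample_id", "age", "variable", "estimate", "sample_error",
           "min_scd", "n_analogues", "no_analogue", "analogues")
  structure(out, corrected = FALSE, feature_kind = calib$feature_kind,
            class = c("recon_series", class(out)))
}
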