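# Random-transfer-function significance test: a reconstruction is retained
# only if it explains more of the fossil-assemblage variance than a chosen
# quantile of reconstructions trained on random environmental variables.

# Fraction of (centred, scaled) response variance explained by a single
# constraint vector.
var_explained_by <- function(Yc, x, total_ss) {
  xc <- x - mean(x)
  ss_x <- sum(xc^2)
  if (ss_x < 1e-24) return(0)
  b <- crossprod(xc, Yc) / ss_x
  sum((xc %*% b)^2) / total_ss
}

#' Significance test of a reconstruction against random alternatives
#'
#' The observed statistic is the fraction of fossil-assemblage variance
#' explained when the reconstructed series is the sole RDA constraint on
#' the (centred and standardised) fossil feature matrix. The null
#' distribution is built by drawing `n_rand` environmental variables
#' uniformly over the calibration climate range of `variable`, training the
#' same MAT transfer function on each (the analogue sets depend only on the
#' assemblages, so each null reconstruction is the analogue-weighted mean
#' of the random variable), and computing the same variance fraction. The
#' reconstruction passes if it exceeds the empirical `quantile` of the null
#' values (default 0.842, the one-standard-deviation compromise threshold).
#'
#' @param fossil_features Samples x features matrix of the fossil record
#'   (same features as used for the reconstruction).
#' @param recon Reconstructed values for `variable`, one per fossil sample
#'   (a `recon_series` may be supplied and is filtered internally).
#' @param calib A [calibration_set()].
#' @param variable Climate variable being tested.
#' @param n_rand Number of random reconstructions (default 999).
#' @param quantile Retention quantile in (0, 1\].
#' @param k Analogue count used in the transfer function.
#' @param seed Optional integer seed.
#' @return An object of class `significance_result`: `observed_var`,
#'   `null_var`, `quantile`, `threshold`, `pass`.
#' @export
significance_test <- function(fossil_features, recon, calib,
                              variable = "mtco", n_rand = 999,
                              quantile = 0.842, k = 6, seed = NULL) {
  if (n_rand < 1) abort("n_rand must be >= 1")
  if (quantile <= 0 || quantile > 1) abort("quantile must lie in (0, 1]")
  if (inherits(recon, "recon_series")) {
    recon <- recon$estimate[recon$variable == variable]
  }
  fossil_features <- check_assemblage(fossil_features, "fossil features")
  stopifnot(length(recon) == nrow(fossil_features))
  ok <- is.finite(recon)
  Y <- fossil_features[ok, , drop = FALSE]
  x_obs <- recon[ok]
  if (sum(ok) < 3) abort("too few samples with finite reconstructions")
  Yc <- scale(Y, center = TRUE, scale = TRUE)
  Yc[, attr(Yc, "scaled:scale") == 0] <- 0
  total_ss <- sum(Yc^2)
  if (total_ss == 0) abort("fossil features have no variance")
  observed <- var_explained_by(Yc, x_obs, total_ss)

  if (!is.null(seed)) set.seed(seed)
  # analogue weights are fixed by the assemblages; precompute them once
  D <- scd_matrix(Y, calib$features)
  n_cal <- nrow(calib$features)
  Wmat <- matrix(0, nrow(Y), n_cal)
  for (i in seq_len(nrow(Y))) {
    m <- mat_from_distances(D[i, ], matrix(0, n_cal, 1), k)
    Wmat[i, m$idx] <- m$w
  }
  rng <- range(calib$climate[[variable]])
  env_rand <- matrix(runif(n_cal * n_rand, rng[1], rng[2]), n_cal, n_rand)
  null_recon <- Wmat %*% env_rand
  null_var <- vapply(seq_len(n_rand), function(j) {
    var_explained_by(Yc, null_recon[, j], total_ss)
  }, numeric(1))
  threshold <- stats::quantile(null_var, quantile, names = FALSE)
  structure(list(observed_var = observed, null_var = null_var,
                 quantile = quantile, threshold = threshold,
                 pass = observed > threshold, variable = variable,
                 n_rand = n_rand),
            class = "significance_result")
}

#' @export
print.significance_result <- function(x, ...) {
  cat(sprintf(
    "<significance_result> %s: observed %.3f vs null %.1f%% quantile %.3f -> %s\n",
    x$variable, x$observed_var, 100 * x$quantile, x$threshold,
    if (x$pass) "retained" else "rejected"))
  invisible(x)
}
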