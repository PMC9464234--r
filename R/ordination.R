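# Constrained ordination diagnostics (RDA, partial RDA variance
# partitioning) for the modern calibration data, and EOF analysis of the
# gridded anomaly reconstructions.

#' Redundancy analysis
#'
#' Eigenanalysis of the least-squares projection of a (column-centred,
#' optionally standardised) response matrix onto one or more constraints.
#' With a conditioning matrix `Z`, both response and constraints are
#' residualised on `Z` first (partial RDA); explained fractions are always
#' reported relative to the total variance of the original response, so
#' partial fractions are directly comparable across fits. Significance is
#' assessed by unrestricted row permutation of `X` with the add-one rule,
#' `p = (1 + #permutations >= observed) / (1 + n_perm)`.
#'
#' @param Y Samples x responses matrix (or data frame).
#' @param X Samples x constraints matrix, data frame or vector.
#' @param Z Optional conditioning matrix (partial RDA).
#' @param n_perm Number of permutations (0 suppresses the test).
#' @param seed Optional integer seed for the permutations.
#' @param scale Standardise response columns to unit variance (default
#'   `TRUE`, appropriate for PFT scores on heterogeneous scales).
#' @return An object of class `rda_result`: eigenvalues (constrained and
#'   unconstrained), `var_explained`, `lambda_ratio` (first constrained /
#'   first unconstrained eigenvalue) and `p_value` (`NA` when
#'   `n_perm = 0`).
#' @export
rda_fit <- function(Y, X, Z = NULL, n_perm = 999, seed = NULL, scale = TRUE) {
  Y <- as.matrix(Y)
  X <- as.matrix(X)
  n <- nrow(Y)
  stopifnot(nrow(X) == n)
  Yc <- scale(Y, center = TRUE, scale = scale)
  if (scale) Yc[, attr(Yc, "scaled:scale") == 0] <- 0
  Yc <- Yc[, , drop = FALSE]
  total <- sum(Yc^2) / (n - 1)
  project <- function(Xp) {
    Xc <- scale(Xp, center = TRUE, scale = FALSE)
    Yr <- Yc
    if (!is.null(Z)) {
      Zc <- scale(as.matrix(Z), center = TRUE, scale = FALSE)
      Yr <- Yr - Zc %*% qr.coef(qr(Zc), Yr)
      Xc <- Xc - Zc %*% qr.coef(qr(Zc), Xc)
    }
    qx <- qr(Xc)
    if (qx$rank < ncol(Xc)) {
      abort("constraint matrix is rank-deficient after conditioning")
    }
    fitted <- qr.fitted(qx, Yr)
    list(fitted = fitted, resid = Yr - fitted)
  }
  pr <- project(X)
  eig_of <- function(M) {
    d <- svd(M, nu = 0, nv = 0)$d
    ev <- d^2 / (n - 1)
    ev[ev > total * 1e-12]
  }
  eig_c <- eig_of(pr$fitted)
  eig_u <- eig_of(pr$resid)
  var_explained <- sum(eig_c) / total
  p_value <- NA_real_
  if (n_perm > 0) {
    if (!is.null(seed)) set.seed(seed)
    obs <- var_explained
    hits <- 0L
    for (b in seq_len(n_perm)) {
      ve <- sum(eig_of(project(X[sample.int(n), , drop = FALSE])$fitted)) / total
      if (ve >= obs - 1e-12) hits <- hits + 1L
    }
    p_value <- (1 + hits) / (1 + n_perm)
  }
  structure(
    list(eig_constrained = eig_c, eig_unconstrained = eig_u,
         var_explained = var_explained,
         lambda_ratio = if (length(eig_u) > 0) eig_c[1] / eig_u[1] else Inf,
         p_value = p_value, total_inertia = total,
         n = n, n_perm = n_perm, partial = !is.null(Z)),
    class = "rda_result")
}

#' @export
print.rda_result <- function(x, ...) {
  cat(sprintf("<rda_result>%s var explained %.3f, lambda1/lambda2 %.3f, p %s\n",
              if (x$partial) " (partial)" else "",
              x$var_explained, x$lambda_ratio,
              ifelse(is.na(x$p_value), "-", format(x$p_value))))
  invisible(x)
}

#' Partition response variance between two explanatory variables
#'
#' Total fractions come from simple RDA on each variable, unique fractions
#' from partial RDA conditioning on the other, and the shared fraction is
#' `combined - unique_x1 - unique_x2` (it may be negative in suppressor
#' situations and is reported as computed). All fractions are of the total
#' response variance, so `unique_x1 + unique_x2 + shared = combined`
#' exactly.
#'
#' @inheritParams rda_fit
#' @param x1,x2 Explanatory variables (vectors or single columns).
#' @return An object of class `variance_partition` with fields `total_x1`,
#'   `total_x2`, `unique_x1`, `unique_x2`, `shared`, `combined`, `p_x1`,
#'   `p_x2` (permutation p-values of the unique contributions).
#' @export
variance_partition <- function(Y, x1, x2, n_perm = 999, seed = NULL,
                               scale = TRUE) {
  x1 <- as.matrix(x1); x2 <- as.matrix(x2)
  t1 <- rda_fit(Y, x1, n_perm = 0, scale = scale)
  t2 <- rda_fit(Y, x2, n_perm = 0, scale = scale)
  # collinear constraints carry no unique information; the shared fraction
  # is everything either one explains
  x1c <- scale(x1, center = TRUE, scale = FALSE)
  r21 <- x2 - mean(x2) - x1c %*% qr.coef(qr(x1c), scale(x2, TRUE, FALSE))
  if (sum(r21^2) < 1e-12 * max(sum(scale(x2, TRUE, FALSE)^2), 1e-300)) {
    return(structure(
      list(total_x1 = t1$var_explained, total_x2 = t2$var_explained,
           unique_x1 = 0, unique_x2 = 0, shared = t1$var_explained,
           combined = t1$var_explained,
           lambda_ratio_x1 = t1$lambda_ratio,
           lambda_ratio_x2 = t2$lambda_ratio,
           p_x1 = NA_real_, p_x2 = NA_real_),
      class = "variance_partition"))
  }
  comb <- rda_fit(Y, cbind(x1, x2), n_perm = 0, scale = scale)
  u1 <- rda_fit(Y, x1, Z = x2, n_perm = n_perm, seed = seed, scale = scale)
  u2 <- rda_fit(Y, x2, Z = x1, n_perm = n_perm,
                seed = if (is.null(seed)) NULL else seed + 1, scale = scale)
  structure(
    list(total_x1 = t1$var_explained, total_x2 = t2$var_explained,
         unique_x1 = u1$var_explained, unique_x2 = u2$var_explained,
         shared = comb$var_explained - u1$var_explained - u2$var_explained,
         combined = comb$var_explained,
         lambda_ratio_x1 = t1$lambda_ratio, lambda_ratio_x2 = t2$lambda_ratio,
         p_x1 = u1$p_value, p_x2 = u2$p_value),
    class = "variance_partition")
}

#' @export
print.variance_partition <- function(x, ...) {
  cat(sprintf(paste0("<variance_partition> combined %.3f ",
                     "(unique %.3f / %.3f, shared %.3f)\n"),
              x$combined, x$unique_x1, x$unique_x2, x$shared))
  invisible(x)
}

#' Empirical orthogonal function analysis of an anomaly field
#'
#' Modes are obtained from the singular value decomposition of the
#' column-centred time x units matrix (equivalently, eigenanalysis of the
#' covariance matrix across units). Units with more than `max_missing`
#' missing time steps inside the window are dropped with a warning;
#' remaining gaps are linearly interpolated. The sign of each mode is fixed
#' so that its spatial-mean loading is non-negative. The reported map is
#' the Pearson correlation between each unit's series and PC1, not the raw
#' loading.
#'
#' @param x Wide tibble whose first (or `time_col`) column is time and
#'   remaining columns are unit anomaly series, or a time x units matrix
#'   with `times` supplied.
#' @param window Optional `c(lo, hi)` time interval (same units as the time
#'   column, bounds inclusive).
#' @param time_col Name of the time column when `x` is a tibble.
#' @param times Time vector when `x` is a matrix.
#' @param max_missing Maximum tolerated fraction of missing steps per unit.
#' @return An object of class `eof_result`: `eigenvalues`,
#'   `variance_fractions`, `pcs` (tibble time x modes), `loadings`,
#'   `correlation_map` (tibble `unit`, `r`).
#' @export
eof_analysis <- function(x, window = NULL, time_col = NULL, times = NULL,
                         max_missing = 0.2) {
  if (is.matrix(x)) {
    stopifnot(!is.null(times))
    M <- x
    tvec <- times
  } else {
    x <- as_tibble(x)
    time_col <- time_col %||% names(x)[1]
    tvec <- x[[time_col]]
    M <- as.matrix(x[setdiff(names(x), time_col)])
  }
  if (!is.null(window)) {
    keep <- tvec >= min(window) & tvec <= max(window)
    M <- M[keep, , drop = FALSE]
    tvec <- tvec[keep]
  }
  if (ncol(M) < 2) abort("EOF needs at least 2 units")
  miss <- colMeans(is.na(M))
  if (any(miss > max_missing)) {
    warn(sprintf("dropping %d unit(s) with > %.0f%% missing steps",
                 sum(miss > max_missing), 100 * max_missing))
    M <- M[, miss <= max_missing, drop = FALSE]
  }
  # fill remaining gaps by linear interpolation (nearest value at the ends)
  M <- apply(M, 2, function(v) {
    if (anyNA(v)) approx(tvec[!is.na(v)], v[!is.na(v)], tvec, rule = 2)$y else v
  })
  zero_var <- apply(M, 2, sd) == 0
  if (any(zero_var)) {
    warn(sprintf("dropping %d zero-variance unit(s)", sum(zero_var)))
    M <- M[, !zero_var, drop = FALSE]
  }
  if (ncol(M) < 2) abort("EOF needs at least 2 usable units")
  nt <- nrow(M)
  Mc <- scale(M, center = TRUE, scale = FALSE)
  sv <- svd(Mc)
  nmode <- sum(sv$d > sv$d[1] * 1e-12)
  d <- sv$d[seq_len(nmode)]
  V <- sv$v[, seq_len(nmode), drop = FALSE]
  U <- sv$u[, seq_len(nmode), drop = FALSE]
  flip <- colMeans(V) < 0
  V[, flip] <- -V[, flip]
  U[, flip] <- -U[, flip]
  pcs <- U %*% diag(d, nmode)
  colnames(pcs) <- paste0("PC", seq_len(nmode))
  rownames(V) <- colnames(M)
  structure(
    list(eigenvalues = d^2 / (nt - 1),
         variance_fractions = d^2 / sum(sv$d^2),
         pcs = tibble(time = tvec) %>% dplyr::bind_cols(as_tibble(pcs)),
         loadings = V,
         correlation_map = tibble(unit = colnames(M),
                                  r = as.numeric(cor(M, pcs[, 1]))),
         times = tvec, units = colnames(M)),
    class = "eof_result")
}

#' @export
print.eof_result <- function(x, ...) {
  cat(sprintf("<eof_result> %d units, %d steps; PC1 explains %.0f%% of variance\n",
              length(x$units), length(x$times),
              100 * x$variance_fractions[1]))
  invisible(x)
}
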