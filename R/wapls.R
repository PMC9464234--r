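# Weighted-averaging partial least squares: iterative component extraction
# on species-weighted centred data with a deshrinking regression. With one
# component and inverse deshrinking this reduces exactly to classic
# weighted averaging.

#' Fit a WA-PLS transfer function
#'
#' Components are extracted iteratively: species scores are the
#' species-weighted averages of the current environmental residuals, site
#' scores the sample-weighted averages of the species scores,
#' orthogonalised against earlier components and standardised; the
#' environmental variable is then regressed on the components (inverse
#' deshrinking) and the residuals feed the next component.
#'
#' @param y Samples x taxa matrix of non-negative abundances (proportions
#'   or scores; rows are weighted by their sums).
#' @param x Environmental variable (one value per sample).
#' @param n_comp Number of components (>= 1, at most `ncol(y) - 1`).
#' @param deshrink `"inverse"` (default) or `"classical"`; classical
#'   deshrinking is only available for the 1-component (plain WA) model,
#'   because for higher components the inverse regression is integral to
#'   component extraction.
#' @return An object of class `wapls_model`.
#' @export
wapls_fit <- function(y, x, n_comp = 2, deshrink = c("inverse", "classical")) {
  deshrink <- match.arg(deshrink)
  y <- check_assemblage(y, "species matrix")
  stopifnot(length(x) == nrow(y))
  if (n_comp < 1) abort("n_comp must be >= 1")
  if (n_comp > ncol(y) - 1) abort("n_comp exceeds the feasible rank (ncol(y) - 1)")
  if (deshrink == "classical" && n_comp > 1) {
    abort("classical deshrinking is only supported for n_comp = 1")
  }
  rs <- rowSums(y)
  if (any(rs == 0)) abort("species matrix has zero-sum rows")
  cs <- colSums(y)
  keep <- cs > 0
  y <- y[, keep, drop = FALSE]
  cs <- cs[keep]
  w <- rs / sum(rs)
  xbar <- sum(w * x)
  e <- x - xbar
  n <- nrow(y); A <- n_comp
  U <- matrix(0, ncol(y), A)        # species scores per component
  P <- matrix(0, n, A)              # standardised site scores
  phi <- matrix(0, A, A)            # orthogonalisation coefficients
  s <- numeric(A)                   # standardisation scales
  coefs <- vector("list", A)        # regression coefficients per n_comp
  for (a in seq_len(A)) {
    U[, a] <- as.numeric(crossprod(y, e)) / cs
    r <- as.numeric(y %*% U[, a]) / rs
    if (a > 1) {
      for (b in seq_len(a - 1)) {
        phi[a, b] <- sum(w * r * P[, b])
        r <- r - phi[a, b] * P[, b]
      }
    }
    s[a] <- sqrt(sum(w * r^2))
    if (s[a] < 1e-12) abort("degenerate component: site scores have zero spread")
    P[, a] <- r / s[a]
    fit <- lm.wfit(cbind(1, P[, seq_len(a), drop = FALSE]), x, w)
    coefs[[a]] <- fit$coefficients
    e <- x - fit$fitted.values
  }
  classical <- NULL
  if (deshrink == "classical") {
    # regress raw site scores on x and invert
    init <- P[, 1] * s[1] + xbar
    cl <- lm.wfit(cbind(1, x), init, w)$coefficients
    classical <- c(b0 = cl[1], b1 = cl[2])
  }
  structure(list(taxa = colnames(y), keep = keep, U = U, phi = phi, s = s,
                 coefs = coefs, xbar = xbar, n_comp = A,
                 deshrink = deshrink, classical = classical),
            class = "wapls_model")
}

#' Predict from a WA-PLS model
#'
#' @param object A `wapls_model`.
#' @param newdata Samples x taxa matrix with the same columns as the
#'   training data.
#' @param n_comp Number of components to use (defaults to the fitted
#'   number).
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.wapls_model <- function(object, newdata, n_comp = object$n_comp, ...) {
  if (is.vector(newdata)) newdata <- matrix(newdata, nrow = 1)
  y <- check_assemblage(newdata, "new species matrix")
  y <- y[, object$keep, drop = FALSE]
  rs <- rowSums(y)
  if (any(rs == 0)) abort("new sample has zero abundance on the model taxa")
  stopifnot(n_comp >= 1, n_comp <= object$n_comp)
  n <- nrow(y)
  P <- matrix(0, n, n_comp)
  for (a in seq_len(n_comp)) {
    r <- as.numeric(y %*% object$U[, a]) / rs
    if (a > 1) {
      for (b in seq_len(a - 1)) r <- r - object$phi[a, b] * P[, b]
    }
    P[, a] <- r / object$s[a]
  }
  if (object$deshrink == "classical") {
    init <- P[, 1] * object$s[1] + object$xbar
    return(as.numeric((init - object$classical["b0"]) / object$classical["b1"]))
  }
  cf <- object$coefs[[n_comp]]
  as.numeric(cbind(1, P) %*% cf)
}

#' @export
print.wapls_model <- function(x, ...) {
  cat(sprintf("<wapls_model> %d component(s), %d taxa, %s deshrinking\n",
              x$n_comp, length(x$taxa), x$deshrink))
  invisible(x)
}

#' Choose the WA-PLS component count by cross-validated RMSEP
#'
#' @param calib A [calibration_set()].
#' @param variable Climate variable name.
#' @param max_comp Largest component count tried.
#' @param seed Unused placeholder for interface symmetry (LOO is
#'   deterministic).
#' @return A list with `n_comp` (the RMSEP-minimising count) and `rmsep`
#'   (per-component LOO RMSEP).
#' @export
wapls_select_ncomp <- function(calib, variable = "mtco", max_comp = 5,
                               seed = NULL) {
  x <- calib$climate[[variable]]
  y <- calib$features
  n <- nrow(y)
  max_comp <- min(max_comp, ncol(y) - 1)
  pred <- matrix(NA_real_, n, max_comp)
  for (i in seq_len(n)) {
    fit <- wapls_fit(y[-i, , drop = FALSE], x[-i], n_comp = max_comp)
    for (a in seq_len(max_comp)) {
      pred[i, a] <- predict(fit, y[i, , drop = FALSE], n_comp = a)
    }
  }
  rmsep <- sqrt(colMeans((pred - x)^2))
  list(n_comp = which.min(rmsep), rmsep = rmsep)
}
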