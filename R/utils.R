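# Internal helpers shared across modules.

# Great-circle distance in km on a 6371-km sphere (haversine), vectorised.
haversine_km <- function(lat1, lon1, lat2, lon2) {
  rad <- pi / 180
  dlat <- (lat2 - lat1) * rad
  dlon <- (lon2 - lon1) * rad
  a <- sin(dlat / 2)^2 + cos(lat1 * rad) * cos(lat2 * rad) * sin(dlon / 2)^2
  2 * 6371 * asin(pmin(1, sqrt(a)))
}

# Normalise longitudes to [-180, 180).
normalize_lon <- function(lon) {
  ((lon + 180) %% 360) - 180
}

#' Derive a stage seed from a master seed
#'
#' Stage seeds are `seed + 1009 * index` where `index` is the position of the
#' stage name in the pipeline's fixed stage list. The scheme is deterministic
#' and keeps seeds well below `2^31` for small master seeds, so any stage can
#' be rerun in isolation with the same stream.
#'
#' @param seed Integer master seed.
#' @param stage Stage name (see [pipeline_stages()]).
#' @return An integer seed.
#' @export
split_seed <- function(seed, stage) {
  idx <- match(stage, pipeline_stages())
  if (is.na(idx)) abort(paste0("unknown pipeline stage: ", stage))
  as.integer(seed + 1009L * idx)
}

#' Pipeline stage names, in dependency order
#' @return Character vector of stage names.
#' @export
pipeline_stages <- function() {
  c("simulate", "screen", "chronology", "pft", "recon", "validate",
    "significance", "correct", "stack", "eof")
}

# Linear-interpolation weight matrix mapping values at `x_in` (sorted,
# unique) to query points `x_out`. Rows for queries outside [min, max] are
# all-NA. Used by the stacking Monte Carlo so that an ensemble of perturbed
# series can be binned with a single matrix product.
interp_weights <- function(x_out, x_in) {
  n_in <- length(x_in)
  W <- matrix(0, nrow = length(x_out), ncol = n_in)
  inside <- x_out >= x_in[1] & x_out <= x_in[n_in]
  idx <- findInterval(x_out, x_in, rightmost.closed = TRUE)
  for (i in seq_along(x_out)) {
    if (!inside[i]) {
      W[i, ] <- NA_real_
      next
    }
    j <- idx[i]
    if (x_out[i] == x_in[j]) {
      W[i, j] <- 1
    } else {
      frac <- (x_out[i] - x_in[j]) / (x_in[j + 1] - x_in[j])
      W[i, j] <- 1 - frac
      W[i, j + 1] <- frac
    }
  }
  W
}

# Linear interpolation with linear extrapolation from the end segments.
approx_extrap <- function(x, y, xout) {
  stopifnot(length(x) >= 2)
  out <- approx(x, y, xout = xout, ties = "ordered")$y
  lo <- xout < x[1]
  hi <- xout > x[length(x)]
  if (any(lo)) {
    s <- (y[2] - y[1]) / (x[2] - x[1])
    out[lo] <- y[1] + s * (xout[lo] - x[1])
  }
  if (any(hi)) {
    n <- length(x)
    s <- (y[n] - y[n - 1]) / (x[n] - x[n - 1])
    out[hi] <- y[n] + s * (xout[hi] - x[n])
  }
  out
}

climate_vars <- function() c("annt", "mtwa", "mtco")

# Validate a numeric matrix of non-negative assemblage data.
check_assemblage <- function(x, what = "assemblage") {
  x <- as.matrix(x)
  if (!is.numeric(x)) abort(paste0(what, " must be numeric"))
  if (anyNA(x)) abort(paste0(what, " contains missing values"))
  if (any(x < 0)) abort(paste0(what, " contains negative values"))
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a
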