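# broom-style tidiers for the fitted-object classes.

#' Tidy an RDA result
#' @param x An `rda_result`.
#' @param ... Unused.
#' @return A tibble with one row per eigenvalue (`component`, `kind`,
#'   `eigenvalue`, `proportion` of total inertia).
#' @exportS3Method generics::tidy
tidy.rda_result <- function(x, ...) {
  bind_rows(
    tibble(component = seq_along(x$eig_constrained), kind = "constrained",
           eigenvalue = x$eig_constrained),
    tibble(component = seq_along(x$eig_unconstrained), kind = "unconstrained",
           eigenvalue = x$eig_unconstrained)
  ) %>%
    mutate(proportion = .data$eigenvalue / x$total_inertia)
}

#' @rdname tidy.rda_result
#' @exportS3Method generics::glance
glance.rda_result <- function(x, ...) {
  tibble(var_explained = x$var_explained, lambda_ratio = x$lambda_ratio,
         p_value = x$p_value, n = x$n, n_perm = x$n_perm,
         partial = x$partial)
}

#' Tidy a variance partition
#' @param x A `variance_partition`.
#' @param ... Unused.
#' @return One row per component (`total_x1`, `total_x2`, `unique_x1`,
#'   `unique_x2`, `shared`, `combined`) with the explained fraction.
#' @exportS3Method generics::tidy
tidy.variance_partition <- function(x, ...) {
  tibble(
    component = c("total_x1", "total_x2", "unique_x1", "unique_x2",
                  "shared", "combined"),
    fraction = c(x$total_x1, x$total_x2, x$unique_x1, x$unique_x2,
                 x$shared, x$combined)
  )
}

#' @rdname tidy.variance_partition
#' @exportS3Method generics::glance
glance.variance_partition <- function(x, ...) {
  tibble(combined = x$combined, shared = x$shared,
         p_x1 = x$p_x1, p_x2 = x$p_x2,
         lambda_ratio_x1 = x$lambda_ratio_x1,
         lambda_ratio_x2 = x$lambda_ratio_x2)
}

#' Tidy an EOF result
#' @param x An `eof_result`.
#' @param ... Unused.
#' @return One row per mode with eigenvalue and variance fraction.
#' @exportS3Method generics::tidy
tidy.eof_result <- function(x, ...) {
  tibble(mode = seq_along(x$eigenvalues), eigenvalue = x$eigenvalues,
         variance_fraction = x$variance_fractions)
}

#' @rdname tidy.eof_result
#' @exportS3Method generics::glance
glance.eof_result <- function(x, ...) {
  tibble(n_units = length(x$units), n_steps = length(x$times),
         pc1_variance_fraction = x$variance_fractions[1])
}

#' Tidy a significance-test result
#' @param x A `significance_result`.
#' @param ... Unused.
#' @return One row per null replicate plus the observed statistic.
#' @exportS3Method generics::tidy
tidy.significance_result <- function(x, ...) {
  bind_rows(
    tibble(kind = "observed", var_explained = x$observed_var),
    tibble(kind = "null", var_explained = x$null_var)
  )
}

#' @rdname tidy.significance_result
#' @exportS3Method generics::glance
glance.significance_result <- function(x, ...) {
  tibble(variable = x$variable, observed_var = x$observed_var,
         threshold = x$threshold, quantile = x$quantile,
         n_rand = x$n_rand, pass = x$pass)
}
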