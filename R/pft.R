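# Biomization-style scoring: pollen proportions -> plant-functional-type
# affinity scores, score(s, pft) = sum_taxa w * sqrt(max(0, p - theta)).

#' Convert counts to proportions
#'
#' @param counts A `pollen_counts` tibble or a numeric samples x taxa
#'   matrix.
#' @return A samples x taxa matrix with rows summing to 1.
#' @export
to_proportions <- function(counts) {
  m <- if (is.matrix(counts)) counts else count_matrix(counts)
  m <- check_assemblage(m, "pollen counts")
  rs <- rowSums(m)
  if (any(rs == 0)) {
    bad <- rownames(m)[which(rs == 0)[1]] %||% which(rs == 0)[1]
    abort(paste0("sample with zero pollen sum: ", bad))
  }
  m / rs
}

#' Compute PFT affinity scores
#'
#' The classic biomization affinity: for each sample and PFT,
#' `sum over taxa of w(taxon, pft) * sqrt(max(0, p - theta))`, where `p` is
#' the taxon proportion and `theta` a small presence threshold (default
#' 0.5%). Taxa absent from the matrix contribute nothing and are reported
#' in the `"unmatched_taxa"` attribute. With `renormalize = TRUE` (the
#' default) proportions are recomputed on the sum of taxa present in the
#' matrix, the standard terrestrial-sum convention.
#'
#' @param props Samples x taxa proportion matrix (see [to_proportions()]),
#'   or a `pollen_counts` tibble (converted internally).
#' @param pft_matrix Taxa-PFT weight tibble (columns `taxon`, optional
#'   `region_id`, then PFT weights in \[0, 1\]); see
#'   [read_taxa_pft_matrix()] and [make_pft_matrix()].
#' @param theta Proportion threshold (>= 0).
#' @param region_id Optional region filter applied to `pft_matrix`.
#' @param renormalize Recompute proportions on the matrix taxa only.
#' @return A samples x PFT score matrix (class `matrix`) with attribute
#'   `unmatched_taxa`.
#' @export
#' @examples
#' pm <- tibble::tibble(taxon = c("A", "B"), tree = c(1, 0), herb = c(0, 1))
#' compute_pft_scores(matrix(c(0.36, 0.64), 1), pft_matrix = pm,
#'                    theta = 0, renormalize = FALSE)
compute_pft_scores <- function(props, pft_matrix, theta = 0.005,
                               region_id = NULL, renormalize = TRUE) {
  if (theta < 0) abort("theta must be >= 0")
  if (inherits(props, "pollen_counts")) props <- to_proportions(props)
  props <- check_assemblage(props, "proportions")
  if (is.null(colnames(props))) abort("proportion matrix must have taxon column names")
  pm <- as_tibble(pft_matrix)
  if (!is.null(region_id) && "region_id" %in% names(pm)) {
    pm <- pm[pm$region_id == region_id, ]
  }
  pfts <- attr(pft_matrix, "pfts") %||% setdiff(names(pm), c("taxon", "region_id"))
  taxa <- colnames(props)
  matched <- intersect(taxa, pm$taxon)
  unmatched <- setdiff(taxa, pm$taxon)
  if (length(matched) == 0) abort("no fossil taxon is covered by the taxa-PFT matrix")
  W <- as.matrix(pm[match(matched, pm$taxon), pfts, drop = FALSE])
  p <- props[, matched, drop = FALSE]
  if (renormalize) {
    rs <- rowSums(p)
    if (any(rs == 0)) {
      # samples with no matrix taxa keep an all-zero row
      rs[rs == 0] <- 1
    }
    p <- p / rs
  }
  scores <- sqrt(pmax(p - theta, 0)) %*% W
  rownames(scores) <- rownames(props)
  structure(scores, unmatched_taxa = unmatched)
}
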