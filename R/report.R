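# Diagnostic data products: PCA, Ward clustering, reproducibility curves,
# volcano-plot source data. All exports are data-only; rendering is left
# to the caller and never affects results.

#' PCA of the samples of a normalized matrix
#'
#' Principal components of the column-centered sample profiles
#' (samples as observations, proteins as variables).
#'
#' @param x normalized matrix (or `normalized_matrix`).
#' @return list with `scores` (samples x components), `explained`
#'   (non-increasing variance fractions summing to <= 1) and the `rotation`.
#' @export
pca_scores <- function(x) {
  x <- as_values(x)
  if (ncol(x) < 2) stop("PCA needs at least 2 samples", call. = FALSE)
  fit <- stats::prcomp(t(x), center = TRUE, scale. = FALSE)
  explained <- fit$sdev^2 / sum(fit$sdev^2)
  list(scores = fit$x, explained = explained, rotation = fit$rotation)
}

#' Ward hierarchical clustering with Euclidean distances
#'
#' Agglomerative clustering under Ward's minimum-variance criterion on
#' Euclidean distances (hclust method "ward.D2"), over rows or columns.
#' This is the clustering used for heatmap row/column ordering.
#'
#' @param x normalized matrix (or `normalized_matrix`).
#' @param axis "rows" (proteins) or "columns" (samples).
#' @return the `hclust` object (merge tree, heights, leaf `order`).
#' @export
ward_clustering <- function(x, axis = c("columns", "rows")) {
  x <- as_values(x)
  axis <- match.arg(axis)
  if (axis == "columns") x <- t(x)
  if (nrow(x) < 2) stop("need at least 2 items to cluster", call. = FALSE)
  if (any(!is.finite(x))) stop("non-finite values in matrix", call. = FALSE)
  stats::hclust(stats::dist(x, method = "euclidean"), method = "ward.D2")
}

#' Bootstrap reproducibility curves of a fitted statistic
#'
#' Tabulates, for every candidate top-list size k, the mean and standard
#' deviation of the bootstrap top-k overlap at the chosen statistic, for
#' the observed data and the group-label-permuted null.
#'
#' @param fit a `rots_fit` from [rots_optimize()].
#' @return data.frame: k, observed_mean, observed_sd, null_mean, null_sd.
#' @export
reproducibility_plot_data <- function(fit) {
  stopifnot(inherits(fit, "rots_fit"))
  data.frame(
    k = fit$ks,
    observed_mean = fit$overlap_obs_mean,
    observed_sd = fit$overlap_obs_sd,
    null_mean = fit$overlap_null_mean,
    null_sd = fit$overlap_null_sd
  )
}

#' Volcano-plot source data
#'
#' @param result a [rots_de()] table.
#' @return data.frame: protein_id, log2_fc (log2 of |signed fold change|,
#'   carrying the sign), neg_log10_p, selected.
#' @export
volcano_data <- function(result) {
  data.frame(
    protein_id = result$protein_id,
    log2_fc = sign(result$fold_change) * log2(abs(result$fold_change)),
    neg_log10_p = -log10(result$p),
    selected = result$selected,
    stringsAsFactors = FALSE
  )
}
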