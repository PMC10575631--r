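# Protein inference, detection filtering and variance stabilization for
# spectral-count matrices.

#' Aggregate peptide evidence into a protein count matrix
#'
#' Applies the two-peptide rule of shotgun proteomics protein inference: a
#' protein is retained only if at least `min_peptides` distinct peptides
#' were identified for it (across all samples, counting peptides with at
#' least one nonzero spectral count). Retained proteins get, per sample,
#' the sum of their peptide spectral counts.
#'
#' @param evidence data.frame with columns protein_id, peptide_id,
#'   sample_id, spectral_count (non-negative integers).
#' @param min_peptides minimum number of distinct identified peptides.
#' @return an integer protein x sample matrix.
#' @export
aggregate_proteins <- function(evidence, min_peptides = 2) {
  min_peptides <- as_count(min_peptides, "min_peptides")
  need <- c("protein_id", "peptide_id", "sample_id", "spectral_count")
  if (!is.data.frame(evidence) || !all(need %in% names(evidence))) {
    stop("evidence must have columns protein_id, peptide_id, sample_id, spectral_count",
         call. = FALSE)
  }
  if (nrow(evidence) == 0) {
    return(matrix(integer(0), nrow = 0, ncol = 0))
  }
  if (any(evidence$spectral_count < 0)) {
    stop("spectral counts must be non-negative", call. = FALSE)
  }
  # distinct peptides with evidence (nonzero somewhere), per protein
  seen <- evidence[evidence$spectral_count > 0, c("protein_id", "peptide_id")]
  seen <- unique(seen)
  npep <- table(seen$protein_id)
  keep <- names(npep)[npep >= min_peptides]
  ev <- evidence[evidence$protein_id %in% keep, , drop = FALSE]
  sample_ids <- unique(evidence$sample_id)
  if (length(keep) == 0) {
    m <- matrix(integer(0), nrow = 0, ncol = length(sample_ids),
                dimnames = list(character(0), sample_ids))
    return(m)
  }
  tab <- stats::xtabs(spectral_count ~ protein_id + sample_id, data = ev)
  m <- matrix(as.integer(tab), nrow = nrow(tab),
              dimnames = list(rownames(tab), colnames(tab)))
  # keep the sample order of first appearance, and sort proteins by id
  m <- m[order(rownames(m)), intersect(sample_ids, colnames(m)), drop = FALSE]
  m
}

#' Detection-based variation filter
#'
#' Keeps proteins detected (spectral count > 0) in at least
#' `min_detected_samples` samples anywhere in the matrix. This is the
#' unsupervised inclusion filter applied before normalization in
#' spectral-count workflows.
#'
#' @param m protein x sample count matrix.
#' @param min_detected_samples minimum number of samples with a nonzero
#'   count.
#' @return the filtered matrix, column order preserved.
#' @export
variation_filter <- function(m, min_detected_samples = 4) {
  min_detected_samples <- as_count(min_detected_samples, "min_detected_samples")
  if (!is.matrix(m) || nrow(m) == 0) stop("matrix must be non-empty",
                                          call. = FALSE)
  if (min_detected_samples > ncol(m)) {
    stop("min_detected_samples exceeds the number of samples", call. = FALSE)
  }
  m[rowSums(m > 0) >= min_detected_samples, , drop = FALSE]
}

#' Calibrated generalized-log variance-stabilizing normalization
#'
#' A two-step transform in the spirit of variance-stabilizing normalization
#' for quantitative proteomics, adapted to overdispersed counts:
#'
#' 1. *Affine calibration.* Each sample is calibrated against a pseudo-
#'    reference sample (the per-protein median across samples) by a robust
#'    linear fit of its nonzero-count quantiles on the reference quantiles,
#'    giving a per-sample offset and scale. This removes run-to-run depth
#'    and background differences.
#' 2. *Generalized log.* Calibrated values x are transformed by the
#'    arsinh-family map asinh(sqrt(phi) * x) / sqrt(phi), linear below the
#'    crossover abundance 1/phi and logarithmic above it -- the
#'    variance-stabilizing shape for counts with variance mu + phi * mu^2.
#'    The overdispersion phi is estimated from the calibrated matrix by a
#'    robust moment fit of the row variance-mean relationship.
#'
#' The transform is strictly increasing within each sample, so raw count
#' order is preserved; after transformation the row-SD versus row-mean
#' trend on overdispersed data is approximately flat.
#'
#' @param m protein x sample count matrix (after [variation_filter()]).
#' @param n_quantiles number of quantile anchors for the calibration fit.
#' @return an object of class `normalized_matrix`: list with `values`
#'   (transformed matrix), `params` (per-sample offset and scale), and
#'   `phi` (estimated overdispersion).
#' @export
glog_normalize <- function(m, n_quantiles = 19) {
  if (!is.matrix(m) || nrow(m) < 2 || ncol(m) < 2) {
    stop("need a matrix with at least 2 rows and 2 columns", call. = FALSE)
  }
  if (any(colSums(m) == 0)) {
    stop("cannot calibrate a sample with all-zero counts", call. = FALSE)
  }
  # reference quantile curve: per-sample quantiles of the nonzero counts,
  # summarized by the across-sample median at each probability, so one
  # aberrant run cannot move the anchor
  probs <- seq_len(n_quantiles) / (n_quantiles + 1)
  Q <- vapply(seq_len(ncol(m)), function(j) {
    x <- m[, j]
    stats::quantile(x[x > 0], probs, names = FALSE)
  }, numeric(n_quantiles))
  qr <- apply(Q, 1, stats::median)

  params <- data.frame(sample_id = colnames(m), offset = NA_real_,
                       scale = NA_real_, stringsAsFactors = FALSE)
  calibrated <- m * 0
  for (j in seq_len(ncol(m))) {
    fit <- robust_line(qr, Q[, j])
    o <- fit[1]; s <- fit[2]
    if (!is.finite(s) || s <= 0) { o <- 0; s <- 1 }
    params$offset[j] <- o
    params$scale[j] <- s
    calibrated[, j] <- (m[, j] - o) / s
  }

  phi <- estimate_phi(calibrated)
  values <- glog_transform(calibrated, phi)
  dimnames(values) <- dimnames(m)
  structure(list(values = values, params = params, phi = phi),
            class = "normalized_matrix")
}

# Robust fit of y ~ a + b x; falls back to OLS, then to median-ratio.
robust_line <- function(x, y) {
  if (length(unique(x)) < 2) return(c(0, stats::median(y / pmax(x, 1e-9))))
  fit <- tryCatch(
    stats::coef(suppressWarnings(MASS::rlm(y ~ x, maxit = 100))),
    error = function(e) stats::coef(stats::lm(y ~ x))
  )
  as.numeric(fit)
}

# Overdispersion of var = mu + phi mu^2 from row moments. The per-row
# ratio (v - m) / m^2 is unbiased for phi but right-skewed, so a trimmed
# mean over the adequately-abundant rows is used.
estimate_phi <- function(calibrated) {
  mu <- rowMeans(calibrated)
  v <- apply(calibrated, 1, stats::var)
  use <- mu > 2
  if (sum(use) < 10) use <- mu > 0
  phi <- mean((v[use] - mu[use]) / mu[use]^2, trim = 0.1, na.rm = TRUE)
  min(max(phi, 1e-4), 10)
}

# Arsinh glog tuned to overdispersed counts: y = asinh(sqrt(phi) x) /
# sqrt(phi). Linear below the crossover abundance 1/phi (where shot noise
# dominates), logarithmic above it (where the phi mu^2 term dominates, so
# log-scale variance is constant at phi); the outer scaling puts the
# high-abundance standard deviation near 1. Smooth and strictly
# increasing on all reals, so small negative calibrated values are safe.
glog_transform <- function(x, phi) {
  b <- sqrt(phi)
  asinh(b * x) / b
}

#' @export
print.normalized_matrix <- function(x, ...) {
  cat(sprintf("normalized_matrix: %d proteins x %d samples (glog, phi = %.3g)\n",
              nrow(x$values), ncol(x$values), x$phi))
  invisible(x)
}
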