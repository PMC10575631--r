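# Reproducibility-optimized differential abundance.
#
# The test statistic family is d = |mean_a - mean_b| / (alpha1 + alpha2 * s),
# with s the pooled standard error. Rather than fixing (alpha1, alpha2), the
# procedure picks the member of the family (together with a top-list size k)
# whose top-k list is maximally reproducible across bootstrap resamples of
# the samples, relative to the same quantity on group-label-permuted data.
# Significance is then assessed by group-label permutation with a pooled
# null, and FDR by the permutation convention (expected null exceedances
# over observed exceedances).

#' Parameters of the reproducibility-optimized statistic
#'
#' @param grid_alpha1 regularization grid for the denominator constant; each
#'   value is paired with alpha2 = 1, and the scale-free variant
#'   (alpha1 = 1, alpha2 = 0, i.e. the plain mean difference) is always
#'   added as a candidate.
#' @param grid_k candidate top-list sizes for the reproducibility
#'   optimization (values larger than the matrix are dropped).
#' @param B number of bootstrap pairs.
#' @param P number of group-label permutations for p-values.
#' @param seed integer seed.
#' @return a validated list of class `rots_params`.
#' @export
rots_params <- function(grid_alpha1 = c(0, 0.01, 0.05, 0.1, 0.5, 1, 2, 5),
                        grid_k = c(25, 50, 100, 200, 400),
                        B = 500, P = 1000, seed = 1) {
  if (length(grid_alpha1) == 0 || any(grid_alpha1 < 0)) {
    stop("field 'grid_alpha1' must be non-empty and non-negative", call. = FALSE)
  }
  if (length(grid_k) == 0 || any(grid_k < 1)) {
    stop("field 'grid_k' must be non-empty positive integers", call. = FALSE)
  }
  structure(list(grid_alpha1 = as.numeric(sort(unique(grid_alpha1))),
                 grid_k = as.integer(sort(unique(grid_k))),
                 B = as_count(B, "B"), P = as_count(P, "P"),
                 seed = as_count(seed, "seed", min = 0)),
            class = "rots_params")
}

#' Reproducibility-optimized test statistic for one protein
#'
#' d = |mean(a) - mean(b)| / (alpha1 + alpha2 * s), where s is the pooled
#' standard error. With alpha1 = 0, alpha2 = 1 this is the absolute
#' ordinary two-sample t statistic; with alpha1 = 1, alpha2 = 0 it is the
#' absolute mean difference.
#'
#' @param a,b numeric vectors (>= 2 finite values each).
#' @param alpha1,alpha2 denominator weights; alpha2 must be 0 or 1 and
#'   alpha1 + alpha2 > 0.
#' @return the non-negative statistic.
#' @export
rots_statistic <- function(a, b, alpha1, alpha2) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) < 2 || length(b) < 2) {
    stop("each group needs at least 2 finite values", call. = FALSE)
  }
  check_alphas(alpha1, alpha2)
  diff <- abs(mean(a) - mean(b))
  if (alpha2 == 0) return(diff / alpha1)
  s <- pooled_se(a, b)
  den <- alpha1 + alpha2 * s
  if (den == 0) return(if (diff == 0) 0 else Inf)
  diff / den
}

check_alphas <- function(alpha1, alpha2) {
  if (!alpha2 %in% c(0, 1)) stop("alpha2 must be 0 or 1", call. = FALSE)
  if (alpha1 < 0) stop("alpha1 must be >= 0", call. = FALSE)
  if (alpha1 == 0 && alpha2 == 0) {
    stop("alpha1 and alpha2 cannot both be 0 (degenerate denominator)",
         call. = FALSE)
  }
  invisible(TRUE)
}

pooled_se <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  sp2 <- ((n1 - 1) * stats::var(a) + (n2 - 1) * stats::var(b)) / (n1 + n2 - 2)
  sqrt(sp2 * (1 / n1 + 1 / n2))
}

# Vectorized over rows of x; ia/ib are column indices (repeats allowed, so
# the same code serves bootstrap resamples).
row_rots_stats <- function(x, ia, ib, alpha1, alpha2) {
  n1 <- length(ia); n2 <- length(ib)
  xa <- x[, ia, drop = FALSE]; xb <- x[, ib, drop = FALSE]
  m1 <- rowMeans(xa); m2 <- rowMeans(xb)
  diff <- abs(m1 - m2)
  if (alpha2 == 0) return(diff / alpha1)
  v1 <- rowSums((xa - m1)^2) / (n1 - 1)
  v2 <- rowSums((xb - m2)^2) / (n2 - 1)
  se <- sqrt(((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2) *
               (1 / n1 + 1 / n2))
  d <- diff / (alpha1 + se)
  d[diff == 0] <- 0  # covers the 0/0 case when alpha1 = 0 and se = 0
  d
}

#' Fraction of shared members between the top-k of two rankings
#'
#' @param ranking_a,ranking_b character vectors ordering the same ids.
#' @param k top-list size, 1 <= k <= n.
#' @return |top-k(a) intersect top-k(b)| / k.
#' @export
topk_overlap <- function(ranking_a, ranking_b, k) {
  n <- length(ranking_a)
  if (length(ranking_b) != n || !setequal(ranking_a, ranking_b)) {
    stop("rankings must order the same id universe", call. = FALSE)
  }
  if (k < 1 || k > n) stop("k out of range", call. = FALSE)
  length(intersect(ranking_a[seq_len(k)], ranking_b[seq_len(k)])) / k
}

#' Choose the statistic and top-list size maximizing bootstrap reproducibility
#'
#' For every candidate (alpha1, alpha2) and every k on the grid, computes
#' the mean top-k overlap R_k(alpha) across B bootstrap pairs (samples
#' resampled with replacement within each group) and the same quantity
#' R0_k(alpha) on group-label-permuted data, then selects the
#' (alpha, k) maximizing the reproducibility Z-score
#' Z_k(alpha) = (R_k - R0_k) / sd_k. Ties are broken toward smaller alpha1,
#' then smaller k.
#'
#' @param x normalized protein x sample matrix (or `normalized_matrix`).
#' @param design study design data.frame.
#' @param contrast character pair (reference condition, test condition).
#' @param params a [rots_params()].
#' @return a list of class `rots_fit`: chosen `alpha1`, `alpha2`, `k`, `Z`,
#'   the full Z table, and per-k overlap summaries for reproducibility
#'   plots.
#' @export
rots_optimize <- function(x, design, contrast, params = rots_params()) {
  x <- as_values(x)
  design <- check_design(design, colnames(x))
  grp <- contrast_samples(design, contrast, colnames(x))
  ia <- match(grp$reference, colnames(x))
  ib <- match(grp$test, colnames(x))
  if (length(ia) < 2 || length(ib) < 2) {
    stop("each contrast side needs at least 2 samples", call. = FALSE)
  }
  if (params$B < 2) stop("field 'B' must be >= 2", call. = FALSE)
  n <- nrow(x)
  alphas <- rbind(data.frame(alpha1 = params$grid_alpha1, alpha2 = 1),
                  data.frame(alpha1 = 1, alpha2 = 0))
  ks <- params$grid_k[params$grid_k <= n]
  if (length(ks) == 0) stop("all grid_k values exceed the number of proteins",
                            call. = FALSE)
  na <- nrow(alphas); nk <- length(ks)

  ov_obs <- array(NA_real_, c(params$B, na, nk))
  ov_null <- array(NA_real_, c(params$B, na, nk))
  all_idx <- c(ia, ib)

  with_seed(substream_seed(params$seed, "rots_bootstrap"), {
    for (b in seq_len(params$B)) {
      ov_obs[b, , ] <- pair_overlaps(x, ia, ib, alphas, ks)
      perm <- sample(all_idx)
      pia <- perm[seq_along(ia)]
      pib <- perm[length(ia) + seq_along(ib)]
      ov_null[b, , ] <- pair_overlaps(x, pia, pib, alphas, ks)
    }
  })

  R <- apply(ov_obs, c(2, 3), mean)
  R0 <- apply(ov_null, c(2, 3), mean)
  sdk <- apply(ov_obs, c(2, 3), stats::sd)
  Z <- (R - R0) / pmax(sdk, 1e-12)

  # maximize Z; ties -> smaller alpha1, then smaller k
  cand <- expand.grid(a = seq_len(na), j = seq_len(nk))
  cand$z <- Z[cbind(cand$a, cand$j)]
  cand <- cand[order(-cand$z, alphas$alpha1[cand$a], ks[cand$j]), ]
  best <- cand[1, ]

  structure(list(
    alpha1 = alphas$alpha1[best$a], alpha2 = alphas$alpha2[best$a],
    k = ks[best$j], Z = best$z,
    Z_table = Z, alphas = alphas, ks = ks,
    overlap_obs_mean = R[best$a, ], overlap_obs_sd = sdk[best$a, ],
    overlap_null_mean = R0[best$a, ],
    overlap_null_sd = apply(ov_null, c(2, 3), stats::sd)[best$a, ],
    contrast = contrast, n_proteins = n
  ), class = "rots_fit")
}

# One bootstrap pair: resample within groups twice, rank by every candidate
# statistic, and return the [alpha, k] overlap matrix.
pair_overlaps <- function(x, ia, ib, alphas, ks) {
  r1 <- resample_ranks(x, ia, ib, alphas)
  r2 <- resample_ranks(x, ia, ib, alphas)
  out <- matrix(NA_real_, nrow(alphas), length(ks))
  for (a in seq_len(nrow(alphas))) {
    for (j in seq_along(ks)) {
      k <- ks[j]
      out[a, j] <- sum(r1[, a] <= k & r2[, a] <= k) / k
    }
  }
  out
}

# Rank positions (1 = largest statistic) per candidate alpha, for one
# within-group bootstrap resample.
resample_ranks <- function(x, ia, ib, alphas) {
  bia <- sample(ia, length(ia), replace = TRUE)
  bib <- sample(ib, length(ib), replace = TRUE)
  n <- nrow(x)
  rnk <- matrix(NA_integer_, n, nrow(alphas))
  for (a in seq_len(nrow(alphas))) {
    d <- row_rots_stats(x, bia, bib, alphas$alpha1[a], alphas$alpha2[a])
    ord <- order(-d)
    rnk[ord, a] <- seq_len(n)
  }
  rnk
}

#' Permutation p-values and permutation FDR for the chosen statistic
#'
#' Group labels are permuted P times (when the design admits no more than P
#' distinct label assignments, all of them are enumerated exactly once
#' instead, making the test exact); the null statistics of all proteins
#' and all permutations are pooled. p(g) = (1 + #null >= d(g)) /
#' (1 + total null count). FDR(g) = (mean per-permutation count of null
#' statistics >= d(g)) / (observed count >= d(g)), clipped to [0, 1] and
#' made monotone non-increasing in d.
#'
#' @param x normalized matrix (or `normalized_matrix`).
#' @param design study design.
#' @param contrast character pair (reference, test).
#' @param alpha1,alpha2 statistic parameters (typically from [rots_optimize()]).
#' @param P number of permutations (>= 1; >= 100 recommended).
#' @param seed integer seed.
#' @return data.frame with protein_id, d, p, fdr.
#' @export
permutation_pvalues <- function(x, design, contrast, alpha1, alpha2,
                                P = 1000, seed = 1) {
  x <- as_values(x)
  if (P < 1) stop("field 'P' must be >= 1", call. = FALSE)
  check_alphas(alpha1, alpha2)
  design <- check_design(design, colnames(x))
  grp <- contrast_samples(design, contrast, colnames(x))
  ia <- match(grp$reference, colnames(x))
  ib <- match(grp$test, colnames(x))
  n <- nrow(x)
  d <- row_rots_stats(x, ia, ib, alpha1, alpha2)

  all_idx <- c(ia, ib)
  n_total <- length(all_idx)
  n_distinct <- choose(n_total, length(ia))
  if (n_distinct <= P) {
    # few enough label assignments: enumerate them all exactly once
    combos <- utils::combn(n_total, length(ia))
    null <- matrix(NA_real_, n, ncol(combos))
    for (p in seq_len(ncol(combos))) {
      pia <- all_idx[combos[, p]]
      pib <- all_idx[-combos[, p]]
      null[, p] <- row_rots_stats(x, pia, pib, alpha1, alpha2)
    }
    P <- ncol(combos)
  } else {
    null <- matrix(NA_real_, n, P)
    with_seed(substream_seed(seed, "rots_permutation"), {
      for (p in seq_len(P)) {
        perm <- sample(all_idx)
        pia <- perm[seq_along(ia)]
        pib <- perm[length(ia) + seq_along(ib)]
        null[, p] <- row_rots_stats(x, pia, pib, alpha1, alpha2)
      }
    })
  }

  sorted_null <- sort(as.vector(null))
  total <- length(sorted_null)
  # null >= d  <=>  total - #(null < d)
  n_lt <- findInterval(d, sorted_null, left.open = TRUE)
  count_ge <- total - n_lt
  pval <- (1 + count_ge) / (1 + total)

  sorted_obs <- sort(d)
  obs_ge <- n - findInterval(d, sorted_obs, left.open = TRUE)
  fdr <- pmin(pmax((count_ge / P) / obs_ge, 0), 1)
  ord <- order(-d)
  fdr[ord] <- rev(cummin(rev(fdr[ord])))

  data.frame(protein_id = rownames(x), d = d, p = pval, fdr = fdr,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Differential abundance for one contrast, end to end
#'
#' Runs [rots_optimize()] then [permutation_pvalues()], and annotates each
#' protein with its signed fold change on the count scale, its total
#' spectral count across the contrast samples, the sign of the normalized
#' mean difference, and the selection flag at the p < `p_cut`,
#' FDR <= `fdr_cut` thresholds.
#'
#' @param normalized `normalized_matrix` (or plain matrix on the glog scale).
#' @param counts the raw count matrix (same proteins; used for fold change
#'   and total spectra).
#' @param design study design.
#' @param contrast character pair (reference condition, test condition).
#' @param params a [rots_params()].
#' @param p_cut,fdr_cut selection thresholds.
#' @return data.frame of class `rots_result` with one row per protein and
#'   the fitted `rots_fit` in attribute "fit".
#' @export
rots_de <- function(normalized, counts, design, contrast,
                    params = rots_params(), p_cut = 0.05, fdr_cut = 0.25) {
  x <- as_values(normalized)
  stopifnot(identical(rownames(x), rownames(counts)))
  fit <- rots_optimize(x, design, contrast, params)
  res <- permutation_pvalues(x, design, contrast, fit$alpha1, fit$alpha2,
                             P = params$P, seed = params$seed)
  grp <- contrast_samples(design, contrast, colnames(x))
  m_ref <- rowMeans(x[, grp$reference, drop = FALSE])
  m_tst <- rowMeans(x[, grp$test, drop = FALSE])
  res$mean_diff <- m_tst - m_ref
  res$fold_change <- fold_change(counts, design, contrast)
  res$total_spectra <- as.integer(rowSums(
    counts[, c(grp$reference, grp$test), drop = FALSE]))
  res$selected <- res$p < p_cut & res$fdr <= fdr_cut
  attr(res, "fit") <- fit
  class(res) <- c("rots_result", class(res))
  res
}

#' Select differential proteins at the p and FDR thresholds
#'
#' @param result a [rots_de()] table (needs p, fdr, mean_diff columns).
#' @param p_cut strict upper bound on the permutation p-value.
#' @param fdr_cut inclusive upper bound on the permutation FDR.
#' @return list with `up`, `down` (split by sign of the normalized mean
#'   difference) and `all` protein id vectors.
#' @export
select_de <- function(result, p_cut = 0.05, fdr_cut = 0.25) {
  sel <- result$p < p_cut & result$fdr <= fdr_cut
  ids <- result$protein_id[sel]
  up <- result$protein_id[sel & result$mean_diff > 0]
  list(up = up, down = setdiff(ids, up), all = ids)
}

#' Three-way Venn partition
#'
#' Counts the 7 disjoint regions of three sets over one id universe; region
#' names encode membership as three 0/1 digits in input-set order
#' (e.g. "110" = in sets 1 and 2 only).
#'
#' @param sets list of three character vectors.
#' @return named integer vector of the 7 region counts.
#' @export
venn_partition <- function(sets) {
  stopifnot(length(sets) == 3)
  u <- unique(unlist(sets))
  member <- vapply(sets, function(s) u %in% s, logical(length(u)))
  if (length(u) == 0) member <- matrix(logical(0), 0, 3)
  if (length(u) == 1) member <- matrix(member, 1, 3)
  code <- apply(member, 1, function(r) paste(as.integer(r), collapse = ""))
  regions <- c("100", "010", "001", "110", "101", "011", "111")
  out <- stats::setNames(integer(7), regions)
  tab <- table(code)
  out[names(tab)[names(tab) %in% regions]] <-
    as.integer(tab[names(tab) %in% regions])
  out
}
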