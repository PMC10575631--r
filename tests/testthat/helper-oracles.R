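# Independent oracles used across test files. Each re-derives the quantity
# under test from first principles (brute force, enumeration, closed form),
# without calling the implementation path it checks.

# Full running-sum enrichment score: walk every rank, O(N).
brute_enrichment_score <- function(scores_desc, is_hit, weight_p) {
  N <- length(scores_desc)
  w <- abs(scores_desc)^weight_p
  W <- sum(w[is_hit])
  miss <- 1 / (N - sum(is_hit))
  run <- numeric(N)
  acc <- 0
  for (i in seq_len(N)) {
    acc <- acc + if (is_hit[i]) (if (W > 0) w[i] / W else 0) else -miss
    run[i] <- acc
  }
  M <- max(abs(run))
  peak <- min(which(abs(run) >= M - 1e-9))  # earliest peak on magnitude ties
  list(es = if (M == 0) 0 else run[peak],
       peak_index = if (M == 0) 0L else peak,
       running_sum = run)
}

# Hypergeometric upper tail P(X >= k) by explicit summation of choose().
brute_hyper_tail <- function(k, K, N, q) {
  if (K == 0) return(1)
  kk <- max(0, q + K - N):min(q, K)
  probs <- choose(K, kk) * choose(N - K, q - kk) / choose(N, q)
  sum(probs[kk >= k])
}

# Exhaustive Ward agglomeration over a small point set. At each step merge
# the pair of clusters with the smallest increase in total within-cluster
# sum of squares; returns the sequence of merged cluster membership sets.
brute_ward_merges <- function(points) {
  clusters <- lapply(seq_len(nrow(points)), identity)
  merges <- list()
  sse <- function(idx) {
    if (length(idx) == 1) return(0)
    ctr <- colMeans(points[idx, , drop = FALSE])
    sum(sweep(points[idx, , drop = FALSE], 2, ctr)^2)
  }
  while (length(clusters) > 1) {
    best <- NULL; best_cost <- Inf
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (i >= j) next
      cost <- sse(c(clusters[[i]], clusters[[j]])) -
        sse(clusters[[i]]) - sse(clusters[[j]])
      if (cost < best_cost - 1e-12) { best_cost <- cost; best <- c(i, j) }
    }
    merged <- sort(c(clusters[[best[1]]], clusters[[best[2]]]))
    merges[[length(merges) + 1]] <- merged
    clusters <- c(clusters[-best], list(merged))
  }
  merges
}

# Membership sets at each hclust merge step.
hclust_merge_sets <- function(hc) {
  n <- nrow(hc$merge) + 1
  sets <- vector("list", nrow(hc$merge))
  for (s in seq_len(nrow(hc$merge))) {
    grab <- function(v) if (v < 0) -v else sets[[v]]
    sets[[s]] <- sort(c(grab(hc$merge[s, 1]), grab(hc$merge[s, 2])))
  }
  sets
}

# Small Gaussian matrix on the normalized scale, with optional planted
# group shifts; used for testing the differential-abundance machinery
# directly, independent of the count simulator.
gaussian_matrix <- function(n_proteins, n_per_group, seed, n_de = 0,
                            effect = 0) {
  set.seed(seed)
  x <- matrix(stats::rnorm(n_proteins * 2 * n_per_group), n_proteins,
              2 * n_per_group)
  dimnames(x) <- list(sprintf("P%04d", seq_len(n_proteins)),
                      sprintf("S%02d", seq_len(2 * n_per_group)))
  de <- integer(0)
  if (n_de > 0) {
    de <- sample(n_proteins, n_de)
    test_cols <- (n_per_group + 1):(2 * n_per_group)
    x[de, test_cols] <- x[de, test_cols] +
      sample(c(-effect, effect), n_de, replace = TRUE)
  }
  design <- data.frame(sample_id = colnames(x),
                       condition = rep(c("healthy", "patient1"),
                                       each = n_per_group),
                       stringsAsFactors = FALSE)
  list(x = x, design = design, de = rownames(x)[de],
       contrast = c("healthy", "patient1"))
}
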