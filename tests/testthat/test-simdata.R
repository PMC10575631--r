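# The count simulator: planted truth bookkeeping, count-model moments,
# peptide partitioning, and gene-set planting.

test_that("config validation names the offending field", {
  expect_error(sim_config(n_proteins = 0), "n_proteins")
  expect_error(sim_config(de_fraction = 1.5), "de_fraction")
  expect_error(sim_config(detection_prob = 0), "detection_prob")
  expect_error(sim_config(dispersion = -1), "dispersion")
  expect_error(sim_config(set_size_range = c(30, 10)), "set_size_range")
})

test_that("no planted signal when de_fraction is 0, and seeds control output", {
  cfg <- sim_config(n_proteins = 100, n_samples_per_group = 3,
                    de_fraction = 0, seed = 5)
  sim <- simulate_counts(cfg)
  expect_length(sim$truth$de_proteins, 0)
  expect_identical(dim(sim$counts), c(100L, 6L))

  sim2 <- simulate_counts(cfg)
  expect_identical(sim$counts, sim2$counts)

  cfg3 <- sim_config(n_proteins = 100, n_samples_per_group = 3,
                     de_fraction = 0, seed = 6)
  expect_false(identical(simulate_counts(cfg3)$counts, sim$counts))
})

test_that("counts are Poisson-like in the small-dispersion limit", {
  # 32 replicates: the chi-square spread of a 16-sample variance ratio
  # alone would push ~7% of true-Poisson rows outside [0.5, 2]
  cfg <- sim_config(n_proteins = 2000, n_samples_per_group = 16,
                    dispersion = 1e-6, detection_prob = 1, de_fraction = 0,
                    seed = 2)
  sim <- simulate_counts(cfg)
  mu <- rowMeans(sim$counts)
  v <- apply(sim$counts, 1, var)
  keep <- mu > 1  # ratio is meaningless for essentially-absent proteins
  ratio <- v[keep] / mu[keep]
  expect_gt(mean(ratio > 0.5 & ratio < 2), 0.95)
})

test_that("counts are overdispersed when dispersion is large", {
  cfg <- sim_config(n_proteins = 1000, n_samples_per_group = 8,
                    dispersion = 1, detection_prob = 1, de_fraction = 0,
                    seed = 2)
  sim <- simulate_counts(cfg)
  mu <- rowMeans(sim$counts)
  v <- apply(sim$counts, 1, var)
  keep <- mu > 5
  expect_gt(median(v[keep] / mu[keep]), 2)
})

test_that("planted rows shift by effect_log2 on the log scale", {
  cfg <- sim_config(n_proteins = 3000, n_samples_per_group = 10,
                    de_fraction = 0.1, effect_log2 = 2, dispersion = 0.3,
                    detection_prob = 1, seed = 8)
  sim <- simulate_counts(cfg)
  up <- names(sim$truth$directions)[sim$truth$directions == "up"]
  lc <- log2(sim$counts + 1)
  healthy <- sim$design$condition == "healthy"
  diff_up <- rowMeans(lc[up, !healthy, drop = FALSE]) -
    rowMeans(lc[up, healthy, drop = FALSE])
  # +1 offset and count noise attenuate the shift; mean recovery within 20%
  expect_equal(mean(diff_up), 2, tolerance = 0.2)
  expect_true(all(sim$truth$de_proteins %in% rownames(sim$counts)))
})

test_that("peptide partition conserves protein counts exactly", {
  m <- matrix(c(5L, 0L, 3L), 1, 3,
              dimnames = list("P0001", c("S01", "S02", "S03")))
  pep <- simulate_peptides(m, c(2, 2), seed = 1)
  sums <- tapply(pep$spectral_count, pep$sample_id, sum)
  expect_identical(as.integer(sums[c("S01", "S02", "S03")]), c(5L, 0L, 3L))
  expect_length(unique(pep$peptide_id), 2L)

  one <- simulate_peptides(m, c(1, 1), seed = 1)
  expect_length(unique(one$peptide_id), 1L)

  empty <- simulate_peptides(m[0, , drop = FALSE], c(1, 3), seed = 1)
  expect_identical(nrow(empty), 0L)
})

test_that("peptide table round-trips through protein aggregation", {
  set.seed(4)
  m <- matrix(rpois(50 * 8, 6), 50, 8,
              dimnames = list(sprintf("P%03d", 1:50), sprintf("S%02d", 1:8)))
  storage.mode(m) <- "integer"
  pep <- simulate_peptides(m, c(1, 5), seed = 9)
  agg <- aggregate_proteins(pep, min_peptides = 2)
  shared <- intersect(rownames(agg), rownames(m))
  expect_gt(length(shared), 0)
  expect_identical(agg[shared, colnames(m)], m[shared, ])
})

test_that("gene-set planting is controlled by planted_set_fraction", {
  cfg <- sim_config(n_proteins = 500, n_samples_per_group = 4,
                    de_fraction = 0.2, n_sets = 80,
                    set_size_range = c(10, 30), planted_set_fraction = 0,
                    seed = 3)
  sim <- simulate_counts(cfg)
  gs <- simulate_genesets(rownames(sim$counts), cfg, sim$truth)
  expect_length(gs$truth$planted_sets, 0)
  # with no planting, no set should overlap the planted proteins beyond
  # chance: Bonferroni-adjusted hypergeometric tail check
  de <- sim$truth$de_proteins
  ps <- vapply(gs$collection, function(s) {
    brute_hyper_tail(length(intersect(s, de)), length(s), 500, length(de))
  }, numeric(1))
  expect_gt(min(ps) * length(ps), 0.01)
})

test_that("a fully planted set draws all members from the planted proteins", {
  cfg <- sim_config(n_proteins = 500, n_samples_per_group = 4,
                    de_fraction = 0.4, n_sets = 1, set_size_range = c(20, 20),
                    planted_set_fraction = 1, seed = 3)
  sim <- simulate_counts(cfg)
  gs <- simulate_genesets(rownames(sim$counts), cfg, sim$truth,
                          de_member_prob = 1)
  set <- gs$collection[[1]]
  expect_length(set, 20L)
  expect_false(anyDuplicated(set) > 0)
  expect_true(all(set %in% sim$truth$de_proteins))
  expect_identical(gs$truth$planted_sets, names(gs$collection))
})

test_that("oversized sets are rejected", {
  cfg <- sim_config(n_proteins = 10, n_samples_per_group = 2, n_sets = 2,
                    set_size_range = c(5, 50), seed = 1)
  sim <- simulate_counts(cfg)
  expect_error(simulate_genesets(rownames(sim$counts), cfg, sim$truth),
               "set_size_range")
})
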