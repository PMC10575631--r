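# Ranked lists, the running-sum enrichment score, permutation significance,
# and leading-edge extraction.

ranked_from <- function(ids, d) {
  build_ranked_list(data.frame(protein_id = ids, d = d,
                               stringsAsFactors = FALSE))
}

test_that("ranking is by |statistic| with deterministic ties", {
  r <- ranked_from(c("A", "B", "C"), c(3, -5, 1))
  expect_identical(r$protein_id, c("B", "A", "C"))

  tied <- ranked_from(c("C", "A", "B"), c(2, 2, 2))
  expect_identical(tied$protein_id, c("A", "B", "C"))

  expect_error(ranked_from(c("A", "A"), c(1, 2)), "duplicate")

  set.seed(61)
  d <- rnorm(50)
  ids <- sprintf("P%02d", 1:50)
  r2 <- ranked_from(ids, d)
  expect_identical(r2$protein_id, ids[order(-abs(d), ids)])
})

test_that("enrichment score matches the brute-force running sum", {
  # single member at rank 1 has ES exactly 1
  r <- ranked_from(sprintf("P%02d", 1:10), 10:1)
  one <- enrichment_score(r, "P01")
  expect_identical(one$es, 1)
  expect_identical(one$peak_index, 1L)

  # a bottom-k set with weight 0 accumulates deficit first: negative ES
  bottom <- enrichment_score(r, sprintf("P%02d", 8:10), weight_p = 0)
  expect_lt(bottom$es, 0)

  expect_error(enrichment_score(r, "absent"), "disjoint")
  expect_error(enrichment_score(r, sprintf("P%02d", 1:10)), "whole universe")

  set.seed(62)
  for (i in 1:1000) {
    scores <- sort(abs(rnorm(10)), decreasing = TRUE)
    ids <- sprintf("G%02d", 1:10)
    hits <- sort(sample(10, 3))
    wp <- sample(c(0, 1, 1.5), 1)
    got <- enrichment_score(ranked_from(ids, scores), ids[hits],
                            weight_p = wp, return_running = TRUE)
    want <- brute_enrichment_score(scores, seq_len(10) %in% hits, wp)
    expect_equal(got$es, want$es, tolerance = 1e-12)
    expect_equal(got$running_sum, want$running_sum, tolerance = 1e-12)
  }
})

test_that("ES is scale-invariant, bounded, and extreme only for prefixes", {
  set.seed(63)
  scores <- sort(abs(rnorm(40)), decreasing = TRUE)
  ids <- sprintf("G%02d", 1:40)
  set <- sample(ids, 8)
  e1 <- enrichment_score(ranked_from(ids, scores), set)
  e2 <- enrichment_score(ranked_from(ids, scores * 7), set)
  expect_equal(e1$es, e2$es, tolerance = 1e-12)
  expect_lte(abs(e1$es), 1)

  # weight 0: |ES| = 1 iff members form a contiguous prefix
  prefix <- enrichment_score(ranked_from(ids, scores), ids[1:5], weight_p = 0)
  expect_equal(prefix$es, 1)
  spread <- enrichment_score(ranked_from(ids, scores), ids[c(1:4, 20)],
                             weight_p = 0)
  expect_lt(abs(spread$es), 1)
})

test_that("weight-0 ES equals the KS running-sum statistic", {
  set.seed(64)
  for (i in 1:50) {
    n <- 30
    ids <- sprintf("G%02d", 1:n)
    scores <- sort(abs(rnorm(n)), decreasing = TRUE)
    hits <- sort(sample(n, 6))
    got <- enrichment_score(ranked_from(ids, scores), ids[hits], weight_p = 0)
    # KS-style oracle: D(i) = hits_ecdf(i) - miss_ecdf(i), max |D|,
    # earliest index on magnitude ties
    hit_ind <- seq_len(n) %in% hits
    D <- cumsum(hit_ind) / 6 - cumsum(!hit_ind) / (n - 6)
    peak <- min(which(abs(D) >= max(abs(D)) - 1e-9))
    expect_equal(got$es, D[peak], tolerance = 1e-12)
  }
})

test_that("ES agrees with the fgsea reference implementation", {
  set.seed(65)
  for (i in 1:50) {
    n <- 50
    stats <- sort(abs(rnorm(n)) + 1e-3, decreasing = TRUE)
    names(stats) <- sprintf("G%02d", 1:n)
    hits <- sort(sample(n, 7))
    ours <- enrichment_score(ranked_from(names(stats), stats),
                             names(stats)[hits], weight_p = 1)
    ref <- fgsea::calcGseaStat(stats, selectedStats = hits, gseaParam = 1)
    expect_equal(ours$es, ref, tolerance = 1e-10)
  }
})

test_that("permutation p-values hit the documented bounds", {
  set.seed(66)
  ids <- sprintf("G%03d", 1:200)
  scores <- sort(abs(rnorm(200, sd = 2)), decreasing = TRUE)
  r <- ranked_from(ids, scores)
  top <- gsea_permutation(r, ids[1:10], P = 200, seed = 3)
  expect_equal(top$nominal_p, 1 / 201)
  expect_gt(top$nes, 1)

  # zero-weight prefix set: every running-sum value is 0, so ES = 0 and,
  # since no null magnitude can be beaten, p = 1
  flat <- ranked_from(ids, rep(0, 200))
  zero <- gsea_permutation(flat, flat$protein_id[1:16], P = 50, seed = 3)
  expect_identical(zero$es, 0)
  expect_identical(zero$nominal_p, 1)
})

test_that("leading edge matches a brute-force peak scan", {
  ids <- sprintf("G%02d", 1:12)
  r <- ranked_from(ids, 12:1)
  one <- enrichment_score(r, "G01")
  expect_identical(enriched_component(r, "G01", one), "G01")

  # all members early: positive peak at the last member, all included
  setA <- c("G01", "G02", "G03")
  esA <- enrichment_score(r, setA)
  expect_identical(enriched_component(r, setA, esA), setA)

  set.seed(67)
  for (i in 1:100) {
    n <- 15
    idsr <- sprintf("H%02d", 1:n)
    sc <- sort(abs(rnorm(n)), decreasing = TRUE)
    hits <- sort(sample(n, 4))
    rr <- ranked_from(idsr, sc)
    es <- enrichment_score(rr, idsr[hits])
    comp <- enriched_component(rr, idsr[hits], es)
    # oracle from the brute running sum
    want <- brute_enrichment_score(sc, seq_len(n) %in% hits, 1)
    if (want$es >= 0) {
      expect_identical(comp, idsr[hits[hits <= want$peak_index]])
    } else {
      expect_identical(comp, idsr[hits[hits >= want$peak_index]])
    }
  }
})

test_that("collection runs skip tiny sets and flag significance", {
  set.seed(68)
  ids <- sprintf("G%03d", 1:100)
  r <- ranked_from(ids, sort(abs(rnorm(100)), decreasing = TRUE))
  coll <- list(big = ids[1:10], tiny = ids[1:2], off = c("zz1", "zz2", "zz3"))
  expect_warning(res <- run_gsea_collection(r, coll, P = 50, seed = 1),
                 "skipping")
  expect_identical(res$set, "big")
  expect_identical(res$significant, res$nominal_p < 0.05)
  expect_true(all(res$component[[1]] %in% coll$big))
})
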