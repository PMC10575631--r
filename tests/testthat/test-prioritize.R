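# Frequency across enriched components, percentile selection, fold change,
# the filter cascade, and disease over-representation.

gsea_stub <- function(components, significant) {
  out <- data.frame(set = sprintf("S%d", seq_along(components)),
                    size = lengths(components),
                    n_hits = lengths(components),
                    es = 0.5, nes = 1, nominal_p = ifelse(significant, 0.01, 0.5),
                    significant = significant, stringsAsFactors = FALSE)
  out$component <- components
  class(out) <- c("gsea_result", class(out))
  out
}

test_that("frequencies count significant components only", {
  r <- gsea_stub(list(c("A", "B"), c("B", "C"), c("B")), c(TRUE, TRUE, TRUE))
  ft <- frequency_table(r)
  expect_identical(ft$frequency[match(c("B", "A", "C"), ft$protein_id)],
                   c(3L, 1L, 1L))

  one <- frequency_table(gsea_stub(list(c("A", "B", "C")), TRUE))
  expect_true(all(one$frequency == 1L))

  none <- frequency_table(gsea_stub(list(c("A", "B")), FALSE))
  expect_identical(nrow(none), 0L)
})

test_that("frequency pooling matches a nested-loop count across collections", {
  set.seed(71)
  u <- sprintf("P%03d", 1:40)
  results <- lapply(1:3, function(i) {
    comps <- lapply(1:6, function(j) sample(u, sample(3:10, 1)))
    gsea_stub(comps, runif(6) < 0.5)
  })
  ft <- frequency_table(results)
  # brute-force nested loop
  want <- integer(0)
  for (r in results) for (i in seq_len(nrow(r))) {
    if (r$significant[i]) for (p in r$component[[i]]) {
      want[p] <- if (is.na(want[p])) 1L else want[p] + 1L
    }
  }
  expect_setequal(ft$protein_id, names(want))
  expect_identical(ft$frequency, unname(want[ft$protein_id]))
})

test_that("percentile selection uses nearest-rank with inclusive ties", {
  ft <- data.frame(protein_id = sprintf("P%03d", 1:100), frequency = 1:100)
  sel <- percentile_select(ft, 90)
  expect_length(sel, 11)  # threshold = 90th smallest = 90; 90..100 pass

  same <- data.frame(protein_id = c("A", "B", "C"), frequency = c(4L, 4L, 4L))
  expect_setequal(percentile_select(same, 90), c("A", "B", "C"))

  single <- data.frame(protein_id = "A", frequency = 7L)
  expect_identical(percentile_select(single, 90), "A")

  # monotone: raising the percentile never adds proteins
  set.seed(72)
  ft2 <- data.frame(protein_id = sprintf("P%03d", 1:50),
                    frequency = rpois(50, 4))
  for (p in c(50, 75, 90)) {
    expect_true(all(percentile_select(ft2, p + 9) %in%
                      percentile_select(ft2, p)))
  }
  expect_error(percentile_select(ft, 0), "percentile")
  expect_error(percentile_select(ft, 100), "percentile")
})

test_that("fold change follows the signed-ratio convention", {
  m <- rbind(equal = c(4, 4, 4, 4), up3 = c(2, 2, 6, 6),
             down3 = c(6, 6, 2, 2))
  colnames(m) <- sprintf("S%02d", 1:4)
  design <- data.frame(sample_id = colnames(m),
                       condition = rep(c("healthy", "patient1"), each = 2))
  fc <- fold_change(m, design, c("healthy", "patient1"))
  expect_equal(unname(fc["equal"]), 1)
  expect_equal(unname(fc["up3"]), 3)    # boundary: retained under >= 3
  expect_equal(unname(fc["down3"]), -3) # boundary: retained under <= -3
})

test_that("the filter cascade enforces all three thresholds", {
  ft <- data.frame(protein_id = c("hi_all", "few_spectra", "small_fc"),
                   frequency = c(9L, 9L, 9L))
  fc <- c(hi_all = 4, few_spectra = 4, small_fc = 2.9)
  sp <- c(hi_all = 40, few_spectra = 9, small_fc = 50)
  cand <- filter_cascade(ft, fc, sp)
  expect_identical(cand$protein_id[cand$candidate], "hi_all")
  expect_false(cand$passed_spectra[cand$protein_id == "few_spectra"])
  expect_false(cand$passed_fc[cand$protein_id == "small_fc"])
})

test_that("filters commute and boundaries are inclusive", {
  set.seed(73)
  n <- 60
  ft <- data.frame(protein_id = sprintf("P%03d", 1:n),
                   frequency = rpois(n, 6))
  fc <- setNames(c(3, -3, runif(n - 2, -6, 6)), ft$protein_id)
  sp <- setNames(c(10, 10, rpois(n - 2, 15)), ft$protein_id)
  cand <- filter_cascade(ft, fc, sp, percentile = 50)
  # conjunction, regardless of filter order: recompute each flag directly
  sel <- percentile_select(ft, 50)
  want <- ft$protein_id %in% sel & abs(fc[ft$protein_id]) >= 3 &
    sp[ft$protein_id] >= 10
  expect_identical(cand$candidate, unname(want))
  # direction is consistent with the fold-change sign
  expect_true(all((cand$fold_change >= 0) == (cand$direction == "up")))
})

test_that("over-representation p equals the closed-form tail", {
  u <- sprintf("P%03d", 1:100)
  lib <- list(term1 = u[1:20], none = u[90:100])
  res <- term_overrepresentation(u[11:20], lib, u)
  # overlap 10 of 10 from a 20-member term
  expect_equal(res$p[res$term == "term1"],
               brute_hyper_tail(10, 20, 100, 10), tolerance = 1e-12)

  # disjoint term: p = 1
  far <- term_overrepresentation(u[1:10], list(t = u[50:60]), u)
  expect_equal(far$p, 1)

  # query inside a term that covers the universe: no enrichment possible
  all_term <- term_overrepresentation(u[1:10], list(t = u), u)
  expect_equal(all_term$p, 1)

  # the documented example table
  res2 <- term_overrepresentation(u[1:10], list(t = u[1:20]), u)
  # with overlap 5: use a constructed query
  q <- c(u[1:5], u[51:55])
  res3 <- term_overrepresentation(q, list(t = u[1:20]), u)
  expect_equal(res3$p, brute_hyper_tail(5, 20, 100, 10), tolerance = 1e-12)

  expect_error(term_overrepresentation(character(0), lib, u), "empty")
  expect_error(term_overrepresentation("zzz", lib, u), "universe")
})

test_that("disease term counts match a brute-force membership scan", {
  u <- sprintf("P%03d", 1:50)
  cand <- u[1:6]
  libs <- list(
    libA = list(strong = c(cand[1:3], u[40:45]),  # enriched in candidates
                broad = u),                       # never significant
    libB = list(other = c(cand[1:2], cand[5], u[30:34]))
  )
  df <- disease_frequency(cand, libs, u)
  # brute-force: which terms are significant, then scan membership
  sig <- list()
  for (ln in names(libs)) for (tn in names(libs[[ln]])) {
    members <- intersect(libs[[ln]][[tn]], u)
    k <- length(intersect(cand, members))
    p <- brute_hyper_tail(k, length(members), length(u), length(cand))
    if (p < 0.05) sig[[paste0(ln, "::", tn)]] <- members
  }
  for (i in seq_along(cand)) {
    want <- sum(vapply(sig, function(m) cand[i] %in% m, logical(1)))
    expect_identical(df$proteins$n_terms[i], as.integer(want))
  }

  # no significant terms: all counts zero
  null_libs <- list(libC = list(t = u[30:45]))
  df0 <- disease_frequency(cand, null_libs, u)
  expect_true(all(df0$proteins$n_terms == 0L))
})
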